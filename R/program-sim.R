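#' Simulate a multi-cycle clonal breeding program
#'
#' End-to-end generator for the structure the cross-cycle validation analysis
#' assumes: an elite pool cycled with a partial circular mating design (4-5
#' crosses per parent), within-family truncation selection on total merit,
#' yearly replicated RCBD trials, and carry-over of a control cultivar plus
#' top-merit genotypes into later trials — the "common genotypes" that link
#' training and testing populations. Trials are labelled `T2, T4, ...` in
#' cycle order.
#'
#' @param n_founders Founder pool size.
#' @param n_markers Markers on the map.
#' @param n_lg Linkage groups.
#' @param total_length_cm Total map length (cM).
#' @param n_cycles Number of yearly trials to generate.
#' @param n_parents Parents selected per cycle.
#' @param crosses_per_parent Crosses each parent enters (4 or 5).
#' @param n_offspring Seedlings raised per cross before selection (no claimed
#'   fidelity to any real program; exposed as a knob).
#' @param n_select_per_family Seedlings advanced per cross.
#' @param n_carryover Genotypes carried over into the next trial (includes the
#'   control).
#' @param pi_zero,h2,ry,n_traits,trait_names Trait-architecture settings; see
#'   [simulate_trait_architecture()].
#' @param n_reps,plots_per_bed,spatial,missing_rate Trial settings; see
#'   [simulate_trial()].
#' @param maf_range Founder allele-frequency range.
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @return A `breeding_program` list: `phenotypes` (long tibble over all
#'   trials), `genotypes` (named list of per-trial [geno_matrix()]),
#'   `rosters` (named list of id vectors), `truth` (per-trial true BVs),
#'   `pedigree`, `population` (cumulative `breeding_pop`), `architecture`,
#'   `control_id`, `trials` (labels in order).
#' @export
#' @examples
#' prog <- simulate_breeding_program(n_founders = 20, n_markers = 100,
#'   n_lg = 4, n_cycles = 2, n_parents = 10, n_offspring = 4,
#'   n_select_per_family = 2, n_carryover = 5, n_traits = 1, seed = 1)
simulate_breeding_program <- function(n_founders = 60, n_markers = 2000,
                                      n_lg = 28, total_length_cm = 1729.5,
                                      n_cycles = 5, n_parents = 35,
                                      crosses_per_parent = 4, n_offspring = 8,
                                      n_select_per_family = 3,
                                      n_carryover = 40,
                                      pi_zero = 0.98, h2 = c(0.2, 0.35, 0.55),
                                      ry = 0.95, n_traits = length(h2),
                                      trait_names = NULL,
                                      n_reps = 5, plots_per_bed = 7,
                                      spatial = "none", missing_rate = 0.01,
                                      maf_range = c(0.1, 0.5), seed = 1) {
  map <- make_genetic_map(n_markers, n_lg = n_lg,
                          total_length_cm = total_length_cm,
                          seed = derive_seed(seed, "map"))
  founders <- make_founders(n_founders, map, maf_range = maf_range,
                            seed = derive_seed(seed, "founders"))
  arch <- simulate_trait_architecture(map, pi_zero = pi_zero, h2_target = h2,
                                      ry_target = ry, n_traits = n_traits,
                                      trait_names = trait_names,
                                      seed = derive_seed(seed, "architecture"))
  control_id <- founders$pedigree$id[1]
  cumulative <- founders
  trials <- sprintf("T%d", 2L * seq_len(n_cycles))
  roster_prev <- NULL
  rosters <- list(); phenos <- list(); genos <- list(); truths <- list()

  merit_of <- function(ids) {
    g <- pop_dosages(cumulative, ids) %*% arch$effects
    sds <- apply(g, 2, stats::sd); sds[!is.finite(sds) | sds == 0] <- 1
    rowSums(scale(g, center = TRUE, scale = sds))
  }

  for (t in seq_len(n_cycles)) {
    pool <- if (is.null(roster_prev)) founders$pedigree$id else roster_prev
    stopifnot(length(pool) >= n_parents)
    parents <- pool[order(merit_of(pool), decreasing = TRUE)][seq_len(n_parents)]
    plan <- partial_circular_mating(parents, crosses_per_parent, n_offspring)
    carry <- if (is.null(roster_prev)) {
      # first trial: control plus established cultivars from the founder pool
      unique(c(control_id,
               founders$pedigree$id[seq_len(min(n_carryover, n_founders))]))
    } else {
      top <- roster_prev[order(merit_of(roster_prev), decreasing = TRUE)]
      unique(c(control_id, utils::head(top, n_carryover - 1L)))
    }
    newpop <- advance_cycle(cumulative, plan,
                            n_select_per_family = n_select_per_family,
                            carryover_ids = carry, architecture = arch,
                            seed = derive_seed(seed, paste0("cycle", t)))
    new_ids <- setdiff(newpop$pedigree$id, cumulative$pedigree$id)
    add <- pop_subset(newpop, new_ids)
    cumulative <- new_breeding_pop(
      dplyr::bind_rows(cumulative$pedigree, add$pedigree),
      rbind(cumulative$H1, add$H1), rbind(cumulative$H2, add$H2), map)
    roster <- newpop$pedigree$id
    sim <- simulate_trial(pop_subset(cumulative, roster), arch, trials[t],
                          n_reps = n_reps, plots_per_bed = plots_per_bed,
                          control_id = control_id, spatial = spatial,
                          missing_rate = missing_rate,
                          seed = derive_seed(seed, paste0("trial", t)))
    rosters[[trials[t]]] <- roster
    phenos[[trials[t]]] <- sim$trial
    genos[[trials[t]]] <- sim$genotypes
    truths[[trials[t]]] <- dplyr::mutate(sim$truth, trial = trials[t],
                                         .before = 1)
    roster_prev <- roster
  }

  structure(list(phenotypes = dplyr::bind_rows(phenos),
                 genotypes = genos,
                 rosters = rosters,
                 truth = dplyr::bind_rows(truths),
                 pedigree = cumulative$pedigree,
                 population = cumulative,
                 architecture = arch,
                 control_id = control_id,
                 trials = trials,
                 seed = seed),
            class = "breeding_program")
}

#' @exportS3Method base::print
print.breeding_program <- function(x, ...) {
  sizes <- vapply(x$rosters, length, integer(1))
  cat(sprintf("<breeding_program> %d trials (%s), roster sizes %s, %d markers\n",
              length(x$trials), paste(x$trials, collapse = ", "),
              paste(sizes, collapse = "/"), nrow(x$population$map)))
  invisible(x)
}

#' Write all program outputs to a directory of plain-text files
#'
#' Emits the simulator's external formats: per-trial VCF and dosage-matrix
#' genotypes, the 4-column map, long-format phenotype CSV and a 3-column
#' pedigree CSV.
#'
#' @param prog A [simulate_breeding_program()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_breeding_program <- function(prog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(prog$phenotypes, file.path(dir, "phenotypes.csv"))
  readr::write_csv(prog$pedigree[, c("id", "dam", "sire")],
                   file.path(dir, "pedigree.csv"))
  write_genetic_map(prog$population$map, file.path(dir, "map.tsv"))
  for (tr in prog$trials) {
    write_genotypes(prog$genotypes[[tr]],
                    file.path(dir, paste0("geno_", tr, ".vcf")), "vcf")
    write_genotypes(prog$genotypes[[tr]],
                    file.path(dir, paste0("geno_", tr, ".tsv")), "matrix")
  }
  invisible(dir)
}
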