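#' Breeding population objects
#'
#' A `breeding_pop` bundles a pedigree (id, dam, sire, cycle of origin) with
#' the two phased haplotypes of every individual and the genetic map. It is
#' the substrate for gene-dropping across breeding cycles: haplotypes are 0/1
#' matrices (individuals x markers) and dosages are their sum.
#'
#' @param pedigree Tibble with columns `id`, `dam`, `sire`, `cycle_born`.
#' @param H1,H2 Integer 0/1 matrices, individuals x markers, rownames = ids.
#' @param map A [as_genetic_map()] object with one row per haplotype column.
#' @return An object of class `breeding_pop`.
#' @export
new_breeding_pop <- function(pedigree, H1, H2, map) {
  assert_that(nrow(H1) == nrow(pedigree) && nrow(H2) == nrow(pedigree),
              "haplotype rows must match pedigree")
  assert_that(ncol(H1) == nrow(map) && ncol(H2) == nrow(map),
              "haplotype length must equal map length")
  assert_that(!anyDuplicated(pedigree$id), "individual ids must be unique")
  assert_that(all(H1 %in% c(0L, 1L)) && all(H2 %in% c(0L, 1L)),
              "haplotype alleles must be binary")
  rownames(H1) <- rownames(H2) <- pedigree$id
  colnames(H1) <- colnames(H2) <- map$marker_id
  structure(list(pedigree = as_tibble(pedigree), H1 = H1, H2 = H2, map = map),
            class = "breeding_pop")
}

#' @exportS3Method base::print
print.breeding_pop <- function(x, ...) {
  cat(sprintf("<breeding_pop> %d individuals x %d markers, cycles %s\n",
              nrow(x$pedigree), nrow(x$map),
              paste(sort(unique(x$pedigree$cycle_born)), collapse = ",")))
  invisible(x)
}

#' Allele dosages of a population
#'
#' @param pop A `breeding_pop`.
#' @param ids Optional subset of individual ids (kept in the given order).
#' @return Integer matrix of 0/1/2 dosages, individuals x markers.
#' @export
pop_dosages <- function(pop, ids = NULL) {
  d <- pop$H1 + pop$H2
  if (!is.null(ids)) {
    missing_ids <- setdiff(ids, rownames(d))
    assert_that(length(missing_ids) == 0L,
                paste("unknown individuals:", paste(utils::head(missing_ids, 5), collapse = ", ")))
    d <- d[ids, , drop = FALSE]
  }
  d
}

#' Subset a population by individual id
#' @param pop A `breeding_pop`.
#' @param ids Ids to keep, in order.
#' @return A `breeding_pop` containing only `ids`.
#' @export
pop_subset <- function(pop, ids) {
  idx <- match(ids, pop$pedigree$id)
  assert_that(!anyNA(idx), "unknown individual id in subset")
  new_breeding_pop(pop$pedigree[idx, ], pop$H1[idx, , drop = FALSE],
                   pop$H2[idx, , drop = FALSE], pop$map)
}

#' Simulate founder individuals in linkage equilibrium
#'
#' Draws one allele frequency per marker uniformly within `maf_range` and then
#' samples founder haplotypes as independent Bernoulli draws, i.e. founders
#' start in linkage equilibrium; LD subsequently accrues purely from family
#' structure during cycling, mirroring populations where most observed LD is
#' relatedness-driven.
#'
#' @param n_founders Number of founders (>= 2).
#' @param map A [as_genetic_map()] object.
#' @param maf_range Length-2 interval within (0, 0.5] for founder minor-allele
#'   frequencies.
#' @param seed Integer seed; identical seeds give identical founders.
#' @return A `breeding_pop` of founders (cycle 0, no parents).
#' @export
#' @examples
#' map <- make_genetic_map(50, n_lg = 2, total_length_cm = 200, seed = 1)
#' founders <- make_founders(20, map, seed = 42)
make_founders <- function(n_founders, map, maf_range = c(0.1, 0.5), seed = NULL) {
  assert_that(inherits(map, "genetic_map") && nrow(map) >= 1L,
              "founders need a non-empty genetic map")
  assert_that(n_founders >= 2, "need at least 2 founders")
  assert_that(length(maf_range) == 2L && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
                maf_range[1] <= maf_range[2],
              "maf_range must lie within (0, 0.5]")
  m <- nrow(map)
  with_seed(seed, {
    p <- stats::runif(m, maf_range[1], maf_range[2])
    H1 <- matrix(stats::rbinom(n_founders * m, 1L, rep(p, each = n_founders)),
                 n_founders, m)
    H2 <- matrix(stats::rbinom(n_founders * m, 1L, rep(p, each = n_founders)),
                 n_founders, m)
  })
  ped <- tibble(id = sprintf("F%03d", seq_len(n_founders)),
                dam = NA_character_, sire = NA_character_, cycle_born = 0L)
  pop <- new_breeding_pop(ped, H1, H2, map)
  attr(pop, "founder_freqs") <- p
  pop
}

#' Partial circular mating design
#'
#' Each parent along an ordered list is paired with its neighbours so that
#' every parent enters exactly `crosses_per_parent` crosses and the pairs fill
#' an off-diagonal band of the cross matrix. For an even number of crosses per
#' parent the band uses offsets `1..k/2`; an odd number adds the diametric
#' pairing, which requires an even number of parents.
#'
#' @param parent_ids Ordered character vector of parent ids.
#' @param crosses_per_parent Crosses each parent enters (4 or 5 in practice).
#' @param n_offspring Seedlings to raise per cross.
#' @return A `cross_plan` tibble with columns `dam`, `sire`, `n_offspring`;
#'   `n_parents * crosses_per_parent / 2` rows, no self-crosses, no duplicate
#'   pairs.
#' @export
#' @examples
#' partial_circular_mating(sprintf("P%02d", 1:10), 4)
partial_circular_mating <- function(parent_ids, crosses_per_parent = 4,
                                    n_offspring = 10) {
  n <- length(parent_ids)
  k <- as.integer(crosses_per_parent)
  assert_that(!anyDuplicated(parent_ids), "parent ids must be unique")
  assert_that(n >= k + 1L,
              sprintf("need at least %d parents for %d crosses per parent", k + 1L, k))
  offsets <- seq_len(k %/% 2L)
  dam <- integer(0); sire <- integer(0)
  for (j in offsets) {
    dam <- c(dam, seq_len(n))
    sire <- c(sire, (seq_len(n) - 1L + j) %% n + 1L)
  }
  if (k %% 2L == 1L) {
    assert_that(n %% 2L == 0L,
                "an odd number of crosses per parent requires an even number of parents")
    half <- seq_len(n %/% 2L)
    dam <- c(dam, half)
    sire <- c(sire, half + n %/% 2L)
  }
  # drop duplicate unordered pairs (arises when the band wraps, e.g. n = k + 1)
  key <- paste(pmin(dam, sire), pmax(dam, sire))
  keep <- !duplicated(key)
  plan <- tibble(dam = parent_ids[dam[keep]], sire = parent_ids[sire[keep]],
                 n_offspring = as.integer(n_offspring))
  assert_that(all(plan$dam != plan$sire), "self-cross produced; check parent list")
  class(plan) <- c("cross_plan", class(plan))
  plan
}

# One gamete per requested parent-row on one chromosome: Poisson crossover
# count with mean = map length in Morgans, positions uniform on the cM scale,
# no interference (Haldane). Returns a 0/1 matrix gametes x markers(lg).
meiose_lg <- function(H1, H2, pos_cm, rows) {
  len_morgan <- (max(pos_cm) - min(pos_cm)) / 100
  ngam <- length(rows)
  out <- matrix(0L, ngam, length(pos_cm))
  n_xo <- stats::rpois(ngam, len_morgan)
  start <- stats::rbinom(ngam, 1L, 0.5)
  for (g in seq_len(ngam)) {
    if (n_xo[g] == 0L) {
      phase <- rep(start[g], length(pos_cm))
    } else {
      xo <- sort(stats::runif(n_xo[g], min(pos_cm), max(pos_cm)))
      phase <- (start[g] + findInterval(pos_cm, xo)) %% 2L
    }
    i <- rows[g]
    out[g, ] <- ifelse(phase == 0L, H1[i, ], H2[i, ])
  }
  out
}

# Gametes for a vector of parent ids (with repetition) across the whole map.
make_gametes <- function(pop, parent_ids) {
  rows <- match(parent_ids, pop$pedigree$id)
  assert_that(!anyNA(rows),
              paste("unknown parent id:",
                    paste(utils::head(unique(parent_ids[is.na(rows)]), 3), collapse = ", ")))
  idx <- lg_index(pop$map)
  gam <- matrix(0L, length(rows), nrow(pop$map))
  for (cols in idx) {
    gam[, cols] <- meiose_lg(pop$H1[, cols, drop = FALSE],
                             pop$H2[, cols, drop = FALSE],
                             pop$map$pos_cm[cols], rows)
  }
  gam
}

#' Advance a breeding population by one cycle
#'
#' Produces offspring for every cross in the plan by meiosis with Haldane
#' recombination, optionally applies within-family truncation selection on a
#' simulated total-merit value (the sum of standardised true breeding values
#' across traits), and carries listed individuals over unchanged into the new
#' roster — these carry-overs become the "common genotypes" shared between
#' successive trials.
#'
#' @param pop A `breeding_pop` containing all plan parents and carry-overs.
#' @param cross_plan A [partial_circular_mating()] plan (columns `dam`, `sire`,
#'   `n_offspring`).
#' @param n_select_per_family Offspring retained per cross after selection.
#' @param carryover_ids Ids copied unchanged into the new roster.
#' @param architecture Optional [simulate_trait_architecture()] object; when
#'   supplied, within-family selection is truncation on total merit, otherwise
#'   retained offspring are a random subset.
#' @param seed Integer seed.
#' @return A `breeding_pop` holding the selected offspring (cycle =
#'   max(parent cycles) + 1) followed by the carry-over individuals.
#' @export
advance_cycle <- function(pop, cross_plan, n_select_per_family = 2,
                          carryover_ids = character(), architecture = NULL,
                          seed = NULL) {
  assert_that(all(c(cross_plan$dam, cross_plan$sire) %in% pop$pedigree$id),
              "unknown parent id in cross plan")
  assert_that(all(carryover_ids %in% pop$pedigree$id),
              "unknown carry-over id")
  n_off <- pmax(cross_plan$n_offspring, n_select_per_family)
  dam_rep <- rep(cross_plan$dam, n_off)
  sire_rep <- rep(cross_plan$sire, n_off)
  fam_rep <- rep(seq_len(nrow(cross_plan)), n_off)
  cycle <- max(pop$pedigree$cycle_born[match(c(cross_plan$dam, cross_plan$sire),
                                             pop$pedigree$id)]) + 1L
  with_seed(seed, {
    H1 <- make_gametes(pop, dam_rep)
    H2 <- make_gametes(pop, sire_rep)
    keep <- unlist(lapply(split(seq_along(fam_rep), fam_rep), function(ix) {
      k <- min(n_select_per_family, length(ix))
      if (is.null(architecture)) {
        sample(ix, k)
      } else {
        g <- (H1[ix, , drop = FALSE] + H2[ix, , drop = FALSE]) %*%
          architecture$effects
        sds <- apply(g, 2, stats::sd)
        sds[!is.finite(sds) | sds == 0] <- 1
        merit <- rowSums(scale(g, center = TRUE, scale = sds))
        merit[!is.finite(merit)] <- 0
        ix[order(merit, decreasing = TRUE)[seq_len(k)]]
      }
    }), use.names = FALSE)
  })
  keep <- sort(keep)
  ped <- tibble(id = sprintf("C%d_%04d", cycle, seq_along(keep)),
                dam = dam_rep[keep], sire = sire_rep[keep],
                cycle_born = cycle)
  newpop <- new_breeding_pop(ped, H1[keep, , drop = FALSE],
                             H2[keep, , drop = FALSE], pop$map)
  if (length(carryover_ids)) {
    co <- pop_subset(pop, carryover_ids)
    newpop <- new_breeding_pop(dplyr::bind_rows(newpop$pedigree, co$pedigree),
                               rbind(newpop$H1, co$H1),
                               rbind(newpop$H2, co$H2), pop$map)
  }
  newpop
}
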