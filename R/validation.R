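#' Build cross-cycle training/testing scenario compositions
#'
#' Reproduces the independent-validation design: with trials in cycle order
#' and a target testing trial, forward compositions grow the training set
#' from the earliest cycle (`T2`, `T24`, `T246`, ...) and backward
#' compositions grow it from the most recent cycle before the test
#' (`T8`, `T86`, `T864`, ...). Labels concatenate the trial numbers. Common
#' genotypes are handled at evaluation time: with `include_common = FALSE`
#' the testing roster drops every individual present in any training trial of
#' the composition (optionally also dropping them from the training side).
#'
#' @param trials Ordered character vector of trial labels (e.g. `T2 ... T10`).
#' @param target_tst The testing trial; must not be inside the training set.
#' @param direction `"forward"` or `"backward"`.
#' @param include_common Logical flag recorded on each composition.
#' @return A tibble with columns `label`, `trn_trials` (list-column),
#'   `tst_trial`, `direction`, `include_common`.
#' @export
#' @examples
#' assign_scenarios(paste0("T", seq(2, 10, 2)), "T10", "forward")
assign_scenarios <- function(trials, target_tst,
                             direction = c("forward", "backward"),
                             include_common = TRUE) {
  direction <- match.arg(direction)
  assert_that(target_tst %in% trials, "target_tst must be one of trials")
  pool <- trials[seq_len(match(target_tst, trials) - 1L)]
  assert_that(length(pool) >= 1, "no trials precede the testing trial")
  assert_that(!target_tst %in% pool, "testing trial cannot be in the training set")
  ordered_pool <- if (direction == "forward") pool else rev(pool)
  comps <- lapply(seq_along(ordered_pool), function(k) ordered_pool[seq_len(k)])
  tibble(
    label = vapply(comps, function(x) paste0("T", paste(gsub("^T", "", x), collapse = "")),
                   character(1)),
    trn_trials = comps,
    tst_trial = target_tst,
    direction = direction,
    include_common = include_common
  )
}

#' Average prediction sets across training cycles
#'
#' Equal-weight mean of GEBVs per individual over the sets in which that
#' individual appears; provenance becomes the union of the inputs'.
#'
#' @param sets List of [prediction_set()] objects sharing a trait.
#' @return A single [prediction_set()].
#' @export
average_predictions <- function(sets) {
  if (inherits(sets, "prediction_set")) sets <- list(sets)
  assert_that(length(sets) >= 1, "no prediction sets supplied")
  traits <- unique(unlist(lapply(sets, function(s) unique(s$trait))))
  assert_that(length(traits) == 1L, "all sets must share a single trait")
  ids <- Reduce(union, lapply(sets, function(s) s$individual_id))
  assert_that(length(Reduce(intersect, lapply(sets, function(s) s$individual_id))) > 0,
              "prediction sets share no individuals")
  stacked <- dplyr::bind_rows(lapply(sets, as_tibble))
  avg <- dplyr::summarise(dplyr::group_by(stacked, .data$individual_id),
                          gebv = mean(.data$gebv), .groups = "drop")
  avg <- avg[match(ids, avg$individual_id), ]
  prov <- unique(unlist(lapply(sets, attr, "training_trials")))
  prediction_set(tibble(individual_id = avg$individual_id, trait = traits,
                        gebv = avg$gebv),
                 training_trials = prov,
                 scenario = attr(sets[[1]], "scenario") %||% "include_common")
}

#' Predictive ability of a prediction set
#'
#' Pearson correlation between predicted breeding values and observed
#' adjusted phenotypes over the matched individuals.
#'
#' @param pred A [prediction_set()].
#' @param observed A BLUE table slice for the testing trial (columns
#'   `genotype_id`, `blue`).
#' @param trn_label,tst_trial,scenario Labels recorded in the result.
#' @return A one-row `validation result` tibble: `trn_label`, `tst_trial`,
#'   `trait`, `scenario`, `pa`, `n_tst` (and `reason` when PA is undefined
#'   because a vector has zero variance).
#' @export
predictive_ability <- function(pred, observed, trn_label = NULL,
                               tst_trial = NA_character_, scenario = NULL) {
  assert_that(all(c("genotype_id", "blue") %in% names(observed)),
              "observed must have columns genotype_id, blue")
  ids <- intersect(pred$individual_id, observed$genotype_id)
  assert_that(length(ids) >= 3, "need at least 3 matched individuals")
  g <- pred$gebv[match(ids, pred$individual_id)]
  o <- observed$blue[match(ids, observed$genotype_id)]
  trn_label <- trn_label %||%
    paste0("T", paste(gsub("^T", "", attr(pred, "training_trials")), collapse = ""))
  scenario <- scenario %||% attr(pred, "scenario") %||% NA_character_
  if (stats::sd(g) == 0 || stats::sd(o) == 0) {
    return(tibble(trn_label = trn_label, tst_trial = tst_trial,
                  trait = pred$trait[1], scenario = scenario,
                  pa = NA_real_, n_tst = length(ids),
                  reason = "zero variance in predictions or observations"))
  }
  tibble(trn_label = trn_label, tst_trial = tst_trial, trait = pred$trait[1],
         scenario = scenario, pa = stats::cor(g, o), n_tst = length(ids),
         reason = NA_character_)
}

#' Trial incidence summary
#'
#' The incidence-matrix population-structure summary of a set of yearly trials:
#' above the diagonal, counts of common genotypes between trial pairs; on the
#' diagonal, the number of full-sib families (distinct dam/sire pairs among
#' entries first tested in that trial); below the diagonal, the number of
#' parents shared between the family sets of the two trials.
#'
#' @param trial_rosters Named list of genotype-id vectors, in trial order.
#' @param pedigree Tibble with columns `id`, `dam`, `sire` covering the
#'   rosters (unknown parents as `NA`).
#' @return An `incidence_summary`: `matrix` (as described), `n_per_trial`,
#'   `trials`.
#' @export
incidence_summary <- function(trial_rosters, pedigree) {
  trials <- names(trial_rosters)
  assert_that(!is.null(trials) && all(nzchar(trials)),
              "trial_rosters must be a named list")
  all_ids <- unique(unlist(trial_rosters))
  assert_that(all(all_ids %in% pedigree$id),
              "pedigree must cover every rostered individual")
  ped <- pedigree[match(all_ids, pedigree$id), ]
  if (anyNA(ped$dam) || anyNA(ped$sire)) {
    warn("individuals with unknown parents counted as parentless (no family)")
  }
  t_n <- length(trials)
  # entries first tested in trial i (carry-overs belong to their first trial)
  first_seen <- rep(NA_integer_, length(all_ids))
  names(first_seen) <- all_ids
  for (i in rev(seq_len(t_n))) first_seen[trial_rosters[[i]]] <- i
  fam_sets <- lapply(seq_len(t_n), function(i) {
    own <- trial_rosters[[i]][first_seen[trial_rosters[[i]]] == i]
    pp <- pedigree[match(own, pedigree$id), ]
    pp <- pp[!is.na(pp$dam) & !is.na(pp$sire), ]
    unique(paste(pmin(pp$dam, pp$sire), pmax(pp$dam, pp$sire), sep = "|"))
  })
  parent_sets <- lapply(fam_sets, function(f) unique(unlist(strsplit(f, "|", fixed = TRUE))))
  M <- matrix(0L, t_n, t_n, dimnames = list(trials, trials))
  for (i in seq_len(t_n)) {
    M[i, i] <- length(fam_sets[[i]])
    if (i < t_n) for (j in seq((i + 1L), t_n)) {
      M[i, j] <- length(intersect(trial_rosters[[i]], trial_rosters[[j]]))
      M[j, i] <- length(intersect(parent_sets[[i]], parent_sets[[j]]))
    }
  }
  structure(list(matrix = M,
                 n_per_trial = vapply(trial_rosters, length, integer(1)),
                 trials = trials),
            class = "incidence_summary")
}

#' Derived per-trial averages from an incidence matrix
#'
#' For each trial, the mean over the other trials of (a) pairwise
#' common-genotype counts (upper triangle, read symmetrically) and (b)
#' pairwise shared-parent counts (lower triangle), rounded half away from
#' zero to integers.
#'
#' @param x An [incidence_summary()] or a bare square matrix laid out the
#'   same way.
#' @return A tibble: `trial`, `avg_common_genotypes`, `avg_shared_parents`.
#' @export
incidence_averages <- function(x) {
  M <- if (inherits(x, "incidence_summary")) x$matrix else as.matrix(x)
  t_n <- nrow(M)
  trials <- rownames(M) %||% paste0("T", seq_len(t_n))
  common <- matrix(0, t_n, t_n); parents <- matrix(0, t_n, t_n)
  common[upper.tri(common)] <- M[upper.tri(M)]
  common <- common + t(common)
  parents[lower.tri(parents)] <- M[lower.tri(M)]
  parents <- parents + t(parents)
  tibble(trial = trials,
         avg_common_genotypes = as.integer(round_half_away(
           rowSums(common) / (t_n - 1))),
         avg_shared_parents = as.integer(round_half_away(
           rowSums(parents) / (t_n - 1))))
}

#' @exportS3Method base::print
print.incidence_summary <- function(x, ...) {
  cat("<incidence_summary> common genotypes above diagonal, families on,",
      "shared parents below\n")
  print(x$matrix)
  invisible(x)
}

#' Published five-trial incidence matrix
#'
#' The incidence matrix of a five-cycle elite strawberry breeding population
#' (trials T2-T10): counts of common genotypes tested among trials above the
#' diagonal, full-sib family counts on the diagonal, counts of common parents
#' of full-sib families below the diagonal, plus entries per trial.
#'
#' @return A list: `matrix` (5 x 5), `n_per_trial`.
#' @export
strawberry_trial_incidence <- function() {
  trials <- c("T2", "T4", "T6", "T8", "T10")
  M <- matrix(c(
    33, 37, 29, 28, 30,
    8, 30, 57, 40, 43,
    2, 7, 45, 88, 69,
    3, 1, 14, 43, 107,
    2, 3, 10, 13, 28), 5, 5, byrow = TRUE,
    dimnames = list(trials, trials))
  list(matrix = M,
       n_per_trial = stats::setNames(c(217L, 240L, 237L, 273L, 266L), trials))
}

#' Evaluate cross-cycle predictive ability scenarios
#'
#' Orchestrates the full independent-validation design on fitted single-trial
#' Bayes B predictions: for each scenario composition, averages the member
#' trials' prediction sets, applies the common-genotype filter to the testing
#' roster, and scores predictive ability against the testing trial's BLUEs.
#'
#' @param pred_by_trial Named list (by training trial) of [prediction_set()]
#'   objects covering the testing individuals, all one trait.
#' @param tst_blues BLUE slice of the testing trial (columns `genotype_id`,
#'   `blue`).
#' @param rosters Named list of trial rosters (ids), used to identify common
#'   genotypes.
#' @param scenarios An [assign_scenarios()] tibble.
#' @param drop_from_trn Also exclude testing individuals from the training
#'   side (informative only for refitting workflows; recorded, not refitted).
#' @return A validation-results tibble, one row per composition
#'   (class `cyclegp_validation` for [autoplot()]).
#' @export
evaluate_scenarios <- function(pred_by_trial, tst_blues, rosters, scenarios,
                               drop_from_trn = FALSE) {
  res <- purrr::pmap(scenarios, function(label, trn_trials, tst_trial,
                                         direction, include_common) {
    sets <- pred_by_trial[trn_trials]
    assert_that(!any(vapply(sets, is.null, logical(1))),
                paste("missing prediction set for", paste(trn_trials, collapse = ",")))
    avg <- average_predictions(unname(sets))
    tst_ids <- rosters[[tst_trial]]
    if (!include_common) {
      common <- intersect(tst_ids, unique(unlist(rosters[trn_trials])))
      tst_ids <- setdiff(tst_ids, common)
    }
    obs <- tst_blues[tst_blues$genotype_id %in% tst_ids, ]
    pa <- predictive_ability(avg, obs, trn_label = label,
                             tst_trial = tst_trial,
                             scenario = if (include_common) "include_common" else "exclude_common")
    pa$direction <- direction
    pa$n_trn_trials <- length(trn_trials)
    pa$trn_filtered <- drop_from_trn && !include_common
    pa
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("cyclegp_validation", class(out))
  out
}
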