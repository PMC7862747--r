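#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_pipeline()]. Unknown keys
#' in any section are rejected before any stage runs. Every stochastic stage
#' derives its own sub-seed from `master_seed`.
#'
#' @param master_seed Master seed for the whole run.
#' @param simulate Named list of [simulate_breeding_program()] overrides.
#' @param qc List with `maf_min`, `max_missing`.
#' @param adjust List with `models` (candidate subset of
#'   `c("base", "spatial_rc", "spatial_rc_ar1")`) and `center`.
#' @param train List of [bayesb_spec()] overrides (e.g. `n_iter`, `burn_in`,
#'   `n_chains`).
#' @param validate List with `tst_trial` (default: last simulated trial),
#'   `directions`, `include_common` (logical vector of scenarios to run).
#' @param ld List with `run` (logical), `trials` (labels or NULL = first and
#'   last), `max_pairs`.
#' @param ne List with `run`, `maf_threshold`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(master_seed = 1,
                            simulate = list(),
                            qc = list(),
                            adjust = list(),
                            train = list(),
                            validate = list(),
                            ld = list(),
                            ne = list()) {
  check_keys <- function(x, allowed, section) {
    bad <- setdiff(names(x), allowed)
    assert_that(length(bad) == 0,
                sprintf("unknown %s key(s): %s", section, paste(bad, collapse = ", ")))
    x
  }
  sim_allowed <- setdiff(names(formals(simulate_breeding_program)), "seed")
  cfg <- list(
    master_seed = as.integer(master_seed),
    simulate = check_keys(simulate, sim_allowed, "simulate"),
    qc = utils::modifyList(list(maf_min = 0.05, max_missing = 0.05),
                           check_keys(qc, c("maf_min", "max_missing"), "qc")),
    adjust = utils::modifyList(list(models = "base", center = "grand_mean"),
                               check_keys(adjust, c("models", "center"), "adjust")),
    train = check_keys(train, setdiff(names(formals(bayesb_spec)), "seed"), "train"),
    validate = utils::modifyList(
      list(tst_trial = NULL, directions = c("forward", "backward"),
           include_common = c(TRUE, FALSE)),
      check_keys(validate, c("tst_trial", "directions", "include_common"),
                 "validate")),
    ld = utils::modifyList(list(run = TRUE, trials = NULL, max_pairs = 20000),
                           check_keys(ld, c("run", "trials", "max_pairs"), "ld")),
    ne = utils::modifyList(list(run = TRUE, maf_threshold = 0.05),
                           check_keys(ne, c("run", "maf_threshold"), "ne")))
  assert_that(all(cfg$adjust$models %in% c("base", "spatial_rc", "spatial_rc_ar1")),
              "unknown adjust model tag")
  assert_that(all(cfg$validate$directions %in% c("forward", "backward")),
              "directions must be forward/backward")
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  s <- deparse(unclass(cfg))
  sprintf("%08x", sum(utf8ToInt(paste(s, collapse = "")) *
                        (seq_along(utf8ToInt(paste(s, collapse = ""))) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run the full multi-cycle analysis pipeline
#'
#' Executes simulate -> QC/impute -> BLUE adjustment -> Bayes B training ->
#' prediction -> cross-cycle validation -> LD -> Ne, writing tidy CSV reports
#' and a manifest to `outdir`. Reruns with an identical configuration are
#' byte-identical (all randomness is derived from the master seed). If the
#' configured testing trial appears inside a training composition the
#' configuration is rejected before any stage runs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @return Invisibly, a list with the per-stage results and output paths.
#' @export
run_pipeline <- function(config, outdir = tempfile("cyclegp_run_")) {
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config()")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage_times <- list()
  tick <- function(name, expr) {
    st <- Sys.time()
    out <- force(expr)
    stage_times[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    out
  }

  prog <- tick("simulate", do.call(simulate_breeding_program,
                                   c(config$simulate,
                                     list(seed = derive_seed(config$master_seed, "simulate")))))
  tst_trial <- config$validate$tst_trial %||% utils::tail(prog$trials, 1)
  assert_that(tst_trial %in% prog$trials, "validate$tst_trial not simulated")

  geno_clean <- tick("qc", lapply(prog$genotypes, function(g) {
    q <- qc_filter(g, config$qc$maf_min, config$qc$max_missing)
    list(genotypes = impute_mean(q$genotypes), report = q$report)
  }))
  qc_report <- dplyr::bind_rows(lapply(names(geno_clean), function(tr) {
    dplyr::mutate(geno_clean[[tr]]$report, trial = tr, .before = 1)
  }))

  traits <- prog$architecture$trait_names
  blues <- tick("adjust", dplyr::bind_rows(lapply(prog$trials, function(tr) {
    dplyr::bind_rows(lapply(traits, function(trt) {
      fits <- lapply(config$adjust$models, function(mdl) {
        fit_trial_model(prog$phenotypes[prog$phenotypes$trial == tr, ], trt,
                        model = mdl, center = config$adjust$center)
      })
      tidy(select_model(fits))
    }))
  })))

  spec <- do.call(bayesb_spec,
                  c(config$train, list(seed = derive_seed(config$master_seed, "train"))))
  trn_trials <- setdiff(prog$trials, tst_trial)
  trn_trials <- trn_trials[match(trn_trials, prog$trials) < match(tst_trial, prog$trials)]
  models <- tick("train", lapply(stats::setNames(trn_trials, trn_trials), function(tr) {
    lapply(stats::setNames(traits, traits), function(trt) {
      b <- blues[blues$trial_id == tr & blues$trait == trt, ]
      bayesb_fit(b, geno_clean[[tr]]$genotypes, spec, trait = trt, trials = tr)
    })
  }))

  preds <- tick("predict", lapply(models, function(by_trait) {
    lapply(by_trait, function(mod) {
      bayesb_predict(mod, geno_clean[[tst_trial]]$genotypes)
    })
  }))

  validation <- tick("validate", {
    grids <- expand.grid(direction = config$validate$directions,
                         include_common = config$validate$include_common,
                         trait = traits, stringsAsFactors = FALSE)
    dplyr::bind_rows(lapply(seq_len(nrow(grids)), function(i) {
      sc <- assign_scenarios(prog$trials, tst_trial, grids$direction[i],
                             grids$include_common[i])
      pred_by_trial <- lapply(preds, function(x) x[[grids$trait[i]]])
      tstb <- blues[blues$trial_id == tst_trial & blues$trait == grids$trait[i], ]
      evaluate_scenarios(pred_by_trial, tstb, prog$rosters, sc)
    }))
  })

  inc <- incidence_summary(prog$rosters, prog$pedigree)

  ld_res <- NULL; ne_res <- NULL
  if (isTRUE(config$ld$run) || isTRUE(config$ne$run)) {
    ld_trials <- config$ld$trials %||% unique(c(prog$trials[1], utils::tail(prog$trials, 1)))
    popg <- tick("ld_ne", lapply(stats::setNames(ld_trials, ld_trials), function(tr) {
      # exclude carried-over duplicates: keep individuals born into this cycle,
      # except the first trial which keeps its founders/ancestors
      roster <- prog$rosters[[tr]]
      if (tr != prog$trials[1]) {
        born <- prog$pedigree$cycle_born[match(roster, prog$pedigree$id)]
        keep <- roster[born == max(born)]
        if (length(keep) >= 10) roster <- keep
      }
      g <- geno_clean[[tr]]$genotypes
      g <- geno_matrix(g$calls[intersect(roster, rownames(g$calls)), , drop = FALSE],
                       map = g$map)
      out <- list()
      if (isTRUE(config$ld$run)) {
        out$ld <- pairwise_r2(g, "within_lg", max_pairs = config$ld$max_pairs,
                              seed = derive_seed(config$master_seed, paste0("ld", tr)))
        out$decay <- tryCatch(fit_ld_decay(out$ld), error = function(e) NULL)
      }
      if (isTRUE(config$ne$run)) {
        out$ne <- tryCatch(
          ne_ld(g, maf_threshold = config$ne$maf_threshold,
                seed = derive_seed(config$master_seed, paste0("ne", tr))),
          error = function(e) NULL)
      }
      out
    }))
    ld_res <- lapply(popg, function(x) x[c("ld", "decay")])
    ne_res <- lapply(popg, function(x) x$ne)
  }

  # ---- reports --------------------------------------------------------------
  hash <- config_hash(config)
  stamp <- function(df) dplyr::mutate(df, config_hash = hash,
                                      master_seed = config$master_seed)
  readr::write_csv(stamp(blues), file.path(outdir, "blues.csv"))
  readr::write_csv(stamp(qc_report), file.path(outdir, "qc_report.csv"))
  readr::write_csv(stamp(as_tibble(validation)), file.path(outdir, "validation.csv"))
  inc_df <- as.data.frame(inc$matrix)
  inc_df <- cbind(trial = rownames(inc$matrix), inc_df,
                  n = as.integer(inc$n_per_trial))
  readr::write_csv(stamp(as_tibble(inc_df)), file.path(outdir, "incidence.csv"))
  readr::write_csv(stamp(incidence_averages(inc)),
                   file.path(outdir, "incidence_averages.csv"))
  if (!is.null(ne_res)) {
    ne_tab <- dplyr::bind_rows(lapply(names(ne_res), function(tr) {
      x <- ne_res[[tr]]
      tibble(trial = tr, ne = if (is.null(x)) NA_real_ else x$ne,
             r2_mean = if (is.null(x)) NA_real_ else x$r2_mean,
             n_pairs = if (is.null(x)) NA_integer_ else x$n_pairs)
    }))
    readr::write_csv(stamp(ne_tab), file.path(outdir, "ne.csv"))
  }
  manifest <- tibble(stage = names(stage_times),
                     seconds = round(unlist(stage_times), 2),
                     config_hash = hash, master_seed = config$master_seed,
                     package_version = as.character(utils::packageVersion("cyclegp")))
  readr::write_csv(manifest, file.path(outdir, "manifest.csv"))

  invisible(list(outdir = outdir, program = prog, blues = blues,
                 qc_report = qc_report, models = models,
                 validation = validation, incidence = inc,
                 ld = ld_res, ne = ne_res, manifest = manifest,
                 total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
}
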