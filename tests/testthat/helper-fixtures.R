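# Shared fixture builders: everything is generated in code, no stored data.

tiny_map <- function(n_markers = 50, n_lg = 2, len = 100, seed = 101) {
  make_genetic_map(n_markers, n_lg = n_lg, total_length_cm = len, seed = seed)
}

tiny_pop <- function(n = 20, n_markers = 50, seed = 202, maf = c(0.2, 0.5)) {
  make_founders(n, tiny_map(n_markers), maf_range = maf, seed = seed)
}

# A hand-buildable population: explicit haplotypes on a custom map.
pop_from_haplotypes <- function(H1, H2, map, ids = NULL) {
  ids <- ids %||% sprintf("P%02d", seq_len(nrow(H1)))
  ped <- tibble::tibble(id = ids, dam = NA_character_, sire = NA_character_,
                        cycle_born = 0L)
  new_breeding_pop(ped, H1, H2, map)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Small simulated program reused by validation-level tests.
small_program <- function(seed = 1, n_cycles = 3, h2 = c(0.3, 0.6)) {
  simulate_breeding_program(
    n_founders = 24, n_markers = 200, n_lg = 4, total_length_cm = 400,
    n_cycles = n_cycles, n_parents = 12, n_offspring = 5,
    n_select_per_family = 3, n_carryover = 8, pi_zero = 0.95, h2 = h2,
    seed = seed)
}

quick_spec <- function(seed = 1, n_iter = 800, burn_in = 200) {
  bayesb_spec(n_iter = n_iter, burn_in = burn_in, thin = 2, n_chains = 1,
              seed = seed)
}

# Clonal-mean phenotypes with a known heritability, for variance-component
# recovery tests: y = Wb (scaled) + e.
sim_h2_panel <- function(n, m, h2, seed, n_lg = 10) {
  map <- make_genetic_map(m, n_lg = n_lg, total_length_cm = 1000,
                          seed = seed + 7)
  f <- make_founders(n, map, maf_range = c(0.1, 0.5), seed = seed)
  arch <- simulate_trait_architecture(map, pi_zero = 0.9, h2_target = h2,
                                      ry_target = 1, n_traits = 1,
                                      seed = seed + 13)
  g <- pop_dosages(f) %*% arch$effects[, 1]
  vg <- stats::var(g)
  e <- withr::with_seed(seed + 19, stats::rnorm(n, 0, sqrt(vg * (1 - h2) / h2)))
  list(geno = impute_mean(geno_matrix(pop_dosages(f), map = map)),
       blues = tibble::tibble(genotype_id = f$pedigree$id,
                              blue = as.numeric(g + e)),
       true_bv = as.numeric(g))
}
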