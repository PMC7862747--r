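test_that("founder allele frequencies follow the configured range", {
  map1 <- make_genetic_map(2, n_lg = 1, total_length_cm = 10, seed = 1)
  f <- make_founders(5000, map1, maf_range = c(0.5, 0.5), seed = 3)
  # 2 * 5000 haplotypes per marker at p = 0.5: binomial 3-SE bound
  obs <- colMeans(rbind(f$H1, f$H2))
  se <- sqrt(0.25 / (2 * 5000))
  expect_true(all(abs(obs - 0.5) < 3 * se))

  # determinism contract
  f2 <- make_founders(5000, map1, maf_range = c(0.5, 0.5), seed = 3)
  expect_identical(f$H1, f2$H1)
  expect_identical(f$H2, f2$H2)

  # frequencies drawn within the requested interval
  f3 <- make_founders(800, tiny_map(100), maf_range = c(0.3, 0.4), seed = 9)
  p <- attr(f3, "founder_freqs")
  expect_true(all(p >= 0.3 & p <= 0.4))

  expect_error(make_founders(5, structure(tibble::tibble(), class = "genetic_map")),
               "non-empty")
  expect_error(make_founders(5, tiny_map(10), maf_range = c(0, 0.5)), "maf_range")
})

test_that("partial circular mating fills the off-diagonal band", {
  plan <- partial_circular_mating(sprintf("P%02d", 1:10), 4)
  expect_equal(nrow(plan), 20)
  counts <- table(c(plan$dam, plan$sire))
  expect_true(all(counts == 4))
  expect_true(all(plan$dam != plan$sire))
  key <- paste(pmin(plan$dam, plan$sire), pmax(plan$dam, plan$sire))
  expect_false(any(duplicated(key)))

  # five parents, four crosses each: the circular design saturates all pairs
  plan5 <- partial_circular_mating(letters[1:5], 4)
  expect_equal(nrow(plan5), choose(5, 2))

  # odd crosses per parent: diametric pairing, even parent count required
  plan5x <- partial_circular_mating(sprintf("P%02d", 1:10), 5)
  expect_equal(nrow(plan5x), 25)
  expect_true(all(table(c(plan5x$dam, plan5x$sire)) == 5))
  expect_error(partial_circular_mating(letters[1:7], 5), "even number")

  expect_error(partial_circular_mating(letters[1:2], 4), "at least 5 parents")
})

test_that("meiosis follows Mendelian segregation and the Haldane map function", {
  map2 <- as_genetic_map(tibble::tibble(
    marker_id = c("A", "B"), linkage_group = 1L, pos_cm = c(0, 10)))
  # dam doubly heterozygous in coupling, sire fully homozygous reference
  pop <- pop_from_haplotypes(
    H1 = rbind(c(1L, 1L), c(0L, 0L)),
    H2 = rbind(c(0L, 0L), c(0L, 0L)), map2, ids = c("dam", "sire"))
  plan <- tibble::tibble(dam = "dam", sire = "sire", n_offspring = 4000L)
  class(plan) <- c("cross_plan", class(plan))
  off <- advance_cycle(pop, plan, n_select_per_family = 4000, seed = 77)
  dos <- pop_dosages(off)          # sire contributes 0: dosage = dam gamete
  expect_true(all(dos %in% 0:1))
  # marginal segregation 1:1 at each marker
  expect_true(all(abs(colMeans(dos) - 0.5) < 3 * sqrt(0.25 / 4000)))
  # recombinant fraction at 10 cM under Haldane: c = (1 - exp(-0.2)) / 2
  rec <- mean(dos[, 1] != dos[, 2])
  c_exp <- (1 - exp(-0.2)) / 2
  expect_lt(abs(rec - c_exp), 3 * sqrt(c_exp * (1 - c_exp) / 4000))

  # homozygous x homozygous is deterministic; AA x aa gives all Aa
  pop2 <- pop_from_haplotypes(
    H1 = rbind(c(1L, 1L), c(0L, 0L)),
    H2 = rbind(c(1L, 1L), c(0L, 0L)), map2, ids = c("AA", "aa"))
  plan2 <- tibble::tibble(dam = "AA", sire = "aa", n_offspring = 50L)
  class(plan2) <- c("cross_plan", class(plan2))
  off2 <- advance_cycle(pop2, plan2, n_select_per_family = 50, seed = 1)
  expect_true(all(pop_dosages(off2) == 1L))

  expect_error(advance_cycle(pop2, tibble::tibble(dam = "AA", sire = "nope",
                                                  n_offspring = 2L), 2),
               "unknown parent")
})

test_that("carry-over individuals enter the next roster unchanged", {
  pop <- tiny_pop(10)
  plan <- partial_circular_mating(pop$pedigree$id[1:6], 4, n_offspring = 3)
  nxt <- advance_cycle(pop, plan, n_select_per_family = 2,
                       carryover_ids = c("F007", "F008"), seed = 5)
  expect_true(all(c("F007", "F008") %in% nxt$pedigree$id))
  expect_identical(pop_dosages(nxt, "F007"), pop_dosages(pop, "F007"))
  expect_true(all(nxt$pedigree$cycle_born[!grepl("^F", nxt$pedigree$id)] == 1L))
})

test_that("trait architecture spike density and year correlation behave", {
  map <- make_genetic_map(10000, n_lg = 20, total_length_cm = 2000, seed = 4)
  arch <- simulate_trait_architecture(map, pi_zero = 0.999, h2_target = 0.5,
                                      ry_target = 0.9, n_traits = 1, seed = 6)
  n_nz <- sum(arch$effects[, 1] != 0)
  se <- sqrt(10000 * 0.001 * 0.999)
  expect_lt(abs(n_nz - 10), 3 * se)

  expect_error(simulate_trait_architecture(map, pi_zero = 1), "pi_zero")
  expect_error(simulate_trait_architecture(map, h2_target = 0), "h2_target")

  # ry = 1: year realisations are exactly the shared effects, so true BVs of
  # two different trial years correlate perfectly
  pop <- tiny_pop(30, 100)
  arch1 <- simulate_trait_architecture(pop$map, pi_zero = 0.8, h2_target = 0.5,
                                       ry_target = 1, n_traits = 1, seed = 8)
  t1 <- simulate_trial(pop, arch1, "T2", seed = 11)
  t2 <- simulate_trial(pop, arch1, "T4", seed = 12)
  expect_equal(stats::cor(t1$truth$true_bv, t2$truth$true_bv), 1)
})

test_that("realized clonal-mean heritability matches the target", {
  h2hat <- vapply(1:20, function(s) {
    pop <- make_founders(300, tiny_map(200, seed = s), seed = s + 50)
    arch <- simulate_trait_architecture(pop$map, pi_zero = 0.9, h2_target = 0.5,
                                        ry_target = 1, n_traits = 1, seed = s)
    st <- simulate_trial(pop, arch, "T2", n_reps = 5, s2_rep = 0, seed = s + 99)
    means <- tapply(st$trial$value, st$trial$genotype, mean)
    tru <- st$truth$true_bv[match(names(means), st$truth$genotype)]
    stats::var(tru) / stats::var(means)
  }, numeric(1))
  expect_gt(mean(h2hat), 0.4)
  expect_lt(mean(h2hat), 0.6)
})

test_that("simulated trials satisfy the RCBD layout contract", {
  pop <- tiny_pop(25, 100)
  arch <- simulate_trait_architecture(pop$map, pi_zero = 0.9, h2_target = 0.4,
                                      n_traits = 1, seed = 2)
  st <- simulate_trial(pop, arch, "T2", n_reps = 5, plots_per_bed = 6,
                       missing_rate = 0.05, seed = 13)
  tr <- st$trial
  # each test genotype exactly once per replicate (the control recurs per bed)
  tab <- table(tr$genotype[!tr$is_control], tr$rep[!tr$is_control])
  expect_true(all(tab == 1))
  # exactly one control plot per bed
  ctrl <- dplyr::count(dplyr::filter(tr, is_control), rep, bed)
  beds <- dplyr::distinct(tr, rep, bed)
  expect_equal(nrow(ctrl), nrow(beds))
  expect_true(all(ctrl$n == 1))
  # missing-rate binomial bound on the genotype matrix
  fmiss <- mean(is.na(st$genotypes$calls))
  expect_lt(abs(fmiss - 0.05),
            3 * sqrt(0.05 * 0.95 / length(st$genotypes$calls)))
  expect_error(simulate_trial(pop, arch, "T2", control_id = "nope", seed = 1),
               "control genotype")
  expect_error(simulate_trial(pop, arch, "T2", n_reps = 3, seed = 1), "n_reps")
})

test_that("noiseless trials repeat genotype values exactly across replicates", {
  pop <- tiny_pop(15, 60)
  arch <- simulate_trait_architecture(pop$map, pi_zero = 0.8, h2_target = 1,
                                      ry_target = 1, n_traits = 1, seed = 3)
  st <- simulate_trial(pop, arch, "T2", n_reps = 5, s2_rep = 0, seed = 21)
  spread <- tapply(st$trial$value, st$trial$genotype,
                   function(v) diff(range(v)))
  expect_true(all(spread < 1e-10))
})

test_that("a zero-correlation AR1 surface shows no lag-1 autocorrelation", {
  set.seed(42)
  s <- cyclegp:::ar1_surface(60, 40, 0, 0, 1)
  lag1 <- stats::cor(as.vector(s[-1, ]), as.vector(s[-nrow(s), ]))
  expect_lt(abs(lag1), 3 / sqrt(length(s)))
})

test_that("allele frequencies drift without direction when unselected", {
  changes <- unlist(lapply(1:8, function(s) {
    pop <- tiny_pop(30, 100, seed = s)
    plan <- partial_circular_mating(pop$pedigree$id[1:10], 4, n_offspring = 3)
    nxt <- advance_cycle(pop, plan, n_select_per_family = 3, seed = s + 1000)
    colMeans(pop_dosages(nxt)) / 2 - colMeans(pop_dosages(pop, pop$pedigree$id[1:10])) / 2
  }))
  expect_lt(abs(mean(changes)), 3 * stats::sd(changes) / sqrt(length(changes)))
})

test_that("program-level carry-over reproduces configured incidence counts", {
  prog <- small_program(seed = 4)
  # founders in the rosters have no recorded parents: warning is expected
  expect_warning(inc <- incidence_summary(prog$rosters, prog$pedigree),
                 "parentless")
  # consecutive trials share exactly the configured carry-over count
  expect_equal(unname(inc$matrix["T2", "T4"]), 8)
  expect_equal(unname(inc$matrix["T4", "T6"]), 8)
  expect_true(all(diag(inc$matrix) > 0))
})

test_that("program outputs round-trip through the external file formats", {
  prog <- small_program(seed = 6, n_cycles = 2, h2 = 0.4)
  dir <- withr::local_tempdir()
  write_breeding_program(prog, dir)
  expect_true(file.exists(file.path(dir, "phenotypes.csv")))
  g <- read_genotypes(file.path(dir, "geno_T2.tsv"), "matrix")
  expect_equal(g$calls, prog$genotypes[["T2"]]$calls)
  gv <- read_genotypes(file.path(dir, "geno_T2.vcf"), "vcf")
  expect_equal(unname(gv$calls[rownames(g$calls), colnames(g$calls)]),
               unname(g$calls))
  map <- read_genetic_map(file.path(dir, "map.tsv"))
  expect_equal(map$marker_id, prog$population$map$marker_id)
})
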