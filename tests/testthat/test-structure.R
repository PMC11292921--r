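test_that("relatedness is centred at zero for unrelated, 0.5 for parent-offspring", {
  sim <- simulate_populations(sim_config(n_pops = 1, n_per_pop = 200L,
                                         n_loci = 20, seed = 3))
  rel <- pairwise_relatedness(sim$table)
  expect_equal(nrow(rel$pairs), choose(200, 2))
  expect_lt(abs(mean(rel$pairs$r, na.rm = TRUE)), 0.02)

  ped <- simulate_pedigree(allele_frequencies(sim$table, "all"),
                           n_trios = 150, seed = 5)
  rel2 <- pairwise_relatedness(ped$table)
  pr <- rel2$pairs
  po <- pr[grepl("_sire$", pr$id1) & grepl("_off$", pr$id2) &
             sub("_sire$", "", pr$id1) == sub("_off$", "", pr$id2), ]
  expect_equal(nrow(po), 150L)
  expect_lt(abs(mean(po$r) - 0.5), 0.03)
})

test_that("pair counts follow n(n-1)/2 within and across groups", {
  sim <- simulate_populations(sim_config(n_pops = 3, n_per_pop = c(5L, 7L, 4L),
                                         n_loci = 4, seed = 11))
  rel <- pairwise_relatedness(sim$table)
  expect_equal(nrow(rel$pairs), choose(16, 2))
  expect_equal(sum(rel$group_means$n_pairs),
               choose(5, 2) + choose(7, 2) + choose(4, 2))
})

test_that("FIS hits the extremes and bootstrap CIs are reproducible", {
  # all homozygotes at p ~ (0.5, 0.5): FIS ~ 1
  a <- matrix(rep(c(100L, 102L), each = 10), 20, 4)
  t <- genotype_table(data.frame(id = sprintf("s%d", 1:20), pop = "p"),
                      sprintf("L%d", 1:4), a, a)
  f <- fis_with_ci(t, "pop", n_boot = 50, seed = 1)
  expect_equal(f$groups$fis[1], 1, tolerance = 1e-9)

  sim <- simulate_populations(sim_config(n_pops = 1, n_per_pop = 300L,
                                         n_loci = 15, seed = 7))
  f1 <- fis_with_ci(sim$table, "pop", n_boot = 200, seed = 2)
  f2 <- fis_with_ci(sim$table, "pop", n_boot = 200, seed = 2)
  expect_identical(f1$groups, f2$groups)
  expect_lt(abs(f1$groups$fis[1]), 0.03)  # HW-consistent data
  expect_true(f1$groups$ci_lo[1] <= f1$groups$fis[1],
              f1$groups$ci_hi[1] >= f1$groups$fis[1])
})

test_that("pairwise theta spans fixation to panmixia with seeded permutations", {
  t <- fixed_diff_table()
  pf <- pairwise_fst(t, "pop", n_perm = 50, seed = 1)
  expect_gt(pf$theta["p1", "p2"], 0.98)
  expect_lt(pf$p["p1", "p2"], 0.05)

  # one population duplicated as two labels: theta ~ 0, p not small
  sim <- simulate_populations(sim_config(n_pops = 1, n_per_pop = 60L,
                                         n_loci = 10, seed = 13))
  tt <- sim$table
  tt$samples$pop <- rep(c("a", "b"), 30)
  pf0 <- pairwise_fst(tt, "pop", n_perm = 99, seed = 2)
  expect_lt(abs(pf0$theta["a", "b"]), 0.02)
  expect_gt(pf0$p["a", "b"], 0.05)
  pf0b <- pairwise_fst(tt, "pop", n_perm = 99, seed = 2)
  expect_identical(pf0$p, pf0b$p)
})

test_that("theta increases with the simulator differentiation parameter", {
  mean_theta <- vapply(c(0.01, 0.05, 0.2), function(fst) {
    mean(vapply(1:5, function(s) {
      sim <- simulate_populations(sim_config(
        n_pops = 2, n_per_pop = c(60L, 60L), n_loci = 10, fst = fst,
        seed = 1000 * fst + s))
      wc_fstats(sim$table, "pop")$fst
    }, 0))
  }, 0)
  expect_true(all(diff(mean_theta) > 0))
  expect_true(all(mean_theta > -0.05 & mean_theta <= 1))
})

test_that("R_ST tracks allele-size divergence and is scale-invariant", {
  mk <- function(sizes2) {
    a <- matrix(c(rep(100L, 10), rep(sizes2, 5)), 20, 1)
    genotype_table(data.frame(id = sprintf("s%d", 1:20),
                              pop = rep(c("p1", "p2"), each = 10)),
                   locus_meta("L1", 2L), a, a)
  }
  near <- pairwise_rst(mk(c(102L, 102L)))["p1", "p2"]
  far <- pairwise_rst(mk(c(130L, 130L)))["p1", "p2"]
  expect_gt(far, near - 1e-12)

  sim <- simulate_populations(sim_config(n_pops = 2, n_per_pop = c(20L, 20L),
                                         n_loci = 5, fst = 0.1, seed = 3))
  r1 <- pairwise_rst(sim$table)
  t2 <- sim$table
  t2$a1 <- t2$a1 * 3L; t2$a2 <- t2$a2 * 3L
  t2$loci$repeat_unit_bp <- t2$loci$repeat_unit_bp * 3L
  expect_equal(pairwise_rst(t2), r1, tolerance = 1e-9)

  # identical groups: RST ~ 0
  tt <- sim$table
  tt$samples$pop <- rep(c("a", "b"), 20)
  expect_lt(abs(pairwise_rst(tt)["a", "b"]), 0.05)
})

test_that("Nei distance matches its closed form and edge cases", {
  t <- genotype_table(
    data.frame(id = sprintf("s%d", 1:4), pop = rep(c("x", "y"), each = 2)),
    "L1",
    a1 = matrix(c(100L, 100L, 100L, 102L), 4),
    a2 = matrix(c(100L, 100L, 100L, 102L), 4))
  f <- allele_frequencies(t, "pop")
  d <- nei_distance(f)
  # x is fixed for 100; y has p = (0.5, 0.5): I = 0.5/sqrt(0.5) = 0.7071
  expect_equal(d["x", "y"], -log(1 / sqrt(2)), tolerance = 1e-12)

  # identical frequencies -> 0; disjoint alleles -> Inf
  t_same <- fixed_diff_table()
  t_same$samples$pop <- rep(c("a", "b"), 10)
  expect_equal(nei_distance(allele_frequencies(t_same, "pop"))["a", "b"], 0,
               tolerance = 1e-12)
  expect_equal(nei_distance(allele_frequencies(fixed_diff_table(), "pop"))["p1", "p2"],
               Inf)
})

test_that("AMOVA partitions variance coherently", {
  # two identical copies of one population: 0% among populations
  sim <- simulate_populations(sim_config(n_pops = 1, n_per_pop = 30L,
                                         n_loci = 8, seed = 17))
  t <- sim$table
  dup <- genotype_table(
    data.frame(id = c(t$samples$id, paste0(t$samples$id, "_2")),
               pop = rep(c("c1", "c2"), each = 30)),
    t$loci, rbind(t$a1, t$a1), rbind(t$a2, t$a2))
  am <- amova(dup, "pop")
  expect_equal(unname(am$percent["among_populations"]), 0)
  expect_equal(sum(am$percent), 100, tolerance = 1e-9)
  expect_equal(am$total, sum(am$components), tolerance = 1e-9)

  # among-population share grows with differentiation
  pct_at <- function(fst, seed) {
    sim <- simulate_populations(sim_config(n_pops = 3,
                                           n_per_pop = rep(40L, 3),
                                           n_loci = 10, fst = fst,
                                           seed = seed))
    amova(sim$table, "pop")$percent[["among_populations"]]
  }
  lo <- mean(vapply(1:4, function(s) pct_at(0.02, s), 0))
  hi <- mean(vapply(1:4, function(s) pct_at(0.2, 100 + s), 0))
  expect_gt(hi, lo)
})

test_that("genotypic LD test detects duplication and is calibrated under the null", {
  sim <- simulate_populations(sim_config(n_pops = 1, n_per_pop = 60L,
                                         n_loci = 2, seed = 19))
  t <- sim$table
  # duplicate locus 1 as locus 2: perfect association
  t$a1[, 2] <- t$a1[, 1]; t$a2[, 2] <- t$a2[, 1]
  p_dup <- genotypic_ld_test(t, "all", t$loci$name, n_perm = 1000, seed = 1)
  expect_lt(unname(p_dup), 0.01)
  expect_identical(p_dup,
                   genotypic_ld_test(t, "all", t$loci$name, n_perm = 1000,
                                     seed = 1))
  # independent loci: rejection rate near 5%
  rej <- vapply(1:150, function(s) {
    sim <- simulate_populations(sim_config(n_pops = 1, n_per_pop = 50L,
                                           n_loci = 2,
                                           alleles_per_locus = 4,
                                           seed = 500 + s))
    unname(genotypic_ld_test(sim$table, "all", sim$table$loci$name,
                             n_perm = 199, seed = s)) < 0.05
  }, NA)
  expect_lt(abs(mean(rej) - 0.05), 0.04)
})
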