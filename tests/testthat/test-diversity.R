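test_that("closed-form diversity statistics match hand-evaluated values", {
  # p = (0.5, 0.5): Nea = 2, I = ln 2, He = 0.5, PIC = 0.375
  t <- genotype_table(data.frame(id = c("a", "b"), pop = "p"), "L1",
                      a1 = matrix(c(100L, 102L), 2),
                      a2 = matrix(c(100L, 102L), 2))
  s <- locus_summary(t, "all")
  expect_equal(s$Nea, 2, tolerance = 1e-12)
  expect_equal(s$I, log(2), tolerance = 1e-12)
  expect_equal(s$He, 0.5, tolerance = 1e-12)
  expect_equal(s$PIC, 0.375, tolerance = 1e-12)

  # p = (0.7, 0.2, 0.1) at n = 10 diploids: He = 0.46, Nea = 1.8519,
  # uHe = 20/19 * 0.46 = 0.48421
  a <- c(rep(100L, 14), rep(102L, 4), rep(104L, 2))
  t2 <- genotype_table(data.frame(id = sprintf("s%d", 1:10), pop = "p"), "L1",
                       a1 = matrix(a[seq(1, 20, 2)], 10),
                       a2 = matrix(a[seq(2, 20, 2)], 10))
  s2 <- locus_summary(t2, "all")
  expect_equal(s2$He, 0.46, tolerance = 1e-12)
  expect_equal(s2$Nea, 1 / 0.54, tolerance = 1e-12)
  expect_equal(s2$uHe, 20 / 19 * 0.46, tolerance = 1e-12)
})

test_that("rarefied allelic richness matches the binomial-coefficient form", {
  # counts (3,1) in 2n = 4 copies, g = 2:
  # AR = [1 - C(1,2)/C(4,2)] + [1 - C(3,2)/C(4,2)] = 1 + 1 - 3/6 = 1.5
  t <- genotype_table(data.frame(id = c("a", "b"), pop = "p"), "L1",
                      a1 = matrix(c(100L, 100L), 2),
                      a2 = matrix(c(100L, 102L), 2))
  expect_equal(allelic_richness(t, "pop", g = 2)$AR, 1.5, tolerance = 1e-12)
  # full depth recovers Na; monomorphic locus gives AR = 1
  expect_equal(allelic_richness(t, "pop", g = 4)$AR, 2, tolerance = 1e-9)
  t0 <- genotype_table(data.frame(id = c("a", "b"), pop = "p"), "L1",
                       a1 = matrix(c(100L, 100L), 2),
                       a2 = matrix(c(100L, 100L), 2))
  expect_equal(allelic_richness(t0, "pop", g = 2)$AR, 1, tolerance = 1e-12)
  expect_error(allelic_richness(t, "pop", g = 10), "exceeds")
})

test_that("HWE exact test enumerates the conditional distribution", {
  # genotypes {AA, BB}: two configurations with probabilities 1/3 and 2/3;
  # the observed one is the least probable, so p = 1/3
  t <- genotype_table(data.frame(id = c("a", "b"), pop = "p"), "L1",
                      a1 = matrix(c(100L, 102L), 2),
                      a2 = matrix(c(100L, 102L), 2))
  expect_equal(unname(hwe_exact_test(t, "all", "L1")), 1 / 3,
               tolerance = 1e-12)
  # all heterozygotes: p is at most the most-heterozygous configuration mass
  t2 <- genotype_table(data.frame(id = c("a", "b"), pop = "p"), "L1",
                       a1 = matrix(c(100L, 100L), 2),
                       a2 = matrix(c(102L, 102L), 2))
  expect_equal(unname(hwe_exact_test(t2, "all", "L1")), 1,
               tolerance = 1e-12)  # {AB,AB} has p=2/3 >= 1/3; total = 1
  # monomorphic convention
  t3 <- genotype_table(data.frame(id = c("a", "b"), pop = "p"), "L1",
                       a1 = matrix(c(100L, 100L), 2),
                       a2 = matrix(c(100L, 100L), 2))
  expect_equal(unname(hwe_exact_test(t3, "all", "L1")), 1)
})

test_that("HWE Monte Carlo agrees with full enumeration", {
  sim <- simulate_populations(sim_config(n_pops = 1, n_per_pop = 12L,
                                         n_loci = 6, alleles_per_locus = 3,
                                         seed = 41))
  for (ln in sim$table$loci$name[1:4]) {
    pe <- unname(hwe_exact_test(sim$table, "all", ln, method = "enumeration"))
    pm <- unname(hwe_exact_test(sim$table, "all", ln, method = "monte_carlo",
                                reps = 1e5, seed = 8))
    expect_lt(abs(pe - pm), 0.01)
  }
})

test_that("HWE p-values are calibrated on equilibrium data", {
  # fraction of tests below 0.05 should be near 0.05 under the null
  ps <- unlist(lapply(1:10, function(s) {
    sim <- simulate_populations(sim_config(n_pops = 1, n_per_pop = 40L,
                                           n_loci = 40, seed = 100 + s))
    ls <- locus_summary(sim$table, "all", hwe_reps = 2000,
                        seed = s)
    ls$hwe_p
  }))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.02)
})

test_that("null-allele estimator matches Brookfield's closed form", {
  expect_equal(null_allele_estimate(0.30, 0.46), 0.16 / 1.46,
               tolerance = 1e-12)
  expect_equal(null_allele_estimate(0, 0.5), 1 / 3, tolerance = 1e-12)
  expect_equal(null_allele_estimate(0.6, 0.5), 0)  # truncation
})

test_that("M-ratio flags gappy allele ladders", {
  t <- genotype_table(data.frame(id = sprintf("s%d", 1:3), pop = "p"),
                      locus_meta("L1", repeat_unit_bp = 4L),
                      a1 = matrix(c(150L, 154L, 158L), 3),
                      a2 = matrix(c(150L, 154L, 158L), 3))
  m <- m_ratio(t, "all")
  expect_equal(m$M, 1)
  expect_false(m$bottleneck)
  t2 <- genotype_table(data.frame(id = c("a", "b"), pop = "p"),
                       locus_meta("L1", repeat_unit_bp = 4L),
                       a1 = matrix(c(150L, 158L), 2),
                       a2 = matrix(c(150L, 158L), 2))
  m2 <- m_ratio(t2, "all")
  expect_equal(m2$M, 2 / 3, tolerance = 1e-12)
  expect_true(m2$bottleneck)
})

test_that("Welch's t-test on Ho vs He matches the textbook formula", {
  s <- data.frame(group = "g", locus = sprintf("L%d", 1:15))
  set.seed(1)
  s$He <- runif(15, 0.4, 0.9)
  s$Ho <- s$He - 0.2
  w <- welch_ho_he(s, "g")
  # independent evaluation of the Welch statistic
  v1 <- var(s$Ho) / 15; v2 <- var(s$He) / 15
  t_ref <- (mean(s$Ho) - mean(s$He)) / sqrt(v1 + v2)
  df_ref <- (v1 + v2)^2 / (v1^2 / 14 + v2^2 / 14)
  expect_equal(w$t, t_ref, tolerance = 1e-12)
  expect_equal(w$df, df_ref, tolerance = 1e-9)
  expect_lt(w$t, 0)
  # identical vectors: t = 0, p = 1
  s$Ho <- s$He
  w0 <- welch_ho_he(s, "g")
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  expect_error(welch_ho_he(s[1, ], "g"), ">= 2 loci")
})

test_that("diversity invariants hold on random frequency vectors", {
  set.seed(5)
  for (i in 1:200) {
    p <- random_freqs(sample(2:8, 1))
    a2 <- sum(p^2); a4 <- sum(p^4)
    he <- 1 - a2
    pic <- 1 - a2 - (a2^2 - a4)
    # sum of squared HW genotype frequencies equals 2 a2^2 - a4
    G <- outer(p, p); gf <- c(p^2, 2 * G[upper.tri(G)])
    expect_equal(sum(gf^2), 2 * a2^2 - a4, tolerance = 1e-12)
    expect_true(he >= pic - 1e-12 && pic >= 0)
    expect_true(1 / a2 <= length(p) + 1e-12)
    expect_true(-sum(p * log(p)) <= log(length(p)) + 1e-12)
  }
})
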