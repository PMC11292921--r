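test_that("identification statistics match hand-derived values at p = (0.5, 0.5)", {
  s <- per_locus_id_stats(one_locus_freqs(c(a = 0.5, b = 0.5)), n = 10)
  expect_equal(s$PID_theoretical, 0.375, tolerance = 1e-12)
  expect_equal(s$PID_sibs, 0.59375, tolerance = 1e-12)
  expect_equal(s$PE, 0.28125, tolerance = 1e-12)
  expect_equal(s$PID_unbiased, 184 / 504, tolerance = 1e-12)
  expect_equal(s$MP, s$PID_theoretical)  # standard MP semantics
})

test_that("monomorphic loci give degenerate identification values", {
  s <- per_locus_id_stats(one_locus_freqs(c(a = 1)), n = 10)
  expect_equal(s$MP, 1)
  expect_equal(s$PID_theoretical, 1)
  expect_equal(s$PID_sibs, 1)
  expect_equal(s$PE, 0, tolerance = 1e-12)
  # unbiased form undefined below n = 4
  s2 <- per_locus_id_stats(one_locus_freqs(c(a = 0.5, b = 0.5)), n = 3)
  expect_true(is.na(s2$PID_unbiased))
})

test_that("panel combination multiplies PIDs and complements PE", {
  s <- per_locus_id_stats(
    stats::setNames(list(c(0.5, 0.5), c(0.5, 0.5)), c("L1", "L2")), n = 10)
  comb <- combine_panel(s)
  expect_equal(comb$PID_theoretical, 0.375^2, tolerance = 1e-12)
  expect_equal(comb$PE, 1 - 0.71875^2, tolerance = 1e-12)
  single <- combine_panel(s, "L1")
  expect_equal(single$PID_sibs, s$PID_sibs[1])
  expect_error(combine_panel(s, "nope"), "no statistics")
})

test_that("PID identities hold over random frequency vectors", {
  set.seed(7)
  for (i in 1:100) {
    p <- random_freqs(sample(2:9, 1))
    s <- per_locus_id_stats(one_locus_freqs(p), n = 1e5)
    # PID_theoretical equals the sum of squared HW genotype frequencies
    G <- outer(p, p)
    gf <- c(p^2, 2 * G[upper.tri(G)])
    expect_equal(s$PID_theoretical, sum(gf^2), tolerance = 1e-12)
    # large-n limit of the unbiased correction
    expect_lt(abs(s$PID_unbiased - s$PID_theoretical) / s$PID_theoretical,
              1e-3)
    expect_gte(s$PID_sibs, s$PID_theoretical)
  }
})

test_that("combined PID shrinks and PE grows as loci are added", {
  sim <- simulate_populations(sim_config(n_pops = 1, n_per_pop = 80L,
                                         n_loci = 10, seed = 3))
  s <- per_locus_id_stats(allele_frequencies(sim$table, "all"))
  loci <- s$locus
  prev <- NULL
  for (k in seq_along(loci)) {
    comb <- combine_panel(s, loci[seq_len(k)])
    if (!is.null(prev)) {
      expect_lte(comb$PID_theoretical, prev$PID_theoretical)
      expect_gte(comb$PE, prev$PE)
    }
    prev <- comb
  }
})

test_that("genotype accumulation matches the exhaustive subset average", {
  sim <- simulate_populations(sim_config(n_pops = 1, n_per_pop = 25L,
                                         n_loci = 5, seed = 9))
  t <- sim$table
  acc <- genotype_accumulation(t, reps = 2000, seed = 1)
  codes <- pawprint:::genotype_codes(t)
  for (s in 1:4) {
    combos <- utils::combn(5, s)
    exact <- mean(apply(combos, 2, function(idx)
      pawprint:::percent_distinguished(codes, idx)))
    expect_lt(abs(acc$mean_pct[acc$size == s] - exact), 0.5)
  }
  expect_true(all(diff(acc$mean_pct) >= -1e-9))  # non-decreasing in size
})

test_that("clones cap the accumulation curve below 100 percent", {
  sim <- simulate_populations(sim_config(n_pops = 1, n_per_pop = 10L,
                                         n_loci = 4, seed = 11))
  t <- sim$table
  clone <- genotype_table(
    data.frame(id = c(t$samples$id, "clone"), pop = "pop1"),
    t$loci, rbind(t$a1, t$a1[1, ]), rbind(t$a2, t$a2[1, ]))
  acc <- genotype_accumulation(clone, reps = 200, seed = 2)
  expect_true(all(acc$mean_pct < 100))
})

test_that("sibling-identity curve counts loci needed per threshold", {
  s <- per_locus_id_stats(
    stats::setNames(rep(list(c(0.5, 0.5)), 6), sprintf("L%d", 1:6)), n = 50)
  s$PID_sibs <- rep(0.5, 6)  # idealized loci
  he <- stats::setNames(rep(0.5, 6), s$locus)
  cur <- pid_sibs_locus_curve(s, he, thresholds = c(1, 0.1, 1e-9))
  expect_equal(unname(cur$loci_needed), c(1L, 4L, NA))  # 0.5^4 = 0.0625 <= 0.1
})

test_that("informative-first ordering never needs more loci than reverse", {
  sim <- simulate_populations(sim_config(n_pops = 1, n_per_pop = 60L,
                                         n_loci = 12, seed = 13))
  f <- allele_frequencies(sim$table, "all")
  s <- per_locus_id_stats(f)
  he <- vapply(pawprint:::pooled_freqs(f), function(p) 1 - sum(p^2), 0)
  for (th in c(0.01, 0.001, 1e-4)) {
    k_desc <- pid_sibs_locus_curve(s, he, "descending", th)$loci_needed
    k_asc <- pid_sibs_locus_curve(s, he, "ascending", th)$loci_needed
    if (!is.na(k_desc) && !is.na(k_asc)) expect_lte(k_desc, k_asc)
  }
})

test_that("match report finds duplicated samples and only those", {
  sim <- simulate_populations(sim_config(n_pops = 1, n_per_pop = 40L,
                                         n_loci = 15, seed = 15))
  t <- sim$table
  expect_equal(nrow(match_report(t)), 0L)  # combined PID << 1
  dup <- genotype_table(
    data.frame(id = c(t$samples$id, "twin"), pop = "pop1"),
    t$loci, rbind(t$a1, t$a1[5, ]), rbind(t$a2, t$a2[5, ]))
  m <- match_report(dup)
  expect_equal(nrow(m), 1L)
  expect_setequal(c(m$id1, m$id2), c(t$samples$id[5], "twin"))
})
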