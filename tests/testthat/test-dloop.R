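test_that("haplotype collapse applies complete deletion before comparison", {
  a <- aln_from(c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC"))
  ht <- collapse_haplotypes(a)
  expect_equal(length(ht$haplotypes), 1L)
  expect_equal(ht$S, 0L)

  a2 <- aln_from(c("AAAA", "AAAA", "ATCA", "ATCA"))
  ht2 <- collapse_haplotypes(a2)
  expect_equal(length(ht2$haplotypes), 2L)
  expect_equal(ht2$S, 2L)

  # sequences differing only in a gap column collapse together
  a3 <- aln_from(c("A-GT", "AAGT"))
  ht3 <- collapse_haplotypes(a3)
  expect_equal(length(ht3$haplotypes), 1L)
  expect_equal(ht3$length, 3L)
  expect_error(collapse_haplotypes(aln_from(c("--", "--"))), "all sites")
})

test_that("diversity statistics match their closed forms", {
  # haplotype counts (2, 2): h = 4/3 * (1 - 1/2) = 2/3
  a <- simulate_dloop_alignment(2, matrix(c(2, 2), 1), length = 100,
                                mut_per_hap = 3, seed = 1)
  ht <- collapse_haplotypes(a)
  d <- dloop_diversity(ht)
  expect_equal(d$h[d$population == "pop1"], 2 / 3, tolerance = 1e-12)
  # k by enumerating the six pairs: (4 pairs x 3 + 2 pairs x 0) / 6 = 2
  expect_equal(d$k[1], 2, tolerance = 1e-12)
  expect_equal(d$pi[1], 0.02, tolerance = 1e-12)
  # theta_S at n = 4, S = 3, L = 100
  expect_equal(d$theta_S[1], 3 / (sum(1 / (1:3)) * 100), tolerance = 1e-12)
  expect_equal(d$theta_S[1], 0.016364, tolerance = 1e-4)
})

test_that("diversity is invariant to haplotype labels and site order", {
  a <- simulate_dloop_alignment(3, matrix(c(3, 2, 1), 1), length = 60,
                                seed = 2)
  d1 <- dloop_diversity(collapse_haplotypes(a))
  # permute the columns of the alignment
  m <- do.call(rbind, strsplit(a$seqs, ""))
  perm <- sample(ncol(m))
  a2 <- dloop_alignment(a$ids, a$pops,
                        apply(m[, perm, drop = FALSE], 1, paste, collapse = ""))
  d2 <- dloop_diversity(collapse_haplotypes(a2))
  expect_equal(d1$h, d2$h)
  expect_equal(d1$pi, d2$pi)
  expect_equal(d1$k, d1$pi * 60)  # k = pi * L under complete deletion
})

test_that("differentiation spans sorting, divergence and identity cases", {
  # complete sorting: each population fixed for its own haplotype
  counts <- matrix(c(4, 0, 0, 4), 2, byrow = TRUE)
  ht <- collapse_haplotypes(
    simulate_dloop_alignment(2, counts, length = 100, seed = 3))
  d <- dloop_differentiation(ht)
  expect_equal(d$G_ST, 1, tolerance = 1e-12)
  expect_equal(d$Phi_ST, 1, tolerance = 1e-12)
  # internally monomorphic pair: D_a = D_xy = 3/100
  expect_equal(d$D_xy, 0.03, tolerance = 1e-12)
  expect_equal(d$D_a, d$D_xy, tolerance = 1e-12)

  # identical populations: D_a ~ 0
  counts2 <- matrix(c(2, 2, 2, 2), 2, byrow = TRUE)
  ht2 <- collapse_haplotypes(
    simulate_dloop_alignment(2, counts2, length = 100, seed = 4))
  d2 <- dloop_differentiation(ht2)
  expect_equal(d2$D_a, 0, tolerance = 1e-12)
  expect_lte(d2$D_a, d2$D_xy + 1e-12)
})

test_that("neutrality statistics reproduce frozen oracle values", {
  # 4 sequences, 20 sites: S = 3, eta = 4, singletons = 3, k = 2.
  # Tajima's D = 2.0119 (independent implementation on this fixture);
  # D* and F* hand-evaluated from the published no-outgroup formulas;
  # Fs = ln(S'/(1-S')) with S' = P(K >= 4 | theta = 2) = 16/120.
  a <- aln_from(c("AAAAAAAAAAAAAAAAAAAA",
                  "AAAAAAAAAACAAAAAAAAA",
                  "AAAAACAAAAAAAAAAAAGA",
                  "AAAAACAAAAAAAAAAAATA"))
  nt <- neutrality_tests(collapse_haplotypes(a))
  row <- nt[nt$population == "all", ]
  expect_equal(row$S, 3L)
  expect_equal(row$eta, 4L)
  expect_equal(row$eta_singletons, 3L)
  expect_equal(row$k, 2, tolerance = 1e-12)
  expect_equal(row$tajima_D, 2.0119, tolerance = 1e-4)
  expect_equal(row$fuli_Dstar, -0.06501, tolerance = 1e-4)
  expect_equal(row$fuli_Fstar, -0.10186, tolerance = 1e-4)
  expect_equal(row$fu_Fs, log((16 / 120) / (1 - 16 / 120)), tolerance = 1e-9)

  # no variation: statistics undefined
  a0 <- aln_from(rep("ACGTACGT", 5))
  nt0 <- neutrality_tests(collapse_haplotypes(a0))
  expect_true(all(is.na(nt0$tajima_D)))
})

test_that("Ewens haplotype-count tail matches naive permutation enumeration", {
  # P(K = j) via cycle counts of all n! permutations weighted
  # theta^cycles / rising factorial -- independent of the Stirling recursion
  naive_tail <- function(n, k_obs, theta) {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
      out
    }
    cycles <- function(p) {
      seen <- rep(FALSE, length(p)); k <- 0L
      for (s in seq_along(p)) {
        if (seen[s]) next
        k <- k + 1L; j <- s
        while (!seen[j]) { seen[j] <- TRUE; j <- p[j] }
      }
      k
    }
    rising <- prod(theta + 0:(n - 1))
    w <- vapply(perms(seq_len(n)), function(p) theta^cycles(p), 0) / rising
    kk <- vapply(perms(seq_len(n)), cycles, 0L)
    sum(w[kk >= k_obs])
  }
  for (n in c(4L, 6L)) for (theta in c(0.5, 2)) for (k_obs in c(2L, n - 1L)) {
    expect_equal(pawprint:::ewens_tail(n, k_obs, theta),
                 naive_tail(n, k_obs, theta), tolerance = 1e-9)
  }
})

test_that("Tajima's D centres on zero for neutral-spectrum simulations", {
  d <- vapply(1:200, function(s) {
    ht <- collapse_haplotypes(simulate_neutral_alignment(20, 5, 423, seed = s))
    neutrality_tests(ht)$tajima_D[1]
  }, 0)
  expect_lt(abs(mean(d, na.rm = TRUE)), 0.15)
})

test_that("mismatch distribution and raggedness follow the stated convention", {
  # two haplotypes in counts (2, 2) differing at 3 sites: classes 0 and 3
  a <- simulate_dloop_alignment(2, matrix(c(2, 2), 1), length = 100,
                                mut_per_hap = 3, seed = 5)
  mm <- mismatch_distribution(a)
  expect_equal(sum(mm$observed), 1, tolerance = 1e-12)
  expect_equal(mm$observed[c(1, 4)], c(2, 4) / 6, tolerance = 1e-12)
  expect_equal(mm$theta, 2, tolerance = 1e-12)
  # identical sequences: single class, raggedness = 1
  a0 <- aln_from(rep("ACGTACGTACGT", 4))
  expect_equal(mismatch_distribution(a0)$raggedness, 1)
  expect_error(mismatch_distribution(aln_from(c("AA", "AA"))), ">= 3")
  # two classes {0, 1} with observed (1/3, 2/3):
  # r = (2/3 - 1/3)^2 + (0 - 2/3)^2 = 5/9 under the trailing-zero convention
  a1 <- aln_from(c("AC", "AC", "AT", "AT"))
  mm1 <- mismatch_distribution(a1)
  expect_equal(mm1$observed, c(2, 4) / 6, tolerance = 1e-12)
  expect_equal(mm1$raggedness, 5 / 9, tolerance = 1e-12)
})
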