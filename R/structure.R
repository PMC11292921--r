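# Weir-Cockerham (1984) variance components for one locus across r groups.
# Returns the per-allele components summed: c(a, b, c). NULL when undefined.
wc_components_locus <- function(a1, a2, groups) {
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]; groups <- groups[ok]
  gl <- unique(groups)
  r <- length(gl)
  n_i <- as.numeric(table(factor(groups, levels = gl)))
  if (sum(n_i) < 2 || all(n_i < 1)) return(NULL)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2L) return(c(a = 0, b = 0, c = 0))
  nbar <- mean(n_i)
  nc <- if (r > 1) (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1) else nbar
  A <- 0; B <- 0; C <- 0
  for (al in alleles) {
    p_i <- vapply(gl, function(g) {
      idx <- groups == g
      (sum(a1[idx] == al) + sum(a2[idx] == al)) / (2 * sum(idx))
    }, 0)
    h_i <- vapply(gl, function(g) {
      idx <- groups == g
      mean((a1[idx] == al) != (a2[idx] == al))
    }, 0)
    pbar <- sum(n_i * p_i) / (r * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    s2 <- if (r > 1) sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar) else 0
    corr <- if (r > 1) (r - 1) / r else 0
    a <- if (r > 1)
      (nbar / nc) * (s2 - (pbar * (1 - pbar) - corr * s2 - hbar / 4) / (nbar - 1))
    else 0
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - corr * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(a = A, b = B, c = C)
}

wc_components <- function(t, groups, loci = NULL) {
  loci <- loci %||% t$loci$name
  comp <- sapply(match(loci, t$loci$name), function(l)
    wc_components_locus(t$a1[, l], t$a2[, l], groups) %||% c(a = NA, b = NA, c = NA))
  comp  # 3 x L matrix
}

#' Weir-Cockerham F-statistics
#'
#' Multilocus theta (F_ST), F_IS and F_IT from the 1984 variance-component
#' estimators, summing components over alleles and loci.
#'
#' @param t a [genotype_table()].
#' @param grouping `"pop"` or `"locality"`.
#' @return list with `fst`, `fis`, `fit` and the component matrix.
#' @export
wc_fstats <- function(t, grouping = c("pop", "locality")) {
  grouping <- match.arg(grouping)
  groups <- group_labels(t, grouping)
  comp <- wc_components(t, groups)
  A <- sum(comp["a", ], na.rm = TRUE)
  B <- sum(comp["b", ], na.rm = TRUE)
  C <- sum(comp["c", ], na.rm = TRUE)
  list(fst = A / (A + B + C), fis = 1 - C / (B + C),
       fit = 1 - C / (A + B + C), components = comp)
}

#' Pairwise Queller-Goodnight relatedness
#'
#' Symmetric-averaged Queller-Goodnight estimator with reference allele
#' frequencies from the pooled sample; per pair the per-locus numerators and
#' denominators are summed before dividing (multilocus weighting).
#'
#' @param t a [genotype_table()].
#' @return list with `pairs` (data.frame `id1`, `id2`, `r`, `n_loci`;
#'   pairs with no shared typed loci get `r = NA`) and `group_means`
#'   (mean and SE of within-group pair r by population).
#' @export
pairwise_relatedness <- function(t) {
  n <- nrow(t$samples)
  if (n < 2L) stop_fmt("need >= 2 samples")
  f <- pooled_freqs(allele_frequencies(t, "all"))
  L <- nrow(t$loci)
  # per-individual per-locus: allele sizes and their pooled frequencies
  pa1 <- matrix(NA_real_, n, L); pa2 <- matrix(NA_real_, n, L)
  for (l in seq_len(L)) {
    pa1[, l] <- f[[l]][as.character(t$a1[, l])]
    pa2[, l] <- f[[l]][as.character(t$a2[, l])]
  }
  ids <- t$samples$id
  res <- matrix(NA_real_, n, n)
  nl <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    ax <- t$a1[i, ]; bx <- t$a2[i, ]
    for (j in (i + 1L):n) {
      ay <- t$a1[j, ]; by <- t$a2[j, ]
      ok <- !is.na(ax) & !is.na(ay)
      if (!any(ok)) next
      sxy <- 0.5 * ((ax == ay) + (ax == by) + (bx == ay) + (bx == by))
      num_x <- sxy[ok] - pa1[i, ok] - pa2[i, ok]
      den_x <- 1 + (ax == bx)[ok] - pa1[i, ok] - pa2[i, ok]
      num_y <- sxy[ok] - pa1[j, ok] - pa2[j, ok]
      den_y <- 1 + (ay == by)[ok] - pa1[j, ok] - pa2[j, ok]
      r_x <- sum(num_x) / sum(den_x)
      r_y <- sum(num_y) / sum(den_y)
      res[i, j] <- (r_x + r_y) / 2
      nl[i, j] <- sum(ok)
    }
  }
  ut <- which(upper.tri(res), arr.ind = TRUE)
  pairs <- data.frame(id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
                      r = res[ut], n_loci = nl[ut], stringsAsFactors = FALSE)
  pops <- t$samples$pop
  same <- pops[ut[, 1]] == pops[ut[, 2]]
  gm <- do.call(rbind, lapply(unique(pops), function(p) {
    v <- res[ut][same & pops[ut[, 1]] == p]
    v <- v[!is.na(v)]
    data.frame(group = p, n_pairs = length(v), mean_r = mean(v),
               se_r = stats::sd(v) / sqrt(length(v)), stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, group_means = gm)
}

#' Inbreeding coefficients with bootstrap confidence intervals
#'
#' Weir-Cockerham F_IS per group (and overall), with a percentile bootstrap
#' over loci for the 95% CI; plus a per-individual inbreeding proxy
#' `1 - (observed heterozygous loci) / (sum of group He over the
#' individual's typed loci)`.
#'
#' @param t a [genotype_table()].
#' @param grouping `"pop"` or `"locality"`.
#' @param n_boot bootstrap replicates over loci.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list with `groups` (data.frame group, fis, ci_lo, ci_hi) and
#'   `individuals` (data.frame id, group, fis).
#' @export
fis_with_ci <- function(t, grouping = c("pop", "locality"), n_boot = 1000L,
                        seed = 1L, conf = 0.95) {
  grouping <- match.arg(grouping)
  groups <- group_labels(t, grouping)
  gl <- c(unique(groups), ".overall")
  L <- nrow(t$loci)
  alpha <- (1 - conf) / 2
  fis_from <- function(comp, idx) {
    B <- sum(comp["b", idx], na.rm = TRUE); C <- sum(comp["c", idx], na.rm = TRUE)
    1 - C / (B + C)
  }
  rows <- list()
  for (g in gl) {
    grp <- if (g == ".overall") groups else {
      sel <- groups == g
      groups[sel]
    }
    tt <- if (g == ".overall") t else subset_genotypes(t, which(groups == g))
    comp <- wc_components(tt, if (g == ".overall") groups else
      rep("one", nrow(tt$samples)))
    est <- fis_from(comp, seq_len(L))
    ci <- c(NA_real_, NA_real_)
    if (L >= 2L) {
      boots <- with_seed(child_seed(seed, match(g, gl)), {
        vapply(seq_len(n_boot), function(b)
          fis_from(comp, sample.int(L, L, replace = TRUE)), 0)
      })
      ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, fis = est, ci_lo = ci[1], ci_hi = ci[2],
      stringsAsFactors = FALSE)
  }
  # per-individual proxy: shortfall of observed heterozygosity against the
  # Hardy-Weinberg expectation accumulated over that individual's typed loci
  f <- allele_frequencies(t, grouping)
  he_mat <- matrix(0, L, length(unique(groups)),
                   dimnames = list(t$loci$name, unique(groups)))
  for (l in seq_len(L)) for (g in unique(groups)) {
    p <- f$freq[[l]][[g]]
    he_mat[l, g] <- if (length(p)) 1 - sum(p^2) else NA_real_
  }
  ind <- vapply(seq_len(nrow(t$samples)), function(i) {
    typed <- !is.na(t$a1[i, ])
    if (!any(typed)) return(NA_real_)
    het <- sum(t$a1[i, typed] != t$a2[i, typed])
    exp_het <- sum(he_mat[typed, groups[i]])
    if (exp_het == 0) return(NA_real_)
    1 - het / exp_het
  }, 0)
  list(groups = do.call(rbind, rows),
       individuals = data.frame(id = t$samples$id, group = groups, fis = ind,
                                stringsAsFactors = FALSE))
}

#' Pairwise F_ST (Weir-Cockerham theta) with permutation p-values
#'
#' Theta for each group pair; significance by permuting individuals between
#' the two groups. A Holm-corrected p matrix is included. The default of 110
#' permutations mirrors common practice for small surveys; >= 999 is
#' recommended for publication-grade p-values.
#'
#' @param t a [genotype_table()].
#' @param grouping `"pop"` or `"locality"`.
#' @param n_perm permutations per pair.
#' @param seed integer seed.
#' @return list of symmetric matrices `theta`, `p`, `p_holm`, plus `n_perm`.
#' @export
pairwise_fst <- function(t, grouping = c("pop", "locality"), n_perm = 110L,
                         seed = 1L) {
  grouping <- match.arg(grouping)
  groups <- group_labels(t, grouping)
  gl <- unique(groups)
  k <- length(gl)
  if (k < 2L) stop_fmt("need >= 2 groups")
  theta <- matrix(NA_real_, k, k, dimnames = list(gl, gl))
  pmat <- theta
  diag(theta) <- 0
  theta_of <- function(sub_t, sub_groups) {
    comp <- wc_components(sub_t, sub_groups)
    sum(comp["a", ], na.rm = TRUE) / sum(comp, na.rm = TRUE)
  }
  pair_id <- 0L
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    pair_id <- pair_id + 1L
    sel <- groups %in% c(gl[i], gl[j])
    if (sum(groups == gl[i]) < 2L || sum(groups == gl[j]) < 2L) next
    tt <- subset_genotypes(t, which(sel))
    gg <- groups[sel]
    obs <- theta_of(tt, gg)
    theta[i, j] <- theta[j, i] <- obs
    hits <- with_seed(child_seed(seed, pair_id), {
      sum(vapply(seq_len(n_perm), function(p)
        theta_of(tt, sample(gg)) >= obs, NA))
    })
    pmat[i, j] <- pmat[j, i] <- (hits + 1) / (n_perm + 1)
  }
  ph <- pmat
  ut <- upper.tri(pmat)
  ph[ut] <- stats::p.adjust(pmat[ut], "holm")
  ph[lower.tri(ph)] <- t(ph)[lower.tri(ph)]
  list(theta = theta, p = pmat, p_holm = ph, n_perm = n_perm)
}

#' Pairwise R_ST (allele-size variance differentiation)
#'
#' Slatkin-style R_ST from a one-way ANOVA on gene-copy allele sizes in
#' repeat units: per locus, `sigma2_a = (MSB - MSW)/n0` among groups and
#' `sigma2_w = MSW` within; `R_ST = sum(sigma2_a) / sum(sigma2_a + sigma2_w)`
#' over loci. Invariant to rescaling the sizes.
#'
#' @param t a [genotype_table()] whose loci carry `repeat_unit_bp`.
#' @param grouping `"pop"` or `"locality"`.
#' @return Symmetric matrix of pairwise R_ST (diagonal 0).
#' @export
pairwise_rst <- function(t, grouping = c("pop", "locality")) {
  grouping <- match.arg(grouping)
  if (any(is.na(t$loci$repeat_unit_bp)))
    stop_fmt("repeat_unit_bp metadata required for R_ST")
  groups <- group_labels(t, grouping)
  gl <- unique(groups)
  k <- length(gl)
  if (k < 2L) stop_fmt("need >= 2 groups")
  rst_pair <- function(g1, g2) {
    num <- 0; den <- 0
    for (l in seq_len(nrow(t$loci))) {
      unit <- t$loci$repeat_unit_bp[l]
      vals <- list()
      for (g in c(g1, g2)) {
        rows <- which(groups == g)
        x <- c(t$a1[rows, l], t$a2[rows, l]) / unit
        vals[[g]] <- x[!is.na(x)]
      }
      n_i <- lengths(vals)
      if (any(n_i < 2L)) next
      N <- sum(n_i)
      means <- vapply(vals, mean, 0)
      gm <- sum(unlist(vals)) / N
      ssb <- sum(n_i * (means - gm)^2)
      ssw <- sum(vapply(vals, function(v) sum((v - mean(v))^2), 0))
      msb <- ssb / 1           # r - 1 = 1 for a pair
      msw <- ssw / (N - 2)
      n0 <- (N - sum(n_i^2) / N) / 1
      s2a <- (msb - msw) / n0
      num <- num + s2a
      den <- den + s2a + msw
    }
    if (den == 0) return(NA_real_)
    num / den
  }
  m <- matrix(0, k, k, dimnames = list(gl, gl))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    m[i, j] <- m[j, i] <- rst_pair(gl[i], gl[j])
  m
}

#' Nei's (1972) standard genetic distance
#'
#' `D = -ln I` with `I = sum_loci sum_a p1 p2 /
#' sqrt(sum_loci sum_a p1^2 * sum_loci sum_a p2^2)`; disjoint allele sets
#' give `D = Inf`.
#'
#' @param f an `allele_freq_table` from [allele_frequencies()].
#' @return Symmetric matrix of D between groups (diagonal 0).
#' @export
nei_distance <- function(f) {
  stopifnot(inherits(f, "allele_freq_table"))
  gl <- f$groups
  k <- length(gl)
  m <- matrix(0, k, k, dimnames = list(gl, gl))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    jxy <- 0; jx <- 0; jy <- 0
    shared <- 0L
    for (l in seq_along(f$loci)) {
      p1 <- f$freq[[l]][[gl[i]]]; p2 <- f$freq[[l]][[gl[j]]]
      if (!length(p1) || !length(p2)) next
      shared <- shared + 1L
      common <- intersect(names(p1), names(p2))
      jxy <- jxy + sum(p1[common] * p2[common])
      jx <- jx + sum(p1^2); jy <- jy + sum(p2^2)
    }
    if (!shared) stop_fmt("groups %s and %s share no typed loci", gl[i], gl[j])
    I <- jxy / sqrt(jx * jy)
    m[i, j] <- m[j, i] <- if (I <= 0) Inf else -log(I)
  }
  m
}

#' Three-level AMOVA for codominant genotypes
#'
#' Hierarchical partition of molecular variance among populations, among
#' individuals within populations, and within individuals, computed per
#' locus on gene copies with the allele-mismatch distance (0/1 per copy
#' pair) and summed over loci. Percentages truncate negative components to
#' zero (raw components are retained); Phi statistics come from the raw
#' components.
#'
#' @param t a [genotype_table()].
#' @param grouping `"pop"` or `"locality"`.
#' @return list with `components` (raw variance components), `percent`,
#'   `phi` (`phi_st`, `phi_is`, `phi_it`), and the df used.
#' @export
amova <- function(t, grouping = c("pop", "locality")) {
  grouping <- match.arg(grouping)
  groups <- group_labels(t, grouping)
  gl <- unique(groups)
  if (length(gl) < 2L) stop_fmt("need >= 2 groups")
  if (any(table(groups) < 2L)) stop_fmt("every group needs >= 2 individuals")
  sig <- c(a = 0, b = 0, c = 0)
  for (l in seq_len(nrow(t$loci))) {
    typed <- !is.na(t$a1[, l])
    if (sum(typed) < 3L) next
    g <- groups[typed]
    if (length(unique(g)) < 2L) next
    a1 <- t$a1[typed, l]; a2 <- t$a2[typed, l]
    n_ind <- length(a1)
    copies <- c(a1, a2)
    cop_g <- c(g, g)
    N <- length(copies)
    P <- length(unique(g))
    ss_pairs <- function(v) {  # sum over pairs of the 0/1 mismatch distance
      n <- length(v)
      choose(n, 2) - sum(choose(table(v), 2))
    }
    ss_tot <- ss_pairs(copies) / N
    ss_wp <- sum(vapply(unique(g), function(gg) {
      v <- copies[cop_g == gg]
      ss_pairs(v) / length(v)
    }, 0))
    ss_wi <- 0.5 * sum(a1 != a2)
    ss_ai <- ss_wp - ss_wi
    ss_ap <- ss_tot - ss_wp
    n_p <- as.numeric(table(g)) * 2   # copies per population
    df_a <- P - 1; df_b <- n_ind - P; df_c <- n_ind
    ms_a <- ss_ap / df_a; ms_b <- ss_ai / df_b; ms_c <- ss_wi / df_c
    nc <- (N - sum(n_p^2) / N) / df_a
    s_c <- ms_c
    s_b <- (ms_b - s_c) / 2
    s_a <- (ms_a - ms_b) / nc
    sig <- sig + c(s_a, s_b, s_c)
  }
  total <- sum(sig)
  trunc <- pmax(sig, 0)
  pct <- 100 * trunc / sum(trunc)
  names(pct) <- names(sig) <- c("among_populations",
                                "among_individuals_within_populations",
                                "within_individuals")
  list(components = sig, percent = pct,
       phi = c(phi_st = (sig[[1]]) / total,
               phi_is = sig[[2]] / (sig[[2]] + sig[[3]]),
               phi_it = (sig[[1]] + sig[[2]]) / total),
       total = total)
}

#' Genotypic linkage-disequilibrium test for a locus pair
#'
#' G-statistic on the two-locus genotype contingency table, with
#' significance from permuting one locus's genotypes among individuals
#' within each group.
#'
#' @param t a [genotype_table()].
#' @param grouping `"pop"`, `"locality"`, or `"all"` (pooled).
#' @param loci character vector of two locus names.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param min_n minimum complete cases per group (default 5).
#' @return Named numeric vector of p-values per group (`NA` with a warning
#'   when a group has too few complete cases).
#' @export
genotypic_ld_test <- function(t, grouping = c("pop", "locality", "all"), loci,
                              n_perm = 1000L, seed = 1L, min_n = 5L) {
  grouping <- match.arg(grouping)
  if (length(loci) != 2L) stop_fmt("loci must name exactly two loci")
  idx <- match(loci, t$loci$name)
  if (anyNA(idx)) stop_fmt("unknown locus: %s", paste(loci[is.na(idx)], collapse = ", "))
  groups <- if (grouping == "all") rep("all", nrow(t$samples)) else
    group_labels(t, grouping)
  codes <- genotype_codes(t)[, idx, drop = FALSE]
  g_stat <- function(x, y) {
    tab <- table(x, y)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    keep <- tab > 0
    2 * sum(tab[keep] * log(tab[keep] / E[keep]))
  }
  gl <- unique(groups)
  out <- stats::setNames(rep(NA_real_, length(gl)), gl)
  for (g in gl) {
    rows <- which(groups == g)
    x <- codes[rows, 1]; y <- codes[rows, 2]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_n) {
      warning(sprintf("group %s: only %d complete cases at %s x %s",
                      g, sum(ok), loci[1], loci[2]))
      next
    }
    x <- x[ok]; y <- y[ok]
    obs <- g_stat(x, y)
    hits <- with_seed(child_seed(seed, match(g, gl)), {
      sum(vapply(seq_len(n_perm), function(p)
        g_stat(x, sample(y)) >= obs - 1e-12, NA))
    })
    out[g] <- (hits + 1) / (n_perm + 1)
  }
  out
}
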