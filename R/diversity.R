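#' Allele frequencies per locus and group
#'
#' Frequencies use pairwise deletion: a sample missing at a locus is dropped
#' from that locus's denominator only. `p_i = count_i / (2 * n_typed)`.
#'
#' @param t a [genotype_table()].
#' @param grouping `"pop"` (breed), `"locality"`, or `"all"` (one pooled
#'   group named `"all"`).
#' @return An object of class `allele_freq_table`: `freq[[locus]][[group]]`
#'   is a named numeric vector (names = allele sizes in bp) summing to 1,
#'   and `n_typed` is a loci x groups matrix of non-missing diploid counts.
#' @export
allele_frequencies <- function(t, grouping = c("pop", "locality", "all")) {
  grouping <- match.arg(grouping)
  if (!nrow(t$samples)) stop_fmt("empty genotype table")
  groups <- if (grouping == "all") rep("all", nrow(t$samples)) else
    group_labels(t, grouping)
  gl <- unique(groups)
  L <- nrow(t$loci)
  freq <- vector("list", L); names(freq) <- t$loci$name
  n_typed <- matrix(0L, L, length(gl), dimnames = list(t$loci$name, gl))
  for (l in seq_len(L)) {
    freq[[l]] <- vector("list", length(gl)); names(freq[[l]]) <- gl
    for (g in seq_along(gl)) {
      rows <- which(groups == gl[g])
      alleles <- c(t$a1[rows, l], t$a2[rows, l])
      alleles <- alleles[!is.na(alleles)]
      n_typed[l, g] <- length(alleles) %/% 2L
      if (length(alleles)) {
        tab <- table(alleles)
        p <- as.numeric(tab) / length(alleles)
        names(p) <- names(tab)
        freq[[l]][[g]] <- p[order(as.integer(names(p)))]
      } else {
        freq[[l]][[g]] <- numeric(0)   # group untyped at this locus
      }
    }
  }
  structure(list(loci = t$loci$name, groups = gl, grouping = grouping,
                 freq = freq, n_typed = n_typed),
            class = "allele_freq_table")
}

# Pooled frequency list (one named vector per locus) from an allele_freq_table,
# weighting each group's frequencies by its typed gene copies.
pooled_freqs <- function(f) {
  stopifnot(inherits(f, "allele_freq_table"))
  out <- vector("list", length(f$loci)); names(out) <- f$loci
  for (l in seq_along(f$loci)) {
    byg <- f$freq[[l]]
    all_alleles <- sort(unique(as.integer(unlist(lapply(byg, names)))))
    if (!length(all_alleles)) { out[[l]] <- numeric(0); next }
    tot <- stats::setNames(numeric(length(all_alleles)), all_alleles)
    for (g in names(byg)) {
      p <- byg[[g]]
      if (!length(p)) next
      tot[names(p)] <- tot[names(p)] + p * 2 * f$n_typed[l, g]
    }
    out[[l]] <- tot / sum(tot)
  }
  out
}

# Observed heterozygosity per locus x group.
observed_het <- function(t, groups) {
  gl <- unique(groups)
  ho <- matrix(NA_real_, nrow(t$loci), length(gl),
               dimnames = list(t$loci$name, gl))
  for (l in seq_len(nrow(t$loci))) for (g in seq_along(gl)) {
    rows <- which(groups == gl[g])
    a1 <- t$a1[rows, l]; a2 <- t$a2[rows, l]
    ok <- !is.na(a1)
    if (any(ok)) ho[l, g] <- mean(a1[ok] != a2[ok])
  }
  ho
}

#' Rarefied allelic richness
#'
#' FSTAT-style rarefaction to a common depth of `g` gene copies:
#' `AR_g = sum_a [1 - choose(2n - N_a, g) / choose(2n, g)]`, where `N_a` is
#' the count of allele `a` among the `2n` typed copies.
#'
#' @param t a [genotype_table()].
#' @param grouping `"pop"` or `"locality"`.
#' @param g rarefaction depth in gene copies; default is, per locus, the
#'   smallest `2 * n_typed` over groups.
#' @return data.frame with columns `locus`, `group`, `g`, `AR`.
#' @export
allelic_richness <- function(t, grouping = c("pop", "locality"), g = NULL) {
  grouping <- match.arg(grouping)
  groups <- group_labels(t, grouping)
  f <- allele_frequencies(t, grouping)
  out <- list()
  for (l in seq_along(f$loci)) {
    depth <- if (is.null(g)) 2L * min(f$n_typed[l, ]) else as.integer(g)
    for (gi in seq_along(f$groups)) {
      n2 <- 2L * f$n_typed[l, gi]
      if (depth > n2)
        stop_fmt("rarefaction depth %d exceeds 2n = %d at locus %s, group %s",
                 depth, n2, f$loci[l], f$groups[gi])
      p <- f$freq[[l]][[gi]]
      counts <- round(p * n2)
      ar <- sum(1 - exp(lchoose(n2 - counts, depth) - lchoose(n2, depth)))
      out[[length(out) + 1L]] <- data.frame(
        locus = f$loci[l], group = f$groups[gi], g = depth, AR = ar,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Null-allele frequency estimate (Brookfield / Chakraborty)
#'
#' Brookfield's estimator 1, `r = (He - Ho) / (1 + He)`, truncated at zero;
#' Chakraborty's `r = (He - Ho) / (He + Ho)` behind a flag.
#'
#' @param ho,he observed and expected heterozygosity (vectorized).
#' @param method `"brookfield1"` (default) or `"chakraborty"`.
#' @return Estimated null-allele frequency, truncated at 0.
#' @export
null_allele_estimate <- function(ho, he, method = c("brookfield1", "chakraborty")) {
  method <- match.arg(method)
  r <- if (method == "brookfield1") (he - ho) / (1 + he) else
    (he - ho) / (he + ho)
  pmax(r, 0)
}

#' M-ratio bottleneck diagnostic
#'
#' `M = k / (r + 1)` with `k` the number of distinct alleles and `r` the
#' allele-size range in repeat units; values below 0.68 flag a past
#' bottleneck. Sizes off the repeat-unit grid trigger a warning and `r` is
#' rounded.
#'
#' @param t a [genotype_table()].
#' @param grouping `"pop"`, `"locality"`, or `"all"`.
#' @param loci optional locus names (default all).
#' @param threshold bottleneck flag threshold (default 0.68).
#' @return data.frame with columns `locus`, `group`, `k`, `r`, `M`,
#'   `bottleneck`.
#' @export
m_ratio <- function(t, grouping = c("pop", "locality", "all"), loci = NULL,
                    threshold = 0.68) {
  grouping <- match.arg(grouping)
  f <- allele_frequencies(t, grouping)
  loci <- loci %||% f$loci
  out <- list()
  for (ln in loci) {
    l <- match(ln, f$loci)
    if (is.na(l)) stop_fmt("unknown locus %s", ln)
    unit <- t$loci$repeat_unit_bp[match(ln, t$loci$name)]
    for (gi in seq_along(f$groups)) {
      p <- f$freq[[l]][[gi]]
      if (!length(p)) next
      sizes <- as.integer(names(p))
      span <- max(sizes) - min(sizes)
      if (span %% unit != 0L)
        warning(sprintf("locus %s: allele sizes not on the %d-bp repeat grid",
                        ln, unit))
      r <- round(span / unit)
      M <- length(sizes) / (r + 1)
      out[[length(out) + 1L]] <- data.frame(
        locus = ln, group = f$groups[gi], k = length(sizes), r = r, M = M,
        bottleneck = M < threshold, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# ------------------------------------------------------ Hardy-Weinberg exact

# log-probability of a genotype configuration conditional on allele counts
# (Levene 1949): P = n! * prod(n_i!) * 2^H / ((2n)! * prod(f_ij!)).
hwe_log_prob <- function(n, allele_counts, het_total, log_fact_genotypes) {
  lfactorial(n) + sum(lfactorial(allele_counts)) + het_total * log(2) -
    lfactorial(2 * n) - log_fact_genotypes
}

# Cheap upper bound on the number of heterozygote-count tables consistent
# with the allele counts (product over allele pairs of the per-pair range).
hwe_config_bound <- function(allele_counts) {
  k <- length(allele_counts)
  if (k < 2L) return(1)
  bound <- 1
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    bound <- bound * (min(allele_counts[i], allele_counts[j]) + 1)
    if (bound > 1e15) return(bound)
  }
  bound
}

# Enumerate heterozygote-count tables consistent with allele counts; calls
# `visit(log_prob)` for each configuration. Returns FALSE if the
# configuration space exceeds `max_configs`.
hwe_enumerate <- function(allele_counts, max_configs, visit) {
  k <- length(allele_counts)
  n <- sum(allele_counts) / 2
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  n_pairs <- nrow(pairs)
  h <- integer(n_pairs)
  count <- 0L
  rec <- function(idx, rem) {
    if (count > max_configs) return(FALSE)
    if (idx > n_pairs) {
      if (any(rem %% 2L != 0L)) return(TRUE)
      f_hom <- rem %/% 2L
      count <<- count + 1L
      lfg <- sum(lfactorial(h)) + sum(lfactorial(f_hom))
      visit(hwe_log_prob(n, allele_counts, sum(h), lfg))
      return(TRUE)
    }
    i <- pairs[idx, 1]; j <- pairs[idx, 2]
    hmax <- min(rem[i], rem[j])
    for (x in 0:hmax) {
      h[idx] <<- x
      rem2 <- rem; rem2[i] <- rem2[i] - x; rem2[j] <- rem2[j] - x
      if (!rec(idx + 1L, rem2)) return(FALSE)
    }
    h[idx] <<- 0L
    TRUE
  }
  rec(1L, allele_counts)
}

# log-prob of the observed sample's genotype table given its allele counts.
hwe_obs_log_prob <- function(a1, a2) {
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  allele_counts <- table(c(a1, a2))
  geno <- table(paste(a1, a2))
  hwe_log_prob(n, as.integer(allele_counts), sum(a1 != a2),
               sum(lfactorial(as.integer(geno))))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on genotype configurations given allele counts
#' (Levene probabilities): `p` is the total probability of configurations no
#' more probable than the observed one. Full enumeration is used when the
#' configuration space is small; otherwise Guo-Thompson-style Monte Carlo
#' (random re-pairings of the observed gene copies, which samples the
#' conditional distribution exactly).
#'
#' @param t a [genotype_table()].
#' @param grouping `"pop"`, `"locality"`, or `"all"`.
#' @param locus locus name.
#' @param method `"auto"` (enumerate when feasible), `"enumeration"`, or
#'   `"monte_carlo"`.
#' @param reps Monte Carlo replicates.
#' @param seed seed for the Monte Carlo path.
#' @param max_configs enumeration cap on the configuration count.
#' @return Named numeric vector of p-values, one per group (monomorphic
#'   groups give `p = 1` by convention).
#' @export
hwe_exact_test <- function(t, grouping = c("pop", "locality", "all"), locus,
                           method = c("auto", "enumeration", "monte_carlo"),
                           reps = 1e5, seed = 1L, max_configs = 1e6) {
  grouping <- match.arg(grouping)
  method <- match.arg(method)
  l <- match(locus, t$loci$name)
  if (is.na(l)) stop_fmt("unknown locus %s", locus)
  groups <- if (grouping == "all") rep("all", nrow(t$samples)) else
    group_labels(t, grouping)
  gl <- unique(groups)
  p_out <- setNames(rep(NA_real_, length(gl)), gl)
  for (g in gl) {
    rows <- which(groups == g)
    a1 <- t$a1[rows, l]; a2 <- t$a2[rows, l]
    ok <- !is.na(a1)
    a1 <- a1[ok]; a2 <- a2[ok]
    if (length(a1) < 2L) { p_out[g] <- NA_real_; next }
    alleles <- sort(unique(c(a1, a2)))
    if (length(alleles) < 2L) { p_out[g] <- 1; next }
    obs_lp <- hwe_obs_log_prob(a1, a2)
    allele_counts <- as.integer(table(c(a1, a2)))
    tol <- 1e-9
    p <- NA_real_
    feasible <- hwe_config_bound(allele_counts) <= max_configs
    if (method == "enumeration" && !feasible)
      stop_fmt("configuration space exceeds %g at locus %s", max_configs, locus)
    if (method != "monte_carlo" && feasible) {
      acc <- 0; total <- 0
      complete <- hwe_enumerate(
        allele_counts, max_configs,
        function(lp) {
          total <<- total + exp(lp)
          if (lp <= obs_lp + tol) acc <<- acc + exp(lp)
        })
      if (complete) p <- min(acc / total, 1)  # total == 1 up to rounding
      else if (method == "enumeration")
        stop_fmt("configuration space exceeds %g at locus %s", max_configs, locus)
    }
    if (is.na(p)) {
      # Monte Carlo: random re-pairings of the observed gene copies sample
      # the Levene conditional distribution exactly. Only the
      # configuration-dependent part of the log-probability is needed.
      k <- length(allele_counts)
      copies <- match(c(a1, a2), sort(unique(c(a1, a2))))
      n <- length(a1)
      geno_obs <- table(paste(pmin(copies[1:n], copies[n + 1:n]),
                              pmax(copies[1:n], copies[n + 1:n])))
      obs_var <- sum(a1 != a2) * log(2) - sum(lfactorial(as.integer(geno_obs)))
      nbins <- k * (k + 1L)
      p <- with_seed(child_seed(seed, match(g, gl)), {
        hits <- 0L
        for (r in seq_len(reps)) {
          perm <- sample(copies)
          b1 <- perm[seq_len(n)]; b2 <- perm[n + seq_len(n)]
          lo <- pmin(b1, b2); hi <- pmax(b1, b2)
          cnt <- tabulate((lo - 1L) * (k + 1L) + hi, nbins = nbins)
          lp <- sum(lo != hi) * log(2) - sum(lfactorial(cnt[cnt > 1L]))
          if (lp <= obs_var + tol) hits <- hits + 1L
        }
        (hits + 1) / (reps + 1)
      })
    }
    p_out[g] <- p
  }
  p_out
}

# ------------------------------------------------------------- locus summary

#' Per-locus, per-group diversity summary
#'
#' One row per locus x group with: `n_typed`, allele count `Na`, effective
#' allele count `Nea = 1/sum(p^2)`, rarefied allelic richness `AR`,
#' Shannon's information index `I = -sum(p log p)`, observed heterozygosity
#' `Ho`, expected heterozygosity `He = 1 - sum(p^2)` plus the unbiased
#' `uHe = 2n/(2n-1) * He`, polymorphic information content
#' `PIC = 1 - sum(p^2) - [ (sum p^2)^2 - sum p^4 ]`, fixation index
#' `F = 1 - Ho/He` (`NA` when `He = 0`), a Hardy-Weinberg exact-test p-value
#' with a Holm-corrected column, the Brookfield null-allele estimate, and
#' the M-ratio.
#'
#' @param t a [genotype_table()].
#' @param grouping `"pop"`, `"locality"`, or `"all"`.
#' @param rarefy_g rarefaction depth (default per-locus minimum `2n`).
#' @param hwe_reps,seed Monte Carlo settings for the HWE test.
#' @return data.frame of class `locus_summary`.
#' @export
locus_summary <- function(t, grouping = c("pop", "locality", "all"),
                          rarefy_g = NULL, hwe_reps = 1e4, seed = 1L) {
  grouping <- match.arg(grouping)
  f <- allele_frequencies(t, grouping)
  groups <- if (grouping == "all") rep("all", nrow(t$samples)) else
    group_labels(t, grouping)
  ho <- observed_het(t, groups)
  ar <- if (grouping == "all")
    allelic_richness_from_freq(f, rarefy_g) else {
      a <- allelic_richness(t, grouping, rarefy_g)
      a
    }
  mr <- m_ratio(t, grouping)
  rows <- list()
  for (l in seq_along(f$loci)) for (g in seq_along(f$groups)) {
    p <- f$freq[[l]][[g]]
    n <- f$n_typed[l, g]
    if (!length(p)) next
    a2 <- power_sum(p, 2); a4 <- power_sum(p, 4)
    he <- 1 - a2
    uhe <- if (n > 0) 2 * n / (2 * n - 1) * he else NA_real_
    pic <- 1 - a2 - (a2^2 - a4)
    hob <- ho[l, g]
    rows[[length(rows) + 1L]] <- data.frame(
      locus = f$loci[l], group = f$groups[g], n_typed = n,
      Na = length(p), Nea = 1 / a2,
      AR = ar$AR[ar$locus == f$loci[l] & ar$group == f$groups[g]],
      I = -sum(p * log(p)), Ho = hob, He = he, uHe = uhe, PIC = pic,
      F = if (he > 0) 1 - hob / he else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$hwe_p <- NA_real_
  for (ln in unique(out$locus)) {
    pv <- hwe_exact_test(t, grouping, ln, method = "auto",
                         reps = hwe_reps,
                         seed = child_seed(seed, match(ln, f$loci)))
    sel <- out$locus == ln
    out$hwe_p[sel] <- pv[out$group[sel]]
  }
  out$hwe_p_holm <- NA_real_
  ok <- !is.na(out$hwe_p)
  out$hwe_p_holm[ok] <- stats::p.adjust(out$hwe_p[ok], "holm")
  out$null_freq <- null_allele_estimate(out$Ho, out$He)
  out$m_ratio <- mr$M[match(paste(out$locus, out$group),
                            paste(mr$locus, mr$group))]
  class(out) <- c("locus_summary", class(out))
  out
}

# Rarefied richness when grouping == "all" (single pooled group).
allelic_richness_from_freq <- function(f, g = NULL) {
  out <- list()
  for (l in seq_along(f$loci)) {
    n2 <- 2L * f$n_typed[l, 1]
    depth <- if (is.null(g)) n2 else as.integer(g)
    p <- f$freq[[l]][[1]]
    counts <- round(p * n2)
    ar <- sum(1 - exp(lchoose(n2 - counts, depth) - lchoose(n2, depth)))
    out[[l]] <- data.frame(locus = f$loci[l], group = f$groups[1], g = depth,
                           AR = ar, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Welch's t-test between observed and expected heterozygosity
#'
#' Treats the per-locus `Ho` and `He` vectors of one group as independent
#' samples (unequal variances, Welch-Satterthwaite df).
#'
#' @param summary a [locus_summary()] data.frame.
#' @param group group label to test (default: first).
#' @return list with `t`, `df`, `p`, and the two means.
#' @export
welch_ho_he <- function(summary, group = NULL) {
  group <- group %||% summary$group[1]
  s <- summary[summary$group == group, ]
  if (nrow(s) < 2L) stop_fmt("need >= 2 loci for Welch's t-test")
  if (stats::sd(s$Ho) == 0 && stats::sd(s$He) == 0)
    stop_fmt("zero variance in both Ho and He; test undefined")
  tt <- stats::t.test(s$Ho, s$He, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_ho = mean(s$Ho), mean_he = mean(s$He))
}
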