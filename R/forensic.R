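#' Per-locus identification and parentage statistics
#'
#' Evaluates, from allele frequencies `p_i` (power sums `a_k = sum(p_i^k)`):
#'
#' * `PID_theoretical = 2 a2^2 - a4` — probability two random individuals in
#'   a randomly mating population share a genotype at the locus;
#' * `PID_unbiased` — the small-sample-corrected form
#'   `[n^3 (2 a2^2 - a4) - 2 n^2 (a3 + 2 a2) + n (9 a2 + 2) - 6] /
#'   [(n-1)(n-2)(n-3)]` (`NA` when `n < 4`);
#' * `PID_sibs = 0.25 + 0.5 a2 + 0.5 a2^2 - 0.25 a4` — probability two full
#'   siblings share a genotype;
#' * `PE = 1 + 4 a4 - 4 a5 - 3 a6 - 8 a2^2 + 8 a2 a3 + 2 a3^2` — probability
#'   the locus excludes a non-parental pair of putative parents;
#' * `MP` — the per-locus random-match probability. The default
#'   (`mp_formula = "standard"`) is the sum of squared Hardy-Weinberg
#'   genotype frequencies, which is algebraically `PID_theoretical`; the
#'   literal product form `prod(p_i^2) * prod(2 p_i p_j)` is available for
#'   auditability but collapses toward zero on polymorphic loci.
#'
#' @param f an `allele_freq_table` from [allele_frequencies()], or a named
#'   list of frequency vectors.
#' @param group group label within `f` (default the first; use
#'   `allele_frequencies(t, "all")` for pooled statistics).
#' @param n sample size used by the unbiased correction; defaults to the
#'   per-locus `n_typed` of the chosen group.
#' @param mp_formula `"standard"` or `"literal"` (see above).
#' @return data.frame of class `id_stats` with one row per locus:
#'   `locus`, `n`, `MP`, `PID_theoretical`, `PID_unbiased`, `PID_sibs`, `PE`.
#' @export
per_locus_id_stats <- function(f, group = NULL, n = NULL,
                               mp_formula = c("standard", "literal")) {
  mp_formula <- match.arg(mp_formula)
  if (inherits(f, "allele_freq_table")) {
    group <- group %||% f$groups[1]
    freqs <- lapply(f$freq, `[[`, group)
    if (is.null(n)) n <- f$n_typed[, group]
  } else {
    freqs <- f
    if (is.null(n)) stop_fmt("n must be given with a raw frequency list")
  }
  n <- rep_len(n, length(freqs))
  rows <- lapply(seq_along(freqs), function(i) {
    p <- freqs[[i]]
    if (!length(p)) return(NULL)
    a2 <- power_sum(p, 2); a3 <- power_sum(p, 3); a4 <- power_sum(p, 4)
    a5 <- power_sum(p, 5); a6 <- power_sum(p, 6)
    pid_t <- 2 * a2^2 - a4
    pid_u <- if (n[i] >= 4) {
      nn <- n[i]
      (nn^3 * (2 * a2^2 - a4) - 2 * nn^2 * (a3 + 2 * a2) +
         nn * (9 * a2 + 2) - 6) / ((nn - 1) * (nn - 2) * (nn - 3))
    } else NA_real_
    pid_s <- 0.25 + 0.5 * a2 + 0.5 * a2^2 - 0.25 * a4
    pe <- 1 + 4 * a4 - 4 * a5 - 3 * a6 - 8 * a2^2 + 8 * a2 * a3 + 2 * a3^2
    mp <- if (mp_formula == "standard") pid_t else {
      het <- outer(p, p)[upper.tri(outer(p, p))]
      prod(p^2) * prod(2 * het)
    }
    data.frame(locus = names(freqs)[i] %||% paste0("L", i), n = n[i],
               MP = mp, PID_theoretical = pid_t, PID_unbiased = pid_u,
               PID_sibs = pid_s, PE = pe, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("id_stats", class(out))
  out
}

#' Combine per-locus identification statistics over a panel
#'
#' `MP` and the three `PID` variants multiply across loci; exclusion power
#' combines as `PE = 1 - prod(1 - PE_locus)`.
#'
#' @param stats an `id_stats` data.frame from [per_locus_id_stats()].
#' @param loci locus names to combine (default all).
#' @return One-row data.frame with `locus = "combined"`.
#' @export
combine_panel <- function(stats, loci = NULL) {
  loci <- loci %||% stats$locus
  idx <- match(loci, stats$locus)
  if (anyNA(idx)) stop_fmt("no statistics for loci: %s",
                           paste(loci[is.na(idx)], collapse = ", "))
  s <- stats[idx, ]
  data.frame(locus = "combined", n = min(s$n),
             MP = prod(s$MP),
             PID_theoretical = prod(s$PID_theoretical),
             PID_unbiased = prod(s$PID_unbiased),
             PID_sibs = prod(s$PID_sibs),
             PE = 1 - prod(1 - s$PE), stringsAsFactors = FALSE)
}

# Integer genotype codes per sample x locus (NA = missing); equal codes at a
# locus mean identical unordered genotypes.
genotype_codes <- function(t) {
  n <- nrow(t$samples); L <- nrow(t$loci)
  codes <- matrix(NA_integer_, n, L, dimnames = dimnames(t$a1))
  for (l in seq_len(L)) {
    key <- paste(t$a1[, l], t$a2[, l])
    key[is.na(t$a1[, l])] <- NA
    codes[, l] <- match(key, unique(key[!is.na(key)]))
  }
  codes
}

# Percent of distinct multilocus genotypes among the individuals completely
# typed at a locus subset (100 = every individual distinguishable).
percent_distinguished <- function(codes, subset_idx) {
  sub <- codes[, subset_idx, drop = FALSE]
  complete <- !rowSums(is.na(sub))
  if (!any(complete)) return(NA_real_)
  sub <- sub[complete, , drop = FALSE]
  key <- do.call(paste, c(as.data.frame(sub), sep = "\r"))
  100 * length(unique(key)) / length(key)
}

#' Genotype accumulation curve
#'
#' For each panel size `s = 1 .. L-1`, draws `reps` random locus subsets and
#' reports the mean (and SD) percentage of individuals whose multilocus
#' genotype is unique among the individuals completely typed at the subset.
#' Mirrors the locus-dropout resampling used to judge how many markers are
#' needed to distinguish all individuals.
#'
#' @param t a [genotype_table()].
#' @param reps random subsets per size.
#' @param seed integer seed.
#' @param drop_missing if `TRUE` (default) individuals missing at a subset
#'   locus are dropped for that subset; if `FALSE` missing genotypes match
#'   anything (wildcard), which lowers the curve.
#' @return data.frame with `size`, `mean_pct`, `sd_pct`, `reps`.
#' @export
genotype_accumulation <- function(t, reps = 1000L, seed = 1L,
                                  drop_missing = TRUE) {
  L <- nrow(t$loci)
  if (L < 2L) stop_fmt("need >= 2 loci")
  if (reps < 1L) stop_fmt("reps must be >= 1")
  codes <- genotype_codes(t)
  eval_subset <- function(idx) {
    if (drop_missing) return(percent_distinguished(codes, idx))
    sub <- codes[, idx, drop = FALSE]
    n <- nrow(sub)
    uniq <- vapply(seq_len(n), function(i) {
      m <- sub == matrix(sub[i, ], n, length(idx), byrow = TRUE)
      m[is.na(m)] <- TRUE  # wildcard semantics
      sum(rowSums(m) == length(idx)) == 1L
    }, NA)
    100 * mean(uniq)
  }
  with_seed(seed, {
    out <- lapply(seq_len(L - 1L), function(s) {
      pct <- vapply(seq_len(reps), function(r)
        eval_subset(sample.int(L, s)), 0)
      data.frame(size = s, mean_pct = mean(pct, na.rm = TRUE),
                 sd_pct = stats::sd(pct), reps = reps)
    })
    do.call(rbind, out)
  })
}

#' Loci needed to reach sibling-identity thresholds
#'
#' Orders loci by expected heterozygosity (descending or ascending),
#' accumulates the product of per-locus `PID_sibs` in that order, and
#' reports the smallest panel size whose cumulative product falls at or
#' below each threshold (`NA` = not reached with all loci). He ties break
#' by locus name.
#'
#' @param stats an `id_stats` data.frame from [per_locus_id_stats()].
#' @param he named per-locus expected heterozygosity (names = loci).
#' @param order `"descending"` (most informative first) or `"ascending"`.
#' @param thresholds probability thresholds (default the 0.01/0.001/0.0001
#'   working range used for individual identification).
#' @return list with `order` (loci in the order used), `cumulative`
#'   (cumulative `PID_sibs` products) and `loci_needed` (named integer per
#'   threshold, `NA` when not reached).
#' @export
pid_sibs_locus_curve <- function(stats, he, order = c("descending", "ascending"),
                                 thresholds = c(0.01, 0.001, 0.0001)) {
  order <- match.arg(order)
  he <- he[stats$locus]
  ord <- order(if (order == "descending") -he else he, stats$locus)
  s <- stats[ord, ]
  cum <- cumprod(s$PID_sibs)
  needed <- vapply(thresholds, function(th) {
    k <- which(cum <= th)[1]
    if (is.na(k)) NA_integer_ else as.integer(k)
  }, 0L)
  names(needed) <- format(thresholds, scientific = FALSE, trim = TRUE)
  list(order = s$locus, cumulative = cum, loci_needed = needed)
}

#' Report sample pairs with matching multilocus genotypes
#'
#' Pairs match when their genotypes are identical at every panel locus where
#' both are typed; pairs with no mutually typed panel locus are excluded
#' (with a warning).
#'
#' @param t a [genotype_table()].
#' @param panel locus names (default all).
#' @return data.frame with `id1`, `id2`, `n_loci_compared`.
#' @export
match_report <- function(t, panel = NULL) {
  panel <- panel %||% t$loci$name
  idx <- match(panel, t$loci$name)
  if (anyNA(idx)) stop_fmt("unknown panel loci: %s",
                           paste(panel[is.na(idx)], collapse = ", "))
  codes <- genotype_codes(t)[, idx, drop = FALSE]
  n <- nrow(codes)
  out <- list(); skipped <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- !is.na(codes[i, ]) & !is.na(codes[j, ])
    if (!any(both)) { skipped <- skipped + 1L; next }
    if (all(codes[i, both] == codes[j, both]))
      out[[length(out) + 1L]] <- data.frame(
        id1 = t$samples$id[i], id2 = t$samples$id[j],
        n_loci_compared = sum(both), stringsAsFactors = FALSE)
  }
  if (skipped > 0)
    warning(sprintf("%d pair(s) had no mutually typed panel locus and were excluded",
                    skipped))
  if (!length(out))
    return(data.frame(id1 = character(), id2 = character(),
                      n_loci_compared = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
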