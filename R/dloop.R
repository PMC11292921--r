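# Character matrix (sequences x sites) from a dloop_alignment.
aln_matrix <- function(a) {
  m <- do.call(rbind, strsplit(a$seqs, ""))
  rownames(m) <- a$ids
  m
}

#' Collapse an alignment into haplotypes
#'
#' Sites containing a gap or `N` in any sequence are removed first (complete
#' deletion, the default convention for D-loop diversity statistics);
#' sequences identical over the retained sites are collapsed into
#' haplotypes. Segregating sites `S` are counted on the retained sites.
#'
#' @param a a [dloop_alignment()].
#' @param site_filter `"complete_deletion"` only (pairwise handling is a
#'   per-statistic option elsewhere).
#' @return An object of class `haplotype_table`: `haplotypes` (named
#'   sequences), `hap_of` (haplotype index per input sequence), `pops`,
#'   `counts` (populations x haplotypes), `S`, `length` (retained sites),
#'   and the filtered site matrix `m`.
#' @export
collapse_haplotypes <- function(a, site_filter = "complete_deletion") {
  m <- aln_matrix(a)
  keep <- colSums(m == "-" | m == "N") == 0L
  if (!any(keep)) stop_fmt("all sites removed by complete deletion")
  m <- m[, keep, drop = FALSE]
  seqs <- apply(m, 1L, paste, collapse = "")
  uniq <- unique(seqs)
  hap_of <- match(seqs, uniq)
  hap_names <- sprintf("hap%02d", seq_along(uniq))
  pops <- unique(a$pops)
  counts <- matrix(0L, length(pops), length(uniq),
                   dimnames = list(pops, hap_names))
  for (i in seq_along(seqs))
    counts[a$pops[i], hap_of[i]] <- counts[a$pops[i], hap_of[i]] + 1L
  S <- sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
  structure(list(haplotypes = stats::setNames(uniq, hap_names),
                 hap_of = hap_of, pops = a$pops, counts = counts,
                 S = S, length = ncol(m), m = m),
            class = "haplotype_table")
}

# Pairwise difference counts between haplotypes (H x H matrix).
hap_diff_matrix <- function(ht) {
  H <- length(ht$haplotypes)
  d <- matrix(0, H, H)
  if (H > 1L) {
    split_h <- strsplit(ht$haplotypes, "")
    for (i in seq_len(H - 1L)) for (j in (i + 1L):H)
      d[i, j] <- d[j, i] <- sum(split_h[[i]] != split_h[[j]])
  }
  d
}

# Mean pairwise difference among a multiset of haplotypes given counts.
mean_pairwise_k <- function(counts, d) {
  n <- sum(counts)
  if (n < 2L) return(NA_real_)
  idx <- which(counts > 0)
  tot <- 0
  for (i in idx) for (j in idx) if (j > i)
    tot <- tot + counts[i] * counts[j] * d[i, j]
  tot / choose(n, 2)
}

# Segregating sites / mutation counts within a subset of sequence rows.
site_counts <- function(m) {
  seg <- 0L; eta <- 0L; eta_s <- 0L
  for (s in seq_len(ncol(m))) {
    tab <- table(m[, s])
    if (length(tab) > 1L) {
      seg <- seg + 1L
      eta <- eta + length(tab) - 1L
      eta_s <- eta_s + sum(tab == 1L)
    }
  }
  list(S = seg, eta = eta, eta_singletons = eta_s)
}

#' D-loop diversity statistics per population
#'
#' For each population (and the pooled `"all"`): number of haplotypes `H`,
#' haplotype diversity `h = n/(n-1) (1 - sum f_i^2)` with Nei's sampling SD,
#' mean pairwise nucleotide differences `k`, nucleotide diversity
#' `pi = k / L` with its sampling SD, and Watterson's per-site
#' `theta_S = S / (a1 L)` from that population's segregating sites.
#'
#' @param ht a [collapse_haplotypes()] result.
#' @return data.frame with one row per population plus `"all"`.
#' @export
dloop_diversity <- function(ht) {
  d <- hap_diff_matrix(ht)
  L <- ht$length
  pops <- c(rownames(ht$counts), "all")
  rows <- lapply(pops, function(p) {
    counts <- if (p == "all") colSums(ht$counts) else ht$counts[p, ]
    n <- sum(counts)
    if (n < 2L)
      return(data.frame(population = p, n = n, H = sum(counts > 0),
                        h = NA_real_, h_sd = NA_real_, k = NA_real_,
                        pi = NA_real_, pi_sd = NA_real_, S = NA_integer_,
                        theta_S = NA_real_, stringsAsFactors = FALSE))
    f <- counts / n
    sum2 <- sum(f^2); sum3 <- sum(f^3)
    h <- n / (n - 1) * (1 - sum2)
    v_h <- 2 / (n * (n - 1)) *
      (2 * (n - 2) * (sum3 - sum2^2) + sum2 - sum2^2)
    k <- mean_pairwise_k(counts, d)
    pi <- k / L
    v_pi <- (n + 1) / (3 * (n - 1)) * pi / L +
      2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
    rows_in <- if (p == "all") seq_len(nrow(ht$m)) else which(ht$pops == p)
    S <- site_counts(ht$m[rows_in, , drop = FALSE])$S
    a1 <- sum(1 / seq_len(n - 1))
    data.frame(population = p, n = n, H = sum(counts > 0), h = h,
               h_sd = sqrt(max(v_h, 0)), k = k, pi = pi,
               pi_sd = sqrt(max(v_pi, 0)), S = S, theta_S = S / (a1 * L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise D-loop differentiation
#'
#' For each population pair: the haplotype-frequency differentiation
#' `G_ST = (H_T - H_S)/H_T` (within-population gene diversities weighted by
#' sample size), the nucleotide-based `F_ST = 1 - pi_within/pi_total`
#' (within/pooled mean pairwise differences), `Phi_ST` from a two-level
#' AMOVA on pairwise nucleotide differences, the per-site between-population
#' divergence `D_xy`, its net version `D_a = D_xy - (pi_X + pi_Y)/2`, and
#' the maternal-haploid gene-flow proxy `N_m = (1 - F_ST)/(2 F_ST)`
#' (undefined when `F_ST <= 0`).
#'
#' @param ht a [collapse_haplotypes()] result.
#' @return data.frame with one row per population pair.
#' @export
dloop_differentiation <- function(ht) {
  pops <- rownames(ht$counts)
  if (length(pops) < 2L) stop_fmt("need >= 2 populations")
  d <- hap_diff_matrix(ht)
  L <- ht$length
  rows <- list()
  for (i in seq_len(length(pops) - 1L)) for (j in (i + 1L):length(pops)) {
    cx <- ht$counts[pops[i], ]; cy <- ht$counts[pops[j], ]
    nx <- sum(cx); ny <- sum(cy)
    fx <- cx / nx; fy <- cy / ny
    hx <- 1 - sum(fx^2); hy <- 1 - sum(fy^2)
    hs <- (nx * hx + ny * hy) / (nx + ny)
    fpool <- (cx + cy) / (nx + ny)
    htot <- 1 - sum(fpool^2)
    gst <- if (htot > 0) (htot - hs) / htot else NA_real_
    kx <- mean_pairwise_k(cx, d); ky <- mean_pairwise_k(cy, d)
    kpool <- mean_pairwise_k(cx + cy, d)
    # between-population mean pairwise differences
    kxy <- sum(outer(cx, cy) * d) / (nx * ny)
    # plug-in within-population diversities (no n/(n-1) correction), so the
    # net divergence of two identical samples is exactly zero
    kx_plug <- sum(outer(cx, cx) * d) / nx^2
    ky_plug <- sum(outer(cy, cy) * d) / ny^2
    k_within <- (choose(nx, 2) * kx + choose(ny, 2) * ky) /
      (choose(nx, 2) + choose(ny, 2))
    fst <- if (kpool > 0) 1 - k_within / kpool else NA_real_
    # two-level AMOVA on the difference counts (copies = sequences)
    N <- nx + ny
    ss_tot <- (choose(nx, 2) * kx + choose(ny, 2) * ky + nx * ny * kxy) / N
    ss_w <- (choose(nx, 2) * kx) / nx + (choose(ny, 2) * ky) / ny
    ms_a <- (ss_tot - ss_w) / 1
    ms_w <- ss_w / (N - 2)
    n0 <- (N - (nx^2 + ny^2) / N) / 1
    s2a <- (ms_a - ms_w) / n0
    phist <- if (s2a + ms_w > 0) s2a / (s2a + ms_w) else NA_real_
    dxy <- kxy / L
    da <- dxy - (kx_plug / L + ky_plug / L) / 2
    nm <- if (!is.na(fst) && fst > 0) (1 - fst) / (2 * fst) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      pop1 = pops[i], pop2 = pops[j], G_ST = gst, F_ST = fst,
      Phi_ST = phist, D_xy = dxy, D_a = da, N_m = nm,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# log of unsigned Stirling numbers of the first kind, row n (j = 1..n),
# computed in log space so large sample sizes do not overflow.
stirling_first_row_log <- function(n) {
  logsum <- function(a, b) {
    m <- pmax(a, b)
    ifelse(is.infinite(m), m, m + log1p(exp(pmin(a, b) - m)))
  }
  row <- 0   # log |S1(0, 0)| = log 1
  for (m in seq_len(n)) {
    new <- c(-Inf, row)                              # |S1(m-1, j-1)| term
    if (m > 1) new[1:m] <- logsum(new[1:m], log(m - 1) + row)
    row <- new
  }
  row[-1L]   # drop j = 0
}

# P(K >= k_obs) under the Ewens sampling formula with parameter theta.
ewens_tail <- function(n, k_obs, theta) {
  lst <- stirling_first_row_log(n)
  log_rising <- sum(log(theta + 0:(n - 1)))
  lp <- lst + seq_len(n) * log(theta) - log_rising
  sum(exp(lp[seq(k_obs, n)]))
}

#' Neutrality tests per population
#'
#' Tajima's D (with the standard a1..e2 constants), Fu and Li's D* and F*
#' without an outgroup (singleton-based, with the corrected small-sample
#' constants), and Fu's Fs via the Ewens sampling formula with
#' `theta = k` (exact Stirling-number recursion). All statistics are `NA`
#' when a population has no segregating sites or fewer than 4 sequences.
#'
#' @param ht a [collapse_haplotypes()] result.
#' @return data.frame with one row per population plus `"all"`:
#'   `tajima_D`, `fuli_Dstar`, `fuli_Fstar`, `fu_Fs`, plus `S`, `eta`,
#'   `eta_singletons`, `k`.
#' @export
neutrality_tests <- function(ht) {
  d <- hap_diff_matrix(ht)
  pops <- c(rownames(ht$counts), "all")
  rows <- lapply(pops, function(p) {
    rows_in <- if (p == "all") seq_len(nrow(ht$m)) else which(ht$pops == p)
    n <- length(rows_in)
    counts <- if (p == "all") colSums(ht$counts) else ht$counts[p, ]
    base <- data.frame(population = p, n = n, S = NA_integer_,
                       eta = NA_integer_, eta_singletons = NA_integer_,
                       k = NA_real_, tajima_D = NA_real_,
                       fuli_Dstar = NA_real_, fuli_Fstar = NA_real_,
                       fu_Fs = NA_real_, stringsAsFactors = FALSE)
    if (n < 4L) return(base)
    sc <- site_counts(ht$m[rows_in, , drop = FALSE])
    k <- mean_pairwise_k(counts, d)
    base$S <- sc$S; base$eta <- sc$eta; base$eta_singletons <- sc$eta_singletons
    base$k <- k
    if (sc$S == 0L) return(base)
    base$tajima_D <- tajima_d(n, sc$S, k)
    fl <- fu_li_no_outgroup(n, sc$eta, sc$eta_singletons, k)
    base$fuli_Dstar <- fl$Dstar; base$fuli_Fstar <- fl$Fstar
    k_obs <- sum(counts > 0)
    if (k > 0) {
      sp <- ewens_tail(n, k_obs, k)
      base$fu_Fs <- if (sp <= 0 || sp >= 1) sign(0.5 - sp) * Inf else
        log(sp / (1 - sp))
    }
    base
  })
  do.call(rbind, rows)
}

# Tajima's (1989) D.
tajima_d <- function(n, S, k) {
  if (S == 0L || n < 4L) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Fu & Li (1993) D* and F* without outgroup (corrected constants).
fu_li_no_outgroup <- function(n, eta, eta_s, k) {
  an <- sum(1 / seq_len(n - 1)); bn <- sum(1 / seq_len(n - 1)^2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  Dstar <- ((n / (n - 1)) * eta - an * eta_s) / sqrt(uD * eta + vD * eta^2)
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an - vF
  Fstar <- (k - ((n - 1) / n) * eta_s) / sqrt(uF * eta + vF * eta^2)
  list(Dstar = Dstar, Fstar = Fstar)
}

#' Mismatch distribution and raggedness index
#'
#' Observed frequencies of pairwise difference counts among one population's
#' sequences, the constant-size expectation `F_i = theta^i / (1+theta)^(i+1)`
#' with `theta = k` (method of moments), and Harpending's raggedness index
#' `r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2` with a trailing zero class
#' (`x_{d+1} = 0`). Small values indicate a smooth, expansion-like
#' distribution; large values a ragged, stationary one.
#'
#' @param a a [dloop_alignment()].
#' @param population population label (default: pool all sequences).
#' @return list with `classes` (0..d), `observed`, `expected`, `theta`,
#'   `raggedness`.
#' @export
mismatch_distribution <- function(a, population = NULL) {
  ht <- collapse_haplotypes(a)
  rows_in <- if (is.null(population)) seq_len(nrow(ht$m)) else
    which(ht$pops == population)
  n <- length(rows_in)
  if (n < 3L) stop_fmt("need >= 3 sequences for a mismatch distribution")
  m <- ht$m[rows_in, , drop = FALSE]
  diffs <- integer()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    diffs <- c(diffs, sum(m[i, ] != m[j, ]))
  dmax <- max(diffs)
  obs <- tabulate(diffs + 1L, nbins = dmax + 1L) / length(diffs)
  theta <- mean(diffs)
  classes <- 0:dmax
  expected <- theta^classes / (1 + theta)^(classes + 1)
  x <- c(obs, 0)
  ragged <- sum(diff(x)^2)
  list(classes = classes, observed = obs, expected = expected,
       theta = theta, raggedness = ragged)
}
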