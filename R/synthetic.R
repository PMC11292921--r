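#' Simulation configuration for genotype tables
#'
#' Defaults emulate the study conditions the package is built around: five
#' breed populations of 59/29/41/37/18 diploids, 15 dinucleotide loci with
#' 5-12 alleles each, ancestral allele frequencies drawn from a symmetric
#' Dirichlet whose concentration (0.5) puts expected heterozygosity near
#' 0.69, and weak differentiation (fst = 0.01). Inbreeding, null alleles and
#' missingness are off by default and can be switched on per scenario.
#'
#' @param n_pops number of populations.
#' @param n_per_pop integer vector of diploid sample sizes (length `n_pops`).
#' @param n_loci number of loci.
#' @param alleles_per_locus integer, or length-2 range sampled uniformly.
#' @param concentration symmetric Dirichlet concentration for ancestral
#'   allele frequencies.
#' @param fst Balding-Nichols differentiation parameter in `[0, 1)`.
#' @param f_is within-population inbreeding: probability a genotype is an
#'   identical-by-descent homozygote.
#' @param null_rate per-locus null-allele frequency in `[0, 1)`.
#' @param missing_rate random genotype dropout rate in `[0, 1)`.
#' @param repeat_unit_bp repeat-unit length for all loci.
#' @param seed integer master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 5L, n_per_pop = c(59L, 29L, 41L, 37L, 18L),
                       n_loci = 15L, alleles_per_locus = c(5L, 12L),
                       concentration = 0.5, fst = 0.01, f_is = 0,
                       null_rate = 0, missing_rate = 0, repeat_unit_bp = 2L,
                       seed = 1L) {
  cfg <- list(n_pops = as.integer(n_pops), n_per_pop = as.integer(n_per_pop),
              n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              concentration = concentration, fst = fst, f_is = f_is,
              null_rate = null_rate, missing_rate = missing_rate,
              repeat_unit_bp = as.integer(repeat_unit_bp),
              seed = as.integer(seed))
  if (length(cfg$n_per_pop) != cfg$n_pops)
    stop_fmt("n_per_pop must have length n_pops")
  if (any(cfg$alleles_per_locus < 1L))
    stop_fmt("alleles_per_locus must be >= 1")
  for (p in c("fst", "null_rate", "missing_rate"))
    if (cfg[[p]] < 0 || cfg[[p]] >= 1) stop_fmt("%s must be in [0, 1)", p)
  if (cfg$f_is < 0 || cfg$f_is > 1) stop_fmt("f_is must be in [0, 1]")
  if (cfg$concentration <= 0) stop_fmt("concentration must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (all(x == 0)) x[sample.int(length(x), 1L)] <- 1
  x / sum(x)
}

#' Simulate multi-population microsatellite genotypes
#'
#' Ancestral allele frequencies are drawn from a symmetric Dirichlet;
#' population frequencies follow a Balding-Nichols-style law
#' (Dirichlet with concentration `p_anc * (1 - fst) / fst`, so each allele's
#' frequency has mean `p_anc` and variance `fst * p_anc * (1 - p_anc)`).
#' Genotypes are drawn with probability `f_is` of an identical-by-descent
#' homozygote, otherwise two independent draws. Null alleles are a hidden
#' allele at frequency `null_rate`: a null/visible genotype is recorded as a
#' visible homozygote and null/null as missing. Allele sizes sit on a
#' `repeat_unit_bp` ladder.
#'
#' @param cfg a [sim_config()].
#' @return A list with `table` (a [genotype_table()]) and `truth`
#'   (ancestral and population allele frequencies, per-locus-and-population
#'   expected heterozygosity `(1 - fst) * (1 - sum(p_anc^2))`, and the
#'   config), deterministic under `cfg$seed`.
#' @export
simulate_populations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    L <- cfg$n_loci
    k_range <- cfg$alleles_per_locus
    k <- if (length(k_range) == 1L) rep(k_range, L) else
      sample(seq(k_range[1], k_range[2]), L, replace = TRUE)
    loci <- locus_meta(sprintf("L%02d", seq_len(L)), cfg$repeat_unit_bp)
    pops <- sprintf("pop%d", seq_len(cfg$n_pops))
    n_tot <- sum(cfg$n_per_pop)
    samples <- data.frame(id = sprintf("S%04d", seq_len(n_tot)),
                          pop = rep(pops, cfg$n_per_pop),
                          stringsAsFactors = FALSE)
    a1 <- matrix(NA_integer_, n_tot, L); a2 <- a1
    anc <- vector("list", L); pop_freqs <- vector("list", L)
    sizes <- vector("list", L); exp_he <- matrix(NA_real_, L, cfg$n_pops)
    for (l in seq_len(L)) {
      start <- 80L + 2L * sample.int(40L, 1L)
      ladder <- sort(sample.int(k[l] + 4L, k[l])) - 1L
      sizes[[l]] <- start + cfg$repeat_unit_bp * ladder
      p_anc <- rdirichlet1(rep(cfg$concentration, k[l]))
      anc[[l]] <- p_anc
      pf <- matrix(0, cfg$n_pops, k[l])
      for (g in seq_len(cfg$n_pops)) {
        pf[g, ] <- if (cfg$fst > 0)
          rdirichlet1(p_anc * (1 - cfg$fst) / cfg$fst) else p_anc
        exp_he[l, g] <- (1 - cfg$fst) * (1 - sum(p_anc^2))
      }
      pop_freqs[[l]] <- pf
      # extend with a hidden null allele, renormalizing the visible ones
      for (g in seq_len(cfg$n_pops)) {
        rows <- which(samples$pop == pops[g])
        n <- length(rows)
        pv <- pf[g, ] * (1 - cfg$null_rate)
        p_full <- c(pv, cfg$null_rate)           # index k+1 = null
        ibd <- stats::runif(n) < cfg$f_is
        g1 <- integer(n); g2 <- integer(n)
        g1 <- sample.int(k[l] + 1L, n, replace = TRUE, prob = p_full)
        g2 <- ifelse(ibd, g1,
                     sample.int(k[l] + 1L, n, replace = TRUE, prob = p_full))
        null1 <- g1 == k[l] + 1L; null2 <- g2 == k[l] + 1L
        v1 <- ifelse(null1 & null2, NA_integer_,
                     ifelse(null1, g2, g1))
        v2 <- ifelse(null1 & null2, NA_integer_,
                     ifelse(null2, v1, g2))
        drop <- stats::runif(n) < cfg$missing_rate
        v1[drop] <- NA_integer_; v2[drop] <- NA_integer_
        a1[rows, l] <- sizes[[l]][v1]
        a2[rows, l] <- sizes[[l]][v2]
      }
    }
    names(anc) <- names(pop_freqs) <- names(sizes) <- loci$name
    tab <- genotype_table(samples, loci, a1, a2)
    list(table = tab,
         truth = list(ancestral = anc, pop_freqs = pop_freqs,
                      allele_sizes = sizes, expected_he = exp_he,
                      expected_mean_he = mean(exp_he), config = cfg))
  })
}

#' Simulate pedigrees (parent-offspring trios and full-sib pairs)
#'
#' Founders are drawn in Hardy-Weinberg proportions from the supplied allele
#' frequencies; each offspring receives one allele from each parent uniformly
#' at random. With `error_rate > 0` each transmitted allele is replaced by a
#' random population allele with that probability. Supports validating the
#' sibling identity and parentage-exclusion statistics empirically.
#'
#' @param founder_freqs named list (per locus) of named allele-frequency
#'   vectors (names = allele sizes in bp), or an `allele_freq_table` from
#'   [allele_frequencies()] (its pooled `"all"` group is used).
#' @param n_trios number of sire/dam/offspring trios.
#' @param n_sib_pairs number of full-sib pairs (each from its own parents;
#'   the parents are not emitted).
#' @param error_rate per-allele genotyping error rate in `[0, 1)`.
#' @param seed integer seed.
#' @return A list with `table` (a [genotype_table()]; the sample `pop` field
#'   holds the role `sire`/`dam`/`offspring`/`sib1`/`sib2` and `locality`
#'   the family id) and `roles` (data.frame of id, role, family).
#' @export
simulate_pedigree <- function(founder_freqs, n_trios = 0L, n_sib_pairs = 0L,
                              error_rate = 0, seed = 1L) {
  if (inherits(founder_freqs, "allele_freq_table"))
    founder_freqs <- pooled_freqs(founder_freqs)
  if (!length(founder_freqs) || !all(vapply(founder_freqs, length, 0L) > 0))
    stop_fmt("empty founder frequencies")
  if (error_rate < 0 || error_rate >= 1) stop_fmt("error_rate must be in [0, 1)")
  L <- length(founder_freqs)
  loci <- locus_meta(names(founder_freqs) %||% sprintf("L%02d", seq_len(L)))
  sizes <- lapply(founder_freqs, function(p) as.integer(names(p)))
  probs <- lapply(founder_freqs, function(p) as.numeric(p) / sum(p))
  with_seed(seed, {
    draw <- function(l, n) sample(sizes[[l]], n, replace = TRUE, prob = probs[[l]])
    transmit <- function(p1, p2, l) {
      n <- length(p1)
      a <- ifelse(stats::runif(n) < 0.5, p1, p2)
      err <- stats::runif(n) < error_rate
      if (any(err)) a[err] <- draw(l, sum(err))
      a
    }
    ids <- character(); roles <- character(); fams <- character()
    A1 <- NULL; A2 <- NULL
    add <- function(id, role, fam, g1, g2) {
      ids <<- c(ids, id); roles <<- c(roles, role); fams <<- c(fams, fam)
      A1 <<- rbind(A1, g1); A2 <<- rbind(A2, g2)
    }
    if (n_trios > 0) {
      s1 <- sapply(seq_len(L), function(l) draw(l, n_trios))
      s2 <- sapply(seq_len(L), function(l) draw(l, n_trios))
      d1 <- sapply(seq_len(L), function(l) draw(l, n_trios))
      d2 <- sapply(seq_len(L), function(l) draw(l, n_trios))
      o1 <- sapply(seq_len(L), function(l) transmit(s1[, l], s2[, l], l))
      o2 <- sapply(seq_len(L), function(l) transmit(d1[, l], d2[, l], l))
      if (n_trios == 1L) { # sapply drops to vector
        s1 <- matrix(s1, 1L); s2 <- matrix(s2, 1L); d1 <- matrix(d1, 1L)
        d2 <- matrix(d2, 1L); o1 <- matrix(o1, 1L); o2 <- matrix(o2, 1L)
      }
      fam <- sprintf("T%05d", seq_len(n_trios))
      add(paste0(fam, "_sire"), rep("sire", n_trios), fam, s1, s2)
      add(paste0(fam, "_dam"), rep("dam", n_trios), fam, d1, d2)
      add(paste0(fam, "_off"), rep("offspring", n_trios), fam, o1, o2)
    }
    if (n_sib_pairs > 0) {
      p1a <- sapply(seq_len(L), function(l) draw(l, n_sib_pairs))
      p1b <- sapply(seq_len(L), function(l) draw(l, n_sib_pairs))
      p2a <- sapply(seq_len(L), function(l) draw(l, n_sib_pairs))
      p2b <- sapply(seq_len(L), function(l) draw(l, n_sib_pairs))
      x1 <- sapply(seq_len(L), function(l) transmit(p1a[, l], p1b[, l], l))
      x2 <- sapply(seq_len(L), function(l) transmit(p2a[, l], p2b[, l], l))
      y1 <- sapply(seq_len(L), function(l) transmit(p1a[, l], p1b[, l], l))
      y2 <- sapply(seq_len(L), function(l) transmit(p2a[, l], p2b[, l], l))
      if (n_sib_pairs == 1L) {
        x1 <- matrix(x1, 1L); x2 <- matrix(x2, 1L)
        y1 <- matrix(y1, 1L); y2 <- matrix(y2, 1L)
      }
      fam <- sprintf("F%05d", seq_len(n_sib_pairs))
      add(paste0(fam, "_sib1"), rep("sib1", n_sib_pairs), fam, x1, x2)
      add(paste0(fam, "_sib2"), rep("sib2", n_sib_pairs), fam, y1, y2)
    }
    if (!length(ids)) stop_fmt("n_trios + n_sib_pairs must be > 0")
    samples <- data.frame(id = ids, pop = roles, locality = fams,
                          stringsAsFactors = FALSE)
    tab <- genotype_table(samples, loci, A1, A2)
    list(table = tab,
         roles = data.frame(id = ids, role = roles, family = fams,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a haplotype alignment
#'
#' Builds `n_haplotypes` sequences on a random backbone: haplotype 1 is the
#' backbone and each further haplotype carries `mut_per_hap` private
#' substitutions at previously unused sites (so any two haplotypes differ at
#' a known number of sites). Individuals are then sampled per population
#' according to `pop_counts`.
#'
#' @param n_haplotypes number of distinct haplotypes.
#' @param pop_counts integer matrix (populations x haplotypes) of how many
#'   individuals of each haplotype each population contains; rownames are
#'   population labels. A single population may be given as a vector.
#' @param length alignment length in bp.
#' @param mut_per_hap substitutions private to each non-backbone haplotype.
#' @param seed integer seed.
#' @return A [dloop_alignment()], deterministic under `seed`.
#' @export
simulate_dloop_alignment <- function(n_haplotypes, pop_counts, length = 423L,
                                     mut_per_hap = 3L, seed = 1L) {
  if (is.vector(pop_counts)) pop_counts <- matrix(pop_counts, nrow = 1L,
                                                  dimnames = list("pop1", NULL))
  if (ncol(pop_counts) != n_haplotypes)
    stop_fmt("pop_counts must have %d columns", n_haplotypes)
  n_sites_needed <- (n_haplotypes - 1L) * mut_per_hap
  if (n_sites_needed > length)
    stop_fmt("length %d too small for %d private substitutions", length,
             n_sites_needed)
  if (is.null(rownames(pop_counts)))
    rownames(pop_counts) <- sprintf("pop%d", seq_len(nrow(pop_counts)))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    backbone <- sample(bases, length, replace = TRUE)
    sites <- if (n_sites_needed > 0) sample.int(length, n_sites_needed) else integer()
    haps <- vector("list", n_haplotypes)
    haps[[1]] <- backbone
    for (h in seq_len(n_haplotypes - 1L)) {
      s <- haps[[1]]
      idx <- sites[((h - 1L) * mut_per_hap + 1L):(h * mut_per_hap)]
      for (i in idx) s[i] <- sample(setdiff(bases, s[i]), 1L)
      haps[[h + 1L]] <- s
    }
    hap_str <- vapply(haps, paste, "", collapse = "")
    ids <- character(); pops <- character(); seqs <- character()
    for (g in seq_len(nrow(pop_counts))) {
      for (h in seq_len(n_haplotypes)) {
        cnt <- pop_counts[g, h]
        if (cnt > 0) {
          new_ids <- sprintf("%s_h%02d_%02d", rownames(pop_counts)[g], h,
                             seq_len(cnt))
          ids <- c(ids, new_ids)
          pops <- c(pops, rep(rownames(pop_counts)[g], cnt))
          seqs <- c(seqs, rep(hap_str[h], cnt))
        }
      }
    }
    dloop_alignment(ids, pops, seqs)
  })
}

#' Simulate a neutral-equilibrium alignment from site-frequency draws
#'
#' Draws data calibrated to the constant-size neutral expectations without a
#' genealogy: the number of segregating sites is Poisson with mean
#' `theta * a1` (`a1 = sum(1/i)` for `i = 1..n-1`), and each site's minor
#' count is drawn from the neutral site-frequency spectrum (probability
#' proportional to `1/i`), with the carriers a uniform random subset. Sites
#' are independent, so the first moments of the summary statistics match
#' the constant-size neutral model (Tajima's D centres on zero); linkage
#' between sites is not reproduced.
#'
#' @param n number of sequences.
#' @param theta scaled mutation rate (per locus).
#' @param length alignment length in bp.
#' @param seed integer seed.
#' @return A [dloop_alignment()] with a single population.
#' @export
simulate_neutral_alignment <- function(n, theta, length = 423L, seed = 1L) {
  stopifnot(n >= 2L, theta > 0)
  a1 <- sum(1 / seq_len(n - 1L))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    S <- stats::rpois(1L, theta * a1)
    S <- min(S, length)
    backbone <- sample(bases, length, replace = TRUE)
    m <- matrix(rep(backbone, each = n), nrow = n)
    if (S > 0) {
      sites <- sample.int(length, S)
      sfs_p <- (1 / seq_len(n - 1L)) / a1
      for (s in sites) {
        i <- sample.int(n - 1L, 1L, prob = sfs_p)
        carriers <- sample.int(n, i)
        m[carriers, s] <- sample(setdiff(bases, backbone[s]), 1L)
      }
    }
    dloop_alignment(sprintf("seq%03d", seq_len(n)), rep("pop1", n),
                    apply(m, 1L, paste, collapse = ""))
  })
}
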