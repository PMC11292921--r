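# Small deterministic fixtures built in code.

# 3 samples x 2 loci, one population; L1 has alleles 100/102, L2 is
# monomorphic except one heterozygote.
toy_table <- function() {
  genotype_table(
    data.frame(id = c("a", "b", "c"), pop = "p1"),
    locus_meta(c("L1", "L2"), repeat_unit_bp = 2L),
    a1 = matrix(c(100L, 100L, 102L, 200L, 200L, 200L), 3),
    a2 = matrix(c(100L, 102L, 102L, 200L, 202L, 200L), 3))
}

# Two populations fixed for different alleles at every locus.
fixed_diff_table <- function(n_per_pop = 10L, n_loci = 3L) {
  n <- 2L * n_per_pop
  a <- matrix(rep(c(100L, 120L), each = n_per_pop), n, n_loci)
  genotype_table(
    data.frame(id = sprintf("s%02d", seq_len(n)),
               pop = rep(c("p1", "p2"), each = n_per_pop)),
    locus_meta(sprintf("L%d", seq_len(n_loci)), 2L),
    a1 = a, a2 = a)
}

# A frequency vector wrapped as the raw-list input of per_locus_id_stats().
one_locus_freqs <- function(p, name = "L1") {
  stats::setNames(list(p), name)
}

# Random frequency vector of length k (not exported randomness helpers).
random_freqs <- function(k) {
  x <- stats::runif(k)
  x / sum(x)
}

# Equal-length alignment from explicit sequences.
aln_from <- function(seqs, pops = NULL) {
  dloop_alignment(sprintf("s%d", seq_along(seqs)),
                  pops %||% rep("pop1", length(seqs)), seqs)
}
`%||%` <- function(a, b) if (is.null(a)) b else a
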