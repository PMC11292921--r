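#' Write a study-shaped synthetic fixture bundle
#'
#' Generates a dataset with the shape of a five-breed survey — populations
#' of 18, 29, 37, 41 and 59 diploids at 15 microsatellite loci, plus a
#' 423-bp haplotype alignment with 14 haplotypes — and writes it as GenePop,
#' wide CSV, locus-metadata YAML, FASTA, and a truth JSON (the generator's
#' parameters and expected values).
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @return Named list of file paths, invisibly; also returns the simulated
#'   objects in `$data`.
#' @export
make_fixture <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(seed = seed)
  sim <- simulate_populations(cfg)
  # D-loop: 14 haplotypes spread over the 5 populations with two common
  # haplotypes shared by all breeds, the rest rarer and patchily shared
  n_hap <- 14L
  with_seed(child_seed(seed, 99L), {
    counts <- matrix(0L, cfg$n_pops, n_hap,
                     dimnames = list(sprintf("pop%d", seq_len(cfg$n_pops)), NULL))
    for (g in seq_len(cfg$n_pops)) {
      n <- cfg$n_per_pop[g]
      w <- c(8, 6, rep(1, n_hap - 2L))          # two common, rest rare
      draw <- sample.int(n_hap, n, replace = TRUE, prob = w / sum(w))
      counts[g, ] <- tabulate(draw, nbins = n_hap)
    }
  })
  aln <- simulate_dloop_alignment(n_hap, counts, length = 423L,
                                  mut_per_hap = 3L,
                                  seed = child_seed(seed, 7L))
  paths <- list(
    genepop = file.path(out_dir, "genotypes.gen"),
    csv = file.path(out_dir, "genotypes.csv"),
    loci = file.path(out_dir, "loci.yaml"),
    fasta = file.path(out_dir, "dloop.fasta"),
    truth = file.path(out_dir, "truth.json"))
  write_genepop(sim$table, paths$genepop, title = "synthetic five-breed fixture")
  write_genotype_csv(sim$table, paths$csv)
  write_locus_meta_yaml(sim$table$loci, paths$loci)
  write_fasta_alignment(aln, paths$fasta)
  truth <- list(config = unclass(sim$truth$config),
                expected_mean_he = sim$truth$expected_mean_he,
                n_haplotypes = n_hap,
                haplotype_counts = counts)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  out <- lapply(paths, normalizePath)
  out$data <- list(genotypes = sim$table, truth = sim$truth, alignment = aln)
  invisible(out)
}

#' Run the full analysis pipeline
#'
#' Orchestrates diversity -> structure -> identification -> panel selection
#' (-> D-loop when an alignment is given) on one genotype table, writing
#' TSV/JSON outputs and a markdown report. Deterministic under `seed`.
#'
#' @param genotypes a [genotype_table()] or path to a GenePop/CSV file.
#' @param fasta optional [dloop_alignment()] or FASTA path.
#' @param grouping `"pop"` or `"locality"`.
#' @param out_dir output directory.
#' @param seed integer master seed for every stochastic stage.
#' @param error_threshold panel-selection error threshold (percent).
#' @param n_perm permutations for pairwise F_ST.
#' @param accumulation_reps genotype-accumulation resampling replicates.
#' @param hwe_reps Monte Carlo replicates for large Hardy-Weinberg tests.
#' @param verbose print one line per stage.
#' @return Invisibly, a list with every stage's results.
#' @export
run_full_pipeline <- function(genotypes, fasta = NULL,
                              grouping = c("pop", "locality"),
                              out_dir = "pawprint_results", seed = 1L,
                              error_threshold = 5, n_perm = 110L,
                              accumulation_reps = 200L, hwe_reps = 1e4,
                              verbose = TRUE) {
  grouping <- match.arg(grouping)
  say <- function(stage, ...) if (verbose)
    message(sprintf("[pawprint] %-12s %s", stage, sprintf(...)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  if (is.character(genotypes)) {
    genotypes <- if (grepl("\\.csv$", genotypes, ignore.case = TRUE))
      read_genotype_csv(genotypes) else read_genepop(genotypes)
  }
  if (is.character(fasta)) fasta <- read_fasta_alignment(fasta)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(seed = seed, grouping = grouping)

  say("diversity", "locus summaries (%s grouping), seed %d", grouping, seed)
  res$locus_summary <- stage("diversity",
    locus_summary(genotypes, grouping, hwe_reps = hwe_reps,
                  seed = child_seed(seed, 1L)))
  res$welch <- stage("diversity", {
    gl <- unique(res$locus_summary$group)
    do.call(rbind, lapply(gl, function(g) {
      w <- welch_ho_he(res$locus_summary, g)
      data.frame(group = g, t = w$t, df = w$df, p = w$p,
                 mean_ho = w$mean_ho, mean_he = w$mean_he)
    }))
  })

  say("structure", "F-statistics, relatedness, AMOVA (%d perms)", n_perm)
  res$fstats <- stage("structure", wc_fstats(genotypes, grouping))
  res$fis <- stage("structure",
    fis_with_ci(genotypes, grouping, seed = child_seed(seed, 2L)))
  res$pairwise_fst <- stage("structure",
    pairwise_fst(genotypes, grouping, n_perm = n_perm,
                 seed = child_seed(seed, 3L)))
  res$pairwise_rst <- stage("structure", pairwise_rst(genotypes, grouping))
  res$nei <- stage("structure",
    nei_distance(allele_frequencies(genotypes, grouping)))
  res$amova <- stage("structure", amova(genotypes, grouping))
  res$relatedness <- stage("structure", pairwise_relatedness(genotypes))

  say("ident", "identification statistics, %d accumulation reps",
      accumulation_reps)
  freqs_all <- allele_frequencies(genotypes, "all")
  res$id_stats <- stage("ident", per_locus_id_stats(freqs_all))
  res$id_combined <- stage("ident", combine_panel(res$id_stats))
  res$accumulation <- stage("ident",
    genotype_accumulation(genotypes, reps = accumulation_reps,
                          seed = child_seed(seed, 4L)))
  he_all <- vapply(pooled_freqs(freqs_all), function(p) 1 - sum(p^2), 0)
  res$sibs_curve <- stage("ident",
    pid_sibs_locus_curve(res$id_stats, he_all))
  res$matches <- stage("ident", match_report(genotypes))

  say("panel", "ACO panel selection at %.1f%% error threshold",
      error_threshold)
  res$panel <- stage("panel",
    aco_select_panel(genotypes, error_threshold = error_threshold,
                     seed = child_seed(seed, 5L)))

  if (!is.null(fasta)) {
    say("dloop", "D-loop diversity and demography")
    ht <- stage("dloop", collapse_haplotypes(fasta))
    res$dloop_diversity <- stage("dloop", dloop_diversity(ht))
    res$dloop_differentiation <- if (nrow(ht$counts) >= 2L)
      stage("dloop", dloop_differentiation(ht)) else NULL
    res$dloop_neutrality <- stage("dloop", neutrality_tests(ht))
    res$dloop_mismatch <- stage("dloop", mismatch_distribution(fasta))
  }

  say("report", "writing outputs to %s", out_dir)
  tabs <- list(locus_summary = res$locus_summary,
               welch_ho_he = res$welch,
               id_stats = rbind(res$id_stats, res$id_combined),
               accumulation = res$accumulation,
               relatedness_group_means = res$relatedness$group_means)
  if (!is.null(res$dloop_diversity)) {
    tabs$dloop_diversity <- res$dloop_diversity
    tabs$dloop_neutrality <- res$dloop_neutrality
    if (!is.null(res$dloop_differentiation))
      tabs$dloop_differentiation <- res$dloop_differentiation
  }
  write_tables(tabs, out_dir)
  json_sum <- list(
    seed = seed, grouping = grouping,
    fst = res$fstats$fst, fis = res$fstats$fis,
    amova_percent = as.list(res$amova$percent),
    combined_id = as.list(res$id_combined[, -1]),
    panel = list(loci = res$panel$loci, size = res$panel$size,
                 mean_pic = res$panel$mean_pic,
                 percent_distinguished = res$panel$percent_distinguished))
  jsonlite::write_json(json_sum, file.path(out_dir, "pipeline_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_report_md(res, file.path(out_dir, "report.md"))
  invisible(res)
}

# Markdown report mirroring the usual diversity / identification / D-loop
# summary tables.
write_report_md <- function(res, path) {
  fmt_df <- function(d) {
    num <- vapply(d, is.numeric, NA)
    d[num] <- lapply(d[num], function(x) signif(x, 4))
    c(paste("|", paste(names(d), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(d)), collapse = " | "), "|"),
      vapply(seq_len(nrow(d)), function(i)
        paste("|", paste(unlist(d[i, ]), collapse = " | "), "|"), ""))
  }
  lines <- c("# pawprint analysis report", "",
             sprintf("Seed: %d; grouping: %s", res$seed, res$grouping), "",
             "## Genetic diversity (per locus and group)", "",
             fmt_df(res$locus_summary[, c("locus", "group", "n_typed", "Na",
                                          "Nea", "AR", "I", "Ho", "He",
                                          "PIC", "F")]), "",
             "## Identification statistics (MP, PE, P(ID) variants)", "",
             fmt_df(rbind(res$id_stats, res$id_combined)), "",
             sprintf("Selected panel (%d loci): %s (mean PIC %.3f, %.2f%% distinguished)",
                     res$panel$size, paste(res$panel$loci, collapse = ", "),
                     res$panel$mean_pic, res$panel$percent_distinguished), "")
  if (!is.null(res$dloop_diversity))
    lines <- c(lines, "## mtDNA D-loop diversity", "",
               fmt_df(res$dloop_diversity), "")
  writeLines(lines, path)
  invisible(path)
}
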