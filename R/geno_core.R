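#' Construct a locus metadata table
#'
#' Microsatellite loci are scored as fragment sizes in base pairs; several
#' statistics (R_ST, the M-ratio) need to convert sizes to repeat units, so
#' every locus carries its repeat-unit length.
#'
#' @param name character vector of unique locus names.
#' @param repeat_unit_bp integer vector (1-6 bp typical) of repeat-unit
#'   lengths, recycled to `length(name)`.
#' @param size_min,size_max optional expected fragment-size range in bp.
#' @return A `data.frame` with columns `name`, `repeat_unit_bp`, `size_min`,
#'   `size_max`.
#' @export
locus_meta <- function(name, repeat_unit_bp = 2L, size_min = NA_integer_,
                       size_max = NA_integer_) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop_fmt("duplicated locus names: %s",
                                    paste(unique(name[duplicated(name)]), collapse = ", "))
  repeat_unit_bp <- as.integer(rep_len(repeat_unit_bp, length(name)))
  if (any(is.na(repeat_unit_bp)) || any(repeat_unit_bp < 1L))
    stop_fmt("repeat_unit_bp must be a positive integer")
  data.frame(name = name, repeat_unit_bp = repeat_unit_bp,
             size_min = as.integer(rep_len(size_min, length(name))),
             size_max = as.integer(rep_len(size_max, length(name))),
             stringsAsFactors = FALSE)
}

#' Construct a genotype table
#'
#' The central container for diploid multilocus genotypes: a rectangular
#' samples-by-loci table of unordered allele pairs (fragment sizes in bp),
#' with a population and a locality label per sample. A genotype is missing
#' when either allele is `NA` or 0; allele pairs are stored in canonical
#' ascending order so heterozygote identity is order-free.
#'
#' @param samples data.frame with columns `id`, `pop`, and optionally
#'   `locality` and `sex`.
#' @param loci locus metadata as from [locus_meta()], or a character vector
#'   of names (repeat unit defaults to 2 bp).
#' @param a1,a2 integer matrices (samples x loci) of allele sizes in bp.
#' @return An object of class `genotype_table` with elements `samples`,
#'   `loci`, `a1`, `a2`.
#' @export
genotype_table <- function(samples, loci, a1, a2) {
  if (is.character(loci)) loci <- locus_meta(loci)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!all(c("id", "pop") %in% names(samples)))
    stop_fmt("samples needs at least columns 'id' and 'pop'")
  if (is.null(samples$locality)) samples$locality <- samples$pop
  if (is.null(samples$sex)) samples$sex <- NA_character_
  samples <- samples[, c("id", "pop", "locality", "sex")]
  samples$id <- as.character(samples$id)
  if (anyDuplicated(samples$id)) stop_fmt("sample ids must be unique")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- nrow(samples); L <- nrow(loci)
  if (!all(dim(a1) == c(n, L)) || !all(dim(a2) == c(n, L)))
    stop_fmt("allele matrices must be %d samples x %d loci", n, L)
  a1[!is.na(a1) & a1 <= 0L] <- NA_integer_
  a2[!is.na(a2) & a2 <= 0L] <- NA_integer_
  miss <- is.na(a1) | is.na(a2)   # pairwise-deletion convention: half-calls count as missing
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  swap <- !miss & a1 > a2
  if (any(swap)) { tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp }
  dimnames(a1) <- dimnames(a2) <- list(samples$id, loci$name)
  structure(list(samples = samples, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples x %d loci, %d populations (%s)\n",
              nrow(x$samples), nrow(x$loci), length(unique(x$samples$pop)),
              paste(unique(x$samples$pop), collapse = ", ")))
  cat(sprintf("missing genotypes: %d / %d\n", sum(is.na(x$a1)), length(x$a1)))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(nrow(x$samples), nrow(x$loci))

# Grouping vector for a table: breed-level ("pop") or locality-level analysis.
group_labels <- function(t, grouping = c("pop", "locality")) {
  grouping <- match.arg(grouping)
  t$samples[[grouping]]
}

#' Subset a genotype table
#'
#' @param t a [genotype_table()].
#' @param samples optional sample ids or logical/integer index.
#' @param loci optional locus names or index.
#' @return A `genotype_table`.
#' @export
subset_genotypes <- function(t, samples = NULL, loci = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(t$samples)) else
    if (is.character(samples)) match(samples, t$samples$id) else samples
  li <- if (is.null(loci)) seq_len(nrow(t$loci)) else
    if (is.character(loci)) match(loci, t$loci$name) else loci
  if (anyNA(si)) stop_fmt("unknown sample id")
  if (anyNA(li)) stop_fmt("unknown locus name")
  genotype_table(t$samples[si, , drop = FALSE], t$loci[li, , drop = FALSE],
                 t$a1[si, li, drop = FALSE], t$a2[si, li, drop = FALSE])
}

# ---------------------------------------------------------------- GenePop I/O

#' Read a GenePop genotype file
#'
#' Parses the GenePop 4.x dialect: a title line, one locus name per line (or
#' one comma-separated line), `POP` markers, and per-sample lines
#' `id , 090110 130130 ...` with 2- or 3-digit allele codes per allele
#' (`0000`/`000000` = missing). Codes are interpreted at face value as
#' fragment sizes in bp. Populations are labelled `pop1`, `pop2`, ... in file
#' order unless the last sample id of a block names the population.
#'
#' @param path file path.
#' @param locus_meta optional [locus_meta()] table; must match the file's
#'   locus names. If omitted, repeat units default to 2 bp.
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path, locus_meta = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop_fmt("%s: not a GenePop file (too short)", path)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3L)
    stop_fmt("%s: no POP line found after the locus list", path)
  locus_lines <- trimws(lines[2:(first_pop - 1L)])
  loci_names <- unlist(strsplit(paste(locus_lines, collapse = ","), ","))
  loci_names <- trimws(loci_names)
  loci_names <- loci_names[nzchar(loci_names)]
  if (is.null(locus_meta)) {
    locus_meta <- locus_meta(loci_names)
  } else {
    if (!setequal(locus_meta$name, loci_names))
      stop_fmt("%s: locus metadata does not match file loci", path)
    locus_meta <- locus_meta[match(loci_names, locus_meta$name), , drop = FALSE]
  }
  L <- length(loci_names)
  ids <- character(); pops <- character(); rows1 <- list(); rows2 <- list()
  pop_idx <- 0L
  for (i in seq_along(lines)) {
    if (i < first_pop) next
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (toupper(line) == "POP") { pop_idx <- pop_idx + 1L; next }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) != 2L)
      stop_fmt("%s line %d: expected 'id , genotypes'", path, i)
    id <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
    if (length(codes) != L)
      stop_fmt("%s line %d: %d genotype fields, expected %d", path, i,
               length(codes), L)
    nc <- nchar(codes)
    if (!all(nc %in% c(4L, 6L)) || length(unique(nc)) != 1L)
      stop_fmt("%s line %d: allele codes must be uniformly 4 or 6 digits", path, i)
    w <- nc[1] / 2L
    v1 <- suppressWarnings(as.integer(substr(codes, 1L, w)))
    v2 <- suppressWarnings(as.integer(substr(codes, w + 1L, nc[1])))
    if (anyNA(v1) || anyNA(v2))
      stop_fmt("%s line %d: non-numeric allele code", path, i)
    v1[v1 == 0L] <- NA_integer_; v2[v2 == 0L] <- NA_integer_
    ids <- c(ids, id); pops <- c(pops, sprintf("pop%d", max(pop_idx, 1L)))
    rows1[[length(rows1) + 1L]] <- v1; rows2[[length(rows2) + 1L]] <- v2
  }
  if (!length(ids)) stop_fmt("%s: no samples parsed", path)
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  genotype_table(data.frame(id = ids, pop = pops, stringsAsFactors = FALSE),
                 locus_meta, do.call(rbind, rows1), do.call(rbind, rows2))
}

#' Write a genotype table as GenePop
#'
#' @param t a [genotype_table()].
#' @param path output path.
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(t, path, title = "pawprint export") {
  sizes <- c(t$a1, t$a2)
  digits <- if (all(is.na(sizes)) || max(sizes, na.rm = TRUE) <= 99L) 2L else 3L
  if (!all(is.na(sizes)) && max(sizes, na.rm = TRUE) > 999L)
    stop_fmt("GenePop codes cannot encode allele sizes > 999 bp")
  fmt <- function(v) {
    v[is.na(v)] <- 0L
    sprintf(paste0("%0", digits, "d"), v)
  }
  out <- c(title, t$loci$name)
  for (p in unique(t$samples$pop)) {
    out <- c(out, "POP")
    idx <- which(t$samples$pop == p)
    for (i in idx) {
      codes <- paste0(fmt(t$a1[i, ]), fmt(t$a2[i, ]))
      out <- c(out, paste0(t$samples$id[i], " , ", paste(codes, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

# -------------------------------------------------------------------- CSV I/O

#' Read genotypes from CSV (wide or long layout)
#'
#' Wide layout: columns `sample,pop[,locality][,sex]` then `<locus>.a1` and
#' `<locus>.a2` per locus. Long layout: columns `sample,pop[,locality],locus,a1,a2`,
#' one row per sample x locus. The layout is detected from the header.
#' Blank, `0` or `NA` alleles mark a missing genotype.
#'
#' @param path file path.
#' @param locus_meta optional [locus_meta()] table.
#' @return A [genotype_table()].
#' @export
read_genotype_csv <- function(path, locus_meta = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("locus", "a1", "a2") %in% names(d))) {
    key <- paste(d$sample, d$locus, sep = "\r")
    if (anyDuplicated(key)) {
      bad <- which(duplicated(key))[1]
      stop_fmt("%s row %d: duplicate sample x locus entry (%s, %s)",
               path, bad + 1L, d$sample[bad], d$locus[bad])
    }
    loci_names <- unique(d$locus)
    ids <- unique(d$sample)
    conv <- function(col, name) {
      x <- suppressWarnings(as.integer(d[[col]]))
      bad <- which(!is.na(d[[col]]) & nzchar(trimws(as.character(d[[col]]))) & is.na(x))
      if (length(bad))
        stop_fmt("%s row %d: non-integer allele '%s'", path, bad[1] + 1L, d[[col]][bad[1]])
      x
    }
    v1 <- conv("a1"); v2 <- conv("a2")
    a1 <- matrix(NA_integer_, length(ids), length(loci_names),
                 dimnames = list(ids, loci_names))
    a2 <- a1
    ri <- match(d$sample, ids); ci <- match(d$locus, loci_names)
    a1[cbind(ri, ci)] <- v1; a2[cbind(ri, ci)] <- v2
    first <- !duplicated(d$sample)
    samples <- data.frame(id = d$sample[first], pop = d$pop[first],
                          stringsAsFactors = FALSE)
    if (!is.null(d$locality)) samples$locality <- d$locality[first]
    if (!is.null(d$sex)) samples$sex <- d$sex[first]
  } else {
    a1_cols <- grep("\\.a1$", names(d), value = TRUE)
    if (!length(a1_cols)) stop_fmt("%s: no '<locus>.a1' columns and no long layout", path)
    loci_names <- sub("\\.a1$", "", a1_cols)
    a2_cols <- paste0(loci_names, ".a2")
    if (!all(a2_cols %in% names(d)))
      stop_fmt("%s: missing .a2 column for loci: %s", path,
               paste(setdiff(loci_names, sub("\\.a2$", "", intersect(a2_cols, names(d)))),
                     collapse = ", "))
    conv <- function(col) {
      x <- suppressWarnings(as.integer(d[[col]]))
      bad <- which(!is.na(d[[col]]) & nzchar(trimws(as.character(d[[col]]))) & is.na(x))
      if (length(bad))
        stop_fmt("%s row %d: non-integer allele '%s' in %s", path, bad[1] + 1L,
                 d[[col]][bad[1]], col)
      x
    }
    a1 <- sapply(a1_cols, conv); a2 <- sapply(a2_cols, conv)
    if (nrow(d) == 1L) { a1 <- matrix(a1, 1L); a2 <- matrix(a2, 1L) }
    colnames(a1) <- colnames(a2) <- loci_names
    samples <- data.frame(id = d$sample, pop = d$pop, stringsAsFactors = FALSE)
    if (!is.null(d$locality)) samples$locality <- d$locality
    if (!is.null(d$sex)) samples$sex <- d$sex
  }
  if (is.null(locus_meta)) locus_meta <- locus_meta(loci_names)
  else locus_meta <- locus_meta[match(loci_names, locus_meta$name), , drop = FALSE]
  genotype_table(samples, locus_meta, a1, a2)
}

#' Write genotypes to CSV
#'
#' @param t a [genotype_table()].
#' @param path output path.
#' @param layout `"wide"` (default) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(t, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (layout == "wide") {
    d <- t$samples
    names(d)[1] <- "sample"
    for (j in seq_len(nrow(t$loci))) {
      d[[paste0(t$loci$name[j], ".a1")]] <- t$a1[, j]
      d[[paste0(t$loci$name[j], ".a2")]] <- t$a2[, j]
    }
  } else {
    n <- nrow(t$samples); L <- nrow(t$loci)
    d <- data.frame(sample = rep(t$samples$id, each = L),
                    pop = rep(t$samples$pop, each = L),
                    locality = rep(t$samples$locality, each = L),
                    locus = rep(t$loci$name, times = n),
                    a1 = as.vector(t(t$a1)), a2 = as.vector(t(t$a2)),
                    stringsAsFactors = FALSE)
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read or write locus metadata as YAML
#'
#' @param path file path.
#' @return [read_locus_meta_yaml()]: a [locus_meta()] table.
#' @export
read_locus_meta_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  locus_meta(vapply(y, function(l) l$name, ""),
             vapply(y, function(l) as.integer(l$repeat_unit_bp), 0L))
}

#' @rdname read_locus_meta_yaml
#' @param meta a [locus_meta()] table.
#' @export
write_locus_meta_yaml <- function(meta, path) {
  y <- lapply(seq_len(nrow(meta)), function(i)
    list(name = meta$name[i], repeat_unit_bp = meta$repeat_unit_bp[i]))
  yaml::write_yaml(y, path)
  invisible(path)
}

# -------------------------------------------------------------- FASTA / D-loop

#' Construct a D-loop alignment
#'
#' An equal-length haplotype alignment over `{A,C,G,T,N,-}` with a population
#' label per sequence.
#'
#' @param ids unique sequence ids.
#' @param pops population labels.
#' @param seqs character vector of equal-length sequences.
#' @return An object of class `dloop_alignment` with elements `ids`, `pops`,
#'   `seqs`, `length`.
#' @export
dloop_alignment <- function(ids, pops, seqs) {
  ids <- as.character(ids); pops <- as.character(pops)
  seqs <- toupper(as.character(seqs))
  if (anyDuplicated(ids)) stop_fmt("sequence ids must be unique")
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop_fmt("alignment error: sequence lengths differ (%s)",
             paste(len, collapse = ", "))
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) stop_fmt("sequence %s contains characters outside {A,C,G,T,N,-}",
                         ids[which(bad)[1]])
  structure(list(ids = ids, pops = pops, seqs = seqs, length = len),
            class = "dloop_alignment")
}

#' @export
print.dloop_alignment <- function(x, ...) {
  cat(sprintf("dloop_alignment: %d sequences x %d bp, %d populations\n",
              length(x$ids), x$length, length(unique(x$pops))))
  invisible(x)
}

#' Read a FASTA haplotype alignment
#'
#' All records must have equal length. The population label is parsed from
#' the header: `>id|pop` or `>id pop` (first token is the id; a `|`-suffix or
#' second whitespace token is the population; otherwise `"pop1"`).
#'
#' @param path FASTA file path.
#' @return A [dloop_alignment()]; sequences are uppercased.
#' @export
read_fasta_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  if (!length(dna)) stop_fmt("%s: no FASTA records", path)
  headers <- names(dna)
  seqs <- vapply(as.character(dna), function(s) paste(s, collapse = ""), "")
  first_tok <- sub("[[:space:]].*$", "", headers)
  rest <- trimws(sub("^[^[:space:]]*", "", headers))
  ids <- first_tok; pops <- rep("pop1", length(ids))
  has_bar <- grepl("|", first_tok, fixed = TRUE)
  ids[has_bar] <- sub("\\|.*$", "", first_tok[has_bar])
  pops[has_bar] <- sub("^[^|]*\\|", "", first_tok[has_bar])
  use_rest <- !has_bar & nzchar(rest)
  pops[use_rest] <- sub("[[:space:]].*$", "", rest[use_rest])
  dloop_alignment(ids, pops, seqs)
}

#' Write a D-loop alignment as FASTA
#'
#' Headers follow the `>id|pop` convention understood by
#' [read_fasta_alignment()].
#'
#' @param a a [dloop_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(a, path) {
  out <- character(2L * length(a$ids))
  out[c(TRUE, FALSE)] <- paste0(">", a$ids, "|", a$pops)
  out[c(FALSE, TRUE)] <- a$seqs
  writeLines(out, path)
  invisible(path)
}

# ------------------------------------------------------------------- writers

#' Write result tables to a directory
#'
#' Writes one TSV per named data.frame plus a `summary.json` manifest with
#' row/column counts. Output is deterministic given the inputs (no
#' timestamps), so repeated runs are byte-identical.
#'
#' @param results named list of data.frames (e.g. a locus summary, ID stats).
#' @param out_dir output directory, created if needed.
#' @return Character vector of files written, invisibly.
#' @export
write_tables <- function(results, out_dir) {
  stopifnot(is.list(results), length(names(results)) == length(results))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  manifest <- list()
  for (nm in names(results)) {
    d <- as.data.frame(results[[nm]])
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    manifest[[nm]] <- list(file = basename(f), rows = nrow(d),
                           columns = names(d))
  }
  jf <- file.path(out_dir, "summary.json")
  jsonlite::write_json(manifest, jf, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, jf))
}
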