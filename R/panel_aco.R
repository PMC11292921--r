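# Panel objective: feasibility (percent distinguished >= 100 - threshold),
# then smallest size, then highest mean PIC, then lexicographic locus names.
# Returns TRUE when x is strictly better than y.
panel_better <- function(x, y) {
  if (is.null(y)) return(TRUE)
  if (x$feasible != y$feasible) return(x$feasible)
  if (x$size != y$size) return(x$size < y$size)
  if (abs(x$mean_pic - y$mean_pic) > 1e-12) return(x$mean_pic > y$mean_pic)
  paste(sort(x$loci), collapse = ",") < paste(sort(y$loci), collapse = ",")
}

# Cached evaluator over locus subsets (bitmask-keyed); percent distinguished
# is computed exactly on the fixed subset.
make_panel_evaluator <- function(codes, pic, threshold) {
  cache <- new.env(parent = emptyenv())
  min_pct <- 100 - threshold
  function(idx) {
    if (!length(idx)) stop_fmt("empty panel")
    idx <- sort(idx)
    key <- paste(idx, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    pct <- percent_distinguished(codes, idx)
    sol <- list(idx = idx, loci = colnames(codes)[idx], size = length(idx),
                mean_pic = mean(pic[idx]), percent = pct,
                feasible = !is.na(pct) && pct >= min_pct - 1e-9)
    cache[[key]] <- sol
    sol
  }
}

panel_solution <- function(sol, iterations = NA_integer_, seed = NA_integer_,
                           method = "aco") {
  structure(list(loci = sol$loci, size = sol$size, mean_pic = sol$mean_pic,
                 percent_distinguished = sol$percent, feasible = sol$feasible,
                 iterations = iterations, seed = seed, method = method),
            class = "panel_solution")
}

#' @export
print.panel_solution <- function(x, ...) {
  cat(sprintf("panel_solution (%s): %d loci [%s]\n", x$method, x$size,
              paste(x$loci, collapse = ", ")))
  cat(sprintf("  mean PIC %.3f, %% distinguished %.2f, feasible: %s\n",
              x$mean_pic, x$percent_distinguished, x$feasible))
  invisible(x)
}

per_locus_pic <- function(t) {
  f <- pooled_freqs(allele_frequencies(t, "all"))
  vapply(f, function(p) {
    if (!length(p)) return(0)
    a2 <- sum(p^2); a4 <- sum(p^4)
    1 - a2 - (a2^2 - a4)
  }, 0)
}

#' Ant-colony-optimized marker panel selection
#'
#' Searches for the smallest locus panel whose exact percent of
#' distinguished individuals is at least `100 - error_threshold`, breaking
#' size ties by higher mean polymorphic information content (PIC). Ants add
#' loci with probability proportional to `tau^alpha * eta^beta`
#' (`eta` = locus PIC) until feasible, then greedily drop redundant loci;
#' pheromone evaporates by `rho` and the iteration-best feasible panel
#' deposits `1/size + mean PIC`.
#'
#' @param t a [genotype_table()].
#' @param error_threshold maximum percent of unresolved individuals
#'   tolerated (default 5).
#' @param ants,iterations colony size and iteration budget.
#' @param alpha,beta,rho pheromone weight, heuristic weight, evaporation.
#' @param seed integer seed.
#' @return A `panel_solution`: selected loci, size, mean PIC, exact percent
#'   distinguished, feasibility flag. If no panel (including all loci) meets
#'   the threshold, the full panel is returned flagged infeasible.
#' @export
aco_select_panel <- function(t, error_threshold = 5, ants = 50L,
                             iterations = 200L, alpha = 1, beta = 2,
                             rho = 0.2, seed = 1L) {
  if (error_threshold <= 0 || error_threshold >= 100)
    stop_fmt("error_threshold must be in (0, 100)")
  codes <- genotype_codes(t)
  pic <- per_locus_pic(t)
  L <- ncol(codes)
  evaluate <- make_panel_evaluator(codes, pic, error_threshold)
  full <- evaluate(seq_len(L))
  if (!full$feasible)
    return(panel_solution(full, iterations = 0L, seed = seed))
  eta <- pmax(pic, 1e-6)^beta
  tau <- rep(1, L)
  best <- NULL
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      iter_best <- NULL
      for (ant in seq_len(ants)) {
        chosen <- integer()
        avail <- seq_len(L)
        sol <- NULL
        while (length(avail)) {
          w <- tau[avail]^alpha * eta[avail]
          pick <- avail[sample.int(length(avail), 1L, prob = w)]
          chosen <- c(chosen, pick)
          avail <- setdiff(avail, pick)
          sol <- evaluate(chosen)
          if (sol$feasible) break
        }
        if (!sol$feasible) next
        # greedy trim: drop loci whose removal keeps the panel feasible
        while (sol$size > 1L) {
          improved <- FALSE
          for (drop in sol$idx) {
            cand <- evaluate(setdiff(sol$idx, drop))
            if (cand$feasible) { sol <- cand; improved <- TRUE; break }
          }
          if (!improved) break
        }
        if (panel_better(sol, iter_best)) iter_best <- sol
      }
      if (!is.null(iter_best)) {
        if (panel_better(iter_best, best)) best <- iter_best
        tau <- (1 - rho) * tau
        tau[iter_best$idx] <- tau[iter_best$idx] +
          1 / iter_best$size + iter_best$mean_pic
      }
    }
  })
  panel_solution(best %||% full, iterations = iterations, seed = seed)
}

#' Exhaustive optimal panel (verification oracle)
#'
#' Enumerates all non-empty locus subsets (feasible only for moderate locus
#' counts) and returns the global optimum under the same objective as
#' [aco_select_panel()]: feasibility, then minimal size, then maximal mean
#' PIC, ties broken lexicographically.
#'
#' @param t a [genotype_table()].
#' @param error_threshold maximum percent unresolved (default 5).
#' @param max_loci enumeration guard (default 15).
#' @return A `panel_solution` (method `"exhaustive"`).
#' @export
exhaustive_best_panel <- function(t, error_threshold = 5, max_loci = 15L) {
  codes <- genotype_codes(t)
  L <- ncol(codes)
  if (L > max_loci) stop_fmt("%d loci exceeds enumeration limit %d", L, max_loci)
  pic <- per_locus_pic(t)
  evaluate <- make_panel_evaluator(codes, pic, error_threshold)
  full <- evaluate(seq_len(L))
  if (!full$feasible)
    return(panel_solution(full, method = "exhaustive"))
  best <- NULL
  # search by size: the first size with a feasible panel is optimal
  for (s in seq_len(L)) {
    combos <- utils::combn(L, s)
    for (c_i in seq_len(ncol(combos))) {
      sol <- evaluate(combos[, c_i])
      if (sol$feasible && panel_better(sol, best)) best <- sol
    }
    if (!is.null(best)) break
  }
  panel_solution(best, method = "exhaustive")
}

#' Evaluate a fixed marker panel
#'
#' No search: reports mean PIC, exact percent of individuals distinguished,
#' and the combined identification statistics for a given locus subset.
#'
#' @param t a [genotype_table()].
#' @param loci locus names.
#' @param error_threshold threshold used for the feasibility flag.
#' @return A `panel_solution` (method `"fixed"`) with an extra
#'   `combined_id_stats` element.
#' @export
evaluate_panel <- function(t, loci, error_threshold = 5) {
  idx <- match(loci, t$loci$name)
  if (anyNA(idx)) stop_fmt("unknown loci: %s",
                           paste(loci[is.na(idx)], collapse = ", "))
  codes <- genotype_codes(t)
  pic <- per_locus_pic(t)
  evaluate <- make_panel_evaluator(codes, pic, error_threshold)
  sol <- panel_solution(evaluate(idx), method = "fixed")
  f <- allele_frequencies(t, "all")
  sol$combined_id_stats <- combine_panel(per_locus_id_stats(f), loci)
  sol
}
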