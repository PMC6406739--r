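# Gene-label permutation control for the selection + enrichment chain.
#
# Each iteration shuffles which gene id carries which (GRE, NGRE) score
# pair, reruns the full extreme-set selection with the SAME selection seed
# (so only the labeling varies), runs term enrichment on both extreme sets,
# and keeps the top_m smallest p-values. The empirical q-value of a set is
# the fraction of iterations whose best (minimum) enrichment p-value is at
# least as small as the observed one; zero beating iterations is reported
# as "< 1/B".

#' Permutation confidence test for term enrichment of the extreme sets
#'
#' @param scores an aggregated `gene_score_table` (or data.frame with
#'   columns `id`, `x`, `y`): the observed assignment of score pairs to
#'   gene ids.
#' @param annotation named list of character vectors (term -> gene ids).
#' @param background universe ids for the enrichment test; defaults to the
#'   scored gene ids.
#' @param selection list of [select_genes()] parameters
#'   (`n_subsets`, `subset_size`, `fraction`, `seed`); the same parameters
#'   and seed are reused inside every iteration.
#' @param B number of permutations, default 500.
#' @param top_m p-values kept per run, default 100.
#' @param seed master seed for the label permutations.
#' @param variant enrichment test variant, see [fisher_tests()].
#' @param estimator `"count"` (q = x/B, default) or `"add_one"`
#'   (the conservative (x+1)/(B+1)).
#' @return object of class `permutation_result`: list with `B`, `top_m`,
#'   `observed_top_p` (list `enriched`/`deficient`, sorted ascending),
#'   `null_top_p` (list of B x top_m matrices), `null_min_p` (list of
#'   length-B vectors), `q_enriched`, `q_deficient`, beat counts
#'   `x_enriched`/`x_deficient`, `seed` and `selection`.
#' @export
permutation_test <- function(scores, annotation, background = NULL,
                             selection = list(), B = 500, top_m = 100,
                             seed = 1L, variant = "standard",
                             estimator = c("count", "add_one")) {
  estimator <- match.arg(estimator)
  if (B < 1) stop("B must be >= 1")
  xy <- as_xy(scores)
  n <- nrow(xy)
  if (is.null(background)) background <- xy$id
  sel_par <- utils::modifyList(
    list(n_subsets = 1000, subset_size = 500, fraction = 0.05, seed = 1L),
    selection)

  run_once <- function(frame) {
    sel <- select_genes(frame, n_subsets = sel_par$n_subsets,
                        subset_size = sel_par$subset_size,
                        fraction = sel_par$fraction, seed = sel_par$seed)
    top_for <- function(ids) {
      res <- term_enrichment(ids, annotation, background, variant = variant)
      sort(res$p_value)[seq_len(min(top_m, nrow(res)))]
    }
    list(enriched = top_for(sel$enriched$id),
         deficient = top_for(sel$deficient$id))
  }

  observed <- run_once(xy)
  obs_min <- vapply(observed, function(p) if (length(p)) min(p) else Inf, 0)

  null_top <- list(enriched = matrix(NA_real_, B, top_m),
                   deficient = matrix(NA_real_, B, top_m))
  perms <- local_seed(seed, replicate(B, sample.int(n), simplify = FALSE))
  for (b in seq_len(B)) {
    frame <- xy
    frame$x <- xy$x[perms[[b]]]
    frame$y <- xy$y[perms[[b]]]
    res <- run_once(frame)
    for (set in c("enriched", "deficient")) {
      p <- res[[set]]
      if (length(p)) null_top[[set]][b, seq_along(p)] <- p
    }
  }
  null_min <- lapply(null_top, function(m) {
    v <- apply(m, 1, function(row) if (all(is.na(row))) Inf
               else min(row, na.rm = TRUE))
    as.numeric(v)
  })
  beats <- vapply(c(enriched = "enriched", deficient = "deficient"),
                  function(s) sum(null_min[[s]] <= obs_min[[s]]), 0L)
  qv <- if (estimator == "count") beats / B else (beats + 1) / (B + 1)

  structure(list(B = B, top_m = top_m,
                 observed_top_p = observed,
                 null_top_p = null_top,
                 null_min_p = null_min,
                 observed_min_p = obs_min,
                 x_enriched = beats[["enriched"]],
                 x_deficient = beats[["deficient"]],
                 q_enriched = qv[["enriched"]],
                 q_deficient = qv[["deficient"]],
                 estimator = estimator,
                 seed = seed, selection = sel_par),
            class = "permutation_result")
}

format_q <- function(x, q, B, estimator) {
  if (estimator == "count" && x == 0) sprintf("< %g", 1 / B)
  else sprintf("%g", q)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation confidence test: B =", x$B, ", top_m =", x$top_m, "\n")
  cat("  enriched:  observed min p =", format(x$observed_min_p[["enriched"]]),
      ", q", format_q(x$x_enriched, x$q_enriched, x$B, x$estimator), "\n")
  cat("  deficient: observed min p =", format(x$observed_min_p[["deficient"]]),
      ", q", format_q(x$x_deficient, x$q_deficient, x$B, x$estimator), "\n")
  invisible(x)
}

#' Long-format null distribution of a permutation test
#'
#' @param x a `permutation_result`.
#' @param set `"enriched"` or `"deficient"`.
#' @return data.frame with columns `iteration`, `rank`, `p`.
#' @export
permutation_null_table <- function(x, set = c("enriched", "deficient")) {
  set <- match.arg(set)
  m <- x$null_top_p[[set]]
  idx <- which(!is.na(m), arr.ind = TRUE)
  out <- data.frame(iteration = idx[, 1], rank = idx[, 2], p = m[idx])
  out[order(out$iteration, out$rank), , drop = FALSE]
}
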