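# Cross-cell-line concordance of score vectors.

#' Pairwise Pearson correlation of scores across cell lines
#'
#' For every pair of cell lines, the Pearson correlation of the chosen
#' score over the ids shared by both tables (ids missing in either table,
#' or with non-finite scores, are dropped pairwise; no imputation). Two-sided
#' p-values come from the t-distribution with `n_shared - 2` degrees of
#' freedom via [stats::cor.test()]. Pairs sharing fewer than 3 ids are
#' flagged missing (`NA`).
#'
#' @param score_tables named list of `gene_score_table` or
#'   `pathway_score_table` objects (names are the cell-line labels; unnamed
#'   tables fall back to their `cell_line` attribute).
#' @param metric one of `"GRE"`, `"NGRE"`, `"PII"`, `"NPII"` (must be a
#'   column of every table).
#' @param diagonal optional named numeric vector (e.g. TFs profiled per
#'   line) stored as informational diagonal metadata.
#' @return object of class `correlation_matrix`: list with `labels`,
#'   symmetric matrices `r`, `p`, `n_shared`, the `metric`, and `diagonal`.
#' @export
correlation_matrix <- function(score_tables,
                               metric = c("GRE", "NGRE", "PII", "NPII"),
                               diagonal = NULL) {
  metric <- match.arg(metric)
  if (length(score_tables) < 2) stop("need at least 2 cell lines")
  labels <- names(score_tables)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- vapply(score_tables, function(t) {
      cl <- attr(t, "cell_line")
      if (is.null(cl) || is.na(cl)) "?" else cl
    }, "")
  vecs <- lapply(score_tables, function(t) {
    if (!metric %in% names(t))
      stop("metric '", metric, "' not present in a score table")
    stats::setNames(t[[metric]], t[[1]])
  })
  m <- length(vecs)
  r <- p <- matrix(NA_real_, m, m, dimnames = list(labels, labels))
  ns <- matrix(0L, m, m, dimnames = list(labels, labels))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(m)) ns[i, i] <- length(vecs[[i]])
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    a <- vecs[[i]]; b <- vecs[[j]]
    shared <- intersect(names(a), names(b))
    av <- a[shared]; bv <- b[shared]
    ok <- is.finite(av) & is.finite(bv)
    ns[i, j] <- ns[j, i] <- sum(ok)
    if (sum(ok) >= 3 && stats::sd(av[ok]) > 0 && stats::sd(bv[ok]) > 0) {
      ct <- stats::cor.test(av[ok], bv[ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(labels = labels, metric = metric, r = r, p = p,
                 n_shared = ns, diagonal = diagonal),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("pairwise Pearson correlation of", x$metric, "across",
      length(x$labels), "cell lines\n")
  off <- x$r[upper.tri(x$r)]
  if (any(is.finite(off)))
    cat(sprintf("  off-diagonal r: median %.3f (range %.3f..%.3f)\n",
                stats::median(off, na.rm = TRUE), min(off, na.rm = TRUE),
                max(off, na.rm = TRUE)))
  print(round(x$r, 3))
  invisible(x)
}

#' Long-format pair table of a correlation matrix
#'
#' @param x a `correlation_matrix`.
#' @return data.frame with columns `line_a`, `line_b`, `metric`, `r`, `p`,
#'   `n_shared`, one row per unordered pair.
#' @export
correlation_pairs <- function(x) {
  stopifnot(inherits(x, "correlation_matrix"))
  m <- length(x$labels)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  data.frame(line_a = x$labels[idx[, 1]], line_b = x$labels[idx[, 2]],
             metric = x$metric, r = x$r[idx], p = x$p[idx],
             n_shared = x$n_shared[idx], stringsAsFactors = FALSE)
}
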