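# Extreme-set selection on the (score, normalized score) scatter.
#
# Genes: 1000 random 500-gene subsets are each fit by ordinary least
# squares; the fits with the highest and lowest slope bound the cloud. The
# 5% of genes strictly above the high-slope line with the largest Euclidean
# point-to-line distance are RRE-enriched; the 5% strictly below the
# low-slope line are RRE-deficient. Pathways: one OLS fit on all points,
# same 5% distance rule on both sides.
#
# "Above/below" is the sign of the vertical residual y - (a x + b); the
# Euclidean distance is used only to rank candidates. Ties are broken by id
# so the selection is order-invariant and fully reproducible from the seed.

#' Ordinary least-squares line fit
#'
#' @param x,y numeric vectors.
#' @return object of class `line_fit` with `slope`, `intercept`, `n_points`.
#' @export
line_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) stop("degenerate fit: x has zero variance")
  slope <- stats::cov(x, y) / vx
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x),
                 n_points = length(x)), class = "line_fit")
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf("line fit: y = %.6g x + %.6g  (n = %d)\n",
              x$slope, x$intercept, x$n_points))
  invisible(x)
}

#' Euclidean distance from points to a line
#'
#' For the line `y = slope * x + intercept`, the distance of `(x, y)` is
#' `|slope * x - y + intercept| / sqrt(slope^2 + 1)`.
#'
#' @param line a `line_fit` (or list with `slope` and `intercept`).
#' @param x,y point coordinates (vectorized).
#' @return numeric vector of distances.
#' @export
#' @examples
#' point_line_distance(list(slope = 1, intercept = 0), 0, 1)  # 1/sqrt(2)
point_line_distance <- function(line, x, y) {
  abs(line$slope * x - y + line$intercept) / sqrt(line$slope^2 + 1)
}

# canonical xy frame: id, x, y sorted by id; accepts a gene_score_table
# (x = GRE, y = NGRE), a pathway_score_table (x = PII, y = NPII) or a
# plain data.frame(id, x, y)
as_xy <- function(points) {
  if (all(c("GRE", "NGRE") %in% names(points))) {
    df <- data.frame(id = points[[1]], x = points$GRE, y = points$NGRE,
                     stringsAsFactors = FALSE)
  } else if (all(c("PII", "NPII") %in% names(points))) {
    df <- data.frame(id = points[[1]], x = points$PII, y = points$NPII,
                     stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("id", "x", "y") %in% names(points)))
    df <- points[, c("id", "x", "y")]
  }
  df <- df[is.finite(df$x) & is.finite(df$y), , drop = FALSE]
  df <- df[order(df$id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

standardize_xy <- function(xy) {
  xy$x <- as.numeric(scale(xy$x))
  xy$y <- as.numeric(scale(xy$y))
  xy
}

# rank candidates on one side of a line and take the quota
pick_side <- function(xy, line, side, quota) {
  resid <- xy$y - (line$slope * xy$x + line$intercept)
  # points numerically on the line are on neither side
  tol <- 1e-9 * (abs(xy$x) + abs(xy$y) + 1)
  keep <- if (side == "above") resid > tol else resid < -tol
  cand <- xy[keep, , drop = FALSE]
  d <- point_line_distance(line, cand$x, cand$y)
  ord <- order(-d, cand$id)
  take <- utils::head(ord, quota)
  data.frame(id = cand$id[take], x = cand$x[take], y = cand$y[take],
             distance = d[take], stringsAsFactors = FALSE)
}

finish_selection <- function(xy, line_high, line_low, fraction, seed = NULL) {
  quota <- floor(fraction * nrow(xy))
  enriched <- pick_side(xy, line_high, "above", quota)
  deficient <- pick_side(xy, line_low, "below", quota)
  structure(list(
    enriched = enriched, deficient = deficient,
    line_high = line_high, line_low = line_low,
    fraction = fraction, quota = quota, n = nrow(xy), seed = seed,
    shortfall = c(enriched = nrow(enriched) < quota,
                  deficient = nrow(deficient) < quota)
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "selection: %d points, fraction %.3g -> quota %d\n", x$n, x$fraction,
    x$quota))
  cat(sprintf("  enriched:  %d (line slope %.4g)\n", nrow(x$enriched),
              x$line_high$slope))
  cat(sprintf("  deficient: %d (line slope %.4g)\n", nrow(x$deficient),
              x$line_low$slope))
  if (any(x$shortfall))
    cat("  shortfall:", paste(names(x$shortfall)[x$shortfall], collapse = ", "),
        "\n")
  invisible(x)
}

#' Select RRE-enriched and RRE-deficient genes
#'
#' Draws `n_subsets` random subsets of `subset_size` genes (without
#' replacement within a subset, independently across subsets), fits each by
#' least squares, and bounds the cloud with the maximum- and minimum-slope
#' fits. The `floor(fraction * N)` genes strictly above the high-slope line
#' with the largest Euclidean distance are enriched; the same count
#' strictly below the low-slope line are deficient. Subset draws are keyed
#' to the canonical ordering of genes by id, so the result depends only on
#' the id/score pairs and the seed, not on input row order. If fewer
#' candidates exist than the quota, all are returned and the shortfall is
#' flagged.
#'
#' @param points a `gene_score_table` (GRE on x, NGRE on y) or a data.frame
#'   with columns `id`, `x`, `y`. Non-finite scores are dropped.
#' @param n_subsets number of random subsets, default 1000.
#' @param subset_size genes per subset, default 500.
#' @param fraction selection fraction per side, default 0.05.
#' @param seed integer seed governing all subset draws.
#' @param standardize scale both axes to unit variance before fitting
#'   (sensitivity analysis; default `FALSE`, raw axes).
#' @return an object of class `selection_result`.
#' @export
select_genes <- function(points, n_subsets = 1000, subset_size = 500,
                         fraction = 0.05, seed = 1L, standardize = FALSE) {
  xy <- as_xy(points)
  if (standardize) xy <- standardize_xy(xy)
  n <- nrow(xy)
  if (subset_size > n)
    stop("subset_size (", subset_size, ") exceeds number of genes (", n, ")")
  idx <- local_seed(seed, {
    vapply(seq_len(n_subsets), function(i) sample.int(n, subset_size),
           integer(subset_size))
  })  # subset_size x n_subsets
  xm <- matrix(xy$x[idx], nrow(idx), ncol(idx))
  ym <- matrix(xy$y[idx], nrow(idx), ncol(idx))
  mx <- colMeans(xm); my <- colMeans(ym)
  vx <- colMeans(xm * xm) - mx^2
  cxy <- colMeans(xm * ym) - mx * my
  ok <- vx > 0
  if (!any(ok)) stop("all subsets degenerate: x has zero variance")
  slopes <- cxy[ok] / vx[ok]
  inter <- my[ok] - slopes * mx[ok]
  hi <- which.max(slopes); lo <- which.min(slopes)
  mk <- function(i) structure(list(slope = slopes[i], intercept = inter[i],
                                   n_points = subset_size), class = "line_fit")
  finish_selection(xy, mk(hi), mk(lo), fraction, seed = seed)
}

#' Select RRE-enriched and RRE-deficient pathways
#'
#' A single least-squares fit on all points (no subsetting); the
#' `floor(fraction * N)` pathways above the line with the largest Euclidean
#' distance are enriched, the same count below are deficient. Tie and
#' shortfall rules match [select_genes()].
#'
#' @param points a `pathway_score_table` (PII on x, NPII on y) or a
#'   data.frame with columns `id`, `x`, `y`.
#' @param fraction selection fraction per side, default 0.05.
#' @param standardize scale both axes to unit variance before fitting
#'   (default `FALSE`).
#' @return an object of class `selection_result`.
#' @export
select_pathways <- function(points, fraction = 0.05, standardize = FALSE) {
  xy <- as_xy(points)
  if (nrow(xy) < 2) stop("need at least 2 pathways with finite scores")
  if (standardize) xy <- standardize_xy(xy)
  fit <- line_fit(xy$x, xy$y)
  finish_selection(xy, fit, fit, fraction)
}

# evaluate expr under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
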