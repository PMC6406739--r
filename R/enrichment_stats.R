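# Exact hypergeometric and Fisher/EASE enrichment statistics.
#
# Tails are accumulated in log space (lchoose + log-sum-exp) so values of
# order 1e-18 keep full relative precision. The two one-sided tests are
# exact complements:
#   upper:  P(X >= k)   -- "the class IS over-represented"
#   lower:  P(X <  k)   -- "the class is NOT over-represented"
# The strict lower tail is the convention under which the depletion
# p-values of the miRNA/lncRNA class tests reproduce; an `inclusive` flag
# gives P(X <= k) instead.

logsumexp <- function(v) {
  if (length(v) == 0) return(-Inf)
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

check_counts <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0)) stop("counts must be non-negative")
  if (K > N) stop("class size K exceeds background N")
  if (n > N) stop("sample size n exceeds background N")
  if (k > min(n, K)) stop("overlap k exceeds min(n, K)")
  if (k < max(0, n - (N - K))) stop("overlap k below max(0, n - (N - K))")
  invisible(TRUE)
}

# log P(X = i) for Hypergeometric(N, K, n), vectorized over i
log_hyper_pmf <- function(i, n, K, N) {
  lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
}

#' Exact hypergeometric tail probability
#'
#' For `X ~ Hypergeometric(N, K, n)` (draw `n` from a background of `N`
#' containing `K` class members), computes the enrichment tail
#' `P(X >= k)` (`tail = "upper"`) or the depletion tail `P(X < k)`
#' (`tail = "lower"`; set `inclusive = TRUE` for `P(X <= k)`). Summation is
#' in log space over the exact support, accurate to at least 12 significant
#' digits.
#'
#' @param k observed overlap count.
#' @param n selected-set size.
#' @param K class size in the background.
#' @param N background size.
#' @param tail `"upper"` or `"lower"`.
#' @param inclusive for the lower tail only: include `P(X = k)` itself.
#' @param log.p return the natural log of the tail probability.
#' @return tail probability (scalar).
#' @export
#' @examples
#' hypergeom_tail(5, 5, 5, 10)            # 1/choose(10,5)
#' hypergeom_tail(2, 10, 20, 60, "lower") # P(X < 2)
hypergeom_tail <- function(k, n, K, N, tail = c("upper", "lower"),
                           inclusive = FALSE, log.p = FALSE) {
  tail <- match.arg(tail)
  check_counts(k, n, K, N)
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  if (tail == "upper") {
    lp <- logsumexp(log_hyper_pmf(k:hi, n, K, N))
  } else {
    top <- if (inclusive) k else k - 1
    lp <- if (top < lo) -Inf else logsumexp(log_hyper_pmf(lo:top, n, K, N))
  }
  lp <- min(lp, 0)
  if (log.p) lp else exp(lp)
}

#' One-sided Fisher's exact enrichment test, with the EASE variant
#'
#' The standard one-sided enrichment p-value of a 2x2 table equals the
#' upper hypergeometric tail `P(X >= k)`. The `"ease"` variant (DAVID's
#' conservative EASE score) replaces `k` with `max(k - 1, 0)` before taking
#' the tail, penalizing terms supported by a single gene.
#'
#' @inheritParams hypergeom_tail
#' @param variant `"standard"` or `"ease"`.
#' @return enrichment p-value (scalar).
#' @export
fisher_tests <- function(k, n, K, N, variant = c("standard", "ease")) {
  variant <- match.arg(variant)
  check_counts(k, n, K, N)
  if (variant == "ease") k <- max(k - 1, 0)
  k <- max(k, max(0, n - (N - K)))  # EASE decrement may undershoot support
  hypergeom_tail(k, n, K, N, tail = "upper")
}

#' Gene-class enrichment or depletion test
#'
#' Builds the contingency counts from id sets (`N = |background|`,
#' `K = |class in background|`, `n = |selected|`,
#' `k = |selected in class|`) and tests the upper tail for
#' `direction = "enriched"` or the strict lower tail for
#' `direction = "depleted"`.
#'
#' @param selected character vector of selected gene ids (must lie in
#'   `background`).
#' @param class_members character vector of class member ids.
#' @param background character vector of background (universe) ids.
#' @param direction `"enriched"` or `"depleted"`.
#' @param inclusive passed to [hypergeom_tail()] for the depleted tail.
#' @return one-row data.frame with `k`, `n`, `K`, `N`, `fold_enrichment`
#'   (`(k/n) / (K/N)`), `p_value` and `test`.
#' @export
class_enrichment <- function(selected, class_members, background,
                             direction = c("enriched", "depleted"),
                             inclusive = FALSE) {
  direction <- match.arg(direction)
  selected <- unique(selected)
  background <- unique(background)
  if (!all(selected %in% background))
    stop("selected set contains ids outside the background")
  class_bg <- unique(intersect(class_members, background))
  k <- length(intersect(selected, class_bg))
  n <- length(selected)
  K <- length(class_bg)
  N <- length(background)
  p <- if (direction == "enriched")
    hypergeom_tail(k, n, K, N, "upper")
  else hypergeom_tail(k, n, K, N, "lower", inclusive = inclusive)
  data.frame(k = k, n = n, K = K, N = N,
             fold_enrichment = if (n > 0 && K > 0) (k / n) / (K / N) else NA,
             p_value = p,
             test = if (direction == "enriched") "hypergeom_upper"
                    else "hypergeom_lower",
             stringsAsFactors = FALSE)
}

#' Term enrichment over an annotation collection
#'
#' Tests each term's gene set (intersected with the background) for
#' over-representation in the selected set. Terms with zero overlap are
#' omitted. Raw p-values are reported with a `significant` flag at `alpha`
#' (no multiple-testing correction by default, matching the 0.05 raw
#' cutoff convention; `adjust = "BH"` adds a Benjamini-Hochberg column and
#' flags on it instead).
#'
#' @param selected character vector of selected gene ids.
#' @param annotation named list of character vectors (term -> gene ids),
#'   e.g. from [read_gmt()].
#' @param background character vector of universe ids.
#' @param variant `"standard"` or `"ease"`, see [fisher_tests()].
#' @param alpha significance cutoff on the reported p, default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame sorted by ascending p with columns `term_id`, `k`,
#'   `n`, `K`, `N`, `fold_enrichment`, `p_value` (and `p_adjusted` when
#'   `adjust = "BH"`), `significant`.
#' @export
term_enrichment <- function(selected, annotation, background,
                            variant = c("standard", "ease"), alpha = 0.05,
                            adjust = c("none", "BH")) {
  variant <- match.arg(variant)
  adjust <- match.arg(adjust)
  if (length(annotation) == 0) stop("empty annotation collection")
  selected <- unique(selected)
  background <- unique(background)
  if (!all(selected %in% background))
    stop("selected set contains ids outside the background")
  n <- length(selected)
  N <- length(background)
  rows <- lapply(names(annotation), function(term) {
    members <- unique(intersect(annotation[[term]], background))
    K <- length(members)
    k <- length(intersect(selected, members))
    if (k == 0) return(NULL)
    data.frame(term_id = term, k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N),
               p_value = fisher_tests(k, n, K, N, variant = variant),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    out <- data.frame(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(),
                      fold_enrichment = numeric(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  rownames(out) <- NULL
  out
}
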