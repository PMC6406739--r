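# Evolutionary age classification of repeat families.
#
# The age proxy is the mean divergence of a family's copies from the
# RepeatMasker consensus: low divergence means recent amplification.
# Families averaging strictly below the threshold (default 8%, roughly the
# human / New World monkey split) form the "young" fraction; the "all"
# fraction reflects genome shaping since the major eutherian radiations.

#' Summarize repeat families by mean divergence
#'
#' Computes, per family, the copy count, arithmetic mean percent divergence
#' and the young/old call (strictly below `young_threshold_pct` is young).
#'
#' @param repeats data.frame of repeat annotations
#'   (see [read_repeatmasker()]).
#' @param young_threshold_pct percent-divergence cutoff, default 8.
#' @param level `"family"` averages per repName (default); `"copy"` treats
#'   every copy as its own unit (per-copy classification).
#' @return data.frame with columns `family`, `n_copies`,
#'   `mean_divergence_pct`, `is_young`, one row per family, ordered by
#'   family name.
#' @export
#' @examples
#' reps <- data.frame(chrom = "chr1", start = c(0, 100), end = c(50, 150),
#'                    strand = "+", family = "AluYa5",
#'                    repeat_class = "SINE", divergence_pct = c(7, 8.8))
#' summarize_families(reps)  # mean 7.9 -> young
summarize_families <- function(repeats, young_threshold_pct = 8,
                               level = c("family", "copy")) {
  level <- match.arg(level)
  if (nrow(repeats) == 0) stop("no repeat annotations to summarize")
  if (young_threshold_pct <= 0 || young_threshold_pct >= 100)
    stop("young_threshold_pct must be in (0, 100)")
  key <- if (level == "family") repeats$family else
    sprintf("%s:%d", repeats$family, seq_len(nrow(repeats)))
  agg <- tapply(repeats$divergence_pct, key, mean)
  cnt <- tapply(rep(1L, nrow(repeats)), key, sum)
  fam <- sort(names(agg))
  data.frame(
    family = fam,
    n_copies = as.integer(cnt[fam]),
    mean_divergence_pct = as.numeric(agg[fam]),
    is_young = as.numeric(agg[fam]) < young_threshold_pct,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Filter repeat annotations to an evolutionary age fraction
#'
#' `fraction = "all"` returns the input unchanged; `fraction = "young"`
#' keeps only copies whose family mean divergence is strictly below the
#' threshold (or, with `level = "copy"`, whose own divergence is).
#' Downstream scoring must tolerate genes with zero hits after young-only
#' filtering: sparse young-RE coverage is expected.
#'
#' @inheritParams summarize_families
#' @param fraction `"all"` or `"young"`.
#' @return data.frame of repeat annotations, a subset of the input rows.
#' @export
filter_by_age <- function(repeats, fraction = c("all", "young"),
                          young_threshold_pct = 8,
                          level = c("family", "copy")) {
  fraction <- match.arg(fraction)
  level <- match.arg(level)
  if (fraction == "all") return(repeats)
  if (nrow(repeats) == 0) stop("no repeat annotations to filter")
  if (level == "copy") {
    keep <- repeats$divergence_pct < young_threshold_pct
  } else {
    fam <- summarize_families(repeats, young_threshold_pct, level = "family")
    young <- fam$family[fam$is_young]
    keep <- repeats$family %in% young
  }
  repeats[keep, , drop = FALSE]
}
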