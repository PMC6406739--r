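# Assignment of TFBS hits to repeat intervals and TSS neighborhoods.
#
# A "hit" is one thresholded ChIP-seq peak (or a signal-weighted variant).
# Under the default model a hit lives at its summit; it is RE-linked iff the
# summit falls inside at least one repeat interval, and it contributes its
# weight to every gene whose TSS window contains the summit (no splitting
# between overlapping windows). Per-gene S (RE-linked weight) and T (total
# weight) feed the GRE/NGRE scores.

#' Describe how peaks are counted as hits
#'
#' @param mode `"summit"` (default; each peak is one hit located at its
#'   summit, weight from the peak's `weight` column), `"any_overlap"`
#'   (a hit is assigned to every window its interval overlaps by >= 1 bp), or
#'   `"signal_weighted"` (summit location, weight from the `signal` column).
#' @param re_rule `"summit_in_re"` (default; RE-linked iff the hit location
#'   is inside a repeat) or `"any_bp_overlap"` (RE-linked iff the peak
#'   interval overlaps a repeat).
#' @return an object of class `hit_model`.
#' @export
hit_model <- function(mode = c("summit", "any_overlap", "signal_weighted"),
                      re_rule = c("summit_in_re", "any_bp_overlap")) {
  structure(list(mode = match.arg(mode), re_rule = match.arg(re_rule)),
            class = "hit_model")
}

#' Compute the 10 kb TSS neighborhood of each gene
#'
#' The transcription start site is `start` (txStart) on the plus strand and
#' `end - 1` (the last transcribed base) on the minus strand. The window
#' spans `flank` bases on either side of the TSS, clipped at position 0, so
#' its width is at most `2 * flank`.
#'
#' @param genes data.frame as returned by [read_gene_table()].
#' @param flank bases on each side of the TSS, default 5000 (a 10 kb
#'   neighborhood).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
#' @examples
#' g <- data.frame(gene_id = "g1", symbol = "g1", chrom = "chr1",
#'                 strand = "+", start = 100000, end = 120000)
#' tss_window(g)  # [95000, 105000)
tss_window <- function(genes, flank = 5000) {
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0, tss - flank), end = tss + flank,
             stringsAsFactors = FALSE)
}

# 0-based half-open data.frame -> GRanges (1-based closed)
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}

# hit location under summit-style models: summit if recorded, else midpoint
hit_location <- function(peaks) {
  ifelse(peaks$summit_offset >= 0,
         peaks$start + peaks$summit_offset,
         floor((peaks$start + peaks$end) / 2))
}

#' Assign TFBS hits to repeats and TSS windows
#'
#' Produces the per-gene RE-linked (`S`) and total (`T`) hit weights within
#' each gene's TSS neighborhood, plus genome-wide and window-restricted
#' totals split by repeat class. Hits on chromosomes absent from both the
#' gene and repeat tables still count toward genome totals but are never
#' window-assigned (reported once per chromosome via `message`). When
#' repeats overlap, class attribution uses the smallest containing repeat
#' (the most specific annotation); RE linkage itself is a boolean.
#'
#' @param peaks data.frame of peaks (see [read_peaks()]); typically the
#'   concatenation over all TFs profiled in one cell line.
#' @param repeats data.frame of repeat annotations, already filtered to the
#'   desired age fraction (see [filter_by_age()]).
#' @param genes data.frame of genes (see [read_gene_table()]).
#' @param model a [hit_model()].
#' @param flank TSS window half-width, default 5000.
#' @param cell_line label stored on the result; defaults to the peaks'
#'   `cell_line` value.
#' @return an object of class `hit_table`: a list with `cell_line`, `genes`
#'   (data.frame `gene_id`, `S`, `T` covering every input gene) and
#'   `genome_totals` (lists `genome` and `tss`, each holding `total`,
#'   `re_linked` and `per_class` weights).
#' @export
assign_hits <- function(peaks, repeats, genes, model = hit_model(),
                        flank = 5000, cell_line = NULL) {
  stopifnot(inherits(model, "hit_model"))
  if (is.null(cell_line)) {
    cl <- unique(peaks$cell_line)
    cell_line <- if (length(cl) == 1) cl else NA_character_
  }
  windows <- tss_window(genes, flank = flank)
  known <- unique(c(genes$chrom, repeats$chrom))
  stray <- setdiff(unique(peaks$chrom), known)
  for (ch in stray)
    message("peaks on chromosome ", ch,
            " absent from gene/repeat tables: genome totals only")

  n <- nrow(peaks)
  weight <- if (model$mode == "signal_weighted") peaks$signal else peaks$weight
  loc <- hit_location(peaks)

  # the query ranges used for RE linkage and for window assignment
  point_gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom, ranges = IRanges::IRanges(loc + 1, loc + 1))
  interval_gr <- as_granges0(peaks)
  re_query <- if (model$re_rule == "summit_in_re") point_gr else interval_gr
  win_query <- if (model$mode == "any_overlap") interval_gr else point_gr

  re_gr <- as_granges0(repeats)
  hit_class <- rep(NA_character_, n)
  re_linked <- rep(FALSE, n)
  if (nrow(repeats) > 0 && n > 0) {
    ov <- GenomicRanges::findOverlaps(re_query, re_gr)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    re_linked[unique(q)] <- TRUE
    if (length(q) > 0) {
      # smallest containing repeat wins class attribution
      w <- repeats$end[s] - repeats$start[s]
      ord <- order(q, w)
      first <- !duplicated(q[ord])
      hit_class[q[ord][first]] <- repeats$repeat_class[s[ord][first]]
    }
  }

  per_gene_S <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  per_gene_T <- per_gene_S
  in_window <- rep(FALSE, n)
  if (nrow(windows) > 0 && n > 0) {
    win_gr <- as_granges0(windows)
    ov <- GenomicRanges::findOverlaps(win_query, win_gr)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    in_window[unique(q)] <- TRUE
    if (length(q) > 0) {
      gid <- windows$gene_id[s]
      tt <- tapply(weight[q], gid, sum)
      per_gene_T[names(tt)] <- as.numeric(tt)
      lk <- re_linked[q]
      if (any(lk)) {
        ss <- tapply(weight[q][lk], gid[lk], sum)
        per_gene_S[names(ss)] <- as.numeric(ss)
      }
    }
  }

  totals_for <- function(idx) {
    per_class <- stats::setNames(numeric(3), c("SINE", "LINE", "LTR/ERV"))
    for (cls in names(per_class)) {
      sel <- idx & re_linked & !is.na(hit_class) & hit_class == cls
      per_class[cls] <- sum(weight[sel])
    }
    list(total = sum(weight[idx]),
         re_linked = sum(weight[idx & re_linked]),
         per_class = per_class)
  }

  structure(list(
    cell_line = cell_line,
    genes = data.frame(gene_id = genes$gene_id, S = unname(per_gene_S),
                       T = unname(per_gene_T), stringsAsFactors = FALSE),
    genome_totals = list(genome = totals_for(rep(TRUE, n)),
                         tss = totals_for(in_window)),
    model = model, flank = flank
  ), class = "hit_table")
}

#' @export
print.hit_table <- function(x, ...) {
  cat("TFBS hit table", if (!is.na(x$cell_line)) paste0("(", x$cell_line, ")"),
      "\n")
  cat("  genes:", nrow(x$genes), " with hits:", sum(x$genes$T > 0), "\n")
  gt <- x$genome_totals$genome
  cat(sprintf("  genome-wide hits: %g (RE-linked %g)\n", gt$total, gt$re_linked))
  invisible(x)
}

#' Per-class fractions of RE-linked hits
#'
#' Expresses, genome-wide and restricted to TSS windows, the percentage of
#' hit weight falling on SINEs, LINEs and LTR/ERVs, plus the overall
#' RE-linked percentage (the table layout mirrors per-cell-line TFBS
#' mapping summaries).
#'
#' @param table a `hit_table` from [assign_hits()].
#' @return data.frame with columns `scope` (`genome`/`tss`), `total`,
#'   `pct_re_linked`, `pct_SINE`, `pct_LINE`, `pct_LTR_ERV`.
#' @export
re_class_summary <- function(table) {
  stopifnot(inherits(table, "hit_table"))
  row_for <- function(scope) {
    t <- table$genome_totals[[scope]]
    if (t$total == 0) stop("zero total hit weight in scope '", scope, "'")
    data.frame(scope = scope, total = t$total,
               pct_re_linked = 100 * t$re_linked / t$total,
               pct_SINE = 100 * t$per_class[["SINE"]] / t$total,
               pct_LINE = 100 * t$per_class[["LINE"]] / t$total,
               pct_LTR_ERV = 100 * t$per_class[["LTR/ERV"]] / t$total,
               stringsAsFactors = FALSE)
  }
  rbind(row_for("genome"), row_for("tss"))
}
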