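# Gene and pathway regulatory-load scores.
#
# GRE_g  = S_g / mean(S)                      (RE-linked load vs the average
#                                              gene; mean over genes = 1)
# NGRE_g = (S_g / mean(S)) / (T_g / mean(T))  (RE-linked load relative to the
#                                              gene's balanced total load;
#                                              0 when T_g = 0)
# PII_p  = sum over scored pathway members of GRE_g        (additive; a
#          size-normalized mean mode is selectable)
# NPII_p = (sum S_g / mean(S)) / (sum T_g / mean(T)) over members (ratio of
#          pooled loads; a sum-of-NGRE mode is selectable)
#
# These are the minimal formulas consistent with the verbal definitions:
# GRE "normalized on the average content of RE-specific TFBS hits for all
# genes", NGRE "double-normalized" to that average and to the gene's
# balanced total, PII an additive pathway aggregate, NPII the relative
# pathway-level counterpart (a pathway whose pooled RE share equals the
# all-gene average share scores exactly 1).

#' Per-gene GRE score
#'
#' @param hit_table a `hit_table` from [assign_hits()], or any data.frame
#'   with columns `gene_id`, `S`, `T`.
#' @return numeric vector of GRE values named by gene id; mean exactly 1.
#' @export
gre <- function(hit_table) {
  g <- hit_genes(hit_table)
  if (all(g$S == 0))
    stop("no RE-linked hits in any window: GRE undefined ",
         "(young-RE fractions can be sparse; check the age filter)")
  stats::setNames(g$S / mean(g$S), g$gene_id)
}

#' Per-gene NGRE score
#'
#' Genes with no hits at all (`T = 0`, hence `S = 0`) get NGRE 0 by
#' convention: a gene with no measured regulation has no measurable RE
#' share. NGRE is invariant under global rescaling of hit weights.
#'
#' @inheritParams gre
#' @return numeric vector of NGRE values named by gene id.
#' @export
ngre <- function(hit_table) {
  g <- hit_genes(hit_table)
  if (all(g$S == 0)) stop("no RE-linked hits in any window: NGRE undefined")
  if (all(g$T == 0)) stop("no hits in any window: NGRE undefined")
  num <- g$S / mean(g$S)
  den <- g$T / mean(g$T)
  out <- ifelse(g$T == 0, 0, num / ifelse(den == 0, NA, den))
  stats::setNames(out, g$gene_id)
}

hit_genes <- function(hit_table) {
  g <- if (inherits(hit_table, "hit_table")) hit_table$genes else hit_table
  stopifnot(is.data.frame(g), all(c("gene_id", "S", "T") %in% names(g)))
  if (nrow(g) == 0) stop("empty gene table")
  if (any(g$S > g$T)) stop("S > T for some gene: invalid hit table")
  g
}

#' Build a per-gene score table (S, T, GRE, NGRE)
#'
#' @inheritParams gre
#' @param cell_line label stored on the table; defaults to the hit table's.
#' @return data.frame of class `gene_score_table` with columns `gene_id`,
#'   `S`, `T`, `GRE`, `NGRE` and a `cell_line` attribute.
#' @export
score_genes <- function(hit_table, cell_line = NULL) {
  g <- hit_genes(hit_table)
  if (is.null(cell_line) && inherits(hit_table, "hit_table"))
    cell_line <- hit_table$cell_line
  out <- data.frame(gene_id = g$gene_id, S = g$S, T = g$T,
                    GRE = unname(gre(hit_table)),
                    NGRE = unname(ngre(hit_table)),
                    stringsAsFactors = FALSE)
  structure(out, cell_line = cell_line,
            class = c("gene_score_table", "data.frame"))
}

#' Per-pathway PII score
#'
#' Additive by default: the sum of member GRE scores over pathway genes
#' present in the score table (missing members are skipped and counted).
#' Pathways with no scored member are flagged and get `NA`, never a silent
#' zero.
#'
#' @param gene_scores a `gene_score_table` from [score_genes()].
#' @param pathways named list of character vectors (see [read_gmt()]).
#' @param mode `"sum"` (default) or `"mean"` (size-normalized).
#' @return data.frame with columns `pathway_id`, `PII`, `n_genes_scored`,
#'   `n_genes_missing`, `flagged`.
#' @export
pii <- function(gene_scores, pathways, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  score <- stats::setNames(gene_scores$GRE, gene_scores$gene_id)
  rows <- lapply(names(pathways), function(id) {
    members <- pathways[[id]]
    hit <- members[members %in% names(score)]
    val <- if (length(hit) == 0) NA_real_
           else if (mode == "sum") sum(score[hit]) else mean(score[hit])
    data.frame(pathway_id = id, PII = val,
               n_genes_scored = length(hit),
               n_genes_missing = length(members) - length(hit),
               flagged = length(hit) == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  miss <- sum(out$n_genes_missing)
  if (miss > 0)
    message(miss, " pathway member id(s) absent from the score table skipped")
  out
}

#' Per-pathway NPII score
#'
#' Default mode pools S and T over the pathway's scored members and takes
#' the ratio of their normalized sums, so a pathway whose pooled RE share
#' equals the all-gene average share scores exactly 1 (and a single-gene
#' pathway scores that gene's NGRE). The alternative `"sum_ngre"` mode sums
#' member NGRE values. Pathways with zero pooled T are flagged (`NA`).
#'
#' @inheritParams pii
#' @param mode `"ratio_of_sums"` (default) or `"sum_ngre"`.
#' @return data.frame with columns `pathway_id`, `NPII`, `n_genes_scored`,
#'   `flagged`.
#' @export
npii <- function(gene_scores, pathways,
                 mode = c("ratio_of_sums", "sum_ngre")) {
  mode <- match.arg(mode)
  ms <- mean(gene_scores$S)
  mt <- mean(gene_scores$T)
  idx <- stats::setNames(seq_len(nrow(gene_scores)), gene_scores$gene_id)
  rows <- lapply(names(pathways), function(id) {
    hit <- idx[pathways[[id]][pathways[[id]] %in% names(idx)]]
    if (length(hit) == 0)
      return(data.frame(pathway_id = id, NPII = NA_real_, n_genes_scored = 0L,
                        flagged = TRUE, stringsAsFactors = FALSE))
    if (mode == "ratio_of_sums") {
      st <- sum(gene_scores$T[hit])
      val <- if (st == 0) NA_real_ else
        (sum(gene_scores$S[hit]) / ms) / (st / mt)
      flag <- st == 0
    } else {
      val <- sum(gene_scores$NGRE[hit])
      flag <- FALSE
    }
    data.frame(pathway_id = id, NPII = val, n_genes_scored = length(hit),
               flagged = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build a per-pathway score table (PII, NPII)
#'
#' @inheritParams pii
#' @param pii_mode passed to [pii()].
#' @param npii_mode passed to [npii()].
#' @return data.frame of class `pathway_score_table` with columns
#'   `pathway_id`, `PII`, `NPII`, `n_genes_scored`, `flagged`.
#' @export
score_pathways <- function(gene_scores, pathways, pii_mode = "sum",
                           npii_mode = "ratio_of_sums") {
  a <- pii(gene_scores, pathways, mode = pii_mode)
  b <- npii(gene_scores, pathways, mode = npii_mode)
  out <- data.frame(pathway_id = a$pathway_id, PII = a$PII, NPII = b$NPII,
                    n_genes_scored = a$n_genes_scored,
                    flagged = a$flagged | b$flagged, stringsAsFactors = FALSE)
  structure(out, cell_line = attr(gene_scores, "cell_line"),
            class = c("pathway_score_table", "data.frame"))
}

#' Aggregate score tables across cell lines
#'
#' Per id, the unweighted arithmetic mean of every numeric score column
#' over the cell lines where the id is present (coverage is recorded).
#' Aggregation is unweighted regardless of how many TFs were profiled per
#' line.
#'
#' @param tables list of `gene_score_table` or `pathway_score_table`
#'   objects (or plain data.frames whose first column is the id).
#' @return data.frame with the union of ids, the mean of each shared
#'   numeric column, and an `n_lines` coverage column; `cell_line`
#'   attribute set to `"aggregate"`.
#' @export
aggregate_scores <- function(tables) {
  if (length(tables) == 0) stop("no score tables to aggregate")
  id_col <- names(tables[[1]])[1]
  num_cols <- names(tables[[1]])[vapply(tables[[1]], is.numeric, TRUE)]
  num_cols <- setdiff(num_cols, c("n_genes_scored"))
  ids <- sort(unique(unlist(lapply(tables, function(t) t[[id_col]]))))
  acc <- matrix(0, length(ids), length(num_cols),
                dimnames = list(ids, num_cols))
  cnt <- matrix(0L, length(ids), length(num_cols),
                dimnames = list(ids, num_cols))
  for (t in tables) {
    m <- as.matrix(t[, num_cols, drop = FALSE])
    rownames(m) <- t[[id_col]]
    ok <- !is.na(m)
    m[!ok] <- 0
    acc[rownames(m), ] <- acc[rownames(m), , drop = FALSE] + m
    cnt[rownames(m), ] <- cnt[rownames(m), , drop = FALSE] + ok
  }
  out <- data.frame(id = ids, acc / ifelse(cnt == 0, NA, cnt),
                    n_lines = apply(cnt, 1, max),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[1] <- id_col
  rownames(out) <- NULL
  structure(out, cell_line = "aggregate",
            class = c(class(tables[[1]])[1], "data.frame"))
}
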