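# Readers and writers for the external formats the pipeline touches.
# Internal convention everywhere: 0-based half-open intervals [start, end);
# conversion to/from 1-based source dialects happens only here.

#' Map a RepeatMasker class string to a repeat class
#'
#' UCSC `repClass` strings (optionally with a `/family` suffix, as in
#' `"LINE/L1"`) are collapsed to the four classes used throughout the
#' pipeline: `SINE`, `LINE`, `LTR/ERV` (LTR retrotransposons and endogenous
#' retroviruses are grouped), and `other` for everything else (DNA
#' transposons, satellites, simple repeats, ...).
#'
#' @param repclass character vector of RepeatMasker class (or class/family)
#'   strings.
#' @return character vector with levels `SINE`, `LINE`, `LTR/ERV`, `other`.
#' @export
#' @examples
#' repeat_class(c("SINE/Alu", "LINE/L1", "LTR/ERVK", "DNA/hAT"))
repeat_class <- function(repclass) {
  prefix <- toupper(sub("/.*$", "", repclass))
  out <- rep("other", length(repclass))
  out[prefix == "SINE"] <- "SINE"
  out[prefix == "LINE"] <- "LINE"
  out[prefix %in% c("LTR", "ERV", "ERVK", "ERVL")] <- "LTR/ERV"
  out
}

REPEAT_CLASSES <- c("SINE", "LINE", "LTR/ERV", "other")

check_intervals <- function(df, what) {
  if (any(df$start < 0)) stop(what, ": negative start coordinate")
  if (any(df$end <= df$start)) stop(what, ": end must be > start (half-open)")
  if (any(!nzchar(df$chrom))) stop(what, ": empty chromosome name")
  invisible(df)
}

read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

#' Read RepeatMasker repeat annotations
#'
#' Supports two dialects: `ucsc_rmsk`, the UCSC Genome Browser `rmsk` table
#' (tab-separated, `genoStart` already 0-based, divergence in `milliDiv`
#' units, i.e. percent x 10), and `rm_out`, native RepeatMasker `.out`
#' output (whitespace-separated, 1-based inclusive coordinates, divergence as
#' a percentage in the "% div" column). Either way the result uses 0-based
#' half-open coordinates and percent divergence.
#'
#' @param path file path.
#' @param dialect `"ucsc_rmsk"` or `"rm_out"`.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `family` (RepeatMasker repName), `repeat_class`, `divergence_pct`.
#'   Rows keep file order.
#' @export
read_repeatmasker <- function(path, dialect = c("ucsc_rmsk", "rm_out")) {
  dialect <- match.arg(dialect)
  lines <- read_lines_checked(path)
  lines <- lines[!grepl("^#", lines)]
  if (dialect == "ucsc_rmsk") {
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) return(empty_repeats())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    # UCSC rmsk has 17 columns with the leading bin column, 16 without
    if (!all(nf %in% c(16L, 17L))) {
      bad <- which(!nf %in% c(16L, 17L))[1]
      stop("malformed ucsc_rmsk line ", bad, ": expected 16 or 17 fields, got ",
           nf[bad])
    }
    off <- ifelse(nf == 17L, 1L, 0L)
    get <- function(i) mapply(function(f, o) f[[i + o]], fields, off)
    start <- suppressWarnings(as.numeric(get(6)))
    end <- suppressWarnings(as.numeric(get(7)))
    mdiv <- suppressWarnings(as.numeric(get(2)))
    bad <- which(is.na(start) | is.na(end) | is.na(mdiv))
    if (length(bad) > 0) stop("malformed ucsc_rmsk line ", bad[1],
                              ": non-numeric coordinate or milliDiv")
    df <- data.frame(
      chrom = get(5), start = start, end = end, strand = get(9),
      family = get(10), repeat_class = repeat_class(get(11)),
      divergence_pct = mdiv / 10,
      stringsAsFactors = FALSE
    )
  } else {
    # skip the .out header: leading lines whose first token is not a score
    lines <- lines[nzchar(trimws(lines))]
    while (length(lines) > 0 &&
           is.na(suppressWarnings(as.numeric(
             strsplit(trimws(lines[1]), "[[:space:]]+")[[1]][1]))))
      lines <- lines[-1]
    if (length(lines) == 0) return(empty_repeats())
    fields <- strsplit(trimws(lines), "[[:space:]]+")
    nf <- lengths(fields)
    if (any(nf < 14)) {
      bad <- which(nf < 14)[1]
      stop("malformed rm_out line ", bad, ": expected >= 14 fields, got ", nf[bad])
    }
    get <- function(i) vapply(fields, `[[`, "", i)
    begin <- suppressWarnings(as.numeric(get(6)))
    end <- suppressWarnings(as.numeric(get(7)))
    div <- suppressWarnings(as.numeric(get(2)))
    bad <- which(is.na(begin) | is.na(end) | is.na(div))
    if (length(bad) > 0) stop("malformed rm_out line ", bad[1],
                              ": non-numeric coordinate or divergence")
    strand <- get(9)
    strand[strand == "C"] <- "-"
    df <- data.frame(
      chrom = get(5), start = begin - 1, end = end, strand = strand,
      family = get(10), repeat_class = repeat_class(get(11)),
      divergence_pct = div,
      stringsAsFactors = FALSE
    )
  }
  if (any(df$divergence_pct < 0 | df$divergence_pct > 100))
    stop("divergence_pct outside [0, 100]")
  check_intervals(df, "repeat annotation")
  df
}

empty_repeats <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             strand = character(), family = character(),
             repeat_class = character(), divergence_pct = numeric(),
             stringsAsFactors = FALSE)
}

#' Write repeat annotations as a UCSC rmsk-style table
#'
#' Emits the 17-column UCSC `rmsk` schema (bin column set to 0; milliDiv
#' rounded to integer percent x 10) so [read_repeatmasker()] round-trips.
#'
#' @param repeats data.frame as returned by [read_repeatmasker()].
#' @param path output file path.
#' @export
write_repeatmasker <- function(repeats, path) {
  n <- nrow(repeats)
  tbl <- data.frame(
    bin = integer(n), swScore = integer(n),
    milliDiv = as.integer(round(repeats$divergence_pct * 10)),
    milliDel = integer(n), milliIns = integer(n),
    genoName = repeats$chrom, genoStart = repeats$start,
    genoEnd = repeats$end, genoLeft = integer(n),
    strand = repeats$strand, repName = repeats$family,
    repClass = repeats$repeat_class, repFamily = repeats$family,
    repStart = integer(n), repEnd = integer(n), repLeft = integer(n),
    id = seq_len(n)
  )
  utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a refGene-style gene table
#'
#' Accepts the UCSC refGene column order (bin, name, chrom, strand, txStart,
#' txEnd, ...; the name2 column, when present, is used as the display
#' symbol) or a minimal 5-column variant (name, chrom, strand, txStart,
#' txEnd). A leading `#` header line is skipped. Duplicate gene ids are
#' collapsed to the first occurrence with a warning.
#'
#' @param path file path to a tab-separated table.
#' @return data.frame with columns `gene_id`, `symbol`, `chrom`, `strand`,
#'   `start` (txStart, 0-based), `end` (txEnd, exclusive).
#' @export
read_gene_table <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0)
    stop("gene table is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5)) stop("gene table line ", which(nf < 5)[1],
                        ": expected >= 5 tab-separated columns")
  ncols <- nf[1]
  # refGene rows start with an integer bin column; the minimal variant starts
  # with the gene name
  has_bin <- ncols >= 10 && !is.na(suppressWarnings(as.integer(fields[[1]][1])))
  off <- if (has_bin) 1L else 0L
  get <- function(i) vapply(fields, `[[`, "", i + off)
  strand <- get(3)
  if (!all(strand %in% c("+", "-")))
    stop("gene table line ", which(!strand %in% c("+", "-"))[1],
         ": strand must be '+' or '-'")
  start <- suppressWarnings(as.numeric(get(4)))
  end <- suppressWarnings(as.numeric(get(5)))
  if (anyNA(start) || anyNA(end))
    stop("gene table: non-numeric txStart/txEnd at line ",
         which(is.na(start) | is.na(end))[1])
  symbol <- if (has_bin && ncols >= 13) get(12) else get(1)
  df <- data.frame(gene_id = get(1), symbol = symbol, chrom = get(2),
                   strand = strand, start = start, end = end,
                   stringsAsFactors = FALSE)
  dup <- duplicated(df$gene_id)
  if (any(dup)) {
    warning(sum(dup), " duplicate gene id(s) collapsed to first occurrence")
    df <- df[!dup, , drop = FALSE]
  }
  check_intervals(df, "gene table")
  rownames(df) <- NULL
  df
}

#' Write a gene table in the minimal 5-column refGene-style layout
#'
#' Columns: name, chrom, strand, txStart, txEnd, preceded by a `#` header.
#'
#' @param genes data.frame as returned by [read_gene_table()].
#' @param path output file path.
#' @export
write_gene_table <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#name\tchrom\tstrand\ttxStart\ttxEnd", con)
  utils::write.table(
    genes[, c("gene_id", "chrom", "strand", "start", "end")],
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read TFBS peak files
#'
#' `narrowPeak` is ENCODE BED6+4: the point-source summit offset is column
#' 10 (-1 when absent) and each peak carries hit weight 1 under the default
#' hit model. `bedGraph` is 4-column; the interval value becomes the hit
#' weight and a synthetic summit is placed at the interval midpoint so both
#' formats feed one hit model.
#'
#' @param path file path.
#' @param format `"narrowPeak"` or `"bedGraph"`.
#' @param tf_name transcription factor label attached to every record.
#' @param cell_line cell line label attached to every record.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `tf_name`, `cell_line`, `summit_offset`, `signal`, `weight`.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bedGraph"),
                       tf_name = NA_character_, cell_line = NA_character_) {
  format <- match.arg(format)
  lines <- read_lines_checked(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) return(empty_peaks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (format == "narrowPeak") 10L else 4L
  if (any(nf != need))
    stop("malformed ", format, " line ", which(nf != need)[1],
         ": expected ", need, " columns, got ", nf[nf != need][1])
  get <- function(i) vapply(fields, `[[`, "", i)
  num <- function(i) {
    v <- suppressWarnings(as.numeric(get(i)))
    if (anyNA(v)) stop("malformed ", format, " line ", which(is.na(v))[1],
                       ": non-numeric field ", i)
    v
  }
  start <- num(2); end <- num(3)
  if (format == "narrowPeak") {
    signal <- num(7)
    summit <- num(10)
    bad <- summit >= 0 & (start + summit < start | start + summit >= end)
    if (any(bad)) stop("narrowPeak line ", which(bad)[1],
                       ": summit outside [start, end)")
    df <- data.frame(chrom = get(1), start = start, end = end,
                     strand = get(6), tf_name = tf_name, cell_line = cell_line,
                     summit_offset = summit, signal = signal, weight = 1,
                     stringsAsFactors = FALSE)
  } else {
    value <- num(4)
    if (any(value < 0)) stop("bedGraph line ", which(value < 0)[1],
                             ": negative value (signal must be non-negative)")
    df <- data.frame(chrom = get(1), start = start, end = end, strand = ".",
                     tf_name = tf_name, cell_line = cell_line,
                     summit_offset = floor((end - start) / 2),
                     signal = value, weight = value,
                     stringsAsFactors = FALSE)
  }
  if (any(df$signal < 0)) stop("signal must be non-negative")
  check_intervals(df, "peak table")
  df
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             strand = character(), tf_name = character(),
             cell_line = character(), summit_offset = numeric(),
             signal = numeric(), weight = numeric(), stringsAsFactors = FALSE)
}

#' Write peaks in ENCODE narrowPeak layout
#'
#' @param peaks data.frame as returned by [read_peaks()].
#' @param path output file path.
#' @export
write_peaks <- function(peaks, path) {
  n <- nrow(peaks)
  tbl <- data.frame(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = sprintf("peak%d", seq_len(n)), score = 0L,
    strand = ifelse(is.na(peaks$strand) | peaks$strand == "", ".", peaks$strand),
    signalValue = peaks$signal, pValue = -1, qValue = -1,
    peak = peaks$summit_offset
  )
  utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is: set name, description, then one or more gene ids, all
#' tab-separated. Member ids are deduplicated per set.
#'
#' @param path file path.
#' @return named list of character vectors (pathway id -> member gene ids),
#'   with the description line stored in the `"description"` attribute
#'   (a named character vector parallel to the list).
#' @export
read_gmt <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(structure(list(), description = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("GMT line ", which(nf < 3)[1], ": expected >= 3 tab-separated fields")
  ids <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate pathway id in GMT: ", ids[duplicated(ids)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  structure(sets, description = stats::setNames(vapply(fields, `[[`, "", 2), ids))
}

#' Write gene sets in GMT format
#'
#' @param pathways named list of character vectors as returned by
#'   [read_gmt()].
#' @param path output file path.
#' @export
write_gmt <- function(pathways, path) {
  desc <- attr(pathways, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(pathways)),
                                             names(pathways))
  lines <- vapply(names(pathways), function(id) {
    paste(c(id, desc[[id]], pathways[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a data.frame as a deterministic tab-separated table
#'
#' The header line starts with `#`; rows are ordered by the first (id)
#' column so repeated runs produce byte-identical files.
#'
#' @param records data.frame.
#' @param path output file path.
#' @export
write_table <- function(records, path) {
  records <- records[order(records[[1]]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(records), collapse = "\t")), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path file path.
#' @return data.frame with column names taken from the `#` header line.
#' @export
read_table <- function(path) {
  lines <- read_lines_checked(path)
  if (length(lines) == 0 || !grepl("^#", lines[1]))
    stop("expected a '#' header line in ", path)
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(text = lines[-1], sep = "\t",
                          col.names = header, stringsAsFactors = FALSE)
  df
}

#' Read a one-id-per-line gene list (e.g. a gene-class label file)
#'
#' Blank lines and `#` comments are skipped; ids are deduplicated.
#'
#' @param path file path.
#' @return character vector of ids.
#' @export
read_id_list <- function(path) {
  lines <- read_lines_checked(path)
  unique(trimws(lines[!grepl("^#", lines) & nzchar(trimws(lines))]))
}
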