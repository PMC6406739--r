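# Independent brute-force oracles and tiny fixture builders shared by the
# unit tests. The oracles are deliberately naive (nested loops, direct
# enumeration) so they stay independent of the implementation they check.

# O(n * m) scan version of assign_hits under the default summit model
brute_force_assign <- function(peaks, repeats, genes, flank = 5000) {
  loc <- ifelse(peaks$summit_offset >= 0,
                peaks$start + peaks$summit_offset,
                floor((peaks$start + peaks$end) / 2))
  n <- nrow(peaks)
  linked <- logical(n)
  cls <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    w_best <- Inf
    for (j in seq_len(nrow(repeats))) {
      if (repeats$chrom[j] == peaks$chrom[i] &&
          loc[i] >= repeats$start[j] && loc[i] < repeats$end[j]) {
        linked[i] <- TRUE
        w <- repeats$end[j] - repeats$start[j]
        if (w < w_best) {
          w_best <- w
          cls[i] <- repeats$repeat_class[j]
        }
      }
    }
  }
  win <- tss_window(genes, flank)
  S <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  T <- S
  in_any <- logical(n)
  for (g in seq_len(nrow(win))) {
    for (i in seq_len(n)) {
      if (peaks$chrom[i] == win$chrom[g] &&
          loc[i] >= win$start[g] && loc[i] < win$end[g]) {
        T[g] <- T[g] + peaks$weight[i]
        in_any[i] <- TRUE
        if (linked[i]) S[g] <- S[g] + peaks$weight[i]
      }
    }
  }
  list(S = S, T = T, linked = linked, cls = cls, in_any = in_any,
       weight = peaks$weight)
}

# exhaustive hypergeometric tail over the support, plain double arithmetic
enum_hyper <- function(k, n, K, N, tail = "upper", inclusive = FALSE) {
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  pmf <- vapply(lo:hi, function(i)
    choose(K, i) * choose(N - K, n - i) / choose(N, n), 0)
  names(pmf) <- lo:hi
  if (tail == "upper") {
    sum(pmf[as.character(k:hi)])
  } else {
    top <- if (inclusive) k else k - 1
    if (top < lo) 0 else sum(pmf[as.character(lo:top)])
  }
}

make_genes <- function(tss, strand = "+", chrom = "chr1", len = 20000) {
  n <- length(tss)
  strand <- rep_len(strand, n)
  data.frame(
    gene_id = sprintf("g%03d", seq_len(n)), symbol = sprintf("g%03d", seq_len(n)),
    chrom = rep_len(chrom, n), strand = strand,
    start = ifelse(strand == "+", tss, pmax(0, tss + 1 - len)),
    end = ifelse(strand == "+", tss + len, tss + 1),
    stringsAsFactors = FALSE)
}

make_repeats <- function(start, end, chrom = "chr1", family = "AluY",
                         class = "SINE", div = 5) {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             strand = rep_len("+", n), family = rep_len(family, n),
             repeat_class = rep_len(class, n),
             divergence_pct = rep_len(div, n), stringsAsFactors = FALSE)
}

# sample() misbehaves on length-1 vectors; draw by index instead
resample <- function(v) v[sample.int(length(v), 1)]

make_peaks <- function(summit, chrom = "chr1", width = 200, weight = 1,
                       signal = 10, cell_line = "CL01", tf = "TF01") {
  n <- length(summit)
  start <- pmax(0, summit - width %/% 2)
  data.frame(chrom = rep_len(chrom, n), start = start,
             end = start + width, strand = ".",
             tf_name = rep_len(tf, n), cell_line = rep_len(cell_line, n),
             summit_offset = summit - start,
             signal = rep_len(signal, n), weight = rep_len(weight, n),
             stringsAsFactors = FALSE)
}

random_assignment_fixture <- function(n_peaks, n_res, n_genes, seed,
                                      chroms = c("chr1", "chr2"),
                                      span = 1e6) {
  set.seed(seed)
  genes <- make_genes(tss = sample.int(span, n_genes),
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      chrom = sample(chroms, n_genes, replace = TRUE))
  st <- sample.int(span, n_res)
  repeats <- make_repeats(start = st, end = st + sample(50:2000, n_res,
                                                        replace = TRUE),
                          chrom = sample(chroms, n_res, replace = TRUE),
                          class = sample(c("SINE", "LINE", "LTR/ERV", "other"),
                                         n_res, replace = TRUE))
  peaks <- make_peaks(summit = sample.int(span, n_peaks),
                      chrom = sample(chroms, n_peaks, replace = TRUE),
                      weight = sample(1:3, n_peaks, replace = TRUE))
  list(genes = genes, repeats = repeats, peaks = peaks)
}

expect_hit_tables_equal <- function(ht, oracle) {
  expect_equal(stats::setNames(ht$genes$S, ht$genes$gene_id), oracle$S)
  expect_equal(stats::setNames(ht$genes$T, ht$genes$gene_id), oracle$T)
  expect_equal(ht$genome_totals$genome$total, sum(oracle$weight))
  expect_equal(ht$genome_totals$genome$re_linked,
               sum(oracle$weight[oracle$linked]))
  for (cls in c("SINE", "LINE", "LTR/ERV")) {
    expect_equal(ht$genome_totals$genome$per_class[[cls]],
                 sum(oracle$weight[oracle$linked & !is.na(oracle$cls) &
                                     oracle$cls == cls]))
    expect_equal(ht$genome_totals$tss$per_class[[cls]],
                 sum(oracle$weight[oracle$in_any & oracle$linked &
                                     !is.na(oracle$cls) & oracle$cls == cls]))
  }
  expect_equal(ht$genome_totals$tss$total, sum(oracle$weight[oracle$in_any]))
}
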