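# Synthetic input bundles with known planted structure.
#
# The generator emits the exact formats the readers consume (UCSC rmsk
# table, refGene-style gene table, narrowPeak files per TF per cell line,
# GMT pathways, gene-class lists) plus a truth JSON. Genes get
# non-overlapping TSS windows; each window carries repeat segments covering
# a configurable fraction of its bases; peaks are placed by a two-step
# draw: first window-vs-background, then (inside a window) RE-vs-non-RE
# with the gene's theta. Planted genes have elevated theta (RRE-enriched
# direction), deficient-planted genes have depressed theta, and planted
# annotation terms cover a fixed fraction of each planted group so the
# whole selection + enrichment + permutation chain has a recoverable
# signal.

#' Configuration for the synthetic-data generator
#'
#' Defaults are desk scale: small enough that every pipeline stage runs in
#' seconds, with the planted effect (theta 0.9 vs 0.3) and window geometry
#' (5 kb flank) matching the study conditions the pipeline assumes.
#'
#' @param n_chroms,n_genes genome shape; windows are laid out on a fixed
#'   grid of `2 * flank + window_gap` bases per gene.
#' @param chrom_length chromosome length; `NULL` (default) sizes
#'   chromosomes to fit the requested genes. An explicit value that cannot
#'   hold the windows is an error.
#' @param flank TSS window half-width (5000 = 10 kb windows).
#' @param window_gap bases between consecutive windows.
#' @param re_families data.frame with columns `family`, `class`,
#'   `mean_div` defining the divergence mixture (defaults straddle the 8%
#'   young/old boundary).
#' @param re_window_fraction fraction of each window's bases covered by
#'   repeat segments.
#' @param bg_res_per_gap background repeats placed in each inter-window gap.
#' @param n_cell_lines,tfs_per_line,peaks_per_tf peak-set shape.
#' @param p_window probability a peak targets a TSS window (vs background).
#' @param theta_background probability a window peak's summit is placed
#'   inside a repeat segment, for unplanted genes.
#' @param theta_planted elevated RE-placement probability for planted
#'   (RRE-enriched direction) genes.
#' @param theta_deficient depressed probability for deficient-planted genes.
#' @param coverage_sdlog log-sd of the lognormal per-gene coverage weights
#'   (genes differ strongly in total TFBS load in real data; without this
#'   heterogeneity every gene has the same relative total coverage and the
#'   (GRE, NGRE) cloud collapses onto a single ray, leaving nothing for the
#'   extreme-set rule to rank).
#' @param planted_coverage_factor coverage multiplier for enriched-planted
#'   genes (< 1: a gene reads as RRE-enriched when its RE share is high
#'   relative to a modest total load, i.e. it lies on a steep ray).
#' @param deficient_coverage_factor coverage multiplier for
#'   deficient-planted genes (> 1: heavy total load, low RE share).
#' @param planted_gene_fraction,deficient_gene_fraction planted group sizes
#'   as fractions of `n_genes` (disjoint groups).
#' @param n_pathways,pathway_size_range background pathway count and size
#'   range.
#' @param planted_pathway_count planted terms per direction.
#' @param planted_term_coverage fraction of each planted group covered by
#'   its planted term(s).
#' @param class_sizes named integer vector of gene-class sizes (e.g.
#'   miRNA-like, lncRNA-like).
#' @param class_planted_overlap fraction of each class drawn from the
#'   planted (enriched) group.
#' @param seed integer seed; the bundle is byte-identical given the config.
#' @return object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_chroms = 2, n_genes = 300,
                             chrom_length = NULL,
                             flank = 5000, window_gap = 5000,
                             re_families = default_re_families(),
                             re_window_fraction = 0.4,
                             bg_res_per_gap = 2,
                             n_cell_lines = 3, tfs_per_line = 3,
                             peaks_per_tf = 2000, p_window = 0.85,
                             theta_background = 0.3, theta_planted = 0.9,
                             theta_deficient = 0.05,
                             coverage_sdlog = 0.5,
                             planted_coverage_factor = 0.5,
                             deficient_coverage_factor = 2,
                             planted_gene_fraction = 0.05,
                             deficient_gene_fraction = 0.05,
                             n_pathways = 60,
                             pathway_size_range = c(10, 40),
                             planted_pathway_count = 1,
                             planted_term_coverage = 0.6,
                             class_sizes = c(miRNA = 75, lncRNA = 60),
                             class_planted_overlap = 0.15,
                             seed = 1L) {
  cfg <- list(n_chroms = n_chroms, n_genes = n_genes,
              chrom_length = chrom_length, flank = flank,
              window_gap = window_gap, re_families = re_families,
              re_window_fraction = re_window_fraction,
              bg_res_per_gap = bg_res_per_gap,
              n_cell_lines = n_cell_lines, tfs_per_line = tfs_per_line,
              peaks_per_tf = peaks_per_tf, p_window = p_window,
              theta_background = theta_background,
              theta_planted = theta_planted,
              theta_deficient = theta_deficient,
              coverage_sdlog = coverage_sdlog,
              planted_coverage_factor = planted_coverage_factor,
              deficient_coverage_factor = deficient_coverage_factor,
              planted_gene_fraction = planted_gene_fraction,
              deficient_gene_fraction = deficient_gene_fraction,
              n_pathways = n_pathways,
              pathway_size_range = pathway_size_range,
              planted_pathway_count = planted_pathway_count,
              planted_term_coverage = planted_term_coverage,
              class_sizes = class_sizes,
              class_planted_overlap = class_planted_overlap,
              seed = seed)
  with(cfg, {
    stopifnot(n_chroms >= 1, n_genes >= 1, n_cell_lines >= 1,
              tfs_per_line >= 1, peaks_per_tf >= 1)
    if (!(theta_background < theta_planted && theta_planted <= 1))
      stop("need 0 <= theta_background < theta_planted <= 1")
    if (!(theta_deficient >= 0 && theta_deficient < theta_background))
      stop("need 0 <= theta_deficient < theta_background")
    if (planted_gene_fraction <= 0 || planted_gene_fraction >= 1 ||
        deficient_gene_fraction <= 0 || deficient_gene_fraction >= 1)
      stop("planted fractions must be in (0, 1)")
    if (re_window_fraction <= 0 || re_window_fraction >= 1)
      stop("re_window_fraction must be in (0, 1)")
  })
  structure(cfg, class = "synthetic_config")
}

default_re_families <- function() {
  data.frame(
    family = c("AluYa5", "AluY", "AluSx", "MIRb",
               "L1PA3", "L1MB5", "HERVK-int", "MLT1D"),
    class = c("SINE", "SINE", "SINE", "SINE",
              "LINE", "LINE", "LTR/ERV", "LTR/ERV"),
    mean_div = c(2, 5, 13, 25, 6, 22, 4, 18),
    stringsAsFactors = FALSE
  )
}

#' Named scale profiles for the synthetic generator
#'
#' `"desk"`: the small default bundle (fast tests). `"table5"`: gene-class
#' test geometry — 25,075 background genes with class sizes 1865
#' (miRNA-like) and 1505 (lncRNA-like) and a 24,389-gene selection
#' universe. `"paper_scale"`: 24,389 genes, 3123 pathways, 13 cell lines.
#' The large profiles size the id universes; peak counts stay modest so
#' the bundles remain generatable.
#'
#' @param profile `"desk"`, `"table5"` or `"paper_scale"`.
#' @return a `synthetic_config`.
#' @export
scale_profile <- function(profile = c("desk", "table5", "paper_scale")) {
  profile <- match.arg(profile)
  switch(profile,
    desk = synthetic_config(),
    table5 = synthetic_config(
      n_chroms = 8, n_genes = 25075,
      class_sizes = c(miRNA = 1865, lncRNA = 1505),
      class_planted_overlap = 0.15,
      planted_gene_fraction = 1219 / 25075,
      deficient_gene_fraction = 1219 / 25075,
      n_pathways = 100, peaks_per_tf = 2000),
    paper_scale = synthetic_config(
      n_chroms = 8, n_genes = 24389, n_pathways = 3123,
      n_cell_lines = 13, tfs_per_line = 3, peaks_per_tf = 2000)
  )
}

#' Generate a synthetic input bundle
#'
#' Writes, under `dir`: `repeats.rmsk.tsv` (UCSC rmsk dialect),
#' `genes.refgene.tsv`, `peaks/<cell>/<tf>.narrowPeak`,
#' `pathways.gmt`, `classes/<class>.txt` and `truth.json`. Rerunning with
#' the same config produces a byte-identical bundle.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the emitted `paths` and the `truth`
#'   (planted gene ids, per-gene theta, planted pathway ids, class
#'   members).
#' @export
generate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  local_seed(config$seed, generate_bundle_impl(config, dir))
}

generate_bundle_impl <- function(cfg, dir) {
  slot <- 2 * cfg$flank + cfg$window_gap
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  needed <- per_chrom * slot + cfg$window_gap
  chrom_length <- cfg$chrom_length
  if (is.null(chrom_length)) chrom_length <- needed
  if (chrom_length < needed)
    stop("genome too small: ", per_chrom, " windows per chromosome need ",
         needed, " bases, chrom_length is ", chrom_length)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))

  ## genes on a fixed window grid
  i <- seq_len(cfg$n_genes)
  chrom_i <- chroms[((i - 1) %/% per_chrom) + 1]
  slot_i <- ((i - 1) %% per_chrom)
  tss <- slot_i * slot + cfg$window_gap %/% 2 + cfg$flank
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  glen <- round(stats::runif(cfg$n_genes, 2000, 20000))
  gene_id <- sprintf("G%05d", i)
  genes <- data.frame(
    gene_id = gene_id, symbol = gene_id, chrom = chrom_i, strand = strand,
    start = ifelse(strand == "+", tss, pmax(0, tss + 1 - glen)),
    end = ifelse(strand == "+", tss + glen, tss + 1),
    stringsAsFactors = FALSE)
  windows <- tss_window(genes, flank = cfg$flank)

  ## repeat segments inside each window: n_seg equal segments on an even
  ## grid, jittered, covering re_window_fraction of window bases
  n_seg <- 4L
  seg_len <- round(cfg$re_window_fraction * 2 * cfg$flank / n_seg)
  cell <- (2 * cfg$flank) %/% n_seg
  seg_rows <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    jit <- floor(stats::runif(n_seg, 0, cell - seg_len))
    s0 <- windows$start[g] + (seq_len(n_seg) - 1) * cell + jit
    fam_idx <- sample.int(nrow(cfg$re_families), n_seg, replace = TRUE)
    seg_rows[[g]] <- data.frame(
      chrom = windows$chrom[g], start = s0, end = s0 + seg_len,
      strand = sample(c("+", "-"), n_seg, replace = TRUE),
      family = cfg$re_families$family[fam_idx],
      repeat_class = cfg$re_families$class[fam_idx],
      divergence_pct = cfg$re_families$mean_div[fam_idx] +
        round(stats::runif(n_seg, -0.5, 0.5), 1),
      gene = g, stringsAsFactors = FALSE)
  }
  window_res <- do.call(rbind, seg_rows)

  ## background repeats in the gaps before each window
  bg_rows <- NULL
  if (cfg$bg_res_per_gap > 0) {
    nbg <- cfg$bg_res_per_gap * cfg$n_genes
    gidx <- rep(seq_len(cfg$n_genes), each = cfg$bg_res_per_gap)
    gap_start <- (slot_i[gidx]) * slot
    pos <- gap_start + floor(stats::runif(nbg, 0, cfg$window_gap %/% 2 - 400))
    fam_idx <- sample.int(nrow(cfg$re_families), nbg, replace = TRUE)
    bg_rows <- data.frame(
      chrom = chrom_i[gidx], start = pos, end = pos + 300,
      strand = sample(c("+", "-"), nbg, replace = TRUE),
      family = cfg$re_families$family[fam_idx],
      repeat_class = cfg$re_families$class[fam_idx],
      divergence_pct = cfg$re_families$mean_div[fam_idx] +
        round(stats::runif(nbg, -0.5, 0.5), 1),
      gene = NA_integer_, stringsAsFactors = FALSE)
  }
  repeats <- rbind(window_res, bg_rows)
  repeats <- repeats[order(repeats$chrom, repeats$start), , drop = FALSE]
  re_cols <- c("chrom", "start", "end", "strand", "family", "repeat_class",
               "divergence_pct")

  ## planted structure
  n_plant <- max(1L, round(cfg$planted_gene_fraction * cfg$n_genes))
  n_def <- max(1L, round(cfg$deficient_gene_fraction * cfg$n_genes))
  planted <- sort(sample(gene_id, n_plant))
  deficient <- sort(sample(setdiff(gene_id, planted), n_def))
  theta <- stats::setNames(rep(cfg$theta_background, cfg$n_genes), gene_id)
  theta[planted] <- cfg$theta_planted
  theta[deficient] <- cfg$theta_deficient
  target_w <- stats::rlnorm(cfg$n_genes, 0, cfg$coverage_sdlog)
  target_w[gene_id %in% planted] <-
    target_w[gene_id %in% planted] * cfg$planted_coverage_factor
  target_w[gene_id %in% deficient] <-
    target_w[gene_id %in% deficient] * cfg$deficient_coverage_factor
  target_w <- target_w / sum(target_w)

  ## peaks: two-step placement draw
  peak_dir <- file.path(dir, "peaks")
  peak_paths <- character(0)
  cell_lines <- sprintf("CL%02d", seq_len(cfg$n_cell_lines))
  for (cl in cell_lines) {
    dir.create(file.path(peak_dir, cl), recursive = TRUE,
               showWarnings = FALSE)
    for (t in seq_len(cfg$tfs_per_line)) {
      tf <- sprintf("TF%02d", t)
      np <- cfg$peaks_per_tf
      in_win <- stats::runif(np) < cfg$p_window
      g <- sample.int(cfg$n_genes, np, replace = TRUE, prob = target_w)
      on_re <- stats::runif(np) < theta[gene_id[g]]
      summit <- numeric(np)
      for (p in which(in_win)) {
        if (on_re[p]) {
          seg <- seg_rows[[g[p]]]
          j <- sample.int(n_seg, 1)
          summit[p] <- seg$start[j] + floor(stats::runif(1, 0, seg_len))
        } else {
          # rejection-sample a non-RE position inside the window
          seg <- seg_rows[[g[p]]]
          repeat {
            pos <- windows$start[g[p]] +
              floor(stats::runif(1, 0, 2 * cfg$flank))
            if (!any(pos >= seg$start & pos < seg$end)) break
          }
          summit[p] <- pos
        }
      }
      nbgp <- sum(!in_win)
      if (nbgp > 0) {
        # background summits in the inter-window gap of the drawn slot
        # (never window-assigned)
        summit[!in_win] <- slot_i[g][!in_win] * slot +
          floor(stats::runif(nbgp, 0, cfg$window_gap %/% 2 - 1))
      }
      chrom_p <- chrom_i[g]
      width <- round(stats::runif(np, 200, 400))
      offset <- floor(width * stats::runif(np, 0.3, 0.7))
      start <- pmax(0, summit - offset)
      pk <- data.frame(chrom = chrom_p, start = start, end = start + width,
                       strand = ".", tf_name = tf, cell_line = cl,
                       summit_offset = summit - start,
                       signal = round(stats::runif(np, 5, 50), 2),
                       weight = 1, stringsAsFactors = FALSE)
      pk <- pk[order(pk$chrom, pk$start), , drop = FALSE]
      path <- file.path(peak_dir, cl, paste0(tf, ".narrowPeak"))
      write_peaks(pk, path)
      peak_paths <- c(peak_paths, path)
    }
  }

  ## pathways: planted terms for both directions + random background sets
  pathways <- list()
  n_cov <- function(ids) max(1L, round(cfg$planted_term_coverage * length(ids)))
  for (j in seq_len(cfg$planted_pathway_count)) {
    pathways[[sprintf("PW_ENR%d", j)]] <- sort(sample(planted, n_cov(planted)))
    pathways[[sprintf("PW_DEF%d", j)]] <-
      sort(sample(deficient, n_cov(deficient)))
  }
  sz <- round(stats::runif(cfg$n_pathways, cfg$pathway_size_range[1],
                           min(cfg$pathway_size_range[2], cfg$n_genes)))
  for (j in seq_len(cfg$n_pathways)) {
    pathways[[sprintf("PW%04d", j)]] <- sort(sample(gene_id, sz[j]))
  }
  attr(pathways, "description") <- stats::setNames(
    rep("synthetic", length(pathways)), names(pathways))

  ## gene classes with planted overlap
  class_dir <- file.path(dir, "classes")
  dir.create(class_dir, showWarnings = FALSE)
  class_members <- list()
  for (cls in names(cfg$class_sizes)) {
    m <- cfg$class_sizes[[cls]]
    n_ov <- min(round(cfg$class_planted_overlap * m), length(planted))
    members <- c(sample(planted, n_ov),
                 sample(setdiff(gene_id, planted), m - n_ov))
    class_members[[cls]] <- sort(members)
    writeLines(class_members[[cls]], file.path(class_dir, paste0(cls, ".txt")))
  }

  paths <- list(
    repeats = file.path(dir, "repeats.rmsk.tsv"),
    genes = file.path(dir, "genes.refgene.tsv"),
    peaks = peak_paths, peak_dir = peak_dir,
    gmt = file.path(dir, "pathways.gmt"),
    classes = stats::setNames(
      file.path(class_dir, paste0(names(cfg$class_sizes), ".txt")),
      names(cfg$class_sizes)),
    truth = file.path(dir, "truth.json"))
  write_repeatmasker(repeats[, re_cols], paths$repeats)
  write_gene_table(genes, paths$genes)
  write_gmt(pathways, paths$gmt)

  truth <- list(
    planted_gene_ids = planted, deficient_gene_ids = deficient,
    theta = as.list(theta),
    planted_pathway_ids = list(
      enriched = grep("^PW_ENR", names(pathways), value = TRUE),
      deficient = grep("^PW_DEF", names(pathways), value = TRUE)),
    class_members = class_members,
    cell_lines = cell_lines,
    n_genes = cfg$n_genes, seed = cfg$seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, truth = truth, genes = genes,
                 repeats = repeats[, re_cols], pathways = pathways))
}

#' Simulate a per-gene score table directly (no file bundle)
#'
#' Draws lognormal per-gene coverage weights, total hit weights
#' `T ~ Poisson(mean_hits x weight)` (shifted so every gene has at least
#' one hit) and RE-linked weights `S ~ Binomial(T, theta_g)`, where a
#' planted fraction of genes carries an elevated theta and a reduced
#' coverage factor (high RE share against a modest total load — the
#' geometry that puts a gene above the bounding regression line), then
#' scores with [score_genes()]. Used where only the (GRE, NGRE) cloud
#' matters — e.g. selection-quota checks at the full 24,389-gene scale —
#' without generating a genome.
#'
#' @param n_genes number of genes.
#' @param mean_hits mean total hit weight per gene.
#' @param theta_background,theta_planted,planted_fraction planted-effect
#'   geometry, as in [synthetic_config()].
#' @param coverage_sdlog,planted_coverage_factor coverage heterogeneity,
#'   as in [synthetic_config()].
#' @param seed integer seed.
#' @return a `gene_score_table` with a `planted` attribute (character ids).
#' @export
simulate_score_table <- function(n_genes, mean_hits = 40,
                                 theta_background = 0.3,
                                 theta_planted = 0.9,
                                 planted_fraction = 0.05,
                                 coverage_sdlog = 0.5,
                                 planted_coverage_factor = 0.5,
                                 seed = 1L) {
  local_seed(seed, {
    gene_id <- sprintf("G%05d", seq_len(n_genes))
    planted <- sort(sample(gene_id, max(1L, round(planted_fraction * n_genes))))
    theta <- stats::setNames(rep(theta_background, n_genes), gene_id)
    theta[planted] <- theta_planted
    w <- stats::rlnorm(n_genes, 0, coverage_sdlog) / exp(coverage_sdlog^2 / 2)
    w[gene_id %in% planted] <- w[gene_id %in% planted] * planted_coverage_factor
    T <- 1L + stats::rpois(n_genes, pmax(0, mean_hits * w - 1))
    S <- stats::rbinom(n_genes, T, theta)
    tab <- score_genes(data.frame(gene_id = gene_id, S = S, T = T,
                                  stringsAsFactors = FALSE),
                       cell_line = "simulated")
    attr(tab, "planted") <- planted
    tab
  })
}
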