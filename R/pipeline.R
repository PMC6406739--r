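# End-to-end pipeline orchestration: read -> age-filter -> assign -> score
# -> aggregate -> select -> enrich -> permute -> concord, with a JSON
# manifest of outputs, parameters and seeds.

#' Build and validate a pipeline configuration
#'
#' @param re_table path to the repeat annotation table.
#' @param re_dialect dialect for [read_repeatmasker()].
#' @param genes path to the gene table.
#' @param peaks either a directory laid out as `<dir>/<cell_line>/<tf>.narrowPeak`
#'   (the generator's layout) or a named list mapping cell-line labels to
#'   character vectors of peak file paths.
#' @param peak_format format for [read_peaks()].
#' @param gmt path to the pathway GMT file.
#' @param class_lists optional named character vector of gene-class list
#'   files (id per line) for class enrichment tests.
#' @param re_fraction `"all"` or `"young"` (see [filter_by_age()]).
#' @param young_threshold_pct young/old divergence cutoff, default 8.
#' @param flank TSS window half-width, default 5000.
#' @param hit_mode,re_rule passed to [hit_model()].
#' @param selection list of [select_genes()] parameters (defaults:
#'   1000 subsets of 500, fraction 0.05, seed 1).
#' @param enrichment list with `variant` (default `"standard"`) and `alpha`
#'   (default 0.05).
#' @param permutation list with `B` (default 500; 0 skips the stage),
#'   `top_m` (default 100) and `seed` (default 1).
#' @param out_dir output directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(re_table, genes, peaks, gmt,
                            class_lists = NULL,
                            re_dialect = "ucsc_rmsk",
                            peak_format = "narrowPeak",
                            re_fraction = c("all", "young"),
                            young_threshold_pct = 8, flank = 5000,
                            hit_mode = "summit", re_rule = "summit_in_re",
                            selection = list(), enrichment = list(),
                            permutation = list(), out_dir = "retroload_out") {
  re_fraction <- match.arg(re_fraction)
  cfg <- list(
    re_table = re_table, re_dialect = re_dialect, genes = genes,
    peaks = peaks, peak_format = peak_format, gmt = gmt,
    class_lists = class_lists, re_fraction = re_fraction,
    young_threshold_pct = young_threshold_pct, flank = flank,
    hit_mode = hit_mode, re_rule = re_rule,
    selection = utils::modifyList(
      list(n_subsets = 1000, subset_size = 500, fraction = 0.05, seed = 1L),
      selection),
    enrichment = utils::modifyList(
      list(variant = "standard", alpha = 0.05), enrichment),
    permutation = utils::modifyList(
      list(B = 500, top_m = 100, seed = 1L), permutation),
    out_dir = out_dir)
  for (p in c(cfg$re_table, cfg$genes, cfg$gmt, unlist(cfg$class_lists)))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; relative input
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  for (key in c("re_table", "genes", "gmt"))
    if (!is.null(raw[[key]])) raw[[key]] <- resolve(raw[[key]])
  if (!is.null(raw$peaks) && is.character(raw$peaks) &&
      length(raw$peaks) == 1)
    raw$peaks <- resolve(raw$peaks)
  if (!is.null(raw$class_lists))
    raw$class_lists <- stats::setNames(
      vapply(raw$class_lists, resolve, ""), names(raw$class_lists))
  do.call(pipeline_config, raw)
}

# expand the peaks argument into a named list cell_line -> file paths
peak_files <- function(peaks) {
  if (is.list(peaks)) return(peaks)
  stopifnot(is.character(peaks), length(peaks) == 1, dir.exists(peaks))
  cells <- list.dirs(peaks, recursive = FALSE)
  if (length(cells) == 0) stop("no cell-line subdirectories under ", peaks)
  out <- lapply(cells, function(d)
    sort(list.files(d, pattern = "\\.(narrowPeak|bedGraph)$",
                    full.names = TRUE)))
  stats::setNames(out, basename(cells))
}

#' Run the full pipeline
#'
#' Executes every stage, writing intermediate TSVs and a `manifest.json`
#' under `config$out_dir`. On a stage error the outputs written so far are
#' renamed with a `.partial` suffix, the manifest records the failing
#' stage, and the error is re-signalled (so a non-interactive run exits
#' non-zero).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  manifest <- list(
    package = as.character(utils::packageVersion("retroload")),
    parameters = config[setdiff(names(config), "class_lists")],
    stages = list(), status = "running")
  out <- function(name) file.path(config$out_dir, name)
  emit <- function(stage, paths) {
    outputs <<- c(outputs, paths)
    manifest$stages[[stage]] <<- as.list(paths)
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  stage <- "read"
  result <- tryCatch({
    ## read
    repeats <- read_repeatmasker(config$re_table, config$re_dialect)
    genes <- read_gene_table(config$genes)
    pathways <- read_gmt(config$gmt)
    peak_sets <- lapply(peak_files(config$peaks), function(paths)
      do.call(rbind, lapply(paths, read_peaks, format = config$peak_format)))
    emit("read", character(0))

    ## age filter
    stage <- "age_filter"
    fam <- summarize_families(repeats, config$young_threshold_pct)
    write_table(fam, out("family_summary.tsv"))
    repeats_used <- filter_by_age(repeats, config$re_fraction,
                                  config$young_threshold_pct)
    emit("age_filter", out("family_summary.tsv"))

    ## assign + score per cell line
    stage <- "assign"
    model <- hit_model(config$hit_mode, config$re_rule)
    hits <- lapply(names(peak_sets), function(cl)
      assign_hits(peak_sets[[cl]], repeats_used, genes, model,
                  flank = config$flank, cell_line = cl))
    names(hits) <- names(peak_sets)
    hit_paths <- vapply(names(hits), function(cl) {
      p <- out(sprintf("hits_%s.tsv", cl))
      df <- hits[[cl]]$genes
      df$cell_line <- cl
      write_table(df, p)
      p
    }, "")
    class_path <- out("re_class_summary.tsv")
    write_table(do.call(rbind, lapply(names(hits), function(cl) {
      s <- re_class_summary(hits[[cl]])
      s$cell_line <- cl
      s
    })), class_path)
    emit("assign", c(hit_paths, class_path))

    stage <- "score"
    gene_scores <- lapply(hits, score_genes)
    pw_scores <- lapply(gene_scores, score_pathways, pathways = pathways)
    score_paths <- unlist(lapply(names(gene_scores), function(cl) {
      pg <- out(sprintf("gene_scores_%s.tsv", cl))
      pp <- out(sprintf("pathway_scores_%s.tsv", cl))
      write_table(as.data.frame(gene_scores[[cl]]), pg)
      write_table(as.data.frame(pw_scores[[cl]]), pp)
      c(pg, pp)
    }))
    emit("score", score_paths)

    stage <- "aggregate"
    agg_genes <- aggregate_scores(gene_scores)
    agg_pw <- aggregate_scores(pw_scores)
    write_table(as.data.frame(agg_genes), out("gene_scores_aggregate.tsv"))
    write_table(as.data.frame(agg_pw), out("pathway_scores_aggregate.tsv"))
    emit("aggregate", c(out("gene_scores_aggregate.tsv"),
                        out("pathway_scores_aggregate.tsv")))

    stage <- "select"
    sp <- config$selection
    sel_genes <- select_genes(agg_genes, n_subsets = sp$n_subsets,
                              subset_size = min(sp$subset_size,
                                                nrow(agg_genes)),
                              fraction = sp$fraction, seed = sp$seed)
    sel_pw <- select_pathways(agg_pw, fraction = sp$fraction)
    write_table(selection_table(sel_genes), out("selection_genes.tsv"))
    write_table(selection_table(sel_pw), out("selection_pathways.tsv"))
    jsonlite::write_json(
      list(genes = selection_meta(sel_genes),
           pathways = selection_meta(sel_pw)),
      out("selection_meta.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    emit("select", c(out("selection_genes.tsv"),
                     out("selection_pathways.tsv"),
                     out("selection_meta.json")))

    stage <- "enrich"
    ep <- config$enrichment
    background <- agg_genes$gene_id
    enr_paths <- character(0)
    for (set in c("enriched", "deficient")) {
      res <- term_enrichment(sel_genes[[set]]$id, pathways, background,
                             variant = ep$variant, alpha = ep$alpha)
      p <- out(sprintf("term_enrichment_%s.tsv", set))
      write_table(res, p)
      enr_paths <- c(enr_paths, p)
    }
    if (!is.null(config$class_lists)) {
      cls_rows <- do.call(rbind, lapply(names(config$class_lists),
        function(cls) {
          members <- read_id_list(config$class_lists[[cls]])
          rbind(
            cbind(class = cls, set = "enriched",
                  class_enrichment(sel_genes$enriched$id, members,
                                   background, "enriched")),
            cbind(class = cls, set = "deficient",
                  class_enrichment(sel_genes$deficient$id, members,
                                   background, "depleted")))
        }))
      write_table(cls_rows, out("class_enrichment.tsv"))
      enr_paths <- c(enr_paths, out("class_enrichment.tsv"))
    }
    emit("enrich", enr_paths)

    stage <- "permute"
    pp <- config$permutation
    if (pp$B > 0) {
      perm <- permutation_test(
        agg_genes, pathways, background = background,
        selection = config$selection, B = pp$B, top_m = pp$top_m,
        seed = pp$seed, variant = ep$variant)
      jsonlite::write_json(
        list(q_enriched = perm$q_enriched, q_deficient = perm$q_deficient,
             x_enriched = perm$x_enriched, x_deficient = perm$x_deficient,
             B = perm$B, top_m = perm$top_m, seed = perm$seed,
             selection_seed = config$selection$seed),
        out("permutation_summary.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      write_table(permutation_null_table(perm, "enriched"),
                  out("permutation_null_enriched.tsv"))
      write_table(permutation_null_table(perm, "deficient"),
                  out("permutation_null_deficient.tsv"))
      emit("permute", c(out("permutation_summary.json"),
                        out("permutation_null_enriched.tsv"),
                        out("permutation_null_deficient.tsv")))
    } else {
      emit("permute", character(0))
    }

    stage <- "concord"
    if (length(gene_scores) >= 2) {
      cm <- correlation_matrix(gene_scores, "GRE")
      cn <- correlation_matrix(gene_scores, "NGRE")
      pairs <- rbind(correlation_pairs(cm), correlation_pairs(cn))
      write_table(pairs, out("concordance_pairs.tsv"))
      emit("concord", out("concordance_pairs.tsv"))
    } else {
      emit("concord", character(0))
    }

    manifest$status <- "ok"
    write_manifest()
    manifest
  }, error = function(e) {
    for (p in outputs[file.exists(outputs)])
      file.rename(p, paste0(p, ".partial"))
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    write_manifest()
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Flatten a selection result to a table
#'
#' @param sel a `selection_result`.
#' @return data.frame with columns `id`, `score_x`, `score_y`, `distance`,
#'   `set`.
#' @export
selection_table <- function(sel) {
  stopifnot(inherits(sel, "selection_result"))
  mk <- function(df, set)
    data.frame(id = df$id, score_x = df$x, score_y = df$y,
               distance = df$distance, set = set, stringsAsFactors = FALSE)
  rbind(mk(sel$enriched, "enriched"), mk(sel$deficient, "deficient"))
}

selection_meta <- function(sel) {
  list(line_high = sel$line_high[c("slope", "intercept", "n_points")],
       line_low = sel$line_low[c("slope", "intercept", "n_points")],
       fraction = sel$fraction, quota = sel$quota, n = sel$n,
       seed = sel$seed, shortfall = as.list(sel$shortfall))
}
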