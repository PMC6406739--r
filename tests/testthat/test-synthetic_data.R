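bundle_hash <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  vapply(files, function(f) digest_file(f), "")
}

digest_file <- function(f) {
  # cheap content fingerprint without extra dependencies
  paste(tools::md5sum(f), collapse = "")
}

small_cfg <- function(...) {
  synthetic_config(n_genes = 120, n_cell_lines = 2, tfs_per_line = 2,
                   peaks_per_tf = 800, ...)
}

test_that("the same config generates a byte-identical bundle twice", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_bundle(small_cfg(seed = 51), d1)
  generate_bundle(small_cfg(seed = 51), d2)
  h1 <- bundle_hash(d1)
  h2 <- bundle_hash(d2)
  expect_equal(unname(h1), unname(h2))
  expect_gt(length(h1), 5)

  d3 <- withr::local_tempdir()
  generate_bundle(small_cfg(seed = 52), d3)
  expect_false(identical(unname(h1), unname(bundle_hash(d3))))
})

test_that("every emitted file re-reads through the io layer without warnings", {
  d <- withr::local_tempdir()
  b <- generate_bundle(small_cfg(seed = 53), d)
  expect_no_warning({
    reps <- read_repeatmasker(b$paths$repeats, "ucsc_rmsk")
    genes <- read_gene_table(b$paths$genes)
    gmt <- read_gmt(b$paths$gmt)
    cls <- lapply(b$paths$classes, read_id_list)
    pks <- lapply(b$paths$peaks, read_peaks, format = "narrowPeak")
  })
  expect_equal(nrow(genes), 120)
  expect_equal(length(gmt), 60 + 2)  # background + one planted term per tail
  expect_true(all(unlist(gmt) %in% genes$gene_id))
  expect_true(all(unlist(b$truth$planted_gene_ids) %in% genes$gene_id))
  expect_true(all(reps$divergence_pct >= 0 & reps$divergence_pct <= 100))
})

test_that("empirical RE-summit fractions concentrate on the planted theta", {
  d <- withr::local_tempdir()
  cfg <- synthetic_config(n_genes = 150, n_cell_lines = 2, tfs_per_line = 3,
                          peaks_per_tf = 3000, planted_coverage_factor = 1,
                          seed = 54)
  b <- generate_bundle(cfg, d)
  reps <- read_repeatmasker(b$paths$repeats)
  genes <- read_gene_table(b$paths$genes)
  pk <- do.call(rbind, lapply(b$paths$peaks, read_peaks,
                              format = "narrowPeak"))
  ht <- assign_hits(pk, reps, genes)
  grp <- function(ids) {
    sel <- ht$genes$gene_id %in% ids
    sum(ht$genes$S[sel]) / sum(ht$genes$T[sel])
  }
  planted <- unlist(b$truth$planted_gene_ids)
  others <- setdiff(genes$gene_id,
                    c(planted, unlist(b$truth$deficient_gene_ids)))
  expect_gt(sum(ht$genes$T[ht$genes$gene_id %in% planted]), 500)
  expect_lt(abs(grp(planted) - cfg$theta_planted), 0.05)
  expect_lt(abs(grp(others) - cfg$theta_background), 0.05)
})

test_that("per-gene S/T estimates theta consistently (CI coverage)", {
  d <- withr::local_tempdir()
  cfg <- synthetic_config(n_genes = 100, n_cell_lines = 2, tfs_per_line = 3,
                          peaks_per_tf = 4000, coverage_sdlog = 0.2,
                          seed = 55)
  b <- generate_bundle(cfg, d)
  ht <- assign_hits(
    do.call(rbind, lapply(b$paths$peaks, read_peaks, format = "narrowPeak")),
    read_repeatmasker(b$paths$repeats), read_gene_table(b$paths$genes))
  theta <- unlist(b$truth$theta)[ht$genes$gene_id]
  ok <- ht$genes$T >= 20
  phat <- ht$genes$S[ok] / ht$genes$T[ok]
  half <- 1.96 * sqrt(pmax(phat * (1 - phat), 0.01) / ht$genes$T[ok])
  covered <- abs(phat - theta[ok]) <= half
  expect_gte(mean(covered), 0.85)
})

test_that("profiles set the full-scale universe sizes and reject unknown names", {
  t5 <- scale_profile("table5")
  expect_equal(t5$n_genes, 25075)
  expect_equal(unname(t5$class_sizes), c(1865, 1505))
  ps <- scale_profile("paper_scale")
  expect_equal(ps$n_pathways, 3123)
  expect_equal(ps$n_genes, 24389)
  expect_equal(ps$n_cell_lines, 13)
  expect_error(scale_profile("galactic"), "arg")
})

test_that("impossible geometry and inconsistent thetas are rejected", {
  expect_error(generate_bundle(synthetic_config(n_genes = 1000, n_chroms = 1,
                                                chrom_length = 1e6, seed = 1),
                               withr::local_tempdir()),
               "genome too small")
  expect_error(synthetic_config(theta_background = 0.9, theta_planted = 0.5),
               "theta")
  expect_error(synthetic_config(planted_gene_fraction = 0), "fraction")
})

test_that("class lists overlap the planted genes as configured", {
  d <- withr::local_tempdir()
  cfg <- small_cfg(seed = 56, class_planted_overlap = 0.5,
                   class_sizes = c(miRNA = 30))
  b <- generate_bundle(cfg, d)
  members <- read_id_list(b$paths$classes[["miRNA"]])
  expect_length(members, 30)
  planted <- unlist(b$truth$planted_gene_ids)
  expect_equal(length(intersect(members, planted)),
               min(round(0.5 * 30), length(planted)))
})
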