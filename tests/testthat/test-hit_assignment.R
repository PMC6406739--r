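test_that("TSS windows follow strand, span 2*flank and clip at zero", {
  g <- make_genes(tss = 100000, strand = "+")
  expect_equal(unlist(tss_window(g)[, c("start", "end")], use.names = FALSE),
               c(95000, 105000))

  gm <- data.frame(gene_id = "g1", symbol = "g1", chrom = "chr1",
                   strand = "-", start = 100000, end = 108000,
                   stringsAsFactors = FALSE)
  w <- tss_window(gm)  # TSS is the last transcribed base, 107999
  expect_equal(c(w$start, w$end), c(102999, 112999))

  gc <- make_genes(tss = 2000, strand = "+")
  wc <- tss_window(gc)
  expect_equal(c(wc$start, wc$end), c(0, 7000))
})

test_that("a hand-enumerated fixture produces the expected S, T and totals", {
  genes <- make_genes(tss = 100000)               # window [95000, 105000)
  reps <- make_repeats(96000, 97000)
  peaks <- make_peaks(c(96500, 104000, 200000))
  ht <- assign_hits(peaks, reps, genes)
  expect_equal(ht$genes$S, 1)
  expect_equal(ht$genes$T, 2)
  expect_equal(ht$genome_totals$genome$total, 3)
  expect_equal(ht$genome_totals$genome$re_linked, 1)
  expect_equal(ht$genome_totals$tss$total, 2)
})

test_that("window boundaries are half-open at the summit", {
  genes <- make_genes(tss = 100000)
  peaks <- make_peaks(c(95000, 104999, 105000))   # end boundary excluded
  ht <- assign_hits(peaks, make_repeats(numeric(0), numeric(0)), genes)
  expect_equal(ht$genes$T, 2)
})

test_that("a summit inside two overlapping windows counts for both genes", {
  genes <- make_genes(tss = c(100000, 103000))    # windows overlap 95-105k/98-108k
  peaks <- make_peaks(100500)
  ht <- assign_hits(peaks, make_repeats(numeric(0), numeric(0)), genes)
  expect_equal(ht$genes$T, c(1, 1))
  expect_gt(sum(ht$genes$T), ht$genome_totals$genome$total)  # no splitting
})

test_that("interval assignment equals the O(n*m) brute-force scan", {
  for (seed in c(1, 2)) {
    fx <- random_assignment_fixture(n_peaks = 1000, n_res = 1000,
                                    n_genes = 60, seed = seed)
    ht <- assign_hits(fx$peaks, fx$repeats, fx$genes)
    oracle <- brute_force_assign(fx$peaks, fx$repeats, fx$genes)
    expect_hit_tables_equal(ht, oracle)
  }
})

test_that("hit tables are invariant to input row order", {
  fx <- random_assignment_fixture(n_peaks = 300, n_res = 100, n_genes = 20,
                                  seed = 3)
  ht1 <- assign_hits(fx$peaks, fx$repeats, fx$genes)
  set.seed(99)
  ht2 <- assign_hits(fx$peaks[sample(nrow(fx$peaks)), ],
                     fx$repeats[sample(nrow(fx$repeats)), ],
                     fx$genes, cell_line = ht1$cell_line)
  expect_equal(ht1$genes, ht2$genes)
  expect_equal(ht1$genome_totals, ht2$genome_totals)
})

test_that("S <= T always, and removing repeats forces S to zero", {
  fx <- random_assignment_fixture(n_peaks = 500, n_res = 200, n_genes = 30,
                                  seed = 4)
  ht <- assign_hits(fx$peaks, fx$repeats, fx$genes)
  expect_true(all(ht$genes$S <= ht$genes$T))
  ht0 <- assign_hits(fx$peaks, fx$repeats[0, ], fx$genes)
  expect_true(all(ht0$genes$S == 0))
  expect_equal(ht0$genes$T, ht$genes$T)
})

test_that("stray chromosomes reach genome totals but never windows", {
  genes <- make_genes(tss = 100000)
  peaks <- rbind(make_peaks(100000), make_peaks(500, chrom = "chrUn"))
  expect_message(ht <- assign_hits(peaks, make_repeats(numeric(0), numeric(0)),
                                   genes), "chrUn")
  expect_equal(ht$genome_totals$genome$total, 2)
  expect_equal(ht$genes$T, 1)
})

test_that("class fractions are percentages of total hit weight", {
  genes <- make_genes(tss = 100000)
  reps <- rbind(make_repeats(c(96000, 97000, 98000), c(96600, 97600, 98600),
                             class = c("SINE", "SINE", "SINE")),
                make_repeats(99000, 99600, class = "LINE"))
  # 3 SINE summits + 1 LINE summit + 6 non-RE summits, all inside the window
  peaks <- make_peaks(c(96100, 96200, 97100, 99100,
                        95100, 95200, 95300, 103000, 103100, 103200))
  s <- re_class_summary(assign_hits(peaks, reps, genes))
  g <- s[s$scope == "genome", ]
  expect_equal(g$pct_SINE, 30)
  expect_equal(g$pct_LINE, 10)
  expect_equal(g$pct_LTR_ERV, 0)
  expect_equal(g$pct_re_linked, 40)

  all_re <- re_class_summary(assign_hits(make_peaks(96100), reps, genes))
  expect_equal(all_re$pct_re_linked, c(100, 100))

  ht <- assign_hits(make_peaks(1)[0, ], reps, genes)
  expect_error(re_class_summary(ht), "zero total")
})

test_that("class attribution uses the smallest containing repeat", {
  genes <- make_genes(tss = 100000)
  reps <- rbind(make_repeats(96000, 99000, class = "LINE"),
                make_repeats(96400, 96800, class = "SINE"))  # nested, smaller
  ht <- assign_hits(make_peaks(96500), reps, genes)
  expect_equal(ht$genome_totals$genome$per_class[["SINE"]], 1)
  expect_equal(ht$genome_totals$genome$per_class[["LINE"]], 0)
})

test_that("signal-weighted and any-overlap hit models change the counting", {
  genes <- make_genes(tss = 100000)
  reps <- make_repeats(96000, 97000)
  pk <- make_peaks(c(96500, 104000), signal = c(4, 6))
  ht <- assign_hits(pk, reps, genes, hit_model("signal_weighted"))
  expect_equal(ht$genes$S, 4)
  expect_equal(ht$genes$T, 10)

  # interval [94890, 95090) straddles the window start: summit outside,
  # interval overlaps
  edge <- make_peaks(94990, width = 200)
  ht2 <- assign_hits(edge, reps, genes, hit_model("any_overlap"))
  expect_equal(ht2$genes$T, 1)
  ht3 <- assign_hits(edge, reps, genes, hit_model("summit"))
  expect_equal(ht3$genes$T, 0)
})
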