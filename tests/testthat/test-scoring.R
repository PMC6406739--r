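hit_df <- function(S, T) {
  data.frame(gene_id = sprintf("g%d", seq_along(S)), S = S, T = T,
             stringsAsFactors = FALSE)
}

test_that("GRE is the mean-normalized RE-linked load", {
  expect_equal(unname(gre(hit_df(c(2, 0, 4), c(4, 2, 4)))), c(1, 0, 2))
  expect_equal(unname(gre(hit_df(c(3, 3, 3), c(5, 5, 5)))), c(1, 1, 1))
  expect_error(gre(hit_df(c(0, 0), c(1, 2))), "no RE-linked hits")
})

test_that("mean GRE is 1 on random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    T <- rpois(50, 20) + 1
    S <- rbinom(50, T, 0.4)
    if (all(S == 0)) next
    expect_equal(mean(gre(hit_df(S, T))), 1)
  }
})

test_that("NGRE double-normalizes and zeroes no-hit genes", {
  v <- ngre(hit_df(c(2, 0, 4), c(4, 2, 4)))
  expect_equal(unname(v), c(5 / 6, 0, 5 / 3))
  # a gene at the average S/T ratio scores exactly 1
  v2 <- ngre(hit_df(c(2, 4), c(4, 8)))
  expect_equal(unname(v2), c(1, 1))
  # T = 0 (hence S = 0) is 0 by convention, not NaN
  v3 <- ngre(hit_df(c(2, 0), c(4, 0)))
  expect_equal(unname(v3)[2], 0)
})

test_that("NGRE is invariant under global rescaling of hit weights", {
  set.seed(11)
  T <- rpois(40, 30) + 1
  S <- rbinom(40, T, 0.3)
  base <- ngre(hit_df(S, T))
  for (c in c(0.5, 3, 100))
    expect_equal(ngre(hit_df(S * c, T * c)), base)
})

test_that("PII sums member GRE over scored genes and flags empty pathways", {
  gs <- score_genes(hit_df(c(2, 0, 4), c(4, 2, 4)))
  pw <- list(P1 = c("g1", "g3"), P2 = "g3", P3 = c("g1", "gX"),
             P4 = c("gY", "gZ"))
  expect_message(res <- pii(gs, pw), "absent")
  expect_equal(res$PII[res$pathway_id == "P1"], 1 + 2)
  expect_equal(res$PII[res$pathway_id == "P2"], 2)      # single member
  expect_equal(res$PII[res$pathway_id == "P3"], 1)      # missing id skipped
  expect_true(res$flagged[res$pathway_id == "P4"])
  expect_true(is.na(res$PII[res$pathway_id == "P4"]))
  expect_equal(res$n_genes_scored, c(2L, 1L, 1L, 0L))
})

test_that("PII matches a brute-force sum on random pathway sets", {
  set.seed(5)
  gs <- score_genes(hit_df(rbinom(30, 20, 0.4) + 1, rep(25, 30)))
  pw <- lapply(1:8, function(i) sample(gs$gene_id, sample(3:10, 1)))
  names(pw) <- sprintf("P%d", 1:8)
  res <- pii(gs, pw)
  for (p in names(pw))
    expect_equal(res$PII[res$pathway_id == p],
                 sum(gs$GRE[gs$gene_id %in% pw[[p]]]))
})

test_that("NPII pools member loads; modes agree on single-gene pathways", {
  gs <- score_genes(hit_df(c(2, 0, 4), c(4, 2, 4)))
  # pathway {g1, g3}: S = 6, T = 8, mean(S) = 2, mean(T) = 10/3
  res <- npii(gs, list(P = c("g1", "g3")))
  expect_equal(res$NPII, (6 / 2) / (8 / (10 / 3)))  # 1.25
  one <- list(P = "g1")
  expect_equal(npii(gs, one)$NPII, gs$NGRE[1])
  expect_equal(npii(gs, one, mode = "sum_ngre")$NPII, gs$NGRE[1])
  # pooled union of all genes scores exactly 1 in ratio-of-sums mode
  expect_equal(npii(gs, list(ALL = gs$gene_id))$NPII, 1)
  # zero pooled T is flagged undefined
  z <- npii(score_genes(hit_df(c(2, 0), c(4, 0))), list(P = "g2"))
  expect_true(z$flagged && is.na(z$NPII))
})

test_that("NPII modes match their brute-force definitions on random data", {
  set.seed(6)
  T <- rpois(40, 30) + 1
  gs <- score_genes(hit_df(rbinom(40, T, 0.35), T))
  pw <- lapply(1:6, function(i) sample(gs$gene_id, sample(2:12, 1)))
  names(pw) <- sprintf("P%d", 1:6)
  r1 <- npii(gs, pw)
  r2 <- npii(gs, pw, mode = "sum_ngre")
  for (p in names(pw)) {
    sel <- gs$gene_id %in% pw[[p]]
    expect_equal(r1$NPII[r1$pathway_id == p],
                 (sum(gs$S[sel]) / mean(gs$S)) / (sum(gs$T[sel]) / mean(gs$T)))
    expect_equal(r2$NPII[r2$pathway_id == p], sum(gs$NGRE[sel]))
  }
})

test_that("aggregation is the per-id unweighted mean across cell lines", {
  a <- score_genes(hit_df(c(2, 0, 4), c(4, 2, 4)), cell_line = "A")
  expect_equal(aggregate_scores(list(a))$GRE, a$GRE)  # single line: identity

  b <- score_genes(hit_df(c(4, 2, 6), c(6, 4, 6)), cell_line = "B")
  agg <- aggregate_scores(list(a, b))
  expect_equal(agg$GRE, (a$GRE + b$GRE) / 2)
  expect_equal(agg$n_lines, rep(2, 3))

  # 13 synthetic lines against the column-mean oracle
  set.seed(9)
  tabs <- lapply(1:13, function(i) {
    T <- rpois(25, 30) + 1
    score_genes(hit_df(rbinom(25, T, 0.4), T), cell_line = paste0("L", i))
  })
  agg13 <- aggregate_scores(tabs)
  m <- match(tabs[[1]]$gene_id, agg13$gene_id)
  expect_equal(agg13$NGRE[m], unname(rowMeans(sapply(tabs, `[[`, "NGRE"))))
  expect_error(aggregate_scores(list()), "no score tables")
})

test_that("ids missing from some lines average over the lines present", {
  a <- score_genes(hit_df(c(2, 4), c(4, 4)), cell_line = "A")        # g1 g2
  b <- score_genes(hit_df(c(1, 2, 3), c(2, 3, 4)), cell_line = "B")  # g1 g2 g3
  agg <- aggregate_scores(list(a, b))
  expect_equal(nrow(agg), 3)
  expect_equal(agg$n_lines[agg$gene_id == "g3"], 1)
  expect_equal(agg$GRE[agg$gene_id == "g3"], b$GRE[3])
})
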