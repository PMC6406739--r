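test_that("hypergeometric tails equal exhaustive enumeration on small tables", {
  set.seed(13)
  for (rep in 1:40) {
    N <- sample(5:60, 1)
    K <- resample(1:N)
    n <- resample(1:N)
    lo <- max(0, n - (N - K))
    k <- resample(lo:min(n, K))
    expect_equal(hypergeom_tail(k, n, K, N, "upper"),
                 enum_hyper(k, n, K, N, "upper"), tolerance = 1e-12)
    expect_equal(hypergeom_tail(k, n, K, N, "lower"),
                 enum_hyper(k, n, K, N, "lower"), tolerance = 1e-12)
    expect_equal(hypergeom_tail(k, n, K, N, "lower", inclusive = TRUE),
                 enum_hyper(k, n, K, N, "lower", inclusive = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("log-space tails agree with phyper to 12 significant digits", {
  cases <- list(c(177, 1219, 1865, 25075), c(72, 1219, 1865, 25075),
                c(5, 20, 30, 100), c(40, 50, 60, 200))
  for (cs in cases) {
    k <- cs[1]; n <- cs[2]; K <- cs[3]; N <- cs[4]
    expect_equal(hypergeom_tail(k, n, K, N, "upper"),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(hypergeom_tail(k, n, K, N, "lower"),
                 phyper(k - 1, K, N - K, n), tolerance = 1e-12)
  }
})

test_that("pmf normalization, tail complement and symmetry hold", {
  set.seed(14)
  for (rep in 1:20) {
    N <- resample(10:60)
    K <- resample(1:N)
    n <- resample(1:N)
    lo <- max(0, n - (N - K)); hi <- min(n, K)
    # support sums to 1
    expect_equal(sum(exp(log_hyper_pmf(lo:hi, n, K, N))), 1,
                 tolerance = 1e-12)
    k <- resample(lo:hi)
    # strict lower tail is the exact complement of the upper tail
    expect_equal(hypergeom_tail(k, n, K, N, "upper") +
                   hypergeom_tail(k, n, K, N, "lower"), 1, tolerance = 1e-12)
    # swapping the roles of sample and class leaves tails unchanged
    expect_equal(hypergeom_tail(k, n, K, N, "upper"),
                 hypergeom_tail(k, K, n, N, "upper"), tolerance = 1e-12)
  }
})

test_that("the upper tail is strictly decreasing in the overlap", {
  p <- vapply(0:10, function(k) hypergeom_tail(k, 10, 15, 50, "upper"), 0)
  expect_true(all(diff(p) < 0))
})

test_that("degenerate and textbook cases are exact", {
  expect_equal(hypergeom_tail(0, 0, 5, 10, "upper"), 1)
  expect_equal(hypergeom_tail(5, 5, 5, 10, "upper"), 1 / choose(10, 5))
  expect_equal(hypergeom_tail(0, 5, 5, 10, "lower"), 0)  # P(X < 0)
  expect_error(hypergeom_tail(6, 5, 5, 10), "exceeds")
  expect_error(hypergeom_tail(1, 5, 11, 10), "exceeds")
})

test_that("one-sided Fisher equals the upper tail; EASE decrements k", {
  expect_equal(fisher_tests(4, 10, 5, 20), hypergeom_tail(4, 10, 5, 20))
  expect_equal(fisher_tests(1, 10, 5, 20, variant = "ease"),
               fisher_tests(0, 10, 5, 20))
  expect_equal(fisher_tests(1, 10, 5, 20, variant = "ease"), 1)
  # cross-check against fisher.test's one-sided enrichment p
  set.seed(15)
  for (rep in 1:15) {
    N <- resample(10:50); K <- resample(1:N); n <- resample(1:N)
    lo <- max(0, n - (N - K)); k <- resample(lo:min(n, K))
    ft <- fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2),
                      alternative = "greater")$p.value
    expect_equal(fisher_tests(k, n, K, N), ft, tolerance = 1e-9)
    expect_equal(fisher_tests(k, n, K, N, "ease"),
                 enum_hyper(max(k - 1, lo), n, K, N, "upper"),
                 tolerance = 1e-12)
  }
})

test_that("class tests build counts by set algebra and pick the right tail", {
  bg <- sprintf("g%03d", 1:200)
  cls <- sprintf("g%03d", 1:40)
  sel <- sprintf("g%03d", seq(1, 120, 2))
  res <- class_enrichment(sel, cls, bg, "enriched")
  expect_equal(res$k, length(intersect(sel, cls)))
  expect_equal(res$n, length(sel))
  expect_equal(res$K, 40)
  expect_equal(res$N, 200)
  expect_equal(res$fold_enrichment, (res$k / res$n) / (res$K / res$N))
  expect_equal(res$p_value,
               hypergeom_tail(res$k, res$n, res$K, res$N, "upper"))
  dep <- class_enrichment(sel, cls, bg, "depleted")
  expect_equal(dep$p_value,
               hypergeom_tail(res$k, res$n, res$K, res$N, "lower"))
  # class members outside the background are dropped before counting
  res2 <- class_enrichment(sel, c(cls, "zzz"), bg, "enriched")
  expect_equal(res2$K, 40)
  expect_error(class_enrichment(c(sel, "zzz"), cls, bg), "outside")
  # selected = background makes enrichment certain
  all_sel <- class_enrichment(bg, cls, bg, "enriched")
  expect_equal(all_sel$k, all_sel$K)
  expect_equal(all_sel$p_value, 1)
})

test_that("term enrichment tests each term and sorts by p", {
  set.seed(16)
  bg <- sprintf("g%03d", 1:150)
  sel <- sample(bg, 30)
  ann <- lapply(1:10, function(i) sample(bg, sample(5:25, 1)))
  names(ann) <- sprintf("T%02d", 1:10)
  ann$DISJOINT <- setdiff(bg, sel)[1:5]
  res <- term_enrichment(sel, ann, bg)
  expect_false("DISJOINT" %in% res$term_id)        # k = 0 omitted
  expect_true(!is.unsorted(res$p_value))
  for (i in seq_len(nrow(res)))
    expect_equal(res$p_value[i],
                 fisher_tests(res$k[i], res$n[i], res$K[i], res$N[i]))
  expect_equal(res$significant, res$p_value < 0.05)

  # a term identical to the selection reaches its minimal possible p
  res2 <- term_enrichment(sel, list(EXACT = sel), bg)
  expect_equal(res2$p_value,
               hypergeom_tail(30, 30, 30, 150, "upper"))
  expect_error(term_enrichment(sel, list(), bg), "empty annotation")

  bh <- term_enrichment(sel, ann, bg, adjust = "BH")
  expect_equal(bh$p_adjusted, p.adjust(bh$p_value, "BH"))
})
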