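test_that("rank test matches enumeration and degenerate cases", {
  expect_equal(rank_test(1:3, 4:6), 0.1)  # U = 0, exact two-sided
  expect_equal(rank_test(c(1.5, 2.5, 9), c(1.5, 2.5, 9) + 1e9 * 0), 1)
  set.seed(23)
  x <- rnorm(4); y <- rnorm(5)
  expect_equal(rank_test(x, y), mw_enumerate_p(x, y))
})

test_that("PTC tallies cross-classify ORF class against DE status", {
  ann <- data.frame(
    transcript_id = paste0("T", 1:10),
    gene_id = "G1",
    orf_class = c(rep("PTC_POSITIVE", 3), rep("PTC_NEGATIVE", 6), "NO_ORF"),
    stringsAsFactors = FALSE
  )
  de <- data.frame(
    transcript_id = paste0("T", 1:9),  # T10 lacks a DE label
    status = c("up", "up", "non", "up", "up", "down", "non", "non", "non"),
    stringsAsFactors = FALSE
  )
  tally <- ptc_tally(ann, de)
  s <- tally$summary
  expect_equal(s$n[s$status == "up"], 4)
  expect_equal(s$n_ptc[s$status == "up"], 2)
  expect_equal(s$pct_ptc[s$status == "up"], 50)
  expect_equal(s$pct_ptc[s$status == "down"], 0)
  expect_equal(tally$overall$n, 9)
  expect_equal(tally$n_excluded, 1)
  # the reported headline arithmetic: 137 of 1,971 is ~7%
  expect_equal(round(100 * 137 / 1971), 7)
})

test_that("length summaries use interpolated percentiles and rank tests", {
  ann <- data.frame(
    transcript_id = paste0("T", 1:7), gene_id = rep(c("G1", "G2"), c(4, 3)),
    orf_class = c(rep("PTC_NEGATIVE", 6), "NO_ORF"),
    utr5_len = c(rep(50, 6), NA), orf_len = c(rep(300, 6), NA),
    utr3_len = c(100, 200, 300, 4, 5, 6, NA), stringsAsFactors = FALSE
  )
  groups <- data.frame(transcript_id = paste0("T", 1:7),
                       group = c("up", "up", "up", "down", "down", "down",
                                 "up"))
  res <- summarize_length_distributions(ann, groups, c("G1", "G2"))
  s <- res$summary[res$summary$feature == "utr3", ]
  expect_equal(s$p50[s$group == "up"], 200)
  expect_equal(s$p25[s$group == "up"], 150)   # linear interpolation
  expect_equal(s$p75[s$group == "up"], 250)
  expect_equal(s$n[s$group == "up"], 3)       # NO_ORF excluded
  t3 <- res$tests[res$tests$feature == "utr3", ]
  # {100,200,300} vs {4,5,6}: U = 9, exact two-sided p = 0.1
  expect_equal(t3$p_value, 0.1)
  # identical groups give p = 1 under the exact test
  groups2 <- data.frame(transcript_id = paste0("T", 1:6),
                        group = rep(c("a", "b"), 3))
  ann2 <- ann[1:6, ]
  ann2$utr3_len <- c(10, 10, 20, 20, 30, 30)
  res2 <- summarize_length_distributions(ann2, groups2, c("G1", "G2"))
  t2 <- res2$tests[res2$tests$feature == "utr3", ]
  expect_true(all(t2$p_value == 1))
  # undersized group comparisons are skipped with a warning
  groups3 <- data.frame(transcript_id = paste0("T", 1:6),
                        group = c(rep("a", 5), "b"))
  w <- testthat::capture_warnings(
    summarize_length_distributions(ann, groups3, c("G1", "G2")))
  expect_true(any(grepl("fewer than 2", w)))
})

test_that("usage shift summaries recover planted fraction changes", {
  u0 <- data.frame(transcript_id = paste0("T", 1:6),
                   gene_id = rep(c("G1", "G2"), each = 3),
                   if_wt = rep(c(.2, .3, .5), 2),
                   if_ko = rep(c(.2, .3, .5), 2))
  u0$dif <- u0$if_ko - u0$if_wt
  primary <- data.frame(transcript_id = paste0("T", 1:6), class = "both")
  res0 <- usage_shift_distributions(u0, primary)
  expect_equal(res0$mean_dif, 0)
  expect_equal(res0$p_value, 1)

  u1 <- u0
  u1$if_ko <- u1$if_wt + 0.25
  u1$dif <- u1$if_ko - u1$if_wt
  primary1 <- data.frame(transcript_id = paste0("T", 1:6),
                         class = "KO_only")
  res1 <- usage_shift_distributions(u1, primary1)
  expect_equal(res1$mean_dif[res1$class == "KO_only"], 0.25)

  # planted mean shift recovery under noise
  set.seed(29)
  n <- 500
  un <- data.frame(transcript_id = paste0("T", 1:n),
                   gene_id = paste0("G", 1:n),
                   if_wt = runif(n, 0.1, 0.5))
  un$if_ko <- pmin(1, un$if_wt + rnorm(n, 0.2, 0.1))
  un$dif <- un$if_ko - un$if_wt
  pn <- data.frame(transcript_id = un$transcript_id, class = "both")
  resn <- usage_shift_distributions(un, pn)
  expect_lt(abs(resn$mean_dif - 0.2), 0.03)
  expect_lt(resn$p_value, 1e-10)
})

test_that("weighted 3'UTR length follows the isoform-fraction weighting", {
  expect_equal(weighted_utr_length(c(100, 500), c(3, 1)), 200)
  expect_equal(weighted_utr_length(42, 7), 42)  # single-isoform identity
  expect_equal(weighted_utr_length(c(100, 500), c(3, 1), "printed_formula"),
               100)
  expect_error(weighted_utr_length(c(1, 2), c(0, 0)), "positive")

  set.seed(31)
  for (i in 1:200) {
    k <- sample(1:6, 1)
    l <- runif(k, 0, 3000)
    e <- rlnorm(k)
    w <- weighted_utr_length(l, e)
    expect_gte(w, min(l) - 1e-6)
    expect_lte(w, max(l) + 1e-6)
    expect_equal(weighted_utr_length(l, e, "printed_formula"), w / k)
  }
  # monotone towards the upweighted isoform's length
  l <- c(100, 500); e <- c(3, 1)
  w1 <- weighted_utr_length(l, e)
  w2 <- weighted_utr_length(l, c(3, 2))
  expect_gt(w2, w1)
})

make_subset_fixture <- function(if_wt, if_ko, utr3, gene_expr = 20) {
  k <- length(if_wt)
  x <- make_expression(paste0("T", seq_len(k)), rep("G1", k),
                       wt = gene_expr * if_wt, ko = gene_expr * if_ko)
  u <- data.frame(transcript_id = x$transcript_id, gene_id = "G1",
                  if_wt = if_wt, if_ko = if_ko, dif = if_ko - if_wt,
                  stringsAsFactors = FALSE)
  ann <- data.frame(transcript_id = x$transcript_id, gene_id = "G1",
                    orf_class = "PTC_NEGATIVE", utr3_len = utr3,
                    stringsAsFactors = FALSE)
  classify_usage_subsets(u, ann, x, fixture_conditions)
}

test_that("usage subsets partition genes by changing isoforms", {
  expect_equal(make_subset_fixture(c(.55, .45), c(.6, .4),
                                   c(100, 500))$subset, "a")
  expect_equal(make_subset_fixture(c(.5, .5), c(.75, .25),
                                   c(100, 500))$subset, "d")
  # boundary: a change of exactly the threshold counts ("minimum 20%")
  expect_equal(make_subset_fixture(c(.3, .35, .35), c(.5, .3, .2),
                                   c(100, 300, 500))$subset, "b")
  # single gene moving expression from short to long isoform
  call <- make_subset_fixture(c(.75, .25), c(.25, .75), c(100, 500))
  expect_equal(call$subset, "d")
  expect_equal(call$weighted_utr_wt, 200)
  expect_equal(call$weighted_utr_ko, 400)
  expect_equal(call$delta_weighted_utr, 200)
  expect_equal(call$mean_gene_expression, 20)
})

test_that("lowly expressed isoforms disqualify genes from subset calls", {
  # one isoform at 0.5 FPKM in WT: gene dropped under the all-expressed rule
  out <- make_subset_fixture(c(.95, .05), c(.5, .5), c(100, 500),
                             gene_expr = 10)
  expect_null(out)
})

test_that("weighted-UTR shifts are compared against the no-change subset", {
  calls <- data.frame(
    gene_id = paste0("G", 1:30),
    subset = rep(c("a", "b"), c(20, 10)),
    delta_weighted_utr = c(rnorm(20, 0, 5), rnorm(10, 300, 5)),
    mean_gene_expression = 10, stringsAsFactors = FALSE
  )
  res <- weighted_utr_shift_by_subset(calls)
  expect_equal(res$summary$n[res$summary$subset == "b"], 10)
  expect_gt(res$summary$p50[res$summary$subset == "b"], 250)
  expect_lt(res$tests$p_value[res$tests$subset == "b"], 1e-5)
  calls_no_a <- calls[calls$subset != "a", ]
  expect_warning(weighted_utr_shift_by_subset(calls_no_a), "subset a empty")
})

test_that("expression stratification reproduces per-bin medians", {
  calls <- data.frame(
    gene_id = paste0("G", 1:6), subset = "b",
    delta_weighted_utr = c(10, 20, 30, 100, 200, 300),
    mean_gene_expression = c(2, 3, 4, 10, 20, 30), stringsAsFactors = FALSE
  )
  res <- expression_stratified_shift(calls)
  expect_equal(res$median_delta[res$bin == "[1,5)" & res$subset == "b"], 20)
  expect_equal(res$median_delta[res$bin == "[5,50)" & res$subset == "b"],
               200)
  expect_equal(res$n[res$bin == "[50,Inf)" & res$subset == "b"], 0)
  # degenerate single bin reproduces the unstratified median
  res1 <- expression_stratified_shift(calls, edges = c(0, Inf))
  expect_equal(res1$median_delta, median(calls$delta_weighted_utr))
})
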