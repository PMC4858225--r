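test_that("quantile normalization maps columns onto the rank means", {
  x <- data.frame(transcript_id = c("T1", "T2"), gene_id = c("G1", "G1"),
                  s1 = c(1, 3), s2 = c(4, 2))
  norm <- quantile_normalize(x)
  # hand calculation: sorted columns (1,3) and (2,4), rank means (1.5, 3.5)
  expect_equal(norm$s1, c(1.5, 3.5))
  expect_equal(norm$s2, c(3.5, 1.5))
  expect_equal(attr(norm, "unit"), "normFPKM")

  # identical columns are a fixed point
  y <- data.frame(transcript_id = paste0("T", 1:4), gene_id = "G1",
                  a = c(5, 1, 3, 2), b = c(5, 1, 3, 2))
  expect_equal(quantile_normalize(y)$a, y$a)

  # ties receive the mean of the reference values for their tied ranks:
  # reference is (1.5, 2.5, 7), so the tied pair maps to 2
  z <- data.frame(transcript_id = paste0("T", 1:3), gene_id = "G1",
                  a = c(2, 2, 5), b = c(1, 3, 9))
  nz <- quantile_normalize(z)
  expect_equal(nz$a, c(2, 2, 7))
  expect_equal(nz$b, c(1.5, 2.5, 7))

  expect_error(quantile_normalize(x[, 1:3]), "at least 2 samples")
})

test_that("normalized tie-free columns share one sorted multiset", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    k <- sample(2:5, 1)
    m <- matrix(rlnorm(n * k, 1, 1), n, k)
    x <- data.frame(transcript_id = paste0("T", 1:n), gene_id = "G1", m)
    norm <- quantile_normalize(x)
    cols <- as.matrix(norm[, -(1:2)])
    ref <- sort(cols[, 1])
    for (j in 2:k) expect_equal(sort(cols[, j]), ref)
  }
})

test_that("tie-free normalization agrees with limma's implementation", {
  skip_if_not_installed("limma")
  set.seed(40)
  for (i in 1:5) {
    n <- sample(15:80, 1)
    k <- sample(2:5, 1)
    m <- matrix(rlnorm(n * k, 1, 1), n, k)
    x <- data.frame(transcript_id = paste0("T", 1:n), gene_id = "G1", m)
    got <- as.matrix(quantile_normalize(x)[, -(1:2)])
    ref <- limma::normalizeQuantiles(m, ties = TRUE)
    expect_equal(unname(got), unname(ref), tolerance = 1e-12)
  }
})

test_that("tied matrices match an independent tie-averaging oracle", {
  set.seed(43)
  for (i in 1:10) {
    n <- sample(8:30, 1)
    k <- sample(2:4, 1)
    m <- matrix(sample(0:6, n * k, replace = TRUE), n, k)  # heavy ties
    x <- data.frame(transcript_id = paste0("T", 1:n), gene_id = "G1", m)
    got <- as.matrix(quantile_normalize(x)[, -(1:2)])
    expect_equal(unname(got), unname(qn_oracle(m)))
  }
})

test_that("gene summation matches brute-force per-gene sums", {
  x <- make_expression(c("T1", "T2", "T3"), c("G1", "G1", "G2"),
                       wt = c(3, 1, 7), ko = c(2, 2, 7))
  g <- sum_gene_expression(x, fixture_conditions)
  expect_equal(g$WT[g$gene_id == "G1"], 4)
  expect_equal(g$WT[g$gene_id == "G2"], 7)   # single-transcript identity
  expect_equal(g$KO[g$gene_id == "G1"], 4)

  set.seed(7)
  big <- data.frame(
    transcript_id = paste0("T", 1:40),
    gene_id = sample(paste0("G", 1:10), 40, replace = TRUE),
    WT_1 = rlnorm(40), WT_2 = rlnorm(40), KO_1 = rlnorm(40),
    KO_2 = rlnorm(40), stringsAsFactors = FALSE
  )
  cond <- c(WT_1 = "WT", WT_2 = "WT", KO_1 = "KO", KO_2 = "KO")
  g2 <- sum_gene_expression(big, cond)
  for (gid in g2$gene_id) {
    rows <- big[big$gene_id == gid, ]
    # independent summation oracle, one sample at a time
    for (s in c("WT_1", "WT_2", "KO_1", "KO_2")) {
      expect_equal(g2[[s]][g2$gene_id == gid], sum(rows[[s]]))
    }
    expect_equal(g2$WT[g2$gene_id == gid],
                 mean(c(sum(rows$WT_1), sum(rows$WT_2))))
  }
})

test_that("isoform fractions divide transcript by gene expression", {
  x <- make_expression(c("T1", "T2", "T3", "T4"),
                       c("G1", "G1", "G2", "G3"),
                       wt = c(3, 1, 5, 0), ko = c(2, 2, 5, 0))
  g <- sum_gene_expression(x, fixture_conditions)
  f <- isoform_fraction(x, g, fixture_conditions, "WT")
  expect_equal(unname(f[c("T1", "T2")]), c(0.75, 0.25))
  expect_equal(unname(f[["T3"]]), 1)           # single isoform
  expect_false("T4" %in% names(f))             # zero-expression gene
  expect_equal(attr(f, "excluded_genes"), "G3")
})

test_that("usage fractions sum to one per gene and condition", {
  set.seed(11)
  x <- data.frame(
    transcript_id = paste0("T", 1:30),
    gene_id = rep(paste0("G", 1:10), each = 3),
    WT_1 = rlnorm(30), WT_2 = rlnorm(30),
    KO_1 = rlnorm(30), KO_2 = rlnorm(30), stringsAsFactors = FALSE
  )
  cond <- c(WT_1 = "WT", WT_2 = "WT", KO_1 = "KO", KO_2 = "KO")
  u <- isoform_usage(x, cond)
  sums_wt <- tapply(u$if_wt, u$gene_id, sum)
  sums_ko <- tapply(u$if_ko, u$gene_id, sum)
  expect_equal(as.numeric(sums_wt), rep(1, 10), tolerance = 1e-12)
  expect_equal(as.numeric(sums_ko), rep(1, 10), tolerance = 1e-12)
  expect_true(all(u$dif >= -1 & u$dif <= 1))
})

test_that("gene filters apply the 1-FPKM rules with strict boundaries", {
  x <- make_expression(c("T1", "T2", "T3", "T4", "T5"),
                       c("G1", "G2", "G3", "G4", "G4"),
                       wt = c(0.5, 1.0, 8, 5, 0.2),
                       ko = c(3.0, 1.0, 6, 3, 0.3))
  g <- sum_gene_expression(x, fixture_conditions)
  kept <- filter_expressed_genes(g)
  expect_false("G1" %in% kept)     # below 1 in WT
  expect_true("G2" %in% kept)      # exactly 1 survives
  expect_true(all(c("G3", "G4") %in% kept))

  multi <- multi_isoform_genes(x, fixture_conditions)
  expect_false("G3" %in% multi)    # one isoform
  expect_false("G4" %in% multi)    # second isoform below cutoff
  x2 <- make_expression(c("A", "B"), c("G9", "G9"), wt = c(5, 3),
                        ko = c(4, 2))
  expect_equal(multi_isoform_genes(x2, fixture_conditions), "G9")
})

test_that("filters are monotone in the cutoff", {
  set.seed(13)
  x <- data.frame(
    transcript_id = paste0("T", 1:60),
    gene_id = rep(paste0("G", 1:20), each = 3),
    WT_1 = rlnorm(60, 0, 1.5), KO_1 = rlnorm(60, 0, 1.5),
    stringsAsFactors = FALSE
  )
  g <- sum_gene_expression(x, fixture_conditions)
  cutoffs <- c(0.5, 1, 2, 4, 8)
  kept <- lapply(cutoffs, function(ct) filter_expressed_genes(g, ct))
  multi <- lapply(cutoffs, function(ct) {
    multi_isoform_genes(x, fixture_conditions, ct)
  })
  for (i in 2:length(cutoffs)) {
    expect_true(all(kept[[i]] %in% kept[[i - 1]]))
    expect_true(all(multi[[i]] %in% multi[[i - 1]]))
  }
})

test_that("primary-expression classes follow the two-sided cutoff rule", {
  x <- make_expression(paste0("T", 1:5), paste0("G", 1:5),
                       wt = c(0.2, 2, 0.5, 5, 1.0),
                       ko = c(5, 3, 0.8, 0.4, 2))
  cls <- classify_primary_expression(x, fixture_conditions)
  expect_equal(cls$class, c("KO_only", "both", "neither", "WT_only",
                            "neither"))  # exact-cutoff WT value -> neither
})

test_that("MA statistics reproduce hand-computed M values", {
  x <- make_expression(paste0("T", 1:3), paste0("G", 1:3),
                       wt = c(10, 10, 5), ko = c(10, 20, 5))
  ann <- data.frame(transcript_id = paste0("T", 1:3),
                    orf_class = c("PTC_NEGATIVE", "PTC_NEGATIVE", "NO_ORF"))
  ma <- ma_summary(x, fixture_conditions, ann, epsilon = 0.01)
  expect_equal(ma$points$M[1], 0)
  expect_equal(ma$points$M[2], log2(20.01 / 10.01))
  expect_equal(ma$points$A[1], log2(10.01))
  # equal conditions everywhere -> flat zero trend
  y <- make_expression(paste0("T", 1:6), paste0("G", 1:6),
                       wt = c(1, 2, 4, 8, 16, 32), ko = c(1, 2, 4, 8, 16, 32))
  ann_y <- data.frame(transcript_id = paste0("T", 1:6),
                      orf_class = "PTC_NEGATIVE")
  ma_y <- ma_summary(y, fixture_conditions, ann_y)
  expect_true(all(ma_y$points$M == 0))
  expect_true(all(ma_y$trend$M_smooth == 0))
})

test_that("the plumbing DE test calls planted shifts and controls nulls", {
  set.seed(17)
  n <- 10
  base <- rlnorm(n, 2, 0.5)
  x <- data.frame(
    transcript_id = paste0("T", 1:n), gene_id = paste0("G", 1:n),
    WT_1 = base * exp(rnorm(n, 0, 0.05)),
    WT_2 = base * exp(rnorm(n, 0, 0.05)),
    WT_3 = base * exp(rnorm(n, 0, 0.05)),
    WT_4 = base * exp(rnorm(n, 0, 0.05)),
    stringsAsFactors = FALSE
  )
  cond <- c(WT_1 = "WT", WT_2 = "WT", WT_3 = "WT", WT_4 = "WT",
            KO_1 = "KO", KO_2 = "KO", KO_3 = "KO", KO_4 = "KO")
  # planted 8-fold up-shift on every transcript, low noise
  for (s in c("KO_1", "KO_2", "KO_3", "KO_4")) {
    x[[s]] <- base * 8 * exp(rnorm(n, 0, 0.05))
  }
  de <- call_differential_expression(x, cond)
  expect_true(all(de$status == "up"))
  expect_true(all(de$log2_fold_change > 0))

  # identical replicate sets give no calls
  x_null <- x
  for (s in c("KO_1", "KO_2", "KO_3", "KO_4")) {
    x_null[[s]] <- x_null[[sub("KO", "WT", s)]]
  }
  de_null <- call_differential_expression(x_null, cond)
  expect_true(all(de_null$status == "non"))

  expect_error(
    call_differential_expression(make_expression("T1", "G1", 1, 2),
                                 fixture_conditions),
    "external")
})

test_that("the rank-sum plumbing test holds its type-I error rate", {
  set.seed(19)
  n <- 1000
  m <- matrix(rlnorm(n * 8, 1, 0.4), n, 8)
  x <- data.frame(transcript_id = paste0("T", 1:n),
                  gene_id = paste0("G", 1:n), m, stringsAsFactors = FALSE)
  names(x)[3:10] <- c(paste0("WT_", 1:4), paste0("KO_", 1:4))
  cond <- setNames(rep(c("WT", "KO"), each = 4), names(x)[3:10])
  de <- call_differential_expression(x, cond)
  expect_lte(mean(de$p_value <= 0.05), 0.07)
})

test_that("expression and DE tables round trip through their TSV dialects", {
  x <- make_expression(c("T1", "T2"), c("G1", "G1"), c(1.5, 2.5), c(3, 4))
  p <- tempfile(); write_expression(x, p)
  expect_equal(read_expression(p), x)
  cp <- tempfile(); write_condition_map(fixture_conditions, cp)
  expect_equal(read_condition_map(cp), fixture_conditions)
  de <- data.frame(transcript_id = "T1", log2_fold_change = 1.2,
                   p_value = 0.01, fdr = 0.04, status = "up",
                   stringsAsFactors = FALSE)
  dp <- tempfile(); write_de_table(de, dp)
  expect_equal(read_de_table(dp), de)
})
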