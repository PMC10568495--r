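test_that("pseudo-bulk sums cells per sample and conserves count mass", {
  cm <- toy_counts()
  pb <- pseudo_bulk(cm)
  expect_equal(as.matrix(pb$values),
               matrix(c(5, 0, 1, 5, 1, 0), 3,
                      dimnames = list(c("g1", "g2", "g3"), c("A", "B"))))

  # single-cell sample: pseudo-bulk equals that cell's column
  one <- count_matrix(cm$values[, "c1", drop = FALSE],
                      c(c1 = "A"))
  expect_equal(as.numeric(pseudo_bulk(one)$values),
               as.numeric(cm$values[, "c1"]))

  # random matrix against a brute-force summation oracle
  set.seed(1)
  m <- matrix(rpois(20 * 50, 2), 20, 50,
              dimnames = list(sprintf("g%d", 1:20), sprintf("c%d", 1:50)))
  soc <- setNames(sample(c("A", "B", "C"), 50, replace = TRUE), colnames(m))
  pb2 <- pseudo_bulk(count_matrix(m, soc))
  for (s in unique(soc)) {
    brute <- sapply(seq_len(20), function(g) sum(m[g, soc == s]))
    expect_equal(as.numeric(pb2$values[, s]), brute)
  }
  expect_equal(sum(pb2$values), sum(m))
})

test_that("log2-CPM follows the prior-adjusted formula and matches edgeR", {
  # frozen direct evaluation: zero count, prior 0.5, library 1e6
  m <- matrix(c(0, 1e6), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  prof <- log2_cpm(m, prior_count = 0.5)
  expect_equal(prof$values["g1", 1], log2(0.5 * 1e6 / (1e6 + 1)),
               tolerance = 1e-12)

  # equal counts in a column give equal values
  m2 <- matrix(c(7, 7, 1), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  v <- log2_cpm(m2)$values
  expect_equal(v["a", 1], v["b", 1])

  # doubling every count with prior 0 leaves CPM unchanged
  set.seed(2)
  m3 <- matrix(rpois(40, 20) + 1, 8, 5,
               dimnames = list(sprintf("g%d", 1:8), sprintf("s%d", 1:5)))
  expect_equal(log2_cpm(m3, prior_count = 0)$values,
               log2_cpm(2 * m3, prior_count = 0)$values, tolerance = 1e-12)

  # independent oracle: edgeR's log-CPM with the same prior
  expect_equal(unname(log2_cpm(m3, prior_count = 2)$values),
               unname(edgeR::cpm(m3, log = TRUE, prior.count = 2)),
               tolerance = 1e-8)

  expect_error(log2_cpm(matrix(0, 2, 1,
                               dimnames = list(c("a", "b"), "s1"))),
               "all-zero column")
})

test_that("dropout rates are per-gene zero fractions with binomial behaviour", {
  cm <- count_matrix(
    matrix(c(0, 0, 1, 4,
             0, 0, 0, 0), 2, 4, byrow = TRUE,
           dimnames = list(c("g1", "g2"), sprintf("c%d", 1:4))),
    setNames(rep("A", 4), sprintf("c%d", 1:4)))
  dr <- dropout_rates(cm, "A")
  expect_equal(unname(dr["g1"]), 0.5)
  expect_equal(unname(dr["g2"]), 1.0)
  expect_error(dropout_rates(cm, "missing"), "unknown sample")

  # binomial sampling oracle: 1000 cells at zero probability 0.7
  set.seed(3)
  x <- matrix(ifelse(runif(1000) < 0.7, 0, 1), 1, 1000,
              dimnames = list("g", sprintf("c%d", 1:1000)))
  dr2 <- dropout_rates(count_matrix(x, setNames(rep("A", 1000),
                                                colnames(x))), "A")
  expect_lt(abs(dr2["g"] - 0.7), 3 * sqrt(0.7 * 0.3 / 1000))
})

test_that("dropout gene counts exclude joint zeros from the denominator", {
  mk <- function(v) count_matrix(matrix(v, ncol = 1,
                                        dimnames = list(sprintf("g%d",
                                                                seq_along(v)),
                                                        "S")))
  res <- dropout_gene_count(mk(c(3, 0, 1)), mk(c(0, 0, 2)), "S")
  expect_equal(res$n_dropout, 1)
  expect_equal(res$denominator, 2)

  # identical support gives zero dropout genes
  res2 <- dropout_gene_count(mk(c(3, 0, 1)), mk(c(5, 0, 9)), "S")
  expect_equal(res2$n_dropout, 0)

  # random paired vectors against the brute-force set difference
  set.seed(4)
  for (i in 1:5) {
    b <- rpois(100, 0.8); p <- rpois(100, 0.8)
    res3 <- dropout_gene_count(mk(b), mk(p), "S")
    expect_equal(res3$n_dropout, length(setdiff(which(b > 0), which(p > 0))))
    expect_equal(res3$denominator, sum(b > 0 | p > 0))
  }
})

test_that("relative log expression centers every gene at its sample median", {
  m <- matrix(c(1, 2, 3,
                5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  r <- relative_log_expression(m)
  expect_equal(unname(r["g1", ]), c(-1, 0, 1))
  expect_equal(unname(r["g2", ]), c(0, 0, 0))
  set.seed(5)
  m2 <- matrix(rnorm(60), 12, 5)
  dimnames(m2) <- list(sprintf("g%d", 1:12), sprintf("s%d", 1:5))
  expect_equal(unname(apply(relative_log_expression(m2), 1, median)),
               rep(0, 12))
  expect_error(relative_log_expression(m[, 1, drop = FALSE]), "2 samples")
})

test_that("binomial downsampling has the right moments and contracts", {
  cm <- toy_counts()
  expect_identical(downsample_counts(cm, 1), cm)
  expect_error(downsample_counts(cm, 0), "proportion")
  expect_error(downsample_counts(cm, 1.2), "proportion")

  big <- count_matrix(matrix(1e6, 1, 1, dimnames = list("g", "c")),
                      c(c = "A"))
  thin <- downsample_counts(big, 0.1, seed = 9)
  expect_lt(abs(as.numeric(thin$values) - 1e5), 3 * sqrt(1e6 * 0.1 * 0.9))

  # fixed seed reproduces bit-identically
  set.seed(10)
  m <- matrix(rpois(200, 30), 20, 10,
              dimnames = list(sprintf("g%d", 1:20), sprintf("c%d", 1:10)))
  cm2 <- count_matrix(m)
  expect_identical(downsample_counts(cm2, 0.3, seed = 11)$values,
                   downsample_counts(cm2, 0.3, seed = 11)$values)

  # thinning at p then q matches a single thinning at pq in moments
  reps <- vapply(1:40, function(i) {
    sum(downsample_counts(downsample_counts(cm2, 0.5, seed = 100 + i),
                          0.4, seed = 200 + i)$values)
  }, numeric(1))
  single <- vapply(1:40, function(i)
    sum(downsample_counts(cm2, 0.2, seed = 300 + i)$values), numeric(1))
  tot <- sum(m)
  se <- sqrt(2 * tot * 0.2 * 0.8 / 40)
  expect_lt(abs(mean(reps) - mean(single)), 4 * se)
})

test_that("mixture threshold separates well-separated expression modes", {
  set.seed(6)
  expr <- c(rnorm(500, 0, 1), rnorm(500, 8, 1))
  truth <- rep(c("low", "high"), each = 500)
  sp <- expression_threshold(expr, seed = 1)
  expect_gt(sp$threshold, 2)
  expect_lt(sp$threshold, 6)
  expect_gt(mean(as.character(sp$labels) == truth), 0.95)
  expect_identical(levels(sp$labels), c("low", "high"))
  # labels respect the threshold exactly
  expect_identical(as.character(sp$labels),
                   ifelse(expr >= sp$threshold, "high", "low"))
  # seed-fixed rerun reproduces the threshold
  expect_identical(expression_threshold(expr, seed = 1)$threshold,
                   sp$threshold)
  expect_error(expression_threshold(rep(1, 100)), "degenerate")
  expect_error(expression_threshold(rnorm(10)), "at least 50")
})

test_that("guided-PCA statistic validates its inputs", {
  set.seed(7)
  m <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:6)))
  expect_error(gpca_batch_pvalue(m, rep("A", 6)), ">= 2 batches")
  expect_error(gpca_batch_pvalue(m, c("A", "B"), n_perm = 10), "one batch label")
  expect_error(gpca_batch_pvalue(m, rep(c("A", "B"), 3), n_perm = 0),
               "n_perm")
  res <- gpca_batch_pvalue(m, rep(c("A", "B"), 3), n_perm = 99, seed = 1)
  expect_true(res$delta >= 0 && res$delta <= 1 + 1e-9)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})
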