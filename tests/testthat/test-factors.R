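test_that("TIN equals 100 exp(entropy)/k with its closed-form extremes", {
  # uniform coverage gives 100 for any transcript length
  for (k in c(1, 3, 50)) expect_equal(tin(rep(2.5, k)), 100)
  # point coverage gives 100/k
  cov1 <- c(7, rep(0, 99))
  expect_equal(tin(cov1), 1.0)
  # frozen direct entropy evaluation for coverage (1, 1, 2)
  expect_equal(tin(c(1, 1, 2)), 94.2809041582, tolerance = 1e-9)

  # permutation- and scale-invariance
  set.seed(1)
  cv <- rgamma(30, 2)
  expect_equal(tin(cv), tin(sample(cv)))
  expect_equal(tin(cv), tin(cv * 17.3))

  expect_error(tin(numeric(0)), "empty")
  expect_error(tin(c(0, 0)), "all-zero")
})

test_that("gene TIN is the median over transcripts", {
  expect_equal(gene_tin(80), 80)
  expect_equal(gene_tin(c(10, 90)), 50)
  expect_equal(gene_tin(c(1, 2, 100)), 2)
  expect_error(gene_tin(numeric(0)), "no transcripts")
})

test_that("GC content counts G+C over A/C/G/T with N excluded", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGT"), 50)
  expect_equal(gc_content("ACGTNNNN"), 50)
  expect_error(gc_content("NNN"), "no A/C/G/T")
  expect_error(gc_content(""), "empty")
})

test_that("mappability reflects genome-wide k-mer uniqueness", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
             collapse = "")
  # oracle: verify no canonical 24-mer (or its reverse complement) repeats
  kmers <- vapply(1:(200 - 23), function(i) substr(s, i, i + 23), "")
  rc <- vapply(kmers, function(k)
    paste(rev(strsplit(chartr("ACGT", "TGCA", k), "")[[1]]), collapse = ""),
    "")
  canon <- pmin(kmers, rc)
  expect_false(anyDuplicated(canon) > 0)
  expect_equal(mappability(c(chr = s), "chr", 50, 150, k = 24), 100)

  # exact tandem duplication: nothing inside one copy is unique
  dup <- paste0(substr(s, 1, 100), substr(s, 1, 100))
  expect_equal(mappability(c(chr = dup), "chr", 30, 70, k = 24), 0)

  expect_error(mappability(c(chr = s), "chr", 10, 20, k = 24),
               "k larger than region")
  expect_error(mappability(c(chr = s), "other", 1, 50, k = 24),
               "unknown sequence")
})

test_that("mappability is monotone in k where larger k removes collisions", {
  # two copies of a short core embedded in otherwise-unique flanks collide at
  # small k; windows longer than the copy resolve them
  set.seed(9)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  core <- "ACGTACGTACGT"
  g <- paste0(flank(40), core, flank(40), core, flank(40))
  m_small <- mappability(c(chr = g), "chr", 41, 58, k = 6)
  m_large <- mappability(c(chr = g), "chr", 41, 58, k = 18)
  expect_lte(m_small, m_large)
})

test_that("correlation filter removes redundant factors but keeps the core set", {
  set.seed(11)
  n <- 500
  x <- rnorm(n)
  tab <- data.frame(A = x, B = x + rnorm(n, 0, 0.01), C = rnorm(n))
  res <- correlation_filter(tab, threshold = 0.9, keep = character(0))
  expect_equal(ncol(res$table), 2)
  expect_equal(nrow(res$report), 1)
  expect_true(res$report$dropped %in% c("A", "B"))

  # independent columns survive
  set.seed(12)
  ind <- as.data.frame(matrix(rnorm(2000 * 5), 2000, 5))
  res2 <- correlation_filter(ind, threshold = 0.9, keep = character(0))
  expect_equal(ncol(res2$table), 5)

  # no remaining pair above threshold
  set.seed(13)
  z <- rnorm(n)
  messy <- data.frame(a = z, b = z + rnorm(n, 0, 0.05),
                      c = z + rnorm(n, 0, 0.05), d = rnorm(n))
  res3 <- correlation_filter(messy, threshold = 0.9, keep = character(0))
  cm <- abs(cor(res3$table)); diag(cm) <- 0
  expect_lt(max(cm), 0.9)

  expect_error(correlation_filter(tab, threshold = 1.5), "threshold")
})

test_that("filtering a full annotation table retains the nine model factors", {
  # table shaped like a full annotation pull: dominant-transcript lengths,
  # their per-gene means, percent and count mappability at four k
  set.seed(14)
  n <- 3000
  z_len <- rnorm(n)
  glen <- exp(9 + z_len)
  cds <- glen * runif(n, 0.35, 0.45)            # tracks gene length
  tx_len <- glen * runif(n, 0.8, 0.95)
  utr3 <- exp(6.5 + 0.4 * z_len + rnorm(n, 0, 0.8))
  utr5 <- exp(5 + 0.3 * z_len + rnorm(n, 0, 0.8))
  mean_of <- function(x) x * runif(n, 0.97, 1.03)
  mp <- function() 100 * rbeta(n, 8, 2)
  mapp <- replicate(4, mp())
  tab <- data.frame(
    GCcontent = 50 + 8 * rnorm(n),
    Genelength = glen, No.transcripts = pmax(1, rpois(n, 3)),
    CDSlength = cds, UTR3length = utr3, UTR5length = utr5,
    Translength = tx_len,
    MeanCDSlength = mean_of(cds), MeanUTR3length = mean_of(utr3),
    MeanUTR5length = mean_of(utr5), MeanTranslength = mean_of(tx_len),
    Mapp.k24 = mapp[, 1], Mapp.k36 = mapp[, 2],
    Mapp.k50 = mapp[, 3], Mapp.k100 = mapp[, 4],
    Mapp.k24.count = mapp[, 1] * glen / 100 * runif(n, 0.98, 1.02),
    Mapp.k36.count = mapp[, 2] * glen / 100 * runif(n, 0.98, 1.02),
    Mapp.k50.count = mapp[, 3] * glen / 100 * runif(n, 0.98, 1.02),
    Mapp.k100.count = mapp[, 4] * glen / 100 * runif(n, 0.98, 1.02))
  expect_equal(ncol(tab), 19)
  res <- correlation_filter(tab, threshold = 0.9)
  kept <- sort(colnames(res$table))
  expect_identical(kept, sort(c("GCcontent", "Genelength", "No.transcripts",
                                "UTR3length", "UTR5length", "Mapp.k24",
                                "Mapp.k36", "Mapp.k50", "Mapp.k100")))
  # every dropped factor names its retained partner
  expect_true(all(res$report$retained %in% colnames(tab)))
})

test_that("kNN imputation fills from similar genes and beats the column mean", {
  tab <- data.frame(a = c(1, 1, 1, 5), b = c(2, 2, 2, 9))
  expect_identical(knn_impute(tab), tab)

  tab2 <- tab; tab2$b[2] <- NA
  expect_equal(knn_impute(tab2, k = 2)$b[2], 2)

  # MCAR holdout on correlated factors: kNN RMSE < column-mean RMSE
  set.seed(15)
  n <- 400
  z <- rnorm(n)
  full <- data.frame(f1 = z + rnorm(n, 0, 0.2), f2 = -z + rnorm(n, 0, 0.2),
                     f3 = 2 * z + rnorm(n, 0, 0.2), f4 = rnorm(n))
  holes <- full
  idx <- cbind(sample(n, 20), sample(1:3, 20, replace = TRUE))
  holes[idx] <- NA
  imp <- knn_impute(holes, k = 5)
  rmse_knn <- sqrt(mean((as.matrix(imp)[idx] - as.matrix(full)[idx])^2))
  mu <- colMeans(holes, na.rm = TRUE)
  rmse_mean <- sqrt(mean((mu[idx[, 2]] - as.matrix(full)[idx])^2))
  expect_lt(rmse_knn, rmse_mean)

  bad <- data.frame(a = c(NA, NA), b = c(1, 2))
  expect_error(knn_impute(bad), "missing for all genes")
})

test_that("center_scale standardizes columns and rejects constants", {
  out <- center_scale(data.frame(x = c(1, 2, 3)))
  expect_equal(out$x, c(-1, 0, 1))
  set.seed(16)
  tab <- data.frame(a = rnorm(50, 3, 2), b = runif(50))
  std <- center_scale(tab)
  expect_equal(unname(colMeans(std)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(std, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(center_scale(std), std, tolerance = 1e-12)
  expect_error(center_scale(data.frame(a = rep(2, 5))), "constant factor")
})

test_that("quantile binning is balanced, monotone, and rank-invariant", {
  b <- bin_factors(data.frame(x = 1:10), n_bins = 5)$x
  expect_identical(b, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L))

  set.seed(17)
  x <- rnorm(1000)
  b1 <- bin_factors(data.frame(x = x))$x
  # monotone transform leaves bins unchanged
  expect_identical(bin_factors(data.frame(x = exp(x)))$x, b1)
  # balanced to within one observation for distinct values
  expect_lte(diff(range(table(b1))), 1)
  # monotone in the raw value
  expect_true(all(diff(b1[order(x)]) >= 0))

  expect_warning(bin_factors(data.frame(x = c(1, 1, 1, 2)), n_bins = 3),
                 "fewer distinct values")
  expect_error(bin_factors(data.frame(x = 1:10), n_bins = 1), "n_bins")

  # equal-width option covers the range evenly
  bw <- bin_factors(data.frame(x = c(0, 0.1, 5, 9.9, 10)), n_bins = 2,
                    method = "width")$x
  expect_identical(bw, c(1L, 1L, 2L, 2L, 2L))
})
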