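test_that("the running-sum enrichment score matches hand-traced examples", {
  scores <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  rk <- ranked_list(scores)
  # members {g1, g2} at the top with w = 1: gains 5/9 then 4/9, peak ES = 1
  expect_equal(enrichment_score(rk, c("g1", "g2"))$es, 1.0)
  # members {g1, g3}: running sum 5/8, 5/8 - 1/3, 5/8 - 1/3 + 3/8, ...
  es <- enrichment_score(rk, c("g1", "g3"))
  expect_equal(es$es, 5 / 8 - 1 / 3 + 3 / 8, tolerance = 1e-12)
  expect_equal(es$peak, 3)
  expect_error(enrichment_score(rk, c("x1", "x2")), "disjoint")
})

test_that("ES agrees with the fgsea statistic and obeys its symmetries", {
  set.seed(31)
  scores <- setNames(rnorm(200), sprintf("g%03d", 1:200))
  rk <- ranked_list(scores)
  set_members <- sample(names(scores), 15)
  ours <- enrichment_score(rk, set_members, weight_exponent = 1)$es
  ref <- fgsea::calcGseaStat(rk, selectedStats = which(names(rk) %in%
                                                         set_members),
                             gseaParam = 1)
  expect_equal(ours, ref, tolerance = 1e-9)

  # reversing the ranked list negates ES for every set
  rev_rk <- rev(-rk)
  expect_equal(enrichment_score(rev_rk, set_members)$es, -ours,
               tolerance = 1e-9)

  # with w = 0, ES is invariant under strictly monotone score transforms
  rk0 <- ranked_list(scores)
  es0 <- enrichment_score(rk0, set_members, weight_exponent = 0)$es
  es0b <- enrichment_score(ranked_list(exp(scores)), set_members,
                           weight_exponent = 0)$es
  expect_equal(es0, es0b, tolerance = 1e-12)

  # uniformly interleaved members with w = 0 have small |ES|
  n <- 400
  sc2 <- setNames(seq(n, 1), sprintf("h%03d", 1:n))
  every20 <- names(sc2)[seq(10, n, by = 20)]
  expect_lt(abs(enrichment_score(ranked_list(sc2), every20,
                                 weight_exponent = 0)$es),
            2 / sqrt(length(every20)))
})

test_that("gene-permutation GSEA calibrates nulls and flags planted signal", {
  set.seed(32)
  scores <- setNames(rnorm(500), sprintf("g%03d", 1:500))
  rk <- ranked_list(scores)

  # planted set occupying the top 5% of ranks
  planted <- names(rk)[1:25]
  sets <- c(list(PLANTED = planted),
            lapply(1:10, function(i) sample(names(scores), 25)))
  names(sets)[-1] <- sprintf("RAND%02d", 1:10)
  res <- gsea_permutation(rk, sets, n_perm = 1000, seed = 5)
  expect_equal(res$nes > 0, res$es > 0)
  pl <- res[res$set == "PLANTED", ]
  expect_gt(pl$nes, 0)
  expect_lt(pl$padj, 0.05)
  expect_true(all(res$padj[res$set != "PLANTED"] > pl$padj))

  # seed-fixed rerun reproduces p-values exactly
  res2 <- gsea_permutation(rk, sets, n_perm = 1000, seed = 5)
  expect_identical(res$pval, res2$pval)

  # null calibration: random sets rarely reach adjusted significance
  hits <- 0; total <- 0
  for (rep in 1:5) {
    set.seed(100 + rep)
    sc <- setNames(rnorm(300), sprintf("n%03d", 1:300))
    nulls <- lapply(1:10, function(i) sample(names(sc), 20))
    names(nulls) <- sprintf("S%02d", 1:10)
    r <- gsea_permutation(ranked_list(sc), nulls, n_perm = 200,
                          seed = 200 + rep)
    hits <- hits + sum(r$padj < 0.05); total <- total + nrow(r)
  }
  expect_lte(hits / total, 0.05)

  expect_error(gsea_permutation(rk, sets, n_perm = 50), ">= 100")
})

test_that("direction labels combine NES sign with BH significance", {
  df <- data.frame(set = c("a", "b", "c"), size = 20,
                   es = c(0.5, -0.4, 0.6), nes = c(2.1, -1.8, 2.5),
                   pval = c(0.001, 0.03, 0.15),
                   padj = c(0.001, 0.04, 0.2))
  out <- classify_direction(df)
  expect_identical(out$direction, c("over", "under", "ns"))
})

test_that("BH adjustment agrees with a brute-force implementation", {
  brute_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- numeric(n)
    run <- Inf
    for (i in n:1) {
      run <- min(run, p[o[i]] * n / i)
      adj[o[i]] <- min(run, 1)
    }
    adj
  }
  set.seed(33)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))^2
    expect_equal(p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("cross-dataset pathway intersections track shared directions", {
  mk <- function(dirs) data.frame(set = names(dirs), size = 20,
                                  direction = unname(dirs),
                                  stringsAsFactors = FALSE)
  a <- mk(c(P1 = "over", P2 = "under", P3 = "ns"))
  b <- mk(c(P1 = "over", P2 = "under", P3 = "under"))
  out <- cross_dataset_pathways(list(A = a, B = b))
  expect_identical(out$shared$over, "P1")
  expect_identical(out$shared$under, "P2")
  expect_identical(dim(out$membership), c(3L, 2L))

  # disjoint significant sets intersect to nothing
  c2 <- mk(c(P1 = "ns", P2 = "ns", P3 = "over"))
  out2 <- cross_dataset_pathways(list(A = a, B = c2))
  expect_length(out2$shared$over, 0)
  expect_error(cross_dataset_pathways(list(A = a)), ">= 2 datasets")
})

test_that("rank-biserial correlation equals 1 - 2U/(n1 n2) exactly", {
  # complete separation gives |r| = 1
  expect_equal(rank_biserial(c(5, 6, 7), c(1, 2))$r, -1)
  expect_equal(rank_biserial(c(1, 2), c(5, 6, 7))$r, 1)

  # brute force over every rank configuration for group sizes 2..6
  for (k in 2:6) {
    all_ranks <- seq_len(2 * k)
    combos <- combn(2 * k, k)
    for (j in seq_len(ncol(combos))) {
      x <- all_ranks[combos[, j]]
      y <- all_ranks[-combos[, j]]
      U_brute <- sum(outer(x, y, ">"))
      res <- rank_biserial(x, y)
      expect_equal(res$U, U_brute)
      expect_equal(res$r, 1 - 2 * U_brute / (k * k))
    }
  }
})

test_that("pathway-factor association detects shifted member distributions", {
  set.seed(34)
  genes <- sprintf("g%04d", 1:1000)
  ft <- data.frame(TIN = rnorm(1000), GC = rnorm(1000), row.names = genes)
  members <- sample(genes, 50)
  ft[members, "TIN"] <- ft[members, "TIN"] + 2
  res <- pathway_factor_association(list(SET = members), ft)
  tin_row <- res[res$factor == "TIN", ]
  gc_row <- res[res$factor == "GC", ]
  expect_lt(tin_row$pval, 0.001)
  expect_lt(tin_row$r, 0)    # members larger => U large => r negative
  expect_gt(gc_row$pval, 0.01)
  expect_lt(abs(gc_row$r), 0.25)
  expect_error(pathway_factor_association(list(SET = members),
                                          data.frame(K = rep(1, 1000),
                                                     row.names = genes)),
               "constant factor")
})
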