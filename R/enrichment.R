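#' Order a named score vector into a ranked gene list
#'
#' Sorts decreasing by score; ties are broken by gene id so the ranking is
#' deterministic.
#' @param scores named numeric vector (e.g. raw dropout-curve residuals)
#' @return the reordered named vector
#' @export
ranked_list <- function(scores) {
  if (is.null(names(scores))) stop("scores must be named by gene id")
  if (anyDuplicated(names(scores))) stop("duplicate gene ids")
  scores[order(-scores, names(scores))]
}

#' Weighted running-sum enrichment score of one gene set
#'
#' Classic preranked GSEA statistic: walking down the ranked list, the running
#' sum gains `|score|^w / sum(|member scores|^w)` at set members and loses
#' `1 / (N - n)` elsewhere; ES is the signed maximum deviation from zero.
#'
#' @param ranked a [ranked_list()] (named numeric, sorted)
#' @param set character vector of member gene ids
#' @param weight_exponent `w` (default 1; 0 gives the unweighted KS form)
#' @return list with `es` and `peak` (index of the extremum)
#' @export
enrichment_score <- function(ranked, set, weight_exponent = 1) {
  hit <- names(ranked) %in% set
  n <- sum(hit); N <- length(ranked)
  if (n == 0L) stop("set is disjoint from the ranked universe")
  if (n >= N) stop("set covers the whole universe")
  w <- abs(ranked)^weight_exponent
  inc <- numeric(N)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (N - n)
  rs <- cumsum(inc)
  peak <- which.max(abs(rs))
  list(es = rs[peak], peak = peak)
}

null_es <- function(stat_w, n, N, n_perm) {
  # null ES for a set of size n: random positions in the ranked list
  vapply(seq_len(n_perm), function(i) {
    pos <- sample.int(N, n)
    hit <- logical(N); hit[pos] <- TRUE
    inc <- numeric(N)
    inc[hit] <- stat_w[hit] / sum(stat_w[hit])
    inc[!hit] <- -1 / (N - n)
    rs <- cumsum(inc)
    rs[which.max(abs(rs))]
  }, numeric(1L))
}

#' Gene-permutation GSEA over a collection of sets
#'
#' Per set, a null ES distribution is built from `n_perm` random same-size
#' gene draws from the ranked universe. NES divides ES by the mean of the
#' sign-matched null ES values; the nominal p is the sign-matched tail
#' frequency with +1 smoothing, adjusted across sets by Benjamini-Hochberg.
#'
#' @param ranked a [ranked_list()]
#' @param sets named list of member-id vectors (sets disjoint from the
#'   universe are dropped with a warning)
#' @param n_perm permutations (>= 100; default 1000)
#' @param seed RNG seed
#' @param weight_exponent GSEA weight (default 1)
#' @return data.frame: `set`, `size`, `es`, `nes`, `pval`, `padj`
#' @export
gsea_permutation <- function(ranked, sets, n_perm = 1000L, seed = 1L,
                             weight_exponent = 1) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  N <- length(ranked)
  sizes <- vapply(sets, function(s) sum(names(ranked) %in% s), 1L)
  if (any(sizes == 0L)) {
    warning("dropping sets disjoint from the universe: ",
            paste(names(sets)[sizes == 0L], collapse = ", "))
    sets <- sets[sizes > 0L]; sizes <- sizes[sizes > 0L]
  }
  if (any(sizes >= N)) stop("a set covers the whole ranked universe")
  es <- vapply(sets, function(s)
    enrichment_score(ranked, s, weight_exponent)$es, numeric(1L))

  stat_w <- abs(ranked)^weight_exponent
  set.seed(seed)
  nulls_by_size <- lapply(unique(sizes), function(n)
    null_es(stat_w, n, N, n_perm))
  names(nulls_by_size) <- as.character(unique(sizes))

  nes <- pval <- numeric(length(sets))
  for (i in seq_along(sets)) {
    null <- nulls_by_size[[as.character(sizes[i])]]
    same <- if (es[i] >= 0) null[null >= 0] else -null[null < 0]
    if (!length(same)) same <- abs(null)
    nes[i] <- sign(es[i]) * abs(es[i]) / mean(same)
    pval[i] <- (1 + sum(same >= abs(es[i]))) / (1 + length(same))
  }
  data.frame(set = names(sets), size = sizes, es = es, nes = nes,
             pval = pval, padj = stats::p.adjust(pval, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify enrichment direction at an FDR cutoff
#'
#' `"over"` when BH-adjusted p < `alpha` and NES > 0 (members carry positive
#' residuals: over-expressed in bulk relative to single-cell), `"under"` for
#' NES < 0, otherwise `"ns"`.
#'
#' @param results a [gsea_permutation()] data.frame
#' @param alpha FDR threshold (default 0.05)
#' @return the data.frame with a `direction` column
#' @export
classify_direction <- function(results, alpha = 0.05) {
  results$direction <- ifelse(
    results$padj < alpha & results$nes > 0, "over",
    ifelse(results$padj < alpha & results$nes < 0, "under", "ns"))
  results
}

#' Intersect significant pathway directions across datasets
#'
#' @param labels_by_dataset named list of [classify_direction()] data.frames
#' @return list with `shared` (over/under set-name vectors common to all
#'   datasets), `membership` (set x dataset direction matrix for Venn-style
#'   reporting) and `counts`
#' @export
cross_dataset_pathways <- function(labels_by_dataset) {
  if (length(labels_by_dataset) < 2L) stop("need >= 2 datasets")
  pick <- function(df, dir) df$set[df$direction == dir]
  shared <- list(
    over = Reduce(intersect, lapply(labels_by_dataset, pick, "over")),
    under = Reduce(intersect, lapply(labels_by_dataset, pick, "under")))
  all_sets <- sort(unique(unlist(lapply(labels_by_dataset, `[[`, "set"))))
  membership <- vapply(labels_by_dataset, function(df)
    df$direction[match(all_sets, df$set)], character(length(all_sets)))
  membership <- matrix(membership, nrow = length(all_sets),
                       dimnames = list(all_sets, names(labels_by_dataset)))
  counts <- data.frame(
    dataset = names(labels_by_dataset),
    n_over = vapply(labels_by_dataset, function(d) sum(d$direction == "over"), 1L),
    n_under = vapply(labels_by_dataset, function(d) sum(d$direction == "under"), 1L),
    stringsAsFactors = FALSE)
  list(shared = shared, membership = membership, counts = counts)
}

#' Rank-biserial correlation from a Mann-Whitney U
#'
#' `r = 1 - 2 U / (n1 n2)` where `U` counts pairs with the first group's
#' value larger (ties count one half). `|r| = 1` under complete separation.
#'
#' @param x,y numeric samples for the two groups
#' @return list with `U`, `r`, `n1`, `n2`
#' @export
rank_biserial <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both groups must be non-empty")
  r_all <- rank(c(x, y))
  U <- sum(r_all[seq_len(n1)]) - n1 * (n1 + 1) / 2
  list(U = U, r = 1 - 2 * U / (n1 * n2), n1 = n1, n2 = n2)
}

#' Test whether pathway members differ in a technical factor
#'
#' For each (set, factor) pair, a two-sided Mann-Whitney test of member vs
#' non-member factor values with the rank-biserial correlation as effect size,
#' BH-adjusted across all pairs.
#'
#' @param sets named list of member-id vectors
#' @param factor_table gene x factor data.frame/matrix with gene rownames
#' @return data.frame: `set`, `factor`, `U`, `r`, `pval`, `padj`
#' @export
pathway_factor_association <- function(sets, factor_table) {
  ft <- as.matrix(factor_table)
  genes <- rownames(ft)
  rows <- list()
  for (s in names(sets)) {
    members <- genes %in% sets[[s]]
    if (!any(members) || all(members)) next
    for (f in colnames(ft)) {
      x <- ft[members, f]; y <- ft[!members, f]
      if (stats::sd(c(x, y)) == 0) stop("constant factor: ", f)
      rb <- rank_biserial(x, y)
      p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
      rows[[length(rows) + 1L]] <-
        data.frame(set = s, factor = f, U = rb$U, r = rb$r, pval = p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pval, method = "BH")
  out
}
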