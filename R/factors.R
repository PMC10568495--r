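#' The retained technical-factor names
#'
#' The covariates of the dropout-rate regression: bulk expression, transcript
#' integrity (TIN), gene length, number of transcripts, UTR3' length,
#' mappability at k = 24/36/50/100, UTR5' length, and GC content.
#' @export
EQ_FACTORS <- c("Expression", "TIN", "Genelength", "No.transcripts",
                "UTR3length", "Mapp.k24", "Mapp.k36", "Mapp.k50",
                "Mapp.k100", "UTR5length", "GCcontent")

#' Transcript integrity number from a coverage vector
#'
#' Measures coverage uniformity along a transcript by Shannon entropy: with
#' `p_i = cov_i / sum(cov)` and `H = -sum(p_i log p_i)` (natural log, zero
#' terms dropped), TIN = `100 * exp(H) / k` for a transcript of `k` positions.
#' Uniform coverage gives 100; coverage concentrated on a single position
#' gives `100 / k`.
#'
#' @param coverage non-negative numeric vector over transcript positions
#' @return TIN in \[0, 100\]
#' @export
tin <- function(coverage) {
  if (!length(coverage)) stop("empty coverage vector")
  if (any(coverage < 0)) stop("negative coverage")
  tot <- sum(coverage)
  if (tot == 0) stop("all-zero coverage")
  p <- coverage[coverage > 0] / tot
  h <- -sum(p * log(p))
  100 * exp(h) / length(coverage)
}

#' Gene-level TIN as the median over its transcripts
#' @param transcript_tins numeric vector of per-transcript TINs
#' @return median TIN
#' @export
gene_tin <- function(transcript_tins) {
  if (!length(transcript_tins)) stop("gene has no transcripts")
  stats::median(transcript_tins)
}

#' GC content of a sequence, in percent
#'
#' `100 * (G + C) / (A + C + G + T)`; N bases are excluded from the
#' denominator.
#' @param sequence A/C/G/T/N string
#' @return percent GC
#' @export
gc_content <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  acgt <- sum(chars %in% c("A", "C", "G", "T"))
  if (acgt == 0) stop("sequence contains no A/C/G/T bases")
  100 * sum(chars %in% c("G", "C")) / acgt
}

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

#' Region mappability from unique k-mers
#'
#' Enumerates every k-mer of the genome (forward strand and reverse complement
#' counted as one key by default); a position of the region is covered if at
#' least one k-mer window containing it occurs exactly once genome-wide.
#' Returns the covered fraction of the region, in percent. Intended for
#' desk-scale sequences; complexity is linear in genome length.
#'
#' @param genome named character vector of sequences
#' @param seq_name sequence holding the region
#' @param start,end 1-based inclusive region coordinates
#' @param k k-mer length (must not exceed the region length)
#' @param canonical count a k-mer and its reverse complement as one key
#'   (default TRUE)
#' @return percent of region positions covered by a unique k-mer
#' @export
mappability <- function(genome, seq_name, start, end, k, canonical = TRUE) {
  if (!seq_name %in% names(genome)) stop("unknown sequence: ", seq_name)
  s <- toupper(genome[[seq_name]])
  len <- end - start + 1L
  if (len < k) stop("k larger than region")
  if (start < 1L || end > nchar(s)) stop("region outside sequence")

  kmer_counts <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(key) {
    assign(key, (if (exists(key, envir = kmer_counts, inherits = FALSE))
      get(key, envir = kmer_counts) else 0L) + 1L, envir = kmer_counts)
  }
  for (sq in toupper(genome)) {
    n <- nchar(sq)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      km <- substr(sq, i, i + k - 1L)
      if (canonical) km <- min(km, revcomp(km))
      add(km)
    }
  }
  n_s <- nchar(s)
  window_unique <- function(w) {   # window starting at w
    km <- substr(s, w, w + k - 1L)
    if (canonical) km <- min(km, revcomp(km))
    get(km, envir = kmer_counts) == 1L
  }
  covered <- logical(len)
  for (pos in start:end) {
    ws <- max(1L, pos - k + 1L):min(pos, n_s - k + 1L)
    for (w in ws) {
      if (window_unique(w)) { covered[pos - start + 1L] <- TRUE; break }
    }
  }
  100 * sum(covered) / len
}

#' Remove highly correlated technical factors
#'
#' Computes both Pearson and Spearman correlations between factors (pairwise
#' complete observations) and iteratively drops, from each offending pair with
#' `max(|Pearson|, |Spearman|) >= threshold`, the factor with the larger mean
#' absolute correlation to everything else. Factors on the keep-list are never
#' dropped.
#'
#' @param table gene x factor data.frame or matrix
#' @param threshold correlation cutoff in (0, 1\] (default 0.9)
#' @param keep factor names that must survive (default [EQ_FACTORS])
#' @return list with `table` (filtered) and `report` (data.frame: dropped
#'   factor, retained partner, the correlation that removed it)
#' @export
correlation_filter <- function(table, threshold = 0.9, keep = EQ_FACTORS) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  m <- as.matrix(table)
  if (ncol(m) < 2L) stop("need >= 2 factors")
  dropped <- character(0); partner <- character(0); corr <- numeric(0)
  repeat {
    cp <- abs(stats::cor(m, use = "pairwise.complete.obs", method = "pearson"))
    cs <- abs(stats::cor(m, use = "pairwise.complete.obs", method = "spearman"))
    cm <- pmax(cp, cs, na.rm = TRUE)
    diag(cm) <- 0
    cm[is.na(cm)] <- 0
    # offending pairs where at least one member is droppable
    idx <- which(cm >= threshold, arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    if (!nrow(idx)) break
    droppable <- !(colnames(m) %in% keep)
    cand <- NULL
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1L]; j <- idx[r, 2L]
      if (!droppable[i] && !droppable[j]) next
      cand <- rbind(cand, c(i, j))
    }
    if (is.null(cand)) break
    mean_abs <- colMeans(cm)
    # pick the droppable factor with largest mean absolute correlation
    members <- unique(as.vector(cand))
    members <- members[droppable[members]]
    victim <- members[which.max(mean_abs[members])]
    row <- cand[which(cand[, 1L] == victim | cand[, 2L] == victim)[1L], ]
    mate <- setdiff(row, victim)
    dropped <- c(dropped, colnames(m)[victim])
    partner <- c(partner, colnames(m)[mate])
    corr <- c(corr, cm[victim, mate])
    m <- m[, -victim, drop = FALSE]
    if (ncol(m) < 2L) break
  }
  out <- table[, colnames(m), drop = FALSE]
  list(table = out,
       report = data.frame(dropped = dropped, retained = partner,
                           correlation = corr, stringsAsFactors = FALSE))
}

#' k-nearest-neighbour imputation of missing factor values
#'
#' Each missing entry is replaced by the mean of that factor over the `k`
#' nearest genes in standardized observed-factor space (Euclidean distance on
#' the factors observed in both genes, normalized by their number).
#'
#' @param table gene x factor data.frame or matrix with NAs
#' @param k neighbours (default 5)
#' @return table of the same shape with NAs filled in
#' @export
knn_impute <- function(table, k = 5L) {
  m <- as.matrix(table)
  if (any(colSums(!is.na(m)) == 0L)) stop("a factor is missing for all genes")
  if (any(rowSums(!is.na(m)) == 0L)) stop("a gene has no observed factor")
  if (!anyNA(m)) return(table)
  mu <- colMeans(m, na.rm = TRUE)
  sdv <- apply(m, 2L, stats::sd, na.rm = TRUE)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  z <- sweep(sweep(m, 2L, mu), 2L, sdv, "/")
  filled <- m
  need <- which(is.na(m), arr.ind = TRUE)
  for (r in unique(need[, 1L])) {
    miss_cols <- need[need[, 1L] == r, 2L]
    obs_cols <- which(!is.na(m[r, ]))
    zr <- z[r, obs_cols]
    for (cc in miss_cols) {
      donors <- which(!is.na(m[, cc]))
      donors <- setdiff(donors, r)
      zz <- z[donors, obs_cols, drop = FALSE]
      d2 <- rowMeans((sweep(zz, 2L, zr))^2, na.rm = TRUE)
      nn <- donors[order(d2)[seq_len(min(k, length(donors)))]]
      filled[r, cc] <- mean(m[nn, cc])
    }
  }
  if (is.data.frame(table)) as.data.frame(filled) else filled
}

#' Center and scale each factor to mean 0, sd 1
#' @param table gene x factor data.frame or matrix (no constant columns)
#' @return standardized table of the same shape
#' @export
center_scale <- function(table) {
  m <- as.matrix(table)
  sdv <- apply(m, 2L, stats::sd)
  if (any(sdv == 0)) stop("constant factor: ",
                          paste(colnames(m)[sdv == 0], collapse = ", "))
  out <- scale(m)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  if (is.data.frame(table)) as.data.frame(out) else out
}

#' Bin each factor into quantile (equal-frequency) bins
#'
#' Bin of a value is `floor((rank - 1) * n_bins / n) + 1` with minimum-rank
#' ties, so bins are monotone in the raw value, invariant to monotone
#' transforms, and balanced to within one gene for distinct-valued input.
#' Equal-width bins over the observed range are available via `method`.
#'
#' @param table gene x factor data.frame or matrix
#' @param n_bins number of bins (default 5)
#' @param method `"quantile"` (default) or `"width"`
#' @return integer-binned table of the same shape
#' @export
bin_factors <- function(table, n_bins = 5L, method = c("quantile", "width")) {
  method <- match.arg(method)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  m <- as.matrix(table)
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (length(unique(x)) < n_bins)
      warning("factor ", colnames(m)[j],
              " has fewer distinct values than bins; bins collapse")
    if (method == "quantile") {
      r <- rank(x, ties.method = "min")
      out[, j] <- floor((r - 1) * n_bins / length(x)) + 1
    } else {
      br <- seq(min(x), max(x), length.out = n_bins + 1L)
      out[, j] <- findInterval(x, br, rightmost.closed = TRUE,
                               all.inside = TRUE)
    }
  }
  storage.mode(out) <- "integer"
  if (is.data.frame(table)) as.data.frame(out) else out
}
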