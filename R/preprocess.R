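#' Aggregate single-cell counts to pseudo-bulk
#'
#' Sums counts over all cells of each sample, producing a gene x sample count
#' matrix. Total count mass per sample is conserved exactly.
#'
#' @param sc a `count_matrix` of cell-level counts with `sample_of_column` set
#' @return a `count_matrix` with one column per sample
#' @export
pseudo_bulk <- function(sc) {
  samples <- samples_of(sc)
  if (any(!samples %in% sc$sample_of_column))
    stop("sample with zero cells")
  v <- sc$values
  out <- vapply(samples, function(s) {
    cols <- which(sc$sample_of_column == s)
    as.numeric(Matrix::rowSums(v[, cols, drop = FALSE]))
  }, numeric(nrow(v)))
  out <- matrix(out, nrow = nrow(v),
                dimnames = list(sc$gene_ids, samples))
  count_matrix(out)
}

#' Log2 counts-per-million with a library-size-adjusted prior count
#'
#' Computes `log2((count + p_j) / (L_j + 2 p_j) * 1e6)` where `L_j` is the
#' column library size and `p_j = prior_count * L_j / mean(L)` — the standard
#' prior-adjusted log-CPM (identical algebra to edgeR's log-CPM). The
#' `"log1p"` dialect instead returns `log2(CPM + 1)`.
#'
#' @param counts a `count_matrix` or numeric matrix (genes x columns)
#' @param prior_count prior count before log (default 2)
#' @param dialect `"prior"` (default) or `"log1p"`
#' @return list of class `expression_profile` with `values` (log2-CPM matrix)
#'   and `library_sizes`
#' @export
log2_cpm <- function(counts, prior_count = 2, dialect = c("prior", "log1p")) {
  dialect <- match.arg(dialect)
  m <- if (inherits(counts, "count_matrix")) as.matrix(counts$values) else as.matrix(counts)
  lib <- colSums(m)
  if (any(lib <= 0)) stop("all-zero column: library size must be positive")
  if (dialect == "prior") {
    adj <- prior_count * lib / mean(lib)
    vals <- log2(t((t(m) + adj) / (lib + 2 * adj)) * 1e6)
  } else {
    vals <- log2(t(t(m) / lib) * 1e6 + 1)
  }
  structure(list(values = vals, library_sizes = lib),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("expression_profile: %d genes x %d samples (log2-CPM)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Per-gene dropout rates in one sample
#'
#' Dropout rate of a gene is the proportion of cells of the sample with zero
#' counts for that gene.
#'
#' @param sc a `count_matrix` of cell-level counts
#' @param sample sample label
#' @return named numeric vector in \[0, 1\] with attribute `n_cells`
#' @export
dropout_rates <- function(sc, sample) {
  cols <- which(sc$sample_of_column == sample)
  if (!length(cols)) stop("unknown sample: ", sample)
  sub <- sc$values[, cols, drop = FALSE]
  nz <- if (inherits(sub, "Matrix")) Matrix::rowSums(sub > 0) else rowSums(sub > 0)
  rate <- 1 - as.numeric(nz) / length(cols)
  structure(stats::setNames(rate, sc$gene_ids), n_cells = length(cols))
}

#' Count dropout genes for one sample
#'
#' Dropout genes are detected in bulk (count > 0) but absent from the
#' pseudo-bulk (count = 0). Genes with zero counts on both platforms are
#' excluded from the denominator used for percentages.
#'
#' @param bulk bulk `count_matrix` (genes x samples)
#' @param pseudo pseudo-bulk `count_matrix` on the same gene universe
#' @param sample sample label (column in both)
#' @return list with `n_dropout`, `denominator`, `pct`
#' @export
dropout_gene_count <- function(bulk, pseudo, sample) {
  if (!identical(bulk$gene_ids, pseudo$gene_ids))
    stop("bulk and pseudo-bulk must share an aligned gene universe")
  b <- as.numeric(bulk$values[, sample])
  p <- as.numeric(pseudo$values[, sample])
  n_drop <- sum(b > 0 & p == 0)
  denom <- sum(b > 0 | p > 0)
  list(n_dropout = n_drop, denominator = denom,
       pct = if (denom > 0) 100 * n_drop / denom else NA_real_)
}

#' Relative log expression
#'
#' Per gene, the deviation of each sample's log-expression from the across-
#' sample median; a normalization diagnostic (per-gene medians of the output
#' are zero by construction).
#'
#' @param profile an `expression_profile` or numeric matrix (genes x samples)
#' @return numeric matrix of the same shape
#' @export
relative_log_expression <- function(profile) {
  m <- if (inherits(profile, "expression_profile")) profile$values else as.matrix(profile)
  if (ncol(m) < 2L) stop("RLE needs at least 2 samples")
  med <- apply(m, 1L, stats::median)
  m - med
}

#' Downsample a count matrix by binomial thinning
#'
#' Each count is replaced by a Binomial(count, proportion) draw, emulating a
#' reduction of sequencing depth at the matrix level; expected library size is
#' `proportion` times the original.
#'
#' @param sc a `count_matrix`
#' @param proportion thinning probability in (0, 1\]
#' @param seed RNG seed
#' @return a `count_matrix` of the same shape
#' @export
downsample_counts <- function(sc, proportion, seed = 1L) {
  if (proportion <= 0 || proportion > 1)
    stop("proportion must be in (0, 1]")
  if (proportion == 1) return(sc)
  set.seed(seed)
  v <- sc$values
  if (inherits(v, "CsparseMatrix")) {
    v@x <- as.double(stats::rbinom(length(v@x), size = as.integer(v@x),
                                   prob = proportion))
    v <- Matrix::drop0(v)
  } else {
    v[] <- stats::rbinom(length(v), size = as.integer(v), prob = proportion)
  }
  count_matrix(v, sc$sample_of_column)
}

#' Split genes into low- and high-expression groups with a Gaussian mixture
#'
#' Fits a univariate Gaussian mixture (unequal variances, components selected
#' by BIC over `n_components`) to a bulk log2-CPM vector and places the
#' threshold at the density crossing between the lowest-mean component and its
#' right neighbour. Genes at or above the threshold are labelled `"high"`.
#'
#' @param expr numeric vector of bulk log2-CPM values (>= 50 genes)
#' @param n_components candidate component counts (default 2:5)
#' @param seed RNG seed for the EM initialisation
#' @return list of class `expression_split` with `threshold`, `labels`
#'   (factor low/high), `n_components`, `mixture` (means, sds, weights)
#' @export
expression_threshold <- function(expr, n_components = 2:5, seed = 1L) {
  if (length(expr) < 50L) stop("need at least 50 genes")
  if (stats::sd(expr) == 0) stop("degenerate constant input")
  set.seed(seed)
  fit <- mclust::Mclust(expr, G = n_components, modelNames = "V",
                        verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  mu <- fit$parameters$mean
  sdv <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sdv) == 1L) sdv <- rep(sdv, length(mu))
  w <- fit$parameters$pro
  ord <- order(mu)
  lo <- ord[1L]; hi <- ord[2L]
  # crossing of the two weighted component densities between their means
  dfun <- function(x) w[lo] * stats::dnorm(x, mu[lo], sdv[lo]) -
    w[hi] * stats::dnorm(x, mu[hi], sdv[hi])
  thr <- tryCatch(
    stats::uniroot(dfun, lower = mu[lo], upper = mu[hi])$root,
    error = function(e) {
      grid <- seq(mu[lo], mu[hi], length.out = 512L)
      grid[which.min(abs(dfun(grid)))]
    })
  labels <- factor(ifelse(expr >= thr, "high", "low"),
                   levels = c("low", "high"))
  structure(list(threshold = thr, labels = labels, n_components = fit$G,
                 mixture = list(mean = mu, sd = sdv, weight = w)),
            class = "expression_split")
}

#' Guided-PCA batch-effect statistic and permutation p-value
#'
#' The delta statistic is the variance explained by the first guided principal
#' component (the data projected through per-batch mean profiles) divided by
#' the variance explained by the first unguided principal component. Its
#' p-value is the one-sided permutation tail probability under shuffled batch
#' labels (with +1 smoothing).
#'
#' @param profile an `expression_profile` or numeric matrix (genes x samples)
#' @param batch vector of batch labels, one per sample (>= 2 batches)
#' @param n_perm number of label permutations (default 999)
#' @param seed RNG seed
#' @return list with `delta`, `p_value`, `n_perm`
#' @export
gpca_batch_pvalue <- function(profile, batch, n_perm = 999L, seed = 1L) {
  m <- if (inherits(profile, "expression_profile")) profile$values else as.matrix(profile)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  batch <- as.factor(batch)
  if (length(batch) != ncol(m)) stop("one batch label per sample required")
  if (nlevels(batch) < 2L) stop("need >= 2 batches")
  if (any(table(batch) == 0L)) stop("batch with zero samples")
  if (ncol(m) < 3L) stop("need >= 3 samples")
  X <- t(m)                       # samples x genes
  X <- scale(X, center = TRUE, scale = FALSE)

  guided_var <- function(X, batch) {
    Y <- stats::model.matrix(~ batch - 1)
    YX <- crossprod(Y, X)         # batches x genes
    sv <- svd(YX, nu = 0L, nv = 1L)
    drop(crossprod(X %*% sv$v))   # variance along first guided axis
  }
  sv1 <- svd(X, nu = 0L, nv = 1L)
  denom <- drop(crossprod(X %*% sv1$v))
  delta <- guided_var(X, batch) / denom

  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    d_i <- guided_var(X, sample(batch)) / denom
    if (d_i >= delta) exceed <- exceed + 1L
  }
  list(delta = delta, p_value = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}
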