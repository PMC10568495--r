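#' Five-parameter logistic dropout curve
#'
#' `f(x) = c + (d - c) / (1 + exp(b (log x - e)))^f`: `c`/`d` are the lower
#' and upper asymptotes (fixed at 0 and 1 for dropout), `e` the log-expression
#' value halfway between them (for `f = 1`), `b` the slope at the inflection
#' and `f > 0` the asymmetry (`f = 1` recovers the symmetric 4PL).
#' [fivepl_logx()] takes the log-expression value directly, which is how the
#' fit parameterizes the curve (the log-expression scale is the bulk log-CPM,
#' so "log x" is that value up to a constant absorbed by `b` and `e`).
#'
#' @param x normalized expression (linear scale, > 0)
#' @param logx log-expression value (e.g. bulk log2-CPM)
#' @param b slope at the inflection point
#' @param e half-way location on the log-expression scale
#' @param f asymmetry parameter (> 0)
#' @param c,d lower and upper asymptotes (defaults 0 and 1)
#' @return predicted dropout in \[c, d\]
#' @export
fivepl_logx <- function(logx, b, e, f, c = 0, d = 1) {
  if (f <= 0) stop("asymmetry parameter f must be > 0")
  z <- b * (logx - e)
  z <- pmin(z, 700 / max(f, 1))        # overflow guard
  c + (d - c) / (1 + exp(z))^f
}

#' @rdname fivepl_logx
#' @export
fivepl <- function(x, b, e, f, c = 0, d = 1) {
  fivepl_logx(log(x), b, e, f, c = c, d = d)
}

#' Kolmogorov-Smirnov distance of residuals from normality
#'
#' One-sample KS D of the residuals against a normal reference, the fit
#' objective of the dropout curve. By default the reference is a zero-mean
#' normal with sd estimated from the residuals: residuals of a well-fit curve
#' are zero-mean, and estimating the mean too (Lilliefors-style,
#' `center = "estimate"`) makes the objective blind to a systematic offset of
#' the curve, leaving its location parameter unidentified.
#'
#' @param res numeric residual vector
#' @param center `"zero"` (default) or `"estimate"`
#' @return D in \[0, 1\]
#' @export
ks_residual_stat <- function(res, center = c("zero", "estimate")) {
  center <- match.arg(center)
  n <- length(res)
  mu <- if (center == "zero") 0 else mean(res)
  s <- if (center == "zero") sqrt(mean(res^2)) else stats::sd(res)
  if (!is.finite(s) || s == 0) return(1)
  z <- sort((res - mu) / s)
  p <- stats::pnorm(z)
  i <- seq_len(n)
  max(i / n - p, p - (i - 1) / n)
}

#' Fit the five-parameter logistic dropout curve by KS minimization
#'
#' Searches (b, e, f) with c = 0 and d = 1 fixed for the parameters that
#' minimize the KS D statistic of the model residuals, computed on the genes
#' with dropout strictly inside (0, 1). The search is a coarse grid pre-scan
#' whose best cells seed multi-start bounded Nelder-Mead refinements (box
#' constraints enforced by a logistic reparameterization); `e` is bounded to
#' the observed log-expression range.
#'
#' @param log_expr per-gene bulk log-expression (log2-CPM scale)
#' @param dropout per-gene dropout rate in \[0, 1\]
#' @param bounds optional list with `b`, `e`, `f` two-element ranges
#' @param n_starts random extra starts beyond the grid seeds (default 16)
#' @param grid_n per-axis size of the pre-scan grid (default 14)
#' @param ks_center reference centering passed to [ks_residual_stat()]
#' @param seed RNG seed
#' @return list of class `fivepl_fit`: `b`, `c`, `d`, `e`, `f`, `D`,
#'   `n_used`, `bounds`, `seed`
#' @export
fit_fivepl_ks <- function(log_expr, dropout, bounds = NULL, n_starts = 16L,
                          grid_n = 14L, ks_center = c("zero", "estimate"),
                          seed = 1L) {
  ks_center <- match.arg(ks_center)
  usable <- which(dropout > 0 & dropout < 1)
  if (length(usable) < 50L)
    stop("need >= 50 genes with dropout strictly in (0, 1)")
  t_u <- log_expr[usable]
  y_u <- dropout[usable]
  if (is.null(bounds))
    bounds <- list(b = c(0.05, 20), e = range(t_u), f = c(0.1, 10))

  obj <- function(p) {   # p = (b, e, f) on natural scale
    ks_residual_stat(y_u - fivepl_logx(t_u, p[1L], p[2L], p[3L]),
                     center = ks_center)
  }
  lb <- c(bounds$b[1L], bounds$e[1L], bounds$f[1L])
  ub <- c(bounds$b[2L], bounds$e[2L], bounds$f[2L])

  # grid pre-scan (b and f on log scale, e linear)
  gb <- exp(seq(log(lb[1L]), log(ub[1L]), length.out = grid_n))
  ge <- seq(lb[2L], ub[2L], length.out = grid_n)
  gf <- exp(seq(log(lb[3L]), log(ub[3L]), length.out = grid_n))
  grid <- as.matrix(expand.grid(b = gb, e = ge, f = gf))
  gvals <- apply(grid, 1L, obj)
  # seeds: global best cells plus the best cell of every f-slice, so starts
  # cover shape-diverse basins of the (b, e, f) ridge
  top <- grid[order(gvals)[1:6], , drop = FALSE]
  slice_best <- t(vapply(seq_along(gf), function(k) {
    sel <- grid[, 3L] == gf[k]
    grid[sel, , drop = FALSE][which.min(gvals[sel]), ]
  }, numeric(3L)))
  set.seed(seed)
  rand <- cbind(exp(stats::runif(n_starts, log(lb[1L]), log(ub[1L]))),
                stats::runif(n_starts, lb[2L], ub[2L]),
                exp(stats::runif(n_starts, log(lb[3L]), log(ub[3L]))))
  starts <- rbind(top, slice_best, rand)

  to_theta <- function(p) stats::qlogis(pmin(pmax((p - lb) / (ub - lb),
                                                  1e-6), 1 - 1e-6))
  from_theta <- function(th) lb + (ub - lb) * stats::plogis(th)
  cand_val <- numeric(nrow(starts))
  cand_par <- matrix(NA_real_, nrow(starts), 3L)
  for (i in seq_len(nrow(starts))) {
    res <- stats::optim(to_theta(starts[i, ]),
                        function(th) obj(from_theta(th)),
                        method = "Nelder-Mead",
                        control = list(maxit = 400L, reltol = 1e-8))
    cand_val[i] <- res$value
    cand_par[i, ] <- from_theta(res$par)
  }
  # the D surface is near-flat along the parameter ridge; among optima within
  # a small D tolerance of the minimum, prefer the curve with the smallest
  # RMS residual (documented tie-break)
  dmin <- min(cand_val)
  near <- which(cand_val <= dmin + 0.01)
  rms <- vapply(near, function(i)
    sqrt(mean((y_u - fivepl_logx(t_u, cand_par[i, 1L], cand_par[i, 2L],
                                 cand_par[i, 3L]))^2)), numeric(1L))
  pick <- near[which.min(rms)]
  structure(list(b = cand_par[pick, 1L], c = 0, d = 1,
                 e = cand_par[pick, 2L], f = cand_par[pick, 3L],
                 D = cand_val[pick], n_used = length(usable),
                 bounds = bounds, seed = seed),
            class = "fivepl_fit")
}

#' @export
print.fivepl_fit <- function(x, ...) {
  cat(sprintf(
    "fivepl_fit: b=%.3f e=%.3f f=%.3f (c=0, d=1) | KS D=%.4f on %d genes\n",
    x$b, x$e, x$f, x$D, x$n_used))
  invisible(x)
}

#' Residuals from the fitted dropout curve, scaled per sample
#'
#' Raw residual of a gene is observed dropout minus curve-predicted dropout
#' (positive = more dropout than its bulk expression predicts, i.e. the gene
#' looks over-expressed in bulk relative to single-cell). Scaled residuals are
#' the z-scores, centered/scaled on the usable-gene universe by default
#' (dropout strictly in (0, 1)), then applied to all genes.
#'
#' @param fit a [fit_fivepl_ks()] result
#' @param log_expr,dropout the vectors the curve was fit to (named by gene)
#' @param z_universe `"usable"` (default) or `"all"`: genes defining the
#'   centering/scaling moments
#' @return data.frame of class `residual_profile`: `gene`, `log_expr`,
#'   `dropout`, `predicted`, `residual`, `z`, `usable`
#' @export
residual_profile <- function(fit, log_expr, dropout,
                             z_universe = c("usable", "all")) {
  z_universe <- match.arg(z_universe)
  genes <- names(dropout)
  if (is.null(genes)) genes <- as.character(seq_along(dropout))
  pred <- fivepl_logx(log_expr, fit$b, fit$e, fit$f, c = fit$c, d = fit$d)
  r <- dropout - pred
  usable <- dropout > 0 & dropout < 1
  ref <- if (z_universe == "usable") r[usable] else r
  s <- stats::sd(ref)
  if (!is.finite(s) || s == 0) stop("residual sd is zero")
  z <- (r - mean(ref)) / s
  structure(data.frame(gene = genes, log_expr = log_expr, dropout = dropout,
                       predicted = pred, residual = r, z = z,
                       usable = usable, stringsAsFactors = FALSE),
            class = c("residual_profile", "data.frame"))
}

#' Call discordant genes from scaled residuals
#'
#' Genes with scaled residual above `tau` are called over-expressed (in bulk
#' relative to single-cell), below `-tau` under-expressed.
#'
#' @param profile a [residual_profile()] data.frame
#' @param tau z threshold (default 2)
#' @return list with `over`, `under` (gene id vectors), `calls` (factor per
#'   gene), `flagged_fraction`
#' @export
call_discordant <- function(profile, tau = 2) {
  z <- profile$z
  calls <- factor(ifelse(z > tau, "over", ifelse(z < -tau, "under", "none")),
                  levels = c("over", "under", "none"))
  list(over = profile$gene[calls == "over"],
       under = profile$gene[calls == "under"],
       calls = stats::setNames(calls, profile$gene),
       flagged_fraction = mean(calls != "none"))
}

#' Intersect discordance calls within and across datasets
#'
#' Within a dataset a gene is "common" if it is called with the same direction
#' in every sample; the across-dataset sets intersect the per-dataset common
#' sets.
#'
#' @param calls_by_dataset named list (dataset) of named lists (sample) of
#'   [call_discordant()] results
#' @return list with `per_dataset` (over/under common sets per dataset),
#'   `shared` (over/under sets common to all datasets) and `counts`
#' @export
intersect_discordant <- function(calls_by_dataset) {
  per_dataset <- lapply(calls_by_dataset, function(ds) {
    list(over = Reduce(intersect, lapply(ds, `[[`, "over")),
         under = Reduce(intersect, lapply(ds, `[[`, "under")))
  })
  shared <- list(
    over = Reduce(intersect, lapply(per_dataset, `[[`, "over")),
    under = Reduce(intersect, lapply(per_dataset, `[[`, "under")))
  counts <- data.frame(
    dataset = names(per_dataset),
    n_over = vapply(per_dataset, function(d) length(d$over), 1L),
    n_under = vapply(per_dataset, function(d) length(d$under), 1L),
    stringsAsFactors = FALSE)
  list(per_dataset = per_dataset, shared = shared, counts = counts)
}
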