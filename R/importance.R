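#' Tuning presets for the dropout-rate models
#'
#' Small named hyperparameter grids tuned by bootstrap-resampled grid search
#' minimizing out-of-bag RMSE. The `"test"` preset uses 5 bootstrap resamples
#' and a reduced grid; `"paper"` uses 25 resamples.
#'
#' @param preset `"test"` (default) or `"paper"`
#' @return list with `n_boot`, `xgb_grid`, `nnet_grid`
#' @export
tuning_preset <- function(preset = c("test", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    list(n_boot = 25L,
         xgb_grid = expand.grid(nrounds = c(50L, 100L, 150L),
                                max_depth = c(2L, 4L, 6L),
                                eta = c(0.1, 0.3),
                                subsample = 0.8,
                                colsample_bytree = c(0.6, 1)),
         nnet_grid = expand.grid(size = 1:3,
                                 decay = c(0.01, 0.1, 0.5)))
  } else {
    list(n_boot = 5L,
         xgb_grid = expand.grid(nrounds = c(50L, 100L),
                                max_depth = c(2L, 4L),
                                eta = 0.3,
                                subsample = 1,
                                colsample_bytree = 1),
         nnet_grid = expand.grid(size = 1:3,
                                 decay = c(0.1, 0.5)))
  }
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

fit_xgb <- function(x, y, par, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
  xgboost::xgb.train(
    params = list(max_depth = par$max_depth, eta = par$eta,
                  subsample = par$subsample,
                  colsample_bytree = par$colsample_bytree,
                  objective = "reg:squarederror", nthread = 1L,
                  seed = seed),
    data = dtrain, nrounds = par$nrounds, verbose = 0)
}

fit_nn <- function(x, y, par, seed) {
  set.seed(seed)
  nnet::nnet(x, y, size = par$size, decay = par$decay, linout = TRUE,
             maxit = 300L, trace = FALSE)
}

predict_model <- function(model, x) {
  if (inherits(model, "xgb.Booster")) {
    stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1L))
  } else {
    as.numeric(stats::predict(model, x))
  }
}

#' Fit a dropout-rate regression on the technical factors
#'
#' Predicts per-gene dropout rate from the technical-factor table with either
#' gradient-boosted trees (`"xgboost"`) or a Bayesian-regularization-style
#' single-hidden-layer neural network (`"brnn"`: 1-3 neurons, L2 weight
#' penalty, linear output). Hyperparameters are tuned by bootstrap-resampled
#' grid search (out-of-bag RMSE); the winning setting is refit on all genes,
#' without feature selection. `data_scale = "binned"` first replaces each
#' factor by its 5-bin quantile bin.
#'
#' @param features gene x factor data.frame or matrix (conditioned:
#'   imputed, centered/scaled or binnable)
#' @param target per-gene dropout rate in \[0, 1\]
#' @param kind `"xgboost"` or `"brnn"`
#' @param data_scale `"original"` or `"binned"`
#' @param tuning a [tuning_preset()] list
#' @param n_bins bins used when `data_scale = "binned"` (default 5)
#' @param seed RNG seed (controls resampling and model fits)
#' @return list of class `fit_result`: `kind`, `data_scale`, `params` (tuned),
#'   `model`, `features` (the matrix actually used), `r2`, `rmse`, `mae`,
#'   `tuning_table`
#' @export
fit_dropout_model <- function(features, target,
                              kind = c("xgboost", "brnn"),
                              data_scale = c("original", "binned"),
                              tuning = tuning_preset("test"),
                              n_bins = 5L, seed = 1L) {
  kind <- match.arg(kind)
  data_scale <- match.arg(data_scale)
  x <- as.matrix(features)
  if (nrow(x) < 100L) stop("need >= 100 genes")
  if (anyNA(x)) stop("NaN/NA in features after conditioning")
  if (any(target < 0 | target > 1)) stop("target must lie in [0, 1]")
  if (data_scale == "binned") {
    x <- as.matrix(bin_factors(x, n_bins = n_bins))
    storage.mode(x) <- "double"
  }
  grid <- if (kind == "xgboost") tuning$xgb_grid else tuning$nnet_grid
  fitter <- if (kind == "xgboost") fit_xgb else fit_nn

  set.seed(seed)
  n <- nrow(x)
  boots <- lapply(seq_len(tuning$n_boot), function(i)
    sample.int(n, n, replace = TRUE))
  grid_rmse <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    par <- grid[g, , drop = FALSE]
    errs <- vapply(seq_along(boots), function(b) {
      idx <- boots[[b]]
      oob <- setdiff(seq_len(n), idx)
      mod <- fitter(x[idx, , drop = FALSE], target[idx], par,
                    seed = seed + 1000L * g + b)
      rmse(target[oob], predict_model(mod, x[oob, , drop = FALSE]))
    }, numeric(1L))
    grid_rmse[g] <- mean(errs)
  }
  best <- which.min(grid_rmse)
  par <- grid[best, , drop = FALSE]
  model <- fitter(x, target, par, seed = seed)
  pred <- predict_model(model, x)
  structure(list(
    kind = kind, data_scale = data_scale,
    params = as.list(par), model = model, features = x,
    r2 = 1 - sum((target - pred)^2) / sum((target - mean(target))^2),
    rmse = rmse(target, pred),
    mae = mean(abs(target - pred)),
    tuning_table = cbind(grid, oob_rmse = grid_rmse)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: %s on %s scale | R2 %.3f, RMSE %.4f, MAE %.4f\n",
              x$kind, x$data_scale, x$r2, x$rmse, x$mae))
  invisible(x)
}

#' Model-agnostic permutation importance of each factor
#'
#' For each factor, shuffles its column `n_repeats` times and records the mean
#' increase in RMSE over the unshuffled fit; negative increases are floored at
#' zero and the profile is rescaled so the largest importance is 100. For
#' boosted trees the gain-based importance is reported alongside.
#'
#' @param fit a [fit_dropout_model()] result
#' @param target the dropout-rate vector the model was fit to
#' @param n_repeats shuffles per factor (default 5)
#' @param seed RNG seed
#' @return data.frame with `factor`, `importance` (0-100), `raw`
#'   (RMSE increase), and `gain` (boosted trees only, 0-100)
#' @export
variable_importance <- function(fit, target, n_repeats = 5L, seed = 1L) {
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  x <- fit$features
  base <- rmse(target, predict_model(fit$model, x))
  set.seed(seed)
  raw <- vapply(seq_len(ncol(x)), function(j) {
    incs <- vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[, j] <- sample(xp[, j])
      rmse(target, predict_model(fit$model, xp)) - base
    }, numeric(1L))
    mean(incs)
  }, numeric(1L))
  raw <- pmax(raw, 0)
  imp <- if (max(raw) > 0) 100 * raw / max(raw) else raw
  out <- data.frame(factor = colnames(x), importance = imp, raw = raw,
                    stringsAsFactors = FALSE)
  if (fit$kind == "xgboost") {
    gi <- xgboost::xgb.importance(model = fit$model)
    gain <- stats::setNames(rep(0, ncol(x)), colnames(x))
    gain[gi$Feature] <- gi$Gain
    out$gain <- if (max(gain) > 0) 100 * gain / max(gain) else gain
  }
  out
}

#' Mean importance per factor with a 95% confidence interval across samples
#'
#' Averages per-sample importance profiles for one dataset and attaches a
#' t-interval for the mean; a single-sample dataset reports the point value
#' with NA bounds.
#'
#' @param profiles list of [variable_importance()] data.frames (one per
#'   sample)
#' @return data.frame: `factor`, `mean`, `ci_lo`, `ci_hi`, `n_samples`
#' @export
importance_summary <- function(profiles) {
  if (!length(profiles)) stop("no profiles")
  facs <- profiles[[1L]]$factor
  m <- vapply(profiles, function(p)
    p$importance[match(facs, p$factor)], numeric(length(facs)))
  m <- matrix(m, nrow = length(facs))
  n <- ncol(m)
  mu <- rowMeans(m)
  if (n > 1L) {
    se <- apply(m, 1L, stats::sd) / sqrt(n)
    tq <- stats::qt(0.975, df = n - 1L)
    lo <- mu - tq * se; hi <- mu + tq * se
  } else {
    lo <- hi <- rep(NA_real_, length(facs))
  }
  data.frame(factor = facs, mean = mu, ci_lo = lo, ci_hi = hi,
             n_samples = n, stringsAsFactors = FALSE)
}

#' Leave-one-cell-type-out importance
#'
#' For each cell group in turn, removes its cells, recomputes the dropout
#' rates of every sample, refits the dropout model and re-ranks factor
#' importance; reveals whether the ranking is driven by a single cell type.
#'
#' @param sc cell-level `count_matrix`
#' @param cell_labels named character vector: group per cell (column)
#' @param features conditioned factor table including an `Expression` column
#' @param kind,data_scale,tuning,seed passed to [fit_dropout_model()]
#' @return named list (per excluded group) of [importance_summary()]
#'   data.frames
#' @export
leave_one_group_out <- function(sc, cell_labels, features,
                                kind = "xgboost", data_scale = "original",
                                tuning = tuning_preset("test"), seed = 1L) {
  if (is.null(names(cell_labels))) names(cell_labels) <- sc$column_ids
  groups <- unique(cell_labels[sc$column_ids])
  if (length(groups) < 2L) stop("need >= 2 cell groups")
  out <- list()
  for (g in groups) {
    keep <- sc$column_ids[cell_labels[sc$column_ids] != g]
    if (!length(keep)) stop("group ", g, " covers all cells")
    sub <- count_matrix(sc$values[, keep, drop = FALSE],
                        sc$sample_of_column[keep])
    profs <- lapply(samples_of(sub), function(s) {
      dr <- dropout_rates(sub, s)
      fit <- fit_dropout_model(features, as.numeric(dr), kind = kind,
                               data_scale = data_scale, tuning = tuning,
                               seed = seed)
      variable_importance(fit, as.numeric(dr), seed = seed)
    })
    out[[g]] <- importance_summary(profs)
  }
  out
}
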