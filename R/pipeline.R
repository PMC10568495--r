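#' Derive per-stage seeds from a master seed
#'
#' Every stochastic stage of the pipeline consumes its own seed drawn
#' deterministically from the master seed, so full runs are reproducible and
#' stages can be re-run in isolation. Seeds stay below 2^31.
#'
#' @param master_seed integer master seed
#' @param n number of seeds
#' @return integer vector of length `n`
#' @export
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(master_seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the full discordance pipeline on a simulated or loaded study
#'
#' Per dataset: pseudo-bulk aggregation, log2-CPM normalization of the bulk,
#' per-sample dropout rates and dropout-gene counts, the KS-minimized
#' five-parameter logistic dropout curve per sample, scaled residuals and
#' discordance calls, per-sample preranked GSEA on raw residuals with
#' within-dataset direction consensus; then cross-dataset intersections of
#' both gene calls and pathway directions. Optionally fits the factor-
#' importance models per sample.
#'
#' @param bundle a study as returned by [simulate_paired_datasets()] (fields
#'   `datasets`, `factors`, `gene_sets`)
#' @param seed master seed; per-stage seeds are derived from it
#' @param tau scaled-residual threshold for discordance calls (default 2)
#' @param alpha FDR threshold for pathway direction (default 0.05)
#' @param n_perm GSEA permutations (default 1000)
#' @param run_importance also fit the factor-importance models (default
#'   FALSE; adds minutes)
#' @param importance_kinds model families when `run_importance` (default both)
#' @param tuning tuning preset for importance fits
#' @return list of class `run_manifest`: per-dataset/per-sample QC (`fits`,
#'   `dropout_summary`), `discordance` (per-dataset and shared sets),
#'   `pathways` (per-dataset directions and shared sets), optional
#'   `importance`, and `seeds`
#' @export
run_all <- function(bundle, seed = 1L, tau = 2, alpha = 0.05,
                    n_perm = 1000L, run_importance = FALSE,
                    importance_kinds = c("xgboost", "brnn"),
                    tuning = tuning_preset("test")) {
  n_stage <- 200L
  seeds <- derive_seeds(seed, n_stage)
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }

  calls_by_dataset <- list()
  labels_by_dataset <- list()
  fits <- list()
  dropout_summary <- list()
  importance <- list()

  for (d in names(bundle$datasets)) {
    ds <- bundle$datasets[[d]]
    al <- align_gene_universe(ds$bulk, ds$sc, bundle$factors)
    pb <- pseudo_bulk(al$sc)
    bulk_prof <- log2_cpm(al$bulk)
    calls <- list()
    labels <- list()
    imp_profiles <- list()
    for (s in samples_of(al$sc)) {
      dr <- dropout_rates(al$sc, s)
      dg <- dropout_gene_count(al$bulk, pb, s)
      lx <- bulk_prof$values[, s]
      fit <- fit_fivepl_ks(lx, as.numeric(dr), seed = next_seed())
      prof <- residual_profile(fit, lx, stats::setNames(as.numeric(dr),
                                                        names(dr)))
      calls[[s]] <- call_discordant(prof, tau = tau)
      rk <- ranked_list(stats::setNames(prof$residual, prof$gene))
      gs <- gsea_permutation(rk, bundle$gene_sets$sets, n_perm = n_perm,
                             seed = next_seed())
      labels[[s]] <- classify_direction(gs, alpha = alpha)
      fits[[s]] <- list(dataset = d, b = fit$b, e = fit$e, f = fit$f,
                        D = fit$D, n_used = fit$n_used,
                        flagged_fraction = calls[[s]]$flagged_fraction)
      dropout_summary[[s]] <- c(dataset = d, n_dropout = dg$n_dropout,
                                denominator = dg$denominator,
                                pct = round(dg$pct, 3))
      if (run_importance) {
        feats <- cbind(Expression = lx, as.matrix(al$factors))
        for (k in importance_kinds) {
          fitm <- fit_dropout_model(center_scale(feats), as.numeric(dr),
                                    kind = k, tuning = tuning,
                                    seed = next_seed())
          imp_profiles[[paste(k, s, sep = ".")]] <-
            variable_importance(fitm, as.numeric(dr), seed = next_seed())
        }
      }
    }
    calls_by_dataset[[d]] <- calls
    # within-dataset pathway consensus: significant with the same direction
    # in a majority of the dataset's samples and never significant with the
    # opposite direction (gene-level calls, by contrast, must agree in every
    # sample)
    cons <- labels[[1L]][, c("set", "size"), drop = FALSE]
    dirs <- vapply(labels, function(l)
      l$direction[match(cons$set, l$set)], character(nrow(cons)))
    dirs <- matrix(dirs, nrow = nrow(cons))
    cons$direction <- apply(dirs, 1L, function(v) {
      n_over <- sum(v == "over"); n_under <- sum(v == "under")
      if (n_over > length(v) / 2 && n_under == 0L) "over"
      else if (n_under > length(v) / 2 && n_over == 0L) "under"
      else "ns"
    })
    labels_by_dataset[[d]] <- cons
    if (run_importance) {
      for (k in importance_kinds) {
        sel <- grep(paste0("^", k, "\\."), names(imp_profiles))
        importance[[paste(d, k, sep = ".")]] <-
          importance_summary(imp_profiles[sel])
      }
    }
  }

  disc <- intersect_discordant(calls_by_dataset)
  paths <- if (length(labels_by_dataset) >= 2L)
    cross_dataset_pathways(labels_by_dataset) else NULL
  structure(list(
    fits = do.call(rbind, lapply(names(fits), function(s)
      data.frame(sample = s, as.list(fits[[s]]), stringsAsFactors = FALSE))),
    dropout_summary = do.call(rbind, lapply(names(dropout_summary),
      function(s) data.frame(sample = s,
                             t(dropout_summary[[s]]),
                             stringsAsFactors = FALSE))),
    discordance = disc,
    pathway_labels = labels_by_dataset,
    pathways = paths,
    importance = if (run_importance) importance else NULL,
    seed = seed, seeds_used = si,
    tau = tau, alpha = alpha, n_perm = n_perm),
    class = "run_manifest")
}

#' Human-readable summary of a pipeline run
#'
#' Deterministic text mirroring the tabular content of the study: per-sample
#' dropout-gene counts and curve fits, gene-level Venn counts, shared-pathway
#' counts and top factors when importance was run.
#'
#' @param manifest a [run_all()] result
#' @return character vector of report lines (also printed)
#' @export
report <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  lines <- c("== dropshift run report ==",
             sprintf("master seed: %d", manifest$seed), "",
             "-- five-parameter logistic fits --")
  f <- manifest$fits
  lines <- c(lines, sprintf(
    "%s [%s]: b=%.3f e=%.3f f=%.3f D=%.4f (n=%d), flagged %.2f%%",
    f$sample, f$dataset, f$b, f$e, f$f, f$D, f$n_used,
    100 * f$flagged_fraction))
  d <- manifest$dropout_summary
  lines <- c(lines, "", "-- dropout genes (bulk-detected, pseudo-bulk zero) --",
             sprintf("%s [%s]: %s of %s (%s%%)", d$sample, d$dataset,
                     d$n_dropout, d$denominator, d$pct))
  dc <- manifest$discordance
  lines <- c(lines, "", "-- discordant genes --",
             sprintf("%s: %d over / %d under (dataset-common)",
                     dc$counts$dataset, dc$counts$n_over, dc$counts$n_under),
             sprintf("shared across all datasets: %d over, %d under",
                     length(dc$shared$over), length(dc$shared$under)))
  if (length(dc$shared$over) + length(dc$shared$under) == 0L)
    lines <- c(lines, "shared discordance sets are empty (zero overlaps)")
  if (!is.null(manifest$pathways)) {
    p <- manifest$pathways
    lines <- c(lines, "", "-- pathways --",
               sprintf("%s: %d over / %d under (within-dataset consensus)",
                       p$counts$dataset, p$counts$n_over, p$counts$n_under),
               sprintf("shared across all datasets: %d over (%s), %d under (%s)",
                       length(p$shared$over),
                       paste(p$shared$over, collapse = ","),
                       length(p$shared$under),
                       paste(p$shared$under, collapse = ",")))
  }
  if (!is.null(manifest$importance)) {
    lines <- c(lines, "", "-- factor importance (mean, 95% CI) --")
    for (nm in names(manifest$importance)) {
      s <- manifest$importance[[nm]]
      s <- s[order(-s$mean), ]
      top <- utils::head(s, 3L)
      lines <- c(lines, sprintf("%s: %s", nm,
                                paste(sprintf("%s=%.1f", top$factor,
                                              top$mean), collapse = ", ")))
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
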