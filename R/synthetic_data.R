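#' Configuration of the paired bulk/single-cell generator
#'
#' Defaults define the desk-scale study conditions used throughout the test
#' suite: 4 datasets of 2-4 samples, 2000 genes, 500 cells per sample, a
#' dropout mechanism driven mainly by bulk expression and secondarily by a
#' TIN-like covariate, 30 planted universally-discordant genes (dropout
#' shifted by `delta` in the same direction in every sample), and 7 planted
#' gene sets whose members share a sub-threshold dropout shift (enriched in
#' residual ranks without being called gene-wise). A `"paper"`-scale preset is
#' available via `scale_preset`.
#'
#' @param n_genes genes per dataset (default 2000)
#' @param n_cells cells per sample (default 500)
#' @param samples_per_dataset integer vector, one entry per dataset
#'   (default c(4, 2, 3, 2))
#' @param bulk_depth bulk library size per sample (default 2e6)
#' @param cell_depth expected per-cell library size scale (default 5000)
#' @param dispersion negative-binomial dispersion of cell-level nonzero
#'   counts (default 0.4)
#' @param bulk_dispersion negative-binomial dispersion of bulk counts
#'   (default 0.02; bulk libraries are far tighter than single cells)
#' @param meanlog,sdlog log-normal parameters of true bulk means
#' @param beta0 dropout-mechanism intercept on the logit scale (default 1.8,
#'   putting mean dropout near 0.8, the droplet regime)
#' @param beta_expr,beta_tin,beta_len,beta_utr3 mechanism coefficients on
#'   standardized covariates (defaults 2.2, 0.35, 0.12, 0.06: expression
#'   dominates, TIN second)
#' @param tin_sample_cor correlation of the sample-level TIN realisation with
#'   the gene-level (median) TIN in the factor table (default 0.9; RNA
#'   integrity is partly a sample property)
#' @param sample_jitter sd of the per-sample logit shift (default 0.1)
#' @param n_discordant planted universally-discordant genes (default 30)
#' @param delta dropout shift of discordant genes (default 0.4)
#' @param n_sets total gene sets (default 20)
#' @param set_size genes per set (default 35)
#' @param n_enriched planted shared-enrichment sets, under direction
#'   (default 7)
#' @param set_shift dropout shift of enriched-set members (default 0.10,
#'   below the gene-wise calling threshold)
#' @param batch_shift optional log-scale bulk mean shift applied to half the
#'   samples on 10% of genes (default 0 = no batch structure)
#' @param scale_preset `"test"` (defaults above) or `"paper"`
#'   (~2e4 genes, 1000 cells)
#' @return list of class `generator_config`
#' @export
generator_config <- function(n_genes = 2000L, n_cells = 500L,
                             samples_per_dataset = c(4L, 2L, 3L, 2L),
                             bulk_depth = 2e6, cell_depth = 5000,
                             dispersion = 0.4, bulk_dispersion = 0.02,
                             meanlog = 1.0, sdlog = 1.6,
                             beta0 = 1.8, beta_expr = 2.2, beta_tin = 0.35,
                             beta_len = 0.12, beta_utr3 = 0.06,
                             tin_sample_cor = 0.9,
                             sample_jitter = 0.1,
                             n_discordant = 30L, delta = 0.4,
                             n_sets = 20L, set_size = 35L,
                             n_enriched = 7L, set_shift = 0.10,
                             batch_shift = 0,
                             scale_preset = c("test", "paper")) {
  scale_preset <- match.arg(scale_preset)
  cfg <- as.list(environment())
  if (scale_preset == "paper") {
    cfg$n_genes <- 19797L
    cfg$n_cells <- 1000L
    cfg$bulk_depth <- 2e7
  }
  stopifnot(cfg$n_genes > 0, cfg$n_cells > 0,
            all(cfg$samples_per_dataset > 0),
            is.finite(c(cfg$beta0, cfg$beta_expr, cfg$beta_tin,
                        cfg$beta_len, cfg$beta_utr3)))
  structure(cfg, class = "generator_config")
}

#' Generate a technical-factor table with known structure
#'
#' Factor marginals mimic real gene annotation: heavy-tailed lengths
#' (log-normal), TIN in \[0, 100\] skewed high, bounded GC%, and mappability
#' percentages correlated across k. Gene length carries the observed ~0.5
#' correlations with GC content and transcript number via a Gaussian copula.
#'
#' @param config a [generator_config()]
#' @param seed RNG seed
#' @return list with `factors` (gene x factor data.frame, no Expression
#'   column) and `latent` (the standardized latent variables that drive the
#'   dropout mechanism: `z_tin`, `z_len`, `z_utr3`)
#' @export
generate_factors <- function(config, seed = 1L) {
  set.seed(seed)
  n <- config$n_genes
  genes <- sprintf("G%05d", seq_len(n))

  # latent Gaussians with the target cross-correlations
  z_len <- stats::rnorm(n)
  z_gc <- 0.5 * z_len + sqrt(1 - 0.25) * stats::rnorm(n)
  z_ntx <- 0.5 * z_len + sqrt(1 - 0.25) * stats::rnorm(n)
  z_tin <- stats::rnorm(n)
  z_utr3 <- 0.4 * z_len + sqrt(1 - 0.16) * stats::rnorm(n)
  z_utr5 <- 0.3 * z_len + sqrt(1 - 0.09) * stats::rnorm(n)
  z_map <- stats::rnorm(n)

  tin_v <- 100 * stats::qbeta(stats::pnorm(z_tin), 5, 1.5)
  map_base <- 100 * stats::qbeta(stats::pnorm(z_map), 8, 2)
  mk <- function(rho, noise_shape) {
    z <- rho * z_map + sqrt(1 - rho^2) * stats::rnorm(n)
    100 * stats::qbeta(stats::pnorm(z), noise_shape, 2)
  }
  factors <- data.frame(
    TIN = tin_v,
    Genelength = round(exp(9 + 1.1 * z_len)),
    No.transcripts = pmax(1L, round(exp(0.9 + 0.5 * z_ntx))),
    UTR3length = round(exp(6.5 + 0.9 * z_utr3)),
    Mapp.k24 = map_base,
    Mapp.k36 = mk(0.9, 9),
    Mapp.k50 = mk(0.85, 10),
    Mapp.k100 = mk(0.8, 12),
    UTR5length = round(exp(5 + 0.8 * z_utr5)),
    GCcontent = pmin(80, pmax(25, 50 + 8 * z_gc)),
    row.names = genes, stringsAsFactors = FALSE)
  list(factors = factors,
       latent = data.frame(z_tin = z_tin, z_len = z_len, z_utr3 = z_utr3,
                           row.names = genes))
}

#' Simulate bulk counts from true gene means
#'
#' Negative-binomial counts per gene and sample at the configured depth:
#' `mu_gs = mean_g / sum(mean) * depth`, `size = 1/dispersion`.
#'
#' @param mu per-gene true relative means (>= 0; zero means give all-zero
#'   counts)
#' @param n_samples number of bulk samples
#' @param depth library size per sample
#' @param dispersion NB dispersion (0 gives Poisson)
#' @param seed RNG seed
#' @param sample_names optional column names
#' @return a `count_matrix` (genes x samples)
#' @export
simulate_bulk <- function(mu, n_samples, depth = 2e6, dispersion = 0.4,
                          seed = 1L, sample_names = NULL) {
  set.seed(seed)
  n <- length(mu)
  genes <- names(mu)
  if (is.null(genes)) genes <- sprintf("G%05d", seq_len(n))
  mus <- mu / sum(mu) * depth
  draw <- function() {
    if (dispersion <= 0) stats::rpois(n, mus)
    else stats::rnbinom(n, mu = mus, size = 1 / dispersion)
  }
  m <- vapply(seq_len(n_samples), function(i) as.numeric(draw()), numeric(n))
  m <- matrix(m, nrow = n)
  if (is.null(sample_names)) sample_names <- sprintf("S%d", seq_len(n_samples))
  dimnames(m) <- list(genes, sample_names)
  count_matrix(m)
}

#' Simulate one sample of single-cell counts with a specified zero mechanism
#'
#' Hurdle parameterization: each (gene, cell) entry is zero with probability
#' `p_zero[gene]`, otherwise drawn from a zero-truncated negative binomial
#' with per-cell mean `cell_depth * mu / sum(mu)` — so the marginal zero
#' fraction matches `p_zero` exactly, up to binomial error.
#'
#' @param p_zero per-gene zero probability in \[0, 1\]
#' @param mu per-gene true relative means (sets nonzero count magnitudes)
#' @param n_cells cells in the sample
#' @param sample sample label
#' @param cell_depth per-cell depth scale (default 5000)
#' @param dispersion NB dispersion of the nonzero component (default 0.4)
#' @param seed RNG seed
#' @return a sparse `count_matrix` (genes x cells)
#' @export
simulate_cells <- function(p_zero, mu, n_cells, sample = "S1",
                           cell_depth = 5000, dispersion = 0.4, seed = 1L) {
  set.seed(seed)
  n <- length(mu)
  stopifnot(length(p_zero) == n, all(p_zero >= 0 & p_zero <= 1))
  genes <- names(mu)
  if (is.null(genes)) genes <- sprintf("G%05d", seq_len(n))
  lam <- mu / sum(mu) * cell_depth
  size <- if (dispersion > 0) 1 / dispersion else Inf

  total <- n * n_cells
  nonzero <- stats::runif(total) >= rep(p_zero, times = n_cells)
  counts <- numeric(total)
  idx <- which(nonzero)
  if (length(idx)) {
    lam_i <- lam[(idx - 1L) %% n + 1L]
    p0 <- stats::pnbinom(0, mu = lam_i, size = size)
    u <- stats::runif(length(idx), min = p0, max = 1)
    counts[idx] <- stats::qnbinom(pmin(u, 1 - 1e-12), mu = lam_i, size = size)
    counts[idx] <- pmax(counts[idx], 1)   # truncation guard at tiny mu
  }
  m <- Matrix::Matrix(counts, nrow = n, ncol = n_cells, sparse = TRUE,
                      dimnames = list(genes,
                                      sprintf("%s_c%04d", sample,
                                              seq_len(n_cells))))
  count_matrix(methods::as(m, "CsparseMatrix"),
               stats::setNames(rep(sample, n_cells), colnames(m)))
}

#' Simulate a full multi-dataset paired bulk/single-cell study
#'
#' Draws true gene means and a factor table once, builds the per-gene dropout
#' mechanism `P(zero) = plogis(beta0 - beta_expr z_expr - beta_tin z_tin -
#' beta_len z_len - beta_utr3 z_utr3)`, plants the discordant genes (dropout
#' shifted by +/- `delta`, same direction everywhere) and the enriched sets
#' (members shifted by -`set_shift`), then simulates every dataset's bulk and
#' cell-level counts.
#'
#' @param config a [generator_config()]
#' @param seed master RNG seed; per-stage seeds are derived from it
#' @return list with `datasets` (each: `name`, `bulk`, `sc`, `p_true` gene x
#'   sample matrix), `factors`, `gene_sets` (GMT-style list), and `truth`
#'   (`mu`, `discordant` data.frame, `enriched_sets`, `p_base`)
#' @export
simulate_paired_datasets <- function(config = generator_config(), seed = 1L) {
  seeds <- derive_seeds(seed, 8L + 2L * length(config$samples_per_dataset) +
                          3L * sum(config$samples_per_dataset))
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }

  fac <- generate_factors(config, seed = next_seed())
  n <- config$n_genes
  genes <- rownames(fac$factors)

  set.seed(next_seed())
  mu <- stats::setNames(stats::rlnorm(n, config$meanlog, config$sdlog), genes)

  z_expr <- as.numeric(scale(log(mu)))
  eta <- config$beta0 - config$beta_expr * z_expr -
    config$beta_tin * fac$latent$z_tin -
    config$beta_len * fac$latent$z_len -
    config$beta_utr3 * fac$latent$z_utr3
  p_base <- stats::plogis(eta)

  # planted universally-discordant genes: up-shifts from mid-low dropout,
  # down-shifts from mid-high dropout so the shifted value stays inside (0,1)
  set.seed(next_seed())
  n_up <- ceiling(config$n_discordant / 2)
  n_dn <- config$n_discordant - n_up
  # plant on covariate-typical genes so the planted effect is delta as
  # labelled, not delta minus a pre-existing covariate offset
  cov_eff <- config$beta_tin * fac$latent$z_tin +
    config$beta_len * fac$latent$z_len +
    config$beta_utr3 * fac$latent$z_utr3
  typical <- abs(cov_eff) < 0.3
  up_pool <- which(p_base > 0.15 & p_base < 0.55 & typical)
  dn_pool <- which(p_base > 0.45 & p_base < 0.85 & typical)
  up_idx <- sample(up_pool, n_up)
  dn_idx <- sample(setdiff(dn_pool, up_idx), n_dn)
  discordant <- data.frame(
    gene = genes[c(up_idx, dn_idx)],
    direction = rep(c("over", "under"), c(n_up, n_dn)),
    stringsAsFactors = FALSE)

  # planted enriched sets (under direction: members get less dropout than
  # their expression predicts) plus null sets drawn at random
  set.seed(next_seed())
  taken <- c(up_idx, dn_idx)
  set_pool <- setdiff(which(p_base > 0.2 & p_base < 0.9 & typical), taken)
  gene_sets <- list()
  enriched_sets <- sprintf("PLANTED_%02d", seq_len(config$n_enriched))
  for (s in enriched_sets) {
    members <- sample(set_pool, config$set_size)
    set_pool <- setdiff(set_pool, members)
    gene_sets[[s]] <- genes[members]
  }
  for (i in seq_len(config$n_sets - config$n_enriched)) {
    gene_sets[[sprintf("NULL_%02d", i)]] <-
      genes[sample.int(n, config$set_size)]
  }

  shift <- numeric(n)
  shift[up_idx] <- config$delta
  shift[dn_idx] <- -config$delta
  enriched_members <- genes %in% unlist(gene_sets[enriched_sets])
  shift[enriched_members] <- shift[enriched_members] - config$set_shift

  datasets <- list()
  for (d in seq_along(config$samples_per_dataset)) {
    ns <- config$samples_per_dataset[d]
    dname <- sprintf("D%d", d)
    snames <- sprintf("%s_S%d", dname, seq_len(ns))
    bulk <- simulate_bulk(mu, ns, depth = config$bulk_depth,
                          dispersion = config$bulk_dispersion,
                          seed = next_seed(), sample_names = snames)
    p_true <- matrix(NA_real_, n, ns, dimnames = list(genes, snames))
    sc_list <- vector("list", ns)
    for (s in seq_len(ns)) {
      set.seed(next_seed())
      jit <- stats::rnorm(1, 0, config$sample_jitter)
      a <- config$tin_sample_cor
      z_tin_s <- a * fac$latent$z_tin + sqrt(1 - a^2) * stats::rnorm(n)
      eta_s <- config$beta0 + jit - config$beta_expr * z_expr -
        config$beta_tin * z_tin_s -
        config$beta_len * fac$latent$z_len -
        config$beta_utr3 * fac$latent$z_utr3
      p_s <- stats::plogis(eta_s) + shift
      clipped <- p_s < 0.01 | p_s > 0.99
      if (any(clipped & shift != 0))
        warning("clipping ", sum(clipped & shift != 0),
                " shifted zero-probabilities into (0.01, 0.99)")
      p_s <- pmin(pmax(p_s, 0.01), 0.99)
      p_true[, s] <- p_s
      sc_list[[s]] <- simulate_cells(
        p_s, mu, config$n_cells, sample = snames[s],
        cell_depth = config$cell_depth, dispersion = config$dispersion,
        seed = next_seed())
    }
    vals <- do.call(cbind, lapply(sc_list, function(x) x$values))
    soc <- do.call(c, lapply(sc_list, function(x) x$sample_of_column))
    datasets[[dname]] <- list(name = dname, bulk = bulk,
                              sc = count_matrix(vals, soc),
                              p_true = p_true)
  }
  list(datasets = datasets, factors = fac$factors,
       gene_sets = list(sets = gene_sets,
                        descriptions = stats::setNames(
                          rep("synthetic", length(gene_sets)),
                          names(gene_sets))),
       truth = list(mu = mu, p_base = p_base, discordant = discordant,
                    enriched_sets = enriched_sets, shift = shift,
                    latent = fac$latent, config = config, seed = seed))
}

#' Write a simulated study to disk as a sample-sheet-ready bundle
#'
#' Per dataset: one MTX triplet per sample plus a bulk TSV; plus the factor
#' TSV, the GMT file, a truth JSON sufficient to score every stage, and a
#' YAML sample sheet.
#'
#' @param config a [generator_config()]
#' @param dir output directory
#' @param seed master RNG seed
#' @return the bundle (invisibly), as from [simulate_paired_datasets()]
#' @export
emit_dataset_bundle <- function(config = generator_config(), dir, seed = 1L) {
  bundle <- simulate_paired_datasets(config, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- list(samples = list())
  for (d in names(bundle$datasets)) {
    ds <- bundle$datasets[[d]]
    write_counts_tsv(ds$bulk, file.path(dir, paste0(d, "_bulk.tsv")))
    for (s in samples_of(ds$sc)) {
      cols <- ds$sc$column_ids[ds$sc$sample_of_column == s]
      sub <- count_matrix(ds$sc$values[, cols, drop = FALSE],
                          ds$sc$sample_of_column[cols])
      sdir <- file.path(dir, paste0(s, "_mtx"))
      write_counts_mtx(sub, sdir)
      sheet$samples[[length(sheet$samples) + 1L]] <-
        list(name = s, dataset = d, sc_counts = paste0(s, "_mtx"),
             bulk_counts = paste0(d, "_bulk.tsv"), bulk_column = s)
    }
  }
  ft <- data.frame(gene_id = rownames(bundle$factors), bundle$factors,
                   check.names = FALSE)
  utils::write.table(ft, file.path(dir, "factors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(bundle$gene_sets, file.path(dir, "gene_sets.gmt"))
  jsonlite::write_json(
    list(discordant = bundle$truth$discordant,
         enriched_sets = bundle$truth$enriched_sets,
         seed = seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(sheet, file.path(dir, "sample_sheet.yaml"))
  invisible(bundle)
}
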