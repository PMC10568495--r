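# Shared fixtures, built once per test run. The default-generator bundle and
# its full pipeline run are reused by several files; both are deterministic
# under the fixed seeds below.

.fixtures <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- suppressWarnings(
      simulate_paired_datasets(generator_config(), seed = 42))
  .fixtures$bundle
}

default_run <- function() {
  if (is.null(.fixtures$run))
    .fixtures$run <- suppressWarnings(run_all(default_bundle(), seed = 43))
  .fixtures$run
}

# tiny deterministic count_matrix for io/preprocess unit tests
toy_counts <- function() {
  m <- matrix(c(5, 0, 0, 0, 0, 1,
                2, 1, 0, 3, 0, 0), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"),
                              c("c1", "c2", "c3", "c4")))
  count_matrix(m, sample_of_column = c(c1 = "A", c2 = "A", c3 = "B", c4 = "B"))
}

# held-out R^2 from a fit's bootstrap tuning table (1 - oob MSE / var)
oob_r2 <- function(fit, target) {
  best <- which.min(fit$tuning_table$oob_rmse)
  1 - fit$tuning_table$oob_rmse[best]^2 / stats::var(target)
}
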