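# Shared small-scale study fixtures, generated in code.

small_config <- function(seed = 1L, ...) {
  demo_config(seed = seed, n_samples_per_platform = 300L,
              n_variants = 400L, n_lipids = 24L, n_subclasses = 3L, ...)
}

# one small cohort reused by read-only tests
.shared_cohort <- generate_cohort(small_config())
.shared_fixtures <- generate_annotation_fixtures(.shared_cohort)

# residualised traits for the shared cohort
.shared_resid <- residualise(
  log_transform(total_signal_normalise(.shared_cohort$lipids)),
  .shared_cohort$covariates)

# minimal raw lipid matrix from explicit values
raw_lm <- function(values) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("L%02d", seq_len(ncol(values)))
  lipid_matrix(values, stage = "raw")
}

# sample skewness (moment estimator)
skewness <- function(x) {
  x <- x[!is.na(x)]
  mean((x - mean(x))^3) / stats::sd(x)^3
}
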