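test_that("total-signal normalisation divides by the per-sample total", {
  m <- raw_lm(matrix(c(2, 3, 5,
                       4, NA, 6), nrow = 2, byrow = TRUE))
  norm <- total_signal_normalise(m)
  expect_equal(unname(norm$values[1, ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(norm$values[2, ]), c(0.4, NA, 0.6))
  expect_equal(rowSums(norm$values, na.rm = TRUE), c(S01 = 1, S02 = 1))
  expect_identical(norm$stage, "normalised")
})

test_that("normalisation is scale-invariant per sample", {
  set.seed(1)
  v <- matrix(stats::rexp(50), 5, 10)
  v[sample(50, 5)] <- NA
  a <- total_signal_normalise(raw_lm(v))
  b <- total_signal_normalise(raw_lm(v * c(1, 10, 0.5, 100, 3)))
  expect_equal(a$values, b$values)
})

test_that("normalisation rejects zero-total and negative samples", {
  z <- raw_lm(matrix(c(0, 0, 0, 1, 2, 3), nrow = 2, byrow = TRUE))
  expect_error(total_signal_normalise(z), "S01")
  neg <- raw_lm(matrix(c(-1, 2, 3, 1, 2, 3), nrow = 2, byrow = TRUE))
  expect_error(total_signal_normalise(neg), "non-negative")
})

test_that("log transform is the natural log and validates positivity", {
  m <- raw_lm(matrix(c(2, 3, 5, 4, 10, 6), nrow = 2, byrow = TRUE))
  norm <- total_signal_normalise(m)
  logged <- log_transform(norm)
  expect_equal(logged$values, log(norm$values))
  expect_equal(exp(logged$values), norm$values, tolerance = 1e-15)
  bad <- norm
  bad$values[1, 1] <- 0
  expect_error(log_transform(bad), "L01")
  # stage gating: logging twice is refused
  expect_error(log_transform(logged), "normalised")
})

test_that("logged synthetic lipid intensities are approximately symmetric", {
  cfg <- sim_config(n_samples_per_platform = 1000L, n_variants = 5L,
                    n_lipids = 60L, n_subclasses = 6L,
                    missing_rate_subjects = 0, missing_rate_lipids = 0,
                    seed = 9L)
  cohort <- generate_cohort(cfg)
  # raw intensities are log-normal by construction: log is symmetric
  sk_raw <- apply(log(cohort$lipids$values), 2, skewness)
  expect_lt(max(abs(sk_raw)), 0.2)
  # the per-sample total in the proportion transform adds a small left
  # skew; the logged proportions stay close to symmetric
  logged <- log_transform(total_signal_normalise(cohort$lipids))
  sk <- apply(logged$values, 2, skewness)
  expect_lt(max(abs(sk)), 0.35)
  expect_lt(abs(stats::median(sk)), 0.15)
})

test_that("missingness filter applies strict thresholds, subjects first", {
  set.seed(2)
  v <- matrix(stats::rexp(100 * 20), 100, 20,
              dimnames = list(sprintf("S%03d", 1:100), sprintf("L%02d", 1:20)))
  v["S001", 1:3] <- NA        # 15% missing  -> removed
  v["S002", 1] <- NA          # 5% missing   -> retained
  v["S003", c(1, 20)] <- NA   # exactly 10%  -> retained ("more than 10%")
  v[4:31, "L20"] <- NA        # >20% of remaining subjects -> removed
  f <- filter_missingness(lipid_matrix(v, "raw"))
  log <- attr(f, "removal_log")
  expect_identical(log$subjects, "S001")
  expect_identical(log$lipids, "L20")
  expect_true(all(c("S002", "S003") %in% rownames(f$values)))
  # idempotent away from threshold-interaction corner cases
  f2 <- filter_missingness(f)
  expect_equal(f2$values, f$values)
  # zero tolerance with missing data everywhere empties the matrix
  allna <- matrix(c(NA, 1, 1, NA), 2, 2,
                  dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(filter_missingness(lipid_matrix(allna, "raw"),
                                  subject_max = 0, lipid_max = 0),
               "removed all", ignore.case = TRUE)
})

test_that("residuals are orthogonal to the design with zero mean", {
  resid <- .shared_resid
  cov <- .shared_cohort$covariates[match(rownames(resid$values),
                                         .shared_cohort$covariates$sample_id), ]
  X <- lipidqtl:::.design_matrix(cov, 6L)
  # per lipid, orthogonality holds on the observed rows
  for (j in seq_len(ncol(resid$values))) {
    ok <- !is.na(resid$values[, j])
    r <- resid$values[ok, j]
    expect_lt(max(abs(crossprod(X[ok, , drop = FALSE], r))), 1e-8 * sum(ok))
    expect_lt(abs(mean(r)), 1e-12)
  }
  # missingness propagates
  expect_identical(is.na(resid$values),
                   is.na(.shared_cohort$lipids$values))
})

test_that("residualisation with null covariate effects reproduces centred values", {
  cfg <- sim_config(n_samples_per_platform = 1000L, n_variants = 5L,
                    n_lipids = 8L, n_subclasses = 2L,
                    covariate_effect_sd = 0,
                    missing_rate_subjects = 0, missing_rate_lipids = 0,
                    seed = 21L)
  cohort <- generate_cohort(cfg)
  logged <- log_transform(total_signal_normalise(cohort$lipids))
  resid <- residualise(logged, cohort$covariates)
  centred <- scale(logged$values, scale = FALSE)
  for (j in seq_len(ncol(centred)))
    expect_gt(stats::cor(resid$values[, j], centred[, j]), 0.99)
})

test_that("rank-deficient covariate designs are rejected with the column named", {
  cov <- .shared_cohort$covariates
  cov$PC2 <- cov$PC1
  logged <- log_transform(total_signal_normalise(.shared_cohort$lipids))
  expect_error(residualise(logged, cov), "PC")
})

test_that("PCA threshold derivation follows the component count", {
  expect_equal(signif(significance_threshold(56), 4), 8.929e-10)
  expect_equal(signif(significance_threshold(112), 4), 4.464e-10)
  # rank-1 matrix needs a single component
  set.seed(3)
  u <- stats::rnorm(50)
  v <- matrix(u, 50, 6) * rep(runif(6, 0.5, 2), each = 50) +
    matrix(stats::rnorm(300, 0, 1e-8), 50, 6)
  m <- lipid_matrix(`dimnames<-`(v, list(sprintf("S%02d", 1:50),
                                         sprintf("L%02d", 1:6))),
                    "residualised")
  thr <- derive_threshold(m)
  expect_equal(thr$n_components, 1L)
  expect_equal(thr$threshold, 5e-8)
  # monotone: a stricter variance target keeps at least as many components
  thr2 <- derive_threshold(.shared_resid, var_target = 0.80)
  thr3 <- derive_threshold(.shared_resid, var_target = 0.95)
  expect_lte(thr2$n_components, thr3$n_components)
  expect_gte(thr2$threshold, thr3$threshold)
})

test_that("lipid ratios behave as log contrasts", {
  norm <- total_signal_normalise(.shared_cohort$lipids)
  ids <- colnames(norm$values)
  same <- compute_ratio(norm, ids[1], ids[1])
  expect_true(all(same[!is.na(same)] == 0))
  ab <- compute_ratio(norm, ids[1], ids[2])
  ba <- compute_ratio(norm, ids[2], ids[1])
  expect_equal(ab, -ba)
  miss <- is.na(norm$values[, ids[1]]) | is.na(norm$values[, ids[2]])
  expect_identical(is.na(ab), miss)
  bad <- norm
  bad$values[3, ids[2]] <- 0
  expect_error(compute_ratio(bad, ids[1], ids[2]), "denominator")
})

test_that("a ratio of two lipids with opposite-sign QTL effects amplifies the signal", {
  cfg <- sim_config(
    n_samples_per_platform = 1000L, n_variants = 20L, n_lipids = 8L,
    n_subclasses = 2L, maf_range = c(0.3, 0.3),
    planted_qtls = list(list(variant = 5L, lipids = 1L, beta = 0.3),
                        list(variant = 5L, lipids = 2L, beta = -0.3)),
    missing_rate_subjects = 0, missing_rate_lipids = 0, seed = 31L)
  cohort <- generate_cohort(cfg)
  norm <- total_signal_normalise(cohort$lipids)
  ids <- colnames(norm$values)
  ratio <- compute_ratio(norm, ids[1], ids[2])
  rmat <- matrix(ratio, ncol = 1,
                 dimnames = list(names(ratio), "ratio"))
  logged <- log_transform(norm)
  resid <- residualise(logged, cohort$covariates)
  rres <- residualise(lipid_matrix(rmat, "logged"), cohort$covariates)
  vid <- cohort$panels[[1]]$variants$variant_id[5]
  dos <- c(cohort$panels[[1]]$dosage[, vid], cohort$panels[[2]]$dosage[, vid])
  dos <- dos[rownames(resid$values)]
  b1 <- regress_additive(dos, resid$values[, ids[1]])$beta
  b2 <- regress_additive(dos, resid$values[, ids[2]])$beta
  br <- regress_additive(dos, rres$values[, 1])$beta
  expect_gt(abs(br), max(abs(b1), abs(b2)))
})
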