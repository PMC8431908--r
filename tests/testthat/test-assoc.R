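# brute-force HWE oracle: direct unnormalised enumeration over heterozygote
# counts conditional on the allele counts
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_AA + n_Aa                      # count of the A allele
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  pr <- vapply(hets, function(h) {
    a <- (na - h) / 2
    b <- n - h - a
    if (a < 0 || b < 0) return(0)
    exp(lchoose(n, a) + lchoose(n - a, h) + h * log(2) - lchoose(2 * n, na))
  }, 0)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

test_that("HWE exact test matches enumeration on canonical tables", {
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-9)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  # equality with the independent oracle across an exhaustive small grid
  for (n in c(5, 13, 40)) {
    tables <- expand.grid(a = 0:n, h = 0:n)
    tables <- tables[tables$a + tables$h <= n, ]
    for (i in seq_len(nrow(tables))) {
      a <- tables$a[i]; h <- tables$h[i]; b <- n - a - h
      expect_equal(hwe_exact_test(a, h, b), hwe_oracle(a, h, b),
                   tolerance = 1e-10)
    }
  }
})

test_that("HWE exact test is conservative under the null", {
  set.seed(42)
  reps <- 2000
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    g <- stats::rbinom(500, 2, 0.3)
    p[i] <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }
  expect_lte(mean(p <= 0.05), 0.06)
})

test_that("variant QC computes MAF, call rate and HWE from the panel", {
  d <- matrix(1, nrow = 100, ncol = 3,
              dimnames = list(sprintf("S%03d", 1:100), c("v1", "v2", "v3")))
  # v2: counts 90/10/0; v3: 3 missing of 100, HWE-consistent genotypes
  d[, 2] <- c(rep(0, 90), rep(1, 10))
  d[, 3] <- c(rep(0, 25), rep(1, 48), rep(2, 27))
  d[1:3, 3] <- NA
  panel <- structure(list(platform = "p", samples = rownames(d),
                          variants = data.frame(variant_id = colnames(d),
                                                info = c(1, 1, 1)),
                          dosage = d), class = "genotype_panel")
  qc <- variant_qc(panel)
  expect_equal(qc$maf[1], 0.5)           # all heterozygous
  expect_equal(qc$maf[2], 0.05)          # alt frequency 10/200
  expect_equal(qc$call_rate[3], 0.97)
  # call rate exactly 0.97 passes the strict "< 0.97" exclusion
  expect_true(variant_qc_pass(qc)[3])
  # all-het is an extreme HWE departure
  expect_lt(qc$hwe_p[1], 1e-7)
  expect_false(variant_qc_pass(qc)[1])
})

test_that("additive regression recovers exact and planted slopes", {
  dosage <- rep(0:2, each = 20)
  fit <- regress_additive(dosage, 0.5 * dosage)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  expect_lt(fit$p, 1e-100)
  expect_error(regress_additive(rep(1, 50), stats::rnorm(50)), "monomorphic")
  expect_error(regress_additive(1:5, stats::rnorm(5)), "observations")
  # planted effect recovered on average across replicates
  set.seed(8)
  reps <- 50
  est <- numeric(reps)
  for (i in seq_len(reps)) {
    g <- stats::rbinom(2000, 2, 0.2)
    y <- 0.3 * g + stats::rnorm(2000)
    est[i] <- regress_additive(g, y)$beta
  }
  mc_se <- stats::sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 0.3), 3 * mc_se)
})

test_that("null regression P values are uniform", {
  set.seed(12)
  p <- replicate(300, {
    g <- stats::rbinom(300, 2, 0.25)
    regress_additive(g, stats::rnorm(300))$p
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("inverse-variance meta-analysis follows the closed form", {
  m <- ivw_meta(list(list(beta = 1, se = 1), list(beta = 0, se = 1)))
  expect_equal(m$beta, 0.5)
  expect_equal(m$se, 1 / sqrt(2))
  m2 <- ivw_meta(list(list(beta = 0.7, se = 0.2), list(beta = 0.7, se = 0.2)))
  expect_equal(m2$beta, 0.7)
  expect_equal(m2$se, 0.2 / sqrt(2))
  one <- list(beta = -0.3, se = 0.11)
  m3 <- ivw_meta(list(one))
  expect_equal(m3$beta, one$beta)
  expect_equal(m3$se, one$se)
  expect_error(ivw_meta(list()), "no association")
  expect_error(ivw_meta(list(list(beta = 1, se = 0))), "positive")
  # pooled se never exceeds the best single-study se
  set.seed(4)
  for (i in 1:20) {
    rs <- lapply(1:3, function(j) list(beta = stats::rnorm(1),
                                       se = stats::runif(1, 0.05, 2)))
    m <- ivw_meta(rs)
    expect_lte(m$se, min(vapply(rs, `[[`, 0, "se")))
  }
})

test_that("post-meta QC enumerates the cross-platform failure reasons", {
  base <- data.frame(p_meta = 1e-11, beta_p1 = 0.3, p_p1 = 1e-12,
                     beta_p2 = 0.25, p_p2 = 0.004)
  pass <- post_meta_qc(base, TRUE, TRUE, 8.929e-10)
  expect_true(pass$qc_pass)
  expect_identical(pass$fail_reasons, "")

  flip <- base; flip$beta_p2 <- -0.1
  r <- post_meta_qc(flip, TRUE, TRUE, 8.929e-10)
  expect_false(r$qc_pass)
  expect_match(r$fail_reasons, "direction")

  weak <- base; weak$p_p1 <- 0.02
  r2 <- post_meta_qc(weak, TRUE, TRUE, 8.929e-10)
  expect_false(r2$qc_pass)
  expect_match(r2$fail_reasons, "platform p")

  r3 <- post_meta_qc(base, TRUE, FALSE, 8.929e-10)
  expect_match(r3$fail_reasons, "platform qc")

  miss <- base; miss$beta_p2 <- NA; miss$p_p2 <- NA
  r4 <- post_meta_qc(miss, TRUE, TRUE, 8.929e-10)
  expect_false(r4$qc_pass)
  expect_match(r4$fail_reasons, "missing")
})

test_that("genomic inflation factor tracks the chi-square median", {
  p_ref <- stats::pchisq(0.4549364, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(rep(p_ref, 101)), 1, tolerance = 1e-6)
  set.seed(19)
  expect_equal(genomic_inflation(stats::runif(1e5)), 1, tolerance = 0.02)
  z <- stats::rnorm(1e5, 0, 1.1)
  p <- 2 * stats::pnorm(-abs(z))
  expect_equal(genomic_inflation(p), 1.21, tolerance = 0.04)
  expect_error(genomic_inflation(numeric(0)), "no P values")
})

test_that("run_gwas covers every variant-trait pair and meta matches ivw_meta", {
  meta <- run_gwas(.shared_cohort$panels, .shared_resid,
                   threshold = 8.929e-10)
  cfg <- .shared_cohort$config
  expect_equal(nrow(meta), cfg$n_variants * cfg$n_lipids)
  # spot-check the vectorised per-platform and meta estimates
  set.seed(6)
  rows <- sample(nrow(meta), 5)
  for (i in rows) {
    vid <- meta$variant_id[i]; tid <- meta$trait_id[i]
    fits <- lapply(.shared_cohort$panels, function(pan) {
      y <- .shared_resid$values[match(pan$samples,
                                      rownames(.shared_resid$values)), tid]
      regress_additive(pan$dosage[, vid], y)
    })
    expect_equal(meta$beta_p1[i], fits[[1]]$beta, tolerance = 1e-10)
    expect_equal(meta$p_p2[i], fits[[2]]$p, tolerance = 1e-8)
    mm <- ivw_meta(fits)
    expect_equal(meta$beta_meta[i], mm$beta, tolerance = 1e-10)
    expect_equal(meta$se_meta[i], mm$se, tolerance = 1e-10)
  }
})

test_that("a strongly planted QTL is detected with qc_pass", {
  cfg <- sim_config(n_samples_per_platform = 1000L, n_variants = 50L,
                    n_lipids = 6L, n_subclasses = 2L,
                    maf_range = c(0.3, 0.3),
                    planted_qtls = list(list(variant = 10L, lipids = 1L,
                                             beta = 1.0)),
                    missing_rate_subjects = 0, missing_rate_lipids = 0,
                    seed = 17L)
  cohort <- generate_cohort(cfg)
  resid <- residualise(log_transform(total_signal_normalise(cohort$lipids)),
                       cohort$covariates)
  meta <- run_gwas(cohort$panels, resid, threshold = 8.929e-10)
  vid <- cohort$panels[[1]]$variants$variant_id[10]
  tid <- cohort$truth$qtls$lipid_id[1]
  hit <- meta[meta$variant_id == vid & meta$trait_id == tid, ]
  expect_true(hit$qc_pass)
})
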