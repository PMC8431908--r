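#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the allele counts: the P value is the
#' sum of probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return Exact two-sided P value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  m <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)  # minor allele count
  probs <- .hwe_het_probs(n, m)
  obs <- probs[as.character(n_Aa)]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# conditional probabilities of every admissible heterozygote count given
# n diploids and m minor alleles; named by heterozygote count
.hwe_het_probs <- function(n, m) {
  h <- seq(m %% 2, m, by = 2)
  r <- (m - h) / 2               # minor-allele homozygotes
  c_ <- n - h - r                # major-allele homozygotes
  keep <- c_ >= 0
  h <- h[keep]; r <- r[keep]; c_ <- c_[keep]
  lp <- lfactorial(n) - lfactorial(r) - lfactorial(h) - lfactorial(c_) +
    h * log(2) + lfactorial(m) + lfactorial(2 * n - m) - lfactorial(2 * n)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  names(p) <- h
  p
}

#' Per-variant quality-control statistics
#'
#' Computes minor allele frequency (mean dosage / 2, folded to at most 0.5),
#' call rate (non-missing fraction), an exact Hardy-Weinberg P value from
#' hard-call genotypes (dosages rounded), and carries through the panel's
#' imputation info score (1 for hard calls).
#'
#' @param panel A \code{genotype_panel}.
#' @return Data frame with columns \code{variant_id}, \code{maf},
#'   \code{call_rate}, \code{hwe_p}, \code{info}, \code{monomorphic}.
#' @export
variant_qc <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosage
  if (ncol(d) == 0) stop("empty genotype panel")
  call_rate <- colMeans(!is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  g <- round(d)
  nAA <- colSums(g == 0, na.rm = TRUE)
  nAa <- colSums(g == 1, na.rm = TRUE)
  naa <- colSums(g == 2, na.rm = TRUE)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    tot <- nAA[j] + nAa[j] + naa[j]
    if (tot == 0) return(NA_real_)
    hwe_exact_test(nAA[j], nAa[j], naa[j])
  }, 0)
  info <- panel$variants$info
  if (is.null(info)) info <- rep(1, ncol(d))
  data.frame(variant_id = colnames(d), maf = maf, call_rate = call_rate,
             hwe_p = hwe_p, info = info, monomorphic = maf == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Platform-level variant QC pass flags
#'
#' A variant fails if its HWE P value is below 1e-7, call rate below 0.97,
#' MAF below 0.01 or info score below 0.80 (strict inequalities: boundary
#' values pass).
#'
#' @param qc Data frame from \code{\link{variant_qc}}.
#' @return Logical vector, one flag per variant.
#' @export
variant_qc_pass <- function(qc) {
  qc$hwe_p >= 1e-7 & qc$call_rate >= 0.97 & qc$maf >= 0.01 & qc$info >= 0.80
}

#' Additive single-variant association by ordinary least squares
#'
#' Regresses a residualised trait on the alt-allele dosage over
#' pairwise-complete samples; the slope is the per-allele effect, with a
#' two-sided t-test P value.
#'
#' @param dosage Numeric vector of dosages in [0, 2].
#' @param trait Numeric vector of residualised trait values.
#' @param min_n Minimum number of paired non-missing observations.
#' @return List with \code{beta}, \code{se}, \code{p}, \code{n}.
#' @export
regress_additive <- function(dosage, trait, min_n = 10L) {
  ok <- !is.na(dosage) & !is.na(trait)
  n <- sum(ok)
  if (n < min_n) stop("fewer than ", min_n, " paired non-missing observations")
  x <- dosage[ok]; y <- trait[ok]
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("monomorphic dosage (zero variance)")
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  rss <- sum((y - mean(y) - beta * (x - mean(x)))^2)
  df <- n - 2L
  se <- sqrt(rss / df / sxx)
  tval <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pt(-abs(tval), df), n = n)
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Combines per-platform estimates with weights \code{1/se^2}; the pooled
#' standard error is \code{(sum of weights)^(-1/2)} and the P value comes
#' from the normal approximation.
#'
#' @param results List of association results, each with \code{beta} and
#'   \code{se} (e.g. from \code{\link{regress_additive}}).
#' @return List with \code{beta}, \code{se}, \code{p} and the number of
#'   studies \code{k}.
#' @export
ivw_meta <- function(results) {
  if (length(results) == 0) stop("no association results to combine")
  beta <- vapply(results, `[[`, 0, "beta")
  se <- vapply(results, `[[`, 0, "se")
  if (any(se <= 0)) stop("standard errors must be positive")
  w <- 1 / se^2
  mb <- sum(w * beta) / sum(w)
  ms <- 1 / sqrt(sum(w))
  list(beta = mb, se = ms, p = 2 * stats::pnorm(-abs(mb / ms)),
       k = length(results))
}

#' Cross-platform post-meta-analysis quality control
#'
#' A meta-analysed variant-trait pair passes only if the meta P value is
#' below \code{threshold}, the variant passes platform QC on both platforms,
#' the per-platform effect estimates agree in sign (neither zero), and both
#' per-platform P values are below 0.01. Failure reasons are enumerated.
#'
#' @param meta Data frame (or list) with columns \code{p_meta},
#'   \code{beta_p1}, \code{p_p1}, \code{beta_p2}, \code{p_p2}.
#' @param qc1,qc2 Logical vectors (or scalars) of platform QC pass flags
#'   aligned with the rows of \code{meta}.
#' @param threshold Meta-analysis significance threshold.
#' @return \code{meta} with added columns \code{qc_pass} and
#'   \code{fail_reasons} (semicolon-separated; empty when passing).
#' @export
post_meta_qc <- function(meta, qc1, qc2, threshold) {
  meta <- as.data.frame(meta)
  miss <- is.na(meta$beta_p1) | is.na(meta$beta_p2)
  reasons <- matrix("", nrow(meta), 5)
  reasons[miss, 1] <- "missing platform result"
  reasons[!miss & !(meta$p_meta < threshold), 2] <- "meta p"
  reasons[!(qc1 & qc2), 3] <- "platform qc"
  dir_ok <- !miss & sign(meta$beta_p1) == sign(meta$beta_p2) &
    sign(meta$beta_p1) != 0
  reasons[!miss & !dir_ok, 4] <- "direction"
  pp_ok <- !miss & meta$p_p1 < 0.01 & meta$p_p2 < 0.01
  reasons[!miss & !pp_ok, 5] <- "platform p"
  fail <- apply(reasons, 1, function(r) paste(r[nzchar(r)], collapse = ";"))
  meta$qc_pass <- !nzchar(fail)
  meta$fail_reasons <- fail
  meta
}

#' Genomic inflation factor
#'
#' The median association chi-square (one degree of freedom) divided by its
#' null median, 0.4549364.
#'
#' @param p_values Vector of association P values in (0, 1].
#' @return The inflation factor lambda.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0) stop("no P values supplied")
  stopifnot(all(p_values > 0), all(p_values <= 1))
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

# vectorised per-platform association of every variant against every trait.
# dosage must be complete (imputed panel); traits may contain NA.
# returns m x t matrices beta, se, p, n.
.fast_assoc <- function(dosage, Y) {
  W <- !is.na(Y)
  Y0 <- ifelse(W, Y, 0)
  storage.mode(W) <- "double"
  n_t <- colSums(W)
  Sx <- crossprod(dosage, W)
  Sxx <- crossprod(dosage^2, W)
  Sxy <- crossprod(dosage, Y0)
  Sy <- colSums(Y0)
  Syy <- colSums(Y0^2)
  nmat <- matrix(n_t, nrow(Sx), ncol(Sx), byrow = TRUE)
  Vxx <- Sxx - Sx^2 / nmat
  Vxy <- Sxy - Sx * matrix(Sy / n_t, nrow(Sx), ncol(Sx), byrow = TRUE)
  Vyy <- matrix(Syy - Sy^2 / n_t, nrow(Sx), ncol(Sx), byrow = TRUE)
  beta <- Vxy / Vxx
  dfree <- nmat - 2
  sigma2 <- pmax(Vyy - beta * Vxy, 0) / dfree
  se <- sqrt(sigma2 / Vxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), dfree)
  mono <- Vxx <= 1e-12
  beta[mono] <- NA; se[mono] <- NA; p[mono] <- NA
  list(beta = beta, se = se, p = p, n = nmat)
}

#' Two-platform genome-wide association with meta-analysis and QC
#'
#' Runs additive OLS association of every variant against every trait on
#' each platform, combines the platforms by fixed-effect inverse-variance
#' weighting, and applies cross-platform post-meta QC.
#'
#' @param panels List of two \code{genotype_panel} objects (disjoint
#'   samples, identical variant panel).
#' @param traits A residualised-stage \code{\link{lipid_matrix}} covering
#'   the samples of both panels, or a plain numeric matrix of residualised
#'   trait values with sample rownames.
#' @param threshold Meta-analysis significance threshold (use the standard
#'   genome-wide 5e-8 for ratio traits).
#' @return Data frame of class \code{meta_result} with one row per variant
#'   x trait: per-platform and meta estimates, QC flags and failure
#'   reasons.
#' @export
run_gwas <- function(panels, traits, threshold = 8.929e-10) {
  stopifnot(length(panels) == 2)
  Y <- if (inherits(traits, "lipid_matrix")) traits$values else traits
  stopifnot(is.matrix(Y), !is.null(rownames(Y)))
  qc <- lapply(panels, variant_qc)
  res <- lapply(panels, function(panel) {
    idx <- match(panel$samples, rownames(Y))
    if (anyNA(idx))
      stop("traits missing for samples on ", panel$platform)
    .fast_assoc(panel$dosage, Y[idx, , drop = FALSE])
  })
  m <- ncol(panels[[1]]$dosage)
  t_ <- ncol(Y)
  w1 <- 1 / res[[1]]$se^2
  w2 <- 1 / res[[2]]$se^2
  beta_meta <- (w1 * res[[1]]$beta + w2 * res[[2]]$beta) / (w1 + w2)
  se_meta <- 1 / sqrt(w1 + w2)
  p_meta <- 2 * stats::pnorm(-abs(beta_meta / se_meta))
  vr <- panels[[1]]$variants
  out <- data.frame(
    variant_id = rep(vr$variant_id, times = t_),
    chrom = rep(vr$chrom, times = t_),
    pos = rep(vr$pos, times = t_),
    trait_id = rep(colnames(Y), each = m),
    beta_meta = as.vector(beta_meta),
    se_meta = as.vector(se_meta),
    p_meta = as.vector(p_meta),
    beta_p1 = as.vector(res[[1]]$beta), se_p1 = as.vector(res[[1]]$se),
    p_p1 = as.vector(res[[1]]$p),
    beta_p2 = as.vector(res[[2]]$beta), se_p2 = as.vector(res[[2]]$se),
    p_p2 = as.vector(res[[2]]$p),
    maf = pmin(qc[[1]]$maf, qc[[2]]$maf),
    info_min = pmin(qc[[1]]$info, qc[[2]]$info),
    stringsAsFactors = FALSE)
  out <- post_meta_qc(out,
                      rep(variant_qc_pass(qc[[1]]), times = t_),
                      rep(variant_qc_pass(qc[[2]]), times = t_),
                      threshold)
  attr(out, "threshold") <- threshold
  attr(out, "qc") <- qc
  class(out) <- c("meta_result", "data.frame")
  out
}
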