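#' Lipid intensity matrix
#'
#' A samples-by-lipids matrix with a processing-stage tag. Stages only move
#' forward: \code{raw} -> \code{normalised} -> \code{logged} ->
#' \code{residualised}.
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids),
#'   lipids in columns (colnames = lipid ids). \code{NA} marks missing.
#' @param stage One of \code{"raw"}, \code{"normalised"}, \code{"logged"},
#'   \code{"residualised"}.
#' @return An object of class \code{lipid_matrix}.
#' @export
lipid_matrix <- function(values, stage = "raw") {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  stage <- match.arg(stage, .lipid_stages)
  structure(list(values = values, stage = stage), class = "lipid_matrix")
}

.lipid_stages <- c("raw", "normalised", "logged", "residualised")

.check_stage <- function(m, required) {
  stopifnot(inherits(m, "lipid_matrix"))
  if (m$stage != required)
    stop(sprintf("expected a '%s'-stage lipid matrix, got '%s'", required, m$stage))
}

#' @export
print.lipid_matrix <- function(x, ...) {
  cat(sprintf("lipid_matrix [%s]: %d samples x %d lipids, %.1f%% missing\n",
              x$stage, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.lipid_matrix <- function(x) dim(x$values)

#' Total-signal normalisation
#'
#' Expresses each intensity as a proportion of the subject's total signal:
#' every value is divided by the sum of the subject's non-missing
#' intensities, so the non-missing values of each sample sum to one.
#'
#' @param m A raw-stage \code{\link{lipid_matrix}} with non-negative values.
#' @return A normalised-stage \code{lipid_matrix}.
#' @export
total_signal_normalise <- function(m) {
  .check_stage(m, "raw")
  v <- m$values
  if (any(v < 0, na.rm = TRUE)) stop("raw intensities must be non-negative")
  totals <- rowSums(v, na.rm = TRUE)
  bad <- totals <= 0 | rowSums(!is.na(v)) == 0
  if (any(bad))
    stop("sample(s) with zero total signal: ",
         paste(rownames(v)[bad], collapse = ", "))
  lipid_matrix(v / totals, stage = "normalised")
}

#' Natural-log transformation
#'
#' @param m A normalised-stage \code{\link{lipid_matrix}} with strictly
#'   positive non-missing values.
#' @return A logged-stage \code{lipid_matrix}.
#' @export
log_transform <- function(m) {
  .check_stage(m, "normalised")
  v <- m$values
  nonpos <- colSums(v <= 0, na.rm = TRUE) > 0
  if (any(nonpos))
    stop("non-positive values in lipid(s): ",
         paste(colnames(v)[nonpos], collapse = ", "))
  lipid_matrix(log(v), stage = "logged")
}

#' Filter subjects and lipids by missingness
#'
#' Removes subjects whose fraction of missing lipids strictly exceeds
#' \code{subject_max}, then lipids whose fraction of missing subjects
#' (computed on the remaining subjects) strictly exceeds \code{lipid_max}.
#' Boundary cases (exactly at the threshold) are retained.
#'
#' @param m A \code{\link{lipid_matrix}} at any stage.
#' @param subject_max Maximum tolerated missing fraction per subject.
#' @param lipid_max Maximum tolerated missing fraction per lipid.
#' @return The filtered \code{lipid_matrix} with attribute
#'   \code{"removal_log"}, a list with \code{subjects} and \code{lipids}
#'   removed.
#' @export
filter_missingness <- function(m, subject_max = 0.10, lipid_max = 0.20) {
  stopifnot(inherits(m, "lipid_matrix"),
            subject_max >= 0, subject_max <= 1,
            lipid_max >= 0, lipid_max <= 1)
  v <- m$values
  subj_frac <- rowMeans(is.na(v))
  drop_subj <- subj_frac > subject_max
  v <- v[!drop_subj, , drop = FALSE]
  lip_frac <- colMeans(is.na(v))
  drop_lip <- lip_frac > lipid_max
  v <- v[, !drop_lip, drop = FALSE]
  if (nrow(v) == 0 || ncol(v) == 0)
    stop("missingness filter removed all subjects or all lipids")
  out <- lipid_matrix(v, stage = m$stage)
  attr(out, "removal_log") <- list(
    subjects = rownames(m$values)[drop_subj],
    lipids = colnames(m$values)[drop_lip])
  out
}

.design_matrix <- function(cov, n_pcs) {
  fml <- ~ age_group + sex + batch + fasting
  X <- stats::model.matrix(fml, cov)
  if (n_pcs > 0) {
    pcs <- as.matrix(cov[, paste0("PC", seq_len(n_pcs)), drop = FALSE])
    X <- cbind(X, pcs)
  }
  X
}

#' Residualise lipids on covariates and genetic principal components
#'
#' Fits, per lipid, an ordinary least squares model of the logged lipid on
#' age group, sex, batch, fasting status and the first \code{n_pcs} genetic
#' principal components, and returns the residuals. Missing lipid values
#' propagate as missing.
#'
#' @param m A logged-stage \code{\link{lipid_matrix}}.
#' @param cov Covariate data frame with columns \code{sample_id},
#'   \code{age_group}, \code{sex}, \code{batch}, \code{fasting} and
#'   \code{PC1}, \code{PC2}, ... ; one row per sample, complete.
#' @param n_pcs Number of genetic principal components to adjust for.
#' @return A residualised-stage \code{lipid_matrix}.
#' @export
residualise <- function(m, cov, n_pcs = 6L) {
  .check_stage(m, "logged")
  v <- m$values
  idx <- match(rownames(v), cov$sample_id)
  if (anyNA(idx)) stop("covariates missing for some samples")
  cov <- cov[idx, , drop = FALSE]
  X <- .design_matrix(cov, n_pcs)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  res <- v
  complete <- !is.na(v)
  all_complete <- colSums(!complete) == 0
  if (any(all_complete)) {
    # one QR serves every lipid without missing values
    res[, all_complete] <- qr.resid(qrX, v[, all_complete, drop = FALSE])
  }
  for (j in which(!all_complete)) {
    ok <- complete[, j]
    res[ok, j] <- qr.resid(qr(X[ok, , drop = FALSE]), v[ok, j])
  }
  lipid_matrix(res, stage = "residualised")
}

#' Closed-form multiple-testing threshold
#'
#' Divides a base genome-wide significance level by the number of principal
#' components needed to explain the target fraction of lipid variance.
#'
#' @param n_components Number of principal components.
#' @param base_alpha Base genome-wide significance level.
#' @return The adjusted significance threshold.
#' @export
significance_threshold <- function(n_components, base_alpha = 5e-8) {
  stopifnot(n_components >= 1)
  base_alpha / n_components
}

#' Derive the PCA-based significance threshold
#'
#' Principal component analysis is run on the lipid matrix
#' (correlation-scaled, after per-lipid mean imputation of remaining missing
#' values); the threshold is the base genome-wide level divided by the
#' smallest number of components whose cumulative explained variance exceeds
#' \code{var_target}.
#'
#' @param m A \code{\link{lipid_matrix}} (residualised stage recommended).
#' @param base_alpha Base genome-wide significance level.
#' @param var_target Target fraction of variance to explain.
#' @return A list with \code{n_components}, \code{threshold},
#'   \code{base_alpha}, \code{var_target} and the cumulative explained
#'   variance profile \code{cumvar}.
#' @export
derive_threshold <- function(m, base_alpha = 5e-8, var_target = 0.95) {
  stopifnot(inherits(m, "lipid_matrix"),
            base_alpha > 0, var_target > 0, var_target < 1)
  v <- mean_impute(m$values)
  sds <- apply(v, 2, stats::sd)
  v <- v[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(v, center = TRUE, scale. = TRUE)
  cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cumvar > var_target)[1]
  list(n_components = as.integer(k),
       threshold = significance_threshold(k, base_alpha),
       base_alpha = base_alpha, var_target = var_target, cumvar = cumvar)
}

#' Per-lipid mean imputation
#'
#' @param v Numeric matrix with missing values.
#' @return The matrix with each \code{NA} replaced by its column mean.
#' @export
mean_impute <- function(v) {
  mu <- colMeans(v, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(idx)) v[idx] <- mu[idx[, 2]]
  v
}

#' Log-ratio trait of two lipids
#'
#' Computes \code{log(numerator / denominator)} per sample on the
#' normalised (pre-log) intensity scale; the result is treated downstream
#' exactly like a single logged lipid (residualised with the same model).
#'
#' @param m A normalised-stage \code{\link{lipid_matrix}}.
#' @param numerator,denominator Lipid ids present in \code{m}.
#' @return Named numeric vector (one value per sample); missing whenever
#'   either lipid is missing.
#' @export
compute_ratio <- function(m, numerator, denominator) {
  .check_stage(m, "normalised")
  v <- m$values
  if (!numerator %in% colnames(v)) stop("unknown numerator lipid: ", numerator)
  if (!denominator %in% colnames(v)) stop("unknown denominator lipid: ", denominator)
  den <- v[, denominator]
  if (any(den == 0, na.rm = TRUE))
    stop("zero denominator values for lipid: ", denominator)
  log(v[, numerator] / den)
}
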