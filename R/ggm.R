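#' Shrinkage estimate of the lipid partial-correlation matrix
#'
#' Estimates the correlation matrix with analytic shrinkage toward the
#' identity (Schafer-Strimmer-style intensity chosen to minimise expected
#' squared loss) and converts its inverse to partial correlations:
#' \code{pcor(i,j) = -Omega_ij / sqrt(Omega_ii * Omega_jj)}. Remaining
#' missing values are mean-imputed per lipid before covariance estimation.
#'
#' @param m A \code{\link{lipid_matrix}} (residualised stage recommended)
#'   or plain numeric matrix (samples x lipids).
#' @param lambda Shrinkage intensity in [0, 1]; \code{NULL} (default)
#'   selects it analytically. \code{lambda = 0} gives the classical
#'   inverse-correlation estimate.
#' @return List with \code{pcor} (symmetric, unit diagonal),
#'   \code{lambda}, \code{n} (samples) and \code{p} (lipids).
#' @export
shrunk_partial_correlation <- function(m, lambda = NULL) {
  X <- if (inherits(m, "lipid_matrix")) m$values else m
  stopifnot(is.matrix(X))
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("at least 3 samples required")
  if (p < 2) stop("at least 2 lipids required")
  X <- mean_impute(X)
  Z <- scale(X)  # sd with denominator n-1
  R <- stats::cor(X)
  if (is.null(lambda)) {
    # var-hat of each correlation from the empirical variance of the
    # standardised cross-products w_kij = z_ki * z_kj
    SW2 <- crossprod(Z^2)            # sum_k w_kij^2
    wbar <- (n - 1) / n * R          # mean_k w_kij
    var_r <- n / (n - 1)^3 * (SW2 - n * wbar^2)
    off <- upper.tri(R)
    denom <- sum(R[off]^2)
    lambda <- if (denom > 0) sum(var_r[off]) / denom else 1
    lambda <- min(max(lambda, 0), 1)
  }
  Rs <- (1 - lambda) * R + lambda * diag(p)
  Om <- solve(Rs)
  d <- 1 / sqrt(diag(Om))
  pcor <- -Om * tcrossprod(d)
  diag(pcor) <- 1
  dimnames(pcor) <- dimnames(R)
  list(pcor = pcor, lambda = lambda, n = n, p = p)
}

#' Edge significance by Fisher transformation with FDR control
#'
#' Two-sided P values per lipid pair from the Fisher z-transform of the
#' partial correlation, with effective degrees of freedom
#' \code{n - p - 1} (floored at 3), followed by Benjamini-Hochberg
#' adjustment across all pairs.
#'
#' @param pcor Partial-correlation matrix.
#' @param n Number of samples.
#' @return List with matrices \code{p} and \code{q} (symmetric, diagonal
#'   \code{NA}).
#' @export
edge_q_values <- function(pcor, n) {
  p_ <- ncol(pcor)
  if (n <= p_) warning("fewer samples than lipids; edge tests are unreliable")
  df_eff <- max(n - p_ - 1, 3)
  z <- atanh(pmin(pmax(pcor, -1 + 1e-15), 1 - 1e-15))
  pm <- 2 * stats::pnorm(-abs(z) * sqrt(df_eff))
  diag(pm) <- NA
  off <- upper.tri(pm)
  qv <- stats::p.adjust(pm[off], method = "BH")
  qm <- matrix(NA_real_, p_, p_, dimnames = dimnames(pcor))
  qm[off] <- qv
  qm[lower.tri(qm)] <- t(qm)[lower.tri(qm)]
  pm[lower.tri(pm)] <- t(pm)[lower.tri(pm)]
  list(p = pm, q = qm)
}

#' Build the lipid Gaussian graphical model edge set
#'
#' Retains lipid pairs whose partial-correlation q value is at most
#' \code{fdr} and whose absolute partial correlation exceeds
#' \code{min_abs_pcor}.
#'
#' @param m A \code{\link{lipid_matrix}} that has passed
#'   \code{\link{filter_missingness}} (or a plain matrix).
#' @param fdr FDR cutoff.
#' @param min_abs_pcor Minimum absolute partial correlation for an edge.
#' @param lambda Optional fixed shrinkage intensity (see
#'   \code{\link{shrunk_partial_correlation}}).
#' @return Object of class \code{lipid_ggm}: list with \code{edges} (data
#'   frame \code{lipid_a}, \code{lipid_b}, \code{pcor}, \code{q}; pairs
#'   stored once with \code{lipid_a < lipid_b}), \code{pcor} and \code{q}
#'   matrices, \code{lambda} and \code{n}.
#' @export
build_ggm <- function(m, fdr = 0.05, min_abs_pcor = 0.2, lambda = NULL) {
  est <- shrunk_partial_correlation(m, lambda = lambda)
  sig <- edge_q_values(est$pcor, est$n)
  off <- which(upper.tri(est$pcor), arr.ind = TRUE)
  keep <- sig$q[upper.tri(est$pcor)] <= fdr &
    abs(est$pcor[upper.tri(est$pcor)]) > min_abs_pcor
  keep[is.na(keep)] <- FALSE
  ids <- colnames(est$pcor)
  a <- ids[off[keep, 1]]; b <- ids[off[keep, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  edges <- data.frame(lipid_a = a, lipid_b = b,
                      pcor = est$pcor[off[keep, , drop = FALSE]],
                      q = sig$q[off[keep, , drop = FALSE]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$lipid_a, edges$lipid_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, pcor = est$pcor, q = sig$q,
                 lambda = est$lambda, n = est$n,
                 fdr = fdr, min_abs_pcor = min_abs_pcor),
            class = "lipid_ggm")
}

#' @export
print.lipid_ggm <- function(x, ...) {
  cat(sprintf("Lipid GGM: %d nodes, %d edges (q <= %g, |pcor| > %g), lambda = %.4f, n = %d\n",
              ncol(x$pcor), nrow(x$edges), x$fdr, x$min_abs_pcor,
              x$lambda, x$n))
  invisible(x)
}
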