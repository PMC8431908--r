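#' Assign variants to fixed 5-Mb chunks
#'
#' Tiles each chromosome with non-overlapping half-open windows
#' \code{[1, 1+size)}, \code{[1+size, 1+2*size)}, ... anchored at position 1,
#' and maps every variant to exactly one chunk.
#'
#' @param variants Data frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}.
#' @param chunk_size Chunk width in base pairs.
#' @return Data frame with columns \code{chunk_id}, \code{chrom},
#'   \code{start}, \code{end} (half-open), \code{variant_id}.
#' @export
assign_chunks <- function(variants, chunk_size = 5e6) {
  idx <- (variants$pos - 1) %/% chunk_size
  start <- idx * chunk_size + 1
  data.frame(chunk_id = sprintf("chr%s:%d-%d", variants$chrom, start,
                                start + chunk_size),
             chrom = variants$chrom,
             start = start,
             end = start + chunk_size,
             variant_id = variants$variant_id,
             stringsAsFactors = FALSE)
}

# Frisch-Waugh-Lovell projection: residualise y (vector/matrix) on [1, C]
.project_out <- function(y, C = NULL) {
  X <- if (is.null(C)) matrix(1, NROW(y), 1) else cbind(1, C)
  qr.resid(qr(X), y)
}

#' Stepwise conditional association within one chunk
#'
#' Starting from the chunk's lead variant (smallest meta-analysis P value),
#' repeatedly adds the current lead to the conditioning set, re-runs the
#' per-platform regressions of the trait on each remaining variant with the
#' selected dosages as covariates, meta-analyses the two platforms, and
#' stops when no conditional meta P value remains below \code{threshold}.
#' Forward selection only; previously selected variants are never removed.
#'
#' @param trait_id Trait (lipid or ratio) identifier.
#' @param variant_ids Variants belonging to the chunk.
#' @param panels List of two \code{genotype_panel} objects.
#' @param traits Residualised \code{\link{lipid_matrix}} (or matrix).
#' @param threshold Conditional significance threshold (the same
#'   meta-analysis threshold at every step).
#' @return Data frame with one row per accepted step: \code{trait_id},
#'   \code{step}, \code{variant_id}, \code{beta}, \code{se}, \code{p}.
#'   Zero rows when no variant is significant unconditionally.
#' @export
stepwise_conditional <- function(trait_id, variant_ids, panels, traits,
                                 threshold) {
  Y <- if (inherits(traits, "lipid_matrix")) traits$values else traits
  ys <- lapply(panels, function(p) Y[match(p$samples, rownames(Y)), trait_id])
  Xs <- lapply(panels, function(p) p$dosage[, variant_ids, drop = FALSE])
  selected <- character(0)
  steps <- list()
  repeat {
    cand <- setdiff(variant_ids, selected)
    if (length(cand) == 0) break
    stats_pf <- lapply(seq_along(panels), function(i) {
      y <- ys[[i]]
      ok <- !is.na(y)
      y <- y[ok]
      C <- Xs[[i]][ok, selected, drop = FALSE]
      yr <- .project_out(y, if (length(selected)) C else NULL)
      Xr <- .project_out(Xs[[i]][ok, cand, drop = FALSE],
                         if (length(selected)) C else NULL)
      k <- length(selected)
      n <- length(y)
      sxx <- colSums(Xr^2)
      keep <- sxx > 1e-8
      if (any(!keep))
        warning("dropping collinear candidate(s): ",
                paste(cand[!keep], collapse = ", "))
      beta <- colSums(Xr * yr) / sxx
      dfree <- n - 2 - k
      rss <- sum(yr^2) - beta^2 * sxx
      se <- sqrt(pmax(rss, 0) / dfree / sxx)
      p <- 2 * stats::pt(-abs(beta / se), dfree)
      p[!keep] <- NA
      list(beta = beta, se = se, p = p)
    })
    w1 <- 1 / stats_pf[[1]]$se^2
    w2 <- 1 / stats_pf[[2]]$se^2
    bm <- (w1 * stats_pf[[1]]$beta + w2 * stats_pf[[2]]$beta) / (w1 + w2)
    sm <- 1 / sqrt(w1 + w2)
    pm <- 2 * stats::pnorm(-abs(bm / sm))
    pm[is.na(stats_pf[[1]]$p) | is.na(stats_pf[[2]]$p)] <- NA
    if (all(is.na(pm)) || min(pm, na.rm = TRUE) >= threshold) break
    lead <- which.min(pm)
    steps[[length(steps) + 1]] <- data.frame(
      trait_id = trait_id, step = length(steps) + 1L,
      variant_id = cand[lead], beta = bm[lead], se = sm[lead], p = pm[lead],
      stringsAsFactors = FALSE)
    selected <- c(selected, cand[lead])
  }
  if (length(steps)) do.call(rbind, steps) else
    data.frame(trait_id = character(), step = integer(),
               variant_id = character(), beta = numeric(), se = numeric(),
               p = numeric(), stringsAsFactors = FALSE)
}

#' Conditional dissection of all significant regions
#'
#' Selects the QC-passing significant variant-trait pairs from a
#' meta-analysis table, identifies the 5-Mb chunks containing them, and runs
#' \code{\link{stepwise_conditional}} per trait and chunk.
#'
#' @param meta A \code{meta_result} table from \code{\link{run_gwas}}.
#' @param panels List of two \code{genotype_panel} objects.
#' @param traits Residualised \code{\link{lipid_matrix}} (or matrix).
#' @param threshold Significance threshold (defaults to the one recorded in
#'   \code{meta}).
#' @param chunk_size Chunk width in base pairs.
#' @return Data frame of conditionally independent sentinels with columns
#'   \code{trait_id}, \code{chunk_id}, \code{step}, \code{variant_id},
#'   \code{chrom}, \code{pos}, \code{beta}, \code{se}, \code{p}.
#' @export
conditional_analysis <- function(meta, panels, traits,
                                 threshold = attr(meta, "threshold"),
                                 chunk_size = 5e6) {
  sig <- meta[meta$qc_pass, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(trait_id = character(), chunk_id = character(),
                      step = integer(), variant_id = character(),
                      chrom = integer(), pos = integer(), beta = numeric(),
                      se = numeric(), p = numeric(), stringsAsFactors = FALSE))
  vr <- panels[[1]]$variants
  chunks <- assign_chunks(vr, chunk_size)
  sig$chunk_id <- chunks$chunk_id[match(sig$variant_id, chunks$variant_id)]
  jobs <- unique(sig[, c("trait_id", "chunk_id")])
  out <- lapply(seq_len(nrow(jobs)), function(i) {
    members <- chunks$variant_id[chunks$chunk_id == jobs$chunk_id[i]]
    s <- stepwise_conditional(jobs$trait_id[i], members, panels, traits,
                              threshold)
    if (nrow(s)) s$chunk_id <- jobs$chunk_id[i]
    s
  })
  res <- do.call(rbind, out[vapply(out, nrow, 0L) > 0])
  if (is.null(res)) res <- data.frame(trait_id = character(),
                                      step = integer(),
                                      variant_id = character(),
                                      beta = numeric(), se = numeric(),
                                      p = numeric(), chunk_id = character(),
                                      stringsAsFactors = FALSE)
  res$chrom <- vr$chrom[match(res$variant_id, vr$variant_id)]
  res$pos <- vr$pos[match(res$variant_id, vr$variant_id)]
  rownames(res) <- NULL
  res
}

#' Cluster sentinel variants into loci
#'
#' Single-linkage clustering per chromosome: sentinels are sorted by
#' position and a new locus starts whenever the gap to the previous
#' sentinel exceeds \code{window}.
#'
#' @param sentinels Data frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos} (duplicated variants are collapsed).
#' @param window Maximum gap in base pairs joining two sentinels into one
#'   locus.
#' @return Data frame with columns \code{locus_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{n_members}, \code{members}
#'   (semicolon-separated variant ids).
#' @export
cluster_loci <- function(sentinels, window = 5e5) {
  s <- unique(sentinels[, c("variant_id", "chrom", "pos")])
  if (nrow(s) == 0)
    return(data.frame(locus_id = character(), chrom = integer(),
                      start = integer(), end = integer(),
                      n_members = integer(), members = character(),
                      stringsAsFactors = FALSE))
  s <- s[order(s$chrom, s$pos), , drop = FALSE]
  new_locus <- c(TRUE, diff(s$pos) > window | diff(as.integer(factor(s$chrom))) != 0)
  grp <- cumsum(new_locus)
  out <- do.call(rbind, lapply(split(s, grp), function(g)
    data.frame(chrom = g$chrom[1], start = min(g$pos), end = max(g$pos),
               n_members = nrow(g),
               members = paste(g$variant_id, collapse = ";"),
               stringsAsFactors = FALSE)))
  out$locus_id <- sprintf("locus%02d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("locus_id", "chrom", "start", "end", "n_members", "members")]
}

#' Cross-cohort locus replication
#'
#' Counts how many discovery loci have at least one replication locus on
#' the same chromosome within \code{window} base pairs (interval distance),
#' and returns the replicated fraction as a percentage.
#'
#' @param discovery,replication Locus tables from \code{\link{cluster_loci}}.
#' @param window Maximum distance in base pairs.
#' @return List with \code{n_discovery}, \code{n_replicated} and
#'   \code{percent}.
#' @export
locus_replication <- function(discovery, replication, window = 5e5) {
  hit <- vapply(seq_len(nrow(discovery)), function(i) {
    same <- replication[replication$chrom == discovery$chrom[i], , drop = FALSE]
    if (nrow(same) == 0) return(FALSE)
    gap <- pmax(same$start - discovery$end[i], discovery$start[i] - same$end, 0)
    any(gap <= window)
  }, TRUE)
  list(n_discovery = nrow(discovery), n_replicated = sum(hit),
       percent = 100 * sum(hit) / nrow(discovery))
}

#' Variance in a trait explained by sentinel variants
#'
#' Multiple-regression R-squared of the residualised trait on all sentinel
#' dosages jointly; collinear dosages are handled by a pivoted fit with a
#' warning.
#'
#' @param trait Numeric vector of residualised trait values.
#' @param dosages Numeric matrix of sentinel dosages (samples x sentinels).
#' @return R-squared in [0, 1].
#' @export
variance_explained <- function(trait, dosages) {
  dosages <- as.matrix(dosages)
  stopifnot(ncol(dosages) >= 1)
  ok <- !is.na(trait) & rowSums(is.na(dosages)) == 0
  y <- trait[ok]; X <- dosages[ok, , drop = FALSE]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1)
    warning("collinear sentinel dosages; using pivoted least squares")
  res <- qr.resid(qrX, y)
  tss <- sum((y - mean(y))^2)
  1 - sum(res^2) / tss
}

#' Sensitivity re-analysis with clinical lipid adjustment
#'
#' Re-estimates a variant-trait association with clinical lipid measures
#' (e.g. total cholesterol, HDL-C, triglycerides) appended to the
#' covariate model, and reports the attenuation of the effect estimate.
#'
#' @param trait Numeric vector of residualised trait values (already
#'   adjusted for the standard covariates).
#' @param dosage Numeric dosage vector.
#' @param clinical Data frame or matrix of clinical measures aligned with
#'   \code{trait}.
#' @return List with \code{beta} (unadjusted), \code{beta_adj},
#'   \code{se_adj}, \code{p_adj} and \code{attenuation}
#'   (\code{beta_adj / beta}).
#' @export
adjust_clinical <- function(trait, dosage, clinical) {
  C <- as.matrix(clinical)
  if (any(is.na(C))) stop("missing values in clinical measures")
  if (any(apply(C, 2, stats::sd) == 0))
    stop("zero-variance clinical covariate")
  base <- regress_additive(dosage, trait)
  ok <- !is.na(dosage) & !is.na(trait)
  yr <- .project_out(trait[ok], C[ok, , drop = FALSE])
  xr <- .project_out(dosage[ok], C[ok, , drop = FALSE])
  n <- sum(ok); k <- ncol(C)
  sxx <- sum(xr^2)
  beta_adj <- sum(xr * yr) / sxx
  rss <- sum((yr - beta_adj * xr)^2)
  dfree <- n - 2 - k
  se_adj <- sqrt(rss / dfree / sxx)
  list(beta = base$beta, beta_adj = beta_adj, se_adj = se_adj,
       p_adj = 2 * stats::pt(-abs(beta_adj / se_adj), dfree),
       attenuation = beta_adj / base$beta)
}
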