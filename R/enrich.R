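#' Bipartite lipid-to-label incidence matrix
#'
#' @param annot Data frame with columns \code{lipid_id} and a label column
#'   (\code{chain} by default); one row per lipid-label pair.
#' @param lipids Optional character vector fixing the row set and order.
#' @param label_col Name of the label column.
#' @return Binary incidence matrix (lipids x labels).
#' @export
chain_incidence <- function(annot, lipids = NULL, label_col = "chain") {
  if (is.null(lipids)) lipids <- unique(annot$lipid_id)
  labels <- sort(unique(annot[[label_col]]))
  M <- matrix(0L, length(lipids), length(labels),
              dimnames = list(lipids, labels))
  idx <- cbind(match(annot$lipid_id, lipids), match(annot[[label_col]], labels))
  idx <- idx[!is.na(idx[, 1]) & !is.na(idx[, 2]), , drop = FALSE]
  M[idx] <- 1L
  M
}

#' Count network edges per unordered annotation-label pair
#'
#' For each edge, every distinct unordered pair formed by one label of each
#' endpoint is counted once (a lipid carrying several fatty-acyl chains
#' contributes one count per chain-pair combination).
#'
#' @param edges Data frame with columns \code{lipid_a}, \code{lipid_b}
#'   (e.g. the \code{edges} element of a \code{lipid_ggm}).
#' @param incidence Binary incidence matrix from
#'   \code{\link{chain_incidence}} covering every edge endpoint.
#' @return Named integer vector of counts over all unordered label pairs
#'   ("X|Y" with X <= Y).
#' @export
count_pair_edges <- function(edges, incidence) {
  labs <- colnames(incidence)
  miss <- setdiff(unique(c(edges$lipid_a, edges$lipid_b)), rownames(incidence))
  if (length(miss))
    stop("unannotated lipid(s): ", paste(miss, collapse = ", "))
  bad <- rownames(incidence)[rowSums(incidence) == 0]
  bad <- intersect(bad, c(edges$lipid_a, edges$lipid_b))
  if (length(bad))
    stop("unannotated lipid(s): ", paste(bad, collapse = ", "))
  A <- incidence[edges$lipid_a, , drop = FALSE]
  B <- incidence[edges$lipid_b, , drop = FALSE]
  pairs <- .label_pairs(labs)
  counts <- integer(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    hit <- if (i == j) A[, i] * B[, i] else
      pmin(A[, i] * B[, j] + A[, j] * B[, i], 1)
    counts[k] <- sum(hit)
  }
  names(counts) <- paste(labs[pairs[, 1]], labs[pairs[, 2]], sep = "|")
  counts
}

.label_pairs <- function(labs) {
  k <- length(labs)
  idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Degree-preserving rewiring of a bipartite annotation
#'
#' Randomises a binary lipid-by-label incidence matrix by repeated
#' checkerboard swaps (pick two incidence ones at distinct rows and
#' columns; if the opposite corners are empty, exchange them), which
#' preserves every row sum and every column sum exactly. The number of
#' attempted swaps is ten times the number of ones.
#'
#' @param incidence Binary incidence matrix.
#' @param n_swaps Number of attempted swaps (default \code{10 * sum(incidence)}).
#' @return A rewired incidence matrix with identical margins. If no valid
#'   swap exists the input is returned unchanged with a warning.
#' @export
rewire_annotation <- function(incidence, n_swaps = 10L * sum(incidence)) {
  M <- incidence
  ones <- which(M == 1L, arr.ind = TRUE)
  K <- nrow(ones)
  if (K < 2 || nrow(unique(ones[, 1, drop = FALSE])) < 2 ||
      nrow(unique(ones[, 2, drop = FALSE])) < 2) {
    warning("degenerate incidence; no rewiring possible")
    return(M)
  }
  i1 <- sample.int(K, n_swaps, replace = TRUE)
  i2 <- sample.int(K, n_swaps, replace = TRUE)
  for (s in seq_len(n_swaps)) {
    a <- i1[s]; b <- i2[s]
    r1 <- ones[a, 1L]; c1 <- ones[a, 2L]
    r2 <- ones[b, 1L]; c2 <- ones[b, 2L]
    if (r1 == r2 || c1 == c2) next
    if (M[r1, c2] == 0L && M[r2, c1] == 0L) {
      M[r1, c1] <- 0L; M[r2, c2] <- 0L
      M[r1, c2] <- 1L; M[r2, c1] <- 1L
      ones[a, 2L] <- c2
      ones[b, 2L] <- c1
    }
  }
  M
}

#' Permutation test of edge enrichment by annotation pair
#'
#' Compares observed per-pair edge counts with a null distribution obtained
#' by rewiring the annotation (degree-preserving checkerboard swaps for
#' multi-label annotations, or label permutation when
#' \code{single_label = TRUE}) while keeping the edge set fixed. Empirical
#' P values are add-one smoothed: \code{p_enrich = (1 + #(null >= obs)) /
#' (n_perm + 1)} and symmetrically for depletion, so they are never zero.
#'
#' @param edges Edge data frame (\code{lipid_a}, \code{lipid_b}).
#' @param incidence Binary incidence matrix covering all endpoints.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for reproducibility.
#' @param single_label If \code{TRUE} the annotation assigns exactly one
#'   label per lipid and the null permutes the label vector (preserving
#'   label frequencies) instead of checkerboard rewiring.
#' @return Data frame of class \code{enrichment_result} with columns
#'   \code{pair}, \code{observed}, \code{null_mean}, \code{null_sd},
#'   \code{p_enrich}, \code{p_deplete}.
#' @export
permutation_enrichment <- function(edges, incidence, n_perm = 1000L,
                                   seed = 1L, single_label = FALSE) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  obs <- count_pair_edges(edges, incidence)
  set.seed(seed)
  ge <- le <- integer(length(obs))
  s1 <- s2 <- numeric(length(obs))
  for (b in seq_len(n_perm)) {
    Mb <- if (single_label) {
      perm <- incidence[sample.int(nrow(incidence)), , drop = FALSE]
      rownames(perm) <- rownames(incidence)
      perm
    } else rewire_annotation(incidence)
    cnt <- count_pair_edges(edges, Mb)
    ge <- ge + (cnt >= obs)
    le <- le + (cnt <= obs)
    s1 <- s1 + cnt
    s2 <- s2 + cnt^2
  }
  out <- data.frame(pair = names(obs), observed = as.integer(obs),
                    null_mean = s1 / n_perm,
                    null_sd = sqrt(pmax(s2 / n_perm - (s1 / n_perm)^2, 0)),
                    p_enrich = (1 + ge) / (n_perm + 1),
                    p_deplete = (1 + le) / (n_perm + 1),
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "n_perm") <- n_perm
  out
}

#' Subclass over/under-representation of network edges
#'
#' Applies the permutation machinery with the lipid subclass as a
#' single-label annotation: the null permutes subclass labels across
#' lipids, preserving subclass sizes. Pairs with \code{p_enrich <= alpha}
#' are flagged over-represented and pairs with \code{p_deplete <= alpha}
#' under-represented.
#'
#' @param edges Edge data frame (\code{lipid_a}, \code{lipid_b}).
#' @param subclass Data frame with columns \code{lipid_id}, \code{subclass}
#'   (exactly one subclass per lipid).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param alpha Flagging threshold.
#' @return An \code{enrichment_result} data frame with an added
#'   \code{flag} column (\code{"over"}, \code{"under"} or \code{""}).
#' @export
subclass_representation <- function(edges, subclass, n_perm = 1000L,
                                    seed = 1L, alpha = 0.05) {
  if (anyDuplicated(subclass$lipid_id))
    stop("each lipid must have exactly one subclass")
  M <- chain_incidence(subclass, label_col = "subclass")
  out <- permutation_enrichment(edges, M, n_perm = n_perm, seed = seed,
                                single_label = TRUE)
  out$flag <- ifelse(out$p_enrich <= alpha, "over",
                     ifelse(out$p_deplete <= alpha, "under", ""))
  out
}
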