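# distance from a position to a gene interval (0 if inside)
.gene_distance <- function(pos, start, end) pmax(start - pos, pos - end, 0)

#' Nearest protein-coding gene to a variant
#'
#' Minimal distance from the variant position to the gene interval (zero
#' when the variant lies inside the gene). Ties are broken by smaller gene
#' start, then lexicographic symbol.
#'
#' @param chrom,pos Variant chromosome and 1-based position.
#' @param genes Gene model data frame: \code{symbol}, \code{chrom},
#'   \code{start}, \code{end}, \code{biotype}.
#' @return One-row data frame: the nearest protein-coding gene with its
#'   \code{distance}.
#' @export
nearest_gene <- function(chrom, pos, genes) {
  g <- genes[genes$chrom == chrom & genes$biotype == "protein_coding", ,
             drop = FALSE]
  if (nrow(g) == 0)
    stop("no protein-coding gene on chromosome ", chrom)
  g$distance <- .gene_distance(pos, g$start, g$end)
  g <- g[order(g$distance, g$start, g$symbol), , drop = FALSE]
  g[1, c("symbol", "chrom", "start", "end", "biotype", "distance")]
}

.eqtl_tissues <- c("subcutaneous adipose", "visceral adipose", "liver",
                   "whole blood")
.nonsyn_consequences <- c("missense_variant", "stop_gained", "stop_lost",
                          "start_lost", "inframe_insertion",
                          "inframe_deletion")

#' Bottom-up functional evidence for a variant
#'
#' Collects variant-centric evidence linking the variant to proximal genes:
#' residing in an exonic sequence, residing in a splice site (within 2 bp
#' of an intron-exon boundary), high LD (r-squared at least 0.8) with a
#' non-synonymous variant, or acting as a cis-eQTL in subcutaneous adipose,
#' visceral adipose, liver or whole blood.
#'
#' @param variant_id Variant identifier.
#' @param consequences Data frame \code{variant_id}, \code{gene},
#'   \code{consequence} (VEP-style terms; splice sites annotated as
#'   \code{splice_acceptor_variant}/\code{splice_donor_variant}/
#'   \code{splice_site}).
#' @param ld Data frame \code{variant_a}, \code{variant_b}, \code{r2}.
#' @param eqtl Data frame \code{variant_id}, \code{gene}, \code{tissue}.
#' @return Data frame \code{variant_id}, \code{gene}, \code{category},
#'   \code{detail}; zero rows when no condition is met.
#' @export
bottom_up <- function(variant_id, consequences, ld, eqtl) {
  ev <- list()
  own <- consequences[consequences$variant_id == variant_id, , drop = FALSE]
  exonic <- own[own$consequence %in% c(.nonsyn_consequences,
                                       "synonymous_variant",
                                       "exonic_variant"), , drop = FALSE]
  if (nrow(exonic))
    ev[[length(ev) + 1]] <- data.frame(variant_id = variant_id,
                                       gene = exonic$gene,
                                       category = "exonic",
                                       detail = exonic$consequence,
                                       stringsAsFactors = FALSE)
  splice <- own[grepl("splice", own$consequence), , drop = FALSE]
  if (nrow(splice))
    ev[[length(ev) + 1]] <- data.frame(variant_id = variant_id,
                                       gene = splice$gene,
                                       category = "splice_site",
                                       detail = splice$consequence,
                                       stringsAsFactors = FALSE)
  prox <- ld[(ld$variant_a == variant_id | ld$variant_b == variant_id) &
               ld$r2 >= 0.8, , drop = FALSE]
  if (nrow(prox)) {
    proxies <- ifelse(prox$variant_a == variant_id,
                      prox$variant_b, prox$variant_a)
    pc <- consequences[consequences$variant_id %in% proxies &
                         consequences$consequence %in% .nonsyn_consequences, ,
                       drop = FALSE]
    if (nrow(pc)) {
      r2 <- prox$r2[match(pc$variant_id, proxies)]
      ev[[length(ev) + 1]] <- data.frame(
        variant_id = variant_id, gene = pc$gene,
        category = "ld_nonsynonymous",
        detail = sprintf("%s (r2=%.2f)", pc$variant_id, r2),
        stringsAsFactors = FALSE)
    }
  }
  eq <- eqtl[eqtl$variant_id == variant_id &
               eqtl$tissue %in% .eqtl_tissues, , drop = FALSE]
  if (nrow(eq))
    ev[[length(ev) + 1]] <- data.frame(variant_id = variant_id,
                                       gene = eq$gene,
                                       category = "cis_eqtl",
                                       detail = eq$tissue,
                                       stringsAsFactors = FALSE)
  if (length(ev)) unique(do.call(rbind, ev)) else
    data.frame(variant_id = character(), gene = character(),
               category = character(), detail = character(),
               stringsAsFactors = FALSE)
}

#' Top-down knowledge-base evidence for a variant
#'
#' Scores all genes within 500 kb of the variant by membership in five
#' lipid-related gene-set databases (one point each; genes in at least two
#' databases are recurrent candidates) and records compound-specific
#' matches where a gene's subclass tags intersect the lipid subclasses
#' associated with the variant.
#'
#' @param chrom,pos Variant chromosome and position.
#' @param genes Gene model data frame.
#' @param genesets Named list of five data frames, each with a \code{gene}
#'   column.
#' @param compound Data frame \code{subclass}, \code{gene}: the
#'   compound-specific subclass-to-gene table.
#' @param associated_subclasses Character vector of lipid subclasses the
#'   variant is associated with.
#' @param max_dist Maximum distance from variant to gene interval edge.
#' @return Data frame \code{gene}, \code{distance}, \code{score},
#'   \code{recurrent}, \code{compound_match} plus one logical column per
#'   database.
#' @export
top_down <- function(chrom, pos, genes, genesets, compound,
                     associated_subclasses = character(0),
                     max_dist = 5e5) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  g$distance <- .gene_distance(pos, g$start, g$end)
  g <- g[g$distance <= max_dist, , drop = FALSE]
  out <- data.frame(gene = g$symbol, distance = g$distance,
                    stringsAsFactors = FALSE)
  for (db in names(genesets))
    out[[db]] <- out$gene %in% genesets[[db]]$gene
  flags <- as.matrix(out[, names(genesets), drop = FALSE])
  out$score <- as.integer(rowSums(flags))
  out$recurrent <- out$score >= 2L
  cm <- compound[compound$subclass %in% associated_subclasses, , drop = FALSE]
  out$compound_match <- out$gene %in% cm$gene
  out[order(-out$score, out$distance, out$gene), , drop = FALSE]
}

#' Hierarchical integration of candidate-gene evidence
#'
#' Applies the prioritisation hierarchy: (1) genes carrying both bottom-up
#' and top-down evidence; else (2) genes with a compound-specific subclass
#' match; else (3) the highest-scoring top-down gene(s) (score at least 1)
#' together with all bottom-up genes; else (4) the nearest protein-coding
#' gene. Each rule fires only when all earlier rules produced no gene.
#'
#' @param bottom Bottom-up evidence from \code{\link{bottom_up}}.
#' @param top Top-down evidence from \code{\link{top_down}}.
#' @param nearest One-row data frame from \code{\link{nearest_gene}}.
#' @return List with \code{genes} (non-empty character vector),
#'   \code{rule} (one of \code{intersection}, \code{compound_specific},
#'   \code{top_score_plus_bottom_up}, \code{nearest_fallback}) and
#'   \code{nearest} (symbol, always reported).
#' @export
integrate_evidence <- function(bottom, top, nearest) {
  bu <- unique(bottom$gene)
  td <- top$gene[top$score >= 1L]
  both <- intersect(bu, td)
  if (length(both))
    return(list(genes = sort(both), rule = "intersection",
                nearest = nearest$symbol))
  cmp <- top$gene[top$compound_match]
  if (length(cmp))
    return(list(genes = sort(unique(cmp)), rule = "compound_specific",
                nearest = nearest$symbol))
  cand <- character(0)
  if (length(td)) {
    best <- max(top$score[top$score >= 1L])
    cand <- top$gene[top$score == best]
  }
  cand <- sort(unique(c(cand, bu)))
  if (length(cand))
    return(list(genes = cand, rule = "top_score_plus_bottom_up",
                nearest = nearest$symbol))
  list(genes = nearest$symbol, rule = "nearest_fallback",
       nearest = nearest$symbol)
}

#' Prioritise candidate causal genes for sentinel variants
#'
#' Runs the full hierarchy (\code{\link{bottom_up}}, \code{\link{top_down}},
#' \code{\link{integrate_evidence}}) for each sentinel variant.
#'
#' @param sentinels Data frame with \code{variant_id}, \code{chrom},
#'   \code{pos}.
#' @param fixtures An \code{annotation_fixtures} list (or any list with
#'   elements \code{genes}, \code{consequences}, \code{ld}, \code{eqtl},
#'   \code{genesets}, \code{compound}).
#' @param associated_subclasses Named list mapping variant id to the
#'   character vector of associated lipid subclasses.
#' @return Data frame of class \code{causal_assignment}: \code{variant_id},
#'   \code{assigned_genes} (semicolon-separated), \code{rule},
#'   \code{nearest_gene}.
#' @export
prioritise_genes <- function(sentinels, fixtures,
                             associated_subclasses = list()) {
  rows <- lapply(seq_len(nrow(sentinels)), function(i) {
    vid <- sentinels$variant_id[i]
    near <- nearest_gene(sentinels$chrom[i], sentinels$pos[i], fixtures$genes)
    bu <- bottom_up(vid, fixtures$consequences, fixtures$ld, fixtures$eqtl)
    td <- top_down(sentinels$chrom[i], sentinels$pos[i], fixtures$genes,
                   fixtures$genesets, fixtures$compound,
                   associated_subclasses[[vid]] %||% character(0))
    res <- integrate_evidence(bu, td, near)
    data.frame(variant_id = vid,
               assigned_genes = paste(res$genes, collapse = ";"),
               rule = res$rule, nearest_gene = res$nearest,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("causal_assignment", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Splice-site membership from exon boundaries
#'
#' A variant is a splice-site variant when it lies within \code{margin}
#' base pairs of an intron-exon boundary.
#'
#' @param pos Variant position(s).
#' @param boundaries Positions of intron-exon boundaries.
#' @param margin Window in base pairs on either side of a boundary.
#' @return Logical vector, one value per position.
#' @export
is_splice_site <- function(pos, boundaries, margin = 2L) {
  vapply(pos, function(p) any(abs(p - boundaries) <= margin), TRUE)
}

#' Concordance of predicted causal genes with ground truth
#'
#' @param assignments A \code{causal_assignment} data frame.
#' @param truth Data frame \code{variant_id}, \code{gene} (the true causal
#'   gene per variant).
#' @return List with per-variant \code{hits} data frame and overall
#'   \code{concordance} fraction.
#' @export
validate_against_truth <- function(assignments, truth) {
  m <- merge(assignments, truth, by = "variant_id")
  m$hit <- mapply(function(genes, g)
    g %in% strsplit(genes, ";", fixed = TRUE)[[1]],
    m$assigned_genes, m$gene)
  list(hits = m[, c("variant_id", "assigned_genes", "rule", "gene", "hit")],
       concordance = mean(m$hit))
}
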