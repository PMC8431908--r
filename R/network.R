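#' Combined gene / lipid-subclass network
#'
#' Assembles the subclass-level summary network: nodes are genes (or locus
#' ids where no single confident causal gene exists) and lipid subclasses;
#' an association edge joins a gene to a subclass when at least one
#' QC-passing significant association links a variant assigned to that gene
#' with at least one lipid of the subclass; signed representation edges
#' join subclass pairs flagged over- or under-represented in the GGM; and
#' functional-interaction edges join gene pairs from a user-supplied
#' interaction table.
#'
#' @param assignments \code{causal_assignment} data frame.
#' @param meta \code{meta_result} table (only \code{qc_pass} rows are
#'   used).
#' @param annotation Lipid annotation data frame (\code{lipid_id},
#'   \code{subclass}).
#' @param representation Optional \code{enrichment_result} from
#'   \code{\link{subclass_representation}} with a \code{flag} column.
#' @param interactions Optional data frame \code{gene_a}, \code{gene_b}.
#' @param loci Optional locus table (from \code{\link{cluster_loci}});
#'   needed to label multi-gene loci by locus id.
#' @return An \code{igraph} object with vertex attribute \code{type}
#'   (\code{gene_or_locus} / \code{lipid_subclass}) and edge attributes
#'   \code{type}, \code{sign}, \code{magnitude}.
#' @export
build_full_network <- function(assignments, meta, annotation,
                               representation = NULL, interactions = NULL,
                               loci = NULL) {
  sig <- meta[meta$qc_pass, , drop = FALSE]
  node_label <- .gene_node_labels(assignments, loci)
  sub_of <- stats::setNames(annotation$subclass, annotation$lipid_id)

  g <- igraph::make_empty_graph(directed = FALSE)
  subclasses <- sort(unique(annotation$subclass))
  g <- igraph::add_vertices(g, length(subclasses), name = subclasses,
                            type = "lipid_subclass")

  assoc_edges <- NULL
  if (nrow(sig)) {
    lab <- node_label[sig$variant_id]
    known <- !is.na(lab)
    if (any(!known))
      sig <- sig[known, , drop = FALSE]
    lab <- lab[known]
    sc <- sub_of[sig$trait_id]
    ok <- !is.na(sc)
    assoc_edges <- unique(data.frame(from = lab[ok], to = sc[ok],
                                     stringsAsFactors = FALSE))
  }
  gene_nodes <- if (!is.null(assoc_edges)) sort(unique(assoc_edges$from))
    else character(0)
  if (length(gene_nodes))
    g <- igraph::add_vertices(g, length(gene_nodes), name = gene_nodes,
                              type = "gene_or_locus")
  if (!is.null(assoc_edges) && nrow(assoc_edges))
    g <- igraph::add_edges(g,
                           as.vector(rbind(assoc_edges$from, assoc_edges$to)),
                           type = "association", sign = NA_character_,
                           magnitude = NA_real_)
  if (!is.null(representation)) {
    rep_sig <- representation[representation$flag != "", , drop = FALSE]
    for (i in seq_len(nrow(rep_sig))) {
      pr <- strsplit(rep_sig$pair[i], "|", fixed = TRUE)[[1]]
      if (!all(pr %in% subclasses) || pr[1] == pr[2]) next
      z <- (rep_sig$observed[i] - rep_sig$null_mean[i]) /
        max(rep_sig$null_sd[i], 1e-9)
      g <- igraph::add_edges(g, pr, type = "ggm_representation",
                             sign = rep_sig$flag[i], magnitude = abs(z))
    }
  }
  if (!is.null(interactions) && nrow(interactions)) {
    keep <- interactions$gene_a %in% gene_nodes &
      interactions$gene_b %in% gene_nodes
    ia <- interactions[keep, , drop = FALSE]
    if (nrow(ia))
      g <- igraph::add_edges(g, as.vector(rbind(ia$gene_a, ia$gene_b)),
                             type = "functional_interaction",
                             sign = NA_character_, magnitude = NA_real_)
  }
  g
}

# one label per variant: its single confident assigned gene, otherwise its
# locus id (or a variant-derived label when no locus table is given)
.gene_node_labels <- function(assignments, loci = NULL) {
  lab <- vapply(seq_len(nrow(assignments)), function(i) {
    genes <- strsplit(assignments$assigned_genes[i], ";", fixed = TRUE)[[1]]
    if (length(genes) == 1) return(genes)
    vid <- assignments$variant_id[i]
    if (!is.null(loci)) {
      hit <- vapply(strsplit(loci$members, ";", fixed = TRUE),
                    function(m) vid %in% m, TRUE)
      if (any(hit)) return(loci$locus_id[which(hit)[1]])
    }
    paste0("locus_", vid)
  }, "")
  stats::setNames(lab, assignments$variant_id)
}

#' Species-level subnetwork for selected subclasses
#'
#' Restricts the network to individual lipid species of the given
#' subclasses, connects them by their GGM partial-correlation edges, and
#' adds gene-to-species association edges.
#'
#' @param meta \code{meta_result} table.
#' @param ggm A \code{lipid_ggm} object.
#' @param annotation Lipid annotation data frame.
#' @param subclass_filter Non-empty character vector of subclasses to keep.
#' @param assignments \code{causal_assignment} data frame.
#' @param loci Optional locus table.
#' @return An \code{igraph} object with vertex types
#'   \code{gene_or_locus} / \code{lipid_species} and edge types
#'   \code{association} / \code{partial_correlation} (attribute
#'   \code{pcor}).
#' @export
build_species_subnetwork <- function(meta, ggm, annotation, subclass_filter,
                                     assignments, loci = NULL) {
  if (length(subclass_filter) == 0) stop("empty subclass filter")
  unknown <- setdiff(subclass_filter, annotation$subclass)
  if (length(unknown))
    stop("unknown subclass(es): ", paste(unknown, collapse = ", "))
  species <- annotation$lipid_id[annotation$subclass %in% subclass_filter]
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(species), name = species,
                            type = "lipid_species")
  e <- ggm$edges[ggm$edges$lipid_a %in% species &
                   ggm$edges$lipid_b %in% species, , drop = FALSE]
  if (nrow(e))
    g <- igraph::add_edges(g, as.vector(rbind(e$lipid_a, e$lipid_b)),
                           type = "partial_correlation", pcor = e$pcor)
  sig <- meta[meta$qc_pass & meta$trait_id %in% species, , drop = FALSE]
  if (nrow(sig)) {
    lab <- .gene_node_labels(assignments, loci)[sig$variant_id]
    ok <- !is.na(lab)
    ae <- unique(data.frame(from = lab[ok], to = sig$trait_id[ok],
                            stringsAsFactors = FALSE))
    genes <- sort(unique(ae$from))
    g <- igraph::add_vertices(g, length(genes), name = genes,
                              type = "gene_or_locus")
    if (nrow(ae))
      g <- igraph::add_edges(g, as.vector(rbind(ae$from, ae$to)),
                             type = "association",
                             pcor = NA_real_)
  }
  g
}

#' Export a network to SIF or GraphML
#'
#' SIF is a lossy three-column format (source, edge type, target); GraphML
#' preserves all node and edge attributes and round-trips losslessly via
#' \code{\link{import_network}}.
#'
#' @param net An \code{igraph} object.
#' @param path Output file path.
#' @param format \code{"sif"} or \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    el <- igraph::as_edgelist(net)
    type <- igraph::edge_attr(net, "type")
    if (is.null(type)) type <- rep("edge", nrow(el))
    lines <- sprintf("%s\t%s\t%s", el[, 1], type, el[, 2])
    writeLines(lines, path)
  } else {
    igraph::write_graph(net, path, format = "graphml")
  }
  invisible(path)
}

#' Import a GraphML network
#'
#' @param path GraphML file written by \code{\link{export_network}}.
#' @return An \code{igraph} object.
#' @export
import_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
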