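# TSV conventions: tab-separated, header row, "NA" for missing.

#' Write a lipid matrix as TSV
#'
#' Samples as rows with a leading \code{sample_id} column, lipid ids as the
#' remaining column headers.
#'
#' @param m A \code{\link{lipid_matrix}}.
#' @param path Output path.
#' @export
write_lipid_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a lipid matrix from TSV
#'
#' @param path TSV written by \code{\link{write_lipid_tsv}}.
#' @param stage Processing stage of the stored values.
#' @return A \code{\link{lipid_matrix}}.
#' @export
read_lipid_tsv <- function(path, stage = "raw") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$sample_id
  lipid_matrix(v, stage = stage)
}

#' Write a genotype panel as a dosage TSV
#'
#' Variants as rows (columns \code{variant_id}, \code{chrom}, \code{pos},
#' \code{ref}, \code{alt}, \code{info}, then one dosage column per sample).
#'
#' @param panel A \code{genotype_panel}.
#' @param path Output path.
#' @export
write_dosage_tsv <- function(panel, path) {
  df <- cbind(panel$variants[, c("variant_id", "chrom", "pos", "ref", "alt",
                                 "info")],
              as.data.frame(t(panel$dosage), check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype panel from a dosage TSV
#'
#' @param path TSV written by \code{\link{write_dosage_tsv}}.
#' @param platform Platform identifier for the panel.
#' @return A \code{genotype_panel}.
#' @export
read_dosage_tsv <- function(path, platform = "platform1") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("variant_id", "chrom", "pos", "ref", "alt", "info")
  dosage <- t(as.matrix(df[, setdiff(colnames(df), meta_cols), drop = FALSE]))
  colnames(dosage) <- df$variant_id
  structure(list(platform = platform, samples = rownames(dosage),
                 variants = df[, meta_cols], dosage = dosage),
            class = "genotype_panel")
}

#' Write a genotype panel as VCF with a DS (dosage) FORMAT field
#'
#' Minimal VCFv4.2 with INFO field \code{INFO} (imputation info score) and
#' per-sample \code{GT:DS} (hard-call genotype from rounded dosage, plus
#' the dosage itself).
#'
#' @param panel A \code{genotype_panel}.
#' @param path Output path (plain text, uncompressed).
#' @export
write_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation info score\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$samples), collapse = "\t")),
             con)
  v <- panel$variants
  g <- round(panel$dosage)
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1], nrow(g), ncol(g))
  for (j in seq_len(nrow(v))) {
    fields <- sprintf("%s:%.4g", gt[, j], panel$dosage[, j])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j],
                       v$alt[j], ".", "PASS",
                       sprintf("INFO=%.4g", v$info[j]), "GT:DS", fields),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read dosages from a VCF
#'
#' Uses the DS FORMAT field when present, otherwise the alt-allele count
#' from GT. Requires the \pkg{vcfR} package.
#'
#' @param path VCF file path.
#' @param platform Platform identifier for the returned panel.
#' @return A \code{genotype_panel}.
#' @export
read_vcf_dosages <- function(path, platform = "platform1") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  fmt <- strsplit(vcf@gt[1, 1], ":", fixed = TRUE)[[1]]
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- matrix(vapply(gsub("[|]", "/", gt), function(x)
      sum(as.integer(strsplit(x, "/", fixed = TRUE)[[1]])), 0),
      nrow(gt), ncol(gt), dimnames = dimnames(gt))
  }
  info <- suppressWarnings(as.numeric(sub(".*INFO=([0-9.eE+-]+).*", "\\1",
                                          fix$INFO)))
  info[is.na(info)] <- 1
  dosage <- t(ds)
  colnames(dosage) <- fix$ID
  structure(list(platform = platform, samples = rownames(dosage),
                 variants = data.frame(variant_id = fix$ID,
                                       chrom = as.integer(fix$CHROM),
                                       pos = as.integer(fix$POS),
                                       ref = fix$REF, alt = fix$ALT,
                                       info = info,
                                       stringsAsFactors = FALSE),
                 dosage = dosage),
            class = "genotype_panel")
}

#' Write annotation fixture tables as TSV files
#'
#' One TSV per table (\code{genes.tsv}, \code{consequences.tsv},
#' \code{ld.tsv}, \code{eqtl.tsv}, \code{db1.tsv}..\code{db5.tsv},
#' \code{compound.tsv}, \code{interactions.tsv}, \code{causal_genes.tsv}).
#'
#' @param fixtures An \code{annotation_fixtures} list.
#' @param dir Output directory (created if absent).
#' @export
write_fixture_tsvs <- function(fixtures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(fixtures$genes, "genes")
  wt(fixtures$consequences, "consequences")
  wt(fixtures$ld, "ld")
  wt(fixtures$eqtl, "eqtl")
  for (db in names(fixtures$genesets)) wt(fixtures$genesets[[db]], db)
  wt(fixtures$compound, "compound")
  wt(fixtures$interactions, "interactions")
  wt(fixtures$causal_genes, "causal_genes")
  invisible(dir)
}
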