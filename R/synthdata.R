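#' Simulation configuration for a synthetic lipidomics-GWAS cohort
#'
#' Describes a two-platform cohort with planted lipid quantitative trait
#' loci (QTLs), block-correlated lipid subclasses, small covariate effects
#' and missing-completely-at-random measurements. The configuration plus its
#' seed fully determine the generated cohort.
#'
#' @param n_samples_per_platform Number of subjects genotyped on each of the
#'   two platforms (disjoint sample sets, identical variant panel).
#' @param n_variants Number of autosomal variants, split across two
#'   chromosomes.
#' @param n_lipids Number of lipid species measured.
#' @param n_subclasses Number of lipid subclasses (at most 14); lipids are
#'   assigned to subclasses in contiguous blocks.
#' @param planted_qtls List of planted genetic effects, each a list with
#'   elements \code{variant} (variant index), \code{lipids} (integer vector
#'   of lipid indices) and \code{beta} (additive effect per alt allele, in
#'   standard-deviation units of the log-scale lipid trait).
#' @param lipid_block_correlation Within-subclass latent-factor correlation
#'   in [0, 1): lipids of one subclass share a latent factor with loading
#'   \code{sqrt(lipid_block_correlation)}.
#' @param lipid_neighbor_correlation Extra variance share contributed by a
#'   latent factor shared between consecutive lipids within a subclass
#'   block, emulating the strong coupling of adjacent species (e.g. one
#'   double-bond apart) seen in lipidomics data; gives adjacent pairs a
#'   partial correlation that survives conditioning on the rest of the
#'   block. Requires \code{lipid_block_correlation +
#'   2 * lipid_neighbor_correlation < 1}.
#' @param missing_rate_subjects Fraction of subjects with elevated dropout
#'   (their measurements are additionally missing with probability 0.15),
#'   emulating poor-quality samples.
#' @param missing_rate_lipids Baseline probability that any single lipid
#'   measurement is missing (MCAR).
#' @param maf_range Interval within (0, 0.5] from which per-variant minor
#'   allele frequencies are drawn uniformly.
#' @param genotype_blur Probability mass \code{eps} moved from each hard
#'   genotype call onto neighbouring genotype classes, emulating imputation
#'   uncertainty; 0 gives hard calls with info score 1.
#' @param covariate_effect_sd Standard deviation of the random per-lipid
#'   covariate effects (kept small so residualisation matters but does not
#'   dominate).
#' @param seed Integer seed; identical configurations with identical seeds
#'   generate byte-identical cohorts.
#'
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_samples_per_platform = 2000L,
                       n_variants = 20000L,
                       n_lipids = 60L,
                       n_subclasses = 6L,
                       planted_qtls = list(),
                       lipid_block_correlation = 0.3,
                       lipid_neighbor_correlation = 0.25,
                       missing_rate_subjects = 0.02,
                       missing_rate_lipids = 0.02,
                       maf_range = c(0.05, 0.5),
                       genotype_blur = 0,
                       covariate_effect_sd = 0.05,
                       seed = 1L) {
  stopifnot(n_samples_per_platform >= 1, n_variants >= 1, n_lipids >= 1,
            n_subclasses >= 1, n_subclasses <= 14,
            lipid_block_correlation >= 0, lipid_block_correlation < 1,
            lipid_neighbor_correlation >= 0,
            lipid_block_correlation + 2 * lipid_neighbor_correlation < 1,
            missing_rate_subjects >= 0, missing_rate_subjects < 1,
            missing_rate_lipids >= 0, missing_rate_lipids < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            genotype_blur >= 0, genotype_blur < 1)
  for (q in planted_qtls) {
    if (!all(c("variant", "lipids", "beta") %in% names(q)))
      stop("each planted QTL needs elements 'variant', 'lipids', 'beta'")
    if (!all(is.finite(q$beta))) stop("planted effect sizes must be finite")
    if (q$variant < 1 || q$variant > n_variants)
      stop("planted QTL variant index out of range: ", q$variant)
    if (any(q$lipids < 1) || any(q$lipids > n_lipids))
      stop("planted QTL lipid index out of range for variant ", q$variant)
  }
  structure(list(n_samples_per_platform = as.integer(n_samples_per_platform),
                 n_variants = as.integer(n_variants),
                 n_lipids = as.integer(n_lipids),
                 n_subclasses = as.integer(n_subclasses),
                 planted_qtls = planted_qtls,
                 lipid_block_correlation = lipid_block_correlation,
                 lipid_neighbor_correlation = lipid_neighbor_correlation,
                 missing_rate_subjects = missing_rate_subjects,
                 missing_rate_lipids = missing_rate_lipids,
                 maf_range = maf_range,
                 genotype_blur = genotype_blur,
                 covariate_effect_sd = covariate_effect_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# subclass labels used in order; first n_subclasses are taken
.subclass_pool <- c("TG", "DG", "SM", "PC", "PE", "PI",
                    "PA", "CE", "Cer", "LPC", "LPE", "PG", "PS", "FA")
.chain_pool <- c("16:0", "16:1", "18:0", "18:1", "18:2", "20:4", "22:6")

#' Generate a synthetic two-platform lipidomics cohort
#'
#' Draws genotypes per variant as binomial(2, maf) for two disjoint sample
#' sets sharing one variant panel, builds log-scale lipid traits as the sum
#' of a subclass latent factor, planted additive genetic effects, small
#' covariate effects and independent noise, exponentiates onto a positive
#' intensity scale (log-normal), and injects missingness.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list of class \code{lipid_cohort} with elements
#'   \code{panels} (two \code{genotype_panel} objects), \code{lipids}
#'   (raw-stage \code{\link{lipid_matrix}}), \code{annotation} (lipid
#'   annotation data frame), \code{covariates}, \code{clinical} (total
#'   cholesterol, HDL-C and triglyceride measures derived from the lipid
#'   traits plus noise), \code{truth} (planted QTLs, causal genes, subclass
#'   and chain ground truth) and the \code{config}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples_per_platform
  m <- config$n_variants
  L <- config$n_lipids
  K <- config$n_subclasses

  ## variant panel (shared by both platforms)
  chrom <- rep(1:2, length.out = m)[order(rep(1:2, length.out = m))]
  n1 <- sum(chrom == 1)
  pos <- c(sort(sample.int(1.2e8, n1)), sort(sample.int(1.2e8, m - n1)))
  variant_id <- sprintf("var%05d_chr%d_%d", seq_len(m), chrom, pos)
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  alleles <- matrix(sample(c("A", "C", "G", "T"), 2 * m, replace = TRUE), ncol = 2)
  same <- alleles[, 1] == alleles[, 2]
  alleles[same, 2] <- ifelse(alleles[same, 1] == "A", "G", "A")

  eps <- config$genotype_blur
  make_panel <- function(platform, prefix) {
    samples <- sprintf("%s_S%05d", prefix, seq_len(n))
    g <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m)
    # imputation-uncertainty blur: mass eps moved onto neighbouring classes
    dosage <- g + eps * (g == 0) - eps * (g == 2)
    post_var <- eps * (1 - eps) * (g != 1) + eps * (g == 1)
    phat <- colMeans(dosage) / 2
    denom <- 2 * phat * (1 - phat)
    info <- ifelse(denom > 0, 1 - colMeans(post_var) / denom, 0)
    info <- pmin(pmax(info, 0), 1)
    dimnames(dosage) <- list(samples, variant_id)
    structure(list(platform = platform,
                   samples = samples,
                   variants = data.frame(variant_id = variant_id,
                                         chrom = chrom, pos = pos,
                                         ref = alleles[, 1], alt = alleles[, 2],
                                         maf_true = maf, info = info,
                                         stringsAsFactors = FALSE),
                   dosage = dosage),
              class = "genotype_panel")
  }
  panels <- list(make_panel("platform1", "P1"), make_panel("platform2", "P2"))

  all_samples <- c(panels[[1]]$samples, panels[[2]]$samples)
  N <- 2L * n

  ## lipid annotation and ground truth
  subclass_labels <- .subclass_pool[seq_len(K)]
  subclass <- subclass_labels[cut(seq_len(L), K, labels = FALSE)]
  lipid_id <- sprintf("%s(%d)", subclass, stats::ave(seq_len(L), subclass, FUN = seq_along))
  n_chains <- sample(1:3, L, replace = TRUE)
  chains <- lapply(n_chains, function(k) sort(sample(.chain_pool, k)))
  chain_cd <- lapply(chains, function(ch) {
    cd <- do.call(rbind, lapply(strsplit(ch, ":"), as.integer))
    colSums(cd)
  })
  annotation <- data.frame(
    lipid_id = lipid_id,
    subclass = subclass,
    ion_mode = sample(c("positive", "negative"), L, replace = TRUE),
    mz = round(stats::runif(L, 400, 950), 4),
    chains = vapply(chains, paste, "", collapse = ";"),
    total_c = vapply(chain_cd, function(x) as.integer(x[1]), 0L),
    total_db = vapply(chain_cd, function(x) as.integer(x[2]), 0L),
    stringsAsFactors = FALSE)

  ## covariates (small planted effects) and genetic PCs
  covariates <- data.frame(
    sample_id = all_samples,
    age_group = factor(sample(paste0("age", 1:5), N, replace = TRUE)),
    sex = factor(sample(c("F", "M"), N, replace = TRUE)),
    batch = factor(sample(paste0("plate", 1:8), N, replace = TRUE)),
    fasting = factor(sample(c("fasted", "nonfasted"), N, replace = TRUE,
                            prob = c(0.25, 0.75))),
    stringsAsFactors = FALSE)
  for (j in 1:6) covariates[[paste0("PC", j)]] <- stats::rnorm(N)

  ## log-scale lipid traits
  rho <- config$lipid_block_correlation
  tau <- config$lipid_neighbor_correlation
  Fct <- matrix(stats::rnorm(N * K), N, K)  # subclass latent factors
  sub_idx <- match(subclass, subclass_labels)
  Z <- sqrt(rho) * Fct[, sub_idx, drop = FALSE]
  # neighbour factors couple consecutive lipids within a subclass block
  nb_load <- integer(L)
  if (tau > 0) {
    nb_pairs <- which(sub_idx[-L] == sub_idx[-1])  # pair (l, l+1)
    if (length(nb_pairs)) {
      G <- matrix(stats::rnorm(N * length(nb_pairs)), N, length(nb_pairs))
      for (k in seq_along(nb_pairs)) {
        l <- nb_pairs[k]
        Z[, l] <- Z[, l] + sqrt(tau) * G[, k]
        Z[, l + 1L] <- Z[, l + 1L] + sqrt(tau) * G[, k]
        nb_load[l] <- nb_load[l] + 1L
        nb_load[l + 1L] <- nb_load[l + 1L] + 1L
      }
    }
  }
  resid_var <- pmax(1 - rho - nb_load * tau, 0.05)
  Z <- Z + matrix(stats::rnorm(N * L), N, L) %*% diag(sqrt(resid_var), L)
  # planted additive genetic effects
  dos_all <- rbind(panels[[1]]$dosage, panels[[2]]$dosage)
  for (q in config$planted_qtls)
    Z[, q$lipids] <- Z[, q$lipids] + q$beta * dos_all[, q$variant]
  # small covariate effects
  D <- stats::model.matrix(~ age_group + sex + batch + fasting +
                             PC1 + PC2 + PC3 + PC4 + PC5 + PC6,
                           covariates)[, -1, drop = FALSE]
  B <- matrix(stats::rnorm(ncol(D) * L, 0, config$covariate_effect_sd), ncol(D), L)
  Z <- Z + D %*% B

  ## positive intensity scale: heterogeneous log-normal baselines
  mu <- stats::rnorm(L, 8, 0.5)
  values <- exp(sweep(Z, 2, mu, `+`))
  dimnames(values) <- list(all_samples, lipid_id)

  ## clinical lipid measures as linear combinations of lipid traits + noise
  pick <- function(k) rowMeans(Z[, sub_idx == k, drop = FALSE])
  clinical <- data.frame(
    sample_id = all_samples,
    total_chol = 0.6 * rowMeans(Z) + 0.8 * stats::rnorm(N),
    hdl_c = 0.5 * pick(min(K, 3)) + 0.9 * stats::rnorm(N),
    triglycerides = 0.8 * pick(1L) + 0.6 * stats::rnorm(N),
    stringsAsFactors = FALSE)

  ## missingness: baseline MCAR plus elevated-dropout subjects
  miss <- matrix(stats::runif(N * L) < config$missing_rate_lipids, N, L)
  bad <- stats::runif(N) < config$missing_rate_subjects
  if (any(bad))
    miss[bad, ] <- miss[bad, ] | matrix(stats::runif(sum(bad) * L) < 0.15, sum(bad), L)
  values[miss] <- NA_real_

  truth <- list(
    qtls = do.call(rbind, c(list(data.frame(variant_id = character(),
                                            lipid_id = character(),
                                            beta = numeric())),
                            lapply(config$planted_qtls, function(q)
                              data.frame(variant_id = variant_id[q$variant],
                                         lipid_id = lipid_id[q$lipids],
                                         beta = q$beta,
                                         stringsAsFactors = FALSE)))),
    subclass = data.frame(lipid_id = lipid_id, subclass = subclass,
                          stringsAsFactors = FALSE),
    chains = data.frame(lipid_id = rep(lipid_id, n_chains),
                        chain = unlist(chains), stringsAsFactors = FALSE))

  structure(list(panels = panels,
                 lipids = lipid_matrix(values, stage = "raw"),
                 annotation = annotation,
                 covariates = covariates,
                 clinical = clinical,
                 truth = truth,
                 config = config),
            class = "lipid_cohort")
}

#' @export
print.lipid_cohort <- function(x, ...) {
  cat("Synthetic lipidomics cohort\n")
  cat(sprintf("  %d samples x 2 platforms, %d variants, %d lipids (%d subclasses)\n",
              x$config$n_samples_per_platform, x$config$n_variants,
              x$config$n_lipids, x$config$n_subclasses))
  cat(sprintf("  %d planted QTL effect(s), seed %d\n",
              nrow(x$truth$qtls), x$config$seed))
  invisible(x)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel '%s': %d samples x %d variants\n",
              x$platform, nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Generate annotation fixture databases with known causal genes
#'
#' Builds the fixture tables consumed by the gene-prioritisation stage:
#' gene models, a variant-consequence table, a pairwise LD table, a
#' cis-eQTL table, five lipid-related gene-set tables (\code{db1}..\code{db5}),
#' a compound-specific subclass-to-gene table and a gene-gene functional
#' interaction table. All tables are synthetic. For every planted variant
#' the ground-truth causal gene is made discoverable through one designated
#' evidence path (cycled across variants: exonic, cis-eQTL,
#' compound-specific, top-down recurrent score, nearest-gene fallback,
#' LD-proxy non-synonymous), recorded in \code{truth$causal_genes}.
#'
#' @param cohort A \code{lipid_cohort} from \code{\link{generate_cohort}}
#'   (carries the variant panel the fixtures must be consistent with).
#' @return A list of class \code{annotation_fixtures} with the tables above;
#'   the cohort's truth table gains a \code{causal_genes} data frame.
#' @export
generate_annotation_fixtures <- function(cohort) {
  stopifnot(inherits(cohort, "lipid_cohort"))
  config <- cohort$config
  set.seed(config$seed + 104729L)  # independent stream from the cohort draw
  variants <- cohort$panels[[1]]$variants
  planted <- unique(vapply(config$planted_qtls, `[[`, 0L, "variant"))
  paths <- c("exonic", "cis_eqtl", "compound_specific",
             "top_down_recurrent", "nearest_fallback", "ld_nonsynonymous")

  genes <- list(); consequences <- list(); ld <- list(); eqtl <- list()
  genesets <- stats::setNames(rep(list(character(0)), 5), paste0("db", 1:5))
  compound <- list(); causal <- list()
  add_gene <- function(symbol, chrom, start, end, biotype = "protein_coding")
    genes[[length(genes) + 1]] <<- data.frame(symbol = symbol, chrom = chrom,
                                              start = start, end = end,
                                              biotype = biotype,
                                              stringsAsFactors = FALSE)

  for (i in seq_along(planted)) {
    v <- planted[i]
    vid <- variants$variant_id[v]
    vchrom <- variants$chrom[v]
    vpos <- variants$pos[v]
    path <- paths[(i - 1L) %% length(paths) + 1L]
    truth_gene <- sprintf("LQTL%d", i)
    decoy1 <- sprintf("DEC%dA", i)
    decoy2 <- sprintf("DEC%dB", i)
    far <- sprintf("FAR%d", i)

    # truth gene near the variant; covers it only for the exonic/splice paths
    if (path %in% c("exonic", "ld_nonsynonymous"))
      add_gene(truth_gene, vchrom, vpos - 5000L, vpos + 5000L)
    else
      add_gene(truth_gene, vchrom, vpos + 20000L, vpos + 60000L)
    # decoys inside the 500-kb window (one non-coding), one gene beyond it
    add_gene(decoy1, vchrom, vpos + 150000L, vpos + 180000L)
    add_gene(decoy2, vchrom, vpos - 300000L, vpos - 250000L, biotype = "lincRNA")
    add_gene(far, vchrom, vpos + 600000L, vpos + 650000L)

    # nearest-fallback variants must have a closer protein-coding decoy
    # carrying no other evidence, so the fallback itself is exercised
    sub_assoc <- unique(cohort$truth$subclass$subclass[
      match(cohort$truth$qtls$lipid_id[cohort$truth$qtls$variant_id == vid],
            cohort$truth$subclass$lipid_id)])

    if (path == "exonic") {
      consequences[[length(consequences) + 1]] <-
        data.frame(variant_id = vid, gene = truth_gene,
                   consequence = "missense_variant", stringsAsFactors = FALSE)
      genesets$db1 <- c(genesets$db1, truth_gene)       # rule 1: intersection
    } else if (path == "cis_eqtl") {
      eqtl[[length(eqtl) + 1]] <-
        data.frame(variant_id = vid, gene = truth_gene, tissue = "liver",
                   stringsAsFactors = FALSE)
      genesets$db2 <- c(genesets$db2, truth_gene)       # rule 1: intersection
      # off-whitelist tissue evidence for a decoy must be ignored
      eqtl[[length(eqtl) + 1]] <-
        data.frame(variant_id = vid, gene = decoy1, tissue = "skeletal muscle",
                   stringsAsFactors = FALSE)
    } else if (path == "compound_specific") {
      compound[[length(compound) + 1]] <-
        data.frame(subclass = sub_assoc, gene = truth_gene,
                   stringsAsFactors = FALSE)
    } else if (path == "top_down_recurrent") {
      genesets$db1 <- c(genesets$db1, truth_gene)       # score 2, recurrent
      genesets$db3 <- c(genesets$db3, truth_gene)
      genesets$db4 <- c(genesets$db4, decoy1)           # score 1, outranked
    } else if (path == "ld_nonsynonymous") {
      proxy <- sprintf("proxy%d_chr%d_%d", i, vchrom, vpos + 1000L)
      ld[[length(ld) + 1]] <-
        data.frame(variant_a = vid, variant_b = proxy, r2 = 0.92,
                   stringsAsFactors = FALSE)
      consequences[[length(consequences) + 1]] <-
        data.frame(variant_id = proxy, gene = truth_gene,
                   consequence = "missense_variant", stringsAsFactors = FALSE)
      genesets$db5 <- c(genesets$db5, truth_gene)       # rule 1: intersection
    }
    # nearest_fallback: no annotation at all; truth gene is the nearest
    # protein-coding gene by construction (20 kb vs 150 kb decoy)

    causal[[length(causal) + 1]] <-
      data.frame(variant_id = vid, gene = truth_gene, path = path,
                 stringsAsFactors = FALSE)
  }

  gene_df <- if (length(genes)) do.call(rbind, genes) else
    data.frame(symbol = character(), chrom = integer(), start = integer(),
               end = integer(), biotype = character())
  bind0 <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  interactions <- if (length(causal) >= 2) {
    syms <- vapply(causal, `[[`, "", "gene")
    data.frame(gene_a = syms[-length(syms)], gene_b = syms[-1],
               stringsAsFactors = FALSE)
  } else data.frame(gene_a = character(), gene_b = character())

  structure(list(
    genes = gene_df,
    consequences = bind0(consequences,
                         data.frame(variant_id = character(), gene = character(),
                                    consequence = character())),
    ld = bind0(ld, data.frame(variant_a = character(), variant_b = character(),
                              r2 = numeric())),
    eqtl = bind0(eqtl, data.frame(variant_id = character(), gene = character(),
                                  tissue = character())),
    genesets = lapply(genesets, function(g)
      data.frame(gene = unique(g), stringsAsFactors = FALSE)),
    compound = bind0(compound, data.frame(subclass = character(),
                                          gene = character())),
    interactions = interactions,
    causal_genes = bind0(causal, data.frame(variant_id = character(),
                                            gene = character(),
                                            path = character()))),
    class = "annotation_fixtures")
}
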