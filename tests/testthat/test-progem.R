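toy_genes <- data.frame(
  symbol = c("NEAR", "TIE_A", "TIE_B", "NC", "CODING", "OTHERCHR"),
  chrom = c(1, 1, 1, 1, 1, 2),
  start = c(100, 5000, 6000, 50000, 52000, 100),
  end = c(200, 5500, 6500, 50100, 52100, 200),
  biotype = c("protein_coding", "protein_coding", "protein_coding",
              "lincRNA", "protein_coding", "protein_coding"),
  stringsAsFactors = FALSE)

test_that("nearest gene uses interval distance, biotype and documented tie-breaks", {
  inside <- nearest_gene(1, 150, toy_genes)
  expect_equal(inside$symbol, "NEAR")
  expect_equal(inside$distance, 0)
  # equidistant between TIE_A end (5500) and TIE_B start (6000): pos 5750
  tie <- nearest_gene(1, 5750, toy_genes)
  expect_equal(tie$symbol, "TIE_A")   # smaller start wins
  # the non-coding NC gene is closer to 50200 than CODING, but is skipped
  near_nc <- nearest_gene(1, 50200, toy_genes)
  expect_equal(near_nc$symbol, "CODING")
  expect_error(nearest_gene(3, 100, toy_genes), "chromosome")
})

test_that("bottom-up evidence respects consequence, LD and tissue rules", {
  cons <- data.frame(
    variant_id = c("v1", "proxy_hi", "proxy_lo", "v2"),
    gene = c("G1", "G2", "G3", "G4"),
    consequence = c("missense_variant", "missense_variant",
                    "missense_variant", "splice_acceptor_variant"),
    stringsAsFactors = FALSE)
  ld <- data.frame(variant_a = c("v1", "v1"),
                   variant_b = c("proxy_hi", "proxy_lo"),
                   r2 = c(0.80, 0.79))
  eqtl <- data.frame(variant_id = c("v1", "v1"),
                     gene = c("G5", "G6"),
                     tissue = c("liver", "skeletal muscle"),
                     stringsAsFactors = FALSE)
  ev <- bottom_up("v1", cons, ld, eqtl)
  expect_setequal(ev$gene[ev$category == "exonic"], "G1")
  # r2 = 0.80 exactly is included, 0.79 is not
  expect_setequal(ev$gene[ev$category == "ld_nonsynonymous"], "G2")
  # only whitelisted tissues count
  expect_setequal(ev$gene[ev$category == "cis_eqtl"], "G5")
  ev2 <- bottom_up("v2", cons, ld, eqtl)
  expect_true("splice_site" %in% ev2$category)
  ev3 <- bottom_up("v_none", cons, ld, eqtl)
  expect_equal(nrow(ev3), 0)
})

test_that("splice-site membership uses the two-base-pair margin", {
  boundaries <- c(1000, 2000)
  expect_true(is_splice_site(1002, boundaries))
  expect_true(is_splice_site(998, boundaries))
  expect_false(is_splice_site(1003, boundaries))
  expect_false(is_splice_site(997, boundaries))
  expect_equal(is_splice_site(c(2000, 2003), boundaries), c(TRUE, FALSE))
})

test_that("top-down scoring applies the 500-kb window and recurrence rule", {
  genes <- data.frame(
    symbol = c("IN_EDGE", "OUT_EDGE", "RECUR", "SINGLE"),
    chrom = 1,
    start = c(1499999, 1500001, 900000, 910000) + 1e6,
    end = c(1599999, 1600001, 950000, 960000) + 1e6,
    biotype = "protein_coding", stringsAsFactors = FALSE)
  pos <- 1e6 + 1e6  # gene IN_EDGE starts exactly 499,999 bp away
  gs <- list(db1 = data.frame(gene = c("RECUR", "SINGLE")),
             db2 = data.frame(gene = "RECUR"),
             db3 = data.frame(gene = character(0)),
             db4 = data.frame(gene = character(0)),
             db5 = data.frame(gene = character(0)))
  cmp <- data.frame(subclass = "TG", gene = "RECUR")
  td <- top_down(1, pos, genes, gs, cmp, associated_subclasses = "TG")
  expect_true("IN_EDGE" %in% td$gene)
  expect_false("OUT_EDGE" %in% td$gene)
  expect_equal(td$score[td$gene == "RECUR"], 2L)
  expect_true(td$recurrent[td$gene == "RECUR"])
  expect_equal(td$score[td$gene == "SINGLE"], 1L)
  expect_false(td$recurrent[td$gene == "SINGLE"])
  expect_true(td$compound_match[td$gene == "RECUR"])
  # no compound match when the variant's subclasses do not intersect
  td2 <- top_down(1, pos, genes, gs, cmp, associated_subclasses = "SM")
  expect_false(any(td2$compound_match))
})

test_that("evidence integration is strictly hierarchical", {
  nearest <- data.frame(symbol = "NEAREST")
  bu <- data.frame(variant_id = "v", gene = c("G", "C"),
                   category = "exonic", detail = "")
  td <- data.frame(gene = c("G", "A", "B"), distance = 0,
                   score = c(1L, 4L, 2L), recurrent = c(FALSE, TRUE, TRUE),
                   compound_match = c(FALSE, FALSE, FALSE))
  r1 <- integrate_evidence(bu, td, nearest)
  expect_equal(r1$genes, "G")
  expect_equal(r1$rule, "intersection")

  td2 <- td; td2$gene <- c("X", "A", "B"); td2$compound_match <- c(FALSE, FALSE, TRUE)
  bu2 <- bu[bu$gene == "C", , drop = FALSE]
  r2 <- integrate_evidence(bu2, td2, nearest)
  expect_equal(r2$genes, "B")
  expect_equal(r2$rule, "compound_specific")

  td3 <- td2; td3$compound_match <- FALSE
  r3 <- integrate_evidence(bu2, td3, nearest)
  expect_setequal(r3$genes, c("A", "C"))   # top scorer plus bottom-up genes
  expect_equal(r3$rule, "top_score_plus_bottom_up")

  # rule-3 ties keep all tied genes
  td4 <- td3; td4$score <- c(0L, 3L, 3L)
  r4 <- integrate_evidence(data.frame(gene = character(0)), td4, nearest)
  expect_setequal(r4$genes, c("A", "B"))

  none <- data.frame(gene = character(0), distance = numeric(0),
                     score = integer(0), recurrent = logical(0),
                     compound_match = logical(0))
  r5 <- integrate_evidence(data.frame(gene = character(0)), none, nearest)
  expect_equal(r5$genes, "NEAREST")
  expect_equal(r5$rule, "nearest_fallback")
})

test_that("prioritisation on cohort fixtures assigns every planted gene", {
  cohort <- .shared_cohort
  fix <- .shared_fixtures
  vr <- cohort$panels[[1]]$variants
  truth <- fix$causal_genes
  sentinels <- vr[match(truth$variant_id, vr$variant_id),
                  c("variant_id", "chrom", "pos")]
  sub_of <- stats::setNames(cohort$truth$subclass$subclass,
                            cohort$truth$subclass$lipid_id)
  assoc_sub <- lapply(stats::setNames(truth$variant_id, truth$variant_id),
                      function(v) {
    unique(unname(sub_of[cohort$truth$qtls$lipid_id[
      cohort$truth$qtls$variant_id == v]]))
  })
  asn <- prioritise_genes(sentinels, fix, assoc_sub)
  expect_true(all(nchar(asn$assigned_genes) > 0))
  val <- validate_against_truth(asn, truth)
  expect_equal(val$concordance, 1.0)
  # the designated evidence path drives the recorded rule
  rule_of <- stats::setNames(asn$rule, asn$variant_id)
  for (i in seq_len(nrow(truth))) {
    expected <- switch(truth$path[i],
                       exonic = , cis_eqtl = , ld_nonsynonymous = "intersection",
                       compound_specific = "compound_specific",
                       top_down_recurrent = "top_score_plus_bottom_up",
                       nearest_fallback = "nearest_fallback")
    expect_identical(unname(rule_of[truth$variant_id[i]]), expected)
  }
})

test_that("with no annotation the concordance equals the nearest-gene hit rate", {
  empty_fix <- list(
    genes = toy_genes,
    consequences = data.frame(variant_id = character(), gene = character(),
                              consequence = character()),
    ld = data.frame(variant_a = character(), variant_b = character(),
                    r2 = numeric()),
    eqtl = data.frame(variant_id = character(), gene = character(),
                      tissue = character()),
    genesets = stats::setNames(rep(list(data.frame(gene = character(0))), 5),
                               paste0("db", 1:5)),
    compound = data.frame(subclass = character(), gene = character()))
  sentinels <- data.frame(variant_id = c("v1", "v2"), chrom = 1,
                          pos = c(150, 52050))
  asn <- prioritise_genes(sentinels, empty_fix)
  expect_true(all(asn$rule == "nearest_fallback"))
  truth <- data.frame(variant_id = c("v1", "v2"), gene = c("NEAR", "TIE_A"))
  val <- validate_against_truth(asn, truth)
  expect_equal(val$concordance, 0.5)  # v1 hits NEAR, v2's truth is elsewhere
})
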