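mk_binding <- function(ids, deltas, classes) {
  data.frame(gene_id = ids, n_dbps = 1L,
             n_up = as.integer(classes == "up"),
             n_down = as.integer(classes == "down"),
             direction_class = classes, mean_delta_lfc = deltas,
             stringsAsFactors = FALSE)
}
mk_deg <- function(ids, lfc, padj, passes = padj < 0.05) {
  data.frame(gene_id = ids, baseMean = 100, log2fc = lfc, p = padj,
             padj = padj, passes_filter = passes, stringsAsFactors = FALSE)
}

test_that("the cross-omic merge is a lossless outer join", {
  gb <- mk_binding(c("g1", "g2"), c(1.2, -0.9), c("up", "down"))
  deg <- mk_deg(c("g2", "g3"), c(-0.8, 0.4), c(0.01, 0.6))
  prot <- data.frame(gene_id = "g4", log2fc = 0.5, q = 0.01,
                     stringsAsFactors = FALSE)
  m <- merge_omics(gb, deg, prot)
  expect_setequal(m$gene_id, c("g1", "g2", "g3", "g4"))

  r1 <- m[m$gene_id == "g1", ]   # binding only
  expect_true(is.na(r1$rna_log2fc) && is.na(r1$protein_log2fc))
  expect_true(is.na(r1$concordant))

  r2 <- m[m$gene_id == "g2", ]   # all layers, concordant down/down
  expect_true(r2$concordant)

  # mixed binding never defines concordance
  gbm <- mk_binding("g9", 0.1, "mixed")
  mm <- merge_omics(gbm, mk_deg("g9", -2, 0.001))
  expect_true(is.na(mm$concordant))
})

test_that("concordance statistics match the closed-form chi-square", {
  # quadrant table [[30,10],[10,30]]: all expected cells are 20, so
  # chi2 = 4 * (10^2/20) = 20 and p is the 1-df upper tail
  ids <- sprintf("g%03d", 1:80)
  classes <- rep(c("up", "down"), each = 40)
  rna <- c(rep(0.5, 30), rep(-0.5, 10), rep(0.5, 10), rep(-0.5, 30))
  rna <- rna + seq(0, 0.01, length.out = 80)  # break rank ties
  gb <- mk_binding(ids, ifelse(classes == "up", 1, -1), classes)
  deg <- mk_deg(ids, rna, rep(0.01, 80))
  cs <- concordance_stats(merge_omics(gb, deg))
  expect_equal(unname(cs$quadrant_table), matrix(c(30, 10, 10, 30), 2),
               ignore_attr = TRUE)
  expect_equal(cs$chi2, 20, tolerance = 1e-10)
  expect_equal(cs$chi2_p, stats::pchisq(20, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # the rank-sum p agrees with the reference implementation on the same split
  expect_equal(cs$mw_p,
               stats::wilcox.test(rna[classes == "up"],
                                  rna[classes == "down"])$p.value)

  # perfectly balanced table: no association
  rna_bal <- rep(c(0.5, -0.5), 40) + seq(0, 0.01, length.out = 80)
  deg_bal <- mk_deg(ids, rna_bal, rep(0.01, 80))
  cs2 <- concordance_stats(merge_omics(gb, deg_bal))
  expect_equal(cs2$chi2, 0, tolerance = 1e-10)
  expect_equal(cs2$chi2_p, 1)

  # symmetry: swapping both direction labels leaves chi2 unchanged
  gb_sw <- mk_binding(ids, -ifelse(classes == "up", 1, -1),
                      rev(sort(classes)))
  deg_sw <- mk_deg(ids, -rna, rep(0.01, 80))
  cs3 <- concordance_stats(merge_omics(gb_sw, deg_sw))
  expect_equal(cs3$chi2, cs$chi2, tolerance = 1e-10)

  # empty margin is an explicit error
  gb_up <- mk_binding(ids[1:10], rep(1, 10), rep("up", 10))
  expect_error(concordance_stats(merge_omics(gb_up, deg)), "margin")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # universe of 10, set of 5, all 5 selected genes inside the set:
  # p = 1 / choose(10, 5) = 1/252
  uni <- letters[1:10]
  sets <- list(S = letters[1:5])
  res <- ora_enrichment(letters[1:5], uni, sets)
  expect_equal(res$p, 1 / 252, tolerance = 1e-12)

  # set == universe and empty selection are the degenerate poles
  expect_equal(ora_enrichment(letters[1:4], uni, list(ALL = uni))$p, 1)
  res0 <- ora_enrichment(character(0), uni, sets)
  expect_equal(res0$p, 1)
  expect_false(any(res0$enriched))
  expect_error(ora_enrichment("zz", uni, sets), "outside the universe")

  # enumeration oracle over random small universes
  set.seed(12)
  for (rep in 1:5) {
    N <- sample(8:15, 1)
    uni <- paste0("u", seq_len(N))
    k <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    set <- sample(uni, k)
    sel <- sample(uni, n)
    x <- length(intersect(set, sel))
    p_pkg <- ora_enrichment(sel, uni, list(S = set))$p
    combos <- utils::combn(N, n)
    p_enum <- mean(apply(combos, 2, function(ix)
      length(intersect(uni[ix], set)) >= x))
    expect_equal(p_pkg, p_enum, tolerance = 1e-12)
  }
})

test_that("BH across sets and the enriched flag behave", {
  set.seed(13)
  uni <- paste0("g", 1:100)
  sel <- paste0("g", 1:20)
  sets <- list(HIT = paste0("g", 1:15),             # strongly enriched
               COLD = paste0("g", 81:100),          # depleted
               RAND = sample(uni, 30))
  res <- ora_enrichment(sel, uni, sets)
  expect_equal(res$padj, stats::p.adjust(res$p, "BH")[order(order(res$p))])
  expect_true(res$enriched[res$set == "HIT"])
  expect_false(res$enriched[res$set == "COLD"])
})

test_that("planted binding-RNA coupling yields growing concordance margins", {
  frac <- sapply(c(0.2, 0.6, 1.5), function(cp) {
    cfg <- sim_config(seed = 17, n_genes = 400, coupling_rna = cp)
    ec <- simulate_eclip(cfg)
    rn <- simulate_rnaseq(cfg, ec$truth)
    rpm <- rpm_normalize(ec$counts, ec$design)
    gb <- aggregate_genes(call_dbps(rpm, ec$design), ec$clusters)
    m <- prefilter_low_counts(rn$counts)
    grp <- factor(rn$design$treatment[match(colnames(m), rn$design$sample_id)],
                  levels = c("untreated", "treated"))
    deg <- significance_filter(de_test(m, grp))
    cs <- concordance_stats(merge_omics(gb, deg))
    cs$frac_concordant
  })
  expect_gt(frac[1], 0.5)
  expect_true(all(diff(frac) > 0))
  expect_lt(frac[3] - 1, 0)
})
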