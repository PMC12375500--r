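test_that("RPM normalisation is exact and linear in the counts", {
  design <- make_design(n_rep = 1, lib = 1e6)
  design$library_size <- c(1e6, 5e6, 1e6, 1e6)
  m <- matrix(c(10, 25, 0, 7), nrow = 1,
              dimnames = list("cl1", design$sample_id))
  rpm <- rpm_normalize(m, design)
  expect_equal(as.numeric(rpm), c(10, 5, 0, 7))

  # linearity: scaling one sample's counts by k scales its RPM column by k
  set.seed(1)
  m2 <- matrix(rpois(40, 50), nrow = 10,
               dimnames = list(paste0("c", 1:10), design$sample_id))
  m3 <- m2; m3[, 2] <- m3[, 2] * 3
  expect_equal(rpm_normalize(m3, design)[, 2], 3 * rpm_normalize(m2, design)[, 2])
  expect_error(rpm_normalize(m2[, 1:2], design[3:4, ]), "no design row")
})

test_that("peak significance matches the exact Fisher oracle", {
  design <- make_design(n_rep = 1, lib = 1e6)
  mk <- function(ip, inp) {
    m <- matrix(0L, nrow = length(ip), ncol = 4,
                dimnames = list(sprintf("cl%d", seq_along(ip)), design$sample_id))
    m[, design$assay == "IP" & design$treatment == "untreated"] <- ip
    m[, design$assay == "input" & design$treatment == "untreated"] <- inp
    m
  }
  # 80 vs 10 reads in equal libraries: log2 enrichment exactly 3, p tiny
  pk <- call_significant_peaks(mk(80L, 10L), design, "untreated", pseudocount = 0)
  expect_equal(pk$log2_enrichment, 3)
  expect_lt(pk$p_value, 1e-10)
  expect_true(pk$significant)

  # 8 vs 1: same enrichment but the exact test cannot reach p <= 0.001
  pk2 <- call_significant_peaks(mk(8L, 1L), design, "untreated", pseudocount = 0)
  expect_equal(pk2$log2_enrichment, 3)
  expect_gt(pk2$p_value, 0.001)
  expect_false(pk2$significant)

  # oracle: one-sided fisher.test on the full 2x2 table, random grid
  set.seed(7)
  ip <- as.integer(rpois(20, 60)); inp <- as.integer(rpois(20, 20))
  pk3 <- call_significant_peaks(mk(ip, inp), design, "untreated")
  oracle <- vapply(seq_along(ip), function(i) {
    tab <- matrix(c(ip[i], inp[i], 1e6 - ip[i], 1e6 - inp[i]), nrow = 2)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }, 0)
  expect_equal(pk3$p_value, oracle, tolerance = 1e-10)

  # zero input reads stay finite with the default pseudocount
  pk4 <- call_significant_peaks(mk(50L, 0L), design, "untreated")
  expect_true(is.finite(pk4$log2_enrichment))
})

test_that("region annotation follows the maximal-overlap rule", {
  ann <- data.frame(
    gene_id = c("G1", "G1", "G2"),
    chrom = c("chr1", "chr1", "chr1"),
    start = c(0L, 100L, 300L), end = c(100L, 300L, 400L),
    strand = "+",
    region = c("CDS", "3UTR", "CDS"), stringsAsFactors = FALSE)
  cl <- data.frame(
    chrom = "chr1",
    start = c(120L, 90L, 5000L),
    end = c(170L, 140L, 5050L),
    cluster_id = c("in3utr", "split", "nowhere"),
    score = 0, strand = c("+", "+", "+"), stringsAsFactors = FALSE)
  got <- annotate_regions(cl, ann)
  expect_equal(got$region, c("3UTR", "3UTR", "intergenic"))  # split: 10bp CDS vs 40bp 3UTR
  expect_equal(got$gene_id, c("G1", "G1", ""))

  # tie in total overlap between two genes -> lexicographically smallest id
  ann2 <- data.frame(gene_id = c("GB", "GA"), chrom = "chr1",
                     start = c(0L, 50L), end = c(100L, 150L), strand = "+",
                     region = "CDS", stringsAsFactors = FALSE)
  cl2 <- data.frame(chrom = "chr1", start = 25L, end = 125L,
                    cluster_id = "tie", score = 0, strand = "+",
                    stringsAsFactors = FALSE)
  expect_equal(annotate_regions(cl2, ann2)$gene_id, "GA")

  # unknown strand "." matches features on either strand
  cl3 <- data.frame(chrom = "chr1", start = 10L, end = 60L,
                    cluster_id = "dot", score = 0, strand = ".",
                    stringsAsFactors = FALSE)
  ann3 <- ann; ann3$strand <- "-"
  expect_equal(annotate_regions(cl3, ann3)$gene_id, "G1")
})

test_that("region distribution summarises significant peaks only", {
  cl <- data.frame(chrom = "chr1", start = 0:9 * 100L, end = 0:9 * 100L + 50L,
                   cluster_id = paste0("c", 1:10), score = 0, strand = "+",
                   gene_id = "G1",
                   region = c(rep("3UTR", 7), rep("CDS", 3)),
                   stringsAsFactors = FALSE)
  expect_equal(unname(region_distribution(cl)["3UTR"]), 0.7)
  pk <- data.frame(cluster_id = paste0("c", 1:10),
                   significant = c(rep(TRUE, 5), rep(FALSE, 5)))
  rd <- region_distribution(cl, pk)
  expect_equal(unname(rd["3UTR"]), 1)
  expect_error(region_distribution(cl[0, ]), "no peaks")
})

test_that("the interaction ANOVA matches stats::aov exactly", {
  design <- make_design(n_rep = 2)
  # textbook cells {10,12},{4,6},{2,3},{2,3}: (IP,untr),(input,untr),(IP,trt),(input,trt)
  rpm <- make_rpm(list(c(10, 12), c(4, 6), c(2, 3), c(2, 3)), design)
  p <- dbp_anova(rpm, design)
  df <- data.frame(y = as.numeric(rpm),
                   assay = design$assay, trt = design$treatment)
  oracle <- summary(stats::aov(y ~ assay * trt, df))[[1]]["assay:trt", "Pr(>F)"]
  expect_equal(unname(p), oracle, tolerance = 1e-12)

  # grid of random designs, replicates 2..5, agreement to >= 10 digits
  for (n_rep in c(2, 3, 5)) {
    d <- make_design(n_rep = n_rep)
    set.seed(n_rep)
    y <- matrix(rnorm(5 * nrow(d), mean = 10), nrow = 5,
                dimnames = list(paste0("cl", 1:5), d$sample_id))
    p <- dbp_anova(y, d)
    for (i in 1:5) {
      df <- data.frame(y = y[i, ], assay = d$assay, trt = d$treatment)
      oracle <- summary(stats::aov(y ~ assay * trt, df))[[1]]["assay:trt", "Pr(>F)"]
      expect_equal(unname(p[i]), oracle, tolerance = 1e-10)
    }
  }
})

test_that("degenerate clusters get p = 1 by convention", {
  design <- make_design(n_rep = 2)
  flat <- make_rpm(list(c(5, 5), c(5, 5), c(5, 5), c(5, 5)), design)
  expect_equal(unname(dbp_anova(flat, design)), 1)
  zero <- flat * 0
  expect_equal(unname(dbp_anova(zero, design)), 1)
  expect_error(dbp_anova(flat[, 1:6], design[1:6, ]), "2x2|replicates")
})

test_that("condition log2 fold changes and their difference are exact", {
  design <- make_design(n_rep = 1)
  # means (IP,untr)=4, (input,untr)=2, (IP,trt)=8, (input,trt)=2, eps=0
  rpm <- make_rpm(list(4, 2, 8, 2), design)
  eff <- dbp_effect(rpm, design, epsilon = 0)
  expect_equal(eff$lfc_treated, 2)
  expect_equal(eff$lfc_untreated, 1)
  expect_equal(eff$delta_lfc, 1)

  expect_equal(dbp_effect(make_rpm(list(3, 3, 3, 3), design),
                          design, epsilon = 0)$delta_lfc, 0)
  expect_equal(dbp_effect(make_rpm(list(8, 2, 2, 2), design),
                          design, epsilon = 0)$delta_lfc, -2)
  expect_warning(
    eff0 <- dbp_effect(make_rpm(list(0, 0, 0, 0), design), design),
    "no reads")
  expect_equal(eff0$delta_lfc, 0)
})

test_that("DBP calls apply both filters and ignore sample order", {
  set.seed(21)
  cfg <- sim_config(seed = 21, n_genes = 120)
  ec <- simulate_eclip(cfg)
  rpm <- rpm_normalize(ec$counts, ec$design)
  dbps <- call_dbps(rpm, ec$design)
  # the direction call is exactly the stated rule
  expect_equal(dbps$direction,
               ifelse(dbps$p_interaction < 0.05 & dbps$delta_lfc > 0.5, "up",
                      ifelse(dbps$p_interaction < 0.05 & dbps$delta_lfc < -0.5,
                             "down", "none")))
  # column-order invariance
  perm <- sample(ncol(rpm))
  dbps2 <- call_dbps(rpm[, perm], ec$design)
  expect_equal(dbps2, dbps)
})

test_that("under a pure null the DBP rate is bounded and monotone in delta_min", {
  design <- make_design(n_rep = 2)
  set.seed(33)
  n <- 3000
  rpm <- matrix(rnorm(n * 8, mean = 50, sd = 5), nrow = n,
                dimnames = list(paste0("cl", 1:n), design$sample_id))
  rates <- vapply(c(0.1, 0.5, 1.0), function(dm)
    mean(call_dbps(rpm, design, delta_min = dm)$direction != "none"), 0)
  expect_true(all(diff(rates) <= 0))
  expect_lte(rates[2], 0.05)
})

test_that("gene direction classes equal brute force over all sign patterns", {
  classify <- function(signs) {  # independent brute-force rule
    if (length(signs) == 0) return(NULL)
    if (all(signs > 0)) "up" else if (all(signs < 0)) "down" else "mixed"
  }
  clusters <- data.frame(chrom = "chr1", start = 0L, end = 1L,
                         cluster_id = "x", gene_id = "g",
                         stringsAsFactors = FALSE)
  for (k in 1:6) {
    patterns <- expand.grid(rep(list(c(-1, 1)), k))
    for (r in seq_len(nrow(patterns))) {
      signs <- as.numeric(patterns[r, ])
      dbps <- data.frame(
        cluster_id = paste0("c", seq_len(k)),
        delta_lfc = signs * seq(0.6, 2, length.out = k),
        direction = ifelse(signs > 0, "up", "down"),
        stringsAsFactors = FALSE)
      cl <- data.frame(chrom = "chr1", start = 0L, end = 1L,
                       cluster_id = dbps$cluster_id, gene_id = "g",
                       stringsAsFactors = FALSE)
      out <- aggregate_genes(dbps, cl)
      expect_equal(out$direction_class, classify(signs))
      expect_equal(out$n_dbps, out$n_up + out$n_down)
      expect_equal(out$mean_delta_lfc, mean(dbps$delta_lfc))
    }
  }
})

test_that("gene aggregation and coordination reproduce the printed eCLIP arithmetic", {
  gs <- data.frame(gene_id = c("a", "b", "c"),
                   n_dbps = c(2L, 2L, 1L), n_up = c(2L, 1L, 0L),
                   n_down = c(0L, 1L, 1L),
                   direction_class = c("up", "mixed", "down"),
                   mean_delta_lfc = c(1, 0.2, -1), stringsAsFactors = FALSE)
  cs <- coordination_summary(gs)
  expect_equal(cs$n_multi, 2L)
  expect_equal(cs$n_coordinated, 1L)

  # printed-count worked examples: 785 coordinated of 837 multi-DBP genes,
  # and 58 mixed-direction genes of 2349 DBP genes
  multi <- data.frame(
    gene_id = sprintf("m%04d", 1:837), n_dbps = 2L,
    n_up = c(rep(2L, 400), rep(0L, 385), rep(1L, 52)),
    n_down = c(rep(0L, 400), rep(2L, 385), rep(1L, 52)),
    direction_class = c(rep("up", 400), rep("down", 385), rep("mixed", 52)),
    mean_delta_lfc = 0, stringsAsFactors = FALSE)
  expect_equal(round(coordination_summary(multi)$pct_coordinated, 1), 93.8)

  allg <- data.frame(
    gene_id = sprintf("g%04d", 1:2349), n_dbps = 1L,
    n_up = 1L, n_down = 0L,
    direction_class = c(rep("mixed", 58), rep("up", 2349 - 58)),
    mean_delta_lfc = 0, stringsAsFactors = FALSE)
  allg$n_dbps[1:58] <- 2L; allg$n_down[1:58] <- 1L
  expect_equal(round(coordination_summary(allg)$pct_mixed, 1), 2.5)
})

test_that("bound-gene overlap is plain set arithmetic", {
  ov <- overlap_summary(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(ov$n_shared, 2L)
  expect_equal(ov$n_lost, 1L)
  expect_equal(ov$n_new, 1L)

  # printed Venn: 5181 untreated vs 4676 treated genes with 4032 shared
  u <- sprintf("g%04d", 1:5181)
  t <- c(sprintf("g%04d", 1:4032), sprintf("n%03d", 1:644))
  ov2 <- overlap_summary(u, t)
  expect_equal(ov2$n_treated, 4676L)
  expect_equal(ov2$n_lost, 1149L)
  expect_equal(ov2$n_new, 644L)
  expect_equal(ov2$shared_pct, 78)

  ov3 <- overlap_summary(u, u)
  expect_equal(ov3$n_lost, 0L)
  expect_equal(ov3$n_new, 0L)
  expect_equal(ov3$shared_pct, 100)
})
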