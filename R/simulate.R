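## Synthetic multi-omic data with planted ground truth.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: a 2x2 (IP/input x treated/untreated) replicated eCLIP design with
## negative-binomial cluster counts and planted interaction effects on the
## treated-IP cell; RNA-seq counts whose true log2 fold change is coupled to
## the planted binding change; LFQ proteomics intensities coupled to the RNA
## effects; and Boltzmann melt curves. Counts use the NB(mu, alpha)
## parameterisation with Var = mu + alpha * mu^2.

#' Configuration for the synthetic-data generators
#'
#' Defaults encode the study design the pipeline targets: duplicate eCLIP
#' IP/input libraries per treatment, triplicate RNA-seq, 4-vs-4 LFQ
#' proteomics, a cluster region mix dominated by 3'UTR sites, and a thermal
#' gradient from 37 to 58 degrees C.
#'
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_genes number of genes carrying eCLIP clusters.
#' @param clusters_per_gene_lambda each gene gets `1 + Poisson(lambda)`
#'   clusters.
#' @param region_composition named probabilities over cluster region labels;
#'   must sum to 1.
#' @param n_replicates eCLIP replicates per (assay x treatment) cell.
#' @param n_rna_replicates RNA-seq replicates per arm.
#' @param n_prot_replicates proteomics replicates per arm.
#' @param library_size nominal mapped reads per eCLIP library (jittered
#'   +/-20% per sample).
#' @param rna_library_depth nominal RNA-seq depth scale (counts are drawn at
#'   the gene level; depth enters through size factors).
#' @param nb_dispersion NB dispersion alpha (Var = mu + alpha mu^2).
#' @param base_abundance_meanlog,base_abundance_sdlog log-normal parameters
#'   of per-cluster base abundance (fraction of the library).
#' @param ip_enrich_mean,ip_enrich_sd normal parameters of the baseline
#'   true IP-over-input log2 enrichment per cluster.
#' @param frac_dbp fraction of clusters planted as differentially bound.
#' @param dbp_delta_min,dbp_delta_max planted |delta log2FC| range (uniform).
#' @param dbp_prob_down probability a planted binding change is a loss.
#' @param coupling_rna slope linking gene-level true binding delta-LFC to
#'   true RNA log2FC.
#' @param coupling_protein slope linking true RNA log2FC to true protein
#'   log2FC.
#' @param rna_base_meanlog,rna_base_sdlog log-normal parameters of baseline
#'   gene expression (normalised counts).
#' @param lfq_mean,lfq_between_sd mean and between-protein SD of baseline
#'   log2 LFQ intensity.
#' @param lfq_noise_sd within-group SD of log2 LFQ intensity.
#' @param lfq_missing_frac fraction of intensity entries zeroed (missing
#'   values are encoded as 0, matching the non-zero-intensity filter).
#' @param frac_contaminant fraction of proteins flagged contaminant/reverse.
#' @param peptide_lambda peptide counts are `1 + Poisson(lambda)`.
#' @param melt_top,melt_bottom,melt_slope Boltzmann plateau and slope
#'   parameters.
#' @param melt_tm named vector of melting temperatures per condition
#'   (degrees C).
#' @param temperatures thermal-gradient temperatures (degrees C).
#' @param melt_noise_sd Gaussian noise SD on the soluble fraction.
#' @param melt_replicates melt-curve replicates per condition.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 800L,
                       clusters_per_gene_lambda = 0.5,
                       region_composition = c("3UTR" = 0.72, "CDS" = 0.20,
                                              "5UTR" = 0.05, "intron" = 0.03),
                       n_replicates = 2L,
                       n_rna_replicates = 3L,
                       n_prot_replicates = 4L,
                       library_size = 1e7,
                       rna_library_depth = 1,
                       nb_dispersion = 0.05,
                       base_abundance_meanlog = log(1e-5),
                       base_abundance_sdlog = 0.8,
                       ip_enrich_mean = 4,
                       ip_enrich_sd = 1.5,
                       frac_dbp = 0.15,
                       dbp_delta_min = 0.5,
                       dbp_delta_max = 2.5,
                       dbp_prob_down = 0.6,
                       coupling_rna = 0.5,
                       coupling_protein = 0.5,
                       rna_base_meanlog = log(500),
                       rna_base_sdlog = 1,
                       lfq_mean = 25,
                       lfq_between_sd = 2,
                       lfq_noise_sd = 0.3,
                       lfq_missing_frac = 0,
                       frac_contaminant = 0.02,
                       peptide_lambda = 5,
                       melt_top = 1,
                       melt_bottom = 0,
                       melt_slope = 1.5,
                       melt_tm = c(vehicle = 45.6, treated = 47.7),
                       temperatures = seq(37, 58, length.out = 8),
                       melt_noise_sd = 0,
                       melt_replicates = 3L) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$region_composition) - 1) > 1e-8)
    stop("region_composition probabilities must sum to 1")
  if (is.null(names(cfg$region_composition)) ||
      !all(names(cfg$region_composition) %in% REGION_LEVELS))
    stop("region_composition must be named with region labels")
  if (cfg$frac_dbp < 0 || cfg$frac_dbp > 1) stop("frac_dbp must be in [0, 1]")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$n_replicates < 1) stop("need at least one replicate per design cell")
  if (cfg$dbp_delta_min < 0 || cfg$dbp_delta_max < cfg$dbp_delta_min)
    stop("invalid dbp delta range")
  if (cfg$lfq_missing_frac < 0 || cfg$lfq_missing_frac > 1)
    stop("lfq_missing_frac must be in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

rnbinom_md <- function(n, mu, alpha) {
  ## NB with Var = mu + alpha mu^2  <=>  size = 1/alpha
  stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

## Fixed synthetic gene architecture (bp, 0-based within-gene offsets):
## 5UTR [0,200) | CDS [200,800) | intron [800,1100) | CDS [1100,1700) |
## 3UTR [1700,2700); genes tiled every 5000 bp over 5 chromosomes.
gene_models <- function(n_genes) {
  gene_len <- 2700L
  spacing <- 5000L
  gene_id <- sprintf("G%04d", seq_len(n_genes))
  chrom <- paste0("chr", 1L + (seq_len(n_genes) - 1L) %% 5L)
  idx_on_chrom <- ave(seq_len(n_genes), chrom, FUN = seq_along)
  offset <- (idx_on_chrom - 1L) * spacing
  strand <- rep(c("+", "-"), length.out = n_genes)
  feat <- data.frame(
    region = c("5UTR", "CDS", "intron", "CDS", "3UTR"),
    fstart = c(0L, 200L, 800L, 1100L, 1700L),
    fend = c(200L, 800L, 1100L, 1700L, 2700L),
    stringsAsFactors = FALSE
  )
  ann <- data.frame(
    gene_id = rep(gene_id, each = nrow(feat)),
    chrom = rep(chrom, each = nrow(feat)),
    start = rep(offset, each = nrow(feat)) + rep(feat$fstart, n_genes),
    end = rep(offset, each = nrow(feat)) + rep(feat$fend, n_genes),
    strand = rep(strand, each = nrow(feat)),
    region = rep(feat$region, n_genes),
    stringsAsFactors = FALSE
  )
  list(annotation = ann, gene_len = gene_len)
}

#' Simulate a replicated eCLIP experiment with planted binding changes
#'
#' Generates cluster intervals placed inside a synthetic gene architecture,
#' a 2x2 factorial count matrix (NB noise), the sample design, a matching
#' gene annotation, and the planted ground truth. Expected counts are
#' `library_size x base_abundance x enrichment(assay, treatment)`: input
#' libraries see the base abundance, IP libraries see it multiplied by
#' `2^enrichment`, and planted DBP clusters receive the interaction effect
#' `2^delta_lfc` on the treated-IP cell only.
#'
#' @param config a [sim_config()].
#' @return list with `clusters` (BED-style data frame, truth columns
#'   `gene_id`/`region` filled), `counts` (clusters x samples integer
#'   matrix), `design`, `annotation` (GTF-lite data frame) and `truth`
#'   (list with `clusters` and `genes` data frames).
#' @export
simulate_eclip <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gm <- gene_models(config$n_genes)
  ann <- gm$annotation

  n_per_gene <- 1L + stats::rpois(config$n_genes, config$clusters_per_gene_lambda)
  gene_of <- rep(seq_len(config$n_genes), n_per_gene)
  n <- length(gene_of)
  cluster_id <- sprintf("CL%05d", seq_len(n))

  region <- sample(names(config$region_composition), n, replace = TRUE,
                   prob = config$region_composition)

  ## place each cluster inside a feature of its drawn region type
  width <- 50L
  gene_ann <- split(seq_len(nrow(ann)), ann$gene_id)
  gene_ids <- sprintf("G%04d", gene_of)
  start <- integer(n)
  for (i in seq_len(n)) {
    rows <- gene_ann[[gene_ids[i]]]
    feats <- ann[rows, ]
    feats <- feats[feats$region == region[i], , drop = FALSE]
    f <- feats[sample.int(nrow(feats), 1L), ]
    start[i] <- f$start + sample.int(f$end - f$start - width, 1L) - 1L
  }
  clusters <- data.frame(
    chrom = ann$chrom[match(gene_ids, ann$gene_id)],
    start = start,
    end = start + width,
    cluster_id = cluster_id,
    score = 0,
    strand = ann$strand[match(gene_ids, ann$gene_id)],
    gene_id = gene_ids,
    region = region,
    stringsAsFactors = FALSE
  )

  ## planted effects
  base_abund <- stats::rlnorm(n, config$base_abundance_meanlog,
                              config$base_abundance_sdlog)
  enrich <- stats::rnorm(n, config$ip_enrich_mean, config$ip_enrich_sd)
  n_dbp <- round(config$frac_dbp * n)
  is_dbp <- rep(FALSE, n)
  is_dbp[sample.int(n, n_dbp)] <- TRUE
  delta <- numeric(n)
  mag <- stats::runif(n_dbp, config$dbp_delta_min, config$dbp_delta_max)
  sgn <- ifelse(stats::runif(n_dbp) < config$dbp_prob_down, -1, 1)
  delta[is_dbp] <- sgn * mag

  ## design: n_replicates per (assay x treatment)
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      assay = c("IP", "input"),
                      treatment = c("untreated", "treated"),
                      stringsAsFactors = FALSE)
  lib <- round(config$library_size * stats::runif(nrow(grid), 0.8, 1.2))
  design <- data.frame(
    sample_id = sprintf("%s_%s_%d", ifelse(grid$assay == "IP", "ip", "in"),
                        ifelse(grid$treatment == "treated", "trt", "untr"),
                        grid$replicate),
    assay = grid$assay,
    treatment = grid$treatment,
    replicate = grid$replicate,
    library_size = lib,
    stringsAsFactors = FALSE
  )
  validate_design(design)

  counts <- matrix(0L, nrow = n, ncol = nrow(design),
                   dimnames = list(cluster_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    f <- if (design$assay[j] == "IP") {
      2^(enrich + if (design$treatment[j] == "treated") delta else 0)
    } else rep(1, n)
    mu <- design$library_size[j] * base_abund * f
    counts[, j] <- as.integer(rnbinom_md(n, mu, config$nb_dispersion))
  }

  gene_delta <- tapply(delta, gene_ids, mean)
  genes <- data.frame(
    gene_id = names(gene_delta),
    binding_delta = as.numeric(gene_delta),
    stringsAsFactors = FALSE
  )
  genes$rna_log2fc <- config$coupling_rna * genes$binding_delta
  genes$protein_log2fc <- config$coupling_protein * genes$rna_log2fc

  truth <- list(
    clusters = data.frame(cluster_id = cluster_id, gene_id = gene_ids,
                          region = region, base_abundance = base_abund,
                          log2_enrichment = enrich, is_dbp = is_dbp,
                          delta_lfc = delta, stringsAsFactors = FALSE),
    genes = genes
  )
  list(clusters = clusters, counts = counts, design = design,
       annotation = ann, truth = truth)
}

#' Simulate RNA-seq counts coupled to planted binding changes
#'
#' Gene counts are negative binomial with true log2 fold change
#' `coupling_rna x` gene-level true binding delta (already materialised in
#' `truth$genes$rna_log2fc`), and planted per-sample size factors.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element of [simulate_eclip()] output.
#' @param size_factors optional planted per-sample size factors
#'   (length `2 x n_rna_replicates`); drawn from U(0.7, 1.4) by default.
#' @return list with `counts` (genes x samples), `design` (sample_id,
#'   treatment, replicate), `size_factors` and `truth` (gene_id, base_expr,
#'   rna_log2fc).
#' @export
simulate_rnaseq <- function(config, truth, size_factors = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genes <- truth$genes
  g <- nrow(genes)
  nrep <- config$n_rna_replicates
  ns <- 2L * nrep
  if (is.null(size_factors)) size_factors <- stats::runif(ns, 0.7, 1.4)
  if (length(size_factors) != ns) stop("size_factors must have one entry per sample")
  base <- stats::rlnorm(g, config$rna_base_meanlog, config$rna_base_sdlog) *
    config$rna_library_depth
  design <- data.frame(
    sample_id = c(sprintf("ctl_%d", seq_len(nrep)), sprintf("trt_%d", seq_len(nrep))),
    treatment = rep(c("untreated", "treated"), each = nrep),
    replicate = rep(seq_len(nrep), 2L),
    stringsAsFactors = FALSE
  )
  counts <- matrix(0L, nrow = g, ncol = ns,
                   dimnames = list(genes$gene_id, design$sample_id))
  for (j in seq_len(ns)) {
    fc <- if (design$treatment[j] == "treated") 2^genes$rna_log2fc else 1
    mu <- base * fc * size_factors[j]
    counts[, j] <- as.integer(rnbinom_md(g, mu, config$nb_dispersion))
  }
  list(counts = counts, design = design, size_factors = size_factors,
       truth = data.frame(gene_id = genes$gene_id, base_expr = base,
                          rna_log2fc = genes$rna_log2fc,
                          stringsAsFactors = FALSE))
}

#' Simulate an LFQ proteomics table coupled to planted RNA effects
#'
#' Log2 intensities are Gaussian around planted per-protein means; treated
#' samples are shifted by the true protein log2FC
#' (`coupling_protein x` true RNA log2FC). A configurable fraction of
#' entries is zeroed to emulate missing values (missing = 0), and a small
#' fraction of rows is flagged contaminant/reverse.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element of [simulate_eclip()] output.
#' @return data frame with `protein_id`, `gene_id`, `peptide_count`,
#'   `reverse`, `contaminant`, `site_only`, intensity columns
#'   `trt_1..n, ctl_1..n`, and a `true_log2fc` truth column.
#' @export
simulate_proteomics <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  genes <- truth$genes
  np <- nrow(genes)
  nrep <- config$n_prot_replicates
  mean_log <- stats::rnorm(np, config$lfq_mean, config$lfq_between_sd)
  trt <- matrix(stats::rnorm(np * nrep,
                             mean = mean_log + genes$protein_log2fc,
                             sd = config$lfq_noise_sd), nrow = np)
  ctl <- matrix(stats::rnorm(np * nrep, mean = mean_log,
                             sd = config$lfq_noise_sd), nrow = np)
  intens <- 2^cbind(trt, ctl)
  colnames(intens) <- c(sprintf("trt_%d", seq_len(nrep)),
                        sprintf("ctl_%d", seq_len(nrep)))
  if (config$lfq_missing_frac > 0) {
    drop <- matrix(stats::runif(length(intens)) < config$lfq_missing_frac,
                   nrow = np)
    intens[drop] <- 0
  }
  out <- data.frame(
    protein_id = paste0("P_", genes$gene_id),
    gene_id = genes$gene_id,
    peptide_count = 1L + stats::rpois(np, config$peptide_lambda),
    reverse = stats::runif(np) < config$frac_contaminant / 2,
    contaminant = stats::runif(np) < config$frac_contaminant / 2,
    site_only = FALSE,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(intens))
  out$true_log2fc <- genes$protein_log2fc
  out
}

#' Boltzmann melt curve
#'
#' `f(T) = bottom + (top - bottom) / (1 + exp((T - tm)/slope))`: a
#' descending sigmoid in temperature whose inflection point is the melting
#' temperature `tm` (the soluble fraction equals `(top + bottom)/2` there).
#'
#' @param temperature temperatures (degrees C).
#' @param top,bottom upper/lower plateaus.
#' @param tm melting temperature (degrees C).
#' @param slope transition width (degrees C, positive).
#' @return soluble fraction at each temperature.
#' @export
boltzmann <- function(temperature, top, bottom, tm, slope) {
  bottom + (top - bottom) / (1 + exp((temperature - tm) / slope))
}

#' Simulate CETSA melt-curve densitometry tables
#'
#' Evaluates the Boltzmann curve at the configured thermal gradient for each
#' condition and replicate, adding optional Gaussian noise.
#'
#' @param config a [sim_config()]; conditions and their melting
#'   temperatures come from `config$melt_tm`.
#' @return data frame with columns `temperature`, `fraction`, `condition`,
#'   `replicate`.
#' @export
simulate_meltcurve <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  out <- list()
  for (cond in names(config$melt_tm)) {
    for (r in seq_len(config$melt_replicates)) {
      f <- boltzmann(config$temperatures, config$melt_top, config$melt_bottom,
                     config$melt_tm[[cond]], config$melt_slope)
      if (config$melt_noise_sd > 0)
        f <- f + stats::rnorm(length(f), 0, config$melt_noise_sd)
      out[[length(out) + 1L]] <- data.frame(
        temperature = config$temperatures, fraction = f,
        condition = cond, replicate = r, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a complete synthetic fixture directory
#'
#' Runs all four generators and writes the files the pipeline stages
#' consume: `clusters.bed`, `eclip_counts.tsv`, `eclip_design.tsv`,
#' `annotation.tsv`, `rna_counts.tsv`, `rna_design.tsv`, `proteomics.tsv`,
#' `meltcurves.csv`, plus `truth_clusters.tsv` and `truth_genes.tsv`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ec <- simulate_eclip(config)
  rn <- simulate_rnaseq(config, ec$truth)
  pr <- simulate_proteomics(config, ec$truth)
  mc <- simulate_meltcurve(config)
  write_bed(ec$clusters, file.path(dir, "clusters.bed"))
  write_count_matrix(ec$counts, file.path(dir, "eclip_counts.tsv"), "cluster_id")
  write_tsv(ec$design, file.path(dir, "eclip_design.tsv"),
            "eCLIP sample design: assay IP/input, treatment, replicate, mapped reads")
  write_tsv(ec$annotation, file.path(dir, "annotation.tsv"),
            "GTF-lite gene annotation: 0-based half-open feature intervals")
  write_count_matrix(rn$counts, file.path(dir, "rna_counts.tsv"), "gene_id")
  write_tsv(rn$design, file.path(dir, "rna_design.tsv"), "RNA-seq sample design")
  write_tsv(pr, file.path(dir, "proteomics.tsv"),
            "synthetic LFQ table; intensity columns trt_*/ctl_*; missing = 0")
  utils::write.csv(mc, file.path(dir, "meltcurves.csv"), row.names = FALSE)
  ## gene sets: two planted-effect sets plus random ones, for the ORA stage
  gt <- ec$truth$genes
  sets <- list()
  dn <- gt$gene_id[gt$rna_log2fc < -0.1]
  up <- gt$gene_id[gt$rna_log2fc > 0.1]
  if (length(dn) >= 2) { attr(dn, "description") <- "planted downregulated"; sets$PLANTED_DOWN <- dn }
  if (length(up) >= 2) { attr(up, "description") <- "planted upregulated"; sets$PLANTED_UP <- up }
  for (k in 1:3) {
    s <- sample(gt$gene_id, min(50, nrow(gt)))
    attr(s, "description") <- "random background set"
    sets[[paste0("RANDOM_", k)]] <- s
  }
  write_gmt(sets, file.path(dir, "gene_sets.gmt"))
  write_tsv(ec$truth$clusters, file.path(dir, "truth_clusters.tsv"),
            "planted per-cluster ground truth (synthetic)")
  write_tsv(ec$truth$genes, file.path(dir, "truth_genes.tsv"),
            "planted per-gene ground truth (synthetic)")
  invisible(dir)
}
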