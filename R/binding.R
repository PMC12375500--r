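## eCLIP differential binding: RPM normalisation, input-normalised peak
## significance, region annotation, the DBP procedure (two-way ANOVA
## interaction on RPM + delta log2FC filter), and gene-level aggregation.

#' RPM-normalise a count matrix
#'
#' Reads-per-million: each count is divided by its sample's mapped-read
#' library size and multiplied by 1e6.
#'
#' @param counts features x samples count matrix.
#' @param design sample design with `sample_id` and `library_size`.
#' @return matrix of RPM values, same shape as `counts`.
#' @export
rpm_normalize <- function(counts, design) {
  idx <- match(colnames(counts), design$sample_id)
  if (anyNA(idx))
    stop("no design row (library size) for sample(s): ",
         paste(colnames(counts)[is.na(idx)], collapse = ", "))
  lib <- design$library_size[idx]
  if (any(lib <= 0)) stop("library_size must be positive")
  sweep(counts, 2, lib / 1e6, "/")
}

#' Input-normalised peak significance calling
#'
#' For each cluster, reads are summed over the IP libraries and over the
#' size-matched input libraries of the chosen condition. Enrichment is
#' `log2(((IP + pseudo)/IP library) / ((input + pseudo)/input library))`;
#' the p-value is the one-sided Fisher exact test (hypergeometric tail) on
#' the 2x2 table of in-peak vs remaining reads in IP vs input. A peak is
#' significant when `log2_enrichment >= enrich_log2_min` and
#' `p_value <= p_max` (defaults: log2 enrichment 3, p 0.001).
#'
#' @param counts clusters x samples count matrix.
#' @param design sample design table.
#' @param treatment optionally restrict to `"treated"` or `"untreated"`
#'   samples; `NULL` uses all.
#' @param enrich_log2_min minimum log2 fold enrichment.
#' @param p_max maximum p-value.
#' @param pseudocount pseudo-reads added to both assays for the enrichment
#'   ratio (not the test), so zero-input clusters stay finite.
#' @return data frame: `cluster_id`, `ip_reads`, `input_reads`,
#'   `log2_enrichment`, `p_value`, `significant`.
#' @export
call_significant_peaks <- function(counts, design, treatment = NULL,
                                   enrich_log2_min = 3, p_max = 0.001,
                                   pseudocount = 1) {
  validate_design(design)
  if (!is.null(treatment)) {
    stopifnot(treatment %in% c("treated", "untreated"))
    design <- design[design$treatment == treatment, , drop = FALSE]
  }
  ip <- design$sample_id[design$assay == "IP"]
  inp <- design$sample_id[design$assay == "input"]
  if (length(ip) < 1 || length(inp) < 1)
    stop("need at least one IP and one input sample in the condition")
  ip <- intersect(ip, colnames(counts))
  inp <- intersect(inp, colnames(counts))
  ip_reads <- rowSums(counts[, ip, drop = FALSE])
  input_reads <- rowSums(counts[, inp, drop = FALSE])
  lib_ip <- sum(design$library_size[design$sample_id %in% ip])
  lib_inp <- sum(design$library_size[design$sample_id %in% inp])
  if (any(ip_reads > lib_ip) || any(input_reads > lib_inp))
    stop("peak read counts exceed library totals")
  enrich <- log2(((ip_reads + pseudocount) / lib_ip) /
                 ((input_reads + pseudocount) / lib_inp))
  ## one-sided Fisher exact p = hypergeometric upper tail of the 2x2 table
  ## [ip_in_peak, input_in_peak; ip_rest, input_rest]
  p <- stats::phyper(ip_reads - 1, lib_ip, lib_inp, ip_reads + input_reads,
                     lower.tail = FALSE)
  data.frame(
    cluster_id = rownames(counts),
    ip_reads = as.numeric(ip_reads),
    input_reads = as.numeric(input_reads),
    log2_enrichment = as.numeric(enrich),
    p_value = as.numeric(p),
    significant = as.numeric(enrich) >= enrich_log2_min & p <= p_max,
    stringsAsFactors = FALSE
  )
}

#' Assign clusters to genes and transcript regions by maximal overlap
#'
#' Each cluster is assigned the gene with the largest total overlap (ties
#' broken by lexicographically smallest `gene_id`), and within that gene the
#' feature label (5UTR/CDS/3UTR/intron) with the largest overlap. Clusters
#' overlapping no annotated feature — including those on chromosomes absent
#' from the annotation — become `intergenic` with an empty `gene_id`.
#' Strand `"."` is treated as unknown and matches either strand.
#'
#' @param clusters BED-style cluster data frame.
#' @param annotation annotation data frame ([read_annotation()] format).
#' @return `clusters` with `gene_id` and `region` columns (re)filled.
#' @export
annotate_regions <- function(clusters, annotation) {
  validate_clusters(clusters)
  if (nrow(annotation) == 0) stop("annotation is empty")
  gr_cl <- clusters_to_granges(clusters)
  gr_ann <- clusters_to_granges(annotation)
  hits <- GenomicRanges::findOverlaps(gr_cl, gr_ann)
  clusters$gene_id <- ""
  clusters$region <- "intergenic"
  if (length(hits) > 0) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::pintersect(gr_cl[q], gr_ann[s])
    w <- GenomicRanges::width(ov)
    hdf <- data.frame(q = q, gene = annotation$gene_id[s],
                      region = annotation$region[s], w = w,
                      stringsAsFactors = FALSE)
    ## total overlap per (cluster, gene)
    per_gene <- stats::aggregate(w ~ q + gene, data = hdf, FUN = sum)
    ## max overlap, ties -> smallest gene_id
    per_gene <- per_gene[order(per_gene$q, -per_gene$w, per_gene$gene), ]
    best <- per_gene[!duplicated(per_gene$q), ]
    clusters$gene_id[best$q] <- best$gene
    ## region: max-overlap feature label within the winning gene
    hdf$key <- paste(hdf$q, hdf$gene)
    best$key <- paste(best$q, best$gene)
    hdf <- hdf[hdf$key %in% best$key, ]
    per_reg <- stats::aggregate(w ~ q + region, data = hdf, FUN = sum)
    per_reg <- per_reg[order(per_reg$q, -per_reg$w, per_reg$region), ]
    breg <- per_reg[!duplicated(per_reg$q), ]
    clusters$region[breg$q] <- breg$region
  }
  clusters
}

#' Region distribution of significant peaks
#'
#' @param clusters annotated cluster data frame (with `region`).
#' @param peak_calls optional [call_significant_peaks()] output; when given,
#'   only significant clusters are summarised.
#' @return named numeric vector of proportions (summing to 1).
#' @export
region_distribution <- function(clusters, peak_calls = NULL) {
  if (!is.null(peak_calls)) {
    keep <- peak_calls$cluster_id[peak_calls$significant]
    clusters <- clusters[clusters$cluster_id %in% keep, , drop = FALSE]
  }
  if (nrow(clusters) == 0) stop("no peaks to summarise")
  tab <- table(clusters$region)
  prop <- as.numeric(tab) / sum(tab)
  names(prop) <- names(tab)
  prop
}

## shared projection machinery for the per-cluster two-way ANOVA
anova_projections <- function(design, samples) {
  idx <- match(samples, design$sample_id)
  if (anyNA(idx)) stop("design rows missing for count-matrix samples")
  assay <- factor(design$assay[idx], levels = c("IP", "input"))
  trt <- factor(design$treatment[idx], levels = c("untreated", "treated"))
  cell_n <- table(assay, trt)
  if (any(cell_n == 0)) stop("empty design cell: need a full 2x2 factorial")
  if (any(cell_n < 2)) stop("need >= 2 replicates in every design cell")
  x_add <- stats::model.matrix(~ assay + trt)
  x_full <- stats::model.matrix(~ assay * trt)
  hat <- function(x) x %*% solve(crossprod(x)) %*% t(x)
  list(h_add = hat(x_add), h_full = hat(x_full),
       df_res = length(idx) - ncol(x_full))
}

#' Per-cluster two-way ANOVA interaction test on RPM values
#'
#' Fits the classical fixed-effects two-way ANOVA (assay x treatment) to
#' each cluster's RPM values and returns the interaction-term p-value. The
#' interaction sum of squares is the residual-sum-of-squares difference
#' between the additive and the full (cell-means) model; with the
#' interaction entered last this equals the sequential ANOVA term. Clusters
#' whose interaction SS and residual SS are both (numerically) zero — e.g.
#' all values identical — get p = 1 by convention.
#'
#' @param rpm clusters x samples RPM matrix.
#' @param design sample design table (2x2 factorial, >= 2 replicates/cell).
#' @return named numeric vector of interaction p-values, one per cluster.
#' @export
dbp_anova <- function(rpm, design) {
  pr <- anova_projections(design, colnames(rpm))
  res_full <- rpm - rpm %*% pr$h_full
  res_add <- rpm - rpm %*% pr$h_add
  rss_full <- rowSums(res_full^2)
  rss_add <- rowSums(res_add^2)
  ss_int <- pmax(rss_add - rss_full, 0)
  f <- (ss_int / 1) / (rss_full / pr$df_res)
  p <- stats::pf(f, 1, pr$df_res, lower.tail = FALSE)
  ## degenerate clusters: no residual variation and no interaction signal
  scale <- rowMeans(rpm^2)
  tol <- 1e-10 * pmax(scale, 1e-300)
  degen <- rss_full <= tol & ss_int <= tol
  p[degen] <- 1
  stats::setNames(as.numeric(p), rownames(rpm))
}

#' Per-cluster condition log2 fold changes and their difference
#'
#' Averages RPM over replicates within each of the four design cells, then
#' `lfc_treated = log2((mean IP,treated + eps)/(mean input,treated + eps))`,
#' likewise for untreated, and `delta_lfc = lfc_treated - lfc_untreated`.
#'
#' @param rpm clusters x samples RPM matrix.
#' @param design sample design table.
#' @param epsilon RPM floor added to numerator and denominator.
#' @return data frame: `cluster_id`, `lfc_treated`, `lfc_untreated`,
#'   `delta_lfc`, `all_zero` (flag for clusters with no reads anywhere,
#'   which get delta 0 and a warning).
#' @export
dbp_effect <- function(rpm, design, epsilon = 0.1) {
  idx <- match(colnames(rpm), design$sample_id)
  if (anyNA(idx)) stop("design rows missing for count-matrix samples")
  cell <- paste(design$assay[idx], design$treatment[idx], sep = ".")
  cells <- c("IP.treated", "input.treated", "IP.untreated", "input.untreated")
  if (!all(cells %in% cell)) stop("all four design cells are required")
  m <- matrix(NA_real_, nrow = nrow(rpm), ncol = length(cells),
              dimnames = list(NULL, cells))
  for (cl in cells)
    m[, cl] <- rowMeans(rpm[, cell == cl, drop = FALSE])
  lfc_t <- log2((m[, "IP.treated"] + epsilon) / (m[, "input.treated"] + epsilon))
  lfc_u <- log2((m[, "IP.untreated"] + epsilon) / (m[, "input.untreated"] + epsilon))
  all_zero <- rowSums(rpm) == 0
  if (any(all_zero))
    warning(sum(all_zero), " cluster(s) have no reads in any sample; delta_lfc set to 0")
  data.frame(
    cluster_id = rownames(rpm),
    lfc_treated = as.numeric(lfc_t),
    lfc_untreated = as.numeric(lfc_u),
    delta_lfc = as.numeric(lfc_t - lfc_u),
    all_zero = all_zero,
    stringsAsFactors = FALSE
  )
}

#' Call differentially bound peaks (DBPs)
#'
#' Composition of [dbp_anova()] and [dbp_effect()]: a cluster is a DBP when
#' its interaction p-value is below `p_max` and `|delta_lfc|` exceeds
#' `delta_min`; `direction` is `"up"`/`"down"` by the sign of `delta_lfc`,
#' else `"none"`. Raw (unadjusted) interaction p-values are thresholded by
#' default; set `bh_adjust = TRUE` to threshold Benjamini-Hochberg adjusted
#' p-values instead (not the default procedure).
#'
#' @param rpm clusters x samples RPM matrix.
#' @param design sample design table.
#' @param p_max interaction p-value threshold (default 0.05).
#' @param delta_min minimum `|delta_lfc|` (default 0.5).
#' @param epsilon RPM floor for the fold-change ratios.
#' @param bh_adjust threshold BH-adjusted interaction p-values.
#' @return data frame: `cluster_id`, `p_interaction`, `lfc_treated`,
#'   `lfc_untreated`, `delta_lfc`, `direction`.
#' @export
call_dbps <- function(rpm, design, p_max = 0.05, delta_min = 0.5,
                      epsilon = 0.1, bh_adjust = FALSE) {
  p <- dbp_anova(rpm, design)
  eff <- dbp_effect(rpm, design, epsilon = epsilon)
  p_used <- if (bh_adjust) stats::p.adjust(p, "BH") else p
  direction <- rep("none", nrow(eff))
  direction[p_used < p_max & eff$delta_lfc > delta_min] <- "up"
  direction[p_used < p_max & eff$delta_lfc < -delta_min] <- "down"
  data.frame(
    cluster_id = eff$cluster_id,
    p_interaction = as.numeric(p),
    lfc_treated = eff$lfc_treated,
    lfc_untreated = eff$lfc_untreated,
    delta_lfc = eff$delta_lfc,
    direction = direction,
    stringsAsFactors = FALSE
  )
}

#' Aggregate DBPs to gene-level binding summaries
#'
#' For every gene owning at least one DBP: the number of up/down DBPs, the
#' direction class (`up`/`down` when coordinated, `mixed` when both signs
#' occur), and the mean `delta_lfc` over the gene's DBPs.
#'
#' @param dbps [call_dbps()] output.
#' @param clusters annotated cluster data frame (provides `gene_id`).
#' @return data frame: `gene_id`, `n_dbps`, `n_up`, `n_down`,
#'   `direction_class`, `mean_delta_lfc`.
#' @export
aggregate_genes <- function(dbps, clusters) {
  gene <- clusters$gene_id[match(dbps$cluster_id, clusters$cluster_id)]
  if (anyNA(gene)) stop("DBP cluster id(s) absent from the cluster table")
  keep <- dbps$direction != "none" & gene != ""
  d <- dbps[keep, , drop = FALSE]
  g <- gene[keep]
  if (nrow(d) == 0)
    return(data.frame(gene_id = character(), n_dbps = integer(),
                      n_up = integer(), n_down = integer(),
                      direction_class = character(),
                      mean_delta_lfc = numeric(), stringsAsFactors = FALSE))
  n_up <- tapply(d$direction == "up", g, sum)
  n_down <- tapply(d$direction == "down", g, sum)
  mean_d <- tapply(d$delta_lfc, g, mean)
  gid <- names(n_up)
  cls <- ifelse(n_up > 0 & n_down > 0, "mixed",
                ifelse(n_up > 0, "up", "down"))
  out <- data.frame(
    gene_id = gid,
    n_dbps = as.integer(n_up + n_down),
    n_up = as.integer(n_up),
    n_down = as.integer(n_down),
    direction_class = as.character(cls),
    mean_delta_lfc = as.numeric(mean_d),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Coordination summary of multi-DBP genes
#'
#' Among genes with more than one DBP, the fraction whose DBPs all share
#' one direction; plus the fraction of all DBP genes with mixed directions.
#'
#' @param gene_summary [aggregate_genes()] output.
#' @return list: `n_multi`, `n_coordinated`, `pct_coordinated`,
#'   `n_genes`, `n_mixed`, `pct_mixed`.
#' @export
coordination_summary <- function(gene_summary) {
  multi <- gene_summary[gene_summary$n_dbps > 1, , drop = FALSE]
  n_multi <- nrow(multi)
  n_coord <- sum(multi$direction_class %in% c("up", "down"))
  n_genes <- nrow(gene_summary)
  n_mixed <- sum(gene_summary$direction_class == "mixed")
  list(
    n_multi = n_multi,
    n_coordinated = n_coord,
    pct_coordinated = if (n_multi > 0) 100 * n_coord / n_multi else NA_real_,
    n_genes = n_genes,
    n_mixed = n_mixed,
    pct_mixed = if (n_genes > 0) 100 * n_mixed / n_genes else NA_real_
  )
}

#' Overlap of bound-gene sets between conditions
#'
#' Set arithmetic for the condition-overlap Venn: genes bound in both
#' conditions, genes no longer bound after treatment, and genes newly bound.
#'
#' @param bound_genes_untreated,bound_genes_treated character vectors of
#'   gene ids owning >= 1 significant peak in each condition.
#' @return list: `n_untreated`, `n_treated`, `n_shared`, `n_lost`, `n_new`,
#'   `shared_fraction_of_untreated` and `shared_pct` (rounded percent).
#' @export
overlap_summary <- function(bound_genes_untreated, bound_genes_treated) {
  u <- unique(bound_genes_untreated)
  t <- unique(bound_genes_treated)
  shared <- intersect(u, t)
  frac <- if (length(u) > 0) length(shared) / length(u) else NA_real_
  list(
    n_untreated = length(u),
    n_treated = length(t),
    n_shared = length(shared),
    n_lost = length(setdiff(u, t)),
    n_new = length(setdiff(t, u)),
    shared_fraction_of_untreated = frac,
    shared_pct = round(100 * frac)
  )
}
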