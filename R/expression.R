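## RNA-seq differential expression: low-count prefilter, median-of-ratios
## size factors, a minimal self-contained negative-binomial Wald test, BH
## adjustment and the baseMean-dependent significance filter. The test is a
## deliberately simple, documented stand-in for a full DE framework (no
## dispersion shrinkage, no outlier handling); numerical agreement with such
## frameworks is not claimed, and significance_filter() also accepts
## externally produced (baseMean, log2fc, padj) tables.

#' Remove genes with a low total count
#'
#' Drops genes whose count sum over all samples is strictly below
#' `min_total` (default 10).
#'
#' @param counts genes x samples count matrix.
#' @param min_total minimum total count to keep a gene.
#' @return filtered count matrix.
#' @export
prefilter_low_counts <- function(counts, min_total = 10) {
  counts[rowSums(counts) >= min_total, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' The per-sample median of count ratios to the per-gene geometric mean,
#' computed over genes with all-positive counts, rescaled so the size
#' factors have geometric mean 1.
#'
#' @param counts genes x samples count matrix.
#' @return named numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  allpos <- rowSums(counts <= 0) == 0
  if (!any(allpos))
    stop("no gene has positive counts in every sample; add a pseudocount ",
         "or filter samples")
  lc <- log(counts[allpos, , drop = FALSE])
  loggeo <- rowMeans(lc)
  sf <- apply(lc, 2, function(x) exp(stats::median(x - loggeo)))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Minimal negative-binomial Wald test for two-group differential expression
#'
#' Counts are normalised by [estimate_size_factors()] (or supplied factors).
#' Per gene: `baseMean` is the mean normalised count over all samples; the
#' log2 fold change compares group means with a 0.5 pseudo-normalised-count;
#' dispersion is a per-gene method-of-moments estimate under
#' `Var = mu + alpha mu^2` (floored at `dispersion_floor`, no shrinkage);
#' the Wald statistic divides the log2FC by a delta-method standard error
#' from the NB variance and is referred to a t distribution with
#' `n1 + n2 - 2` degrees of freedom (the variance is estimated from few
#' residual degrees of freedom, so the normal reference is
#' anti-conservative at typical replicate numbers). P-values are BH-adjusted
#' across tested genes.
#'
#' @param counts genes x samples count matrix (prefiltered).
#' @param group factor/character of length `ncol(counts)` with two levels;
#'   the log2FC is second level vs first.
#' @param size_factors optional per-sample size factors.
#' @param dispersion_floor lower bound for the dispersion estimate.
#' @param pseudo pseudo-normalised-count added to group means for the ratio.
#' @return data frame: `gene_id`, `baseMean`, `log2fc`, `stat`, `p`, `padj`.
#' @export
de_test <- function(counts, group, size_factors = NULL,
                    dispersion_floor = 1e-8, pseudo = 0.5) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (length(group) != ncol(counts)) stop("one group label per sample required")
  n1 <- sum(group == levels(group)[1])
  n2 <- sum(group == levels(group)[2])
  if (n1 < 2 || n2 < 2) stop("need >= 2 replicates per group")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  norm <- sweep(counts, 2, size_factors, "/")
  g1 <- group == levels(group)[1]
  g2 <- !g1
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  base_mean <- rowMeans(norm)
  log2fc <- log2((m2 + pseudo) / (m1 + pseudo))

  ## method-of-moments dispersion from pooled within-group variance:
  ## Var(K/s) ~= mu * mean(1/s) + alpha * mu^2
  v1 <- apply(norm[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, stats::var)
  vpool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mu_w <- (n1 * m1 + n2 * m2) / (n1 + n2)
  zbar <- mean(1 / size_factors)
  alpha <- pmax((vpool - mu_w * zbar) / pmax(mu_w^2, 1e-300), dispersion_floor)

  z1 <- mean(1 / size_factors[g1])
  z2 <- mean(1 / size_factors[g2])
  var1 <- m1 * z1 + alpha * m1^2
  var2 <- m2 * z2 + alpha * m2^2
  se <- sqrt(var1 / (n1 * (m1 + pseudo)^2) + var2 / (n2 * (m2 + pseudo)^2)) / log(2)
  stat <- log2fc / pmax(se, 1e-300)
  p <- 2 * stats::pt(-abs(stat), df = n1 + n2 - 2)
  data.frame(
    gene_id = rownames(counts),
    baseMean = as.numeric(base_mean),
    log2fc = as.numeric(log2fc),
    stat = as.numeric(stat),
    p = as.numeric(p),
    padj = stats::p.adjust(p, "BH"),
    stringsAsFactors = FALSE
  )
}

#' baseMean-dependent fold-change threshold
#'
#' `t(b) = 5/sqrt(b) + 0.6`: the minimum |log2 fold change| a gene with
#' baseMean `b` must exceed. Strictly decreasing in `b` and approaching 0.6
#' as `b` grows, so highly expressed genes need at least a
#' `2^0.6 ~ 1.52`-fold change while a gene at baseMean 5 needs roughly a
#' seven-fold change.
#'
#' @param base_mean baseMean value(s).
#' @return threshold on the |log2FC| scale.
#' @export
de_threshold <- function(base_mean) 5 / sqrt(base_mean) + 0.6

#' Apply the baseMean-dependent significance filter
#'
#' A gene passes when `padj < padj_max`, `baseMean > base_min` (default 5)
#' and `|log2fc| > 5/sqrt(baseMean) + 0.6`.
#'
#' @param records data frame with `baseMean`, `log2fc`, `padj` (e.g.
#'   [de_test()] output, or an externally produced stats table).
#' @param padj_max adjusted-p threshold (default 0.05).
#' @param base_min minimum baseMean (default 5).
#' @return `records` with `lfc_threshold` and `passes_filter` columns added.
#' @export
significance_filter <- function(records, padj_max = 0.05, base_min = 5) {
  need <- c("baseMean", "log2fc", "padj")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  records$lfc_threshold <- de_threshold(records$baseMean)
  records$passes_filter <- records$padj < padj_max &
    records$baseMean > base_min &
    abs(records$log2fc) > records$lfc_threshold
  records
}

#' PCA quality control on log-normalised counts
#'
#' PCA of samples on `log2(normalised count + 1)` (genes centred).
#'
#' @param counts genes x samples count matrix.
#' @param size_factors optional per-sample size factors.
#' @return list: `var_explained` (fractions summing to 1) and `scores`
#'   (samples x components).
#' @export
pca_qc <- function(counts, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  lx <- log2(sweep(counts, 2, size_factors, "/") + 1)
  pc <- stats::prcomp(t(lx), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(var_explained = ve, scores = pc$x)
}
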