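## LFQ proteomics: detection/peptide filtering and a two-sample t test with
## permutation-based FDR (SAM-style median-ratio q by default, BH on
## per-protein permutation p behind a flag).

#' Filter an LFQ protein table
#'
#' Keeps proteins with a non-zero intensity in every sample, at least
#' `min_peptides` peptides, and no reverse/contaminant/site-only flag (flag
#' columns are optional).
#'
#' @param tbl protein table with `peptide_count`, intensity columns, and
#'   optional logical `reverse`, `contaminant`, `site_only` columns.
#' @param intensity_cols names of the intensity columns.
#' @param min_peptides minimum peptide count (default 3).
#' @return the filtered table.
#' @export
filter_lfq <- function(tbl, intensity_cols, min_peptides = 3) {
  miss <- setdiff(intensity_cols, names(tbl))
  if (length(miss) > 0)
    stop("intensity column(s) missing: ", paste(miss, collapse = ", "))
  x <- as.matrix(tbl[, intensity_cols, drop = FALSE])
  if (any(x < 0)) stop("negative LFQ intensity")
  keep <- rowSums(x <= 0) == 0 & tbl$peptide_count >= min_peptides
  for (fl in c("reverse", "contaminant", "site_only"))
    if (fl %in% names(tbl)) keep <- keep & !tbl[[fl]]
  tbl[keep, , drop = FALSE]
}

## all balanced label assignments: which columns play group 1
balanced_permutations <- function(n_total, n1, n_permutations, seed,
                                  max_exhaustive = 1000) {
  total <- choose(n_total, n1)
  if (total <= max_exhaustive) {
    perms <- utils::combn(n_total, n1, simplify = FALSE)
    attr(perms, "exhaustive") <- TRUE
    return(perms)
  }
  set.seed(seed)
  perms <- lapply(seq_len(n_permutations), function(i) sort(sample.int(n_total, n1)))
  attr(perms, "exhaustive") <- FALSE
  perms
}

moderated_t <- function(x, idx1, idx2, s0) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(x[, idx1, drop = FALSE])
  m2 <- rowMeans(x[, idx2, drop = FALSE])
  v1 <- apply(x[, idx1, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, idx2, drop = FALSE], 1, stats::var)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2) + s0)
}

#' Two-sample t test with permutation-based FDR
#'
#' Intensities are log2-transformed. The statistic is
#' `d = (mean1 - mean2) / (pooled SE + s0)`; with `s0 = 0` it is the
#' classical equal-variance two-sample t statistic. Group labels are
#' permuted over all balanced assignments (exhaustive when at most
#' `choose(n, n1) <= 1000`, otherwise `n_permutations` random draws under
#' `seed`). The default SAM-style q for protein i is the median over
#' permutations of the count of permuted `|d|` at or above `|d_i|`, divided
#' by the observed count at or above `|d_i|`, clipped to `[0, 1]` and
#' monotonised (non-decreasing as `|d|` decreases). `method = "bh"` instead
#' BH-adjusts per-protein permutation p-values.
#'
#' @param tbl filtered protein table ([filter_lfq()]).
#' @param group1_cols,group2_cols intensity column names of the two groups.
#' @param n_permutations permutations when sampling (default 250).
#' @param s0 variance-stabilising offset added to the denominator.
#' @param seed RNG seed for sampled permutations.
#' @param method `"sam"` (default) or `"bh"`.
#' @return `tbl` with `log2fc` (group1 - group2 mean log2 intensity),
#'   `t_stat`, `p` (per-protein permutation p) and `q` columns added.
#' @export
perm_t_test <- function(tbl, group1_cols, group2_cols, n_permutations = 250,
                        s0 = 0, seed = 1, method = c("sam", "bh")) {
  method <- match.arg(method)
  cols <- c(group1_cols, group2_cols)
  miss <- setdiff(cols, names(tbl))
  if (length(miss) > 0)
    stop("intensity column(s) missing: ", paste(miss, collapse = ", "))
  n1 <- length(group1_cols); n2 <- length(group2_cols)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  x <- as.matrix(tbl[, cols, drop = FALSE])
  if (any(x <= 0)) stop("non-positive intensity after filtering; run filter_lfq() first")
  lx <- log2(x)
  n <- nrow(lx)
  idx1 <- seq_len(n1); idx2 <- n1 + seq_len(n2)
  d_obs <- moderated_t(lx, idx1, idx2, s0)

  perms <- balanced_permutations(n1 + n2, n1, n_permutations, seed)
  exhaustive <- isTRUE(attr(perms, "exhaustive"))
  nperm <- length(perms)
  abs_obs <- abs(d_obs)
  ord <- order(abs_obs, decreasing = TRUE)
  sorted_abs <- abs_obs[ord]
  ## observed count of |d| >= |d_i| (rank within sorted absolute statistics)
  obs_count <- findInterval(-abs_obs, -sorted_abs)

  perm_counts <- matrix(0L, nrow = n, ncol = nperm)
  exceed_own <- integer(n)
  for (k in seq_len(nperm)) {
    i1 <- perms[[k]]
    i2 <- setdiff(seq_len(n1 + n2), i1)
    d_p <- moderated_t(lx, i1, i2, s0)
    abs_p <- abs(d_p)
    ## for each observed |d_i|: how many permuted |d| are >= it
    perm_counts[, k] <- length(abs_p) -
      findInterval(abs_obs, sort(abs_p), left.open = TRUE)
    exceed_own <- exceed_own + (abs_p >= abs_obs)
  }
  p <- if (exhaustive) exceed_own / nperm else (1 + exceed_own) / (1 + nperm)

  if (method == "sam") {
    med_false <- apply(perm_counts, 1, stats::median)
    q <- pmin(pmax(med_false / pmax(obs_count, 1), 0), 1)
    ## monotonise: q non-decreasing as |d| decreases
    q_sorted <- cummax(q[ord])
    q[ord] <- q_sorted
  } else {
    q <- stats::p.adjust(p, "BH")
  }
  tbl$log2fc <- rowMeans(lx[, idx1, drop = FALSE]) -
    rowMeans(lx[, idx2, drop = FALSE])
  tbl$t_stat <- as.numeric(d_obs)
  tbl$p <- as.numeric(p)
  tbl$q <- as.numeric(q)
  tbl
}

#' Count significant protein hits by direction
#'
#' @param tbl [perm_t_test()] output.
#' @param q_max q-value threshold (default 0.05).
#' @param lfc_min minimum |log2 fold change| (default 0).
#' @return list: `n_down`, `n_up`, `hits` (the significant rows).
#' @export
summarize_hits <- function(tbl, q_max = 0.05, lfc_min = 0) {
  if (nrow(tbl) == 0 || !all(c("q", "log2fc") %in% names(tbl)))
    return(list(n_down = 0L, n_up = 0L, hits = tbl[integer(0), , drop = FALSE]))
  sig <- tbl$q <= q_max & abs(tbl$log2fc) >= lfc_min
  hits <- tbl[sig, , drop = FALSE]
  list(n_down = sum(hits$log2fc < 0), n_up = sum(hits$log2fc > 0), hits = hits)
}
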