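## Cross-omic integration: gene-level merge of binding, RNA and protein
## changes; quadrant/concordance statistics; hypergeometric
## over-representation analysis of gene sets.

#' Merge binding, RNA-seq and proteomics results at the gene level
#'
#' Outer join on `gene_id`: every gene present in any layer is kept, and
#' missing layers stay `NA` (never imputed). `concordant` is defined only
#' for genes with a directional binding class (`up`/`down`) and a
#' significant RNA change; it is `TRUE` when the binding direction matches
#' the sign of the RNA log2 fold change.
#'
#' @param gene_binding [aggregate_genes()] output.
#' @param deg_table [significance_filter()] output (or any table with
#'   `gene_id`, `log2fc`, `padj`, optionally `passes_filter`).
#' @param protein_stats optional [perm_t_test()] output (needs `gene_id`,
#'   `log2fc`, `q`).
#' @param q_max protein significance threshold (default 0.05).
#' @return data frame: `gene_id`, `binding_delta`, `binding_class`,
#'   `rna_log2fc`, `rna_sig`, `protein_log2fc`, `protein_sig`, `concordant`.
#' @export
merge_omics <- function(gene_binding, deg_table, protein_stats = NULL,
                        q_max = 0.05) {
  genes <- unique(c(gene_binding$gene_id, deg_table$gene_id,
                    if (!is.null(protein_stats)) protein_stats$gene_id))
  out <- data.frame(gene_id = sort(genes), stringsAsFactors = FALSE)
  ib <- match(out$gene_id, gene_binding$gene_id)
  out$binding_delta <- gene_binding$mean_delta_lfc[ib]
  out$binding_class <- gene_binding$direction_class[ib]
  out$binding_class[is.na(out$binding_class)] <- "none"
  ir <- match(out$gene_id, deg_table$gene_id)
  out$rna_log2fc <- deg_table$log2fc[ir]
  out$rna_sig <- if ("passes_filter" %in% names(deg_table))
    deg_table$passes_filter[ir] else deg_table$padj[ir] < 0.05
  if (!is.null(protein_stats)) {
    ip <- match(out$gene_id, protein_stats$gene_id)
    out$protein_log2fc <- protein_stats$log2fc[ip]
    out$protein_sig <- protein_stats$q[ip] <= q_max
  } else {
    out$protein_log2fc <- NA_real_
    out$protein_sig <- NA
  }
  defined <- out$binding_class %in% c("up", "down") &
    !is.na(out$rna_sig) & out$rna_sig & !is.na(out$rna_log2fc)
  out$concordant <- NA
  out$concordant[defined] <-
    (out$binding_class[defined] == "up") == (out$rna_log2fc[defined] > 0)
  out
}

#' Binding-vs-RNA concordance statistics
#'
#' Builds the 2x2 quadrant table (binding up/down x RNA log2FC up/down)
#' over genes with a directional binding class and an observed RNA change
#' (mixed-class genes are excluded), and reports the 1-df chi-square
#' statistic without continuity correction plus the Wilcoxon rank-sum
#' (Mann-Whitney) p comparing RNA log2FC between binding-up and
#' binding-down genes.
#'
#' @param records [merge_omics()] output.
#' @param sig_only restrict to genes with a significant RNA change.
#' @return list: `quadrant_table` (2x2 matrix), `chi2`, `chi2_p`, `mw_p`,
#'   `n_concordant`, `n_total`, `frac_concordant`.
#' @export
concordance_stats <- function(records, sig_only = FALSE) {
  keep <- records$binding_class %in% c("up", "down") & !is.na(records$rna_log2fc)
  if (sig_only) keep <- keep & !is.na(records$rna_sig) & records$rna_sig
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0) stop("no genes with directional binding and RNA data")
  binding <- factor(r$binding_class, levels = c("up", "down"))
  rna <- factor(ifelse(r$rna_log2fc > 0, "up", "down"), levels = c("up", "down"))
  tab <- table(binding, rna)
  if (any(rowSums(tab) == 0))
    stop("empty margin: need genes in both binding directions")
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  mw <- stats::wilcox.test(r$rna_log2fc[binding == "up"],
                           r$rna_log2fc[binding == "down"])
  conc <- (binding == "up" & rna == "up") | (binding == "down" & rna == "down")
  list(
    quadrant_table = unclass(tab),
    chi2 = unname(chi$statistic),
    chi2_p = unname(chi$p.value),
    mw_p = unname(mw$p.value),
    n_concordant = sum(conc),
    n_total = nrow(r),
    frac_concordant = mean(conc)
  )
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p per gene set (sets are intersected with the
#' universe first), BH adjustment across sets; a set is enriched when
#' `padj <= fdr_max`.
#'
#' @param selected_genes character vector of selected genes (must be a
#'   subset of `universe`).
#' @param universe character vector of all testable genes.
#' @param gene_sets named list of character vectors ([read_gmt()] output).
#' @param fdr_max BH-adjusted p threshold (default 0.05).
#' @return data frame: `set`, `set_size`, `n_selected`, `overlap`, `p`,
#'   `padj`, `enriched`.
#' @export
ora_enrichment <- function(selected_genes, universe, gene_sets, fdr_max = 0.05) {
  universe <- unique(universe)
  selected_genes <- unique(selected_genes)
  stray <- setdiff(selected_genes, universe)
  if (length(stray) > 0)
    stop("selected gene(s) outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  n_sel <- length(selected_genes)
  big_n <- length(universe)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    k <- length(set)
    x <- length(intersect(set, selected_genes))
    p <- if (k == 0) 1 else
      stats::phyper(x - 1, k, big_n - k, n_sel, lower.tail = FALSE)
    data.frame(set = nm, set_size = k, n_selected = n_sel, overlap = x,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, "BH")
  out$enriched <- out$padj <= fdr_max & out$overlap > 0
  out[order(out$p), , drop = FALSE]
}
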