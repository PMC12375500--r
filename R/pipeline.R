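## End-to-end wiring: simulate -> dbp -> de -> prot -> cetsa -> integrate,
## with a YAML-configurable threshold set and a JSON run report.

default_thresholds <- function() {
  list(
    enrich_log2_min = 3, peak_p_max = 0.001, pseudocount = 1,
    dbp_p_max = 0.05, delta_min = 0.5, epsilon = 0.1,
    padj_max = 0.05, base_min = 5,
    min_peptides = 3, q_max = 0.05, s0 = 0, n_permutations = 250,
    fdr_max = 0.05
  )
}

#' Build a pipeline configuration
#'
#' Thresholds default to the analysis' canonical values (log2 enrichment
#' >= 3 and p <= 0.001 for peak significance; interaction p < 0.05 and
#' |delta LFC| > 0.5 for DBPs; padj < 0.05 plus the baseMean-dependent
#' fold-change rule for DEGs; q <= 0.05 for proteins; BH FDR <= 0.05 for
#' enrichment). A YAML file with any subset of the fields can override
#' them, and `...` overrides both.
#'
#' @param yaml_path optional YAML config file.
#' @param seed seed for the synthetic-data stage.
#' @param ... named overrides (any threshold name, `seed`, or `sim` — a
#'   named list passed to [sim_config()]).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(yaml_path = NULL, seed = 1L, ...) {
  cfg <- default_thresholds()
  cfg$seed <- seed
  cfg$sim <- list()
  if (!is.null(yaml_path)) {
    y <- yaml::read_yaml(yaml_path)
    for (nm in names(y)) cfg[[nm]] <- y[[nm]]
  }
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full synthetic-data pipeline
#'
#' Generates a complete fixture directory (or reuses one), then runs the
#' binding, expression, proteomics, melt-curve and integration stages,
#' writing each stage's TSV outputs and a JSON run report under `out_dir`.
#' Outputs are deterministic given the configuration seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param input_dir directory with pre-existing pipeline inputs; when
#'   `NULL` (default) synthetic inputs are generated under
#'   `out_dir/sim` first.
#' @param quiet suppress progress messages.
#' @return the run report, invisibly (a named list; also written as
#'   `run_report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         input_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  if (is.null(input_dir)) {
    say("stage simulate: generating synthetic inputs")
    input_dir <- file.path(out_dir, "sim")
    stage("simulate", {
      sc <- do.call(sim_config, c(list(seed = config$seed), config$sim))
      write_fixture_dir(sc, input_dir)
    })
  }
  req <- c("clusters.bed", "eclip_counts.tsv", "eclip_design.tsv",
           "annotation.tsv", "rna_counts.tsv", "rna_design.tsv",
           "proteomics.tsv", "meltcurves.csv")
  missing <- req[!file.exists(file.path(input_dir, req))]
  if (length(missing) > 0)
    stop("pipeline stage 'inputs' failed: missing input file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  ## ---- binding -------------------------------------------------------------
  say("stage dbp: differential binding analysis")
  binding <- stage("dbp", {
    clusters <- read_bed(file.path(input_dir, "clusters.bed"))
    cm <- read_count_matrix(file.path(input_dir, "eclip_counts.tsv"),
                            file.path(input_dir, "eclip_design.tsv"))
    ann <- read_annotation(file.path(input_dir, "annotation.tsv"))
    clusters <- annotate_regions(clusters, ann)
    rpm <- rpm_normalize(cm$counts, cm$design)
    peaks_u <- call_significant_peaks(cm$counts, cm$design, "untreated",
                                      config$enrich_log2_min, config$peak_p_max,
                                      config$pseudocount)
    peaks_t <- call_significant_peaks(cm$counts, cm$design, "treated",
                                      config$enrich_log2_min, config$peak_p_max,
                                      config$pseudocount)
    dbps <- call_dbps(rpm, cm$design, config$dbp_p_max, config$delta_min,
                      config$epsilon)
    gene_summary <- aggregate_genes(dbps, clusters)
    gid <- function(pk) unique(clusters$gene_id[
      clusters$cluster_id %in% pk$cluster_id[pk$significant] &
        clusters$gene_id != ""])
    ov <- overlap_summary(gid(peaks_u), gid(peaks_t))
    rd <- region_distribution(clusters, peaks_u)
    write_tsv(dbps, file.path(out_dir, "dbp_results.tsv"),
              "per-cluster interaction p, condition log2FCs, delta LFC, direction")
    write_tsv(gene_summary, file.path(out_dir, "gene_summary.tsv"),
              "gene-level DBP counts, direction class and mean delta LFC")
    write_tsv(data.frame(metric = names(unlist(ov)), value = unlist(ov)),
              file.path(out_dir, "overlap_summary.tsv"),
              "bound-gene overlap between conditions")
    write_tsv(data.frame(region = names(rd), proportion = as.numeric(rd)),
              file.path(out_dir, "region_distribution.tsv"),
              "region mix of significant untreated peaks")
    list(clusters = clusters, dbps = dbps, gene_summary = gene_summary,
         overlap = ov, region_distribution = rd,
         peaks_untreated = peaks_u, peaks_treated = peaks_t)
  })

  ## ---- expression ----------------------------------------------------------
  say("stage de: differential expression")
  de <- stage("de", {
    rc <- read_tsv(file.path(input_dir, "rna_counts.tsv"))
    rdsn <- read_tsv(file.path(input_dir, "rna_design.tsv"))
    m <- as.matrix(rc[, -1, drop = FALSE]); rownames(m) <- rc[[1]]
    storage.mode(m) <- "integer"
    m <- prefilter_low_counts(m)
    grp <- factor(rdsn$treatment[match(colnames(m), rdsn$sample_id)],
                  levels = c("untreated", "treated"))
    deg <- de_test(m, grp)
    deg <- significance_filter(deg, padj_max = config$padj_max,
                               base_min = config$base_min)
    write_tsv(deg, file.path(out_dir, "deg_table.tsv"),
              "gene-level DE: baseMean, log2FC, p, BH padj, baseMean-dependent filter")
    deg
  })

  ## ---- proteomics ----------------------------------------------------------
  say("stage prot: permutation-FDR proteomics")
  prot <- stage("prot", {
    pt <- read_tsv(file.path(input_dir, "proteomics.tsv"))
    trt_cols <- grep("^trt_", names(pt), value = TRUE)
    ctl_cols <- grep("^ctl_", names(pt), value = TRUE)
    flt <- filter_lfq(pt, c(trt_cols, ctl_cols),
                      min_peptides = config$min_peptides)
    res <- perm_t_test(flt, trt_cols, ctl_cols,
                       n_permutations = config$n_permutations,
                       s0 = config$s0, seed = config$seed)
    write_tsv(res, file.path(out_dir, "protein_stats.tsv"),
              "filtered LFQ proteins with t statistic, permutation p and q")
    res
  })

  ## ---- meltcurve -----------------------------------------------------------
  say("stage cetsa: melt-curve fitting")
  melt <- stage("cetsa", {
    mc <- read_meltcurve_csv(file.path(input_dir, "meltcurves.csv"))
    conds <- unique(mc$condition)
    fits <- list()
    rows <- list()
    for (cond in conds) {
      sub <- mc[mc$condition == cond, , drop = FALSE]
      for (r in unique(sub$replicate)) {
        f <- fit_melt(sub[sub$replicate == r, , drop = FALSE])
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, replicate = r, tm = f$tm, slope = f$slope,
          top = f$top, bottom = f$bottom, r2 = f$r2,
          tm_ci_low = f$tm_ci[1], tm_ci_high = f$tm_ci[2])
      }
      fits[[cond]] <- fit_melt(sub)  # pooled fit over replicates
    }
    fit_tab <- do.call(rbind, rows)
    write_tsv(fit_tab, file.path(out_dir, "melt_fits.tsv"),
              "per-replicate Boltzmann fits; Tm = inflection temperature")
    cmp <- NULL
    if (length(conds) >= 2) {
      cmp <- compare_tm(fits[[conds[1]]], fits[[conds[2]]])
      write_tsv(data.frame(metric = names(unlist(cmp)), value = unlist(cmp)),
                file.path(out_dir, "melt_comparison.tsv"),
                sprintf("pooled-fit Tm comparison: %s vs %s", conds[2], conds[1]))
    }
    list(fits = fit_tab, comparison = cmp)
  })

  ## ---- integration ---------------------------------------------------------
  say("stage integrate: cross-omic merge and concordance")
  integ <- stage("integrate", {
    merged <- merge_omics(binding$gene_summary, de, prot, q_max = config$q_max)
    conc <- concordance_stats(merged)
    write_tsv(merged, file.path(out_dir, "integration_table.tsv"),
              "gene-level binding/RNA/protein merge; concordance flags")
    conc_df <- data.frame(
      metric = c("chi2", "chi2_p", "mw_p", "n_concordant", "n_total",
                 "frac_concordant"),
      value = c(conc$chi2, conc$chi2_p, conc$mw_p, conc$n_concordant,
                conc$n_total, conc$frac_concordant))
    write_tsv(conc_df, file.path(out_dir, "concordance.tsv"),
              "binding-vs-RNA quadrant chi-square and rank-sum statistics")
    gmt_path <- file.path(input_dir, "gene_sets.gmt")
    enr <- NULL
    if (file.exists(gmt_path)) {
      sets <- read_gmt(gmt_path)
      sel <- de$gene_id[de$passes_filter]
      enr <- ora_enrichment(sel, de$gene_id, sets, fdr_max = config$fdr_max)
      write_tsv(enr, file.path(out_dir, "enrichment.tsv"),
                "hypergeometric over-representation of DEG sets")
    }
    list(merged = merged, concordance = conc, enrichment = enr)
  })

  report <- list(
    package_version = as.character(utils::packageVersion("rbpshift")),
    seed = config$seed,
    thresholds = config[names(default_thresholds())],
    n_significant_peaks_untreated = sum(binding$peaks_untreated$significant),
    n_significant_peaks_treated = sum(binding$peaks_treated$significant),
    n_dbps_up = sum(binding$dbps$direction == "up"),
    n_dbps_down = sum(binding$dbps$direction == "down"),
    n_dbp_genes = nrow(binding$gene_summary),
    bound_gene_overlap = binding$overlap,
    region_distribution = as.list(binding$region_distribution),
    n_degs = sum(de$passes_filter),
    n_protein_hits = sum(prot$q <= config$q_max),
    melt_delta_tm = if (!is.null(melt$comparison)) melt$comparison$delta_tm else NA,
    concordance = integ$concordance[c("chi2", "chi2_p", "mw_p",
                                      "frac_concordant")]
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: ", out_dir)
  invisible(report)
}
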