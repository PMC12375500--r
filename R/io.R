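#' rbpshift: multi-omic analysis of perturbed RNA-binding-protein activity
#'
#' The package is organised around the stages of the analysis:
#' synthetic-data generation ([simulate_eclip()] and friends), eCLIP
#' differential binding ([call_significant_peaks()], [call_dbps()]),
#' RNA-seq differential expression ([de_test()], [significance_filter()]),
#' permutation-FDR proteomics ([perm_t_test()]), CETSA melt-curve fitting
#' ([fit_melt()]) and cross-omic integration ([merge_omics()],
#' [concordance_stats()], [ora_enrichment()]). [run_pipeline()] wires the
#' stages end to end.
#'
#' @keywords internal
#' @aliases rbpshift-package
"_PACKAGE"

REGION_LEVELS <- c("5UTR", "CDS", "3UTR", "intron", "intergenic", "other")

## ---- validation helpers ----------------------------------------------------

validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s table missing column(s): %s", what, paste(miss, collapse = ", ")))
  if (any(df$start < 0)) stop(sprintf("%s: negative start coordinate", what))
  bad <- which(df$end <= df$start)
  if (length(bad) > 0)
    stop(sprintf("%s: end <= start for record(s) %s", what,
                 paste(utils::head(bad, 5), collapse = ", ")))
  if (!all(df$strand %in% c("+", "-", ".")))
    stop(sprintf("%s: strand must be one of '+', '-', '.'", what))
  invisible(df)
}

validate_clusters <- function(clusters) {
  validate_intervals(clusters, "cluster")
  if (!"cluster_id" %in% names(clusters)) stop("cluster table needs a 'cluster_id' column")
  if (anyDuplicated(clusters$cluster_id) > 0) stop("cluster_id values must be unique")
  invisible(clusters)
}

validate_design <- function(design) {
  stopifnot(is.data.frame(design))
  need <- c("sample_id", "assay", "treatment", "replicate", "library_size")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0)
    stop("design table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(design$assay %in% c("IP", "input")))
    stop("design 'assay' must be 'IP' or 'input'")
  if (!all(design$treatment %in% c("treated", "untreated")))
    stop("design 'treatment' must be 'treated' or 'untreated'")
  if (any(design$library_size <= 0)) stop("library_size must be positive")
  key <- paste(design$assay, design$treatment, design$replicate)
  if (anyDuplicated(key) > 0)
    stop("(assay, treatment, replicate) combinations must be unique")
  invisible(design)
}

## ---- coordinate conventions ------------------------------------------------

#' Convert 1-based closed coordinates to the package's 0-based half-open form
#'
#' All interval tables in the package are BED-style: 0-based starts,
#' exclusive ends. Inputs exported from 1-based tools (GTF-style) pass
#' through this single helper.
#'
#' @param df data frame with `start` and `end` columns in 1-based closed form.
#' @return The data frame with `start` shifted to 0-based (end unchanged:
#'   a 1-based closed end equals a 0-based exclusive end).
#' @export
from_one_based <- function(df) {
  stopifnot(all(c("start", "end") %in% names(df)))
  df$start <- df$start - 1L
  df
}

## GRanges bridge: "." strand is unknown and matches either strand ("*").
clusters_to_granges <- function(df) {
  strand <- ifelse(df$strand == ".", "*", df$strand)
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

## ---- BED -------------------------------------------------------------------

#' Read a BED file of eCLIP clusters/peaks
#'
#' Parses BED (>= 3 columns; BED6 recommended) as 0-based half-open
#' intervals. Column 4 becomes `cluster_id` (auto-generated when absent),
#' column 5 `score`, column 6 `strand` (`"."` when absent, meaning unknown).
#' Columns beyond 6 are preserved as `extra1`, `extra2`, ... so that
#' narrowPeak-style files round-trip.
#'
#' @param path path to a BED file.
#' @return data frame with columns `chrom`, `start`, `end`, `cluster_id`,
#'   `score`, `strand` (+ any extras), one row per record.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("BED file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 tab-separated fields")
  starts <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  ends   <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad) > 0)
    stop("malformed BED line ", bad[1], ": non-integer coordinates")
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = starts,
    end = ends,
    cluster_id = if (max(nf) >= 4)
      vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, "")
      else sprintf("cluster_%06d", seq_along(fields)),
    score = if (max(nf) >= 5)
      suppressWarnings(as.numeric(vapply(fields, function(f)
        if (length(f) >= 5) f[5] else "0", "")))
      else 0,
    strand = if (max(nf) >= 6)
      vapply(fields, function(f) if (length(f) >= 6) f[6] else ".", "")
      else ".",
    stringsAsFactors = FALSE
  )
  maxextra <- max(nf) - 6L
  if (maxextra > 0) {
    for (k in seq_len(maxextra)) {
      df[[paste0("extra", k)]] <- vapply(fields, function(f)
        if (length(f) >= 6 + k) f[6 + k] else NA_character_, "")
    }
  }
  bad <- which(df$end <= df$start)
  if (length(bad) > 0)
    stop("invalid BED line ", bad[1], ": start >= end")
  validate_clusters(df)
  df
}

#' Write clusters to BED
#'
#' @param clusters cluster data frame as returned by [read_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(clusters, path) {
  validate_clusters(clusters)
  cols <- c("chrom", "start", "end", "cluster_id")
  if ("score" %in% names(clusters)) cols <- c(cols, "score")
  if ("strand" %in% names(clusters)) cols <- c(cols, "strand")
  extras <- grep("^extra[0-9]+$", names(clusters), value = TRUE)
  out <- clusters[, c(cols, extras), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- TSV with commented header ---------------------------------------------

#' Write a data frame as TSV with a commented description header
#'
#' All tabular outputs of the pipeline use this format: `#`-prefixed
#' description lines, then a header row, then tab-separated values.
#'
#' @param df data frame.
#' @param path output path.
#' @param comments character vector of description lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (comment lines are skipped)
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

## ---- count matrices and designs --------------------------------------------

#' Read a count matrix plus its sample design table
#'
#' The matrix TSV has feature ids in the first column and one column per
#' sample; the design TSV has columns `sample_id`, `assay`, `treatment`,
#' `replicate`, `library_size`. Every matrix column must have a design row.
#'
#' @param path count matrix TSV.
#' @param design_path sample design TSV.
#' @return list with `counts` (integer matrix, features x samples) and
#'   `design` (data frame, ordered to match the matrix columns).
#' @export
read_count_matrix <- function(path, design_path) {
  tab <- read_tsv(path)
  if (ncol(tab) < 2) stop("count matrix needs a feature-id column plus >= 1 sample")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids) > 0) stop("duplicate feature ids in count matrix")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric count value in matrix")
  if (any(m < 0)) stop("negative count in matrix")
  if (any(m != round(m))) stop("non-integer count in matrix")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  design <- read_tsv(design_path)
  validate_design(design)
  missing <- setdiff(colnames(m), design$sample_id)
  if (length(missing) > 0)
    stop("sample(s) in count matrix absent from design: ",
         paste(missing, collapse = ", "))
  design <- design[match(colnames(m), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  list(counts = m, design = design)
}

#' Write a count matrix to TSV
#' @param counts matrix with feature rownames and sample colnames.
#' @param path output path.
#' @param id_col name for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, id_col = "feature_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path, comments = sprintf(
    "%s: raw read counts, one column per sample", id_col))
}

## ---- gene annotation -------------------------------------------------------

#' Read a simplified gene annotation table
#'
#' A GTF-lite TSV with columns `gene_id`, `chrom`, `start` (0-based),
#' `end` (exclusive), `strand`, `region` (one of 5UTR/CDS/3UTR/intron).
#' Features of one gene must share chromosome and strand.
#'
#' @param path annotation TSV.
#' @return validated annotation data frame.
#' @export
read_annotation <- function(path) {
  ann <- read_tsv(path)
  need <- c("gene_id", "chrom", "start", "end", "strand", "region")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0)
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  validate_intervals(ann, "annotation")
  if (!all(ann$region %in% REGION_LEVELS))
    stop("annotation region labels must be in: ", paste(REGION_LEVELS, collapse = ", "))
  chk <- tapply(paste(ann$chrom, ann$strand), ann$gene_id,
                function(x) length(unique(x)))
  if (any(chk > 1))
    stop("features of gene(s) ", paste(names(chk)[chk > 1][1]),
         " span multiple chromosomes/strands")
  ann
}

## ---- GMT gene sets ---------------------------------------------------------

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`.
#' Members are deduplicated; lines with fewer than three fields, or with no
#' members, are an error.
#'
#' @param path GMT file.
#' @return named list of gene sets; each element is a character vector of
#'   member ids with a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed GMT line ", which(nf < 3)[1],
         ": expected name, description and >= 1 member")
  sets <- lapply(fields, function(f) {
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) stop("GMT set '", f[1], "' has no members")
    attr(members, "description") <- f[2]
    members
  })
  names(sets) <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names(sets)) > 0) stop("duplicate gene-set names in GMT")
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors (optionally with a
#'   `description` attribute each).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    desc <- attr(sets[[i]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(names(sets)[i], desc, as.character(sets[[i]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

## ---- melt-curve CSV --------------------------------------------------------

#' Read a CETSA densitometry table
#'
#' CSV with columns `temperature` (degrees C), `fraction` (band intensity
#' normalised to the lowest temperature), `condition`, `replicate`.
#'
#' @param path CSV file.
#' @return data frame.
#' @export
read_meltcurve_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature", "fraction", "condition", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("melt-curve table missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$temperature) || !is.numeric(df$fraction))
    stop("temperature and fraction must be numeric")
  df
}
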