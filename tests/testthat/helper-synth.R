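# Small in-code fixture builders shared across test files.

# 2x2 eCLIP design with n replicates per cell and equal library sizes
make_design <- function(n_rep = 2, lib = 1e6) {
  grid <- expand.grid(replicate = seq_len(n_rep),
                      assay = c("IP", "input"),
                      treatment = c("untreated", "treated"),
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_%s_%d", ifelse(grid$assay == "IP", "ip", "in"),
                        ifelse(grid$treatment == "treated", "trt", "untr"),
                        grid$replicate),
    assay = grid$assay, treatment = grid$treatment,
    replicate = grid$replicate, library_size = lib,
    stringsAsFactors = FALSE)
}

# One-cluster RPM matrix from per-cell replicate values, cells in order
# (IP,untreated), (input,untreated), (IP,treated), (input,treated)
make_rpm <- function(cell_values, design, id = "cl1") {
  m <- matrix(NA_real_, nrow = 1, ncol = nrow(design),
              dimnames = list(id, design$sample_id))
  key <- paste(design$assay, design$treatment)
  cells <- c("IP untreated", "input untreated", "IP treated", "input treated")
  for (i in seq_along(cells)) m[1, key == cells[i]] <- cell_values[[i]]
  m
}

# LFQ table with given log2 intensity matrix (rows proteins; first n1
# columns group 1)
make_lfq <- function(log2_intensities, n1 = 4, peptides = 5L) {
  n <- nrow(log2_intensities)
  n2 <- ncol(log2_intensities) - n1
  tbl <- data.frame(protein_id = sprintf("P%04d", seq_len(n)),
                    gene_id = sprintf("G%04d", seq_len(n)),
                    peptide_count = rep(peptides, length.out = n),
                    stringsAsFactors = FALSE)
  x <- 2^log2_intensities
  colnames(x) <- c(sprintf("t_%d", seq_len(n1)), sprintf("c_%d", seq_len(n2)))
  cbind(tbl, as.data.frame(x))
}

lfq_cols <- function(tbl) {
  list(g1 = grep("^t_", names(tbl), value = TRUE),
       g2 = grep("^c_", names(tbl), value = TRUE))
}
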