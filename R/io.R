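## TSV dialects. Tab is the single delimiter everywhere; gene ids may
## contain commas in annotation sources, so CSV is deliberately avoided.

#' Read a gene x sample count matrix from TSV
#'
#' First column gene id, header = sample ids. Duplicated gene ids,
#' negative or non-integer counts are rejected with row-numbered messages.
#'
#' @param path TSV file path.
#' @return Integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stopf("count table needs a gene column plus samples")
  genes <- as.character(d[[1]])
  if (anyDuplicated(genes))
    stopf("duplicated gene id at row %d: %s",
          which(duplicated(genes))[1], genes[duplicated(genes)][1])
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("counts must be numeric")
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stopf("negative or non-integer count at row %d (gene %s), sample %s",
          bad[1, 1], genes[bad[1, 1]], colnames(m)[bad[1, 2]])
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Read a sample metadata table from TSV
#'
#' Columns `sample`, `species` (one of `parentA`, `parentB`, `hybrid`),
#' `tissue`, `individual`.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_samples <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "species", "tissue", "individual")
  if (!all(need %in% names(d)))
    stopf("sample table must have columns: %s", paste(need, collapse = ", "))
  bad <- !d$species %in% c("parentA", "parentB", "hybrid")
  if (any(bad))
    stopf("unknown species label '%s' at row %d", d$species[bad][1],
          which(bad)[1])
  if (anyDuplicated(d$sample))
    stopf("duplicated sample id at row %d: %s",
          which(duplicated(d$sample))[1], d$sample[duplicated(d$sample)][1])
  d
}

#' Read a phased allelic count table from TSV
#'
#' Columns `gene`, `individual`, `tissue`, `snp`, `hapA`, `hapB`,
#' `phase_set`. Counts must be non-negative; (gene, individual, tissue,
#' snp) must be unique.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_allele_counts <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "individual", "tissue", "snp", "hapA", "hapB",
            "phase_set")
  if (!all(need %in% names(d)))
    stopf("allele count table must have columns: %s",
          paste(need, collapse = ", "))
  bad <- which(d$hapA < 0 | d$hapB < 0)
  if (length(bad)) stopf("negative allelic count at row %d", bad[1])
  key <- paste(d$gene, d$individual, d$tissue, d$snp)
  if (anyDuplicated(key))
    stopf("duplicated (gene, individual, tissue, snp) at row %d",
          which(duplicated(key))[1])
  d
}

#' Read a gene annotation table from TSV
#'
#' Requires `gene`, `chrom_class`, `length`; `cne_flag` and the covariates
#' (`ppi`, `tau`, `phi`, `piNpiS`, `dNdS`, `fst`) are optional and loaded
#' as missing (`NA`) when absent.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom_class", "length")
  if (!all(need %in% names(d)))
    stopf("annotation must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(d$gene))
    stopf("duplicated gene id at row %d", which(duplicated(d$gene))[1])
  ok_cls <- c("autosome", "Z", "mito", "unassigned")
  bad <- !d$chrom_class %in% ok_cls
  if (any(bad))
    stopf("unknown chromosome class '%s' at row %d (expected %s)",
          d$chrom_class[bad][1], which(bad)[1], paste(ok_cls, collapse = "/"))
  for (cc in c("cne_flag", "ppi", "tau", "phi", "piNpiS", "dNdS", "fst"))
    if (!cc %in% names(d)) d[[cc]] <- NA
  if (!is.logical(d$cne_flag)) d$cne_flag <- as.logical(d$cne_flag)
  d
}

#' Cross-validate a count matrix against its sample table
#'
#' @param counts count matrix.
#' @param samples sample table.
#' @return Invisibly TRUE; errors list the offending sample ids.
#' @export
validate_inputs <- function(counts, samples) {
  missing_meta <- setdiff(colnames(counts), samples$sample)
  if (length(missing_meta))
    stopf("sample(s) in counts but absent from the sample table: %s",
          paste(missing_meta, collapse = ", "))
  missing_cts <- setdiff(samples$sample, colnames(counts))
  if (length(missing_cts))
    stopf("sample(s) in the sample table but absent from counts: %s",
          paste(missing_cts, collapse = ", "))
  invisible(TRUE)
}

#' Write a table as TSV with stable numeric formatting
#'
#' Doubles are written in scientific notation with 6 significant digits so
#' that output diffs are stable across platforms; integers and strings are
#' written as-is.
#'
#' @param d data.frame.
#' @param path output path.
#' @return Invisibly `path`.
#' @export
write_tsv <- function(d, path) {
  d <- as.data.frame(d)
  for (j in seq_along(d))
    if (is.double(d[[j]])) d[[j]] <- formatC(d[[j]], format = "e", digits = 5)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a count matrix as TSV (gene column first)
#'
#' @param counts matrix with gene rownames.
#' @param path output path.
#' @return Invisibly `path`.
#' @export
write_counts <- function(counts, path) {
  d <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
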