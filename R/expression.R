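#' Transcripts per million from counts and effective lengths
#'
#' Per sample: length-normalized count rates rescaled to sum to 1e6.
#' An all-zero sample keeps an all-zero column (with a message) rather than
#' dividing by zero.
#'
#' @param counts genes x samples count matrix.
#' @param effective_lengths positive numeric per gene (same order/names).
#' @return genes x samples TPM matrix.
#' @examples
#' tpm(matrix(c(100, 300), 2, 1), c(1000, 3000))
#' @export
tpm <- function(counts, effective_lengths) {
  counts <- as.matrix(counts)
  if (length(effective_lengths) != nrow(counts))
    stopf("one effective length per gene required")
  bad <- !is.finite(effective_lengths) | effective_lengths <= 0
  if (any(bad))
    stopf("zero or missing effective length for gene(s): %s",
          paste(head((rownames(counts) %||% seq_len(nrow(counts)))[bad], 5),
                collapse = ", "))
  rate <- counts / effective_lengths
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    message(sum(zero), " all-zero sample(s) kept as all-zero TPM columns")
    tot[zero] <- 1
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Tissue-specificity index tau
#'
#' For a per-gene expression profile across n >= 2 tissues,
#' `tau = sum(1 - x / max(x)) / (n - 1)`: 0 for a uniform profile, 1 for
#' expression confined to a single tissue. By convention the index is
#' computed on log-damped mean expression, `log2(mean TPM + 1)`, because the
#' raw index is scale-sensitive; set `transform = "none"` to use the values
#' as given. All-zero genes are undefined (`NA`).
#'
#' @param expr genes x tissues matrix of per-tissue mean expression (>= 0).
#' @param transform `"log2p1"` (default) or `"none"`.
#' @return Numeric vector of tau per gene.
#' @examples
#' tau_index(rbind(c(8, 8, 8), c(5, 0, 0)), transform = "none")
#' @export
tau_index <- function(expr, transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stopf("tau needs >= 2 tissues")
  if (any(expr < 0, na.rm = TRUE)) stopf("expression values must be >= 0")
  if (transform == "log2p1") expr <- log2(expr + 1)
  mx <- apply(expr, 1, max)
  t_out <- rowSums(1 - expr / mx) / (ncol(expr) - 1)
  t_out[mx == 0] <- NA_real_
  setNames(t_out, rownames(expr))
}

#' Per-species tau and the cross-species consensus
#'
#' Computes tau separately for each species group from within-group mean
#' TPM per tissue, then summarizes the species-specific indices by their
#' first principal component ("the major variation in tissue specificity
#' across species"), sign-fixed to correlate positively with the per-species
#' values and min-max rescaled to [0, 1].
#'
#' @param tpm_mat genes x samples TPM matrix.
#' @param samples sample table with `sample`, `species`, `tissue`.
#' @param transform passed to [tau_index()].
#' @return data.frame: `gene`, one tau column per species, `consensus`.
#' @export
tau_by_species <- function(tpm_mat, samples, transform = "log2p1") {
  species <- unique(samples$species)
  taus <- sapply(species, function(sp) {
    sub <- samples[samples$species == sp, ]
    bytis <- sapply(split(sub$sample, sub$tissue), function(ss)
      rowMeans(tpm_mat[, ss, drop = FALSE]))
    tau_index(bytis, transform = transform)
  })
  ok <- complete.cases(taus)
  consensus <- rep(NA_real_, nrow(taus))
  if (sum(ok) >= 2) {
    pc <- prcomp(taus[ok, , drop = FALSE], center = TRUE, scale. = FALSE)
    sc <- pc$x[, 1]
    if (cor(sc, rowMeans(taus[ok, , drop = FALSE])) < 0) sc <- -sc
    rng <- range(sc)
    consensus[ok] <- if (diff(rng) > 0) (sc - rng[1]) / diff(rng) else 0.5
  }
  out <- data.frame(gene = rownames(tpm_mat) %||% seq_len(nrow(tpm_mat)),
                    taus, consensus = consensus, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out)[1 + seq_along(species)] <- paste0("tau_", species)
  out
}

#' Census of expressed genes (group mean TPM strictly above a threshold)
#'
#' @param tpm_mat genes x samples TPM matrix.
#' @param groups factor per sample (e.g. the species:tissue interaction).
#' @param threshold strict lower bound on the within-group mean TPM
#'   (default 1: a mean of exactly 1.0 is not counted).
#' @return Named integer vector: expressed-gene count per group level.
#' @export
count_expressed <- function(tpm_mat, groups, threshold = 1) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0) || length(groups) != ncol(tpm_mat))
    stopf("'groups' must assign every sample to a nonempty group")
  sapply(split(seq_along(groups), groups), function(idx)
    sum(rowMeans(tpm_mat[, idx, drop = FALSE]) > threshold))
}

#' Expressed-gene census per species and tissue
#'
#' @param tpm_mat genes x samples TPM matrix.
#' @param samples sample table.
#' @param threshold passed to [count_expressed()].
#' @return data.frame `species`, `tissue`, `n_expressed`.
#' @export
expressed_census <- function(tpm_mat, samples, threshold = 1) {
  grid <- unique(samples[, c("species", "tissue")])
  grid$n_expressed <- mapply(function(sp, tt) {
    ss <- samples$sample[samples$species == sp & samples$tissue == tt]
    sum(rowMeans(tpm_mat[, ss, drop = FALSE]) > threshold)
  }, grid$species, grid$tissue)
  rownames(grid) <- NULL
  grid
}

#' Mean TPM of marker genes per group
#'
#' For named marker sets (e.g. spermatogenesis stages), reports the
#' within-group mean TPM of every matched marker gene and the per-set
#' median of those means. Markers absent from the matrix are listed under
#' `unmatched` rather than failing.
#'
#' @param tpm_mat genes x samples TPM matrix.
#' @param marker_sets named list of character gene-id vectors, or a
#'   two-column data.frame (`set_name`, `gene_id`).
#' @param groups factor per sample.
#' @return List: `gene_means` (data.frame set, gene, one column per group),
#'   `set_medians`, `unmatched` (character).
#' @export
marker_profile <- function(tpm_mat, marker_sets, groups) {
  if (is.data.frame(marker_sets))
    marker_sets <- split(marker_sets[[2]], marker_sets[[1]])
  groups <- as.factor(groups)
  all_ids <- unlist(marker_sets, use.names = FALSE)
  unmatched <- setdiff(all_ids, rownames(tpm_mat))
  gm <- sapply(split(seq_along(groups), groups), function(idx)
    rowMeans(tpm_mat[, idx, drop = FALSE]))

  rows <- lapply(names(marker_sets), function(set) {
    hit <- intersect(marker_sets[[set]], rownames(tpm_mat))
    if (!length(hit)) {
      warnf("marker set '%s' has no matched genes", set)
      return(NULL)
    }
    data.frame(set = set, gene = hit, gm[hit, , drop = FALSE],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  gene_means <- do.call(rbind, rows)
  set_medians <- if (!is.null(gene_means) && nrow(gene_means))
    aggregate(gene_means[, levels(groups), drop = FALSE],
              by = list(set = gene_means$set), FUN = median)
  else NULL
  list(gene_means = gene_means, set_medians = set_medians,
       unmatched = unmatched)
}
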