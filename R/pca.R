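#' PCA of samples on gene-wise centered expression
#'
#' Principal components of the sample x gene matrix after centering each
#' gene across samples (no scaling). The returned model retains the
#' centering vector and loadings so held-out samples can be projected.
#'
#' @param mat genes x samples matrix of transformed expression (see
#'   [rlog_like()]).
#' @return List of class `hx_pca`: `scores` (samples x PCs), `loadings`
#'   (genes x PCs), `center` (per-gene means), `var_fraction`.
#' @export
pca_expression <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stopf("PCA needs >= 2 samples")
  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  structure(list(scores = pc$x, loadings = pc$rotation, center = pc$center,
                 var_fraction = pc$sdev^2 / sum(pc$sdev^2)),
            class = "hx_pca")
}

#' Project held-out samples onto a fitted PCA
#'
#' Centers the new profiles with the training centering vector and
#' multiplies onto the loadings. Projecting a training sample returns its
#' original score; projecting the training mean profile returns the origin.
#'
#' @param model an `hx_pca` from [pca_expression()].
#' @param newmat genes x new-samples matrix on the same gene universe
#'   (same genes, same order).
#' @return new-samples x PCs score matrix.
#' @export
project_samples <- function(model, newmat) {
  newmat <- as.matrix(newmat)
  if (nrow(newmat) != length(model$center))
    stopf("gene universe mismatch: model has %d genes, new data %d",
          length(model$center), nrow(newmat))
  if (!is.null(rownames(newmat)) && !is.null(rownames(model$loadings)) &&
      !identical(rownames(newmat), rownames(model$loadings)))
    stopf("gene universe mismatch: gene ids differ from the fitted model")
  sweep(t(newmat), 2, model$center) %*% model$loadings
}

#' Between-groups PCA inertia with a Monte-Carlo permutation test
#'
#' Quantifies the percentage of total expression variance ("explained
#' inertia") attributable to a grouping factor: after gene-wise centering,
#' each sample profile is replaced by its group mean and the ratio of
#' between-group to total sum of squares is reported. Significance comes
#' from a Monte-Carlo test: labels are permuted `n_perm` times and
#' `p = (#{permuted inertia >= observed} + 1) / (n_perm + 1)`, so the
#' smallest attainable p with 99 permutations is 0.01.
#'
#' A second, conditioning factor can be supplied (e.g. tissue identity when
#' testing species): the data are then centered within each conditioning
#' level before the between-groups step, and permutations are restricted
#' within conditioning levels.
#'
#' @param mat genes x samples matrix of transformed expression.
#' @param labels grouping factor per sample.
#' @param n_perm number of Monte-Carlo permutations (default 99).
#' @param condition_on optional conditioning factor per sample.
#' @param seed optional integer seed for the permutation stream.
#' @return List of class `hx_bgpca`: `inertia` (percent), `p`, `n_perm`,
#'   `perm_inertia`.
#' @export
between_group_pca <- function(mat, labels, n_perm = 99, condition_on = NULL,
                              seed = NULL) {
  mat <- as.matrix(mat)
  labels <- droplevels(as.factor(labels))
  if (any(table(labels) == 0) || length(labels) != ncol(mat))
    stopf("'labels' must assign every sample to a nonempty group")
  y <- t(mat)
  y <- sweep(y, 2, colMeans(y))
  if (!is.null(condition_on)) {
    condition_on <- droplevels(as.factor(condition_on))
    for (lv in levels(condition_on)) {
      idx <- condition_on == lv
      y[idx, ] <- sweep(y[idx, , drop = FALSE],
                        2, colMeans(y[idx, , drop = FALSE]))
    }
  }
  total <- sum(y^2)
  inertia_of <- function(lab) {
    if (total == 0) return(0)
    gm <- rowsum(y, lab)
    gm <- gm / as.vector(table(lab)[rownames(gm)])
    sum(gm[as.character(lab), , drop = FALSE]^2) / total * 100
  }
  obs <- inertia_of(labels)

  perm_one <- function() {
    if (is.null(condition_on)) sample(labels)
    else {
      out <- labels
      for (lv in levels(condition_on)) {
        idx <- which(condition_on == lv)
        out[idx] <- labels[sample(idx)]
      }
      out
    }
  }
  runner <- function() vapply(seq_len(n_perm),
                              function(i) inertia_of(perm_one()), 0)
  perm <- if (is.null(seed)) runner() else with_seed(seed, runner())
  p <- (sum(perm >= obs) + 1) / (n_perm + 1)
  structure(list(inertia = obs, p = p, n_perm = n_perm, perm_inertia = perm),
            class = "hx_bgpca")
}

#' @export
print.hx_bgpca <- function(x, ...) {
  cat(sprintf("between-groups PCA: %.2f%% inertia, Monte-Carlo p = %.4g (%d permutations)\n",
              x$inertia, x$p, x$n_perm))
  invisible(x)
}
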