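## Vectorized IRLS fit of the per-gene NB GLM  log mu = b1 + b2 * x + log sf
## at fixed dispersion. `ridge` is the precision (1/variance, natural-log
## scale) of a zero-centered Gaussian prior on b2; 0 gives the MLE.
fit_nb_glm <- function(counts, sf, disp, x, ridge = 0,
                       max_iter = 100, tol = 1e-8) {
  counts <- as.matrix(counts)
  ng <- nrow(counts); n <- ncol(counts)
  off <- matrix(log(sf), ng, n, byrow = TRUE)
  xm <- matrix(x, ng, n, byrow = TRUE)
  disp <- rep_len(disp, ng)

  norm <- sweep(counts, 2, sf, "/")
  m1 <- rowMeans(norm[, x == 1, drop = FALSE])
  m0 <- rowMeans(norm[, x == 0, drop = FALSE])
  b1 <- log(pmax(m0, 0.1))
  b2 <- log(pmax(m1, 0.1)) - log(pmax(m0, 0.1))

  active <- rowSums(counts) > 0
  conv <- !active
  for (it in seq_len(max_iter)) {
    if (all(conv)) break
    idx <- which(!conv)
    eta <- b1[idx] + outer(b2[idx], x) + off[idx, , drop = FALSE]
    eta <- pmin(eta, 30)
    mu <- exp(eta)
    w <- mu / (1 + disp[idx] * mu)
    z <- eta - off[idx, , drop = FALSE] + (counts[idx, , drop = FALSE] - mu) / mu
    a11 <- rowSums(w)
    a12 <- as.vector(w %*% x)
    a22 <- as.vector(w %*% (x^2)) + ridge
    bb1 <- rowSums(w * z)
    bb2 <- as.vector((w * z) %*% x)
    det <- a11 * a22 - a12^2
    det[det < 1e-12] <- 1e-12
    nb1 <- (a22 * bb1 - a12 * bb2) / det
    nb2 <- (a11 * bb2 - a12 * bb1) / det
    nb2 <- pmin(pmax(nb2, -25), 25)
    nb1 <- pmin(pmax(nb1, -50), 50)
    delta <- pmax(abs(nb1 - b1[idx]), abs(nb2 - b2[idx]))
    b1[idx] <- nb1; b2[idx] <- nb2
    conv[idx] <- delta < tol
  }

  ## observed-information SE of b2 at the fit (unpenalized information)
  eta <- b1 + outer(b2, x) + off
  eta <- pmin(eta, 30)
  mu <- exp(eta)
  w <- mu / (1 + disp * mu)
  a11 <- rowSums(w)
  a12 <- as.vector(w %*% x)
  a22 <- as.vector(w %*% (x^2))
  det <- pmax(a11 * a22 - a12^2, 1e-12)
  se2 <- sqrt(a11 / det)

  list(b1 = b1, b2 = b2, se2 = se2, converged = conv | !active,
       active = active)
}

contrast_design <- function(samples_sub, contrast) {
  keep <- samples_sub$species %in% contrast
  x <- as.numeric(samples_sub$species[keep] == contrast[1])
  list(keep = keep, x = x)
}

#' Per-gene NB Wald test for a two-group contrast
#'
#' Fits, for every gene, a negative-binomial log-link GLM with a group
#' indicator by iteratively reweighted least squares at fixed gene-wise
#' dispersion, and tests the group coefficient with a Wald statistic
#' against the standard normal. Log2 fold changes are reported as
#' numerator-group over denominator-group. P-values are adjusted by
#' Benjamini-Hochberg over tested genes; genes with all-zero counts (or a
#' non-converged fit) are `untested` with undefined p.
#'
#' @param counts genes x samples count matrix (samples of the two groups).
#' @param sf size factors for those samples.
#' @param dispersions per-gene dispersion phi from [estimate_dispersions()].
#' @param group factor/character per sample with exactly the two contrasted
#'   levels.
#' @param contrast length-2 character: (numerator level, denominator level).
#' @param alpha FDR threshold for the `DE` status call (default 0.05).
#' @return data.frame (one row per gene): `gene`, `baseMean`, `lfc`, `se`,
#'   `stat`, `p`, `padj`, `status` in `{DE, nDE, untested}`, `dispersion`.
#' @export
wald_test <- function(counts, sf, dispersions, group, contrast,
                      alpha = 0.05) {
  counts <- as.matrix(counts)
  group <- as.character(group)
  if (!all(contrast %in% group))
    stopf("both contrast groups must be present among samples")
  keep <- group %in% contrast
  counts <- counts[, keep, drop = FALSE]
  sf <- sf[keep]
  x <- as.numeric(group[keep] == contrast[1])

  fit <- fit_nb_glm(counts, sf, dispersions, x)
  ln2 <- log(2)
  lfc <- fit$b2 / ln2
  se <- fit$se2 / ln2
  stat <- fit$b2 / fit$se2
  p <- 2 * pnorm(-abs(stat))
  tested <- fit$active & fit$converged
  p[!tested] <- NA_real_
  lfc[!fit$active] <- NA_real_
  se[!fit$active] <- NA_real_
  stat[!fit$active] <- NA_real_
  n_nc <- sum(fit$active & !fit$converged)
  if (n_nc > 0) warnf("%d gene(s) did not converge and are untested", n_nc)

  padj <- rep(NA_real_, length(p))
  padj[tested] <- p.adjust(p[tested], method = "BH")
  status <- ifelse(!tested, "untested", ifelse(padj < alpha, "DE", "nDE"))

  data.frame(gene = rownames(counts) %||% seq_len(nrow(counts)),
             baseMean = rowMeans(sweep(counts, 2, sf, "/")),
             lfc = lfc, se = se, stat = stat, p = p, padj = padj,
             status = status, dispersion = rep_len(dispersions, nrow(counts)),
             stringsAsFactors = FALSE)
}

#' Shrunken log2 fold changes under a zero-centered normal prior
#'
#' Refits the per-gene NB GLM with a zero-centered Gaussian prior on the
#' group coefficient and reports the posterior mode (MAP) log2 fold change.
#' The prior variance is either fixed or estimated from the empirical
#' spread of high-information fold changes (genes in the upper quartile of
#' base mean): `max(mean(lfc^2) - mean(se^2), 0.0625)`. Shrinkage strictly
#' decreases the magnitude of finite-information fold changes and leaves
#' high-count genes nearly untouched; all-zero genes get 0.
#'
#' @param counts,sf,dispersions,group,contrast as in [wald_test()].
#' @param result the [wald_test()] result (used to estimate the prior
#'   variance when `prior_var` is `NULL`).
#' @param prior_var prior variance of the log2 fold change; `NULL` to
#'   estimate, `Inf` for no shrinkage.
#' @return Numeric vector of shrunken log2 fold changes, prior variance in
#'   `attr(, "prior_var")`.
#' @export
shrink_lfc <- function(counts, sf, dispersions, group, contrast, result,
                       prior_var = NULL) {
  counts <- as.matrix(counts)
  group <- as.character(group)
  keep <- group %in% contrast
  counts <- counts[, keep, drop = FALSE]
  sf <- sf[keep]
  x <- as.numeric(group[keep] == contrast[1])

  if (is.null(prior_var)) {
    ok <- result$status != "untested" & is.finite(result$lfc) &
      is.finite(result$se)
    hi <- ok & result$baseMean >= quantile(result$baseMean[ok], 0.75,
                                           na.rm = TRUE)
    prior_var <- if (sum(hi) >= 10)
      max(mean(result$lfc[hi]^2) - mean(result$se[hi]^2), 0.0625)
    else 1
  }
  ridge <- if (is.infinite(prior_var)) 0 else 1 / (prior_var * log(2)^2)
  fit <- fit_nb_glm(counts, sf, dispersions, x, ridge = ridge)
  s <- fit$b2 / log(2)
  s[!fit$active] <- 0
  attr(s, "prior_var") <- prior_var
  s
}

#' Run the DE engine for one tissue and contrast
#'
#' Convenience wrapper: subsets a tissue, computes size factors across all
#' of that tissue's samples, estimates dispersions using all species groups,
#' runs the Wald test for the requested contrast and appends shrunken log2
#' fold changes.
#'
#' Contrast codes follow the orientation conventions `CP` =
#' log2(parentA/parentB), `HC` = log2(hybrid/parentA), `HP` =
#' log2(hybrid/parentB).
#'
#' @param counts full genes x samples count matrix.
#' @param samples sample table (`sample`, `species`, `tissue`, `individual`).
#' @param tissue tissue to analyse.
#' @param contrast one of `"CP"`, `"HC"`, `"HP"`, or a length-2 vector of
#'   species levels (numerator, denominator).
#' @param alpha FDR threshold for DE status.
#' @param prior_var prior variance passed to [shrink_lfc()].
#' @param pseudo_reference passed to [size_factors()].
#' @return A `DEResult` data.frame as in [wald_test()] plus `shrunkenLfc`.
#' @export
run_de <- function(counts, samples, tissue, contrast = "CP", alpha = 0.05,
                   prior_var = NULL, pseudo_reference = FALSE) {
  codes <- list(CP = c("parentA", "parentB"),
                HC = c("hybrid", "parentA"),
                HP = c("hybrid", "parentB"))
  if (is.character(contrast) && length(contrast) == 1) {
    if (!contrast %in% names(codes)) stopf("unknown contrast '%s'", contrast)
    contrast <- codes[[contrast]]
  }
  sub <- samples$tissue == tissue
  if (!any(sub)) stopf("no samples for tissue '%s'", tissue)
  cts <- counts[, samples$sample[sub], drop = FALSE]
  grp <- samples$species[sub]
  sf <- size_factors(cts, pseudo_reference = pseudo_reference)
  phi <- estimate_dispersions(cts, sf, grp)
  keep <- grp %in% contrast
  res <- wald_test(cts[, keep, drop = FALSE], sf[keep], phi, grp[keep],
                   contrast, alpha = alpha)
  res$shrunkenLfc <- shrink_lfc(cts[, keep, drop = FALSE], sf[keep], phi,
                                grp[keep], contrast, res,
                                prior_var = prior_var)
  res
}

#' Run all three pairwise contrasts (CP, HC, HP) for one tissue
#'
#' @inheritParams run_de
#' @return Named list of `DEResult` data.frames (`CP`, `HC`, `HP`).
#' @export
de_contrasts <- function(counts, samples, tissue, alpha = 0.05,
                         prior_var = NULL, pseudo_reference = FALSE) {
  setNames(lapply(c("CP", "HC", "HP"), function(cc)
    run_de(counts, samples, tissue, cc, alpha = alpha,
           prior_var = prior_var, pseudo_reference = pseudo_reference)),
    c("CP", "HC", "HP"))
}

#' Venn-cell counts of DE genes across tissues
#'
#' Given the per-tissue sets of DE genes on a shared gene universe, counts
#' the genes in every exclusive intersection cell (all 2^T - 1 nonempty
#' tissue subsets) plus the genes DE in no tissue.
#'
#' @param de_sets named list of character vectors of DE gene ids.
#' @param universe character vector: the shared gene universe.
#' @return data.frame with columns `cell` (tissue names joined by `&`, or
#'   `"none"`) and `count`. Cells with zero genes are included.
#' @export
de_overlap <- function(de_sets, universe) {
  stray <- setdiff(unlist(de_sets), universe)
  if (length(stray))
    stopf("gene universes mismatch: %d DE gene(s) not in universe (e.g. %s)",
          length(stray), stray[1])
  tn <- names(de_sets)
  memb <- sapply(de_sets, function(s) universe %in% s)
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(universe))
  subsets <- unlist(lapply(seq_along(tn), function(k)
    combn(tn, k, paste, collapse = "&", simplify = FALSE)))
  pattern <- apply(memb, 1, function(r)
    if (!any(r)) "none" else paste(tn[r], collapse = "&"))
  counts <- table(factor(pattern, levels = c(subsets, "none")))
  data.frame(cell = names(counts), count = as.integer(counts),
             stringsAsFactors = FALSE)
}
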