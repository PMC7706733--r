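#' Median-of-ratios size factors
#'
#' Computes per-sample scaling factors as the median, over reference genes,
#' of the ratio between the sample's count and the gene's geometric mean
#' across samples. Reference genes are those with no zero count; with
#' `pseudo_reference = TRUE` the geometric mean is instead taken over the
#' positive counts of each gene (useful for sparse matrices where no gene is
#' positive everywhere), and the median is taken over positive ratios.
#' No rescaling is applied beyond the formula itself.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param pseudo_reference fall back to a positive-count pseudo-reference
#'   when no gene has all-positive counts.
#' @return Named numeric vector of size factors, one per sample.
#' @examples
#' size_factors(matrix(c(10, 30, 20, 60), 2, 2))
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  ref <- rowSums(counts == 0) == 0
  if (!any(ref) && !pseudo_reference)
    stopf(paste("no gene has all-positive counts; rerun with",
                "'pseudo_reference = TRUE' to use a positive-count",
                "pseudo-reference"))
  if (any(ref) && !pseudo_reference) {
    gm <- exp(rowMeans(log(counts[ref, , drop = FALSE])))
    sf <- apply(counts[ref, , drop = FALSE] / gm, 2, median)
  } else {
    lc <- log(counts)
    lc[!is.finite(lc)] <- NA
    gm <- exp(rowMeans(lc, na.rm = TRUE))
    keep <- is.finite(gm) & gm > 0
    ratios <- counts[keep, , drop = FALSE] / gm[keep]
    sf <- apply(ratios, 2, function(r) median(r[r > 0]))
  }
  if (any(!is.finite(sf) | sf <= 0))
    stopf("degenerate size factors; check for all-zero samples")
  setNames(sf, colnames(counts))
}

#' Regularized-log-like transform
#'
#' `log2(count / size_factor + pseudocount)`. A monotone, depth-normalizing
#' transform used as input to PCA and between-groups PCA; a deliberate
#' simplification of a full regularized-log transform that preserves the
#' sample-distance structure those analyses need.
#'
#' @param counts genes x samples count matrix.
#' @param sf size factors from [size_factors()].
#' @param pseudocount added before taking logs (default 1, so count 0 at
#'   size factor 1 maps to 0).
#' @return Real matrix of the same dimension as `counts`.
#' @export
rlog_like <- function(counts, sf = size_factors(counts), pseudocount = 1) {
  counts <- as.matrix(counts)
  if (length(sf) != ncol(counts)) stopf("one size factor per sample required")
  log2(sweep(counts, 2, sf, "/") + pseudocount)
}

#' Gene-wise NB dispersion estimation with trend shrinkage
#'
#' Three stages. (1) A method-of-moments estimate per gene,
#' `max(0, (var - mean) / mean^2)`, using within-group variances of
#' normalized counts pooled across groups. (2) A mean-dispersion trend
#' `a0 + a1 / mean` fitted by iterative Gamma regression over genes with a
#' positive estimate, excluding outliers. (3) The final dispersion as the
#' posterior mode in log dispersion: the Cox-Reid-adjusted NB profile
#' log-likelihood (group means fitted, adjusted by half the log determinant
#' of the weighted information) plus a normal prior centered on the log
#' trend with fixed variance `prior_var`. The moment estimate thus
#' initializes and anchors the trend; the posterior mode shrinks each
#' gene's log dispersion toward it. `method = "moment"` instead takes a
#' closed-form precision-weighted average of the log moment estimate and
#' the log trend (cheaper, noisier).
#'
#' @param counts genes x samples count matrix.
#' @param sf size factors.
#' @param groups factor of group membership per sample (>= 2 samples per
#'   group; a single group is allowed with a warning).
#' @param prior_var prior variance of log dispersion about the trend
#'   (default 0.25).
#' @param min_disp floor for the gene-wise estimate before log shrinkage.
#' @param method `"map"` (Cox-Reid posterior mode, default) or `"moment"`.
#' @return Named numeric vector of final dispersions phi, one per gene, with
#'   the raw method-of-moments estimates in `attr(, "gene_est")` and the
#'   trend coefficients in `attr(, "trend")`.
#' @export
estimate_dispersions <- function(counts, sf = size_factors(counts), groups,
                                 prior_var = 0.25, min_disp = 1e-8,
                                 method = c("map", "moment")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) == 1)
    warnf("a single group: dispersion estimated from that group alone")
  tab <- table(groups)
  if (any(tab < 2)) stopf("every group needs >= 2 samples")
  norm <- sweep(counts, 2, sf, "/")

  num <- den <- mu_all <- rep(0, nrow(counts))
  wsum <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    m <- rowMeans(norm[, idx, drop = FALSE])
    v <- apply(norm[, idx, drop = FALSE], 1, var)
    w <- length(idx) - 1
    num <- num + w * (v - m)
    den <- den + w * m^2
    mu_all <- mu_all + length(idx) * m
    wsum <- wsum + length(idx)
  }
  mu <- mu_all / wsum
  gene_est <- ifelse(den > 0, pmax(num / den, 0), 0)

  trend <- fit_dispersion_trend(gene_est, mu)
  trend_val <- pmax(trend[1] + trend[2] / pmax(mu, 1e-8), min_disp)

  if (method == "moment") {
    m <- ncol(counts); p <- nlevels(groups)
    s2 <- trigamma(max((m - p) / 2, 0.5))
    log_est <- log(pmax(gene_est, min_disp))
    phi <- exp((log_est / s2 + log(trend_val) / prior_var) /
                 (1 / s2 + 1 / prior_var))
    phi[mu == 0] <- trend[1]
  } else {
    prior_sd <- sqrt(prior_var)
    X <- model.matrix(~groups)
    ## fitted means per gene: group-wise weighted means on the sf scale
    qhat <- sapply(levels(groups), function(g) {
      i <- groups == g
      rowSums(counts[, i, drop = FALSE]) / sum(sf[i])
    })
    if (is.null(dim(qhat))) qhat <- matrix(qhat, nrow = nrow(counts))
    muhat <- qhat[, as.integer(groups), drop = FALSE] *
      rep(sf, each = nrow(counts))
    phi <- vapply(seq_len(nrow(counts)), function(g) {
      k <- counts[g, ]; mg <- muhat[g, ]; lt <- log(trend_val[g])
      if (all(k == 0)) return(trend[1])
      f <- function(la) {
        a <- exp(la)
        w <- mg / (1 + a * mg)
        ## genes with an all-zero group make the information singular;
        ## bound the objective so the optimizer stays finite
        ll <- sum(dnbinom(k, mu = mg, size = 1 / a, log = TRUE)) -
          0.5 * as.numeric(determinant(crossprod(X, X * w),
                                       logarithm = TRUE)$modulus) +
          dnorm(la, lt, prior_sd, log = TRUE)
        if (!is.finite(ll)) -1e10 else ll
      }
      exp(optimize(f, c(-15, 3), maximum = TRUE, tol = 1e-4)$maximum)
    }, 0)
  }
  phi <- setNames(phi, rownames(counts))
  attr(phi, "gene_est") <- gene_est
  attr(phi, "trend") <- trend
  phi
}

## iterative Gamma-family fit of dispersion ~ a0 + a1/mean, outlier-robust
fit_dispersion_trend <- function(disp, mu, max_iter = 10) {
  use <- disp > 1e-7 & mu > 0
  if (sum(use) < 10) {
    a0 <- if (any(use)) median(disp[use]) else 0.01
    return(c(a0 = max(a0, 1e-6), a1 = 0))
  }
  d <- disp[use]; m <- mu[use]
  co <- c(median(d), 1)
  for (it in seq_len(max_iter)) {
    fit <- tryCatch(
      glm(d ~ I(1 / m), family = Gamma(link = "identity"),
          start = pmax(co, 1e-6)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) break
    new <- coef(fit)
    if (any(!is.finite(new))) break
    pred <- pmax(new[1] + new[2] / m, 1e-8)
    keep <- d / pred < 15 & d / pred > 1e-4
    if (max(abs(new - co) / pmax(abs(co), 1e-8)) < 1e-6) { co <- new; break }
    co <- new
    d <- d[keep]; m <- m[keep]
    if (length(d) < 10) break
  }
  c(a0 = max(co[1], 1e-6), a1 = max(co[2], 0))
}
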