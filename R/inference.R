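#' Mann-Whitney U association between a value and a binary flag
#'
#' Two-sided Mann-Whitney U test of the values of flagged vs unflagged
#' genes, with a separate direction flag (sign of the difference in group
#' medians) rather than one-sided testing. For group sizes both at or below
#' `exact_max` the null distribution of U is enumerated exactly over all
#' label assignments (ties included); otherwise the tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param values numeric per gene (e.g. absolute shrunken log2 fold
#'   changes).
#' @param flags logical per gene (e.g. population ASE status).
#' @param exact_max switch to exact enumeration when both groups are at or
#'   below this size (default 10).
#' @return List of class `hx_assoc`: `U` (statistic of the flagged group),
#'   `p`, `direction` (-1/0/1), `n1`, `n0`, `method`; `p` is `NA` with
#'   `method = "untestable"` when a group is empty.
#' @export
mwu_association <- function(values, flags, exact_max = 10) {
  keep <- is.finite(values) & !is.na(flags)
  values <- values[keep]; flags <- as.logical(flags[keep])
  n1 <- sum(flags); n0 <- sum(!flags)
  if (n1 == 0 || n0 == 0)
    return(structure(list(U = NA_real_, p = NA_real_, direction = NA_real_,
                          n1 = n1, n0 = n0, method = "untestable"),
                     class = "hx_assoc"))
  r <- rank(values)
  u_obs <- sum(r[flags]) - n1 * (n1 + 1) / 2
  direction <- sign(median(values[flags]) - median(values[!flags]))

  if (n1 <= exact_max && n0 <= exact_max) {
    nn <- n1 + n0
    u_all <- combn(nn, n1, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u_obs + 1e-9),
                        mean(u_all >= u_obs - 1e-9)))
    method <- "exact"
  } else {
    nn <- n1 + n0
    ties <- table(r)
    sigma2 <- n1 * n0 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - n1 * n0 / 2) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    method <- "normal"
  }
  structure(list(U = u_obs, p = p, direction = direction, n1 = n1, n0 = n0,
                 method = method), class = "hx_assoc")
}

#' @export
print.hx_assoc <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %s, p = %s (%s; n1 = %d, n0 = %d)\n",
              format(x$U), format(x$p), x$method, x$n1, x$n0))
  invisible(x)
}

#' Continuity-corrected chi-squared test on a 2x2 table
#'
#' Pearson chi-squared with Yates continuity correction (|O - E| reduced by
#' 0.5, floored at 0), referred to chi-squared with 1 df.
#'
#' @param table 2x2 matrix of non-negative counts with positive marginals.
#' @return List `statistic`, `p`.
#' @examples
#' chisq_yates(matrix(c(5, 81, 27, 1542), 2, 2))
#' @export
chisq_yates <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2) || any(table < 0))
    stopf("a 2x2 table of non-negative counts is required")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("all marginals must be positive")
  res <- suppressWarnings(chisq.test(table, correct = TRUE))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' One-sided hypergeometric enrichment tail
#'
#' For a 2x2 of DE/nDE by Z/autosome, computes P(X >= de_z) where X is
#' hypergeometric with population N = all genes, K = DE genes, and n = Z
#' genes drawn. The tail is summed in log space for numerical stability.
#'
#' @param de_z,nde_z,de_a,nde_a non-negative counts: DE and non-DE genes on
#'   the Z chromosome and autosomes.
#' @return One-sided p-value.
#' @export
hypergeom_enrichment <- function(de_z, nde_z, de_a, nde_a) {
  cnt <- c(de_z, nde_z, de_a, nde_a)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stopf("counts must be non-negative integers")
  N <- sum(cnt)
  if (N == 0) stopf("empty table")
  K <- de_z + de_a
  n <- de_z + nde_z
  lo <- max(0, n - (N - K)); hi <- min(K, n)
  if (de_z > hi) stopf("observed count exceeds the marginals")
  if (de_z <= lo) return(1)
  k <- de_z:hi
  lp <- lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
  min(exp(logsumexp(lp)), 1)
}

#' Fast-Z enrichment of differential expression, per tissue
#'
#' For each tissue, tests whether Z-linked genes are overrepresented among
#' DE genes with the one-sided hypergeometric tail; the background is the
#' genes tested in that tissue and assigned to autosomes or Z. P-values are
#' Holm-adjusted across the tested tissues. Tissues with no Z (or no
#' autosomal) gene are untestable and reported with `NA`.
#'
#' @param de_results named list (by tissue) of `DEResult` data.frames for
#'   the parental contrast.
#' @param chrom_class named character vector (gene -> `autosome`/`Z`/...).
#' @return data.frame per tissue: `de_z`, `nde_z`, `de_a`, `nde_a`, `p`,
#'   `p_holm`.
#' @export
fast_z_test <- function(de_results, chrom_class) {
  rows <- lapply(names(de_results), function(tt) {
    d <- de_results[[tt]]
    cls <- chrom_class[d$gene]
    use <- d$status != "untested" & cls %in% c("autosome", "Z")
    de <- d$status[use] == "DE"; z <- cls[use] == "Z"
    cnt <- c(de_z = sum(de & z), nde_z = sum(!de & z),
             de_a = sum(de & !z), nde_a = sum(!de & !z))
    p <- if (sum(z) == 0 || sum(!z) == 0) NA_real_
    else hypergeom_enrichment(cnt[1], cnt[2], cnt[3], cnt[4])
    data.frame(tissue = tt, t(cnt), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- NA_real_
  testable <- !is.na(out$p)
  out$p_holm[testable] <- adjust_pvalues(out$p[testable], "Holm")
  out
}

#' Association between expression divergence and ASE, per source group
#'
#' Applies [mwu_association()] to the absolute shrunken parental log2 fold
#' changes of autosomal genes, flagged by population-level ASE status in
#' each source group (hybrids, parentA, parentB). A significant association
#' that is specific to hybrids supports cis-regulatory divergence, because
#' segregating within-species variation produces ASE in parents and hybrids
#' alike.
#'
#' @param de_cp `DEResult` data.frame (with `shrunkenLfc`) for the parental
#'   contrast of one tissue.
#' @param ase_populations named list (by source, e.g. `hybrid`, `parentA`,
#'   `parentB`) of population ASE data.frames from [run_ase()] (columns
#'   `gene`, `status`), already subset to the same tissue.
#' @param chrom_class named character vector of chromosome classes.
#' @return data.frame per source: `n_ase`, `n_non`, `U`, `p`, `direction`,
#'   `method`.
#' @export
ase_de_association <- function(de_cp, ase_populations, chrom_class) {
  auto <- de_cp$status != "untested" &
    chrom_class[de_cp$gene] %in% "autosome"
  vals <- setNames(abs(de_cp$shrunkenLfc[auto]), de_cp$gene[auto])
  rows <- lapply(names(ase_populations), function(src) {
    pop <- ase_populations[[src]]
    pop <- pop[pop$status != "untested" & pop$gene %in% names(vals), ]
    flags <- setNames(pop$status == "ASE", pop$gene)
    a <- mwu_association(vals[pop$gene], flags)
    data.frame(source = src, n_ase = a$n1, n_non = a$n0, U = a$U, p = a$p,
               direction = a$direction, method = a$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Misexpression x ASE compensation test
#'
#' Cis-trans compensation conserves parental expression while making the
#' two regulatory backgrounds incompatible in hybrids, so it predicts an
#' overrepresentation of hybrid ASE among CP-conserved genes that are
#' misexpressed in hybrids. This builds the 2x2 of misexpression status by
#' hybrid population ASE status over autosomal eligible genes and applies
#' the continuity-corrected chi-squared test; when a margin is empty (no
#' assessable misexpressed gene) the test is not performed and `p` is `NA`.
#'
#' @param misexpression data.frame from [call_misexpression()].
#' @param hybrid_ase population ASE data.frame (columns `gene`, `status`)
#'   for hybrids in the same tissue.
#' @param chrom_class named character vector of chromosome classes.
#' @return List: `table` (2x2: misexpressed x ASE), `statistic`, `p`.
#' @export
compensation_test <- function(misexpression, hybrid_ase, chrom_class) {
  elig <- misexpression[misexpression$eligible &
                          chrom_class[misexpression$gene] %in% "autosome", ]
  pop <- hybrid_ase[hybrid_ase$status != "untested", ]
  m <- merge(elig, pop[, c("gene", "status")], by = "gene")
  tab <- matrix(c(sum(m$misexpressed & m$status == "ASE"),
                  sum(m$misexpressed & m$status != "ASE"),
                  sum(!m$misexpressed & m$status == "ASE"),
                  sum(!m$misexpressed & m$status != "ASE")),
                2, 2, byrow = TRUE,
                dimnames = list(c("misexpressed", "not_misexpressed"),
                                c("ASE", "non_ASE")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, statistic = NA_real_, p = NA_real_))
  res <- chisq_yates(tab)
  list(table = tab, statistic = res$statistic, p = res$p)
}

#' Determinants of expression divergence: binomial GLM / linear model
#'
#' Regresses differential expression on the six gene-level covariates
#' (PPI count, tissue specificity tau, expression dispersion phi, piN/piS,
#' dN/dS, FST), either as a logistic GLM on the 0/1 DE status (`binomial`
#' mode) or as an ordinary least-squares fit on the absolute shrunken log2
#' fold change (`linear` mode). Covariates are z-scored over complete-case
#' genes so coefficients are comparable; analysis is restricted to
#' autosomal, tested genes.
#'
#' @param de `DEResult` data.frame with `shrunkenLfc` for one tissue.
#' @param annotation gene annotation data.frame (see
#'   [simulate_annotation()] / [read_annotation()]).
#' @param mode `"binomial"` or `"linear"`.
#' @param covariates covariate column names (default the six above).
#' @param min_genes minimum complete-case genes (default 50).
#' @return data.frame per covariate: `estimate`, `statistic`, `p`.
#' @export
glm_determinants <- function(de, annotation, mode = c("binomial", "linear"),
                             covariates = c("ppi", "tau", "phi", "piNpiS",
                                            "dNdS", "fst"),
                             min_genes = 50) {
  mode <- match.arg(mode)
  d <- merge(de, annotation, by = "gene")
  d <- d[d$status != "untested" & d$chrom_class %in% "autosome", ]
  cc <- complete.cases(d[, covariates])
  d <- d[cc, ]
  if (nrow(d) < min_genes)
    stopf("need >= %d complete-case genes, got %d", min_genes, nrow(d))
  X <- scale(as.matrix(d[, covariates]))
  if (any(!is.finite(X)))
    stopf("constant covariate(s): %s",
          paste(covariates[apply(!is.finite(X), 2, any)], collapse = ", "))
  df <- data.frame(X)

  if (mode == "binomial") {
    df$y <- as.integer(d$status == "DE")
    if (length(unique(df$y)) < 2)
      stopf("DE status has no variation; the binomial GLM cannot be fit")
    fit <- glm(y ~ ., family = binomial(), data = df)
    co <- summary(fit)$coefficients
    if (any(is.na(coef(fit))))
      stopf("rank-deficient design: %s",
            paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
    if (any(abs(coef(fit)[-1]) > 15))
      stopf("perfect separation suspected for covariate: %s",
            names(which.max(abs(coef(fit)[-1]))))
  } else {
    df$y <- abs(d$shrunkenLfc)
    fit <- lm(y ~ ., data = df)
    if (any(is.na(coef(fit))))
      stopf("rank-deficient design: %s",
            paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
    co <- summary(fit)$coefficients
  }
  co <- co[covariates, , drop = FALSE]
  data.frame(covariate = covariates, estimate = co[, 1],
             statistic = co[, 3], p = co[, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}
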