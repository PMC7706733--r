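#' Filter phased SNP allelic counts for ASE testing
#'
#' Keeps SNPs with total coverage `hapA + hapB >= min_coverage` and minor
#' allelic depth `min(hapA, hapB) > min_allelic_depth` (strictly greater),
#' then drops (gene, individual, tissue) units left with fewer than
#' `min_snps` surviving SNPs.
#'
#' @param table data.frame with columns `gene`, `individual`, `tissue`,
#'   `snp`, `hapA`, `hapB` (see [read_allele_counts()]).
#' @param min_coverage minimum total coverage per SNP (default 10).
#' @param min_allelic_depth strict lower bound on the minor allele depth
#'   (default 2: a SNP with minor depth exactly 2 is dropped).
#' @param min_snps minimum surviving SNPs per gene/individual/tissue
#'   (default 2).
#' @param verbose report the number of dropped rows.
#' @return The filtered table.
#' @export
filter_snps <- function(table, min_coverage = 10, min_allelic_depth = 2,
                        min_snps = 2, verbose = TRUE) {
  n0 <- nrow(table)
  cov_ok <- table$hapA + table$hapB >= min_coverage
  dep_ok <- pmin(table$hapA, table$hapB) > min_allelic_depth
  table <- table[cov_ok & dep_ok, , drop = FALSE]
  key <- paste(table$gene, table$individual, table$tissue, sep = "\r")
  n_by <- table(key)
  table <- table[n_by[key] >= min_snps, , drop = FALSE]
  if (verbose)
    message("filter_snps: dropped ", n0 - nrow(table), " of ", n0, " rows")
  table
}

## beta-binomial log-likelihood; rho = 0 is the binomial limit
bb_loglik <- function(a, n, r, rho) {
  if (rho <= 0) return(sum(dbinom(a, n, r, log = TRUE)))
  al <- r * (1 - rho) / rho
  be <- (1 - r) * (1 - rho) / rho
  sum(lchoose(n, a) + lbeta(a + al, n - a + be) - lbeta(al, be))
}

#' Method-of-moments beta-binomial overdispersion around ratio 0.5
#'
#' For SNP counts assumed balanced on average, the variance of the
#' haplotype-A count is `n/4 * (1 + (n - 1) rho)`; matching moments over all
#' SNPs of an individual gives
#' `rho = (sum((a - n/2)^2) - sum(n)/4) / (sum(n (n - 1))/4)`,
#' clamped to [0, 0.5]. With fewer than `min_snps` SNPs (or only
#' coverage-1 SNPs, where the estimator is undefined) the fallback default
#' is returned with a warning.
#'
#' @param hapA,hapB SNP allelic counts for one individual.
#' @param fallback default rho when the estimate is undefined (default
#'   0.02).
#' @param min_snps minimum SNPs for estimation (default 50).
#' @return rho in [0, 0.5].
#' @export
estimate_overdispersion <- function(hapA, hapB, fallback = 0.02,
                                    min_snps = 50) {
  n <- hapA + hapB
  den <- sum(n * (n - 1)) / 4
  if (length(n) < min_snps || den <= 0) {
    warnf("overdispersion not estimable (%d SNPs); using fallback %.3g",
          length(n), fallback)
    return(fallback)
  }
  rho <- (sum((hapA - n / 2)^2) - sum(n) / 4) / den
  min(max(rho, 0), 0.5)
}

#' Gene-level beta-binomial likelihood-ratio test for ASE
#'
#' Aggregates the phased SNPs of one gene in one individual: under the
#' null every SNP's haplotype-A count is beta-binomial with ratio 0.5 and
#' overdispersion rho; under the alternative the SNPs share a gene-level
#' ratio estimated by maximum likelihood. The likelihood-ratio statistic is
#' referred to chi-squared with 1 degree of freedom. At rho = 0 this is
#' exactly the binomial LRT.
#'
#' @param hapA,hapB aligned haplotype counts for >= 2 phased SNPs.
#' @param rho beta-binomial overdispersion in [0, 1).
#' @return List: `ratio` (gene-level MLE), `lr`, `p`, `n_snps`, `a`, `b`
#'   (aggregate counts).
#' @examples
#' gene_ase_test(c(15, 20), c(15, 20), rho = 0)$p
#' @export
gene_ase_test <- function(hapA, hapB, rho) {
  if (!is.numeric(rho) || rho < 0 || rho >= 1)
    stopf("'rho' must lie in [0, 1)")
  if (length(hapA) < 2) stopf("gene-level ASE test needs >= 2 SNPs")
  n <- hapA + hapB
  opt <- optimize(function(r) bb_loglik(hapA, n, r, rho),
                  interval = c(1e-9, 1 - 1e-9), maximum = TRUE,
                  tol = 1e-9)
  l0 <- bb_loglik(hapA, n, 0.5, rho)
  lr <- max(2 * (opt$objective - l0), 0)
  list(ratio = opt$maximum, lr = lr,
       p = pchisq(lr, df = 1, lower.tail = FALSE),
       n_snps = length(hapA), a = sum(hapA), b = sum(hapB))
}

#' Multiple-testing adjustment (Benjamini-Hochberg or Holm)
#'
#' Standard step-up BH / step-down Holm adjustments with monotonicity
#' enforcement, capped at 1.
#'
#' @param p numeric p-values in [0, 1].
#' @param method `"BH"` or `"Holm"`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("BH", "Holm")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1))) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = c(BH = "BH", Holm = "holm")[method])
}

#' Population-level ASE call from per-individual adjusted p-values
#'
#' A gene is `untested` when fewer than two individuals were tested, `ASE`
#' when at least two individuals have adjusted p below the threshold, and
#' `non-ASE` otherwise. (Direction concordance between the significant
#' individuals is not required.)
#'
#' @param padj per-individual adjusted p-values for one gene (NA allowed,
#'   counted as not tested).
#' @param alpha significance threshold (default 0.05).
#' @return `"ASE"`, `"non-ASE"` or `"untested"`.
#' @export
population_ase <- function(padj, alpha = 0.05) {
  tested <- !is.na(padj)
  if (sum(tested) < 2) return("untested")
  if (sum(padj[tested] < alpha) >= 2) "ASE" else "non-ASE"
}

#' Full ASE pipeline: filter, overdispersion, gene tests, population calls
#'
#' Filters SNPs, estimates one overdispersion rho per individual x tissue
#' (genome-wide, around ratio 0.5), runs the gene-level beta-binomial LRT
#' for every (gene, individual, tissue) unit, adjusts p-values by BH within
#' individual x tissue, and applies the population rule per gene x tissue.
#' When the table mixes species groups (hybrids and parents), run it per
#' group: population-level ASE is defined within a source group.
#'
#' @param table allelic count table (columns `gene`, `individual`,
#'   `tissue`, `snp`, `hapA`, `hapB`).
#' @param min_coverage,min_allelic_depth,min_snps passed to [filter_snps()].
#' @param rho_fallback,rho_min_snps passed to [estimate_overdispersion()].
#' @param alpha significance threshold for the population rule.
#' @param two_pass refine the overdispersion estimate once by excluding
#'   genes called significant in a first pass (default TRUE). The
#'   genome-wide moment estimator assumes SNPs balanced around 0.5, so
#'   genes with genuine allelic imbalance inflate rho and cost power; the
#'   second pass estimates rho from the null-consistent remainder.
#' @param verbose passed to [filter_snps()].
#' @return List: `individual` (per gene/individual/tissue: `n_snps`, `a`,
#'   `b`, `ratio`, `lr`, `p`, `padj`, `rho`), `population` (per
#'   gene/tissue: `n_tested`, `n_significant`, `status`).
#' @export
run_ase <- function(table, min_coverage = 10, min_allelic_depth = 2,
                    min_snps = 2, rho_fallback = 0.02, rho_min_snps = 50,
                    alpha = 0.05, two_pass = TRUE, verbose = FALSE) {
  flt <- filter_snps(table, min_coverage, min_allelic_depth, min_snps,
                     verbose = verbose)
  if (!nrow(flt))
    return(list(individual = NULL, population = NULL))

  est_rho <- function(rows) vapply(
    split(rows, paste(rows$individual, rows$tissue, sep = "\r")),
    function(d) suppressWarnings(
      estimate_overdispersion(d$hapA, d$hapB, fallback = rho_fallback,
                              min_snps = rho_min_snps)),
    0)

  test_all <- function(rows, rho_by) {
    unit <- split(rows,
                  paste(rows$gene, rows$individual, rows$tissue, sep = "\r"))
    ind <- do.call(rbind, lapply(unit, function(d) {
      rho <- rho_by[[paste(d$individual[1], d$tissue[1], sep = "\r")]]
      tst <- gene_ase_test(d$hapA, d$hapB, rho)
      data.frame(gene = d$gene[1], individual = d$individual[1],
                 tissue = d$tissue[1], n_snps = tst$n_snps, a = tst$a,
                 b = tst$b, ratio = tst$ratio, lr = tst$lr, p = tst$p,
                 rho = rho, stringsAsFactors = FALSE)
    }))
    rownames(ind) <- NULL
    ind$padj <- NA_real_
    key <- paste(ind$individual, ind$tissue, sep = "\r")
    for (k in unique(key)) {
      idx <- key == k
      ind$padj[idx] <- adjust_pvalues(ind$p[idx], "BH")
    }
    ind
  }

  ind <- test_all(flt, est_rho(flt))
  if (two_pass) {
    sig <- ind[ind$padj < alpha, c("gene", "individual", "tissue")]
    if (nrow(sig)) {
      hit <- paste(flt$gene, flt$individual, flt$tissue, sep = "\r") %in%
        paste(sig$gene, sig$individual, sig$tissue, sep = "\r")
      ind <- test_all(flt, est_rho(flt[!hit, , drop = FALSE]))
    }
  }

  pop <- do.call(rbind, lapply(
    split(ind, paste(ind$gene, ind$tissue, sep = "\r")), function(d)
      data.frame(gene = d$gene[1], tissue = d$tissue[1],
                 n_tested = nrow(d),
                 n_significant = sum(d$padj < alpha),
                 status = population_ase(d$padj, alpha),
                 stringsAsFactors = FALSE)))
  rownames(pop) <- NULL
  list(individual = ind, population = pop)
}
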