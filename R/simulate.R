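#' Simulate an RNA-seq count matrix for two parental species and F1 hybrids
#'
#' Draws negative-binomial read counts for every gene and sample under a
#' per-gene, per-tissue inheritance mode. Parental group means differ by the
#' gene's true log2 fold change; the hybrid group mean sits at the log-scale
#' midpoint (additive), equals one parent (dominant), or is offset beyond
#' both parents by `effect_size_log2` (over-/underdominant). Regulatory
#' regimes are assigned conditionally on the mode: expression-divergent
#' genes are cis or trans (split by the `regime_fractions` weights),
#' misexpressed genes are compensatory or trans, conserved genes are null.
#' The hybrid allelic ratio implied by the regime is recorded in the truth
#' table for [simulate_allele_counts()].
#'
#' @param config a [sim_config()] object.
#' @return A list of class `hx_sim` with elements
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples.}
#'     \item{samples}{data.frame with columns `sample`, `species`
#'       (`parentA` = collared, `parentB` = pied, `hybrid`), `tissue`,
#'       `individual`.}
#'     \item{truth}{data.frame per gene x tissue: `mode`, `regime`,
#'       `lfc_cp` (true log2 parentA/parentB), `hybrid_ratio`
#'       (parentA-allele fraction in hybrids), `cne_flag`; gene-level
#'       parameters in `attr(truth, "gene_params")`.}
#'   }
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 100, n_tissues = 2, seed = 1))
#' head(sim$truth)
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  set.seed(stream_seed(config$seed, "counts"))

  ng <- config$n_genes
  tissues <- tissue_names(config$n_tissues)
  ids <- individual_ids(config)
  genes <- sprintf("g%05d", seq_len(ng))

  samples <- do.call(rbind, lapply(tissues, function(tt) {
    data.frame(
      sample = paste(c(ids$parentA, ids$parentB, ids$hybrid), tt, sep = "_"),
      species = rep(c("parentA", "parentB", "hybrid"),
                    c(config$n_parentA, config$n_parentB, config$n_hybrid)),
      tissue = tt,
      individual = c(ids$parentA, ids$parentB, ids$hybrid),
      stringsAsFactors = FALSE)
  }))
  ns <- nrow(samples)

  sf <- config$library_size_factors %||% rlnorm(ns, 0, 0.15)

  ## gene-level parameters
  q0 <- rlnorm(ng, config$base_mean_log_mean, config$base_mean_log_sd)
  alpha <- if (is.finite(config$dispersion_log_mean))
    rlnorm(ng, config$dispersion_log_mean, config$dispersion_log_sd)
  else rep(0, ng)

  ## per-tissue baseline multiplier (tissue identity dominates total variance)
  tis_mult <- matrix(rlnorm(ng * length(tissues), 0, config$tissue_effect_sd),
                     ng, length(tissues), dimnames = list(genes, tissues))

  ## per gene x tissue inheritance mode
  mf <- config$mode_fractions
  modes_all <- c(names(mf), "conserved")
  probs <- c(mf, conserved = max(0, 1 - sum(mf)))
  mode <- matrix(sample(modes_all, ng * length(tissues), replace = TRUE,
                        prob = probs),
                 ng, length(tissues), dimnames = list(genes, tissues))

  sgn <- matrix(sample(c(-1, 1), ng * length(tissues), replace = TRUE),
                ng, length(tissues))
  e <- config$effect_size_log2
  divergent <- mode %in% c("additive", "pied_dominant", "collared_dominant")
  lfc_cp <- matrix(0, ng, length(tissues))
  lfc_cp[divergent] <- (sgn * e)[divergent]

  ## regulatory regime conditional on mode
  rf <- config$regime_fractions
  p_cis <- if (rf[["cis"]] + rf[["trans"]] > 0)
    rf[["cis"]] / (rf[["cis"]] + rf[["trans"]]) else 0
  p_comp <- if (rf[["compensatory"]] + rf[["trans"]] > 0)
    rf[["compensatory"]] / (rf[["compensatory"]] + rf[["trans"]]) else 0
  u <- matrix(runif(ng * length(tissues)), ng, length(tissues))
  regime <- matrix("null", ng, length(tissues), dimnames = list(genes, tissues))
  regime[divergent] <- ifelse(u[divergent] < p_cis, "cis", "trans")
  misexp <- mode %in% c("overdominant", "underdominant")
  regime[misexp] <- ifelse(u[misexp] < p_comp, "compensatory", "trans")

  ## hybrid allelic ratio (parentA-allele fraction)
  ratio <- matrix(0.5, ng, length(tissues))
  is_cis <- regime == "cis"
  ratio[is_cis] <- 2^lfc_cp[is_cis] / (1 + 2^lfc_cp[is_cis])
  comp_sgn <- matrix(sample(c(-1, 1), ng * length(tissues), replace = TRUE),
                     ng, length(tissues))
  is_comp <- regime == "compensatory"
  ratio[is_comp] <- 2^(comp_sgn[is_comp] * e) / (1 + 2^(comp_sgn[is_comp] * e))

  ## group mean matrices per tissue
  qA <- tis_mult * q0 * 2^(lfc_cp / 2)
  qB <- tis_mult * q0 * 2^(-lfc_cp / 2)
  qH <- tis_mult * q0
  qH[mode == "collared_dominant"] <- qA[mode == "collared_dominant"]
  qH[mode == "pied_dominant"] <- qB[mode == "pied_dominant"]
  qH[mode == "overdominant"] <- (tis_mult * q0 * 2^e)[mode == "overdominant"]
  qH[mode == "underdominant"] <- (tis_mult * q0 * 2^-e)[mode == "underdominant"]

  counts <- matrix(0L, ng, ns, dimnames = list(genes, samples$sample))
  pois <- alpha == 0
  for (j in seq_len(ns)) {
    ti <- match(samples$tissue[j], tissues)
    q <- switch(samples$species[j], parentA = qA, parentB = qB, hybrid = qH)
    mu <- sf[j] * q[, ti]
    col <- integer(ng)
    if (any(pois)) col[pois] <- rpois(sum(pois), mu[pois])
    if (any(!pois)) col[!pois] <- rnbinom(sum(!pois), mu = mu[!pois],
                                          size = 1 / alpha[!pois])
    counts[, j] <- as.integer(col)
  }

  ## gene-level CNE fixed-difference flag, enriched among cis-regime genes
  gene_cis <- rowSums(is_cis) > 0
  cne <- runif(ng) < ifelse(gene_cis, config$cne_flag_prob_given_cis,
                            config$cne_flag_prob_given_not_cis)

  truth <- data.frame(
    gene = rep(genes, length(tissues)),
    tissue = rep(tissues, each = ng),
    mode = as.vector(mode), regime = as.vector(regime),
    lfc_cp = as.vector(lfc_cp), hybrid_ratio = as.vector(ratio),
    cne_flag = rep(cne, length(tissues)),
    stringsAsFactors = FALSE)
  attr(truth, "gene_params") <- data.frame(
    gene = genes, base_mean = q0, dispersion = alpha,
    gene_cis = gene_cis, cne_flag = cne,
    divergent = rowSums(mode != "conserved") > 0,
    stringsAsFactors = FALSE)

  structure(list(counts = counts, samples = samples, truth = truth,
                 size_factors_true = setNames(sf, samples$sample),
                 config = config),
            class = "hx_sim")
}

## beta-binomial draw; rho = 0 falls back to the binomial
rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  rbinom(n, size, rbeta(n, a, b))
}

#' Simulate phased allelic counts per gene, individual, tissue and SNP
#'
#' Every (gene, individual) pair receives `2 + Poisson` phased heterozygous
#' SNPs; per-SNP total coverage is negative-binomial around
#' `snp_coverage_mean`, and the haplotype-A (parentA-allele) count is
#' beta-binomial with the gene's true hybrid allelic ratio for hybrid
#' individuals and 0.5 for parental individuals unless the (gene,
#' individual) pair carries segregating within-species ASE. A configurable
#' fraction of SNPs is generated below the coverage filter so the filtering
#' stage has work to do.
#'
#' @param truth truth table from [simulate_counts()].
#' @param config the same [sim_config()].
#' @param tissues optional subset of tissues to generate (default all).
#' @param species optional subset of species groups (default all three).
#' @return data.frame with columns `gene`, `individual`, `species`,
#'   `tissue`, `snp`, `hapA`, `hapB`, `phase_set`.
#' @export
simulate_allele_counts <- function(truth, config, tissues = NULL,
                                   species = c("parentA", "parentB", "hybrid")) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  set.seed(stream_seed(config$seed, "alleles"))
  tissues <- tissues %||% unique(truth$tissue)
  missing_t <- setdiff(tissues, unique(truth$tissue))
  if (length(missing_t))
    stopf("truth table has no rows for tissue(s): %s",
          paste(missing_t, collapse = ", "))
  genes <- unique(truth$gene)
  ids <- individual_ids(config)
  species <- match.arg(species, several.ok = TRUE)

  inds <- data.frame(
    individual = unlist(ids[species], use.names = FALSE),
    species = rep(species, lengths(ids[species])),
    stringsAsFactors = FALSE)

  ## SNP count and within-species ASE ratio are (gene, individual) level
  ng <- length(genes); ni <- nrow(inds)
  K <- matrix(2L + rpois(ng * ni, max(config$snps_per_gene_mean - 2, 0)),
              ng, ni)
  par_ase <- matrix(runif(ng * ni) < config$parental_ase_prob, ng, ni)
  par_ratio <- matrix(rbeta(ng * ni, 2, 2), ng, ni)

  ## truth lookup: hybrid ratio per gene x tissue
  ratio_tab <- matrix(NA_real_, ng, length(tissues),
                      dimnames = list(genes, tissues))
  tr <- truth[truth$tissue %in% tissues, ]
  ratio_tab[cbind(match(tr$gene, genes), match(tr$tissue, tissues))] <-
    tr$hybrid_ratio
  if (anyNA(ratio_tab)) {
    bad <- genes[which(rowSums(is.na(ratio_tab)) > 0)[1]]
    stopf("truth table is missing rows for gene %s", bad)
  }

  out <- vector("list", length(tissues))
  for (ti in seq_along(tissues)) {
    gi <- rep(rep(seq_len(ng), ni), times = as.vector(K))
    ii <- rep(rep(seq_len(ni), each = ng), times = as.vector(K))
    snp_rank <- sequence(as.vector(K))
    n_snp <- length(gi)

    cov <- rnbinom(n_snp, mu = config$snp_coverage_mean, size = 5)
    viol <- runif(n_snp) < config$filter_violation_prob
    cov[viol] <- sample(1:9, sum(viol), replace = TRUE)
    cov <- pmax(cov, 1L)

    hyb <- inds$species[ii] == "hybrid"
    r <- ifelse(hyb, ratio_tab[cbind(gi, ti)],
                ifelse(par_ase[cbind(gi, ii)], par_ratio[cbind(gi, ii)], 0.5))
    hapA <- rbetabinom(n_snp, cov, r, config$ase_overdispersion)

    out[[ti]] <- data.frame(
      gene = genes[gi],
      individual = inds$individual[ii],
      species = inds$species[ii],
      tissue = tissues[ti],
      snp = sprintf("%s_snp%02d", genes[gi], snp_rank),
      hapA = hapA, hapB = cov - hapA,
      phase_set = paste0(genes[gi], "_", inds$individual[ii], "_ps1"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a gene annotation table matched to a simulated truth
#'
#' Chromosome class (autosome/Z), effective length, the CNE fixed-difference
#' flag (taken from the truth table, where it was drawn Bernoulli with
#' probability `cne_flag_prob_given_cis` for cis-regime genes and
#' `cne_flag_prob_given_not_cis` otherwise) and the six annotation
#' covariates used by the determinant regressions. Setting
#' `covariate_de_shift > 0` in the config plants a logit-scale shift in tau
#' and FST for expression-divergent genes.
#'
#' @param truth truth table from [simulate_counts()].
#' @param config the same [sim_config()].
#' @return data.frame with columns `gene`, `chrom_class`, `length`,
#'   `cne_flag`, `ppi`, `tau`, `phi`, `piNpiS`, `dNdS`, `fst`.
#' @export
simulate_annotation <- function(truth, config) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  set.seed(stream_seed(config$seed, "annotation"))
  gp <- attr(truth, "gene_params")
  if (is.null(gp)) stopf("truth table lacks gene-level parameters")
  ng <- nrow(gp)

  shift <- config$covariate_de_shift * as.numeric(gp$divergent)
  tau_cov <- plogis(qlogis(pmin(pmax(rbeta(ng, 2, 2), 1e-6), 1 - 1e-6)) + shift)
  fst <- plogis(qlogis(pmin(pmax(rbeta(ng, 2, 8), 1e-6), 1 - 1e-6)) + shift)

  data.frame(
    gene = gp$gene,
    chrom_class = ifelse(runif(ng) < config$z_fraction, "Z", "autosome"),
    length = pmax(200L, as.integer(round(rlnorm(ng, log(1500), 0.6)))),
    cne_flag = gp$cne_flag,
    ppi = rpois(ng, 8),
    tau = tau_cov,
    phi = if (all(gp$dispersion == 0)) rlnorm(ng, log(0.05), 0.5) else gp$dispersion,
    piNpiS = rlnorm(ng, log(0.25), 0.4),
    dNdS = rlnorm(ng, log(0.15), 0.5),
    fst = fst,
    stringsAsFactors = FALSE)
}
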