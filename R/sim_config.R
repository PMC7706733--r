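#' Configuration for the synthetic study-design generator
#'
#' Collects every tunable of the synthetic-data generators in one validated
#' object. The defaults emulate the sampling design the analysis targets:
#' two parental species with five sequenced males each plus three F1 hybrid
#' males, each sampled in five tissues (brain, heart, kidney, liver, testis),
#' with negative-binomial counts, gene-wise dispersions and phased allelic
#' counts under cis / trans / compensatory / null regulatory regimes.
#'
#' @param n_genes number of genes to simulate. The default is a desk-scale
#'   gene universe; the real flycatcher annotation is an order of magnitude
#'   larger, which only changes runtime, not structure.
#' @param n_tissues number of tissues (first five are named brain, heart,
#'   kidney, liver, testis).
#' @param n_parentA,n_parentB,n_hybrid group sizes (individuals per group).
#'   Parents and hybrids each need at least 2 individuals so the
#'   population-level ASE rule (two tested individuals) is exercisable.
#' @param mode_fractions named fractions of gene-tissue pairs assigned to the
#'   divergent inheritance modes (`additive`, `pied_dominant`,
#'   `collared_dominant`, `overdominant`, `underdominant`); the remainder is
#'   `conserved`. Must sum to at most 1.
#' @param effect_size_log2 mean absolute log2 fold change of divergent genes.
#' @param dispersion_log_mean,dispersion_log_sd parameters of the log-normal
#'   distribution of gene-wise NB dispersions. `dispersion_log_mean = -Inf`
#'   gives the Poisson limit (dispersion 0).
#' @param base_mean_log_mean,base_mean_log_sd log-normal parameters of the
#'   per-gene baseline expression level (expected counts at size factor 1).
#' @param tissue_effect_sd standard deviation (log scale) of the per-gene,
#'   per-tissue baseline multiplier; drives the dominance of tissue identity
#'   in expression variance.
#' @param library_size_factors optional vector of per-sample scaling factors;
#'   if `NULL`, drawn log-normal with sd 0.15.
#' @param regime_fractions named fractions for regulatory regimes (`cis`,
#'   `trans`, `compensatory`, `null`). Regimes are assigned conditionally on
#'   the inheritance mode (see [simulate_counts()]): the `cis`/`trans`
#'   entries set the split among expression-divergent genes and the
#'   `compensatory`/`trans` entries the split among misexpressed genes, so
#'   only their ratios matter.
#' @param ase_overdispersion beta-binomial overdispersion rho in [0, 1) of
#'   simulated allelic counts.
#' @param snps_per_gene_mean mean number of phased heterozygous SNPs per gene
#'   and individual (minimum 2, Poisson-distributed excess).
#' @param snp_coverage_mean mean total read coverage per SNP.
#' @param parental_ase_prob probability that a (gene, parental individual)
#'   pair carries segregating within-species ASE, in which case its allelic
#'   ratio is drawn from a shared Beta(2, 2) prior instead of being 0.5.
#' @param filter_violation_prob fraction of SNPs deliberately generated below
#'   the coverage filter, standing in for upstream dropouts and mapping-bias
#'   removal.
#' @param z_fraction fraction of genes assigned to the Z chromosome; the
#'   default matches the flycatcher annotation ratio (623 Z-linked of 16,221
#'   annotated genes).
#' @param cne_flag_prob_given_cis,cne_flag_prob_given_not_cis probability of
#'   carrying a fixed difference in an associated conserved noncoding element
#'   for cis-regime and non-cis genes respectively.
#' @param covariate_de_shift optional logit-scale shift planted between
#'   divergent and conserved genes in the tau and FST annotation covariates
#'   (0 = covariates independent of expression divergence).
#' @param seed integer global seed; every generator derives its own
#'   sub-stream from it, so identical configs give bit-identical output.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 200, n_tissues = 2, seed = 7)
#' sim <- simulate_counts(cfg)
#' dim(sim$counts)
#' @export
sim_config <- function(n_genes = 2000,
                       n_tissues = 5,
                       n_parentA = 5, n_parentB = 5, n_hybrid = 3,
                       mode_fractions = c(additive = 0.05,
                                          pied_dominant = 0.04,
                                          collared_dominant = 0.06,
                                          overdominant = 0.025,
                                          underdominant = 0.025),
                       effect_size_log2 = 1,
                       dispersion_log_mean = log(0.01),
                       dispersion_log_sd = 0.5,
                       base_mean_log_mean = log(250),
                       base_mean_log_sd = 1,
                       tissue_effect_sd = 1,
                       library_size_factors = NULL,
                       regime_fractions = c(cis = 0.10, trans = 0.10,
                                            compensatory = 0.05, null = 0.75),
                       ase_overdispersion = 0.02,
                       snps_per_gene_mean = 6,
                       snp_coverage_mean = 30,
                       parental_ase_prob = 0.05,
                       filter_violation_prob = 0.05,
                       z_fraction = 0.0384,
                       cne_flag_prob_given_cis = 0.30,
                       cne_flag_prob_given_not_cis = 0.10,
                       covariate_de_shift = 0,
                       seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  n_tissues <- assert_count(n_tissues, "n_tissues")
  n_parentA <- assert_count(n_parentA, "n_parentA", min = 2L)
  n_parentB <- assert_count(n_parentB, "n_parentB", min = 2L)
  n_hybrid <- assert_count(n_hybrid, "n_hybrid", min = 2L)

  known_modes <- c("additive", "pied_dominant", "collared_dominant",
                   "overdominant", "underdominant")
  if (length(mode_fractions) == 0) mode_fractions <- setNames(numeric(0), character(0))
  if (!all(names(mode_fractions) %in% known_modes))
    stopf("unknown inheritance mode(s): %s",
          paste(setdiff(names(mode_fractions), known_modes), collapse = ", "))
  assert_prob(mode_fractions, "mode_fractions")
  if (sum(mode_fractions) > 1 + 1e-12)
    stopf("mode_fractions must sum to at most 1 (got %.3f)", sum(mode_fractions))
  mf <- setNames(numeric(length(known_modes)), known_modes)
  mf[names(mode_fractions)] <- mode_fractions

  known_regimes <- c("cis", "trans", "compensatory", "null")
  if (!all(names(regime_fractions) %in% known_regimes))
    stopf("unknown regulatory regime(s): %s",
          paste(setdiff(names(regime_fractions), known_regimes), collapse = ", "))
  assert_prob(regime_fractions, "regime_fractions")
  if (sum(regime_fractions) > 1 + 1e-12)
    stopf("regime_fractions must sum to at most 1")
  rf <- setNames(numeric(4), known_regimes)
  rf[names(regime_fractions)] <- regime_fractions

  if (!is.numeric(effect_size_log2) || effect_size_log2 <= 0)
    stopf("'effect_size_log2' must be positive")
  if (!is.numeric(ase_overdispersion) || ase_overdispersion < 0 ||
      ase_overdispersion >= 1)
    stopf("'ase_overdispersion' must lie in [0, 1)")
  assert_prob(parental_ase_prob, "parental_ase_prob")
  assert_prob(filter_violation_prob, "filter_violation_prob")
  assert_prob(z_fraction, "z_fraction")
  assert_prob(cne_flag_prob_given_cis, "cne_flag_prob_given_cis")
  assert_prob(cne_flag_prob_given_not_cis, "cne_flag_prob_given_not_cis")
  if (snps_per_gene_mean <= 0) stopf("'snps_per_gene_mean' must be positive")
  if (snp_coverage_mean <= 0) stopf("'snp_coverage_mean' must be positive")
  n_samples <- (n_parentA + n_parentB + n_hybrid) * n_tissues
  if (!is.null(library_size_factors)) {
    if (length(library_size_factors) != n_samples ||
        any(library_size_factors <= 0))
      stopf("'library_size_factors' must be %d positive values", n_samples)
  }
  seed <- assert_count(seed, "seed", min = 0L)

  structure(list(
    n_genes = n_genes, n_tissues = n_tissues,
    n_parentA = n_parentA, n_parentB = n_parentB, n_hybrid = n_hybrid,
    mode_fractions = mf, effect_size_log2 = effect_size_log2,
    dispersion_log_mean = dispersion_log_mean,
    dispersion_log_sd = dispersion_log_sd,
    base_mean_log_mean = base_mean_log_mean,
    base_mean_log_sd = base_mean_log_sd,
    tissue_effect_sd = tissue_effect_sd,
    library_size_factors = library_size_factors,
    regime_fractions = rf,
    ase_overdispersion = ase_overdispersion,
    snps_per_gene_mean = snps_per_gene_mean,
    snp_coverage_mean = snp_coverage_mean,
    parental_ase_prob = parental_ase_prob,
    filter_violation_prob = filter_violation_prob,
    z_fraction = z_fraction,
    cne_flag_prob_given_cis = cne_flag_prob_given_cis,
    cne_flag_prob_given_not_cis = cne_flag_prob_given_not_cis,
    covariate_de_shift = covariate_de_shift,
    seed = seed), class = "sim_config")
}

tissue_names <- function(n) {
  base <- c("brain", "heart", "kidney", "liver", "testis")
  if (n <= 5) base[seq_len(n)] else c(base, paste0("tissue", 6:n))
}

individual_ids <- function(config) {
  list(parentA = sprintf("COL%02d", seq_len(config$n_parentA)),
       parentB = sprintf("PIE%02d", seq_len(config$n_parentB)),
       hybrid  = sprintf("HYB%02d", seq_len(config$n_hybrid)))
}
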