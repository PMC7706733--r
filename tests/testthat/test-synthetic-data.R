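test_that("identical config and seed reproduce all generators bit-for-bit", {
  cfg <- tiny_config()
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  a1 <- simulate_allele_counts(s1$truth, cfg)
  a2 <- simulate_allele_counts(s2$truth, cfg)
  expect_identical(a1, a2)
  expect_identical(simulate_annotation(s1$truth, cfg),
                   simulate_annotation(s2$truth, cfg))
})

test_that("generator streams are split: allele simulation does not perturb counts", {
  cfg <- tiny_config()
  s1 <- simulate_counts(cfg)
  invisible(simulate_allele_counts(s1$truth, cfg))
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
})

test_that("config validation rejects bad fractions, sizes and rho", {
  expect_error(sim_config(n_parentA = 1), "n_parentA")
  expect_error(sim_config(n_genes = 10.5), "n_genes")
  expect_error(sim_config(ase_overdispersion = 1), "ase_overdispersion")
  expect_error(sim_config(mode_fractions = c(additive = 0.7,
                                             overdominant = 0.5)), "sum")
  expect_error(sim_config(mode_fractions = c(bogus = 0.1)), "unknown")
})

test_that("all-zero mode fractions give a pure null: parental groups differ only by noise", {
  cfg <- sim_config(n_genes = 2000, n_tissues = 1,
                    mode_fractions = c(additive = 0),
                    library_size_factors = rep(1, 13), seed = 1)
  s <- simulate_counts(cfg)
  expect_true(all(s$truth$mode == "conserved"))
  a <- s$samples$sample[s$samples$species == "parentA"]
  b <- s$samples$sample[s$samples$species == "parentB"]
  lc <- log2(s$counts + 1)
  pv <- vapply(seq_len(nrow(lc)), function(g)
    stats::t.test(lc[g, a], lc[g, b])$p.value, 0)
  expect_gt(mean(pv < 0.05), 0.02)
  expect_lt(mean(pv < 0.05), 0.08)
})

test_that("zero-dispersion limit is Poisson: variance/mean ratio near 1", {
  cfg <- sim_config(n_genes = 10000, n_tissues = 1,
                    mode_fractions = c(additive = 0),
                    dispersion_log_mean = -Inf, dispersion_log_sd = 0,
                    library_size_factors = rep(1, 13), seed = 2)
  s <- simulate_counts(cfg)
  a <- s$samples$sample[s$samples$species == "parentA"]
  m <- rowMeans(s$counts[, a])
  v <- apply(s$counts[, a], 1, var)
  keep <- m > 5
  expect_equal(mean(v[keep] / m[keep]), 1, tolerance = 0.05)
})

test_that("NB moments match mean + alpha * mean^2 at fixed dispersion", {
  alpha <- 0.1
  cfg <- sim_config(n_genes = 10000, n_tissues = 1,
                    mode_fractions = c(additive = 0),
                    dispersion_log_mean = log(alpha), dispersion_log_sd = 0,
                    library_size_factors = rep(1, 13),
                    base_mean_log_sd = 0, seed = 3)
  s <- simulate_counts(cfg)
  a <- s$samples$sample[s$samples$species == "parentA"]
  m <- rowMeans(s$counts[, a])
  v <- apply(s$counts[, a], 1, var)
  est <- mean((v - m)) / mean(m^2)
  expect_equal(est, alpha, tolerance = 0.2)
})

test_that("hybrid group means encode the inheritance modes", {
  cfg <- sim_config(n_genes = 3000, n_tissues = 1, effect_size_log2 = 2,
                    dispersion_log_mean = -Inf, dispersion_log_sd = 0,
                    base_mean_log_mean = log(5000), base_mean_log_sd = 0,
                    library_size_factors = rep(1, 13), tissue_effect_sd = 0,
                    mode_fractions = c(additive = 0.2, pied_dominant = 0.2,
                                       collared_dominant = 0.2,
                                       overdominant = 0.1,
                                       underdominant = 0.1),
                    seed = 4)
  s <- simulate_counts(cfg)
  grp <- function(sp) rowMeans(s$counts[, s$samples$sample[
    s$samples$species == sp], drop = FALSE])
  mA <- grp("parentA"); mB <- grp("parentB"); mH <- grp("hybrid")
  tr <- s$truth[match(rownames(s$counts), s$truth$gene), ]
  lx <- log2(mH / mA); ly <- log2(mH / mB)
  add <- tr$mode == "additive"
  expect_equal(unname(lx[add]), unname(-tr$lfc_cp[add] / 2), tolerance = 0.2)
  cd <- tr$mode == "collared_dominant"
  expect_lt(max(abs(lx[cd])), 0.2)
  expect_equal(unname(ly[cd]), unname(tr$lfc_cp[cd]), tolerance = 0.25)
  ov <- tr$mode == "overdominant"
  expect_true(all(lx[ov] > 1 & ly[ov] > 1))
})

test_that("allelic ratios follow the regulatory regime", {
  cfg <- sim_config(n_genes = 400, n_tissues = 1,
                    mode_fractions = c(additive = 0.5),
                    regime_fractions = c(cis = 0.5, trans = 0.5),
                    ase_overdispersion = 0, snp_coverage_mean = 100,
                    parental_ase_prob = 0, filter_violation_prob = 0,
                    seed = 5)
  s <- simulate_counts(cfg)
  tr <- s$truth
  ## SimTruth invariants
  cis <- tr[tr$regime == "cis", ]
  expect_true(all((cis$hybrid_ratio != 0.5) == (cis$lfc_cp != 0)))
  expect_true(all(tr$hybrid_ratio[tr$regime %in% c("trans", "null")] == 0.5))
  expect_true(all(tr$lfc_cp[tr$mode == "conserved"] == 0))

  ac <- simulate_allele_counts(tr, cfg, species = "hybrid")
  frac <- tapply(ac$hapA, ac$gene, sum) / tapply(ac$hapA + ac$hapB, ac$gene,
                                                 sum)
  tru <- setNames(tr$hybrid_ratio, tr$gene)[names(frac)]
  ## cis genes with L = +1 sit at 2:1 (empirical fraction near 2/3)
  up <- names(tru)[tru > 0.6]
  expect_equal(mean(frac[up]), 2 / 3, tolerance = 0.02)
  ## trans genes balanced
  bal <- names(tru)[tru == 0.5]
  expect_equal(mean(frac[bal]), 0.5, tolerance = 0.02)
})

test_that("balanced beta-binomial SNPs are symmetric at rho = 0", {
  cfg <- sim_config(n_genes = 2000, n_tissues = 1,
                    mode_fractions = c(additive = 0),
                    ase_overdispersion = 0, snp_coverage_mean = 100,
                    parental_ase_prob = 0, filter_violation_prob = 0,
                    seed = 6)
  s <- simulate_counts(cfg)
  ac <- simulate_allele_counts(s$truth, cfg, species = "hybrid")
  ac <- ac[ac$individual == ac$individual[1], ]
  expect_gt(nrow(ac), 5000)
  expect_equal(sum(ac$hapA) / sum(ac$hapA + ac$hapB), 0.5, tolerance = 0.01)
})

test_that("allele simulation names missing truth tissues", {
  cfg <- tiny_config()
  s <- simulate_counts(cfg)
  expect_error(simulate_allele_counts(s$truth, cfg, tissues = "testis"),
               "testis")
})

test_that("degenerate CNE probabilities make the flag equal the cis indicator", {
  cfg <- tiny_config(n_genes = 300, cne_flag_prob_given_cis = 1,
                     cne_flag_prob_given_not_cis = 0,
                     mode_fractions = c(additive = 0.4),
                     regime_fractions = c(cis = 0.5, trans = 0.5))
  s <- simulate_counts(cfg)
  ann <- simulate_annotation(s$truth, cfg)
  gp <- attr(s$truth, "gene_params")
  expect_identical(ann$cne_flag, gp$gene_cis)
})

test_that("equal CNE probabilities leave the flag independent of regime", {
  ## chi-squared on flag x cis over replicate seeds stays at calibration
  pv <- vapply(1:15, function(sd) {
    cfg <- sim_config(n_genes = 400, n_tissues = 1,
                      mode_fractions = c(additive = 0.4),
                      regime_fractions = c(cis = 0.5, trans = 0.5),
                      cne_flag_prob_given_cis = 0.2,
                      cne_flag_prob_given_not_cis = 0.2, seed = sd)
    s <- simulate_counts(cfg)
    gp <- attr(s$truth, "gene_params")
    suppressWarnings(stats::chisq.test(table(gp$cne_flag,
                                             gp$gene_cis))$p.value)
  }, 0)
  expect_lte(sum(pv < 0.05), 3)  # binomial(15, 0.05) upper tail
  expect_gt(min(pv), 0)
})

test_that("zero Z fraction gives an all-autosome annotation", {
  cfg <- tiny_config(z_fraction = 0)
  s <- simulate_counts(cfg)
  ann <- simulate_annotation(s$truth, cfg)
  expect_true(all(ann$chrom_class == "autosome"))
})

test_that("generated tables pass the pipeline's own validators unchanged", {
  cfg <- tiny_config()
  s <- simulate_counts(cfg)
  td <- withr::local_tempdir()
  write_counts(s$counts, file.path(td, "counts.tsv"))
  write.table(s$samples, file.path(td, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ac <- simulate_allele_counts(s$truth, cfg)
  write.table(ac[, c("gene", "individual", "tissue", "snp", "hapA", "hapB",
                     "phase_set")],
              file.path(td, "allele_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ann <- simulate_annotation(s$truth, cfg)
  write.table(ann, file.path(td, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cts <- read_counts(file.path(td, "counts.tsv"))
  smp <- read_samples(file.path(td, "samples.tsv"))
  expect_identical(cts, s$counts)
  expect_identical(smp, s$samples)
  expect_silent(validate_inputs(cts, smp))
  expect_equal(nrow(read_allele_counts(file.path(td, "allele_counts.tsv"))),
               nrow(ac))
  expect_identical(read_annotation(file.path(td, "annotation.tsv"))$gene,
                   ann$gene)
})
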