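test_that("Mann-Whitney worked examples: tie saturation and exact enumeration", {
  a <- mwu_association(c(1, 2, 3, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE,
                                              FALSE, FALSE))
  expect_equal(a$p, 1)
  b <- mwu_association(c(1, 2, 3, 4, 5, 6), rep(c(TRUE, FALSE), each = 3))
  expect_equal(b$U, 0)
  expect_equal(b$p, 0.1)  # 2/20 label assignments as extreme
  expect_equal(b$direction, -1)
  u <- mwu_association(numeric(0), logical(0))
  expect_equal(u$method, "untestable")
  expect_true(is.na(u$p))
})

test_that("normal approximation agrees with a permutation oracle and wilcox.test", {
  set.seed(43)
  x <- rnorm(30); y <- rnorm(30, 0.3)
  vals <- c(x, y); flags <- rep(c(TRUE, FALSE), each = 30)
  a <- mwu_association(vals, flags)
  expect_equal(a$method, "normal")
  ## permutation oracle on the U statistic
  r <- rank(vals)
  u_obs <- sum(r[flags]) - 30 * 31 / 2
  perm <- vapply(1:40000, function(i)
    sum(r[sample(60, 30)]) - 30 * 31 / 2, 0)
  p_perm <- min(1, 2 * min(mean(perm <= u_obs), mean(perm >= u_obs)))
  expect_equal(a$p, p_perm, tolerance = 0.005)
  expect_equal(a$p, wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-6)
})

test_that("exact enumeration matches wilcox.test for small tie-free groups", {
  set.seed(44)
  for (i in 1:10) {
    n1 <- sample(3:8, 1); n0 <- sample(3:8, 1)
    v <- sample(100, n1 + n0)  # tie-free
    f <- rep(c(TRUE, FALSE), c(n1, n0))
    expect_equal(mwu_association(v, f)$p,
                 wilcox.test(v[f], v[!f], exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("Yates chi-squared: balanced table is null; zero marginal errors", {
  bal <- chisq_yates(matrix(10, 2, 2))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p, 1)
  expect_error(chisq_yates(matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)),
               "marginal")
  expect_error(chisq_yates(matrix(1, 3, 3)), "2x2")
})

test_that("hypergeometric tail equals enumeration and phyper; edge and monotone cases", {
  ## brute-force enumeration on the (2, 2, 2, 94) table
  enum <- sum(vapply(2:4, function(k)
    choose(4, k) * choose(96, 4 - k) / choose(100, 4), 0))
  expect_equal(hypergeom_enrichment(2, 2, 2, 94), enum, tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(2, 2, 2, 94),
               phyper(1, 4, 96, 4, lower.tail = FALSE), tolerance = 1e-12)
  ## de_z = 0 is the support minimum: p = 1
  expect_equal(hypergeom_enrichment(0, 10, 5, 85), 1)
  ## monotone non-increasing in de_z at fixed marginals
  ps <- vapply(0:10, function(k)
    hypergeom_enrichment(k, 10 - k, 20 - k, 70 + k), 0)
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(hypergeom_enrichment(-1, 1, 1, 1), "non-negative")
  expect_error(hypergeom_enrichment(0.5, 1, 1, 1), "integer")
})

test_that("fast-Z test flags planted Z enrichment and Holm-adjusts across tissues", {
  mk_de <- function(n_auto, n_z, de_rate_a, de_rate_z, seed) {
    set.seed(seed)
    data.frame(
      gene = paste0("g", 1:(n_auto + n_z)),
      status = c(ifelse(runif(n_auto) < de_rate_a, "DE", "nDE"),
                 ifelse(runif(n_z) < de_rate_z, "DE", "nDE")),
      stringsAsFactors = FALSE)
  }
  cls <- setNames(rep(c("autosome", "Z"), c(2000, 500)),
                  paste0("g", 1:2500))
  de <- list(brain = mk_de(2000, 500, 0.03, 0.09, 1),
             testis = mk_de(2000, 500, 0.03, 0.03, 2))
  fz <- fast_z_test(de, cls)
  expect_lt(fz$p[fz$tissue == "brain"], 0.01)
  expect_gt(fz$p[fz$tissue == "testis"], 0.05)
  expect_true(all(fz$p_holm >= fz$p))
  ## no Z genes: untestable
  cls_a <- setNames(rep("autosome", 2500), paste0("g", 1:2500))
  expect_true(all(is.na(fast_z_test(de, cls_a)$p)))
})

test_that("compensation test returns NA when no misexpressed gene is assessable", {
  mis <- data.frame(gene = paste0("g", 1:50), eligible = TRUE,
                    misexpressed = FALSE, stringsAsFactors = FALSE)
  pop <- data.frame(gene = paste0("g", 1:50),
                    status = rep(c("ASE", "non-ASE"), 25),
                    stringsAsFactors = FALSE)
  cls <- setNames(rep("autosome", 50), paste0("g", 1:50))
  ct <- compensation_test(mis, pop, cls)
  expect_true(is.na(ct$p))
  expect_equal(sum(ct$table["misexpressed", ]), 0)
})

test_that("compensation test detects a planted misexpression-ASE association", {
  set.seed(47)
  n <- 1200
  mis_flag <- runif(n) < 0.08
  ase_flag <- ifelse(mis_flag, runif(n) < 0.4, runif(n) < 0.08)
  mis <- data.frame(gene = paste0("g", 1:n), eligible = TRUE,
                    misexpressed = mis_flag, stringsAsFactors = FALSE)
  pop <- data.frame(gene = paste0("g", 1:n),
                    status = ifelse(ase_flag, "ASE", "non-ASE"),
                    stringsAsFactors = FALSE)
  cls <- setNames(rep("autosome", n), paste0("g", 1:n))
  expect_lt(compensation_test(mis, pop, cls)$p, 1e-6)
})

test_that("GLM determinants recover a planted tau effect and stay calibrated", {
  mk_data <- function(beta_tau, n, seed) {
    set.seed(seed)
    ann <- data.frame(gene = paste0("g", 1:n), chrom_class = "autosome",
                      length = 1000L, cne_flag = FALSE,
                      ppi = rpois(n, 8), tau = runif(n),
                      phi = rlnorm(n, log(0.05), 0.5),
                      piNpiS = rlnorm(n, log(0.25), 0.4),
                      dNdS = rlnorm(n, log(0.15), 0.5),
                      fst = rbeta(n, 2, 8), stringsAsFactors = FALSE)
    eta <- -2.5 + beta_tau * scale(ann$tau)[, 1]
    de <- data.frame(gene = ann$gene,
                     status = ifelse(runif(n) < plogis(eta), "DE", "nDE"),
                     shrunkenLfc = rnorm(n, 0, 0.3),
                     stringsAsFactors = FALSE)
    list(de = de, ann = ann)
  }
  ## planted positive effect: sign recovered in (nearly) all replicates
  signs <- vapply(1:5, function(i) {
    d <- mk_data(0.8, 2000, i)
    fit <- glm_determinants(d$de, d$ann, mode = "binomial")
    sign(fit$estimate[fit$covariate == "tau"]) *
      (fit$p[fit$covariate == "tau"] < 0.05)
  }, 0)
  expect_gte(sum(signs == 1), 4)
  ## null covariates: p roughly uniform across replicates
  pv <- vapply(1:20, function(i) {
    d <- mk_data(0, 600, 100 + i)
    fit <- glm_determinants(d$de, d$ann, mode = "binomial")
    fit$p[fit$covariate == "tau"]
  }, 0)
  expect_lte(sum(pv < 0.05), 4)
  expect_gt(mean(pv), 0.25)
  ## linear mode runs and returns one row per covariate
  d <- mk_data(0.5, 800, 3)
  lin <- glm_determinants(d$de, d$ann, mode = "linear")
  expect_equal(lin$covariate, c("ppi", "tau", "phi", "piNpiS", "dNdS",
                                "fst"))
  ## degenerate inputs
  d0 <- mk_data(0, 200, 4)
  d0$de$status[] <- "nDE"
  expect_error(glm_determinants(d0$de, d0$ann), "no variation")
  expect_error(glm_determinants(d$de[1:10, ], d$ann[1:10, ]), ">= 50")
})

test_that("ASE-DE association is hybrid-specific under a cis-only architecture", {
  cfg <- sim_config(n_genes = 600, n_tissues = 1,
                    mode_fractions = c(additive = 0.15),
                    regime_fractions = c(cis = 1),
                    snp_coverage_mean = 60, seed = 51)
  s <- simulate_counts(cfg)
  de <- run_de(s$counts, s$samples, "brain", "CP")
  ac <- simulate_allele_counts(s$truth, cfg)
  pops <- lapply(split(ac, ac$species), function(d)
    run_ase(d, min_coverage = 30)$population)
  ann <- simulate_annotation(s$truth, cfg)
  cls <- setNames(ann$chrom_class, ann$gene)
  res <- ase_de_association(de, pops, cls)
  expect_lt(res$p[res$source == "hybrid"], 0.05)
  expect_gt(min(res$p[res$source != "hybrid"]), 0.05)
  ## flags all false: untestable
  none <- pops$hybrid
  none$status <- "non-ASE"
  res2 <- ase_de_association(de, list(hybrid = none), cls)
  expect_equal(res2$method, "untestable")
})
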