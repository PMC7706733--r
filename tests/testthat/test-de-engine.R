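test_that("size factors follow the median-of-ratios worked examples", {
  expect_equal(unname(size_factors(matrix(c(5, 7, 5, 7), 2, 2))), c(1, 1))
  ## hand evaluation: geometric means (sqrt(200), sqrt(1800)),
  ## ratios per column (1/sqrt 2, sqrt 2)
  expect_equal(unname(size_factors(matrix(c(10, 30, 20, 60), 2, 2))),
               c(sqrt(0.5), sqrt(2)), tolerance = 1e-7)
  ## a gene with a zero count is excluded from the reference set:
  ## rows (0, 5) and (10, 10) leave only the balanced second gene
  expect_equal(unname(size_factors(matrix(c(0, 5, 10, 10), 2, 2,
                                          byrow = TRUE))), c(1, 1))
})

test_that("size factors error without an all-positive gene, unless pseudo-reference", {
  m <- matrix(c(0, 5, 10, 0), 2, 2)
  expect_error(size_factors(m), "pseudo_reference")
  expect_length(size_factors(m, pseudo_reference = TRUE), 2)
})

test_that("size factors match the DESeq2 reference implementation", {
  suppressPackageStartupMessages(requireNamespace("DESeq2"))
  cfg <- tiny_config(n_genes = 300, n_tissues = 1)
  s <- simulate_counts(cfg)
  ## agreement up to the even-count median midpoint convention
  ## (arithmetic vs geometric mean of the two central ratios)
  expect_equal(unname(size_factors(s$counts)),
               unname(DESeq2::estimateSizeFactorsForMatrix(s$counts)),
               tolerance = 1e-4)
})

test_that("rlog-like transform: zero maps to zero, depth-invariant, monotone", {
  m <- matrix(c(0L, 4L, 9L, 19L), 2, 2)
  lt <- rlog_like(m, sf = c(1, 1))
  expect_equal(lt[1, 1], 0)
  expect_equal(lt[2, 2], log2(20))
  ## doubling counts and the size factor leaves values invariant
  expect_equal(rlog_like(2L * m, sf = c(2, 2)), rlog_like(m, sf = c(1, 1)))
  ## monotone within a sample
  expect_true(all(diff(rlog_like(matrix(0:10), sf = 1)) > 0))
})

test_that("dispersion: constant counts give a zero moment estimate shrunk to the trend floor", {
  m <- matrix(rep(c(50L, 100L), each = 6), 2, 6, byrow = TRUE)
  phi <- suppressWarnings(
    estimate_dispersions(m, sf = rep(1, 6), groups = rep(c("a", "b"), 3)))
  expect_equal(unname(attr(phi, "gene_est")), c(0, 0))
  expect_true(all(phi < attr(phi, "trend")[1] + 1e-6))
})

test_that("dispersion: Poisson counts give small phi, NB recovers the truth", {
  set.seed(7)
  ## Poisson: median phi below 0.05 (coverage 20-200, 5000 genes)
  mu <- runif(5000, 20, 200)
  m <- matrix(rpois(5000 * 10, rep(mu, 10)), ncol = 10)
  phi <- estimate_dispersions(m, sf = rep(1, 10),
                              groups = rep(c("a", "b"), each = 5))
  expect_lt(median(phi), 0.05)
  ## NB with alpha = 0.1 for all genes, n = 10 samples
  m2 <- matrix(rnbinom(5000 * 10, mu = rep(mu, 10), size = 10), ncol = 10)
  phi2 <- estimate_dispersions(m2, sf = rep(1, 10),
                               groups = rep(c("a", "b"), each = 5))
  expect_gt(median(phi2), 0.07)
  expect_lt(median(phi2), 0.13)
})

test_that("wald test is symmetric on identical groups and flags all-zero genes", {
  m <- matrix(c(10L, 60L, 0L, 10L, 60L, 0L), 3, 2)
  m <- cbind(m, m)  # two groups with literally identical column sets
  grp <- rep(c("x", "y"), each = 2)
  res <- wald_test(m, sf = rep(1, 4), dispersions = rep(0.05, 3),
                   group = grp, contrast = c("x", "y"))
  nz <- res$status != "untested"
  expect_equal(res$lfc[nz], rep(0, sum(nz)), tolerance = 1e-6)
  expect_equal(res$p[nz], rep(1, sum(nz)), tolerance = 1e-6)
  expect_equal(res$status[3], "untested")
  expect_true(is.na(res$p[3]))
})

test_that("scaling one sample's counts scales its size factor and preserves LFCs", {
  cfg <- tiny_config(n_genes = 200, n_tissues = 1, seed = 9)
  s <- simulate_counts(cfg)
  keep <- s$samples$species %in% c("parentA", "parentB")
  m <- s$counts[, s$samples$sample[keep]]
  m <- m[rowSums(m == 0) == 0, ]  # keep the reference set stable
  grp <- s$samples$species[keep]
  sf1 <- size_factors(m)
  m2 <- m
  m2[, 3] <- 5L * m2[, 3]
  sf2 <- size_factors(m2)
  ## the formula is unscaled, so scaling one column scales its factor by 5
  ## relative to the others (all factors share a 5^(-1/n) geometric-mean
  ## shift, which cancels in every ratio)
  expect_equal(sf2[3] / sf2[1], 5 * sf1[3] / sf1[1], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sf2[-3] / sf2[1], sf1[-3] / sf1[1], tolerance = 1e-12,
               ignore_attr = TRUE)
  ## per-sample normalized counts are exactly invariant
  expect_equal(sweep(m2, 2, sf2 / sf2[1], "/"),
               sweep(m, 2, sf1 / sf1[1], "/"), tolerance = 1e-12)
  ## the dispersion-weighted MLE reweights the rescaled sample, so LFC
  ## invariance is exact only when the groups fit the model perfectly;
  ## construct such a matrix and require 1e-8 agreement there
  mp <- rbind(c(64L, 64L, 64L, 128L, 128L, 128L),
              c(40L, 40L, 40L, 10L, 10L, 10L),
              c(100L, 100L, 100L, 100L, 100L, 100L))
  grp_p <- rep(c("parentA", "parentB"), each = 3)
  mp2 <- mp; mp2[, 2] <- 5L * mp2[, 2]
  phi_p <- rep(0.05, 3)
  rp1 <- wald_test(mp, rep(1, 6), phi_p, grp_p, c("parentA", "parentB"))
  rp2 <- wald_test(mp2, c(1, 5, 1, 1, 1, 1), phi_p, grp_p,
                   c("parentA", "parentB"))
  expect_equal(rp1$lfc, rp2$lfc, tolerance = 1e-8)
  ## on noisy data the invariance holds to first order
  phi <- rep(0.02, nrow(m))
  r1 <- wald_test(m, sf1, phi, grp, c("parentA", "parentB"))
  r2 <- wald_test(m2, sf2, phi, grp, c("parentA", "parentB"))
  expect_equal(r1$lfc, r2$lfc, tolerance = 0.1)
})

test_that("padj equals a brute-force BH reference exactly", {
  set.seed(11)
  p <- runif(500)^2
  expect_identical(adjust_pvalues(p, "BH"), bh_brute(p))
})

test_that("LFC shrinkage is monotone in information and vanishes with a flat prior", {
  ## two genes, identical raw fold change, coverage 5x apart
  m <- matrix(c(20L, 24L, 16L, 80L, 84L, 76L,
                100L, 120L, 80L, 400L, 420L, 380L), 2, 6, byrow = TRUE)
  grp <- rep(c("a", "b"), each = 3)
  sf <- rep(1, 6)
  phi <- rep(0.01, 2)
  res <- wald_test(m, sf, phi, grp, c("b", "a"))
  expect_equal(res$lfc[1], res$lfc[2], tolerance = 0.01)
  s <- shrink_lfc(m, sf, phi, grp, c("b", "a"), res, prior_var = 0.25)
  expect_lt(abs(s[1]), abs(s[2]))          # low coverage shrinks more
  expect_lt(abs(s[2]), abs(res$lfc[2]))    # shrinkage reduces magnitude
  ## flat prior recovers the raw fold change
  s_inf <- shrink_lfc(m, sf, phi, grp, c("b", "a"), res, prior_var = Inf)
  expect_equal(s_inf, res$lfc, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("all-zero genes get shrunken LFC exactly 0", {
  m <- rbind(c(0L, 0L, 0L, 0L), c(30L, 25L, 40L, 35L))
  grp <- rep(c("a", "b"), each = 2)
  res <- wald_test(m, rep(1, 4), rep(0.05, 2), grp, c("a", "b"))
  s <- shrink_lfc(m, rep(1, 4), rep(0.05, 2), grp, c("a", "b"), res,
                  prior_var = 0.25)
  expect_identical(s[1], 0)
})

test_that("planted strong effects are recovered with high power", {
  cfg <- sim_config(n_genes = 800, n_tissues = 1,
                    mode_fractions = c(additive = 0.3),
                    effect_size_log2 = 2, base_mean_log_mean = log(500),
                    seed = 4)
  s <- simulate_counts(cfg)
  de <- run_de(s$counts, s$samples, "brain", "CP")
  tr <- s$truth[match(de$gene, s$truth$gene), ]
  planted <- tr$mode == "additive" & de$baseMean >= 100
  expect_gte(mean(de$padj[planted] < 0.05, na.rm = TRUE), 0.95)
})

test_that("DE overlap cells match a brute-force enumeration", {
  sets <- list(t1 = c("a", "b"), t2 = c("b", "c"), t3 = "b")
  uni <- c("a", "b", "c", "d")
  ov <- de_overlap(sets, uni)
  cell <- function(nm) ov$count[ov$cell == nm]
  expect_equal(cell("t1&t2&t3"), 1L)  # {b}
  expect_equal(cell("t1"), 1L)        # {a}
  expect_equal(cell("t2"), 1L)        # {c}
  expect_equal(cell("none"), 1L)      # {d}
  expect_equal(sum(ov$count), length(uni))
  ## disjoint sets leave all multi-tissue cells empty
  ov2 <- de_overlap(list(t1 = "a", t2 = "b"), uni)
  expect_equal(ov2$count[ov2$cell == "t1&t2"], 0L)
  ## identical sets fill only the all-tissues and none cells
  ov3 <- de_overlap(list(t1 = c("a", "b"), t2 = c("a", "b")), uni)
  expect_equal(ov3$count[ov3$cell == "t1&t2"], 2L)
  expect_equal(sum(ov3$count[ov3$cell %in% c("t1", "t2")]), 0L)
  expect_error(de_overlap(list(t1 = "z"), uni), "universe")
})
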