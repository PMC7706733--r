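# shared tiny configurations; every fixture is generated in code

tiny_config <- function(...) {
  defaults <- list(n_genes = 150, n_tissues = 2, seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# brute-force BH reference (textbook step-up with monotonicity)
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- n / seq_len(n) * p[o]
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force Holm reference (textbook step-down)
holm_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- cummax((n - seq_len(n) + 1) * p[o])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# closed-form binomial LRT over shared-ratio alternative (ASE oracle)
binom_lrt <- function(a, n) {
  r <- sum(a) / sum(n)
  l1 <- sum(dbinom(a, n, r, log = TRUE))
  l0 <- sum(dbinom(a, n, 0.5, log = TRUE))
  max(2 * (l1 - l0), 0)
}
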