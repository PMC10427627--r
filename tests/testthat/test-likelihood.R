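test_that("region depth likelihood matches its limits and normalises", {
  cn <- rep(2, 10)
  rho <- rep(0.1, 10)
  # Poisson limit of the Gamma-Poisson at huge inverse dispersion
  for (dd in c(0L, 3L, 10L, 25L))
    expect_equal(region_depth_loglik(dd, 100, cn, 1, rho, 1e9),
                 dpois(dd, 10, log = TRUE), tolerance = 1e-4)
  # pmf sums to one
  p <- sum(exp(vapply(0:10000, function(dd)
    region_depth_loglik(dd, 100, cn, 2, rep(c(0.2, 0.0889), c(1, 9)), 5),
    0)))
  expect_equal(p, 1, tolerance = 1e-8)
  # high-precision check against the log-gamma form of the NB pmf (m = 4)
  m <- 40 * 2 * 0.1 / sum(cn * rho)
  theta <- 10
  direct <- lgamma(5 + theta) - lgamma(6) - lgamma(theta) +
    theta * log(theta / (theta + m)) + 5 * log(m / (theta + m))
  expect_equal(region_depth_loglik(5, 40, cn, 3, rho, theta), direct,
               tolerance = 1e-12)
  expect_error(region_depth_loglik(5, 100, rep(0, 10), 1, rho, 10),
               "all-zero")
})

test_that("beta-binomial matches the binomial limit, normalises, and agrees
           with numerical integration", {
  for (a in 0:10)
    expect_equal(beta_binomial_loglik(a, 10, 0.5, 1e8),
                 dbinom(a, 10, 0.5, log = TRUE), tolerance = 1e-4)
  p <- sum(exp(beta_binomial_loglik(0:25, 25, 0.3, 50)))
  expect_equal(p, 1, tolerance = 1e-10)
  # independent oracle: integrate the binomial against the beta density
  ora <- integrate(function(p) dbinom(3, 10, p) * dbeta(p, 50 * 0.5, 50 * 0.5),
                   0, 1, rel.tol = 1e-12)$value
  expect_equal(beta_binomial_loglik(3, 10, 0.5, 50), log(ora),
               tolerance = 1e-9)
  expect_error(beta_binomial_loglik(3, 10, 0, 50), "strictly inside")
})

test_that("allelic likelihood reduces correctly without dropout and matches
           hand enumeration with dropout", {
  p <- model_params()
  # no dropout, het: plain beta-binomial at f = 1/2
  expect_equal(allelic_loglik(4, 12, 1, 1, 0, p),
               beta_binomial_loglik(4, 12, 0.5, p$omega_het))
  # no dropout, hom ref: error-rate beta-binomial
  expect_equal(allelic_loglik(1, 12, 1, 0, 0, p),
               beta_binomial_loglik(1, 12, p$eps, p$omega_hom))
  # (c_r, c_a) = (2, 1), mu = 0.3: enumerate the five admissible terms
  mu <- 0.3; a <- 4; dd <- 12
  terms <- c()
  for (k in 0:2) for (l in 0:1) {
    if (k + l == 0) next
    f <- (l * (1 - p$eps) + k * p$eps) / (k + l)
    om <- if (k == 0 || l == 0) p$omega_hom else p$omega_het
    terms <- c(terms, choose(2, k) * choose(1, l) * mu^(3 - k - l) *
                 (1 - mu)^(k + l) * exp(beta_binomial_loglik(a, dd, f, om)))
  }
  expect_equal(allelic_loglik(a, dd, 2, 1, mu, p),
               log(sum(terms) / (1 - mu^3)), tolerance = 1e-12)
  # literal (unrenormalised) form via the switch
  p2 <- model_params(dropout_renormalize = FALSE)
  expect_equal(allelic_loglik(a, dd, 2, 1, mu, p2), log(sum(terms)),
               tolerance = 1e-12)
  expect_equal(allelic_loglik(3, 0, 1, 1, 0.1, p), 0) # no reads, no info
  expect_error(allelic_loglik(0, 5, 0, 0, 0.1, p), "deleted")
})

test_that("compiled attachment log-likelihoods equal the scalar composition", {
  set.seed(4)
  cfg <- sim_config(n_cells = 8, n_regions = 5, n_nodes = 3, n_snvs = 2,
                    n_cnas = 1, doublet_rate = 0, fraction_germline = 0.5)
  out <- simulate_dataset(cfg, seed = 4)
  d <- out$data
  p <- model_params(doublet_rate = 0, dropout_rates = 0.07)
  rho <- ampliclone:::default_region_weights(d)
  mu <- rep(0.07, nrow(d$variants))
  ll <- attachment_logliks(out$tree, d, p)
  for (nd in seq_along(out$tree$parent)) {
    g <- node_genotype(out$tree, nd, d)
    for (j in seq_along(d$cell_ids))
      expect_equal(ll$singlet_ll[j, nd],
                   scalar_cell_ll(g, j, d, p, rho, mu), tolerance = 1e-10)
  }
})

test_that("tree likelihood equals brute-force attachment enumeration", {
  for (s in 1:25) {
    set.seed(s)
    delta <- if (s %% 2 == 0) 0.1 else 0
    cfg <- sim_config(n_cells = sample(4:8, 1), n_regions = 4,
                      n_nodes = sample(2:4, 1), n_snvs = 3,
                      n_cnas = sample(0:1, 1), doublet_rate = delta,
                      fraction_germline = 0.5)
    out <- simulate_dataset(cfg, seed = s + 1000)
    d <- out$data
    p <- model_params(doublet_rate = delta, dropout_rates = 0.06)
    n <- length(out$tree$parent)
    pi <- rgamma(n, 1) + 0.05
    pi <- pi / sum(pi)
    rho <- ampliclone:::default_region_weights(d)
    mu <- rep(0.06, nrow(d$variants))
    expect_equal(tree_loglik(out$tree, d, p, pi),
                 brute_force_tree_loglik(out$tree, d, p, pi, rho, mu),
                 tolerance = 1e-8)
  }
})

test_that("tree likelihood is additive over cells and invariant under node
           relabelling", {
  set.seed(9)
  cfg <- sim_config(n_cells = 6, n_regions = 4, n_nodes = 3, n_snvs = 3,
                    n_cnas = 1, doublet_rate = 0, fraction_germline = 0)
  out <- simulate_dataset(cfg, seed = 9)
  d <- out$data
  p <- model_params(doublet_rate = 0)
  pi <- c(0.5, 0.3, 0.2)
  full <- tree_loglik(out$tree, d, p, pi)
  parts <- vapply(seq_along(d$cell_ids), function(j) {
    dj <- d
    for (f in c("region_depth", "alt_counts", "var_depth"))
      dj[[f]] <- dj[[f]][j, , drop = FALSE]
    dj$cell_total <- dj$cell_total[j]
    dj$cell_ids <- dj$cell_ids[j]
    tree_loglik(out$tree, dj, p, pi)
  }, 0)
  expect_equal(full, sum(parts), tolerance = 1e-9)

  # relabel nodes 2 and 3 (leaf children of the root) with pi permuted
  tr <- out$tree
  if (all(tr$parent[2:3] == 1)) {
    tr2 <- tr
    tr2$events[[2]] <- tr$events[[3]]
    tr2$events[[3]] <- tr$events[[2]]
    expect_equal(tree_loglik(tr2, d, p, pi[c(1, 3, 2)]), full,
                 tolerance = 1e-9)
  }
})

test_that("doublet likelihood is continuous at delta -> 0", {
  set.seed(11)
  cfg <- sim_config(n_cells = 5, n_regions = 4, n_nodes = 3, n_snvs = 3,
                    n_cnas = 0, doublet_rate = 0, fraction_germline = 0)
  out <- simulate_dataset(cfg, seed = 11)
  d <- out$data
  pi <- c(0.2, 0.5, 0.3)
  l0 <- tree_loglik(out$tree, d, model_params(doublet_rate = 0), pi)
  leps <- tree_loglik(out$tree, d, model_params(doublet_rate = 1e-12), pi)
  expect_equal(l0, leps, tolerance = 1e-9)
})
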