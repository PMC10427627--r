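test_that("e_step responsibilities follow Bayes' rule", {
  d <- toy_panel(n_cells = 5, n_regions = 3, n_variants = 2)
  p <- model_params(doublet_rate = 0)
  # single node: everything at the root
  tr1 <- event_tree(NA, list(list(ev_snv(1), ev_snv(2))))
  st <- e_step(tr1, d, p)
  expect_equal(unname(st$responsibilities[, 1]), rep(1, 5))

  # two genotype-identical nodes: the likelihood cancels, prior remains
  tr2 <- event_tree(c(NA, 1), list(list(ev_snv(1), ev_snv(2)), list()))
  st2 <- e_step(tr2, d, p, pi = c(0.3, 0.7))
  expect_equal(unname(st2$responsibilities),
               matrix(c(0.3, 0.7), 5, 2, byrow = TRUE), tolerance = 1e-9)

  # general case: rows normalise and match the scalar likelihoods
  tr3 <- event_tree(c(NA, 1), list(list(ev_snv(2)), list(ev_snv(1))))
  pi <- c(0.4, 0.6)
  st3 <- e_step(tr3, d, p, pi = pi)
  expect_equal(rowSums(st3$responsibilities), rep(1, 5), tolerance = 1e-8)
  rho <- ampliclone:::default_region_weights(d)
  mu <- rep(p$dropout_rates, 2)
  for (j in 1:5) {
    lw <- vapply(1:2, function(nd)
      log(pi[nd]) + scalar_cell_ll(node_genotype(tr3, nd, d), j, d, p, rho,
                                   mu), 0)
    expect_equal(unname(st3$responsibilities[j, ]),
                 unname(exp(lw - max(lw)) / sum(exp(lw - max(lw)))),
                 tolerance = 1e-8)
  }
})

test_that("dropout-configuration posteriors match hand enumeration", {
  # het genotype (1,1), mu = 0.1, one cell with a = 0, d = 20
  rd <- matrix(40L, 1, 1, dimnames = list("c1", "R1"))
  vars <- data.frame(id = "v1", region = 1, chrom = "chr1", pos = 1)
  regs <- data.frame(id = "R1", chrom = "chr1", order_index = 1,
                     n_amplicons = 1)
  d <- panel_data(rd, matrix(0L, 1, 1), matrix(20L, 1, 1), vars, regs)
  p <- model_params(doublet_rate = 0, dropout_rates = 0.1)
  tr <- event_tree(NA, list(list(ev_snv(1))))
  st <- e_step(tr, d, p)
  q <- st$dropout_posteriors[[1]][[1]]
  cfg <- attr(q, "configs")
  # hand enumeration over (k, l) in {(1,0), (0,1), (1,1)}
  mu <- 0.1
  w <- c(mu * (1 - mu) * exp(beta_binomial_loglik(0, 20, p$eps, p$omega_hom)),
         mu * (1 - mu) * exp(beta_binomial_loglik(0, 20, 1 - p$eps,
                                                  p$omega_hom)),
         (1 - mu)^2 * exp(beta_binomial_loglik(0, 20, 0.5, p$omega_het)))
  names(w) <- c("1,0", "0,1", "1,1")
  got <- setNames(as.numeric(q[1, ]), paste(cfg$k, cfg$l, sep = ","))
  expect_equal(got[names(w)], w / sum(w), tolerance = 1e-10)
})

test_that("m_step recovers hard-assignment weights and the prior-only
           dropout fixed point", {
  d <- toy_panel(n_cells = 10, n_regions = 3, n_variants = 2)
  p <- model_params(doublet_rate = 0)
  tr <- event_tree(c(NA, 1), list(list(ev_snv(2)), list(ev_snv(1))))
  st <- e_step(tr, d, p, pi = c(0.5, 0.5))
  # overwrite with hard assignments: 3 of 10 cells at node 2
  st$responsibilities <- cbind(rep(c(1, 0), c(7, 3)), rep(c(0, 1), c(7, 3)))
  upd <- m_step(st, tr, d)
  expect_equal(upd$pi, c(0.7, 0.3))

  # no data at a variant: iterating the updates converges to the
  # symmetric-prior fixed point (alpha-1)/(alpha+beta-2) = 1/2
  d0 <- d
  d0$var_depth[] <- 0L
  d0$alt_counts[] <- 0L
  p_sym <- model_params(doublet_rate = 0, dropout_prior_mean = 0.5,
                        dropout_prior_strength = 10)
  em0 <- fit_em(tr, d0, p_sym, max_iter = 300, tol = 0)
  expect_equal(em0$mu, rep(0.5, 2), tolerance = 1e-4)
})

test_that("m_step dropout update maximises the expected complete-data log
           posterior", {
  set.seed(3)
  cfg <- sim_config(n_cells = 2, n_regions = 3, n_nodes = 2, n_snvs = 1,
                    n_cnas = 0, doublet_rate = 0, fraction_germline = 0)
  out <- simulate_dataset(cfg, seed = 3)
  d <- out$data
  p <- model_params(doublet_rate = 0, dropout_rates = 0.12)
  st <- e_step(out$tree, d, p, pi = c(0.5, 0.5))
  upd <- m_step(st, out$tree, d, dropout_prior = c(2, 38))
  # numeric maximisation of the expected complete-data log posterior
  obj <- function(m, vi) {
    tot <- (2 - 1) * log(m) + (38 - 1) * log1p(-m)
    for (a in seq_len(ncol(st$responsibilities))) {
      q <- st$dropout_posteriors[[vi]][[a]]
      cfg_kl <- attr(q, "configs")
      cc <- st$attachments$cr[a, vi] + st$attachments$ca[a, vi]
      for (j in seq_len(nrow(q))) {
        for (t in seq_len(ncol(q))) {
          nd <- cc - cfg_kl$k[t] - cfg_kl$l[t]
          tot <- tot + st$responsibilities[j, a] * q[j, t] *
            (nd * log(m) + (cc - nd) * log1p(-m) - log1p(-m^cc))
        }
      }
    }
    tot
  }
  for (i in seq_len(nrow(d$variants))) {
    opt <- optimize(obj, c(1e-4, 0.5), vi = i, maximum = TRUE,
                    tol = 1e-10)$maximum
    expect_equal(upd$mu[i], opt, tolerance = 1e-5)
  }
})

test_that("compiled EM agrees with one R-level E/M cycle", {
  set.seed(6)
  cfg <- sim_config(n_cells = 20, n_regions = 4, n_nodes = 3, n_snvs = 2,
                    n_cnas = 1, doublet_rate = 0, fraction_germline = 0.5)
  out <- simulate_dataset(cfg, seed = 6)
  d <- out$data
  p <- model_params(doublet_rate = 0)
  st <- e_step(out$tree, d, p)
  upd <- m_step(st, out$tree, d,
                dropout_prior = c(p$dropout_prior_alpha,
                                  p$dropout_prior_beta))
  em1 <- fit_em(out$tree, d, p, max_iter = 1, tol = -1)
  expect_equal(unname(em1$responsibilities), unname(st$responsibilities),
               tolerance = 1e-8)
  em2 <- fit_em(out$tree, d, p, max_iter = 2, tol = -1)
  expect_equal(em2$pi, upd$pi, tolerance = 1e-8)
  expect_equal(em2$mu, upd$mu, tolerance = 1e-5)
})

test_that("EM is monotone, converges in one step for a one-node tree, and
           recovers simulated dropout rates and node weights", {
  d1 <- toy_panel(n_cells = 8, n_regions = 3, n_variants = 1)
  p <- model_params(doublet_rate = 0)
  tr1 <- event_tree(NA, list(list(ev_snv(1))))
  em1 <- fit_em(tr1, d1, p, max_iter = 50, tol = 1e-4)
  expect_lte(em1$n_iter, 3) # pi has nothing to learn
  expect_true(all(diff(em1$log_post_trace) > -1e-7))

  # balanced clones keep every variant identifiable at this small scale
  cfg <- sim_config(n_cells = 500, n_regions = 15, n_nodes = 4, n_snvs = 4,
                    n_cnas = 0, doublet_rate = 0, dropout_mean = 0.08,
                    dropout_sd = 0, fraction_germline = 0.5,
                    concentration = 5)
  out <- simulate_dataset(cfg, seed = 21)
  em <- fit_em(out$tree, out$data, p, max_iter = 200, tol = 1e-5,
               rho = out$truth$region_weights)
  expect_true(all(diff(em$log_post_trace) > -1e-7))
  expect_gte(mean(abs(em$mu - out$truth$dropout_rates) <= 0.03), 0.8)
  expect_lte(max(abs(em$pi - out$truth$node_weights)), 0.05)
})

test_that("EM with doublets keeps responsibilities normalised over the
           extended attachment space", {
  set.seed(13)
  cfg <- sim_config(n_cells = 30, n_regions = 4, n_nodes = 3, n_snvs = 2,
                    n_cnas = 0, doublet_rate = 0.2, fraction_germline = 0.5)
  out <- simulate_dataset(cfg, seed = 13)
  p <- model_params(doublet_rate = 0.2)
  em <- fit_em(out$tree, out$data, p, max_iter = 30, tol = 1e-4)
  n <- length(out$tree$parent)
  expect_equal(ncol(em$responsibilities), n + n * (n + 1) / 2)
  expect_equal(rowSums(em$responsibilities),
               rep(1, length(out$data$cell_ids)), tolerance = 1e-8)
  expect_true(all(diff(em$log_post_trace) > -1e-7))
  expect_equal(sum(em$pi), 1, tolerance = 1e-8)
})
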