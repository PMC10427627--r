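test_that("simulated trees satisfy the constraints and the support rule", {
  for (s in 1:20) {
    set.seed(s)
    cfg <- sim_config(n_cells = 1, n_regions = 8, n_nodes = sample(2:6, 1),
                      n_snvs = 6, n_cnas = sample(0:3, 1))
    sim <- simulate_tree(cfg)
    expect_length(validate_tree(sim$tree, sim$data_template), 0)
    if (cfg$n_cnas == 0)
      expect_equal(nrow(ampliclone:::cna_placements(sim$tree)), 0)
    # with full support, every CNA has an SNV or LOH at or below its node
    sup <- classify_cna_support(sim$tree, sim$data_template)
    expect_true(all(sup))
  }
  # unsupported CNAs live in SNV-free leaves
  set.seed(2)
  cfg <- sim_config(n_cells = 1, n_regions = 10, n_nodes = 6, n_snvs = 5,
                    n_cnas = 2, snv_support_fraction = 0)
  sim <- simulate_tree(cfg)
  sup <- classify_cna_support(sim$tree, sim$data_template)
  expect_true(all(!sup))
})

test_that("generated counts satisfy the container invariants", {
  out <- simulate_dataset(sim_config(n_cells = 200, n_regions = 8,
                                     n_nodes = 3, n_snvs = 3, n_cnas = 1),
                          seed = 3)
  d <- out$data
  expect_true(all(d$alt_counts <= d$var_depth))
  expect_equal(d$cell_total, unname(rowSums(d$region_depth)))
  expect_equal(length(out$truth$attachment), length(d$cell_ids))
})

test_that("noise-free allele fractions hit their genotype expectations", {
  cfg <- sim_config(n_cells = 400, n_regions = 6, n_nodes = 2, n_snvs = 1,
                    n_cnas = 1, eps = 0.001, dropout_mean = 0.01,
                    dropout_sd = 0, doublet_rate = 0, depth_mean = 200,
                    fraction_germline = 1, n_germline = 2,
                    coverage_mode = "uniform")
  # find a simulation whose CNA is a CNLOH on a variant-bearing region
  for (s in 1:50) {
    out <- simulate_dataset(cfg, seed = 1000 + s)
    cr <- out$truth$genotype_cr
    ca <- out$truth$genotype_ca
    het <- cr >= 1 & ca >= 1
    hom_alt <- cr == 0 & ca >= 1
    vaf <- out$data$alt_counts / pmax(out$data$var_depth, 1)
    if (sum(het) > 100) {
      f_het <- ca[het] / (cr[het] + ca[het])
      expect_equal(mean(vaf[het] - f_het), 0, tolerance = 0.02)
    }
    if (sum(hom_alt) > 50) {
      expect_equal(mean(vaf[hom_alt]), 1, tolerance = 0.02)
      break
    }
  }
})

test_that("doublet and dropout frequencies match their rates", {
  cfg <- sim_config(n_cells = 3000, n_regions = 8, n_nodes = 3, n_snvs = 2,
                    n_cnas = 0, doublet_rate = 0.08, dropout_mean = 0.1,
                    dropout_sd = 0, fraction_germline = 1)
  out <- simulate_dataset(cfg, seed = 8)
  n <- length(out$data$cell_ids)
  frac <- mean(out$truth$is_doublet)
  expect_lt(abs(frac - 0.08), 3 * sqrt(0.08 * 0.92 / n))

  # per-variant dropout frequency among het singlet cells: each of the two
  # copies independently fails with mu, conditioned on not both failing
  cr <- out$truth$genotype_cr; ca <- out$truth$genotype_ca
  for (i in seq_len(ncol(cr))) {
    het <- which(cr[, i] == 1 & ca[, i] == 1 & !out$truth$is_doublet)
    if (length(het) < 200) next
    single <- (out$truth$amplified_ref[het, i] == 0) |
      (out$truth$amplified_alt[het, i] == 0)
    mu <- out$truth$dropout_rates[i]
    expected <- 2 * mu * (1 - mu) / (1 - mu^2)
    expect_lt(abs(mean(single) - expected),
              3 * sqrt(expected * (1 - expected) / length(het)))
  }
})

test_that("region depths match the negative-binomial moments", {
  cfg <- sim_config(n_cells = 3000, n_regions = 6, n_nodes = 1, n_snvs = 0,
                    n_cnas = 0, n_germline = 1, doublet_rate = 0, theta = 6,
                    coverage_mode = "uniform", depth_mean = 40)
  out <- simulate_dataset(cfg, seed = 12)
  d <- out$data
  rho <- out$truth$region_weights
  # conditional on the latent cell total, each region depth is
  # NB(mean = T_j rho_k, theta): pooled standardised moments
  for (k in seq_len(6)) {
    m <- out$truth$latent_total * rho[k]
    z <- (d$region_depth[, k] - m) / sqrt(m + m^2 / 6)
    expect_equal(mean(z), 0, tolerance = 0.08)
    expect_equal(var(z), 1, tolerance = 0.12)
  }
})

test_that("uniform-coverage per-amplicon depth is exchangeable across
           regions", {
  cfg <- sim_config(n_cells = 2000, n_regions = 5, n_nodes = 1, n_snvs = 0,
                    n_cnas = 0, n_germline = 1, doublet_rate = 0,
                    coverage_mode = "uniform")
  out <- simulate_dataset(cfg, seed = 14)
  d <- out$data
  per_amp <- colMeans(d$region_depth) / d$regions$n_amplicons
  expect_lt(max(abs(per_amp / mean(per_amp) - 1)), 0.05)
})

test_that("coverage correlations create block structure in depth fractions", {
  base <- list(n_cells = 2000, n_regions = 10, n_nodes = 1, n_snvs = 0,
               n_cnas = 0, n_germline = 1, doublet_rate = 0)
  cfg_on <- do.call(sim_config, c(base, list(
    coverage_mode = "uniform", coverage_correlation = "on",
    correlation_gamma = 0.6)))
  out_on <- simulate_dataset(cfg_on, seed = 15)
  frac <- out_on$data$region_depth / out_on$data$cell_total
  cc <- cor(frac)
  tilted <- out_on$truth$tilted_regions
  block <- cc[tilted, tilted][upper.tri(diag(length(tilted)))]

  cfg_off <- do.call(sim_config, c(base, list(coverage_mode = "uniform")))
  out_off <- simulate_dataset(cfg_off, seed = 16)
  cc0 <- cor(out_off$data$region_depth / out_off$data$cell_total)
  # the latent factor makes the tilted block co-vary positively, while
  # plain compositional noise gives near-zero (slightly negative) values
  expect_gt(mean(block), mean(cc0[upper.tri(cc0)]) + 0.03)
})
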