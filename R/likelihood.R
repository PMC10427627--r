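#' Negative-binomial log-likelihood of a region read depth
#'
#' The expected depth of region `k` in a cell with total depth `d_j`
#' attached to a genotype with region copy numbers `c` is
#' `d_j * c[k] * rho[k] / sum(c * rho)`; the observed depth is modelled as
#' negative binomial (Gamma-Poisson) around that mean with inverse
#' dispersion `theta` (variance `m + m^2/theta`).
#'
#' @param d_kj observed reads in the region (vectorised).
#' @param d_j total reads of the cell.
#' @param cn_profile per-region copy-number vector of the attached genotype.
#' @param k region index.
#' @param rho region weight simplex.
#' @param theta inverse dispersion.
#' @return Log-probability (vector along `d_kj`).
#' @export
region_depth_loglik <- function(d_kj, d_j, cn_profile, k, rho, theta) {
  stopifnot(d_j > 0, theta > 0, all(cn_profile >= 0))
  denom <- sum(cn_profile * rho)
  if (denom <= 0)
    stop("all-zero copy-number profile: no genome to attach to", call. = FALSE)
  m <- d_j * cn_profile[k] * rho[k] / denom
  if (m == 0) return(ifelse(d_kj == 0, 0, -Inf))
  dnbinom(d_kj, size = theta, mu = m, log = TRUE)
}

#' Beta-binomial log-likelihood of an ALT read count
#'
#' @param a ALT reads (vectorised with `d`).
#' @param d total reads at the locus.
#' @param f expected ALT read fraction, strictly inside (0,1).
#' @param omega concentration; the binomial is recovered as `omega -> Inf`.
#' @return Log-probability.
#' @export
beta_binomial_loglik <- function(a, d, f, omega) {
  stopifnot(all(a >= 0), all(a <= d), omega > 0)
  if (f <= 0 || f >= 1)
    stop("f must lie strictly inside (0,1); clamp with the error rate upstream",
         call. = FALSE)
  lchoose(d, a) + lbeta(a + omega * f, d - a + omega * (1 - f)) -
    lbeta(omega * f, omega * (1 - f))
}

# admissible dropout configurations for allele copies (c_r, c_a):
# data.frame(k, l, log_weight, f, omega); k/l = amplified REF/ALT copies
dropout_terms <- function(c_r, c_a, mu, eps, omega_hom, omega_het) {
  grid <- expand.grid(k = 0:c_r, l = 0:c_a)
  grid <- grid[grid$k + grid$l > 0L, , drop = FALSE]
  c_tot <- c_r + c_a
  n_drop <- c_tot - grid$k - grid$l
  lw <- lchoose(c_r, grid$k) + lchoose(c_a, grid$l) +
    ifelse(n_drop == 0L, 0, n_drop * log(mu)) +
    (grid$k + grid$l) * log1p(-mu)
  f <- (grid$l * (1 - eps) + grid$k * eps) / (grid$k + grid$l)
  omega <- ifelse(grid$k == 0L | grid$l == 0L, omega_hom, omega_het)
  data.frame(k = grid$k, l = grid$l, log_weight = lw, f = f, omega = omega)
}

#' Allelic log-likelihood with allele-specific dropout
#'
#' Mixture over the possible numbers `(k, l)` of amplified REF and ALT
#' copies, excluding total dropout `(0, 0)`: each copy amplifies
#' independently with probability `1 - mu`, the expected ALT fraction of
#' the amplified material is error-adjusted, and the read count follows a
#' beta-binomial whose concentration depends on whether the amplified
#' copies are single-allele (`omega_hom`) or mixed (`omega_het`).  By
#' default the mixture is renormalised by `1 - mu^(c_r+c_a)` (conditioning
#' on the locus amplifying at all); set `dropout_renormalize = FALSE` in
#' `params` for the unnormalised form.
#'
#' @param a_ij,d_ij ALT and total reads at the locus for one cell.
#' @param c_r,c_a REF and ALT allele copy numbers of the attached genotype
#'   (`c_r + c_a >= 1`).
#' @param mu_i dropout rate of the variant, in `[0, 1)`.
#' @param params a [model_params] object (supplies `eps`, `omega_hom`,
#'   `omega_het`, `dropout_renormalize`).
#' @return Log-probability.
#' @export
allelic_loglik <- function(a_ij, d_ij, c_r, c_a, mu_i,
                           params = model_params()) {
  stopifnot(c_r >= 0, c_a >= 0, mu_i >= 0, mu_i < 1)
  if (c_r + c_a == 0)
    stop("locus deleted in this genotype (c_r + c_a = 0); ",
         "handle deleted loci in the caller", call. = FALSE)
  if (d_ij == 0) return(0)
  tt <- dropout_terms(c_r, c_a, mu_i, params$eps,
                      params$omega_hom, params$omega_het)
  ll <- logsumexp(tt$log_weight +
                    mapply(function(f, om) beta_binomial_loglik(a_ij, d_ij, f, om),
                           tt$f, tt$omega))
  if (isTRUE(params$dropout_renormalize) && mu_i > 0)
    ll <- ll - log1p(-mu_i^(c_r + c_a))
  ll
}

# caches of depth/count transforms that are fixed for a (data, params) pair
make_ll_cache <- function(data, params) {
  list(
    lg_d_theta = lgamma(data$region_depth + params$theta),
    lg_d1 = lgamma(data$region_depth + 1),
    lchoose_da = lchoose(data$var_depth, data$alt_counts),
    lg_d_omhom = lgamma(data$var_depth + params$omega_hom),
    lg_d_omhet = lgamma(data$var_depth + params$omega_het))
}

# build per-attachment genotype matrices; singlets first, then (if doublets)
# unordered node pairs (a <= b).  Returns list(region_cn, cr, ca, pair_a,
# pair_b) with pair_a/b = 0 for singlet rows.
attachment_genotypes <- function(tree, data, doublets = FALSE) {
  g <- genotypes_all(tree, data)
  if (length(g$violations) > 0L)
    stop("invalid tree: ", g$violations[1L], call. = FALSE)
  n <- n_nodes(tree)
  region_cn <- g$region_cn
  cr <- g$cr
  ca <- g$ca
  pair_a <- rep(0L, n)
  pair_b <- rep(0L, n)
  if (doublets) {
    pairs <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
    region_cn <- rbind(region_cn,
                       (g$region_cn[pairs[, 1L], , drop = FALSE] +
                          g$region_cn[pairs[, 2L], , drop = FALSE]) / 2)
    cr <- rbind(cr, g$cr[pairs[, 1L], , drop = FALSE] +
                  g$cr[pairs[, 2L], , drop = FALSE])
    ca <- rbind(ca, g$ca[pairs[, 1L], , drop = FALSE] +
                  g$ca[pairs[, 2L], , drop = FALSE])
    pair_a <- c(pair_a, pairs[, 1L])
    pair_b <- c(pair_b, pairs[, 2L])
  }
  list(region_cn = region_cn, cr = cr, ca = ca,
       pair_a = pair_a, pair_b = pair_b, n_nodes = n)
}

#' Per-cell per-attachment log-likelihoods
#'
#' Computes `log P(D_j, A_j | attachment)` for every cell and every
#' attachment: the tree's nodes (singlets) and, when `params$doublet_rate >
#' 0`, every unordered node pair (doublets, whose genotype sums allele
#' copies and averages region copies).
#'
#' @param tree an [event_tree].
#' @param data a [panel_data] object.
#' @param params a [model_params] object.
#' @param rho optional region weight simplex; defaults to
#'   `params$region_weights` or uniform per amplicon.
#' @return A list with `singlet_ll` (`n_cells x n_nodes`), `doublet_ll`
#'   (`n_cells x n_pairs` or `NULL`) and `pairs` (2-column matrix of node
#'   ids for the doublet columns).
#' @export
attachment_logliks <- function(tree, data, params = model_params(),
                               rho = NULL) {
  rho <- rho %||% default_region_weights(data, params)
  mu <- dropout_vector(data, params)
  doublets <- params$doublet_rate > 0
  at <- attachment_genotypes(tree, data, doublets = doublets)
  cache <- make_ll_cache(data, params)
  ll <- cpp_attach_loglik(
    data$region_depth, as.numeric(data$cell_total),
    data$alt_counts, data$var_depth,
    at$region_cn, at$cr, at$ca, mu, rho,
    params$theta, params$eps, params$omega_hom, params$omega_het,
    isTRUE(params$dropout_renormalize),
    cache$lg_d_theta, cache$lg_d1, cache$lchoose_da,
    cache$lg_d_omhom, cache$lg_d_omhet)
  n <- at$n_nodes
  singlet <- ll[, seq_len(n), drop = FALSE]
  doublet <- NULL
  pairs <- NULL
  if (doublets && ncol(ll) > n) {
    doublet <- ll[, -seq_len(n), drop = FALSE]
    pairs <- cbind(at$pair_a[-seq_len(n)], at$pair_b[-seq_len(n)])
  }
  list(singlet_ll = singlet, doublet_ll = doublet, pairs = pairs)
}

# log attachment-prior weights matching attachment_logliks columns:
# (1-delta) pi_n for singlets; delta pi_a pi_b (x2 if a != b) for pairs
attachment_log_weights <- function(pi, delta, pairs = NULL) {
  lp <- log(pi)
  if (is.null(pairs) || delta == 0) {
    if (delta > 0) lp <- lp + log1p(-delta)
    return(lp)
  }
  wsing <- log1p(-delta) + lp
  wpair <- log(delta) + lp[pairs[, 1L]] + lp[pairs[, 2L]] +
    ifelse(pairs[, 1L] != pairs[, 2L], log(2), 0)
  c(wsing, wpair)
}

#' Attachment-marginalised log-likelihood of an event tree
#'
#' Marginalises the cell attachments analytically: each cell contributes
#' `log[(1-delta) sum_n pi_n P(cell | n) + delta sum_{n,n'} pi_n pi_n'
#' P(cell | n, n')]`, with the doublet term dropped when
#' `params$doublet_rate` is zero.
#'
#' @inheritParams attachment_logliks
#' @param pi node weight simplex.
#' @return The total log-likelihood (a scalar).
#' @export
tree_loglik <- function(tree, data, params = model_params(), pi = NULL,
                        rho = NULL) {
  n <- n_nodes(tree)
  if (is.null(pi)) pi <- rep(1 / n, n)
  stopifnot(length(pi) == n, abs(sum(pi) - 1) < 1e-6)
  ll <- attachment_logliks(tree, data, params, rho)
  lw <- attachment_log_weights(pi, params$doublet_rate, ll$pairs)
  mat <- cbind(ll$singlet_ll, ll$doublet_ll)
  sum(row_logsumexp(sweep(mat, 2L, lw, `+`)))
}
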