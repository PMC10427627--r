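#' Error-model parameters
#'
#' Collects the noise and nuisance parameters of the read-count model:
#'
#' * `theta`: inverse dispersion of the negative binomial model for region
#'   depths (variance `m + m^2/theta` at mean `m`); smaller values mean
#'   noisier amplification.
#' * `eps`: per-read sequencing error rate.
#' * `omega_hom`, `omega_het`: beta-binomial concentrations of the allelic
#'   count model when the amplified copies are single-allele respectively
#'   mixed (overdispersion is stronger in the heterozygous case).
#' * `dropout_rates`: per-variant allelic dropout probabilities `mu_i`;
#'   usually fitted by [fit_em()] rather than supplied.
#' * `dropout_prior_mean`, `dropout_prior_strength`: mean and total
#'   concentration `alpha + beta` of the beta prior on dropout rates
#'   (defaults centre the prior on 0.05 with `alpha = 2, beta = 38`).
#' * `doublet_rate`: probability `delta` that a barcode contains two cells.
#' * `region_weights`: simplex of per-region amplification propensities
#'   `rho_k`; `NULL` defers to a uniform-per-amplicon default.
#' * `dropout_renormalize`: if `TRUE` (default) the allelic likelihood is
#'   conditioned on at least one chromosomal copy amplifying, i.e. the
#'   dropout mixture is renormalised by `1 - mu^(c_r+c_a)`; if `FALSE` the
#'   unnormalised mixture (which slightly penalises high-copy genotypes) is
#'   used.
#'
#' @param theta,eps,omega_hom,omega_het,doublet_rate,dropout_prior_mean,dropout_prior_strength
#'   scalars as described above.
#' @param dropout_rates numeric vector or scalar recycled per variant.
#' @param region_weights optional simplex vector.
#' @param dropout_renormalize logical.
#' @return An object of class `model_params`.
#' @export
model_params <- function(theta = 6, eps = 0.01, omega_hom = 50,
                         omega_het = 15, dropout_rates = 0.05,
                         dropout_prior_mean = 0.05,
                         dropout_prior_strength = 40,
                         doublet_rate = 0.05, region_weights = NULL,
                         dropout_renormalize = TRUE) {
  stopifnot(theta > 0, eps > 0, eps < 0.5, omega_hom > 0, omega_het > 0,
            doublet_rate >= 0, doublet_rate < 1,
            all(dropout_rates > 0), all(dropout_rates < 1),
            dropout_prior_mean > 0, dropout_prior_mean < 1,
            dropout_prior_strength > 2)
  if (!is.null(region_weights)) {
    stopifnot(all(region_weights > 0))
    if (abs(sum(region_weights) - 1) > 1e-9)
      stop("region_weights must sum to 1", call. = FALSE)
  }
  alpha <- dropout_prior_mean * dropout_prior_strength
  beta <- dropout_prior_strength - alpha
  structure(list(theta = theta, eps = eps, omega_hom = omega_hom,
                 omega_het = omega_het, dropout_rates = dropout_rates,
                 dropout_prior_alpha = alpha, dropout_prior_beta = beta,
                 doublet_rate = doublet_rate, region_weights = region_weights,
                 dropout_renormalize = dropout_renormalize),
            class = "model_params")
}

# rho: supplied weights, else uniform per amplicon
default_region_weights <- function(data, params = NULL) {
  rho <- params$region_weights
  if (is.null(rho)) rho <- data$regions$n_amplicons / sum(data$regions$n_amplicons)
  rho
}

# per-variant dropout-rate vector
dropout_vector <- function(data, params) {
  mu <- params$dropout_rates
  if (length(mu) == 1L) mu <- rep(mu, nrow(data$variants))
  if (length(mu) != nrow(data$variants))
    stop("dropout_rates has wrong length", call. = FALSE)
  mu
}

#' Tree-prior penalty parameters
#'
#' The tree prior uses four empirical penalty weights: `p1` scales the
#' node-count times mutation-count term, `p2` the copy-number event term
#' (the main knob; increase it if too many CNAs are called), `p3` a flat
#' cost for placing any variant away from the root and `p4` an additional
#' cost proportional to the variant's population allele frequency (so that
#' likely-germline variants resist being called somatic).
#'
#' @param p1,p2,p3,p4 non-negative penalty weights.
#' @return An object of class `prior_penalties`.
#' @export
prior_penalties <- function(p1 = 0.1, p2 = 0.01, p3 = 3, p4 = 20) {
  stopifnot(p1 >= 0, p2 >= 0, p3 >= 0, p4 >= 0)
  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4),
            class = "prior_penalties")
}
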