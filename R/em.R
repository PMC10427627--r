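#' E-step: posteriors of cell attachments and dropout configurations
#'
#' Computes, at the current node weights and dropout rates, the posterior
#' probability of each cell's attachment (Bayes rule over nodes, and over
#' node pairs when doublets are enabled) and, for every
#' (variant, attachment) combination, the posterior distribution of the
#' number of REF/ALT copies that escaped dropout.
#'
#' This is the transparent reference implementation used on small problems
#' and in tests; [fit_em()] runs the same computation in compiled code.
#'
#' @param tree an [event_tree].
#' @param data a [panel_data] object.
#' @param params a [model_params] object (dropout rates taken from
#'   `params$dropout_rates`).
#' @param pi node weight simplex.
#' @param rho optional region weights.
#' @return An `em_state` list: `responsibilities` (cells x attachments, rows
#'   summing to 1), `dropout_posteriors` (nested list
#'   `[[variant]][[attachment]]`, each a cells x configurations matrix with
#'   attribute `configs`), `pi`, `mu`, `pairs`.
#' @export
e_step <- function(tree, data, params = model_params(), pi = NULL,
                   rho = NULL) {
  n <- n_nodes(tree)
  if (is.null(pi)) pi <- rep(1 / n, n)
  mu <- dropout_vector(data, params)
  ll <- attachment_logliks(tree, data, params, rho)
  lw <- attachment_log_weights(pi, params$doublet_rate, ll$pairs)
  mat <- sweep(cbind(ll$singlet_ll, ll$doublet_ll), 2L, lw, `+`)
  norm <- row_logsumexp(mat)
  resp <- exp(mat - norm)

  at <- attachment_genotypes(tree, data, doublets = params$doublet_rate > 0)
  n_attach <- nrow(at$cr)
  nv <- nrow(data$variants)
  dropout_posteriors <- vector("list", nv)
  for (i in seq_len(nv)) {
    per_attach <- vector("list", n_attach)
    for (a in seq_len(n_attach)) {
      cr <- at$cr[a, i]; ca <- at$ca[a, i]
      if (cr + ca == 0) { per_attach[[a]] <- NULL; next }
      tt <- dropout_terms(cr, ca, mu[i], params$eps,
                          params$omega_hom, params$omega_het)
      lp <- outer(rep(1, length(data$cell_ids)), tt$log_weight)
      has_reads <- data$var_depth[, i] > 0
      if (any(has_reads)) {
        bb <- sapply(seq_len(nrow(tt)), function(t)
          beta_binomial_loglik(data$alt_counts[has_reads, i],
                               data$var_depth[has_reads, i],
                               tt$f[t], tt$omega[t]))
        lp[has_reads, ] <- lp[has_reads, , drop = FALSE] +
          matrix(bb, nrow = sum(has_reads))
      }
      q <- exp(lp - apply(lp, 1L, logsumexp))
      attr(q, "configs") <- tt[, c("k", "l")]
      per_attach[[a]] <- q
    }
    dropout_posteriors[[i]] <- per_attach
  }
  structure(list(responsibilities = resp,
                 dropout_posteriors = dropout_posteriors,
                 pi = pi, mu = mu, pairs = ll$pairs,
                 attachments = at),
            class = "em_state")
}

#' M-step: update node weights and dropout rates
#'
#' Node weights are the mean attachment responsibilities (flat Dirichlet
#' prior); a doublet attachment credits half a cell to each member of the
#' pair.  Dropout rates maximise the expected complete-data log posterior
#' under a beta prior: with the default amplification-conditioned model
#' this is done numerically per variant, otherwise by the closed-form
#' posterior-mode ratio of expected dropped to total copies.  Rates are
#' clamped to `[1e-4, 0.5]`.
#'
#' @param state an `em_state` from [e_step()].
#' @param tree,data as in [e_step()].
#' @param dropout_prior `c(alpha, beta)` of the beta prior.
#' @param renormalize match the likelihood's `dropout_renormalize` switch.
#' @return A list with updated `pi` and `mu`.
#' @export
m_step <- function(state, tree, data, dropout_prior = c(2, 38),
                   renormalize = TRUE) {
  resp <- state$responsibilities
  at <- state$attachments
  n <- at$n_nodes
  n_cells <- nrow(resp)
  alpha <- dropout_prior[1L]; beta <- dropout_prior[2L]

  credit <- matrix(0, nrow(resp), n)
  for (a in seq_len(ncol(resp))) {
    if (at$pair_a[a] == 0L) credit[, a] <- credit[, a] + resp[, a]
    else if (at$pair_a[a] == at$pair_b[a])
      credit[, at$pair_a[a]] <- credit[, at$pair_a[a]] + resp[, a]
    else {
      credit[, at$pair_a[a]] <- credit[, at$pair_a[a]] + resp[, a] / 2
      credit[, at$pair_b[a]] <- credit[, at$pair_b[a]] + resp[, a] / 2
    }
  }
  pi <- colSums(credit) / n_cells

  nv <- nrow(data$variants)
  mu <- state$mu
  for (i in seq_len(nv)) {
    s_drop <- 0; c_tot <- 0
    w_c <- numeric(13)
    for (a in seq_len(ncol(resp))) {
      q <- state$dropout_posteriors[[i]][[a]]
      if (is.null(q)) next
      cfg <- attr(q, "configs")
      cc <- at$cr[a, i] + at$ca[a, i]
      edrop <- as.numeric(q %*% (cc - cfg$k - cfg$l))
      s_drop <- s_drop + sum(resp[, a] * edrop)
      c_tot <- c_tot + sum(resp[, a]) * cc
      w_c[cc] <- w_c[cc] + sum(resp[, a])
    }
    if (c_tot <= 0) {
      warning("variant ", i, " absent from all attached genotypes; ",
              "dropout rate kept", call. = FALSE)
      next
    }
    if (renormalize) {
      obj <- function(m) {
        (alpha - 1 + s_drop) * log(m) +
          (beta - 1 + c_tot - s_drop) * log1p(-m) -
          sum(w_c[w_c > 0] * log1p(-m^(which(w_c > 0))))
      }
      mu[i] <- optimize(obj, c(1e-4, 0.5), maximum = TRUE,
                        tol = 1e-10)$maximum
    } else {
      mu[i] <- (alpha - 1 + s_drop) / (alpha + beta - 2 + c_tot)
    }
    mu[i] <- min(max(mu[i], 1e-4), 0.5)
  }
  list(pi = pi, mu = mu)
}

#' Fit node weights and dropout rates for a fixed tree by EM
#'
#' Alternates [e_step()] and [m_step()] (in compiled code) until the log
#' posterior (attachment-marginalised log-likelihood plus the beta
#' log-prior of the dropout rates) improves by less than `tol` or
#' `max_iter` is reached.  The trace is checked to be non-decreasing; a
#' decrease beyond a small slack signals an implementation bug and raises
#' an error.
#'
#' @inheritParams e_step
#' @param max_iter,tol EM budget.
#' @param pi0,mu0 optional warm starts (defaults: uniform weights, dropout
#'   rates from `params`).
#' @return An object of class `em_fit`: list with `pi`, `mu`,
#'   `responsibilities`, `loglik`, `log_post_trace`, `pairs`, `n_iter`.
#' @export
fit_em <- function(tree, data, params = model_params(), max_iter = 50,
                   tol = 1e-4, rho = NULL, pi0 = NULL, mu0 = NULL,
                   cache = NULL) {
  n <- n_nodes(tree)
  rho <- rho %||% default_region_weights(data, params)
  if (is.null(pi0)) pi0 <- rep(1 / n, n)
  stopifnot(length(pi0) == n)
  # floor the starting weights: a node started at exactly zero could never
  # regain mass, since its posterior attachment odds would be -Inf
  pi0 <- pmax(pi0, 1e-6)
  pi0 <- pi0 / sum(pi0)
  if (is.null(mu0)) mu0 <- dropout_vector(data, params)
  doublets <- params$doublet_rate > 0
  at <- attachment_genotypes(tree, data, doublets = doublets)
  cache <- cache %||% make_ll_cache(data, params)
  res <- cpp_fit_em(
    data$region_depth, as.numeric(data$cell_total),
    data$alt_counts, data$var_depth,
    at$region_cn, at$cr, at$ca,
    as.integer(at$pair_a), as.integer(at$pair_b), n,
    params$doublet_rate, pi0, mu0, rho,
    params$theta, params$eps, params$omega_hom, params$omega_het,
    isTRUE(params$dropout_renormalize),
    params$dropout_prior_alpha, params$dropout_prior_beta,
    as.integer(max_iter), tol,
    cache$lg_d_theta, cache$lg_d1, cache$lchoose_da,
    cache$lg_d_omhom, cache$lg_d_omhet)
  tr <- res$log_post_trace
  if (any(is.na(tr)))
    stop("EM produced a non-finite log posterior", call. = FALSE)
  if (length(tr) > 1L && any(diff(tr) < -1e-7))
    stop("EM log-posterior trace decreased: implementation bug",
         call. = FALSE)
  pairs <- NULL
  if (doublets && length(at$pair_a) > n)
    pairs <- cbind(at$pair_a[-seq_len(n)], at$pair_b[-seq_len(n)])
  structure(list(pi = as.numeric(res$pi), mu = as.numeric(res$mu),
                 responsibilities = res$responsibilities,
                 loglik = res$loglik, log_post_trace = tr,
                 pairs = pairs, n_iter = length(tr)),
            class = "em_fit")
}
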