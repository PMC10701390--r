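#' MCMC configuration
#'
#' Settings for the multi-kernel Gibbs sampler. Variance components get
#' scaled-inverse-chi-square priors with `df0` degrees of freedom; the
#' scales are set so that each random term's prior mode captures an
#' equal share of `r2` of the observed phenotypic variance, with the
#' residual prior mode at the remaining `1 - r2` share.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in discarded iterations (`< n_iter`).
#' @param thin keep every `thin`-th post-burn-in sample (>= 1).
#' @param seed optional RNG seed for the chain.
#' @param df0 prior degrees of freedom for every variance component.
#' @param r2 prior share of phenotypic variance assigned to the random
#'   terms jointly.
#' @param fixed_variances optional named numeric: variance components
#'   (term labels and/or `"resid"`) held fixed at the given values
#'   instead of being sampled.
#' @param store_effect_chains keep per-sample effect vectors (memory-
#'   hungry; meant for small oracle instances).
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 6000, burn_in = 1000, thin = 5,
                        seed = NULL, df0 = 5, r2 = 0.5,
                        fixed_variances = NULL,
                        store_effect_chains = FALSE) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter",
                              call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed, df0 = df0, r2 = r2,
                 fixed_variances = fixed_variances,
                 store_effect_chains = store_effect_chains),
            class = "mcmc_config")
}

# eigendecomposition of a kernel term, with PSD jitter repair
kernel_eigen <- function(term, jitter = 1e-8) {
  if (!is.null(term$eig)) return(term$eig)
  K <- term$K
  e <- eigen(K, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-10
  if (min(e$values) < -tol * 10) {
    K <- K + diag(jitter * mean(diag(K)), nrow(K))
    e <- eigen(K, symmetric = TRUE)
    if (min(e$values) < -max(abs(e$values)) * 1e-8) {
      stop("covariance structure '", term$label,
           "' is not PSD even after jitter", call. = FALSE)
    }
  }
  keep <- e$values > max(e$values) * 1e-10
  list(vectors = e$vectors[, keep, drop = FALSE], values = e$values[keep])
}

#' Fit a multi-kernel Gaussian model by Gibbs sampling
#'
#' Bayesian GBLUP / reaction-norm sampler for
#' `y = mu + sum_t b_t + e`, `b_t ~ N(0, sigma2_t K_t)`,
#' `e ~ N(0, sigma2 I)`. Each random block is sampled in the eigenbasis
#' of its covariance structure (coordinates are conditionally
#' independent because eigenvectors are orthonormal), and missing cells
#' are handled by data augmentation: they contribute no information but
#' receive predictions. Deterministic under a fixed seed.
#'
#' @param y numeric response over `kernels$records`; `NA` marks cells to
#'   predict.
#' @param kernels a [build_kernels()] kernel set.
#' @param mcmc an [mcmc_config()].
#' @return object of class `gp_fit`: posterior means `mu`, `effects`
#'   (named list of length-N vectors), `var_components` (named, incl.
#'   `resid`), `yhat = mu + sum of effects`, `records`, variance and
#'   `mu` chains, `n_retained`, optional effect chains, and the config.
#' @export
fit_gibbs <- function(y, kernels, mcmc = mcmc_config()) {
  stopifnot(inherits(kernels, "kernel_set"), inherits(mcmc, "mcmc_config"))
  N <- nrow(kernels$records)
  if (length(y) != N) stop("y must match the record index", call. = FALSE)
  obs <- !is.na(y)
  if (!any(obs)) stop("at least one observed record is required", call. = FALSE)
  .seed_if(mcmc$seed)

  terms <- kernels$terms
  T_ <- length(terms)
  eigs <- lapply(terms, kernel_eigen)
  labels <- names(terms)

  vy <- var(y[obs])
  if (!is.finite(vy) || vy <= 0) vy <- 1e-8
  df0 <- mcmc$df0
  share <- mcmc$r2 * vy / T_
  S_t <- rep(share * (df0 + 2) / df0, T_)
  S_e <- (1 - mcmc$r2) * vy * (df0 + 2) / df0
  fixed <- mcmc$fixed_variances

  sig2 <- setNames(rep(share, T_), labels)
  se2 <- (1 - mcmc$r2) * vy
  if (se2 <= 0) se2 <- 1e-8
  for (lab in labels) if (!is.null(fixed[[lab]])) sig2[lab] <- fixed[[lab]]
  if (!is.null(fixed[["resid"]])) se2 <- fixed[["resid"]]

  mu <- mean(y[obs])
  b <- lapply(seq_len(T_), function(t) numeric(N))
  yw <- y
  yw[!obs] <- mu
  e <- yw - mu

  n_ret <- (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
  sum_mu <- 0; sum_b <- lapply(seq_len(T_), function(t) numeric(N))
  var_chain <- matrix(NA_real_, n_ret, T_ + 1,
                      dimnames = list(NULL, c(labels, "resid")))
  mu_chain <- numeric(n_ret)
  eff_chain <- if (mcmc$store_effect_chains) {
    lapply(seq_len(T_), function(t) matrix(NA_real_, n_ret, N))
  }
  kept <- 0L

  for (it in seq_len(mcmc$n_iter)) {
    # data augmentation: redraw the residual of unobserved cells
    n_mis <- N - sum(obs)
    if (n_mis > 0) e[!obs] <- rnorm(n_mis, 0, sqrt(se2))

    for (t in seq_len(T_)) {
      U <- eigs[[t]]$vectors
      d <- eigs[[t]]$values
      e <- e + b[[t]]
      v <- drop(crossprod(U, e))
      post_var <- 1 / (1 / se2 + 1 / (sig2[t] * d))
      gamma <- post_var * v / se2 + sqrt(post_var) * rnorm(length(d))
      b[[t]] <- drop(U %*% gamma)
      e <- e - b[[t]]
      if (is.null(fixed[[labels[t]]])) {
        ss <- sum(gamma^2 / d)
        sig2[t] <- (df0 * S_t[t] + ss) / rchisq(1, df0 + length(d))
      }
    }
    e <- e + mu
    mu <- rnorm(1, mean(e), sqrt(se2 / N))
    e <- e - mu
    if (is.null(fixed[["resid"]])) {
      se2 <- (df0 * S_e + sum(e^2)) / rchisq(1, df0 + N)
    }

    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0) {
      kept <- kept + 1L
      sum_mu <- sum_mu + mu
      for (t in seq_len(T_)) {
        sum_b[[t]] <- sum_b[[t]] + b[[t]]
        if (!is.null(eff_chain)) eff_chain[[t]][kept, ] <- b[[t]]
      }
      var_chain[kept, ] <- c(sig2, se2)
      mu_chain[kept] <- mu
    }
  }

  effects <- lapply(sum_b, function(s) s / kept)
  names(effects) <- labels
  mu_hat <- sum_mu / kept
  yhat <- mu_hat + Reduce(`+`, effects)
  structure(list(
    mu = mu_hat,
    effects = effects,
    var_components = colMeans(var_chain[seq_len(kept), , drop = FALSE]),
    yhat = yhat,
    records = kernels$records,
    model = kernels$model,
    n_retained = kept,
    chains = list(mu = mu_chain[seq_len(kept)],
                  var = var_chain[seq_len(kept), , drop = FALSE],
                  effects = eff_chain),
    config = mcmc
  ), class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("gp_fit %s: %d records, %d retained samples\n",
              x$model %||% "?", nrow(x$records), x$n_retained))
  cat("variance components:\n")
  print(round(x$var_components, 4))
  invisible(x)
}

#' Predict RIL-in-environment cells from a fit
#'
#' Returns the posterior-mean linear predictor
#' `mu + E_j + L_i (+ F_k) + g_i (+ gE_ij + FE_kj)` for each requested
#' cell. Never-observed RILs receive RIL-identity effects shrunk to
#' zero, with genomic information entering through G.
#'
#' @param fit a [fit_gibbs()] result.
#' @param cells data.frame with `ril_id` and `env_id` (subset of the
#'   fit's record index).
#' @return data.frame `ril_id`, `env_id`, `y_pred`.
#' @export
predict_missing <- function(fit, cells) {
  stopifnot(inherits(fit, "gp_fit"))
  key <- paste(fit$records$ril_id, fit$records$env_id, sep = "\r")
  want <- paste(cells$ril_id, cells$env_id, sep = "\r")
  idx <- match(want, key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("cell not in record index: ", cells$ril_id[bad], " x ",
         cells$env_id[bad], call. = FALSE)
  }
  data.frame(ril_id = cells$ril_id, env_id = cells$env_id,
             y_pred = fit$yhat[idx], stringsAsFactors = FALSE)
}
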