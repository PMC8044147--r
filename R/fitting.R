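#' Truncated-normal priors over observer parameters
#'
#' Default priors: `h` ~ TN(0.2, 0.1) on \[0, 1\]; `sigma_inf` and
#' `sigma_sel` ~ TN(0.5, 0.2) on \[0, 10\]; `p_lapse` ~ TN(0.01, 0.05) on
#' \[0, 1\].
#'
#' @param h,sigma_inf,sigma_sel,p_lapse Numeric vectors
#'   `c(mean, sd, lower, upper)`.
#' @return An object of class `rl_prior`.
#' @export
prior_spec <- function(h = c(0.2, 0.1, 0, 1),
                       sigma_inf = c(0.5, 0.2, 0, 10),
                       sigma_sel = c(0.5, 0.2, 0, 10),
                       p_lapse = c(0.01, 0.05, 0, 1)) {
  as_row <- function(x) {
    stopifnot(length(x) == 4, x[2] > 0, x[4] > x[3])
    list(mean = x[1], sd = x[2], lower = x[3], upper = x[4])
  }
  structure(list(h = as_row(h), sigma_inf = as_row(sigma_inf),
                 sigma_sel = as_row(sigma_sel), p_lapse = as_row(p_lapse)),
            class = "rl_prior")
}

prior_logdensity <- function(prior, params) {
  sum(vapply(names(prior), function(nm) {
    p <- prior[[nm]]
    dtnorm(params[[nm]], p$mean, p$sd, p$lower, p$upper, log = TRUE)
  }, numeric(1)))
}

prior_draw <- function(prior, free) {
  vals <- list(h = 0.125, sigma_inf = 0, sigma_sel = 0, p_lapse = 0)
  for (nm in names(prior)) {
    if (nm %in% free) {
      p <- prior[[nm]]
      vals[[nm]] <- rtnorm(1, p$mean, p$sd, p$lower, p$upper)
    }
  }
  # h is always a model parameter; when not free it stays at the true value
  do.call(model_params, vals)
}

# response likelihood given the posterior belief L (vectorized over L)
response_lik <- function(L, r, r_prev, sigma_sel, p_lapse) {
  sgn <- if (r == 1L) 1 else -1
  p_sel <- if (sigma_sel > 0) {
    pnorm(sgn * L / sigma_sel)
  } else {
    ifelse(sgn * L > 0, 1, ifelse(L == 0, 0.5, 0))
  }
  (1 - p_lapse) * p_sel + p_lapse * as.numeric(r == r_prev)
}

# systematic resampling: one uniform, stratified inverse-CDF lookup
systematic_resample <- function(w) {
  n <- length(w)
  u <- (runif(1) + seq_len(n) - 1) / n
  cs <- cumsum(w / sum(w))
  pmin(findInterval(u, cs, left.open = TRUE) + 1L, n)
}

#' Particle-filter likelihood of observed responses
#'
#' Bootstrap filter over the latent log-odds belief: particles are
#' propagated through the noisy belief update
#' \eqn{L_t \sim N(F(L_{t-1}) + \mathcal{L}_t, n\,\sigma_{inf}^2)},
#' weighted by the response likelihood (sign of a Gaussian decision
#' variable with SD `sigma_sel`, mixed with the lapse probability), and
#' systematically resampled every trial. The running product of mean
#' weights is an unbiased estimate of the marginal response likelihood
#' \eqn{p(r_{1:T} | \Theta_{1:T}, \phi)}; the filter also returns the
#' response-conditioned belief trajectory used by downstream analyses.
#'
#' @param params [model_params()].
#' @param block An `rl_block`.
#' @param responses Observed responses in `{1, 2}` (defaults to those
#'   stored in the block).
#' @param n_particles Number of particles (>= 2).
#' @param seed Optional seed.
#' @return An object of class `rl_pf`: `loglik` (unbiased log marginal
#'   likelihood estimate), `prior_mean` and `post_mean` (response-
#'   conditioned filtered means of \eqn{F(L_{t-1})} and \eqn{L_t}), `ess`
#'   (effective sample size per trial).
#' @export
particle_filter <- function(params, block, responses = block$responses,
                            n_particles = 1000L, seed = NULL) {
  stopifnot(inherits(params, "rl_params"), n_particles >= 2)
  if (is.null(responses)) stop("responses are required")
  with_seed(seed, {
    n <- block$n_trials
    L <- rep(0, n_particles)
    loglik <- 0
    prior_mean <- post_mean <- ess <- numeric(n)
    r_prev <- block$initial_response
    for (t in seq_len(n)) {
      ev <- sequence_evidence(block$tilts[[t]], block$state[t], block$kappa)
      m <- length(ev$per_stimulus)
      Fprev <- leak_prior(L, params$h)
      L <- Fprev + ev$total
      if (params$sigma_inf > 0)
        L <- L + rnorm(n_particles, 0, sqrt(m) * params$sigma_inf)
      w <- response_lik(L, responses[t], r_prev, params$sigma_sel, params$p_lapse)
      sw <- sum(w)
      if (sw <= 0)
        stop(sprintf("particle filter degenerate at trial %d: all weights zero", t))
      wn <- w / sw
      loglik <- loglik + log(sw / n_particles)
      prior_mean[t] <- sum(wn * Fprev)
      post_mean[t] <- sum(wn * L)
      ess[t] <- min(1 / sum(wn^2), n_particles)
      idx <- systematic_resample(wn)
      L <- L[idx]
      r_prev <- responses[t]
    }
    structure(list(loglik = loglik, prior_mean = prior_mean,
                   post_mean = post_mean, ess = ess,
                   n_particles = n_particles),
              class = "rl_pf")
  })
}

#' Log-likelihood of a dataset of blocks
#'
#' Sums the particle-filter log-likelihood estimates over blocks. With
#' `sigma_inf = 0` the latent trajectory is deterministic and the estimate
#' is exact (it equals the closed-form product of response probabilities).
#'
#' @param params [model_params()].
#' @param blocks List of `rl_block` objects with responses.
#' @param n_particles Particles per block.
#' @param seed Optional seed.
#' @return Scalar log-likelihood estimate.
#' @export
loglik_blocks <- function(params, blocks, n_particles = 1000L, seed = NULL) {
  with_seed(seed, {
    sum(vapply(blocks, function(b)
      particle_filter(params, b, n_particles = n_particles)$loglik, numeric(1)))
  })
}

free_default <- c("h", "sigma_inf")

params_from_free <- function(theta, free) {
  vals <- list(h = 0.125, sigma_inf = 0, sigma_sel = 0, p_lapse = 0)
  vals[free] <- as.list(theta)
  do.call(model_params, vals)
}

# natural <-> unconstrained transforms per parameter (bounded: scaled logit)
to_unconstrained <- function(theta, prior, free) {
  vapply(seq_along(free), function(i) {
    p <- prior[[free[i]]]
    logit((theta[i] - p$lower) / (p$upper - p$lower))
  }, numeric(1))
}

from_unconstrained <- function(psi, prior, free) {
  vapply(seq_along(free), function(i) {
    p <- prior[[free[i]]]
    p$lower + (p$upper - p$lower) * ilogit(psi[i])
  }, numeric(1))
}

log_jacobian <- function(psi, prior, free) {
  sum(vapply(seq_along(free), function(i) {
    p <- prior[[free[i]]]
    log(p$upper - p$lower) + log(ilogit(psi[i])) + log(1 - ilogit(psi[i]))
  }, numeric(1)))
}

#' Particle MCMC over observer parameters
#'
#' Pseudo-marginal Metropolis sampler targeting the parameter posterior
#' \eqn{p(\phi | r_{1:T}, \Theta_{1:T})}: the intractable likelihood is
#' replaced by the unbiased particle-filter estimate, which leaves the
#' chain's invariant distribution unchanged. The random walk operates on
#' scaled-logit-transformed parameters; its proposal covariance is adapted
#' (adaptive-Metropolis style) during the burn-in only, then frozen.
#' Reduced models are expressed through `free`: parameters not listed are
#' fixed at zero (`h` at 0.125), so the same sampler serves every model
#' variant compared by [bms()].
#'
#' @param blocks List of `rl_block` objects with responses; an empty list
#'   gives a prior-only chain (constant likelihood).
#' @param prior [prior_spec()].
#' @param free Character vector of fitted parameters, a subset of
#'   `c("h", "sigma_inf", "sigma_sel", "p_lapse")`.
#' @param n_iter Total iterations (including burn-in).
#' @param n_particles Particles per likelihood evaluation.
#' @param burn_frac Fraction of iterations used as burn-in (default 0.2).
#' @param init Optional named numeric of initial values for `free`.
#' @param seed Optional seed.
#' @return An object of class `rl_posterior`: `draws` (matrix, post
#'   burn-in), `loglik` per kept draw, `acceptance`, `burn_in`, `free`,
#'   `prior`, `settings`.
#' @export
pmcmc_sample <- function(blocks, prior = prior_spec(), free = free_default,
                         n_iter = 2000L, n_particles = 1000L,
                         burn_frac = 0.2, init = NULL, seed = NULL) {
  stopifnot(all(free %in% names(prior)))
  # an empty dataset is allowed: the likelihood is constant and the
  # chain targets the prior
  with_seed(seed, {
    d <- length(free)
    n_burn <- max(1L, floor(n_iter * burn_frac))
    logpost <- function(theta) {
      pars <- params_from_free(theta, free)
      lp <- prior_logdensity(prior, pars[names(prior)])
      if (!is.finite(lp)) return(list(lp = -Inf, ll = -Inf))
      ll <- tryCatch(loglik_blocks(pars, blocks, n_particles),
                     error = function(e) -Inf)
      list(lp = lp, ll = ll)
    }
    # initialize at a prior draw with finite posterior density
    theta <- NULL
    for (try in 1:50) {
      cand <- if (!is.null(init) && try == 1L) {
        unlist(init)[free]
      } else {
        p0 <- prior_draw(prior, free)
        vapply(free, function(nm) p0[[nm]], numeric(1))
      }
      ev <- logpost(cand)
      if (is.finite(ev$lp + ev$ll)) { theta <- cand; break }
    }
    if (is.null(theta))
      stop("could not find a finite posterior density at initialization; re-seed")
    psi <- to_unconstrained(theta, prior, free)
    cur <- list(psi = psi, lp = ev$lp, ll = ev$ll,
                lj = log_jacobian(psi, prior, free))
    prop_cov <- diag(0.05, d)
    chol_prop <- chol(prop_cov)
    hist_psi <- matrix(NA_real_, n_iter, d)
    draws <- matrix(NA_real_, n_iter, d, dimnames = list(NULL, free))
    logliks <- numeric(n_iter)
    n_accept <- 0L
    for (i in seq_len(n_iter)) {
      psi_new <- cur$psi + drop(rnorm(d) %*% chol_prop)
      theta_new <- from_unconstrained(psi_new, prior, free)
      ev <- logpost(theta_new)
      lj_new <- log_jacobian(psi_new, prior, free)
      log_alpha <- (ev$lp + ev$ll + lj_new) - (cur$lp + cur$ll + cur$lj)
      if (is.finite(log_alpha) && log(runif(1)) < log_alpha) {
        cur <- list(psi = psi_new, lp = ev$lp, ll = ev$ll, lj = lj_new)
        n_accept <- n_accept + 1L
      }
      hist_psi[i, ] <- cur$psi
      draws[i, ] <- from_unconstrained(cur$psi, prior, free)
      logliks[i] <- cur$ll
      # adapt proposal covariance during burn-in only
      if (i <= n_burn && i >= 20L && i %% 10L == 0L) {
        S <- stats::cov(hist_psi[seq_len(i), , drop = FALSE])
        prop_cov <- 2.38^2 / d * (S + diag(1e-6, d))
        chol_prop <- chol(prop_cov)
      }
    }
    keep <- (n_burn + 1L):n_iter
    structure(list(draws = draws[keep, , drop = FALSE],
                   loglik = logliks[keep],
                   acceptance = n_accept / n_iter,
                   burn_in = n_burn,
                   free = free,
                   prior = prior,
                   settings = list(n_iter = n_iter, n_particles = n_particles)),
              class = "rl_posterior")
  })
}

#' @export
print.rl_posterior <- function(x, ...) {
  m <- colMeans(x$draws)
  s <- apply(x$draws, 2, sd)
  cat(sprintf("<rl_posterior> %d draws (burn-in %d), acceptance %.2f\n",
              nrow(x$draws), x$burn_in, x$acceptance))
  for (nm in colnames(x$draws))
    cat(sprintf("  %-10s %.4f +/- %.4f\n", nm, m[nm], s[nm]))
  invisible(x)
}

#' @export
summary.rl_posterior <- function(object, ...) {
  data.frame(parameter = colnames(object$draws),
             mean = colMeans(object$draws),
             sd = apply(object$draws, 2, sd),
             row.names = NULL)
}

#' Marginal likelihood of a model by prior importance sampling
#'
#' Estimates \eqn{\log p(r_{1:T} | \Theta_{1:T})} as the log of the average
#' particle-filter likelihood estimate over draws from the prior,
#' \eqn{p(r|\Theta) = E_{\phi \sim p(\phi)}[\hat p(r|\Theta,\phi)]}, which
#' is unbiased because the particle-filter estimate itself is unbiased.
#' Used as model evidence in [bms()].
#'
#' @param blocks List of `rl_block` objects with responses.
#' @param prior [prior_spec()].
#' @param free Fitted parameters of the model variant (others fixed to 0).
#' @param n_draws Prior draws.
#' @param n_particles Particles per likelihood evaluation.
#' @param seed Optional seed.
#' @return Scalar log marginal likelihood estimate.
#' @export
marginal_likelihood <- function(blocks, prior = prior_spec(),
                                free = free_default, n_draws = 100L,
                                n_particles = 500L, seed = NULL) {
  with_seed(seed, {
    lls <- vapply(seq_len(n_draws), function(i) {
      pars <- prior_draw(prior, free)
      tryCatch(loglik_blocks(pars, blocks, n_particles),
               error = function(e) -Inf)
    }, numeric(1))
    log_sum_exp(lls) - log(n_draws)
  })
}

#' Bayesian model selection over fitted model variants
#'
#' Fixed-effects comparison sums log marginal likelihoods over
#' participants. The random-effects comparison estimates the population
#' distribution over models with the variational Dirichlet update (the
#' parameterization the group-level BMS literature uses): starting from a
#' uniform Dirichlet, each participant's posterior model assignment and the
#' Dirichlet counts are iterated to convergence; exceedance probabilities
#' are computed by Monte-Carlo sampling of the fitted Dirichlet.
#'
#' @param log_ml Numeric matrix, participants x models, of log marginal
#'   likelihoods.
#' @param n_samples Dirichlet samples for the exceedance probabilities.
#' @param seed Optional seed.
#' @return An object of class `rl_bms`: `fixed_effects` (summed log-ML per
#'   model), `alpha` (Dirichlet parameters), `expected_freq`, `exceedance`.
#' @export
bms <- function(log_ml, n_samples = 1e5, seed = NULL) {
  log_ml <- as.matrix(log_ml)
  if (!all(is.finite(log_ml))) stop("log_ml must be finite")
  n_sub <- nrow(log_ml); n_mod <- ncol(log_ml)
  if (is.null(colnames(log_ml)))
    colnames(log_ml) <- paste0("model", seq_len(n_mod))
  fixed <- colSums(log_ml)
  if (n_mod == 1L) {
    warning("single model: degenerate model selection")
    return(structure(list(fixed_effects = fixed, alpha = n_sub + 1,
                          expected_freq = 1, exceedance = 1), class = "rl_bms"))
  }
  with_seed(seed, {
    alpha0 <- rep(1, n_mod)
    alpha <- alpha0
    for (it in 1:200) {
      lg <- sweep(log_ml, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
      g <- exp(lg - apply(lg, 1, max))
      g <- g / rowSums(g)
      alpha_new <- alpha0 + colSums(g)
      if (max(abs(alpha_new - alpha)) < 1e-8) { alpha <- alpha_new; break }
      alpha <- alpha_new
    }
    draws <- matrix(rgamma(n_samples * n_mod, shape = rep(alpha, each = n_samples)),
                    n_samples, n_mod)
    winner <- max.col(draws)
    exceed <- tabulate(winner, n_mod) / n_samples
    names(exceed) <- colnames(log_ml)
    structure(list(fixed_effects = fixed,
                   alpha = stats::setNames(alpha, colnames(log_ml)),
                   expected_freq = stats::setNames(alpha / sum(alpha),
                                                   colnames(log_ml)),
                   exceedance = exceed),
              class = "rl_bms")
  })
}

#' @export
print.rl_bms <- function(x, ...) {
  cat("<rl_bms>\n  fixed-effects log-ML:",
      paste(sprintf("%s=%.1f", names(x$fixed_effects), x$fixed_effects),
            collapse = ", "),
      "\n  exceedance:",
      paste(sprintf("%s=%.3f", names(x$exceedance), x$exceedance),
            collapse = ", "), "\n")
  invisible(x)
}
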