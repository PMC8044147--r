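#' Parameters of the noisy Bayesian observer
#'
#' The observer is controlled by four parameters: the perceived hazard rate
#' `h` (subjective per-trial reversal probability), the inference noise SD
#' `sigma_inf` (internal noise added per stimulus update), the selection
#' noise SD `sigma_sel` (noise on the decision variable at response time,
#' equivalent to a softmax policy), and the lapse probability `p_lapse`
#' (fraction of trials on which the previous response is blindly repeated).
#'
#' @param h Hazard rate in (0, 1).
#' @param sigma_inf Inference-noise SD, >= 0.
#' @param sigma_sel Selection-noise SD, >= 0.
#' @param p_lapse Lapse probability in \[0, 1\].
#' @return An object of class `rl_params`.
#' @export
#' @examples
#' optimal_params()           # the Bayes-optimal observer
#' model_params(h = 0.19, sigma_inf = 0.5)
model_params <- function(h, sigma_inf = 0, sigma_sel = 0, p_lapse = 0) {
  stopifnot(h > 0, h < 1, sigma_inf >= 0, sigma_sel >= 0,
            p_lapse >= 0, p_lapse <= 1)
  structure(list(h = h, sigma_inf = sigma_inf, sigma_sel = sigma_sel,
                 p_lapse = p_lapse), class = "rl_params")
}

#' @rdname model_params
#' @export
optimal_params <- function() model_params(h = 0.125)

#' @export
print.rl_params <- function(x, ...) {
  cat(sprintf("<rl_params> h=%.4g sigma_inf=%.4g sigma_sel=%.4g p_lapse=%.4g\n",
              x$h, x$sigma_inf, x$sigma_sel, x$p_lapse))
  invisible(x)
}

#' Leaky carry-over of the posterior belief
#'
#' Given the posterior log-odds belief `L` at the end of a trial and a
#' hazard rate `h`, returns the prior log-odds belief carried into the next
#' trial:
#' \deqn{F(L) = L + \log((1-h)/h + e^{-L}) - \log((1-h)/h + e^{+L}).}
#' `F` is odd in `L`, shrinks towards 0 (`|F(L)| <= |L|`), preserves the
#' sign of `L` whenever `h < 1/2`, collapses to 0 for all `L` at `h = 1/2`
#' (total forgetting), and tends to the identity as `h -> 0`.
#'
#' @param L Log-odds belief (vectorized).
#' @param h Hazard rate in (0, 1).
#' @return Prior log-odds belief, same shape as `L`.
#' @export
#' @examples
#' leak_prior(2, 1/8)
leak_prior <- function(L, h) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0 || h >= 1)
    stop("h must be a single value in (0, 1)")
  L <- clip_logodds(L)
  r <- (1 - h) / h
  L + log(r + exp(-L)) - log(r + exp(L))
}

#' Tilt-based log-odds evidence of a stimulus sequence
#'
#' The evidence provided by a sequence in favour of hidden state 1 versus 2
#' is \eqn{\pm\sum_i 2\kappa\cos(2\delta_i)}, positive when the hidden state
#' is 1. Because it depends only on the pre-generated tilts and the hidden
#' state, matched Cb/Ob blocks built from the same tilts yield identical
#' evidence streams for any response history.
#'
#' @param tilts Numeric vector of tilts for one sequence.
#' @param state Hidden state of the trial, 1 or 2.
#' @param kappa Von Mises concentration.
#' @return List with `total` (scalar log-odds) and `per_stimulus`
#'   (\eqn{\ell_i}, signed the same way).
#' @export
#' @examples
#' sequence_evidence(c(0, 0), state = 2, kappa = 0.5)$total  # -2
sequence_evidence <- function(tilts, state, kappa) {
  stopifnot(length(tilts) >= 1, state %in% c(1L, 2L))
  sgn <- if (state == 1L) 1 else -1
  ell <- sgn * 2 * kappa * cos(2 * tilts)
  list(total = sum(ell), per_stimulus = ell)
}

#' Simulate responses of the noisy Bayesian observer on one block
#'
#' Runs the belief recursion
#' \eqn{L_t \sim N(F(L_{t-1}) + \mathcal{L}_t,\ n\,\sigma_{inf}^2)}
#' (the per-stimulus updates each receive independent
#' \eqn{N(0, \sigma_{inf}^2)} noise, of which the trial-level draw is the
#' marginal), then selects the response from the sign of a decision
#' variable \eqn{N(L_t, \sigma_{sel}^2)}; with probability `p_lapse` the
#' previous response is repeated instead (the belief is still updated).
#' An exact zero decision variable is resolved by a fair coin flip.
#'
#' Under the `"stimulus_level"` scheme the reported within-sequence beliefs
#' \eqn{L_{t,i}} are the beliefs after stimuli `1..i-1` of the trial; under
#' `"response_level"` they are frozen at the trial's prior.
#'
#' @param params [model_params()].
#' @param block An `rl_block`.
#' @param scheme `"stimulus_level"` or `"response_level"` (affects only the
#'   reported within-sequence beliefs).
#' @param seed Optional seed.
#' @return An object of class `rl_simulation`: list with `responses`,
#'   `trajectory` (data frame with `trial`, `prior`, `posterior`,
#'   `evidence`), `within` (list of per-stimulus belief vectors), the
#'   updated `block` (responses and orientations attached), `params`,
#'   `scheme`.
#' @export
#' @examples
#' pair <- realize_block_pair("stable", seed = 2)
#' sim <- simulate_responses(optimal_params(), pair$cb, seed = 3)
#' accuracy(sim$responses, pair$cb$state)
simulate_responses <- function(params, block,
                               scheme = c("stimulus_level", "response_level"),
                               seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(params, "rl_params"), inherits(block, "rl_block"))
  with_seed(seed, {
    n <- block$n_trials
    responses <- integer(n)
    prior <- posterior <- evid <- numeric(n)
    within <- vector("list", n)
    L <- 0
    r_prev <- block$initial_response
    for (t in seq_len(n)) {
      ev <- sequence_evidence(block$tilts[[t]], block$state[t], block$kappa)
      m <- length(ev$per_stimulus)
      eps <- if (params$sigma_inf > 0) rnorm(m, 0, params$sigma_inf) else numeric(m)
      prior[t] <- leak_prior(L, params$h)
      steps <- cumsum(ev$per_stimulus + eps)
      within[[t]] <- if (scheme == "stimulus_level")
        prior[t] + c(0, steps[-m]) else rep(prior[t], m)
      L <- prior[t] + steps[m]
      posterior[t] <- L
      evid[t] <- ev$total
      dv <- if (params$sigma_sel > 0) L + rnorm(1, 0, params$sigma_sel) else L
      r <- if (dv > 0) 1L else if (dv < 0) 2L else sample(1:2, 1)
      if (params$p_lapse > 0 && runif(1) < params$p_lapse) r <- r_prev
      responses[t] <- r
      r_prev <- r
    }
    block$responses <- responses
    block$orientations <- realize_orientations(block, responses)
    structure(list(responses = responses,
                   trajectory = data.frame(trial = seq_len(n), prior = prior,
                                           posterior = posterior, evidence = evid),
                   within = within,
                   block = block,
                   params = params,
                   scheme = scheme),
              class = "rl_simulation")
  })
}

#' Fraction of responses matching the hidden state
#'
#' @param responses Integer responses in `{1, 2}`.
#' @param states Integer hidden states in `{1, 2}`.
#' @return Fraction in \[0, 1\].
#' @export
accuracy <- function(responses, states) {
  if (length(responses) != length(states))
    stop("responses and states must have equal length")
  mean(responses == states)
}

#' Deterministic belief trajectory at a given hazard rate
#'
#' Noise-free forward recursion \eqn{L_t = F(L_{t-1}) + \mathcal{L}_t} at
#' hazard rate `h`. Because the tilt-based evidence does not depend on the
#' response history, this trajectory is a function of the stimuli alone; it
#' is the fast belief source used when recomputing the consistency variable
#' under alternative hazard rates. For response-conditioned beliefs under
#' inference noise use [particle_filter()].
#'
#' @param block An `rl_block`.
#' @param h Hazard rate.
#' @param scheme Within-sequence belief convention, as in
#'   [simulate_responses()].
#' @return List with `prior`, `posterior` (numeric vectors) and `within`
#'   (list of per-stimulus beliefs \eqn{L_{t,i}}).
#' @export
belief_trajectory <- function(block, h,
                              scheme = c("stimulus_level", "response_level")) {
  scheme <- match.arg(scheme)
  n <- block$n_trials
  prior <- posterior <- numeric(n)
  within <- vector("list", n)
  L <- 0
  for (t in seq_len(n)) {
    ev <- sequence_evidence(block$tilts[[t]], block$state[t], block$kappa)
    m <- length(ev$per_stimulus)
    prior[t] <- leak_prior(L, h)
    steps <- cumsum(ev$per_stimulus)
    within[[t]] <- if (scheme == "stimulus_level")
      prior[t] + c(0, steps[-m]) else rep(prior[t], m)
    L <- prior[t] + steps[m]
    posterior[t] <- L
  }
  list(prior = prior, posterior = posterior, within = within)
}
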