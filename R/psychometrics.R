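#' Evidence in favour of the previous response
#'
#' For each trial after the first, the sequence evidence re-signed in
#' favour of the previous response: positive when the intervening sequence
#' supports repeating `r[t-1]`, negative when it conflicts with it. Equal
#' to the state-1-vs-2 evidence when the previous response reported state
#' 1, and its negative otherwise. First trials of a block have no previous
#' response within the block's evidence stream and are returned as `NA`.
#'
#' @param block An `rl_block`.
#' @param responses Responses in `{1, 2}` (defaults to those stored).
#' @return Numeric vector (length `n_trials`), `NA` at trial 1.
#' @export
repetition_evidence <- function(block, responses = block$responses) {
  if (is.null(responses)) stop("responses are required")
  n <- block$n_trials
  ev <- vapply(seq_len(n), function(t)
    sequence_evidence(block$tilts[[t]], block$state[t], block$kappa)$total,
    numeric(1))
  r_prev <- c(NA_integer_, responses[-n])
  out <- ifelse(r_prev == 1L, ev, -ev)
  out[1] <- NA_real_
  out
}

#' Assemble repetition-curve data from blocks
#'
#' @param blocks List of `rl_block` objects with responses.
#' @param responses_list Optional list of response vectors.
#' @return Data frame with `evidence` (\eqn{\mathcal{L}_{rep}}) and
#'   `repeated` (logical), first trials excluded.
#' @export
repetition_data <- function(blocks, responses_list = NULL) {
  if (inherits(blocks, "rl_block")) blocks <- list(blocks)
  out <- lapply(seq_along(blocks), function(b) {
    bl <- blocks[[b]]
    resp <- if (!is.null(responses_list)) responses_list[[b]] else bl$responses
    ev <- repetition_evidence(bl, resp)
    rep_ <- resp == c(NA_integer_, resp[-bl$n_trials])
    data.frame(evidence = ev[-1], repeated = rep_[-1])
  })
  do.call(rbind, out)
}

#' Assemble reversal-curve data from blocks
#'
#' Indexes each trial by its position `k` within the current hidden-state
#' episode (`k = 1` at the first trial after a reversal) and marks whether
#' the response identified the current hidden state.
#'
#' @inheritParams repetition_data
#' @return Data frame with `block`, `episode`, `k`, `episode_len`,
#'   `first_episode`, `correct`.
#' @export
reversal_data <- function(blocks, responses_list = NULL) {
  if (inherits(blocks, "rl_block")) blocks <- list(blocks)
  out <- lapply(seq_along(blocks), function(b) {
    bl <- blocks[[b]]
    resp <- if (!is.null(responses_list)) responses_list[[b]] else bl$responses
    k <- stats::ave(seq_len(bl$n_trials), bl$episode, FUN = seq_along)
    len <- stats::ave(seq_len(bl$n_trials), bl$episode, FUN = length)
    data.frame(block = b, episode = bl$episode, k = k, episode_len = len,
               first_episode = bl$episode == 1L,
               correct = resp == bl$state)
  })
  do.call(rbind, out)
}

reversal_predict <- function(k, p0, t_rev, p_rev) {
  p0 + (p_rev - p0) * (1 - exp(-k / t_rev))
}

# episode bookkeeping for the vectorized likelihood: the curve within an
# episode is p(k) = p_rev - a e^{-k/t} with a = p_rev - p0, and the
# episode-chained p0 gives the recursion a' = (2 p_rev - 1) - a q^len
# (q = e^{-1/t}); episodes of the same rank across blocks update together
prep_reversal <- function(data) {
  ord <- order(data$block, data$episode, data$k)
  d <- data[ord, , drop = FALSE]
  ep_key <- paste(d$block, d$episode)
  ep_id <- match(ep_key, unique(ep_key))
  first <- !duplicated(ep_id)
  ep_block <- d$block[first]
  ep_len <- d$episode_len[first]
  ep_rank <- stats::ave(seq_along(ep_block), ep_block, FUN = seq_along)
  list(correct = d$correct, k = d$k, ep_id = ep_id, ep_len = ep_len,
       rank_idx = split(seq_along(ep_len), ep_rank))
}

reversal_probs_prepped <- function(pr, t_rev, p_rev) {
  q <- exp(-1 / t_rev)
  a <- numeric(length(pr$ep_len))
  for (r in seq_along(pr$rank_idx)) {
    idx <- pr$rank_idx[[r]]
    a[idx] <- if (r == 1L) p_rev - 0.5
              else (2 * p_rev - 1) - a[idx - 1L] * q^pr$ep_len[idx - 1L]
  }
  p_rev - a[pr$ep_id] * q^pr$k
}

# per-trial predicted probabilities in the row order of `data`
reversal_probs <- function(data, t_rev, p_rev) {
  pr <- prep_reversal(data)
  p <- reversal_probs_prepped(pr, t_rev, p_rev)
  p[order(order(data$block, data$episode, data$k))]
}

#' Fit the saturating-exponential reversal curve
#'
#' Fits \eqn{p(r_k = s) = p_0 + (p_{rev} - p_0)(1 - e^{-k/t_{rev}})} to
#' trial-level correctness by maximum (Bernoulli) likelihood. The initial
#' rate \eqn{p_0} is not fitted: it is 0.5 for the first episode of each
#' block and `1 -` the previous episode's last-trial value afterwards.
#' Bounded optimization (`t_rev` in \[1e-2, 1e2\], `p_rev` in \[0.5, 1\])
#' with 5 starting points.
#'
#' @param data Data frame from [reversal_data()].
#' @return An object of class `rl_reversal_fit`: `t_rev`, `p_rev`,
#'   `logLik`, `n`.
#' @export
fit_reversal_curve <- function(data) {
  if (nrow(data) == 0 || all(data$first_episode))
    stop("no reversals in data: cannot fit a reversal curve")
  pr <- prep_reversal(data)
  nll <- function(par) {
    p <- reversal_probs_prepped(pr, par[1], par[2])
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(ifelse(pr$correct, log(p), log1p(-p)))
  }
  starts <- rbind(c(1, 0.9), c(0.5, 0.85), c(2, 0.95), c(0.2, 0.99), c(5, 0.8))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], nll, method = "L-BFGS-B",
            lower = c(1e-2, 0.5), upper = c(1e2, 1)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("reversal-curve optimization failed")
  structure(list(t_rev = best$par[1], p_rev = best$par[2],
                 logLik = -best$value, n = nrow(data)),
            class = "rl_reversal_fit")
}

#' @export
print.rl_reversal_fit <- function(x, ...) {
  cat(sprintf("<rl_reversal_fit> t_rev=%.3f p_rev=%.3f (n=%d)\n",
              x$t_rev, x$p_rev, x$n))
  invisible(x)
}

repetition_predict <- function(evidence, beta, beta_rep, p_rep) {
  p_rep + (1 - p_rep) / (1 + exp(-beta * evidence + beta_rep))
}

#' Fit the three-parameter repetition sigmoid
#'
#' Fits \eqn{p(r_t = r_{t-1}) = p_{rep} + (1 - p_{rep}) \,
#' \sigma(\beta \mathcal{L}_{rep} - \beta_{rep})} by maximum (Bernoulli)
#' likelihood, with `beta` in \[-20, 20\] (a signed slope keeps the family
#' closed under mirroring the evidence axis) and `p_rep` in \[0, 0.5\]. The
#' repetition criterion `beta_rep` is reparameterized as the point of
#' subjective equivalence (PSE), the evidence level at which repeating and
#' switching are equiprobable. Complete separation (all repeats or all
#' switches) is flagged and leaves parameters at their bounds.
#'
#' @param data Data frame with columns `evidence` and `repeated` (from
#'   [repetition_data()]), or two vectors via `evidence=` and `repeated=`.
#' @param evidence,repeated Alternative vector interface.
#' @return An object of class `rl_repetition_fit`: `beta`, `beta_rep`,
#'   `p_rep`, `pse`, `separation`, `logLik`, `n`.
#' @export
fit_repetition_curve <- function(data = NULL, evidence = data$evidence,
                                 repeated = data$repeated) {
  keep <- is.finite(evidence) & !is.na(repeated)
  evidence <- evidence[keep]; repeated <- as.logical(repeated[keep])
  n <- length(evidence)
  if (n < 10) stop("too few trials to fit a repetition curve")
  separation <- all(repeated) || all(!repeated)
  if (separation) warning("complete separation: parameters at bounds")
  nll <- function(par) {
    p <- repetition_predict(evidence, par[1], par[2], par[3])
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(ifelse(repeated, log(p), log1p(-p)))
  }
  starts <- rbind(c(2, 2, 0.05), c(1, 0, 0.01), c(4, 4, 0.1),
                  c(2, -2, 0.05), c(0.5, 1, 0.2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], nll, method = "L-BFGS-B",
            lower = c(-20, -50, 0), upper = c(20, 50, 0.5)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("repetition-curve optimization failed")
  beta <- best$par[1]; beta_rep <- best$par[2]; p_rep <- best$par[3]
  structure(list(beta = beta, beta_rep = beta_rep, p_rep = p_rep,
                 pse = pse_from_params(beta, beta_rep, p_rep),
                 separation = separation, logLik = -best$value, n = n),
            class = "rl_repetition_fit")
}

#' Point of subjective equivalence of a fitted repetition curve
#'
#' Inverts the three-parameter sigmoid at probability 0.5 and reports the
#' amount of evidence *against* the previous response at which repeating
#' and switching are equiprobable (a belief-carrying observer crosses 0.5
#' at conflicting evidence, so the PSE is positive). Undefined (returns
#' `NA`) when the lower asymptote already exceeds 0.5 or the slope is
#' zero.
#'
#' @param beta,beta_rep,p_rep Sigmoid parameters.
#' @return Scalar PSE in log-odds units (positive = conflicting evidence
#'   needed to switch).
#' @export
pse_from_params <- function(beta, beta_rep, p_rep) {
  q <- (0.5 - p_rep) / (1 - p_rep)
  if (q <= 0 || q >= 1 || beta == 0) return(NA_real_)
  -(beta_rep + logit(q)) / beta
}

#' @export
print.rl_repetition_fit <- function(x, ...) {
  cat(sprintf("<rl_repetition_fit> beta=%.3f pse=%.3f p_rep=%.3f (n=%d)%s\n",
              x$beta, x$pse, x$p_rep, x$n,
              if (x$separation) " [separation]" else ""))
  invisible(x)
}

#' Binned repetition-curve points for plotting
#'
#' @param data Data frame from [repetition_data()].
#' @param breaks Number of evidence bins (quantile-based).
#' @return Data frame with bin centers and observed repeat fractions.
#' @export
repetition_curve_points <- function(data, breaks = 10L) {
  keep <- is.finite(data$evidence)
  ev <- data$evidence[keep]; rp <- data$repeated[keep]
  qs <- unique(quantile(ev, probs = seq(0, 1, length.out = breaks + 1)))
  bin <- cut(ev, qs, include.lowest = TRUE)
  data.frame(evidence = tapply(ev, bin, mean),
             p_repeat = tapply(rp, bin, mean),
             n = as.integer(table(bin)),
             row.names = NULL)
}
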