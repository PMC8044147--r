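#' Per-stimulus characteristics: orientation, change, evidence, consistency
#'
#' For every stimulus of every trial in a block, computes the four
#' characteristics used by the encoding analyses: (1) the orientation as
#' the pair \eqn{(\cos 2\theta_i, \sin 2\theta_i)}; (2) the change
#' \eqn{|\theta_i - \theta_{i-1}|}, a circular distance on the
#' \eqn{\pi}-periodic orientation circle (in \eqn{[0, \pi/2]}; the first
#' stimulus of a block has no predecessor and gets `NA`); (3) the evidence
#' strength, the tilt from the nearest category boundary (boundaries lie
#' \eqn{\pm\pi/4} from the category means, so this is in
#' \eqn{[0, \pi/4]}); and (4) the consistency, the evidence strength
#' signed by the agreement between the stimulus's evidence \eqn{\ell_i}
#' and the current belief \eqn{L_{t,i}}. An exactly neutral belief is
#' imputed the sign of the incoming evidence, so the stimulus counts as
#' consistent (positive).
#'
#' Beliefs come from the noise-free recursion at `h` by default; a
#' precomputed `within` belief list (e.g. response-conditioned
#' particle-filter trajectories) can be supplied instead.
#'
#' @param block An `rl_block` with responses (Ob orientations depend on
#'   them).
#' @param responses Responses in `{1, 2}`.
#' @param h Hazard rate used for the belief trajectory.
#' @param scheme `"stimulus_level"` (belief after stimuli `1..i-1` of the
#'   trial) or `"response_level"` (belief frozen at the trial's prior).
#' @param within Optional list of per-trial within-sequence belief
#'   vectors overriding the internal trajectory.
#' @return Data frame, one row per stimulus: `trial`, `stim`,
#'   `orientation`, `cos2`, `sin2`, `change`, `evidence_strength`,
#'   `consistency`, `ell`, `belief`.
#' @export
stimulus_characteristics <- function(block, responses = block$responses,
                                     h = 0.125,
                                     scheme = c("stimulus_level", "response_level"),
                                     within = NULL) {
  scheme <- match.arg(scheme)
  orientations <- block$orientations %||% realize_orientations(block, responses)
  if (is.null(within)) within <- belief_trajectory(block, h, scheme)$within
  mu_B <- (block$mu_A + pi / 2) %% pi
  rows <- lapply(seq_len(block$n_trials), function(t) {
    th <- orientations[[t]]
    ell <- sequence_evidence(block$tilts[[t]], block$state[t], block$kappa)$per_stimulus
    # distance to the nearest category boundary (pi/4 off the means)
    d_mean <- pmin(circ_dist_pi(th, block$mu_A[t]), circ_dist_pi(th, mu_B[t]))
    strength <- pi / 4 - d_mean
    L <- within[[t]]
    # neutral belief: treat the stimulus as consistent with itself
    sgn <- ifelse(L == 0, 1, sign(ell * L))
    data.frame(trial = t, stim = seq_along(th), orientation = th,
               cos2 = cos(2 * th), sin2 = sin(2 * th),
               change = NA_real_, evidence_strength = strength,
               consistency = strength * sgn, ell = ell, belief = L)
  })
  out <- do.call(rbind, rows)
  all_th <- out$orientation
  out$change <- c(NA_real_, circ_dist_pi(all_th[-1], all_th[-length(all_th)]))
  out
}

#' Default hazard grid for neural-hazard estimation
#'
#' 13 log-spaced candidate hazard rates spanning 1/32 to 1/2.
#' @return Numeric vector of length 13.
#' @export
hazard_grid_default <- function() exp(seq(log(1 / 32), log(1 / 2), length.out = 13))

#' Hazard tuning curve of a consistency code
#'
#' Given unit-activity features whose consistency channel was generated at
#' some true hazard rate, recomputes the consistency variable under every
#' candidate hazard rate in `grid` (beliefs re-run at that hazard), and
#' measures the cross-validated coding precision of the features for each
#' variant. The tuning curve of precision versus \eqn{\log h} is smoothed
#' by a quadratic polynomial fitted in a window of up to seven grid
#' points around the empirical peak (a global quadratic is biased when
#' the curve is sharply peaked) and the neural hazard rate `h_star` is
#' its vertex, clipped to the grid hull; if the quadratic has no interior
#' maximum the grid argmax is returned with a warning.
#'
#' @param features Numeric matrix, units x stimuli, aligned with the
#'   stimuli of `blocks` in order.
#' @param blocks List of `rl_block` objects with responses.
#' @param responses_list Optional response vectors per block.
#' @param grid Candidate hazard rates (default [hazard_grid_default()]).
#' @param n_folds Cross-validation folds for [encode_cv()].
#' @param scheme Within-sequence belief convention.
#' @return An object of class `rl_hazard_tuning`: `grid`, `precision`
#'   (raw), `relative` (fraction of maximum), `h_star`, `quad` (fit
#'   coefficients), `interior_max`.
#' @export
hazard_tuning <- function(features, blocks, responses_list = NULL,
                          grid = hazard_grid_default(), n_folds = 12L,
                          scheme = "stimulus_level") {
  if (inherits(blocks, "rl_block")) blocks <- list(blocks)
  precision <- vapply(grid, function(h) {
    x <- unlist(lapply(seq_along(blocks), function(b) {
      resp <- if (!is.null(responses_list)) responses_list[[b]] else NULL
      ch <- stimulus_characteristics(blocks[[b]], responses = resp %||%
                                       blocks[[b]]$responses, h = h,
                                     scheme = scheme)
      ch$consistency
    }))
    encode_cv(features, x, n_folds = n_folds)$precision
  }, numeric(1))
  relative <- precision / max(precision)
  lh <- log(grid)
  # quadratic smoothing in a window around the empirical peak: a global
  # quadratic is badly biased when the tuning curve is sharply peaked
  peak <- which.max(precision)
  win <- max(1L, peak - 3L):min(length(grid), peak + 3L)
  quad <- lm(precision[win] ~ lh[win] + I(lh[win]^2))
  co <- coef(quad)
  interior <- is.finite(co[3]) && co[3] < 0
  if (interior) {
    h_star <- exp(-co[2] / (2 * co[3]))
    h_star <- min(max(h_star, min(grid)), max(grid))
  } else {
    warning("tuning curve has no interior maximum; using grid argmax")
    h_star <- grid[which.max(precision)]
  }
  structure(list(grid = grid, precision = precision, relative = relative,
                 h_star = unname(h_star), quad = unname(co),
                 interior_max = interior),
            class = "rl_hazard_tuning")
}

#' @export
print.rl_hazard_tuning <- function(x, ...) {
  cat(sprintf("<rl_hazard_tuning> h*=%.4f over grid [%.3f, %.3f] (%d points)\n",
              x$h_star, min(x$grid), max(x$grid), length(x$grid)))
  invisible(x)
}
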