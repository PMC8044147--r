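test_that("repetition evidence is the sequence evidence signed by the previous response", {
  block <- manual_block(list(0, 0, c(0.2, -0.4)), c(1, 1, 2))
  # previous response reported state 1 -> evidence kept; state 2 -> flipped
  ev <- repetition_evidence(block, responses = c(1L, 2L, 1L))
  expect_true(is.na(ev[1]))
  expect_equal(ev[2], 1)    # prev r=1, state 1, single zero tilt: +2*kappa
  s3 <- sequence_evidence(block$tilts[[3]], 2, 0.5)$total
  expect_equal(ev[3], -s3)  # prev r=2 flips the state-1-vs-2 evidence
  # antisymmetry in the previous response
  ev2 <- repetition_evidence(block, responses = c(2L, 2L, 1L))
  expect_equal(ev2[2], -1)
  # cross-module consistency on simulated data
  set.seed(41)
  pair <- realize_block_pair("stable")
  sim <- simulate_responses(model_params(0.15, 0.5), pair$cb, seed = 2)
  ev3 <- repetition_evidence(sim$block)
  seq_ev <- sim$trajectory$evidence
  r_prev <- c(NA, sim$responses[-72])
  expect_equal(ev3[-1], ifelse(r_prev[-1] == 1, seq_ev[-1], -seq_ev[-1]))
})

test_that("reversal curve recovers generating parameters", {
  # independent generator: Bernoulli draws straight from the saturating
  # exponential with chained episode-initial rates
  gen_rev_data <- function(t_rev, p_rev, n_blocks, seed) {
    set.seed(seed)
    rows <- list()
    for (b in seq_len(n_blocks)) {
      lens <- sample_episode_lengths(6, 72)
      p0 <- 0.5
      for (e in seq_along(lens)) {
        k <- seq_len(lens[e])
        p <- p0 + (p_rev - p0) * (1 - exp(-k / t_rev))
        rows[[length(rows) + 1L]] <- data.frame(
          block = b, episode = e, k = k, episode_len = lens[e],
          first_episode = e == 1L, correct = runif(lens[e]) < p)
        p0 <- 1 - p[lens[e]]
      }
    }
    do.call(rbind, rows)
  }
  d <- gen_rev_data(1.0, 0.9, n_blocks = 1700, seed = 42)  # ~1e4 episodes
  fit <- fit_reversal_curve(d)
  expect_lt(abs(fit$t_rev - 1.0), 0.05)
  expect_lt(abs(fit$p_rev - 0.9), 0.01)
  # step-like data: the fitted curve is indistinguishable from a step
  # (the likelihood is flat in t_rev once e^{-1/t} ~ 0), and p_rev tracks
  # the empirical plateau
  d2 <- gen_rev_data(0.011, 0.9, n_blocks = 300, seed = 43)
  fit2 <- fit_reversal_curve(d2)
  expect_lt(exp(-1 / fit2$t_rev), 0.05)
  expect_lt(abs(fit2$p_rev - 0.9), 0.02)
})

test_that("reversal fit is invariant to relabeling the hidden states", {
  set.seed(44)
  blocks <- simulated_blocks(model_params(0.19, 0.5), n_blocks = 2, seed = 44)
  d1 <- reversal_data(blocks)
  flipped <- lapply(blocks, function(b) {
    b$state <- 3L - b$state
    b$responses <- 3L - b$responses
    b
  })
  d2 <- reversal_data(flipped)
  expect_equal(d1$correct, d2$correct)
  f1 <- fit_reversal_curve(d1); f2 <- fit_reversal_curve(d2)
  expect_equal(f1$t_rev, f2$t_rev)
  expect_equal(f1$p_rev, f2$p_rev)
})

test_that("repetition sigmoid recovers parameters at scale", {
  set.seed(45)
  n <- 1e4
  beta <- 2.1; p_rep <- 0.03; pse <- 1.0
  # beta_rep chosen so the curve crosses 0.5 at evidence -pse
  q <- (0.5 - p_rep) / (1 - p_rep)
  beta_rep <- -beta * pse - log(q / (1 - q))
  ev <- rnorm(n, 0, 2)
  p <- p_rep + (1 - p_rep) / (1 + exp(-beta * ev + beta_rep))
  d <- data.frame(evidence = ev, repeated = runif(n) < p)
  fit <- fit_repetition_curve(d)
  expect_lt(abs(fit$beta - beta), 0.1)
  expect_lt(abs(fit$pse - pse), 0.1)
  expect_lt(abs(fit$p_rep - p_rep), 0.03)
  # an unbiased observer has zero PSE
  p0 <- 1 / (1 + exp(-2 * ev))
  d0 <- data.frame(evidence = ev, repeated = runif(n) < p0)
  fit0 <- fit_repetition_curve(d0)
  expect_lt(abs(fit0$pse), 0.05)
})

test_that("the PSE equals the root of the fitted curve at 0.5", {
  set.seed(46)
  ev <- rnorm(3000, 0, 2)
  p <- 0.05 + 0.95 / (1 + exp(-1.8 * ev + 2.2))
  d <- data.frame(evidence = ev, repeated = runif(3000) < p)
  fit <- fit_repetition_curve(d)
  curve_fun <- function(x)
    fit$p_rep + (1 - fit$p_rep) / (1 + exp(-fit$beta * x + fit$beta_rep)) - 0.5
  root <- uniroot(curve_fun, c(-20, 20), tol = 1e-10)$root
  expect_equal(fit$pse, -root, tolerance = 1e-6)
})

test_that("mirroring the evidence axis negates the PSE", {
  # with a zero lower asymptote the sigmoid family is closed under
  # evidence mirroring: the slope flips sign, the PSE is negated
  set.seed(47)
  ev <- rnorm(4000, 0, 2)
  p <- 1 / (1 + exp(-2 * ev + 1.5))
  d <- data.frame(evidence = ev, repeated = runif(4000) < p)
  f1 <- fit_repetition_curve(d)
  f2 <- fit_repetition_curve(data.frame(evidence = -ev, repeated = d$repeated))
  expect_equal(f2$pse, -f1$pse, tolerance = 0.02)
  expect_equal(abs(f2$beta), abs(f1$beta), tolerance = 0.02)
  expect_lt(f2$p_rep, 0.03)
})

test_that("separation is flagged and missing reversals error", {
  ev <- rnorm(100)
  expect_warning(fit_repetition_curve(data.frame(evidence = ev,
                                                 repeated = TRUE)),
                 "separation")
  one_episode <- data.frame(block = 1, episode = 1, k = 1:20,
                            episode_len = 20, first_episode = TRUE,
                            correct = TRUE)
  expect_error(fit_reversal_curve(one_episode[0, ]), "no reversals")
  expect_error(fit_reversal_curve(one_episode), "no reversals")
})

test_that("binned repetition points track the fitted curve", {
  set.seed(48)
  ev <- rnorm(5000, 0, 2)
  p <- 1 / (1 + exp(-2 * ev + 2))
  d <- data.frame(evidence = ev, repeated = runif(5000) < p)
  pts <- repetition_curve_points(d, breaks = 8)
  expect_equal(nrow(pts), 8)
  expect_true(all(diff(pts$p_repeat) >= -0.12))  # roughly monotone
})
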