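closed_form_loglik <- function(params, block, responses) {
  # valid only at sigma_inf = 0: deterministic latent trajectory
  traj <- belief_trajectory(block, params$h)
  r_prev <- c(block$initial_response, responses[-block$n_trials])
  sum(log(vapply(seq_len(block$n_trials), function(t) {
    sgn <- if (responses[t] == 1L) 1 else -1
    p_sel <- if (params$sigma_sel > 0) {
      pnorm(sgn * traj$posterior[t] / params$sigma_sel)
    } else {
      if (sgn * traj$posterior[t] > 0) 1 else if (traj$posterior[t] == 0) 0.5 else 0
    }
    (1 - params$p_lapse) * p_sel +
      params$p_lapse * as.numeric(responses[t] == r_prev[t])
  }, numeric(1))))
}

test_that("particle filter matches the closed-form likelihood at sigma_inf = 0", {
  set.seed(31)
  pair <- realize_block_pair("stable")
  pars_gen <- model_params(0.15, 0.3, 0.5, 0.02)
  sim <- simulate_responses(pars_gen, pair$cb, seed = 4)
  pars_fit <- model_params(0.2, 0, 0.8, 0.05)
  pf <- particle_filter(pars_fit, sim$block, n_particles = 200, seed = 1)
  expect_equal(pf$loglik, closed_form_loglik(pars_fit, sim$block, sim$responses),
               tolerance = 1e-10)
  expect_true(all(pf$ess > 0 & pf$ess <= 200))
})

test_that("likelihood-estimate noise shrinks with the particle count", {
  set.seed(32)
  pair <- realize_block_pair("stable")
  sim <- simulate_responses(model_params(0.15, 0.5, 0.3), pair$cb, seed = 4)
  pars <- model_params(0.15, 0.5, 0.3)
  ll <- function(n_p) vapply(1:15, function(i)
    particle_filter(pars, sim$block, n_particles = n_p)$loglik, numeric(1))
  v100 <- var(ll(100)); v1000 <- var(ll(1000))
  expect_gt(v100, v1000)
})

test_that("degenerate weights raise an error naming the trial", {
  block <- manual_block(list(c(0, 0), c(0, 0)), c(1, 1))
  # p_lapse = 1 but the observed responses do not repeat the guess
  expect_error(
    particle_filter(model_params(0.125, 0, 0, 1), block,
                    responses = c(2L, 2L), n_particles = 50),
    "trial 1")
  # full lapse with all-repeating responses has likelihood exactly 1
  pf <- particle_filter(model_params(0.125, 0, 0, 1), block,
                        responses = c(1L, 1L), n_particles = 50)
  expect_equal(pf$loglik, 0)
})

test_that("pseudo-marginal chain recovers generating parameters", {
  set.seed(33)
  gen <- model_params(0.19, 0.5)
  blocks <- simulated_blocks(gen, n_blocks = 4, seed = 33)
  post <- pmcmc_sample(blocks, n_iter = 400, n_particles = 200, seed = 34)
  s <- summary(post)
  expect_lt(abs(s$mean[s$parameter == "h"] - 0.19),
            2.5 * s$sd[s$parameter == "h"] + 0.02)
  expect_lt(abs(s$mean[s$parameter == "sigma_inf"] - 0.5),
            2.5 * s$sd[s$parameter == "sigma_inf"] + 0.05)
  expect_gt(post$acceptance, 0.05)
  expect_true(all(post$draws[, "h"] > 0 & post$draws[, "h"] < 1))
})

test_that("a prior-only chain reproduces the prior moments", {
  post <- pmcmc_sample(list(), n_iter = 3000, n_particles = 10, seed = 35)
  s <- summary(post)
  pr <- prior_spec()
  # truncated-normal prior moments by numeric integration
  tn_mean <- function(p) integrate(function(x)
    x * dnorm(x, p$mean, p$sd) /
      (pnorm(p$upper, p$mean, p$sd) - pnorm(p$lower, p$mean, p$sd)),
    p$lower, p$upper)$value
  expect_lt(abs(s$mean[s$parameter == "h"] - tn_mean(pr$h)), 0.02)
  expect_lt(abs(s$mean[s$parameter == "sigma_inf"] - tn_mean(pr$sigma_inf)), 0.04)
})

test_that("model selection: symmetry, dominance and the Dirichlet oracle", {
  set.seed(36)
  # identical evidence: exceedance near 1/2 each
  m <- matrix(rnorm(20), 10, 2)
  m[, 2] <- m[, 1]
  b <- bms(m, seed = 1)
  expect_lt(abs(b$exceedance[1] - 0.5), 0.05)
  # dominance by 10 log-units per participant
  m2 <- cbind(rnorm(10), rnorm(10) + 10)
  b2 <- bms(m2, seed = 2)
  expect_gt(b2$exceedance[2], 0.99)
  # 3-model table: exceedance matches an independent stick-breaking
  # Dirichlet sampler at the fitted alpha
  m3 <- cbind(rnorm(8), rnorm(8) + 1.5, rnorm(8) - 1)
  b3 <- bms(m3, n_samples = 2e5, seed = 3)
  alpha <- b3$alpha
  n_mc <- 2e5
  g <- vapply(alpha, function(a) rgamma(n_mc, a), numeric(n_mc))
  # re-draw through Beta marginals (stick-breaking construction)
  v1 <- rbeta(n_mc, alpha[1], alpha[2] + alpha[3])
  v2 <- rbeta(n_mc, alpha[2], alpha[3])
  p1 <- v1; p2 <- (1 - v1) * v2; p3 <- 1 - p1 - p2
  oracle <- c(mean(p1 > p2 & p1 > p3), mean(p2 > p1 & p2 > p3),
              mean(p3 > p1 & p3 > p2))
  expect_equal(unname(b3$exceedance), oracle, tolerance = 0.02)
  # single model degenerates with a warning
  expect_warning(bms(matrix(rnorm(5), 5, 1)), "degenerate")
})

test_that("marginal likelihood separates right and wrong model classes", {
  set.seed(37)
  gen <- model_params(0.19, 0.5)
  blocks <- simulated_blocks(gen, n_blocks = 2, seed = 37)
  # model with inference noise vs pure-lapse model
  ml_noise <- marginal_likelihood(blocks, free = c("h", "sigma_inf"),
                                  n_draws = 40, n_particles = 200, seed = 1)
  ml_lapse <- marginal_likelihood(blocks, free = c("h", "p_lapse"),
                                  n_draws = 40, n_particles = 200, seed = 2)
  expect_true(is.finite(ml_noise))
  expect_gt(ml_noise, ml_lapse)
})
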