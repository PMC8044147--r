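test_that("characteristics have the documented geometry and ranges", {
  set.seed(51)
  pair <- realize_block_pair("stable")
  sim <- simulate_responses(model_params(0.15, 0.4), pair$cb, seed = 1)
  ch <- stimulus_characteristics(sim$block, h = 0.15)
  expect_true(all(ch$evidence_strength >= 0 & ch$evidence_strength <= pi / 4 + 1e-12))
  expect_true(all(ch$change[-1] >= 0 & ch$change[-1] <= pi / 2 + 1e-12))
  expect_true(is.na(ch$change[1]))
  expect_equal(abs(ch$consistency), ch$evidence_strength)
  expect_equal(ch$cos2, cos(2 * ch$orientation))
})

test_that("consistency sign follows the belief and resolves ties by the evidence", {
  # stimulus at the category mean with a strong same-sign belief:
  # consistency is + pi/4
  block <- manual_block(list(c(0, 0, 0), 0), c(1, 1), mu_A = c(0.3, 0.3))
  ch <- stimulus_characteristics(block, responses = c(1L, 1L), h = 0.125)
  # after the first update the belief is strongly positive; stimulus 2 of
  # trial 1 sits at the mean with positive evidence
  expect_equal(ch$evidence_strength[2], pi / 4)
  expect_gt(ch$belief[2], 0)
  expect_equal(ch$consistency[2], pi / 4)
  # the very first stimulus has a zero prior: the neutral belief is
  # imputed the stimulus's own sign, so it counts as consistent
  expect_equal(ch$belief[1], 0)
  expect_equal(ch$consistency[1], ch$evidence_strength[1])
  # same rule when the first stimulus carries negative evidence
  block2 <- manual_block(list(c(pi / 2, 0.1)), 1, mu_A = 0.3)
  ch2 <- stimulus_characteristics(block2, responses = 1L, h = 0.125)
  expect_lt(ch2$ell[1], 0)
  expect_equal(ch2$consistency[1], ch2$evidence_strength[1])
})

test_that("consistency flips sign with mid-sequence belief reversals", {
  # strong conflicting evidence mid-sequence flips the belief; identical
  # stimuli before and after the flip get opposite consistency
  block <- manual_block(list(c(0, 0), c(pi / 2, pi / 2, 0, 0)), c(1, 1))
  ch <- stimulus_characteristics(block, responses = c(1L, 1L), h = 0.125)
  tr2 <- ch[ch$trial == 2, ]
  # stimulus 1 of trial 2: belief positive (carried over), evidence
  # negative (tilt pi/2) -> inconsistent
  expect_lt(tr2$consistency[1], 0)
  # after two conflicting stimuli the belief switched sign; stimulus 3
  # (tilt 0, positive evidence) is now inconsistent with the negative belief
  expect_lt(tr2$belief[3], 0)
  expect_lt(tr2$consistency[3], 0)
  expect_gt(tr2$consistency[4] * tr2$belief[4], 0)
})

test_that("stimulus-level and response-level consistency differ only on flip trials", {
  set.seed(52)
  pair <- realize_block_pair("volatile")
  sim <- simulate_responses(model_params(0.15, 0), pair$cb, seed = 3)
  sl <- stimulus_characteristics(sim$block, h = 0.15, scheme = "stimulus_level")
  rl <- stimulus_characteristics(sim$block, h = 0.15, scheme = "response_level")
  traj <- belief_trajectory(sim$block, 0.15, scheme = "stimulus_level")
  # restrict to generic trials (nonzero prior and within-beliefs, the
  # rule rather than the exception after trial 1)
  generic <- vapply(seq_len(72), function(t)
    traj$prior[t] != 0 && all(traj$within[[t]] != 0), logical(1))
  flip_trial <- vapply(seq_len(72), function(t) {
    w <- traj$within[[t]]
    any(sign(w) != sign(traj$prior[t]))
  }, logical(1))
  differs <- vapply(seq_len(72), function(t)
    any(sl$consistency[sl$trial == t] != rl$consistency[rl$trial == t]),
    logical(1))
  expect_gt(sum(generic), 60)
  expect_true(any(differs[generic]))
  # the two schemes differ exactly on the trials whose belief changes
  # sign somewhere within the sequence
  expect_equal(differs[generic], flip_trial[generic])
})

test_that("stimulus-driven characteristics are mutually decorrelated", {
  # the trial-wise re-randomization of the category axes decorrelates
  # orientation, change and evidence strength from one another and from
  # the belief-dependent consistency variable; consistency itself is
  # definitionally coupled to evidence strength (|consistency| equals the
  # strength), so only its orientation correlations are near zero
  set.seed(53)
  tabs <- list()
  for (i in 1:30) {
    pair <- realize_block_pair(if (i %% 2) "stable" else "volatile")
    sim <- simulate_responses(model_params(0.15, 0.4), pair$cb)
    tabs[[i]] <- cbind(block = i, stimulus_characteristics(sim$block, h = 0.15))
  }
  ch <- do.call(rbind, tabs)
  ch <- ch[!is.na(ch$change), ]
  expect_gt(nrow(ch), 1e4)
  cm <- cor(ch[, c("cos2", "sin2", "change", "evidence_strength")])
  expect_true(all(abs(cm[upper.tri(cm)]) < 0.05))
  expect_lt(abs(cor(ch$cos2, ch$consistency)), 0.05)
  expect_lt(abs(cor(ch$sin2, ch$consistency)), 0.05)
  # successive stimuli: evidence strength is a function of the i.i.d.
  # tilt alone and decorrelates; successive orientations within a trial
  # share the drawing mean, leaving the small structural correlation
  # cov = (E[cos 2 delta])^2 / 2 against variance 1/2, i.e.
  # r = (E[cos 2 delta])^2, predicted in closed form
  expect_lt(abs(cor(ch$evidence_strength[-nrow(ch)],
                    ch$evidence_strength[-1])), 0.05)
  kappa <- 0.5
  r_struct <- (besselI(kappa, 1) / besselI(kappa, 0))^2
  same_trial <- ch$block[-nrow(ch)] == ch$block[-1] &
    ch$trial[-nrow(ch)] == ch$trial[-1]
  lag_cos <- cor(ch$cos2[-nrow(ch)][same_trial], ch$cos2[-1][same_trial])
  expect_lt(abs(lag_cos - r_struct), 0.03)
})

test_that("hazard tuning recovers the generating hazard rate", {
  set.seed(54)
  blocks <- lapply(1:2, function(i) {
    pair <- realize_block_pair(if (i == 1) "stable" else "volatile")
    simulate_responses(model_params(0.15, 0.3), pair$cb)$block
  })
  h_true <- 1 / 8
  x <- unlist(lapply(blocks, function(b)
    stimulus_characteristics(b, h = h_true)$consistency))
  pop <- coding_population(n = 120, n_sel = 60, sigma = 0.5, omega = 1)
  Z <- simulate_population(as.numeric(scale(x)), pop, "a", seed = 55)
  tune <- hazard_tuning(Z, blocks)
  expect_s3_class(tune, "rl_hazard_tuning")
  expect_true(tune$h_star >= min(tune$grid) && tune$h_star <= max(tune$grid))
  # recovery within grid resolution (adjacent grid points ~1.26x apart)
  expect_lt(abs(log(tune$h_star / h_true)), log(1.26) * 1.5)
})

test_that("belief-independent features give a flat tuning warning path", {
  set.seed(56)
  pair <- realize_block_pair("stable")
  sim <- simulate_responses(model_params(0.15, 0.3), pair$cb)
  x <- stimulus_characteristics(sim$block, h = 0.125)$evidence_strength
  pop <- coding_population(n = 60, n_sel = 30, sigma = 0.5, omega = 1)
  Z <- simulate_population(as.numeric(scale(x)), pop, "a", seed = 57)
  # evidence strength carries no belief dependence: the tuning curve in h
  # is flat up to noise, so an interior maximum is not guaranteed
  tune <- withCallingHandlers(
    hazard_tuning(Z, list(sim$block), grid = hazard_grid_default()[c(1, 7, 13)]),
    warning = function(w) invokeRestart("muffleWarning"))
  expect_true(is.finite(tune$h_star))
  expect_true(tune$h_star >= min(tune$grid) && tune$h_star <= max(tune$grid))
})
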