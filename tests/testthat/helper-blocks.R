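# fixtures built in code: hand-rolled blocks with known tilts/states, and
# small simulated datasets

# block with fully specified tilts and states (Cb by default)
manual_block <- function(tilts, states, mu_A = NULL, kappa = 0.5,
                         condition = "Cb", initial_response = 1L) {
  n <- length(tilts)
  episode <- cumsum(c(1L, diff(states) != 0))
  structure(list(condition = condition, volatility = "stable", pair_id = 1L,
                 n_trials = n, kappa = kappa, tilts = tilts,
                 n_stim = vapply(tilts, length, integer(1)),
                 state = as.integer(states), episode = episode,
                 mu_A = mu_A %||% rep(0.3, n),
                 initial_response = initial_response,
                 responses = NULL, orientations = NULL),
            class = "rl_block")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small set of simulated blocks of one condition at given parameters
simulated_blocks <- function(params, n_blocks = 4, seed = 1,
                             config = task_config()) {
  set.seed(seed)
  lapply(seq_len(n_blocks), function(i) {
    vol <- if (i %% 2 == 1) "stable" else "volatile"
    pair <- realize_block_pair(vol, config)
    simulate_responses(params, pair$cb)$block
  })
}
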