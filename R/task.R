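#' Task configuration for the reversal learning design
#'
#' Collects the generative parameters of the two-category reversal learning
#' task: block length, admissible sequence lengths, the von Mises
#' concentration of stimulus orientations around the generative category
#' mean, the episode-length bounds of the truncated exponential, and the
#' number of hidden-state episodes per block for the two volatility levels.
#'
#' @param trials_per_block Number of trials per block (default 72).
#' @param sequence_lengths Admissible numbers of stimuli per trial
#'   (default `c(2, 4, 6, 8)`, sampled uniformly across trials).
#' @param kappa Von Mises concentration of stimulus orientations around the
#'   generative category mean (default 0.5; practice blocks used 1.5).
#' @param episode_min,episode_max Bounds (in trials) of the truncated
#'   exponential distribution of hidden-state episode lengths (defaults 4, 24).
#' @param n_episodes_stable,n_episodes_volatile Number of episodes per
#'   72-trial block in the "more stable" (hazard 1/12) and "more volatile"
#'   (hazard 1/6) blocks (defaults 6 and 12).
#' @param hazard_true Overall true hazard rate used by the optimal observer
#'   (default 0.125, the average of 1/12 and 1/6).
#'
#' @return An object of class `rl_task_config`.
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$hazard_true
task_config <- function(trials_per_block = 72L,
                        sequence_lengths = c(2L, 4L, 6L, 8L),
                        kappa = 0.5,
                        episode_min = 4L,
                        episode_max = 24L,
                        n_episodes_stable = 6L,
                        n_episodes_volatile = 12L,
                        hazard_true = 0.125) {
  stopifnot(trials_per_block >= 1, kappa > 0,
            episode_min >= 1, episode_max >= episode_min,
            all(sequence_lengths >= 1))
  structure(list(trials_per_block = as.integer(trials_per_block),
                 sequence_lengths = as.integer(sequence_lengths),
                 kappa = kappa,
                 episode_min = as.integer(episode_min),
                 episode_max = as.integer(episode_max),
                 n_episodes_stable = as.integer(n_episodes_stable),
                 n_episodes_volatile = as.integer(n_episodes_volatile),
                 hazard_true = hazard_true),
            class = "rl_task_config")
}

# rate of the discrete truncated exponential on {min..max} whose mean is
# `target`; rate 0 gives the uniform mean (min+max)/2, so the sign of the
# rate is set by which side of the midpoint the target lies on
truncexp_rate <- function(target, min, max) {
  k <- min:max
  stopifnot(target >= min, target <= max)
  mean_at <- function(lambda) {
    w <- exp(-lambda * (k - min))
    sum(k * w) / sum(w)
  }
  if (abs(target - mean_at(0)) < 1e-12) return(0)
  # targets at (or numerically beyond) the attainable mean range: use the
  # strongest tilt; rejection then concentrates on the boundary composition
  if (target >= mean_at(-5)) return(-5)
  if (target <= mean_at(5)) return(5)
  uniroot(function(l) mean_at(l) - target, c(-5, 5), tol = 1e-12)$root
}

#' Sample hidden-state episode lengths for one block
#'
#' Episode lengths (in trials) are drawn i.i.d. from a discrete truncated
#' exponential distribution on `min:max` whose rate is chosen so that the
#' mean length equals `total / n_episodes`, and the draw is rejected until
#' the lengths sum exactly to `total`. This preserves the stated marginal
#' distribution while satisfying the block-length constraint, and makes the
#' realized hazard rate match the nominal `n_episodes / total`.
#'
#' @param n_episodes Number of episodes in the block.
#' @param total Total number of trials the lengths must sum to.
#' @param min,max Truncation bounds in trials (defaults 4 and 24).
#' @param max_tries Rejection-sampling cap before erroring.
#'
#' @return Integer vector of `n_episodes` lengths in `[min, max]` summing to
#'   `total`.
#' @export
#' @examples
#' set.seed(1)
#' sample_episode_lengths(6, 72)
sample_episode_lengths <- function(n_episodes, total, min = 4L, max = 24L,
                                   max_tries = 10000L) {
  n_episodes <- as.integer(n_episodes)
  total <- as.integer(total)
  if (n_episodes < 1)
    stop("n_episodes must be >= 1")
  if (total < n_episodes * min || total > n_episodes * max)
    stop(sprintf("infeasible episode structure: %d trials cannot be split into %d episodes of %d-%d trials",
                 total, n_episodes, min, max))
  if (n_episodes == 1L) return(total)
  k <- min:max
  lambda <- truncexp_rate(total / n_episodes, min, max)
  pmf <- exp(-lambda * (k - min))
  pmf <- pmf / sum(pmf)
  for (i in seq_len(max_tries)) {
    lengths <- sample(k, n_episodes, replace = TRUE, prob = pmf)
    if (sum(lengths) == total) return(as.integer(lengths))
  }
  stop("episode-length rejection sampling failed within max_tries")
}

# exact rejection sampler for x ~ von Mises(0, kappa) on (-pi, pi],
# uniform envelope; acceptance rate I0(kappa)/exp(kappa)
rvonmises0 <- function(n, kappa) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * exp(kappa) / besselI(kappa, 0)) + 8L
    x <- runif(m, -pi, pi)
    keep <- runif(m) < exp(kappa * (cos(x) - 1))
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

#' Generate pre-generated stimulus tilts for a set of sequences
#'
#' Stimulus sequences are pre-generated as tilts \eqn{\delta_i} from the
#' generative category mean rather than as orientations, so that the same
#' tilts can later be realized as orientations under either condition.
#' Orientations are \eqn{\pi}-periodic, so the doubled tilt
#' \eqn{2\delta_i} is drawn from a von Mises distribution with mean 0 and
#' concentration `kappa`; tilts live in \eqn{(-\pi/2, \pi/2]}. The
#' per-stimulus log-odds evidence is \eqn{\ell_i = 2\kappa\cos(2\delta_i)}.
#'
#' @param seq_lengths Integer vector: number of stimuli per trial.
#' @param kappa Von Mises concentration.
#'
#' @return List of numeric tilt vectors, one per trial.
#' @export
generate_tilts <- function(seq_lengths, kappa) {
  stopifnot(kappa > 0, all(seq_lengths >= 1))
  draws <- rvonmises0(sum(seq_lengths), kappa) / 2
  split(draws, rep(seq_along(seq_lengths), seq_lengths))
}

# hidden-state trajectory from episode lengths and an initial state
states_from_episodes <- function(lengths, s0) {
  s <- s0
  states <- integer(0)
  episode <- integer(0)
  for (e in seq_along(lengths)) {
    states <- c(states, rep(s, lengths[e]))
    episode <- c(episode, rep(e, lengths[e]))
    s <- 3L - s
  }
  list(state = states, episode = episode)
}

#' Realize a matched pair of cue-based and outcome-based blocks
#'
#' Builds one cue-based (Cb) and one outcome-based (Ob) block from the same
#' pre-generated tilts and the same hidden-state trajectory. Because the
#' log-odds evidence of a sequence depends only on its tilts and the current
#' hidden state, the two blocks provide exactly the same evidence stream
#' for any response history, even though the realized orientations in the
#' Ob block depend on the previous response. Cb orientations are realized
#' immediately; Ob orientations are realized lazily once responses are
#' known (see [realize_orientations()]).
#'
#' @param volatility `"stable"` (6 episodes per 72 trials) or `"volatile"`
#'   (12 episodes).
#' @param config A [task_config()].
#' @param pair_id Identifier linking the two matched blocks.
#' @param seed Optional seed for the shared tilt/state draw.
#'
#' @return List with elements `cb` and `ob`, each of class `rl_block`.
#' @export
#' @examples
#' pair <- realize_block_pair("stable", task_config(), seed = 1)
#' pair$cb$condition; pair$ob$condition
realize_block_pair <- function(volatility = c("stable", "volatile"),
                               config = task_config(),
                               pair_id = 1L, seed = NULL) {
  volatility <- match.arg(volatility)
  with_seed(seed, {
    core <- generate_block_core(volatility, config)
    cb <- new_block("Cb", volatility, pair_id, core, config)
    ob <- new_block("Ob", volatility, pair_id, core, config)
    cb$orientations <- realize_orientations(cb)
    list(cb = cb, ob = ob)
  })
}

# shared randomness of a matched pair: tilts, episode structure, states,
# trial-wise category means, sequence lengths, initial guess
generate_block_core <- function(volatility, config) {
  n_ep <- if (volatility == "stable") config$n_episodes_stable else config$n_episodes_volatile
  lengths <- sample_episode_lengths(n_ep, config$trials_per_block,
                                    config$episode_min, config$episode_max)
  s0 <- sample(1:2, 1)
  st <- states_from_episodes(lengths, s0)
  n_stim <- sample(config$sequence_lengths, config$trials_per_block, replace = TRUE)
  list(tilts = generate_tilts(n_stim, config$kappa),
       n_stim = n_stim,
       state = st$state,
       episode = st$episode,
       mu_A = runif(config$trials_per_block, 0, pi),
       initial_response = sample(1:2, 1))
}

new_block <- function(condition, volatility, pair_id, core, config) {
  structure(list(condition = condition,
                 volatility = volatility,
                 pair_id = pair_id,
                 n_trials = length(core$state),
                 kappa = config$kappa,
                 tilts = core$tilts,
                 n_stim = core$n_stim,
                 state = core$state,
                 episode = core$episode,
                 mu_A = core$mu_A,
                 initial_response = core$initial_response,
                 responses = NULL,
                 orientations = NULL),
            class = "rl_block")
}

#' @export
print.rl_block <- function(x, ...) {
  cat(sprintf("<rl_block> %s / %s, %d trials, %d episodes, pair %s\n",
              x$condition, x$volatility, x$n_trials, max(x$episode),
              as.character(x$pair_id)))
  invisible(x)
}

#' Realize stimulus orientations from tilts
#'
#' Maps pre-generated tilts to orientations
#' \eqn{\theta_i = (\delta_i + \mu_t) \bmod \pi}, where the drawing mean
#' \eqn{\mu_t} is the trial's category-A mean or its orthogonal category-B
#' mean. In the Cb condition \eqn{\mu_t} follows the hidden state alone; in
#' the Ob condition it follows the hidden state combined with the previous
#' response (the drawn deck depends on which key was pressed).
#'
#' @param block An `rl_block`.
#' @param responses Integer responses in `{1, 2}`; required for Ob blocks
#'   (the previous response determines the drawing mean). Defaults to the
#'   responses stored in the block.
#'
#' @return List of orientation vectors in `[0, pi)`, one per trial.
#' @export
realize_orientations <- function(block, responses = block$responses) {
  n <- block$n_trials
  mu_B <- (block$mu_A + pi / 2) %% pi
  if (block$condition == "Cb") {
    mu_t <- ifelse(block$state == 1L, block$mu_A, mu_B)
  } else {
    if (is.null(responses))
      stop("Ob orientations depend on responses; simulate or supply them first")
    r_prev <- c(block$initial_response, responses[-n])
    # state 1: previous L draws from A, previous R from B; state 2 flips it
    use_A <- (block$state == 1L) == (r_prev == 1L)
    mu_t <- ifelse(use_A, block$mu_A, mu_B)
  }
  lapply(seq_len(n), function(t) (block$tilts[[t]] + mu_t[t]) %% pi)
}

#' Log-odds evidence recomputed from realized orientations
#'
#' Computes the sequence evidence for hidden state 1 versus 2 directly from
#' realized orientations: in Cb, \eqn{\sum_i 2\kappa\cos(2(\theta_i-\mu_A))};
#' in Ob the reference mean is \eqn{\mu_A} or \eqn{\mu_B} depending on the
#' previous response. Used as the orientation-space cross-check of the
#' tilt-based evidence returned by [sequence_evidence()].
#'
#' @param block An `rl_block` with orientations realized.
#' @param responses Responses in `{1, 2}` (needed for Ob).
#' @return Numeric vector of per-trial log-odds evidence.
#' @export
evidence_from_orientations <- function(block, responses = block$responses) {
  orientations <- block$orientations %||% realize_orientations(block, responses)
  n <- block$n_trials
  mu_B <- (block$mu_A + pi / 2) %% pi
  if (block$condition == "Cb") {
    mu_ref <- block$mu_A
  } else {
    r_prev <- c(block$initial_response, responses[-n])
    mu_ref <- ifelse(r_prev == 1L, block$mu_A, mu_B)
  }
  vapply(seq_len(n), function(t) {
    sum(2 * block$kappa * cos(2 * (orientations[[t]] - mu_ref[t])))
  }, numeric(1))
}

#' Flatten blocks into a trial table
#'
#' One row per trial; tilt and orientation lists are stored as
#' semicolon-joined strings so the table round-trips through a plain
#' delimited file.
#'
#' @param blocks A single `rl_block` or a list of them.
#' @param responses_list Optional list of response vectors matching `blocks`.
#' @return A `data.frame` with one row per trial.
#' @export
blocks_to_table <- function(blocks, responses_list = NULL) {
  if (inherits(blocks, "rl_block")) blocks <- list(blocks)
  join <- function(x) vapply(x, function(v)
    paste(formatC(v, digits = 12, format = "g"), collapse = ";"), character(1))
  tabs <- lapply(seq_along(blocks), function(b) {
    bl <- blocks[[b]]
    resp <- if (!is.null(responses_list)) responses_list[[b]] else bl$responses
    ori <- bl$orientations
    if (is.null(ori) && (bl$condition == "Cb" || !is.null(resp)))
      ori <- realize_orientations(bl, resp)
    data.frame(block = b,
               pair_id = bl$pair_id,
               condition = bl$condition,
               volatility = bl$volatility,
               trial = seq_len(bl$n_trials),
               episode = bl$episode,
               state = bl$state,
               n_stim = bl$n_stim,
               mu_A = bl$mu_A,
               initial_response = bl$initial_response,
               tilts = join(bl$tilts),
               orientations = if (is.null(ori)) NA_character_ else join(ori),
               response = if (is.null(resp)) NA_integer_ else resp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, tabs)
}

#' Write / read the delimited trial table
#'
#' Tab-separated table (one row per trial) with an optional JSON sidecar
#' carrying the task configuration and seeds.
#'
#' @param table Trial table from [blocks_to_table()].
#' @param path Output path (`.tsv`); the sidecar is written to
#'   `paste0(path, ".json")` when `sidecar` is non-NULL.
#' @param sidecar Optional list serialized as JSON next to the table.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path, sidecar = NULL) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(sidecar))
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Rebuild `rl_block` objects from a trial table
#'
#' @param table A trial table as produced by [blocks_to_table()].
#' @param kappa Von Mises concentration to attach (not stored per row).
#' @return List of `rl_block` objects.
#' @export
table_to_blocks <- function(table, kappa = 0.5) {
  split_num <- function(s) lapply(strsplit(s, ";", fixed = TRUE),
                                  function(v) as.numeric(v))
  lapply(split(table, factor(table$block, levels = unique(table$block))), function(tb) {
    tb <- tb[order(tb$trial), ]
    bl <- structure(list(condition = tb$condition[1],
                         volatility = tb$volatility[1],
                         pair_id = tb$pair_id[1],
                         n_trials = nrow(tb),
                         kappa = kappa,
                         tilts = split_num(tb$tilts),
                         n_stim = tb$n_stim,
                         state = tb$state,
                         episode = tb$episode,
                         mu_A = tb$mu_A,
                         initial_response = tb$initial_response[1],
                         responses = if (all(is.na(tb$response))) NULL else tb$response,
                         orientations = NULL),
                    class = "rl_block")
    if (!all(is.na(tb$orientations))) bl$orientations <- split_num(tb$orientations)
    bl
  })
}
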