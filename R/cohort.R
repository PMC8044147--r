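#' Specification of a synthetic behavioural cohort
#'
#' Between-subject distributions of the observer parameters per condition.
#' Group means follow the fitted group-level values (hazard rate: Cb
#' 0.191, Ob 0.115; inference noise: Cb 0.512, Ob 0.550); the printed
#' group SEMs are converted to between-subject SDs by multiplying by
#' \eqn{\sqrt{N}}. Inference noise is correlated across conditions within
#' subject (target Pearson r = 0.63) through a shared latent Gaussian
#' factor. Parameters are truncated to their prior ranges.
#'
#' @param n_subjects Number of subjects (default 24).
#' @param h_mean,h_sem Named `c(cb=, ob=)` group mean and SEM of the
#'   hazard rate.
#' @param sigma_mean,sigma_sem Group mean and SEM of the inference noise.
#' @param sigma_corr Cross-condition correlation of inference noise.
#' @param sem_n Sample size behind the quoted SEMs (default 24); the
#'   between-subject SD is `SEM * sqrt(sem_n)` independently of how many
#'   subjects are generated.
#' @param sigma_sel,p_lapse Selection noise and lapse rate (defaults 0; the
#'   retained behavioural model has neither).
#' @return An object of class `rl_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 24L,
                        h_mean = c(cb = 0.191, ob = 0.115),
                        h_sem = c(cb = 0.022, ob = 0.015),
                        sigma_mean = c(cb = 0.512, ob = 0.550),
                        sigma_sem = c(cb = 0.024, ob = 0.033),
                        sigma_corr = 0.63,
                        sem_n = 24L,
                        sigma_sel = 0, p_lapse = 0) {
  structure(list(n_subjects = as.integer(n_subjects),
                 h_mean = h_mean, h_sd = h_sem * sqrt(sem_n),
                 sigma_mean = sigma_mean,
                 sigma_sd = sigma_sem * sqrt(sem_n),
                 sigma_corr = sigma_corr,
                 sigma_sel = sigma_sel, p_lapse = p_lapse),
            class = "rl_cohort_spec")
}

# subject-level parameter draw: independent truncated-normal hazard rates,
# inference noise correlated across conditions via a shared latent factor
sample_subject_params <- function(spec) {
  draw_h <- function(cond)
    rtnorm(1, spec$h_mean[[cond]], spec$h_sd[[cond]], 1e-3, 1 - 1e-3)
  rho <- sqrt(spec$sigma_corr)
  z0 <- rnorm(1)
  repeat {
    z <- rho * z0 + sqrt(1 - rho^2) * rnorm(2)
    s <- spec$sigma_mean + spec$sigma_sd * z
    if (all(s >= 0 & s <= 10)) break
    z0 <- rnorm(1)
  }
  list(cb = model_params(draw_h("cb"), s[[1]], spec$sigma_sel, spec$p_lapse),
       ob = model_params(draw_h("ob"), s[[2]], spec$sigma_sel, spec$p_lapse))
}

#' Generate one synthetic session (8 matched blocks)
#'
#' Four matched Cb/Ob block pairs — two stable and two volatile — with
#' responses simulated from condition-specific observer parameters.
#'
#' @param params_cb,params_ob [model_params()] per condition.
#' @param config [task_config()].
#' @param scheme Within-sequence belief convention.
#' @param seed Optional seed.
#' @return List with `blocks` (named list of 8 simulated `rl_block`s) and
#'   `simulations` (matching `rl_simulation` objects).
#' @export
generate_session <- function(params_cb, params_ob, config = task_config(),
                             scheme = "stimulus_level", seed = NULL) {
  with_seed(seed, {
    vols <- c("stable", "stable", "volatile", "volatile")
    blocks <- list(); sims <- list()
    for (p in seq_along(vols)) {
      pair <- realize_block_pair(vols[p], config, pair_id = p)
      sim_cb <- simulate_responses(params_cb, pair$cb, scheme = scheme)
      sim_ob <- simulate_responses(params_ob, pair$ob, scheme = scheme)
      nm_cb <- sprintf("cb_%s_%d", vols[p], p)
      nm_ob <- sprintf("ob_%s_%d", vols[p], p)
      blocks[[nm_cb]] <- sim_cb$block
      blocks[[nm_ob]] <- sim_ob$block
      sims[[nm_cb]] <- sim_cb
      sims[[nm_ob]] <- sim_ob
    }
    list(blocks = blocks, simulations = sims)
  })
}

#' Generate a synthetic cohort
#'
#' For each subject, draws condition-specific observer parameters from the
#' cohort spec and simulates a full session of 8 blocks (4 per condition
#' as matched pairs, half stable and half volatile).
#'
#' @param spec [cohort_spec()].
#' @param config [task_config()].
#' @param scheme Within-sequence belief convention.
#' @param seed Optional seed.
#' @return An object of class `rl_cohort`: list of subjects, each with
#'   `params` (per condition) and `session` (see [generate_session()]).
#' @export
generate_cohort <- function(spec = cohort_spec(), config = task_config(),
                            scheme = "stimulus_level", seed = NULL) {
  with_seed(seed, {
    subjects <- lapply(seq_len(spec$n_subjects), function(s) {
      pars <- sample_subject_params(spec)
      list(id = s, params = pars,
           session = generate_session(pars$cb, pars$ob, config, scheme))
    })
    structure(list(subjects = subjects, spec = spec, config = config),
              class = "rl_cohort")
  })
}

#' @export
print.rl_cohort <- function(x, ...) {
  cat(sprintf("<rl_cohort> %d subjects x %d blocks\n",
              length(x$subjects), length(x$subjects[[1]]$session$blocks)))
  invisible(x)
}

#' Per-condition blocks of a cohort subject
#'
#' @param subject One element of `cohort$subjects`.
#' @param condition `"Cb"` or `"Ob"`.
#' @return List of `rl_block`s of that condition.
#' @export
subject_blocks <- function(subject, condition = c("Cb", "Ob")) {
  condition <- match.arg(condition)
  Filter(function(b) b$condition == condition, subject$session$blocks)
}

#' Specification of synthetic MEG-like features
#'
#' Describes, per stimulus characteristic, the linear coding subpopulation
#' that carries it: number of selective units, background-noise SD, and
#' cross-condition coding similarity omega. The consistency channel is
#' generated from beliefs computed at condition-specific true hazard
#' rates (`h_true`). Subpopulations are disjoint across characteristics.
#' This generator is synthetic plumbing standing in for recordings: it
#' reproduces the statistical structure the encoding analyses assume, not
#' real sensor data.
#'
#' @param characteristics Named list; each element is a list with `n_sel`,
#'   `sigma`, `omega`.
#' @param n Total units.
#' @param h_true Named `c(cb=, ob=)` hazard rates generating the
#'   consistency channel.
#' @return An object of class `rl_meg_spec`.
#' @export
meg_spec <- function(characteristics = list(
                       cos2 = list(n_sel = 40L, sigma = 1, omega = 1),
                       sin2 = list(n_sel = 40L, sigma = 1, omega = 1),
                       change = list(n_sel = 40L, sigma = 1, omega = 0.93),
                       evidence_strength = list(n_sel = 40L, sigma = 1, omega = 1),
                       consistency = list(n_sel = 40L, sigma = 1, omega = 1)),
                     n = 300L,
                     h_true = c(cb = 0.319, ob = 0.216)) {
  total_sel <- sum(vapply(characteristics, function(c)
    2L * c$n_sel - as.integer(round(c$omega * c$n_sel)), integer(1)))
  if (total_sel > n)
    stop("characteristic subpopulations exceed the population size")
  structure(list(characteristics = characteristics, n = as.integer(n),
                 h_true = h_true), class = "rl_meg_spec")
}

# per-stimulus characteristic table for a set of blocks, standardized
characteristic_matrix <- function(blocks, h, scheme = "stimulus_level") {
  tabs <- lapply(blocks, function(b)
    stimulus_characteristics(b, h = h, scheme = scheme))
  tab <- do.call(rbind, tabs)
  cols <- c("cos2", "sin2", "change", "evidence_strength", "consistency")
  X <- as.matrix(tab[, cols])
  X[is.na(X)] <- 0  # first-stimulus change has no predecessor
  scale(X)
}

#' Generate synthetic MEG-like unit activity for one subject
#'
#' Builds one feature matrix per condition: the activity of `n` linear
#' units, each selective to at most one stimulus characteristic, driven by
#' the standardized characteristics of the subject's stimuli (consistency
#' computed at the spec's condition-specific `h_true`) plus i.i.d.
#' Gaussian background noise. Within each characteristic's unit range the
#' two conditions share a fraction `omega` of selective units.
#'
#' @param subject One element of `cohort$subjects` (blocks must carry
#'   responses).
#' @param spec [meg_spec()].
#' @param scheme Within-sequence belief convention.
#' @param seed Optional seed.
#' @return List with `Z` (named list `cb`, `ob` of unit x stimulus
#'   matrices), `x` (named list of characteristic matrices per condition),
#'   `assignment` (unit ranges per characteristic), `spec`.
#' @export
generate_meg_features <- function(subject, spec = meg_spec(),
                                  scheme = "stimulus_level", seed = NULL) {
  with_seed(seed, {
    conds <- c(cb = "Cb", ob = "Ob")
    X <- lapply(names(conds), function(cd) {
      characteristic_matrix(subject_blocks(subject, conds[[cd]]),
                            h = spec$h_true[[cd]], scheme = scheme)
    })
    names(X) <- names(conds)
    n_samples <- nrow(X$cb)
    chars <- spec$characteristics
    offset <- 0L
    assignment <- list()
    sigma_units <- rep(1, spec$n)
    Zc <- list(cb = matrix(0, spec$n, n_samples),
               ob = matrix(0, spec$n, nrow(X$ob)))
    for (nm in names(chars)) {
      cc <- chars[[nm]]
      n_ov <- round(cc$omega * cc$n_sel)
      span <- 2L * cc$n_sel - n_ov
      units <- offset + seq_len(span)
      sel <- list(cb = units[seq_len(cc$n_sel)],
                  ob = units[c(seq_len(n_ov), cc$n_sel + seq_len(cc$n_sel - n_ov))])
      for (cd in names(Zc))
        Zc[[cd]][sel[[cd]], ] <- Zc[[cd]][sel[[cd]], , drop = FALSE] +
          rep(X[[cd]][, nm], each = cc$n_sel)
      assignment[[nm]] <- sel
      sigma_units[units] <- cc$sigma
      offset <- offset + span
    }
    for (cd in names(Zc))
      Zc[[cd]] <- Zc[[cd]] + matrix(rnorm(length(Zc[[cd]]), 0, sigma_units),
                                    nrow(Zc[[cd]]))
    list(Z = Zc, x = X, assignment = assignment, spec = spec)
  })
}
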