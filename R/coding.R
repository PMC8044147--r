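#' Population of linear coding units
#'
#' A population of `n` linear units of which `n_sel` are "selective" to a
#' scalar stimulus characteristic `x`: selective units respond
#' \eqn{z_i = x + \varepsilon}, non-selective units are pure background
#' noise \eqn{\varepsilon \sim N(0, \sigma^2)} (i.i.d. across units and
#' samples; gains are fixed at 1 for selective units). The same population
#' simulated in two conditions shares a fraction `omega` of its selective
#' units (`round(omega * n_sel)` common indices): `omega` is the coding
#' similarity between conditions.
#'
#' @param n Total units (default 300).
#' @param n_sel Selective units per condition (default 100).
#' @param sigma Background-noise SD (scalar, or `c(a, b)` per condition).
#' @param omega Fraction of selective units shared across conditions.
#' @return An object of class `rl_population` with the per-condition
#'   selective index sets.
#' @export
#' @examples
#' pop <- coding_population(omega = 0.5)
#' length(intersect(pop$sel_a, pop$sel_b))  # 50
coding_population <- function(n = 300L, n_sel = 100L, sigma = 1, omega = 1) {
  stopifnot(omega >= 0, omega <= 1, n_sel >= 1, all(sigma >= 0))
  n <- as.integer(n); n_sel <- as.integer(n_sel)
  n_ov <- as.integer(round(omega * n_sel))
  if (n < 2L * n_sel - n_ov)
    stop("n too small for the requested overlap: need n >= 2*n_sel - round(omega*n_sel)")
  sigma <- rep_len(sigma, 2L)
  structure(list(n = n, n_sel = n_sel,
                 sigma = sigma, omega = omega,
                 sel_a = seq_len(n_sel),
                 sel_b = c(seq_len(n_ov),
                           seq_len(n_sel - n_ov) + n_sel)),
            class = "rl_population")
}

#' Simulate unit activity for one condition
#'
#' @param x Standardized stimulus characteristic, one value per sample.
#' @param population A [coding_population()].
#' @param condition `"a"` or `"b"` (which selective set and noise SD).
#' @param seed Optional seed.
#' @return Numeric matrix, `n` units x `length(x)` samples.
#' @export
simulate_population <- function(x, population, condition = c("a", "b"),
                                seed = NULL) {
  condition <- match.arg(condition)
  with_seed(seed, {
    sel <- if (condition == "a") population$sel_a else population$sel_b
    sigma <- population$sigma[if (condition == "a") 1L else 2L]
    Z <- matrix(rnorm(population$n * length(x), 0, sigma),
                population$n, length(x))
    Z[sel, ] <- Z[sel, , drop = FALSE] + rep(x, each = length(sel))
    Z
  })
}

cv_folds <- function(n_samples, n_folds) ((seq_len(n_samples) - 1L) %% n_folds) + 1L

# per-fold training statistics and univariate least-squares weights for
# all folds at once, via complement sums (train stats = totals minus the
# held-out fold), avoiding a full pass over the data per fold
encode_fold_stats <- function(Z, x, fold, n_folds) {
  n <- length(x)
  Fm <- matrix(0, n, n_folds)
  Fm[cbind(seq_len(n), fold)] <- 1
  n_f <- colSums(Fm)
  S1 <- Z %*% Fm                    # per-fold feature sums
  S2 <- (Z * Z) %*% Fm              # per-fold feature sums of squares
  P <- Z %*% (Fm * x)               # per-fold feature-x cross sums
  sx <- colSums(Fm * x)
  sx2 <- colSums(Fm * x^2)
  n_tr <- n - n_f
  mu <- sweep(rowSums(S1) - S1, 2, n_tr, `/`)
  varz <- sweep(pmax(rowSums(S2) - S2 - sweep(mu^2, 2, n_tr, `*`), 0),
                2, n_tr - 1, `/`)
  sdv <- sqrt(varz)
  zero <- sdv <= 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance feature(s): weight set to 0",
                    sum(colSums(zero) > 0)))
    sdv[zero] <- 1
  }
  xbar <- (sum(sx) - sx) / n_tr
  sxx <- (sum(sx2) - sx2) - n_tr * xbar^2
  num <- (rowSums(P) - P) - sweep(mu, 2, n_tr * xbar, `*`)
  w <- sweep(num / sdv, 2, sxx, `/`)
  w[zero] <- 0
  list(w = w, mu = mu, sd = sdv)
}

# legacy single-fold interface used by tests of degenerate inputs
encode_weights <- function(Z_train, x_train) {
  n <- ncol(Z_train)
  mu <- rowMeans(Z_train)
  sdv <- sqrt(pmax(rowSums(Z_train^2) - n * mu^2, 0) / (n - 1))
  zero <- sdv <= 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance feature(s): weight set to 0", sum(zero)))
    sdv[zero] <- 1
  }
  Zs <- (Z_train - mu) / sdv
  xc <- x_train - mean(x_train)
  w <- drop(Zs %*% xc) / sum(xc^2)
  w[zero] <- 0
  list(w = w, mu = mu, sd = sdv)
}

#' Cross-validated linear encoding precision
#'
#' Estimates, per interleaved cross-validation fold, a univariate
#' least-squares encoding weight for every feature (feature regressed
#' against the characteristic on the training folds, features
#' standardized on the training folds), projects the held-out data onto
#' the weight vector to obtain predictions \eqn{\hat x}, concatenates the
#' predictions across folds, and reports the Fisher transform of their
#' correlation with the true characteristic. The correlation is capped at
#' \eqn{1 - 10^{-12}} in magnitude so a perfect prediction maps to a
#' finite precision.
#'
#' @param Z Numeric matrix, features x samples.
#' @param x Characteristic, one value per sample.
#' @param n_folds Interleaved folds (default 12).
#' @param pool `"concatenate"` (one correlation over pooled predictions,
#'   the default) or `"average"` (mean of per-fold Fisher precisions).
#' @return List: `precision` (Fisher-z), `r`, `predictions`, `weights`
#'   (features x folds), `folds`.
#' @export
encode_cv <- function(Z, x, n_folds = 12L, pool = c("concatenate", "average")) {
  pool <- match.arg(pool)
  stopifnot(ncol(Z) == length(x), length(x) >= n_folds)
  fold <- cv_folds(length(x), n_folds)
  st <- encode_fold_stats(Z, x, fold, n_folds)
  pred <- numeric(length(x))
  W <- st$w
  for (f in seq_len(n_folds)) {
    te <- fold == f
    ws <- st$w[, f] / st$sd[, f]
    pred[te] <- drop(crossprod(Z[, te, drop = FALSE], ws)) -
      sum(ws * st$mu[, f])
  }
  cap <- function(r) sign(r) * pmin(abs(r), 1 - 1e-12)
  if (pool == "concatenate") {
    r <- cap(cor(pred, x))
    precision <- atanh(r)
  } else {
    rs <- vapply(seq_len(n_folds), function(f)
      cap(cor(pred[fold == f], x[fold == f])), numeric(1))
    precision <- mean(atanh(rs))
    r <- tanh(precision)
  }
  list(precision = precision, r = r, predictions = pred, weights = W,
       folds = fold)
}

# cross-condition variant: weights trained on condition "train",
# predictions computed on the matching fold of condition "test";
# identical train/test volumes as the within-condition analysis
encode_cv_cross <- function(Z_train_cond, x_train_cond, Z_test_cond,
                            x_test_cond, n_folds = 12L) {
  stopifnot(ncol(Z_train_cond) == ncol(Z_test_cond))
  fold <- cv_folds(length(x_train_cond), n_folds)
  st <- encode_fold_stats(Z_train_cond, x_train_cond, fold, n_folds)
  pred <- numeric(length(x_test_cond))
  for (f in seq_len(n_folds)) {
    te <- fold == f
    ws <- st$w[, f] / st$sd[, f]
    pred[te] <- drop(crossprod(Z_test_cond[, te, drop = FALSE], ws)) -
      sum(ws * st$mu[, f])
  }
  r <- sign(cor(pred, x_test_cond)) *
    min(abs(cor(pred, x_test_cond)), 1 - 1e-12)
  list(precision = atanh(r), r = r, predictions = pred)
}

#' Within- and between-condition coding precision
#'
#' The four coding-precision values of the cross-condition generalization
#' analysis: within condition a, within condition b, weights from a
#' applied to b, and weights from b applied to a, all computed with
#' identical training and test volumes (the same interleaved fold
#' structure in each direction).
#'
#' @param Z_a,Z_b Feature matrices (features x samples) per condition.
#' @param x_a,x_b Characteristic per condition (equal sample counts).
#' @param n_folds Interleaved folds.
#' @return An object of class `rl_precision`: numeric vector
#'   `c(within_a, within_b, a_to_b, b_to_a)` with the fold scheme as an
#'   attribute.
#' @export
precision_scores <- function(Z_a, Z_b, x_a, x_b, n_folds = 12L) {
  if (length(x_a) != length(x_b))
    stop("conditions must have the same sample count")
  out <- c(within_a = encode_cv(Z_a, x_a, n_folds)$precision,
           within_b = encode_cv(Z_b, x_b, n_folds)$precision,
           a_to_b = encode_cv_cross(Z_a, x_a, Z_b, x_b, n_folds)$precision,
           b_to_a = encode_cv_cross(Z_b, x_b, Z_a, x_a, n_folds)$precision)
  structure(out, class = "rl_precision", n_folds = n_folds)
}

#' Simulated precision quadruple at given similarity parameters
#'
#' @param omega Coding similarity.
#' @param sigma_a,sigma_b Background-noise SDs.
#' @param x_a,x_b Characteristics per condition.
#' @param n,n_sel Population size and selective count.
#' @param n_folds Folds.
#' @param seed Seed (common random numbers make the similarity-fit
#'   objective smooth).
#' @return Numeric vector `c(within_a, within_b, a_to_b, b_to_a)`.
#' @export
simulate_precision <- function(omega, sigma_a, sigma_b, x_a, x_b,
                               n = 300L, n_sel = 100L, n_folds = 12L,
                               seed = NULL) {
  with_seed(seed, {
    pop <- coding_population(n, n_sel, c(sigma_a, sigma_b), omega)
    Z_a <- simulate_population(x_a, pop, "a")
    Z_b <- simulate_population(x_b, pop, "b")
    as.numeric(precision_scores(Z_a, Z_b, x_a, x_b, n_folds))
  })
}

#' Fit coding similarity to observed precision values
#'
#' Least-squares fit of the three population parameters
#' \eqn{(\omega, \sigma_a, \sigma_b)} to an observed quadruple of within-
#' and between-condition precisions: candidate parameters are scored by
#' simulating the coding-unit population (with common random numbers so
#' the objective is smooth) and comparing the simulated quadruple to the
#' observed one. \eqn{\omega} is box-constrained to \[0, 1\] through a
#' logit transform.
#'
#' @param observed Numeric length-4 vector (or [precision_scores()]
#'   output): within_a, within_b, a_to_b, b_to_a.
#' @param x_a,x_b Characteristics used to simulate candidate populations.
#' @param n,n_sel,n_folds Population / fold settings.
#' @param n_rep Simulation replicates averaged per objective evaluation.
#' @param seed Seed for the common random numbers.
#' @return An object of class `rl_similarity_fit`: `omega`, `sigma_a`,
#'   `sigma_b`, `residual`, `predicted`, `observed`.
#' @export
fit_similarity <- function(observed, x_a, x_b, n = 300L, n_sel = 100L,
                           n_folds = 12L, n_rep = 1L, seed = 1L) {
  observed <- as.numeric(observed)
  stopifnot(length(observed) == 4)
  quad_at <- function(omega, sa, sb) {
    rowMeans(vapply(seq_len(n_rep), function(r)
      simulate_precision(omega, sa, sb, x_a, x_b, n, n_sel, n_folds,
                         seed = seed + r), numeric(4)))
  }
  obj <- function(par) {
    omega <- ilogit(par[1]); sa <- exp(par[2]); sb <- exp(par[3])
    sum((quad_at(omega, sa, sb) - observed)^2)
  }
  # stage 1: noise SDs by inverting the matched-filter precision
  # r = 1/sqrt(1 + sigma^2/n_sel) of the within-condition values
  r_w <- pmin(pmax(tanh(observed[1:2]), 0.05), 1 - 1e-9)
  sigma0 <- sqrt(n_sel * pmax(1 / r_w^2 - 1, 1e-4))
  # stage 2: coarse profile over omega at the stage-1 noise levels (the
  # objective is simulated with common random numbers, so it is smooth)
  omega_grid <- seq(0.01, 0.99, length.out = 15)
  vals <- vapply(omega_grid, function(o)
    obj(c(logit(o), log(sigma0))), numeric(1))
  omega0 <- omega_grid[which.min(vals)]
  # stage 3: Nelder-Mead polish of all three parameters
  fit <- optim(c(logit(omega0), log(sigma0)), obj, method = "Nelder-Mead",
               control = list(maxit = 150, reltol = 1e-6))
  omega <- ilogit(fit$par[1]); sa <- exp(fit$par[2]); sb <- exp(fit$par[3])
  structure(list(omega = omega, sigma_a = sa, sigma_b = sb,
                 residual = fit$value,
                 predicted = quad_at(omega, sa, sb),
                 observed = observed),
            class = "rl_similarity_fit")
}

#' @export
print.rl_similarity_fit <- function(x, ...) {
  cat(sprintf("<rl_similarity_fit> omega=%.3f sigma_a=%.3f sigma_b=%.3f (rss=%.4f)\n",
              x$omega, x$sigma_a, x$sigma_b, x$residual))
  invisible(x)
}

#' Cross-condition generalization plus similarity fit
#'
#' Convenience wrapper: computes the four precision values from two
#' condition datasets and fits \eqn{(\omega, \sigma_a, \sigma_b)} to them.
#'
#' @inheritParams precision_scores
#' @param ... Passed to [fit_similarity()].
#' @return List with `precision` ([precision_scores()]) and `fit`
#'   ([fit_similarity()]).
#' @export
generalize_and_fit <- function(Z_a, Z_b, x_a, x_b, n_folds = 12L, ...) {
  prec <- precision_scores(Z_a, Z_b, x_a, x_b, n_folds)
  fit <- fit_similarity(prec, x_a, x_b, n_folds = n_folds, ...)
  list(precision = prec, fit = fit)
}

#' Jackknifed similarity estimates
#'
#' Optional leave-one-out wrapper over a list of per-dataset precision
#' quadruples: refits the similarity parameters on each leave-one-out
#' mean quadruple.
#'
#' @param quadruples Numeric matrix, datasets x 4.
#' @param x_a,x_b Characteristics for the simulated populations.
#' @param ... Passed to [fit_similarity()].
#' @return Data frame of jackknifed `omega`, `sigma_a`, `sigma_b`.
#' @export
jackknife_similarity <- function(quadruples, x_a, x_b, ...) {
  quadruples <- as.matrix(quadruples)
  out <- lapply(seq_len(nrow(quadruples)), function(i) {
    fit <- fit_similarity(colMeans(quadruples[-i, , drop = FALSE]),
                          x_a, x_b, ...)
    data.frame(omega = fit$omega, sigma_a = fit$sigma_a,
               sigma_b = fit$sigma_b)
  })
  do.call(rbind, out)
}
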