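# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- function(p) log(p) - log1p(-p)
ilogit <- function(x) 1 / (1 + exp(-x))

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# clip log-odds before exponentials; transparent at behavioural scales
clip_logodds <- function(L, bound = 50) pmin(pmax(L, -bound), bound)

# circular distance on the pi-periodic orientation circle, in [0, pi/2]
circ_dist_pi <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

# truncated normal density / sampler / quantile (scalar parameters, vector x)
dtnorm <- function(x, mean, sd, lower, upper, log = FALSE) {
  z <- pnorm(upper, mean, sd) - pnorm(lower, mean, sd)
  d <- ifelse(x >= lower & x <= upper, dnorm(x, mean, sd) / z, 0)
  if (log) log(d) else d
}

rtnorm <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
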