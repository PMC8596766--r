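# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG
# stream. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Truncated normal sampling by inverse-CDF; exact, vectorised, no rejection.
rtnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- runif(n, plo, phi)
  q <- stats::qnorm(u, mean, sd)
  pmin(pmax(q, lower), upper)
}

# Dirichlet sample centred on `mean` with concentration parameter `conc`
# (alpha = conc * mean). conc = Inf gives the degenerate point mass at `mean`.
rdirichlet_mean <- function(n, mean, conc) {
  mean <- mean / sum(mean)
  if (!is.finite(conc)) {
    return(matrix(rep(mean, each = n), nrow = n))
  }
  k <- length(mean)
  g <- matrix(rgamma(n * k, shape = conc * rep(mean, each = n)), nrow = n)
  g / rowSums(g)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
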