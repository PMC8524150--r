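## Internal helpers: seeded evaluation, RT distributions, seed fan-out.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Ex-Gaussian deviates: normal(mu, sigma) + exponential(mean tau), truncated
# at zero by resampling (negligible mass for RT-scale parameters; a hard
# floor after 100 rounds guards pathological inputs).
rexgauss <- function(n, mu, sigma, tau) {
  x <- rnorm(n, mu, sigma) + if (tau > 0) rexp(n, 1 / tau) else 0
  for (i in seq_len(100)) {
    bad <- x < 0
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mu, sigma) + if (tau > 0) rexp(sum(bad), 1 / tau) else 0
  }
  pmax(x, 0)
}

# Normal deviates truncated at zero by resampling (same guard).
rnormPos <- function(n, mean, sd) {
  if (sd <= 0) return(rep(max(mean, 0), n))
  x <- rnorm(n, mean, sd)
  for (i in seq_len(100)) {
    bad <- x < 0
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmax(x, 0)
}

# Derive a stream of child seeds from one master seed; recorded alongside
# outputs so any subject/session can be re-simulated in isolation.
fanOutSeeds <- function(master_seed, n) {
  withSeed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# Mean of max(0, X - c) for X ~ Normal(mean, sd); sd = 0 collapses to
# max(0, mean - c). Used by the closed-form expected slope.
expectedPositivePart <- function(mean, sd, c = 0) {
  m <- mean - c
  if (sd <= 0) return(max(m, 0))
  z <- m / sd
  m * pnorm(z) + sd * dnorm(z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
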