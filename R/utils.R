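# Internal helpers shared across modules.

# Clip probabilities away from 0/1 before logit transforms.
clip_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# Deterministic per-unit substream seed derived from a master seed and a
# counter, so per-stay draws are stable when the cohort size changes.
# Kept below 2^31 - 1.
substream_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + as.double(counter) * 16807) %% 2147483629L)
}

# Truncated normal draw by rejection (bounds are loose; cheap at our scales).
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

# Ordinary least-squares slope of y on t (per hour); NA with < 2 distinct t.
ols_slope <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(NA_real_)
  st <- sum(t); sy <- sum(y)
  den <- n * sum(t * t) - st * st
  if (den <= .Machine$double.eps * n * max(1, max(abs(t)))^2) return(NA_real_)
  (n * sum(t * y) - st * sy) / den
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
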