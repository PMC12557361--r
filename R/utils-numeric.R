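# Log-space quadrature primitives shared by the acceleration profiles, the
# hazard models, the likelihood and the synthetic sampler. Everything that
# integrates exp(beta*V) goes through these so that identities such as
# "EATR at gamma = 1 equals k0 * tau_accel" hold to machine precision.
# beta*V can exceed 700, so plain exp() would overflow; all accumulation is
# done on shifted exponentials.

logAddExp <- function(x, y) {
  m <- pmax(x, y)
  out <- m + log1p(exp(-abs(x - y)))
  both <- is.infinite(m) & m < 0
  out[both] <- -Inf
  out
}

logSumExp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(if (m > 0) Inf else -Inf)
  m + log(sum(exp(x - m)))
}

# Trapezoid weights on an arbitrary strictly increasing grid: the integral of
# a piecewise-linear integrand is sum(w * f).
trapWeights <- function(t) {
  n <- length(t)
  d <- diff(t)
  w <- numeric(n)
  w[1L] <- d[1L] / 2
  w[n] <- d[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (d[-1L] + d[-(n - 1L)]) / 2
  w
}

# log of the cumulative trapezoid integral of exp(a(t)) at every grid point;
# exact running log-sum-exp (a short serial loop, robust to a spanning
# hundreds of log-units within one profile).
logCumTrapzExp <- function(t, a) {
  n <- length(t)
  L <- numeric(n)
  L[1L] <- -Inf
  if (n == 1L) return(L)
  inc <- log(diff(t) / 2) + logAddExp(a[-n], a[-1L])
  for (j in 2:n) L[j] <- logAddExp(L[j - 1L], inc[j - 1L])
  L
}

# Truncate a (time, value) grid at tStar, appending the linearly interpolated
# point. tStar must lie in (0, max(time)]. Returns list(t, v).
truncateGrid <- function(time, value, tStar) {
  n <- length(time)
  if (tStar >= time[n]) return(list(t = time, v = value))
  if (tStar <= time[1L])
    stop("evaluation time lies at or before the start of the grid")
  j <- findInterval(tStar, time)          # time[j] <= tStar < time[j+1]
  frac <- (tStar - time[j]) / (time[j + 1L] - time[j])
  vStar <- value[j] + frac * (value[j + 1L] - value[j])
  if (tStar == time[j]) return(list(t = time[seq_len(j)], v = value[seq_len(j)]))
  list(t = c(time[seq_len(j)], tStar), v = c(value[seq_len(j)], vStar))
}

# log of int_0^tStar exp(a(t)) dt with a piecewise-linear on the grid.
logTrapzExpAt <- function(time, a, tStar) {
  g <- truncateGrid(time, a, tStar)
  logSumExp(log(trapWeights(g$t)) + g$v)
}
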