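# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

# Deterministic fan-out of a master seed into per-task child seeds.
# Keeps every derived seed inside 32-bit integer range.
fanout_seed <- function(master_seed, k) {
  stopifnot(length(master_seed) == 1, length(k) >= 1)
  m <- 2147483647
  s <- (as.double(master_seed) %% m)
  vapply(k, function(ki) {
    as.integer((s * 48271 + 12345 + 1000003 * as.double(ki)) %% m)
  }, integer(1))
}

# Indices of strict local maxima of x (interior points only).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

local_minima <- function(x) local_maxima(-x)

# Analytic-signal envelope via FFT (Hilbert transform).
envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Trapezoidal integral of y sampled at spacing dt.
trapz_int <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(0)
  dt * sum((y[-1] + y[-n]) / 2)
}
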