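# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring caller RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministically expand one seed into n independent stream seeds.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Analytic signal of a real vector via one-sided spectrum (FFT method).
analytic_signal <- function(x) {
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
  stats::fft(X * h, inverse = TRUE) / n
}

# Band-limited (FFT zero-padding) upsampling by an integer factor U.
# Original sample values are reproduced exactly at their grid points.
fft_upsample <- function(x, U = 4L) {
  n <- length(x)
  m <- n * U
  X <- stats::fft(x)
  Y <- complex(m)
  h <- n %/% 2
  Y[1:h] <- X[1:h]
  Y[h + 1] <- X[h + 1] / 2            # split the Nyquist bin
  Y[m - h + 1] <- Conj(X[h + 1]) / 2
  if (h > 1) Y[(m - h + 2):m] <- X[(h + 2):n]
  Re(stats::fft(Y, inverse = TRUE)) * U / m
}

# Gaussian smoothing of a vector, sigma in samples; edges replicated.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, kern, sides = 2))[(half + 1):(half + length(x))]
}

# Parabolic refinement of a local extremum at index i of y; returns
# list(x = sub-sample index, y = refined value).
parabolic_peak <- function(y, i) {
  n <- length(y)
  if (i <= 1 || i >= n) return(list(x = i, y = y[i]))
  d <- (y[i - 1] - 2 * y[i] + y[i + 1])
  if (d == 0) return(list(x = i, y = y[i]))
  dx <- 0.5 * (y[i - 1] - y[i + 1]) / d
  list(x = i + dx, y = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * dx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
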