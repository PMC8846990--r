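# Multilevel wavelet machinery for the baseline-wander estimator. The
# analysis low-pass filter is a Meyer-type filter generated numerically:
# the Meyer frequency response, built from the auxiliary polynomial
# nu(t) = t^4 (35 - 84 t + 70 t^2 - 20 t^3), is sampled on a fine grid,
# inverse-Fourier-transformed and truncated to 62 taps (the conventional
# length for the discretized Meyer filter).
#
# The decomposition itself is the undecimated (a-trous) form: the level-L
# approximation band is the cascade of the scaling filter dilated by
# 2^0, 2^1, ..., 2^(L-1), applied zero-phase. Because the Meyer response is
# flat below one third of each stage's band edge and zero above two thirds,
# the cascade's total response equals the Meyer scaling-function spectrum
# with no spectral leaks, and unlike the decimated transform it remains
# numerically exact at arbitrary depth on short records. The cascade is
# evaluated in the frequency domain on a reflect-padded copy of the signal.

.pkg_cache <- new.env(parent = emptyenv())

meyer_aux <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3)
}

#' Meyer-type wavelet analysis filter
#'
#' Low-pass (scaling) filter taps of the discretized Meyer wavelet,
#' generated numerically from the Meyer frequency response.
#'
#' @param ntaps Filter length (even), default 62.
#' @return Numeric vector of `ntaps` coefficients summing to `sqrt(2)`.
#' @keywords internal
meyer_scaling_filter <- function(ntaps = 62L) {
  key <- paste0("meyer_", ntaps)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  ngrid <- 2^14
  omega <- 2 * pi * (seq_len(ngrid) - 1L) / ngrid
  omega <- ifelse(omega > pi, 2 * pi - omega, omega)  # symmetric response
  m0 <- ifelse(omega <= pi / 3, 1,
               ifelse(omega >= 2 * pi / 3, 0,
                      cos(pi / 2 * meyer_aux(3 * omega / pi - 1))))
  h_full <- Re(fft(m0, inverse = TRUE)) / ngrid * sqrt(2)
  # impulse response is centered at lag 0; take taps -ntaps/2 .. ntaps/2 - 1
  lags <- seq.int(-ntaps %/% 2L, ntaps %/% 2L - 1L)
  h <- h_full[(lags %% ngrid) + 1L]
  h <- h * sqrt(2) / sum(h)  # exact DC gain after truncation
  .pkg_cache[[key]] <- h
  h
}

# Zero-phase frequency response of the scaling filter (unit DC gain) at
# angular frequencies `omega`. The taps cover lags -ntaps/2 .. ntaps/2 - 1
# of the symmetric Meyer impulse response, so lag zero sits at tap index
# ntaps/2 and centering there makes the response real (zero phase).
meyer_freq_response <- function(omega, h) {
  lags <- seq_along(h) - 1 - length(h) / 2
  resp <- exp(-1i * outer(omega, lags)) %*% (h / sqrt(2))
  as.vector(resp)
}

# Reflect-pad x at the end up to the next power of two (keeps the circular
# FFT evaluation free of wrap-around artifacts). Callers crop back to n.
pad_dyadic <- function(x) {
  n <- length(x)
  npad <- 2^ceiling(log2(n))
  if (npad == n) return(x)
  extra <- npad - n
  refl <- x[seq.int(n - 1L, by = -1L, length.out = min(extra, n - 1L))]
  while (length(refl) < extra) {
    refl <- c(refl, refl[seq_len(min(extra - length(refl), length(refl)))])
  }
  c(x, refl)
}

# Level-`levels` approximation-band reconstruction of x (undecimated
# cascade, zero phase). Input length must be even (dyadic preferred).
approx_band <- function(x, levels, h = meyer_scaling_filter()) {
  n <- length(x)
  key <- sprintf("cascade_%d_%d_%d", n, levels, length(h))
  total <- .pkg_cache[[key]]
  if (is.null(total)) {
    omega <- 2 * pi * (seq_len(n) - 1L) / n
    total <- rep(1 + 0i, n)
    for (j in seq_len(levels) - 1L) {
      total <- total * meyer_freq_response(2^j * omega, h)
    }
    .pkg_cache[[key]] <- total
  }
  Re(fft(fft(x) * total, inverse = TRUE)) / n
}
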