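#' Entropy estimator configuration
#'
#' Bundles the parameters shared by the four single-scale estimators and
#' their refined composite multiscale versions. Defaults follow the standard
#' recommendations for pulse-wave complexity analysis: embedding dimension
#' `m` of 3, tolerance of 0.15 times the signal SD, fuzzy membership
#' exponent `n = 2`, `c = 6` dispersion classes and unit delay.
#'
#' @param m Embedding dimension (template/pattern length), integer `>= 1`.
#' @param r_factor Tolerance as a multiple of the signal standard deviation,
#'   `> 0`. Used by sample and fuzzy entropy.
#' @param fuzzy_power Exponent `n` of the fuzzy membership function
#'   `exp(-(d/r)^n)`, `> 0`.
#' @param n_classes Number of amplitude classes `c` for dispersion entropy,
#'   integer `>= 2`.
#' @param delay Embedding delay `d` (samples), integer `>= 1`. Applies to the
#'   pattern-based estimators (permutation, dispersion).
#'
#' @return An object of class `entropy_params`.
#' @examples
#' entropy_params()
#' entropy_params(m = 2, r_factor = 0.2)
#' @export
entropy_params <- function(m = 3L, r_factor = 0.15, fuzzy_power = 2,
                           n_classes = 6L, delay = 1L) {
  m <- as.integer(m); n_classes <- as.integer(n_classes); delay <- as.integer(delay)
  stopifnot(m >= 1L, is_scalar_number(r_factor), r_factor > 0,
            is_scalar_number(fuzzy_power), fuzzy_power > 0,
            n_classes >= 2L, delay >= 1L)
  structure(list(m = m, r_factor = r_factor, fuzzy_power = fuzzy_power,
                 n_classes = n_classes, delay = delay),
            class = "entropy_params")
}

#' @export
print.entropy_params <- function(x, ...) {
  cat("Entropy parameters: m =", x$m, ", r =", x$r_factor,
      "* SD, n =", x$fuzzy_power, ", c =", x$n_classes, ", delay =", x$delay, "\n")
  invisible(x)
}

#' Pulse record container
#'
#' A single-channel pressure-pulse time series with its sampling rate and
#' subject metadata. Loaders reject non-finite samples so downstream code can
#' assume a clean numeric vector.
#'
#' @param samples Numeric vector of amplitudes (arbitrary pressure units).
#' @param fs Sampling rate in Hz (`> 0`). Default 200.
#' @param subject_id Opaque subject identifier.
#' @param sex One of `"male"`, `"female"`, `"unknown"`.
#' @param hand One of `"left"`, `"right"`, `"unknown"`.
#'
#' @return An object of class `pulse_record`.
#' @examples
#' rec <- pulse_record(sin(seq(0, 10, by = 0.005)), fs = 200)
#' length(rec$samples)
#' @export
pulse_record <- function(samples, fs = 200, subject_id = "anon",
                         sex = c("unknown", "male", "female"),
                         hand = c("unknown", "left", "right")) {
  sex <- match.arg(sex); hand <- match.arg(hand)
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("pulse record must contain at least one sample")
  if (any(!is.finite(samples))) stop("pulse record contains non-finite samples")
  stopifnot(is_scalar_number(fs), fs > 0)
  structure(list(samples = samples, fs = fs, subject_id = as.character(subject_id),
                 sex = sex, hand = hand),
            class = "pulse_record")
}

#' @export
print.pulse_record <- function(x, ...) {
  cat(sprintf("Pulse record '%s' (%s, %s hand): %d samples @ %g Hz (%.2f s)\n",
              x$subject_id, x$sex, x$hand, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

as_pulse_record <- function(x) {
  if (inherits(x, "pulse_record")) return(x)
  if (is.numeric(x)) return(pulse_record(x))
  stop("cannot interpret input as a pulse record")
}
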