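# Single-scale entropy estimators: sample entropy (SaEn), fuzzy entropy
# (FuEn), permutation entropy (PeEn) and dispersion entropy (DiEn).
#
# Conventions shared by all four:
#   * natural logarithms everywhere; PeEn is normalized by ln(m!) and DiEn
#     by ln(c^m), so both lie in [0, 1];
#   * 0 * ln(0) is taken as 0 in every Shannon sum;
#   * template starting indices run i = 1..N-m for both the m- and
#     (m+1)-length templates, keeping the two pair sets comparable;
#   * an undefined sample entropy (no matched pairs at either length) is a
#     first-class NA return, not an error -- the refined composite
#     multiscale framework exists precisely to make it rare.

series_of <- function(x) {
  if (inherits(x, "pulse_record")) x$samples else as.numeric(x)
}

resolve_tolerance <- function(x, params, r_absolute) {
  if (!is.null(r_absolute)) {
    stopifnot(is_scalar_number(r_absolute), r_absolute > 0)
    return(r_absolute)
  }
  s <- sd(x)
  if (s == 0)
    stop("constant series: tolerance r = r_factor * SD would be zero; ",
         "supply r_absolute instead")
  params$r_factor * s
}

#' Chebyshev (infinity-norm) distance
#'
#' Maximum absolute componentwise difference between two equal-length
#' vectors; the distance used for template matching in sample and fuzzy
#' entropy.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A single non-negative number.
#' @examples
#' chebyshev_distance(c(1, 5), c(2, 3))  # 2
#' @export
chebyshev_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  max(abs(u - v))
}

#' Sample entropy
#'
#' `SaEn = -ln(A / B)` where `B` is the number of template pairs of length
#' `m` within Chebyshev distance `r` (self-matches excluded) and `A` the
#' same count for length `m + 1`. Returns `NA` (the distinguished
#' "undefined" value) when either count is zero.
#'
#' @param x Numeric series or [pulse_record]; needs `length(x) >= m + 2`.
#' @param params An [entropy_params()].
#' @param r_absolute Optional absolute tolerance overriding
#'   `r_factor * sd(x)` (needed e.g. for constant series).
#' @return A non-negative number, or `NA` when undefined.
#' @examples
#' sample_entropy(rnorm(200))
#' @export
sample_entropy <- function(x, params = entropy_params(), r_absolute = NULL) {
  x <- series_of(x)
  m <- params$m
  if (length(x) < m + 2L) stop("series too short: need N >= m + 2")
  r <- resolve_tolerance(x, params, r_absolute)
  cnt <- sampen_pair_counts(x, m, r)
  if (cnt[["a"]] == 0 || cnt[["b"]] == 0) return(NA_real_)
  -log(cnt[["a"]] / cnt[["b"]])
}

#' Fuzzy entropy
#'
#' Same pipeline as [sample_entropy()], but each crisp match is replaced by
#' the graded membership `exp(-(d/r)^n)` summed over template pairs, making
#' the estimate continuous in the tolerance. Always finite for
#' `length(x) >= m + 2` since memberships are strictly positive.
#'
#' @inheritParams sample_entropy
#' @return A non-negative number.
#' @examples
#' fuzzy_entropy(rnorm(200))
#' @export
fuzzy_entropy <- function(x, params = entropy_params(), r_absolute = NULL) {
  x <- series_of(x)
  m <- params$m
  if (length(x) < m + 2L) stop("series too short: need N >= m + 2")
  r <- resolve_tolerance(x, params, r_absolute)
  s <- fuzzy_pair_sums(x, m, r, params$fuzzy_power)
  -log(s[["a"]] / s[["b"]])
}

#' Ordinal pattern of a window
#'
#' The permutation of indices that sorts the window ascending; ties are
#' broken by original index order (stable sort), the common deterministic
#' convention.
#'
#' @param window Numeric vector of length `m`.
#' @return An integer vector: the sorting permutation.
#' @examples
#' ordinal_pattern(c(9, 1, 5))  # 2 3 1
#' ordinal_pattern(c(2, 2, 1))  # 3 1 2
#' @export
ordinal_pattern <- function(window) {
  order(window)  # radix order is stable: ties keep index order
}

# Rank vectors of all embedded windows, stable in ties, fully vectorized:
# rank_j = 1 + #{k : w_k < w_j, or w_k == w_j and k < j}.
window_ranks <- function(x, m, d) {
  n_win <- length(x) - (m - 1L) * d
  W <- matrix(0, n_win, m)
  for (j in seq_len(m)) W[, j] <- x[seq_len(n_win) + (j - 1L) * d]
  R <- matrix(1L, n_win, m)
  for (j in seq_len(m)) for (k in seq_len(m)) {
    if (k == j) next
    if (k < j) R[, j] <- R[, j] + (W[, k] <= W[, j])
    else       R[, j] <- R[, j] + (W[, k] <  W[, j])
  }
  R
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Permutation entropy
#'
#' Shannon entropy of the relative frequencies of ordinal patterns over all
#' `N - (m-1) d` embedded windows, normalized by `ln(m!)` to lie in
#' `[0, 1]`. Depends only on the order structure of the series, so it is
#' invariant under any strictly increasing amplitude transform.
#'
#' @param x Numeric series or [pulse_record].
#' @param params An [entropy_params()]; uses `m` and `delay`.
#' @return A number in `[0, 1]`.
#' @examples
#' permutation_entropy(1:100)        # 0: a monotone series is fully regular
#' permutation_entropy(rnorm(1000))  # close to 1
#' @export
permutation_entropy <- function(x, params = entropy_params()) {
  x <- series_of(x)
  m <- params$m; d <- params$delay
  n_win <- length(x) - (m - 1L) * d
  if (n_win < 2L) stop("series too short: need N - (m-1)*d >= 2")
  R <- window_ranks(x, m, d)
  code <- as.vector((R - 1L) %*% m^(seq_len(m) - 1L))
  p <- tabulate(code + 1L, nbins = m^m)
  p <- p / n_win
  shannon(p) / log(factorial(m))
}

#' Map a series to dispersion classes
#'
#' Amplitudes are passed through the normal cumulative distribution function
#' (fitted by the series mean and SD) and the resulting `y` in (0, 1) is
#' linearly assigned to integer classes `round(c * y + 0.5)` (round half
#' away from zero), clipped to `1..c`.
#'
#' @param x Numeric series with positive SD.
#' @param n_classes Number of classes `c`.
#' @return Integer vector of classes in `1..c`.
#' @examples
#' table(dispersion_map(rnorm(1000), 6))
#' @export
dispersion_map <- function(x, n_classes = 6L) {
  x <- series_of(x)
  s <- sd(x)
  if (s == 0) stop("constant series cannot be dispersion-mapped (zero SD)")
  y <- pnorm((x - mean(x)) / s)
  z <- floor(n_classes * y + 0.5 + 0.5)  # round-half-away of c*y + 0.5
  as.integer(pmin(pmax(z, 1), n_classes))
}

#' Dispersion entropy
#'
#' The class series from [dispersion_map()] is embedded with dimension `m`
#' and delay `d`; the Shannon entropy of the relative frequencies of the
#' `c^m` dispersion patterns is normalized by `ln(c^m)` to lie in `[0, 1]`.
#'
#' @param x Numeric series or [pulse_record] with positive SD.
#' @param params An [entropy_params()]; uses `m`, `n_classes`, `delay`.
#' @return A number in `[0, 1]`.
#' @examples
#' dispersion_entropy(rnorm(1000))
#' @export
dispersion_entropy <- function(x, params = entropy_params()) {
  x <- series_of(x)
  p <- dispersion_distribution(x, params)
  shannon(p) / log(as.double(params$n_classes)^params$m)
}

# Relative frequencies over the c^m dispersion patterns (internal; shared
# with the refined composite pathway, which averages these distributions).
dispersion_distribution <- function(x, params) {
  n_win <- length(x) - (params$m - 1L) * params$delay
  if (n_win < 2L) stop("series too short: need N - (m-1)*d >= 2")
  z <- dispersion_map(x, params$n_classes)
  class_pattern_distribution(z, params$m, params$delay, params$n_classes)
}

# Dispersion-pattern relative frequencies of an already-classified series.
class_pattern_distribution <- function(z, m, d, cc) {
  n_win <- length(z) - (m - 1L) * d
  if (n_win < 2L) stop("series too short: need N - (m-1)*d >= 2")
  code <- integer(n_win)
  for (j in seq_len(m))
    code <- code + (z[seq_len(n_win) + (j - 1L) * d] - 1L) * cc^(j - 1L)
  tabulate(code + 1L, nbins = cc^m) / n_win
}

# Relative frequencies over ordinal-pattern codes (internal; shared with
# the refined composite pathway). Codes index a superset of size m^m; the
# mapping from rank vectors is injective, which is all a Shannon sum needs.
permutation_distribution <- function(x, params) {
  m <- params$m; d <- params$delay
  n_win <- length(x) - (m - 1L) * d
  if (n_win < 2L) stop("series too short: need N - (m-1)*d >= 2")
  R <- window_ranks(x, m, d)
  code <- as.vector((R - 1L) %*% m^(seq_len(m) - 1L))
  tabulate(code + 1L, nbins = m^m) / n_win
}
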