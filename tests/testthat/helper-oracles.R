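# Independent brute-force oracles, written directly from the estimator
# definitions: explicit template matrices and pairwise distance enumeration,
# full pattern tabulation by string key, and explicit offset-series
# construction for the refined composite pathway. Deliberately naive -- they
# share no code with the package implementation.

embed_templates <- function(x, m) {
  n_t <- length(x) - m  # starting indices 1..N-m for both lengths
  t(vapply(seq_len(n_t), function(i) x[i:(i + m - 1)], numeric(m)))
}

pair_counts_bf <- function(x, m, r, fuzzy = FALSE, fuzzy_n = 2) {
  n_t <- length(x) - m
  Tm <- embed_templates(x, m)
  Tm1 <- t(vapply(seq_len(n_t), function(i) x[i:(i + m)], numeric(m + 1)))
  a <- 0; b <- 0
  for (i in seq_len(n_t - 1)) {
    for (j in (i + 1):n_t) {
      dm <- max(abs(Tm[i, ] - Tm[j, ]))
      dm1 <- max(abs(Tm1[i, ] - Tm1[j, ]))
      if (fuzzy) {
        b <- b + exp(-(dm / r)^fuzzy_n)
        a <- a + exp(-(dm1 / r)^fuzzy_n)
      } else {
        if (dm <= r) b <- b + 1
        if (dm1 <= r) a <- a + 1
      }
    }
  }
  c(a = a, b = b)
}

sampen_bf <- function(x, m, r) {
  cnt <- pair_counts_bf(x, m, r, fuzzy = FALSE)
  if (cnt["a"] == 0 || cnt["b"] == 0) return(NA_real_)
  -log(cnt[["a"]] / cnt[["b"]])
}

fuzen_bf <- function(x, m, r, fuzzy_n = 2) {
  cnt <- pair_counts_bf(x, m, r, fuzzy = TRUE, fuzzy_n = fuzzy_n)
  -log(cnt[["a"]] / cnt[["b"]])
}

pattern_table_bf <- function(keys) {
  tab <- table(keys)
  as.numeric(tab) / length(keys)
}

ordinal_keys_bf <- function(x, m, d) {
  n_win <- length(x) - (m - 1) * d
  vapply(seq_len(n_win), function(i) {
    w <- x[i + (0:(m - 1)) * d]
    paste(order(w), collapse = "-")
  }, character(1))
}

peen_bf <- function(x, m, d = 1) {
  p <- pattern_table_bf(ordinal_keys_bf(x, m, d))
  -sum(p * log(p)) / log(factorial(m))
}

dispersion_classes_bf <- function(x, n_classes) {
  y <- pnorm((x - mean(x)) / sd(x))
  z <- floor(n_classes * y + 1)  # round-half-away of c*y + 0.5
  pmin(pmax(z, 1), n_classes)
}

dispersion_keys_bf <- function(x, m, n_classes, d) {
  z <- dispersion_classes_bf(x, n_classes)
  n_win <- length(z) - (m - 1) * d
  vapply(seq_len(n_win), function(i)
    paste(z[i + (0:(m - 1)) * d], collapse = "-"), character(1))
}

dien_bf <- function(x, m, n_classes, d = 1) {
  p <- pattern_table_bf(dispersion_keys_bf(x, m, n_classes, d))
  -sum(p * log(p)) / log(n_classes^m)
}

# Explicit offset coarse-grained series, straight from the definition.
offset_series_bf <- function(x, tau, k) {
  n_win <- (length(x) - k + 1) %/% tau
  vapply(seq_len(n_win), function(j)
    mean(x[((j - 1) * tau + k):(j * tau + k - 1)]), numeric(1))
}

rc_template_bf <- function(x, m, r, tau, fuzzy = FALSE, fuzzy_n = 2) {
  a <- 0; b <- 0
  for (k in seq_len(tau)) {
    cnt <- pair_counts_bf(offset_series_bf(x, tau, k), m, r,
                          fuzzy = fuzzy, fuzzy_n = fuzzy_n)
    a <- a + cnt[["a"]]; b <- b + cnt[["b"]]
  }
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

rc_pattern_bf <- function(x, m, tau, d = 1, n_classes = NULL) {
  # averaged pattern distributions across offsets; keys unify the support
  keys_by_k <- lapply(seq_len(tau), function(k) {
    y <- offset_series_bf(x, tau, k)
    if (is.null(n_classes)) ordinal_keys_bf(y, m, d)
    else dispersion_keys_bf(y, m, n_classes, d)
  })
  support <- unique(unlist(keys_by_k))
  p_bar <- rowMeans(vapply(keys_by_k, function(keys) {
    counts <- table(factor(keys, levels = support))
    as.numeric(counts) / length(keys)
  }, numeric(length(support))))
  h <- -sum(p_bar[p_bar > 0] * log(p_bar[p_bar > 0]))
  norm <- if (is.null(n_classes)) log(factorial(m)) else log(n_classes^m)
  h / norm
}

# Assorted test signals with mixed character, for parameterised oracle runs.
random_test_series <- function(n, kind, seed) {
  set.seed(seed)
  switch(kind,
    gauss = rnorm(n),
    uniform = runif(n, -1, 1),
    ar1 = as.numeric(stats::arima.sim(list(ar = 0.8), n)),
    logistic = {
      x0 <- runif(1, 0.1, 0.9)
      for (i in 1:100) x0 <- 4 * x0 * (1 - x0)
      out <- numeric(n)
      for (i in seq_len(n)) { x0 <- 4 * x0 * (1 - x0); out[i] <- x0 }
      out
    },
    sine_noise = sin(seq_len(n) / 5) + 0.3 * rnorm(n))
}

series_kinds <- c("gauss", "uniform", "ar1", "logistic", "sine_noise")

# One-sided power fraction below f_hi (Hz) from the raw periodogram.
power_fraction_below <- function(x, fs, f_hi) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f <= fs / 2
  sum(p[keep & f < f_hi]) / sum(p[keep])
}

# Power at a single frequency (nearest bin).
power_at <- function(x, fs, f0) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(fft(x))^2
  k <- round(f0 * n / fs) + 1
  p[k]
}
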