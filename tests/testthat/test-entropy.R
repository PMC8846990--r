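test_that("chebyshev distance matches the componentwise maximum", {
  expect_equal(chebyshev_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(chebyshev_distance(c(1, 5), c(2, 3)), 2)
  expect_error(chebyshev_distance(1:3, 1:4), "equal length")
  set.seed(2)
  for (i in 1:20) {
    u <- rnorm(5); v <- rnorm(5)
    expect_equal(chebyshev_distance(u, v), max(abs(u - v)))
  }
})

test_that("constant series give zero sample and fuzzy entropy with absolute r", {
  x <- rep(5, 50)
  expect_equal(sample_entropy(x, r_absolute = 0.1), 0)
  expect_equal(fuzzy_entropy(x, r_absolute = 0.1), 0)
  # without an absolute tolerance the SD-relative r would be zero
  expect_error(sample_entropy(x), "constant")
})

test_that("sample entropy matches the brute-force oracle", {
  p <- entropy_params(m = 3, r_factor = 0.15)
  x <- as.numeric(1:50)
  expect_equal(sample_entropy(x, p), sampen_bf(x, 3, 0.15 * sd(x)),
               tolerance = 1e-12)
  set.seed(10)
  for (i in 1:5) {
    y <- rnorm(120)
    expect_equal(sample_entropy(y, p), sampen_bf(y, 3, 0.15 * sd(y)),
                 tolerance = 1e-12)
  }
  expect_error(sample_entropy(rnorm(4), entropy_params(m = 3)), "short")
})

test_that("fuzzy entropy matches the brute-force oracle and is finite", {
  p <- entropy_params()
  set.seed(11)
  y <- rnorm(200)
  expect_equal(fuzzy_entropy(y, p), fuzen_bf(y, 3, 0.15 * sd(y)),
               tolerance = 1e-12)
  expect_true(is.finite(fuzzy_entropy(rnorm(10), p)))
})

test_that("fuzzy entropy is continuous in r where sample entropy can jump", {
  set.seed(12)
  y <- rnorm(150)
  r0 <- 0.15 * sd(y)
  rs <- seq(0.95, 1.05, length.out = 21) * r0
  fu <- vapply(rs, function(r) fuzzy_entropy(y, r_absolute = r), numeric(1))
  # over a 0.5% step in r the fuzzy estimate moves smoothly, and halving
  # the step roughly halves the largest move (Lipschitz behaviour)
  expect_lt(max(abs(diff(fu))), 0.05)
  expect_lt(max(abs(diff(fu))), 0.6 * max(abs(diff(fu[seq(1, 21, by = 2)]))))
})

test_that("ordinal patterns sort ascending with stable ties", {
  expect_equal(ordinal_pattern(c(1, 2, 3)), c(1L, 2L, 3L))
  expect_equal(ordinal_pattern(c(9, 1, 5)), c(2L, 3L, 1L))
  expect_equal(ordinal_pattern(c(2, 2, 1)), c(3L, 1L, 2L))
  set.seed(13)
  for (i in 1:20) {
    w <- sample(1:4, 5, replace = TRUE)  # force ties
    expect_equal(ordinal_pattern(w), sort.list(w, method = "radix"))
  }
})

test_that("permutation entropy: regular, hand-enumerated and asymptotic cases", {
  expect_equal(permutation_entropy(1:100, entropy_params(m = 3)), 0)
  expect_equal(permutation_entropy(1:100, entropy_params(m = 5)), 0)

  # 6 ordinal pairs: 4 ascents, 2 descents
  x <- c(4, 7, 9, 10, 6, 11, 3)
  want <- (-(4 / 6) * log(4 / 6) - (2 / 6) * log(2 / 6)) / log(2)
  expect_equal(permutation_entropy(x, entropy_params(m = 2)), want,
               tolerance = 1e-12)

  set.seed(14)
  u <- runif(1e5)
  expect_gt(permutation_entropy(u, entropy_params(m = 3)), 0.99)
})

test_that("permutation entropy matches the oracle including delays and ties", {
  p2 <- entropy_params(m = 3, delay = 2)
  set.seed(15)
  for (i in 1:5) {
    y <- rnorm(100)
    expect_equal(permutation_entropy(y, p2), peen_bf(y, 3, 2), tolerance = 1e-12)
    yt <- sample(1:5, 100, replace = TRUE)  # heavy ties
    expect_equal(permutation_entropy(yt, entropy_params(m = 3)),
                 peen_bf(yt, 3, 1), tolerance = 1e-12)
  }
})

test_that("dispersion mapping lands in 1..c with near-uniform occupancy", {
  set.seed(16)
  x <- rnorm(1e5)
  z <- dispersion_map(x, 6)
  expect_true(all(z %in% 1:6))
  # NCDF with fitted mean/SD makes classes equiprobable for normal data
  frac <- tabulate(z, 6) / length(z)
  expect_true(all(abs(frac - 1 / 6) < 0.02))
  # symmetric data: median samples fall in the middle classes
  med_class <- z[abs(x - median(x)) < 0.01]
  expect_true(all(med_class %in% 3:4))
  expect_error(dispersion_map(rep(2, 10), 6), "constant")
})

test_that("dispersion entropy matches the oracle and its degenerate limits", {
  p <- entropy_params(m = 3, n_classes = 6)
  x <- as.numeric(1:1000)
  expect_equal(dispersion_entropy(x, p), dien_bf(x, 3, 6), tolerance = 1e-12)
  set.seed(17)
  y <- rnorm(500)
  expect_equal(dispersion_entropy(y, p), dien_bf(y, 3, 6), tolerance = 1e-12)
  expect_gt(dispersion_entropy(rnorm(1e4), p), 0.85)
  expect_lt(dispersion_entropy(rnorm(1e4), p), 1)

  # a constant class sequence has a single pattern, hence zero entropy
  dist <- pulsentropy:::class_pattern_distribution(rep(3L, 100), 3, 1, 6)
  expect_equal(-sum(dist[dist > 0] * log(dist[dist > 0])), 0)
})

test_that("amplitude invariances hold across the four measures", {
  set.seed(18)
  x <- rnorm(300)
  y <- 2.5 * x + 7  # affine, positive slope
  p <- entropy_params()
  expect_equal(sample_entropy(x, p), sample_entropy(y, p), tolerance = 1e-10)
  expect_equal(fuzzy_entropy(x, p), fuzzy_entropy(y, p), tolerance = 1e-10)
  expect_identical(permutation_entropy(x, p), permutation_entropy(y, p))
  expect_equal(dispersion_entropy(x, p), dispersion_entropy(y, p),
               tolerance = 1e-10)
  # any strictly increasing transform preserves ordinal structure
  expect_identical(permutation_entropy(x, p), permutation_entropy(exp(x), p))
})

test_that("normalized measures stay within their bounds", {
  set.seed(19)
  p <- entropy_params()
  for (i in 1:10) {
    y <- random_test_series(150, series_kinds[(i %% 5) + 1], seed = 100 + i)
    pe <- permutation_entropy(y, p)
    de <- dispersion_entropy(y, p)
    expect_gte(pe, 0); expect_lte(pe, 1)
    expect_gte(de, 0); expect_lte(de, 1)
    fe <- fuzzy_entropy(y, p)
    expect_gte(fe, -1e-12)
    se <- sample_entropy(y, p)
    if (!is.na(se)) expect_gte(se, -1e-12)
  }
  # chaotic but deterministic: strictly inside (0, 1)
  lx <- generate_reference("logistic_map", 2000, seed = 20)$samples
  pe <- permutation_entropy(lx, p)
  expect_gt(pe, 0); expect_lt(pe, 1)
})
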