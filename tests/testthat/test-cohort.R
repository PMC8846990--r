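test_that("normality gate holds its level and detects skew", {
  level_p <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    normality_check(rnorm(100))$p_value
  }, numeric(1))
  expect_gte(mean(level_p > 0.05), 0.90)

  skew_p <- vapply(1:100, function(s) {
    set.seed(2000 + s)
    normality_check(rexp(100))$p_value
  }, numeric(1))
  expect_gte(mean(skew_p < 0.05), 0.90)

  expect_error(normality_check(c(1, 2)), "3 <= n")
})

test_that("group comparison: null identity, power and summary algebra", {
  set.seed(40)
  a <- rnorm(30)
  same <- compare_groups(a, a)
  expect_equal(same$p_value, 1)
  expect_equal(same$statistic, 0)

  # d = 1 at n = 100: essentially always detected
  hits <- vapply(1:100, function(s) {
    set.seed(3000 + s)
    compare_groups(rnorm(100), rnorm(100, 1))$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.99)

  # pooled t reconstructed from (mean, sd, n) equals t from raw data
  b <- rnorm(25, 0.4)
  cmp <- compare_groups(a, b)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * sd(a)^2 + (nb - 1) * sd(b)^2) / (na + nb - 2)
  t_summary <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  expect_equal(cmp$statistic, t_summary, tolerance = 1e-12)
})

test_that("degenerate variances follow the stated conventions", {
  expect_equal(compare_groups(rep(1, 5), rep(1, 4))$p_value, 1)
  expect_error(compare_groups(rep(1, 5), rep(2, 5)), "degenerate")
  # one degenerate group is fine for the pooled test
  set.seed(41)
  expect_lt(compare_groups(rep(1, 10), rnorm(10, 3))$p_value, 0.01)
})

test_that("non-normal data trigger the Mann-Whitney fallback when enabled", {
  set.seed(42)
  a <- rexp(80); b <- rexp(80)
  cmp <- compare_groups(a, b, fallback = TRUE)
  expect_equal(cmp$test_used, "mann_whitney")
  cmp2 <- compare_groups(rnorm(80), rnorm(80), fallback = TRUE)
  expect_equal(cmp2$test_used, "t_test")
})

test_that("run_study produces well-formed tables and is deterministic", {
  coh <- generate_cohort(cohort_spec(n_per_group = 4, duration_s = 5, seed = 50))
  st <- run_study(coh$manifest, coh$records, tau_max = 5)
  expect_s3_class(st, "pulse_study")
  expect_named(st$tables, paste0(c("rc_mse", "rc_mfe", "rc_mpe", "rc_mde"), ".left"))
  tab <- st$tables[["rc_mfe.left"]]
  expect_equal(tab$tau, 1:5)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(tab$p_holm >= tab$p_value))
  expect_true(all(tab$male_sd >= 0 & tab$female_sd >= 0))

  st2 <- run_study(coh$manifest, coh$records, tau_max = 5)
  expect_identical(st$tables, st2$tables)

  dir <- withr::local_tempdir()
  paths <- write_study_tables(st, dir)
  expect_length(paths, 4)
  expect_true(all(file.exists(paths)))
})

test_that("identical subjects in both groups give p = 1 everywhere", {
  rec <- generate_pulse(duration_s = 5, seed = 51)
  manifest <- data.frame(record_path = "",
                         subject_id = c("a", "b", "c", "d"),
                         sex = c("male", "male", "female", "female"),
                         hand = "left", stringsAsFactors = FALSE)
  st <- run_study(manifest, list(rec, rec, rec, rec), tau_max = 3)
  for (tab in st$tables) expect_true(all(tab$p_value == 1))
})

test_that("an empty sex/hand cell is reported by name", {
  coh <- generate_cohort(cohort_spec(n_per_group = 3, duration_s = 5, seed = 52))
  manifest <- coh$manifest
  manifest$sex <- "male"
  manifest$subject_id <- paste0("s", 1:6)  # keep keys unique
  expect_error(run_study(manifest, coh$records, tau_max = 3), "fewer than 2")
})

test_that("records failing the quality gate are excluded and logged", {
  coh <- generate_cohort(cohort_spec(n_per_group = 3, duration_s = 5, seed = 53))
  flat <- pulse_record(rep(1, 1000), 200,
                       subject_id = "flat", sex = "male", hand = "left")
  manifest <- rbind(coh$manifest,
                    data.frame(record_path = "", subject_id = "flat",
                               sex = "male", hand = "left",
                               stringsAsFactors = FALSE))
  st <- run_study(manifest, c(coh$records, list(flat)), tau_max = 3)
  expect_false(st$log$included[st$log$subject_id == "flat"])
  expect_match(st$log$note[st$log$subject_id == "flat"], "onset|variance")
  expect_equal(sum(st$log$included), 6)
})

test_that("permuting group labels yields uniform p-values on a null cohort", {
  coh <- generate_cohort(cohort_spec(n_per_group = 20, duration_s = 5,
                                     effect = 0, seed = 54))
  vals <- vapply(coh$records, function(r) {
    fuzzy_entropy(preprocess_record(r)$record)
  }, numeric(1))
  set.seed(55)
  pvals <- vapply(1:200, function(i) {
    lab <- sample(rep(c(TRUE, FALSE), each = 20))
    compare_groups(vals[lab], vals[!lab])$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
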