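# Cohort-level comparison: per-scale group means/SDs and two-group
# significance tests, one summary table per (measure, hand), with a
# Shapiro-Wilk normality gate. Per-scale p-values are reported unadjusted
# (the convention in the pulse-complexity literature); a Holm-corrected
# column is emitted alongside, clearly separated, since the uncorrected
# convention is a known weakness.

#' Shapiro-Wilk normality check
#'
#' @param values Numeric vector of per-subject entropies at one scale;
#'   `3 <= n <= 5000`.
#' @return A list with `statistic` (W) and `p_value`.
#' @examples
#' normality_check(rnorm(50))
#' @export
normality_check <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  sw <- shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value)
}

#' Two-group comparison at one scale
#'
#' Pooled-variance (Student) two-sample t-test by default, the literal
#' independent two-sample t-test; Welch available via `var_equal = FALSE`.
#' When `fallback = TRUE` and either group fails the Shapiro-Wilk check at
#' `alpha`, a Mann-Whitney test is used instead and flagged in `test_used`.
#' If both groups have zero variance and equal means the comparison is
#' vacuous and `p = 1` by convention; zero variance in both groups with
#' different means is a degenerate-variance error.
#'
#' @param a,b Numeric vectors (e.g. male and female entropies), `n >= 2`
#'   each.
#' @param alpha Significance level for the normality gate (default 0.05).
#' @param fallback Use Mann-Whitney when normality fails? Default `FALSE`
#'   (a guard, off by default since the pooled t-test is the primary
#'   analysis).
#' @param var_equal Pooled-variance t-test? Default `TRUE`.
#' @return A list with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `statistic`,
#'   `p_value`, `test_used` and (when computed) `normal_a_p`, `normal_b_p`.
#' @examples
#' compare_groups(rnorm(30), rnorm(30, 1))
#' @export
compare_groups <- function(a, b, alpha = 0.05, fallback = FALSE,
                           var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  out <- list(mean_a = mean(a), sd_a = sd(a), mean_b = mean(b), sd_b = sd(b))
  if (out$sd_a == 0 && out$sd_b == 0) {
    if (isTRUE(all.equal(out$mean_a, out$mean_b))) {
      out$statistic <- 0; out$p_value <- 1
      out$test_used <- "t_test"
      return(out)
    }
    stop("degenerate variance: both groups constant with different means")
  }
  use_mw <- FALSE
  if (fallback) {
    na <- tryCatch(normality_check(a)$p_value, error = function(e) NA_real_)
    nb <- tryCatch(normality_check(b)$p_value, error = function(e) NA_real_)
    out$normal_a_p <- na; out$normal_b_p <- nb
    use_mw <- isTRUE(na < alpha) || isTRUE(nb < alpha)
  }
  if (use_mw) {
    w <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    out$statistic <- unname(w$statistic)
    out$p_value <- w$p.value
    out$test_used <- "mann_whitney"
  } else {
    tt <- t.test(a, b, var.equal = var_equal)
    out$statistic <- unname(tt$statistic)
    out$p_value <- tt$p.value
    out$test_used <- if (var_equal) "t_test" else "welch_t"
  }
  out
}

#' Run the full two-group study
#'
#' Preprocesses every record, computes the four refined composite multiscale
#' profiles, and for every (measure, hand, scale) cell compares the male and
#' female groups: group means, SDs, pooled t-test p-value and a
#' Holm-corrected p-value (adjusted across scales within each table).
#' Records that fail the automated quality gate (fewer than two detectable
#' beat onsets) are excluded and logged, the automated stand-in for manual
#' artifact rejection.
#'
#' @param manifest Data frame with columns `record_path`, `subject_id`,
#'   `sex`, `hand` (see [read_manifest()]).
#' @param records List of [pulse_record]s in manifest order, or `NULL` to
#'   load each `record_path` (relative to `base_dir`) with
#'   [read_pulse_csv()].
#' @param params An [entropy_params()].
#' @param tau_max Largest scale, default 10.
#' @param preprocess Apply [preprocess_record()] first? Default `TRUE`.
#' @param pre_params A [preprocess_params()].
#' @param fallback Passed to [compare_groups()].
#' @param base_dir Directory resolving `record_path` when `records` is
#'   `NULL`.
#' @param fs Sampling rate used when loading records from disk.
#' @return An object of class `pulse_study`: a list with `tables` (named
#'   `"<measure>.<hand>"`, each a data frame with columns `tau`,
#'   `male_mean`, `male_sd`, `female_mean`, `female_sd`, `p_value`,
#'   `p_holm`, `test_used`), `log` (per-record data frame: subject, hand,
#'   included, drift_detected, n_samples) and `normality` (per-cell
#'   Shapiro-Wilk p-values by group).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_per_group = 3, duration_s = 5, seed = 1))
#' study <- run_study(cohort$manifest, cohort$records, tau_max = 3)
#' study$tables[["rc_mde.left"]]
#' @export
run_study <- function(manifest, records = NULL, params = entropy_params(),
                      tau_max = 10L, preprocess = TRUE,
                      pre_params = preprocess_params(), fallback = FALSE,
                      base_dir = ".", fs = 200) {
  manifest <- validate_manifest(manifest)
  n_rec <- nrow(manifest)
  if (is.null(records)) {
    records <- lapply(seq_len(n_rec), function(i)
      read_pulse_csv(file.path(base_dir, manifest$record_path[i]), fs = fs,
                     subject_id = manifest$subject_id[i],
                     sex = manifest$sex[i], hand = manifest$hand[i]))
  }
  if (length(records) != n_rec)
    stop("records list does not match manifest length")

  profs <- vector("list", n_rec)
  log_rows <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    rec <- as_pulse_record(records[[i]])
    res <- tryCatch({
      if (preprocess) {
        pp <- preprocess_record(rec, pre_params)
        list(profiles = profile_record(pp$record, params, tau_max),
             drift = pp$drift_detected, n = length(pp$record$samples))
      } else {
        list(profiles = profile_record(rec, params, tau_max),
             drift = NA, n = length(rec$samples))
      }
    }, pulse_quality_error = function(e) e)
    excluded <- inherits(res, "error")
    log_rows[[i]] <- data.frame(
      subject_id = manifest$subject_id[i], sex = manifest$sex[i],
      hand = manifest$hand[i], included = !excluded,
      drift_detected = if (excluded) NA else res$drift,
      n_samples = if (excluded) NA_integer_ else res$n,
      note = if (excluded) conditionMessage(res) else "",
      stringsAsFactors = FALSE)
    if (!excluded) profs[[i]] <- res$profiles
  }
  keep <- !vapply(profs, is.null, logical(1))

  hands <- unique(manifest$hand)
  tables <- list()
  norm_rows <- list()
  for (hand in hands) {
    for (ms in rc_measures) {
      sel_m <- keep & manifest$hand == hand & manifest$sex == "male"
      sel_f <- keep & manifest$hand == hand & manifest$sex == "female"
      if (sum(sel_m) < 2L || sum(sel_f) < 2L)
        stop(sprintf("cell %s/%s hand has fewer than 2 usable subjects per sex",
                     ms, hand))
      val_m <- do.call(rbind, lapply(profs[sel_m], function(p) p[[ms]]$values))
      val_f <- do.call(rbind, lapply(profs[sel_f], function(p) p[[ms]]$values))
      rows <- lapply(seq_len(tau_max), function(tau) {
        a <- val_m[, tau]; b <- val_f[, tau]
        a_ok <- a[is.finite(a)]; b_ok <- b[is.finite(b)]
        if (length(a_ok) < 2L || length(b_ok) < 2L)
          stop(sprintf("cell %s/%s tau=%d: fewer than 2 defined values per sex",
                       ms, hand, tau))
        cmp <- compare_groups(a_ok, b_ok, fallback = fallback)
        for (grp in c("male", "female")) {
          v <- if (grp == "male") a_ok else b_ok
          swp <- if (length(v) >= 3L && sd(v) > 0)
            tryCatch(normality_check(v)$p_value, error = function(e) NA_real_)
          else NA_real_
          norm_rows[[length(norm_rows) + 1L]] <<- data.frame(
            measure = ms, hand = hand, tau = tau, group = grp,
            shapiro_p = swp, stringsAsFactors = FALSE)
        }
        data.frame(tau = tau, male_mean = cmp$mean_a, male_sd = cmp$sd_a,
                   female_mean = cmp$mean_b, female_sd = cmp$sd_b,
                   p_value = cmp$p_value, test_used = cmp$test_used,
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      tab$p_holm <- p.adjust(tab$p_value, method = "holm")
      tab <- tab[c("tau", "male_mean", "male_sd", "female_mean", "female_sd",
                   "p_value", "p_holm", "test_used")]
      tables[[paste(ms, hand, sep = ".")]] <- tab
    }
  }
  structure(list(tables = tables,
                 log = do.call(rbind, log_rows),
                 normality = do.call(rbind, norm_rows)),
            class = "pulse_study")
}

#' @export
print.pulse_study <- function(x, ...) {
  n_inc <- sum(x$log$included)
  cat(sprintf("Pulse complexity study: %d/%d records included, %d tables\n",
              n_inc, nrow(x$log), length(x$tables)))
  sig <- vapply(x$tables, function(t) sum(t$p_value < 0.05), integer(1))
  cat("Cells with p < 0.05 per table:\n")
  print(sig)
  invisible(x)
}

#' Write all study summary tables
#'
#' One CSV per (measure, hand) via [write_summary_table()], named
#' `summary_<measure>_<hand>.csv`.
#'
#' @param study A `pulse_study` from [run_study()].
#' @param dir Output directory (created if missing).
#' @return Character vector of paths, invisibly.
#' @export
write_study_tables <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(study$tables)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    path <- file.path(dir, sprintf("summary_%s_%s.csv", parts[1], parts[2]))
    write_summary_table(study$tables[[nm]], path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
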