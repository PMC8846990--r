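# Text-format I/O: pulse sample files, cohort manifests, per-record scale
# profiles and per-scale group-summary tables. All formats are plain CSV so
# fixtures stay human-inspectable; undefined entropy values are written as
# the literal token "NA".

#' Read a pulse recording from a one-column CSV file
#'
#' The sample file holds one numeric amplitude per line, optionally preceded
#' by a single non-numeric header line. The sampling rate is not stored in
#' the sample file; it is supplied by the caller (typically from the cohort
#' manifest).
#'
#' @param path Path to the sample file.
#' @param fs Sampling rate in Hz.
#' @param subject_id,sex,hand Metadata attached to the returned record.
#' @return A [pulse_record].
#' @seealso [write_pulse_csv()], [read_manifest()]
#' @export
read_pulse_csv <- function(path, fs = 200, subject_id = "anon",
                           sex = "unknown", hand = "unknown") {
  if (!file.exists(path)) stop("pulse file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("pulse file is empty: ", path)
  start <- 1L
  first <- suppressWarnings(as.numeric(lines[1L]))
  if (is.na(first)) start <- 2L  # single header line allowed
  if (start > length(lines)) stop("pulse file has a header but no samples: ", path)
  vals <- suppressWarnings(as.numeric(lines[start:length(lines)]))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L] + start - 1L
    stop(sprintf("non-numeric value at line %d of %s: '%s'", bad, path, lines[bad]))
  }
  pulse_record(vals, fs = fs, subject_id = subject_id, sex = sex, hand = hand)
}

#' Write a pulse recording as a one-column CSV file
#'
#' Samples are rendered with 17 significant digits so a write/read round trip
#' reproduces the vector bit-exactly.
#'
#' @param record A [pulse_record].
#' @param path Output path.
#' @param header Write a `"amplitude"` header line? Default `FALSE`
#'   (headerless, the minimal interchange form).
#' @return `path`, invisibly.
#' @export
write_pulse_csv <- function(record, path, header = FALSE) {
  record <- as_pulse_record(record)
  lines <- sprintf("%.17g", record$samples)
  if (header) lines <- c("amplitude", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `record_path`, `subject_id`, `sex`,
#' `hand`, one row per recording. The (subject_id, hand) pairs must be
#' unique and sexes limited to male/female/unknown.
#'
#' @param path Manifest path.
#' @return A data frame with the four manifest columns, in file order.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_manifest(m)
}

#' Write a cohort manifest
#'
#' @param manifest Data frame with columns `record_path`, `subject_id`,
#'   `sex`, `hand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_manifest <- function(m) {
  need <- c("record_path", "subject_id", "sex", "hand")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  m <- m[need]
  ok_sex <- m$sex %in% c("male", "female", "unknown")
  if (!all(ok_sex)) stop("manifest contains invalid sex values: ",
                         paste(unique(m$sex[!ok_sex]), collapse = ", "))
  ok_hand <- m$hand %in% c("left", "right", "unknown")
  if (!all(ok_hand)) stop("manifest contains invalid hand values: ",
                          paste(unique(m$hand[!ok_hand]), collapse = ", "))
  key <- paste(m$subject_id, m$hand)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, hand) pairs in manifest: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  m
}

#' Construct a per-record scale profile
#'
#' Holds the entropy value for one record, one measure, at scales
#' `tau = 1..tau_max`. Undefined values (possible for crisp sample-entropy
#' counting when no template pairs match) are stored as `NA`.
#'
#' @param values Numeric vector of entropy values, one per scale, in order
#'   `tau = 1, 2, ...`.
#' @param measure One of `"rc_mse"`, `"rc_mfe"`, `"rc_mpe"`, `"rc_mde"`.
#' @param subject_id,hand Record metadata.
#' @return An object of class `scale_profile`.
#' @export
scale_profile <- function(values, measure, subject_id = "anon", hand = "unknown") {
  measure <- match.arg(measure, c("rc_mse", "rc_mfe", "rc_mpe", "rc_mde"))
  values <- as.numeric(values)
  if (length(values) < 1L) stop("a scale profile needs at least one scale")
  names(values) <- seq_along(values)
  structure(list(subject_id = as.character(subject_id), hand = hand,
                 measure = measure, values = values),
            class = "scale_profile")
}

#' @export
print.scale_profile <- function(x, ...) {
  cat(sprintf("%s profile for '%s' (%s hand), tau = 1..%d\n",
              toupper(x$measure), x$subject_id, x$hand, length(x$values)))
  print(round(x$values, 4))
  invisible(x)
}

#' Write scale profiles to CSV
#'
#' Long format with columns `subject_id`, `hand`, `measure`, `tau`, `value`;
#' undefined entropies are written as the token `NA`.
#'
#' @param profiles A `scale_profile` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "scale_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(subject_id = p$subject_id, hand = p$hand, measure = p$measure,
               tau = as.integer(names(p$values)), value = unname(p$values),
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read scale profiles from CSV
#'
#' @param path Path written by [write_profiles()].
#' @return A list of `scale_profile` objects, one per
#'   (subject_id, hand, measure) combination, in file order.
#' @export
read_profiles <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  key <- paste(d$subject_id, d$hand, d$measure, sep = "\r")
  lapply(split(d, factor(key, levels = unique(key))), function(g) {
    g <- g[order(g$tau), ]
    if (!identical(g$tau, seq_along(g$tau)))
      stop("profile scales must be consecutive integers starting at 1")
    scale_profile(g$value, g$measure[1L], g$subject_id[1L], g$hand[1L])
  })
}

#' Write a per-scale group-summary table
#'
#' One row per scale with group means, SDs and the between-group p-value,
#' mirroring the standard mean +/- SD presentation: columns `tau`,
#' `male_mean`, `male_sd`, `female_mean`, `female_sd`, `p_value`, all
#' rendered to 4 decimals.
#'
#' @param rows Data frame with (at least) those six columns, one row per
#'   scale. Scales must be unique.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(rows, path) {
  need <- c("tau", "male_mean", "male_sd", "female_mean", "female_sd", "p_value")
  if (!all(need %in% names(rows)))
    stop("summary rows must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(rows$tau))
    stop("duplicate scale tau in summary rows: ",
         paste(unique(rows$tau[duplicated(rows$tau)]), collapse = ", "))
  out <- rows[need]
  out <- out[order(out$tau), ]
  for (col in need[-1L]) out[[col]] <- sprintf("%.4f", rows[[col]][order(rows$tau)])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
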