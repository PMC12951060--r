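#' Construct a waveform record
#'
#' @param subject_id subject identifier.
#' @param hand `"left"` or `"right"`.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param samples numeric vector of PPG samples (arbitrary units), at
#'   least 2 s worth, no missing values.
#' @return object of class `waveform_record`.
#' @export
waveform_record <- function(subject_id, hand, sampling_rate, samples) {
  hand <- match.arg(hand, c("left", "right"))
  check_scalar(sampling_rate, "sampling_rate", lower = 1e-9)
  if (!is.numeric(samples) || anyNA(samples))
    stop("samples must be numeric with no missing values")
  if (length(samples) < 2 * sampling_rate)
    stop("record must contain at least 2 seconds of samples")
  structure(list(subject_id = as.character(subject_id), hand = hand,
                 sampling_rate = sampling_rate,
                 samples = as.numeric(samples)),
            class = "waveform_record")
}

#' Write a waveform record to a plain-text CSV file
#'
#' Two columns (`time_s`, `amplitude`) preceded by a single header
#' comment line carrying the subject id, hand and sampling rate, e.g.
#' `# subject_id=S001 hand=left sampling_rate_hz=200`. Numbers are
#' written with 12 significant digits so read/write round-trips are
#' byte-stable.
#'
#' @param record a `waveform_record`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# subject_id=%s hand=%s sampling_rate_hz=%s",
                     record$subject_id, record$hand,
                     format(record$sampling_rate, digits = 12)), con)
  writeLines("time_s,amplitude", con)
  t <- (seq_along(record$samples) - 1L) / record$sampling_rate
  writeLines(paste(format(t, digits = 12, trim = TRUE, scientific = FALSE),
                   format(record$samples, digits = 12, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

#' Read a waveform record written by [write_waveform()]
#'
#' Validates the header, time monotonicity and sample completeness;
#' parse failures report the offending line number.
#'
#' @param path file path.
#' @return a `waveform_record`.
#' @export
read_waveform <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "#"))
    stop(sprintf("%s: line 1: missing '# subject_id=... hand=... sampling_rate_hz=...' header", path))
  hdr <- lines[1L]
  grab <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "=([^ ]+)"), hdr))[[1L]]
    if (length(m) < 2L)
      stop(sprintf("%s: line 1: header lacks '%s='", path, key))
    m[2L]
  }
  sid <- grab("subject_id")
  hand <- grab("hand")
  fs <- suppressWarnings(as.numeric(grab("sampling_rate_hz")))
  if (!is.finite(fs) || fs <= 0)
    stop(sprintf("%s: line 1: bad sampling rate", path))

  dat <- utils::read.csv(text = lines[-1L])
  if (!all(c("time_s", "amplitude") %in% names(dat)))
    stop(sprintf("%s: line 2: expected columns time_s,amplitude", path))
  bad <- which(!is.finite(dat$amplitude))
  if (length(bad))
    stop(sprintf("%s: line %d: missing or non-finite amplitude",
                 path, bad[1L] + 2L))
  dt <- diff(dat$time_s)
  if (any(!is.finite(dt)) || any(dt <= 0)) {
    k <- which(!is.finite(dt) | dt <= 0)[1L]
    stop(sprintf("%s: line %d: non-monotone time column", path, k + 3L))
  }
  waveform_record(sid, hand, fs, dat$amplitude)
}

#' Write cohort metadata to CSV
#'
#' @param cohort list of subjects as returned by [generate_cohort()], or a
#'   data frame with columns `subject_id`, `sex`, `age`, `syntax_score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- if (is.data.frame(cohort)) cohort else cohort_table(cohort)
  utils::write.csv(df[, c("subject_id", "sex", "age", "syntax_score")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cohort metadata written by [write_cohort()]
#' @param path file path.
#' @return data frame with `subject_id`, `sex`, `age`, `syntax_score` and a
#'   derived logical `label` column (`syntax_score >= 22`).
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age", "syntax_score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  df$label <- df$syntax_score >= 22
  df
}

#' Write a per-subject feature table to CSV
#'
#' One row per subject. Column names use the portable mapping documented
#' in [feature_row()] (`dC6` for the signed order-6 amplitude difference,
#' `absdC9CV` for the absolute amplitude-CV difference, ...). Numbers are
#' formatted at 12 significant digits for byte-stable round trips.
#'
#' @param features data frame with a `subject_id` column and numeric
#'   feature columns (e.g. rbind of [feature_row()] outputs, optionally
#'   merged with metadata columns `sex`, `age`, `syntax_score`, `label`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  if (!is.data.frame(features))
    stop("features must be a data frame")
  if (nrow(features) > 0) {
    num <- vapply(features, is.numeric, logical(1))
    bad <- features$subject_id[!stats::complete.cases(features[, num, drop = FALSE])]
    if (length(bad))
      stop(sprintf("missing features for subjects: %s",
                   paste(bad, collapse = ", ")))
  }
  out <- features
  for (j in which(vapply(out, is.double, logical(1))))
    out[[j]] <- format(out[[j]], digits = 12, trim = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path file path.
#' @return data frame, numeric columns restored.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(subject_id = "character"))
}

#' Serialize a fitted model (or validation report) to JSON
#'
#' JSON with an explicit `schema` version field so downstream readers can
#' detect format changes.
#'
#' @param x a `fitted_model`, validation report, or plain list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(x, path) {
  payload <- list(schema = "pulseharmonics/model/1", object = unclass_deep(x))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a JSON model/report written by [write_model_json()]
#' @param path file path.
#' @return the deserialized object (as plain lists/vectors).
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$schema) || !startsWith(payload$schema, "pulseharmonics/"))
    stop(sprintf("%s: not a pulseharmonics model JSON", path))
  payload$object
}

# strip S3 classes recursively so jsonlite serializes plain structures;
# named atomic vectors become lists so their names survive as JSON keys
unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, unclass_deep)
    return(unclass(x))
  }
  if (is.data.frame(x)) return(x)
  x <- unclass(x)
  if (is.atomic(x) && !is.null(names(x))) x <- as.list(x)
  x
}
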