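#' Hemodynamic recording container
#'
#' Per-channel HbO and HbR concentration-change time series with sampling rate,
#' paradigm annotation and channel labels. Units are arbitrary micromolar
#' unless stated otherwise in a manifest; every feature downstream is either
#' scale-covariant or scale-invariant, so the unit convention does not affect
#' classification.
#'
#' @param hbo,hbr Numeric matrices, samples x channels.
#' @param sampling_hz Sampling rate in Hz.
#' @param paradigm A [task_paradigm()] (optional but required by windowed ops).
#' @param channel_ids Channel labels; default `ch01`, `ch02`, ...
#' @param units Unit string recorded in manifests.
#' @return An object of class `hemo_recording`.
#' @export
hemo_recording <- function(hbo, hbr, sampling_hz, paradigm = NULL,
                           channel_ids = NULL, units = "uM") {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  assert_that(all(dim(hbo) == dim(hbr)), "HbO and HbR must share dimensions")
  assert_that(ncol(hbo) >= 1, "recording needs at least one channel")
  assert_that(!anyNA(hbo) && !anyNA(hbr), "recording contains NA/NaN values")
  assert_that(all(is.finite(hbo)) && all(is.finite(hbr)), "recording contains non-finite values")
  assert_that(is_number(sampling_hz) && sampling_hz > 0, "sampling_hz must be positive")
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%02d", seq_len(ncol(hbo)))
  assert_that(length(channel_ids) == ncol(hbo), "channel_ids length mismatch")
  if (!is.null(paradigm)) {
    assert_that(inherits(paradigm, "task_paradigm"), "paradigm must be a task_paradigm()")
    assert_that(nrow(hbo) == n_samples(paradigm),
                sprintf("recording has %d samples but the paradigm implies %d",
                        nrow(hbo), n_samples(paradigm)))
  }
  colnames(hbo) <- colnames(hbr) <- channel_ids
  structure(
    list(hbo = hbo, hbr = hbr, sampling_hz = sampling_hz, paradigm = paradigm,
         channel_ids = channel_ids, units = units),
    class = "hemo_recording"
  )
}

#' @export
print.hemo_recording <- function(x, ...) {
  cat(sprintf("Hemodynamic recording: %d samples x %d channels @ %g Hz (%s)\n",
              nrow(x$hbo), ncol(x$hbo), x$sampling_hz, x$units))
  invisible(x)
}

paradigm_to_list <- function(p) {
  if (is.null(p)) return(NULL)
  list(pre_rest_s = p$pre_rest_s, task_s = p$task_s, post_rest_s = p$post_rest_s,
       sampling_hz = p$sampling_hz)
}

paradigm_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  task_paradigm(l$pre_rest_s, l$task_s, l$post_rest_s, l$sampling_hz)
}

#' Write a recording as TSV plus JSON manifest
#'
#' Columns are `ch01_HbO ... chNN_HbO, ch01_HbR ... chNN_HbR`; rows are
#' samples. A sidecar `<path>.json` manifest stores sampling rate, paradigm,
#' units and channel ids.
#'
#' @param recording A [hemo_recording()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  assert_that(inherits(recording, "hemo_recording"), "recording must be a hemo_recording")
  m <- cbind(recording$hbo, recording$hbr)
  colnames(m) <- c(paste0(recording$channel_ids, "_HbO"),
                   paste0(recording$channel_ids, "_HbR"))
  utils::write.table(format(m, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(sampling_hz = recording$sampling_hz,
                   paradigm = paradigm_to_list(recording$paradigm),
                   channel_ids = recording$channel_ids,
                   units = recording$units)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from TSV (+ manifest)
#'
#' Validates the on-disk matrix: every cell numeric (a parse error names the
#' offending row and column), no NaN run longer than one second, and the
#' sample count consistent with the manifest paradigm when one is present.
#'
#' @param path TSV path written by [write_recording()].
#' @param manifest Optional manifest path; defaults to `<path>.json`.
#' @return A [hemo_recording()].
#' @export
read_recording <- function(path, manifest = paste0(path, ".json")) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  raw <- utils::read.table(path, sep = "\t", header = TRUE, colClasses = "character",
                           check.names = FALSE)
  m <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = list(NULL, names(raw)))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    missing_token <- is.na(raw[[j]]) | raw[[j]] %in% c("NA", "NaN", "nan")
    bad <- which(is.na(v) & !missing_token)
    if (length(bad) > 0) {
      stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                   bad[1], names(raw)[j], raw[bad[1], j]), call. = FALSE)
    }
    m[, j] <- v
  }
  info <- if (file.exists(manifest)) jsonlite::read_json(manifest, simplifyVector = TRUE) else NULL
  sampling_hz <- if (!is.null(info)) info$sampling_hz else stop(
    "no manifest found; supply one, since the sampling rate cannot be inferred", call. = FALSE)
  cn <- colnames(m)
  hbo_cols <- grep("_HbO$", cn)
  hbr_cols <- grep("_HbR$", cn)
  assert_that(length(hbo_cols) >= 1 && length(hbo_cols) == length(hbr_cols),
              "expected matching *_HbO and *_HbR column sets")
  # NaN policy: runs of missing values no longer than 1 s are interpolated,
  # longer runs are a load error.
  max_run <- as.integer(round(sampling_hz))
  for (j in seq_len(ncol(m))) {
    if (anyNA(m[, j])) {
      r <- rle(is.na(m[, j]))
      if (any(r$lengths[r$values] > max_run)) {
        stop(sprintf("column '%s' has a missing-value run longer than 1 s", cn[j]),
             call. = FALSE)
      }
      m[, j] <- stats::approx(which(!is.na(m[, j])), m[!is.na(m[, j]), j],
                              xout = seq_len(nrow(m)), rule = 2)$y
    }
  }
  paradigm <- paradigm_from_list(info$paradigm)
  if (!is.null(paradigm) && nrow(m) != n_samples(paradigm)) {
    stop(sprintf("sampling-rate/paradigm mismatch: %d samples on disk, %d expected",
                 nrow(m), n_samples(paradigm)), call. = FALSE)
  }
  ids <- sub("_HbO$", "", cn[hbo_cols])
  hemo_recording(m[, hbo_cols, drop = FALSE], m[, hbr_cols, drop = FALSE],
                 sampling_hz = sampling_hz, paradigm = paradigm,
                 channel_ids = ids,
                 units = if (!is.null(info$units)) info$units else "uM")
}

#' Write a synthetic cohort to a directory
#'
#' One TSV per subject (`sub001.tsv`, ...) plus a cohort manifest
#' (`cohort.json`) with labels, seed and paradigm.
#'
#' @param cohort An `fnirs_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @param spec The [cohort_spec()] used (stored in the manifest), optional.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  labels <- cohort_labels(cohort)
  files <- character(length(cohort))
  for (i in seq_along(cohort)) {
    files[i] <- sprintf("sub%03d.tsv", i)
    write_recording(cohort[[i]]$recording, file.path(dir, files[i]))
  }
  paradigm <- if (length(cohort) > 0) paradigm_to_list(cohort[[1]]$recording$paradigm) else NULL
  manifest <- list(n_subjects = length(cohort), labels = labels, files = files,
                   paradigm = paradigm,
                   seed = if (!is.null(spec)) spec$seed else NULL)
  jsonlite::write_json(manifest, file.path(dir, "cohort.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Write a feature table as TSV
#'
#' First column `subject_id`, then one column per feature, last column `label`.
#' Numeric values are written with 15 significant digits (lossless round trip
#' to 12+ digits).
#'
#' @param table A [feature_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  assert_that(inherits(table, "feature_table"), "table must be a feature_table")
  assert_that(!anyDuplicated(colnames(table$features)), "duplicate feature names")
  df <- data.frame(subject_id = table$subject_ids, check.names = FALSE)
  if (ncol(table$features) > 0) {
    fm <- as.data.frame(format(table$features, digits = 15, trim = TRUE,
                               scientific = TRUE), check.names = FALSE)
    df <- cbind(df, fm)
  }
  df$label <- as.character(table$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path TSV path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  assert_that(names(df)[1] == "subject_id" && names(df)[ncol(df)] == "label",
              "feature table must have subject_id first and label last")
  feat_cols <- setdiff(names(df), c("subject_id", "label"))
  x <- matrix(0, nrow(df), length(feat_cols),
              dimnames = list(NULL, feat_cols))
  for (j in seq_along(feat_cols)) x[, j] <- as.numeric(df[[feat_cols[j]]])
  feature_table(x, labels = df$label, subject_ids = df$subject_id)
}
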