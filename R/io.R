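# Disk formats: one CSV per recording (samples x channels) plus a JSON
# sidecar with the metadata; a JSON manifest lists a dataset. Feature
# matrices round-trip through CSV (17 significant digits, lossless for
# doubles) plus a JSON sidecar. Any loader producing `recording` objects can
# replace the synthetic generator; the pipeline depends only on that contract.

.rec_stem <- function(rec) {
  sprintf("s%s_%s_t%d", rec$subject_id, rec$class_code, rec$trial_index)
}

#' Write one recording to disk
#'
#' @param rec A [recording()].
#' @param dir Output directory (created if missing).
#' @param stem File stem; default `s<subject>_<class>_t<trial>`.
#' @return Invisibly, the CSV path.
#' @export
write_recording <- function(rec, dir, stem = .rec_stem(rec)) {
  stopifnot(inherits(rec, "recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  m <- t(rec$data)  # samples x channels
  colnames(m) <- paste0("ch", seq_len(ncol(m)))
  utils::write.csv(.fmt_num(m), csv, row.names = FALSE, quote = FALSE)
  meta <- list(subject_id = rec$subject_id, class_code = rec$class_code,
               trial_index = rec$trial_index, fs = rec$fs,
               n_samples = ncol(rec$data))
  jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Read one recording from disk
#'
#' @param csv Path to the recording CSV written by [write_recording()]; the
#'   JSON sidecar is expected next to it.
#' @return A [recording()].
#' @export
read_recording <- function(csv) {
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", csv), simplifyVector = TRUE)
  m <- as.matrix(utils::read.csv(csv))
  recording(t(m), meta$fs, meta$subject_id, meta$class_code, meta$trial_index)
}

#' Write a dataset and its manifest
#'
#' @param recordings List of [recording()] objects.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(recordings, dir) {
  files <- vapply(recordings, function(r) basename(write_recording(r, dir)),
                  character(1))
  manifest <- list(n_recordings = length(files), files = files)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a dataset from its manifest
#'
#' @param manifest Path to `manifest.json` written by [write_dataset()].
#' @return List of [recording()] objects.
#' @export
read_dataset <- function(manifest) {
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  lapply(file.path(dirname(manifest), m$files), read_recording)
}

# Format numerics with enough digits for exact double round-trip.
.fmt_num <- function(m) {
  out <- apply(m, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, colnames(m)))
  out
}

#' Write a feature matrix (CSV + JSON sidecar)
#'
#' @param fm A `feature_matrix`.
#' @param stem Path stem; writes `<stem>.csv` and `<stem>.json`.
#' @return Invisibly, the CSV path.
#' @export
write_feature_matrix <- function(fm, stem) {
  stopifnot(inherits(fm, "feature_matrix"))
  dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
  csv <- paste0(stem, ".csv")
  utils::write.csv(.fmt_num(fm$values), csv, row.names = FALSE, quote = FALSE)
  side <- list(labels = fm$labels, info = fm$info,
               meta = list(feature_set = fm$meta$feature_set,
                           srd_s = fm$meta$srd_s, fs = fm$meta$fs,
                           window_ms = fm$meta$seg$window_ms,
                           increment_ms = fm$meta$seg$increment_ms))
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(csv)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param stem Path stem used at write time.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  values <- as.matrix(utils::read.csv(paste0(stem, ".csv"), check.names = FALSE))
  srd <- side$meta$srd_s
  structure(
    list(values = values, labels = side$labels,
         info = as.data.frame(side$info, stringsAsFactors = FALSE),
         meta = list(feature_set = side$meta$feature_set,
                     srd_s = if (is.null(srd)) NULL else srd,
                     fs = side$meta$fs,
                     seg = segmentation_params(side$meta$window_ms,
                                               side$meta$increment_ms))),
    class = "feature_matrix")
}
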