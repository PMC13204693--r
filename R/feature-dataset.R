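#' Windowed EEG feature dataset
#'
#' The universal data container of the package: a three-dimensional numeric
#' array of per-window, per-channel, per-band features (typically differential
#' entropy, in nats) together with per-sample labels and subject/session
#' metadata.  All downstream stages -- hemisphere splitting, normalization,
#' model fitting, evaluation protocols -- consume and produce this class.
#'
#' @param features numeric array `[n_samples x n_channels x n_bands]`; all
#'   values must be finite.
#' @param labels integer class labels in `1..C` per sample, or `NA` for
#'   unlabeled (target-domain) samples.
#' @param subject_id character vector, one entry per sample.
#' @param session_id character vector, one entry per sample.
#' @param channel_names unique electrode names, length `n_channels`.
#' @param band_names ordered frequency-band names, length `n_bands`.
#'
#' @return An object of class `feature_dataset`: a list with the fields above.
#' @examples
#' fd <- feature_dataset(array(rnorm(10 * 4 * 2), c(10, 4, 2)),
#'                       labels = rep(1:2, 5),
#'                       subject_id = rep("S01", 10),
#'                       session_id = rep("ses1", 10),
#'                       channel_names = c("F3", "F4", "C3", "C4"),
#'                       band_names = c("beta", "gamma"))
#' dim(fd$features)
#' @export
feature_dataset <- function(features, labels, subject_id, session_id,
                            channel_names, band_names) {
  if (!is.array(features) || length(dim(features)) != 3L)
    stop("`features` must be a 3-d array [samples x channels x bands]")
  ds <- structure(
    list(features = features,
         labels = as.integer(labels),
         subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         channel_names = as.character(channel_names),
         band_names = as.character(band_names)),
    class = "feature_dataset")
  validate_feature_dataset(ds)
  ds
}

#' Validate a feature dataset
#'
#' Checks the class invariants: finite features, metadata vectors of length
#' `n_samples`, unique channel names matching the channel axis, and band names
#' matching the band axis.  Called by every constructor and loader; exported so
#' user-assembled objects can be checked too.
#'
#' @param ds a [feature_dataset()].
#' @return `ds`, invisibly, if valid; otherwise an error naming the violation
#'   (for non-finite features, the offending sample/channel/band indices).
#' @export
validate_feature_dataset <- function(ds) {
  stopifnot(inherits(ds, "feature_dataset"))
  d <- dim(ds$features)
  n <- d[1L]
  bad <- which(!is.finite(ds$features), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    head_bad <- utils::head(bad, 5L)
    stop("non-finite feature values at [sample, channel, band] indices: ",
         paste(apply(head_bad, 1L, paste, collapse = ","), collapse = "; "))
  }
  if (length(ds$labels) != n || length(ds$subject_id) != n ||
      length(ds$session_id) != n)
    stop("labels, subject_id and session_id must all have length n_samples (",
         n, ")")
  if (anyNA(ds$subject_id) || anyNA(ds$session_id))
    stop("subject_id and session_id must not contain NA")
  if (length(ds$channel_names) != d[2L])
    stop("channel_names length (", length(ds$channel_names),
         ") does not match channel axis (", d[2L], ")")
  if (anyDuplicated(ds$channel_names))
    stop("channel_names must be unique")
  if (length(ds$band_names) != d[3L])
    stop("band_names length does not match band axis")
  lab <- ds$labels[!is.na(ds$labels)]
  if (length(lab) && any(lab < 1L))
    stop("labels must be positive integers (1..C) or NA")
  invisible(ds)
}

#' @export
print.feature_dataset <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf(
    "<feature_dataset> %d samples x %d channels x %d bands\n", d[1], d[2], d[3]))
  cat("  subjects:", paste(unique(x$subject_id), collapse = ", "), "\n")
  cat("  sessions:", paste(unique(x$session_id), collapse = ", "), "\n")
  nlab <- sum(!is.na(x$labels))
  cat(sprintf("  labels:   %d labeled / %d total (classes: %s)\n",
              nlab, d[1],
              paste(sort(unique(x$labels[!is.na(x$labels)])), collapse = ", ")))
  cat("  bands:   ", paste(x$band_names, collapse = ", "), "\n")
  invisible(x)
}

#' Subset a feature dataset by sample index
#'
#' @param ds a [feature_dataset()].
#' @param idx integer or logical sample index.
#' @return the subsetted `feature_dataset`.
#' @export
subset_samples <- function(ds, idx) {
  validate_feature_dataset(ds)
  feature_dataset(ds$features[idx, , , drop = FALSE],
                  ds$labels[idx], ds$subject_id[idx], ds$session_id[idx],
                  ds$channel_names, ds$band_names)
}

#' Save a feature dataset to a portable on-disk container
#'
#' The container is a directory of plain-text files: `features.csv` (one row
#' per sample, channel-major / band-minor columns), `samples.csv` (label,
#' subject_id, session_id) and `meta.json` (dimensions, channel and band
#' names).  The layout is language-portable and round-trips through
#' [load_feature_dataset()] losslessly up to text-storage precision
#' (15 significant digits).
#'
#' @param ds a valid [feature_dataset()]; validated before any file is written.
#' @param path directory to create (must not be an existing non-container
#'   file).
#' @return `path`, invisibly.
#' @export
save_feature_dataset <- function(ds, path) {
  validate_feature_dataset(ds)
  if (file.exists(path) && !dir.exists(path))
    stop("`path` exists and is not a directory: ", path)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ds$features)
  mat <- flatten_bands(ds)
  dt <- data.table::as.data.table(mat)
  data.table::fwrite(dt, file.path(path, "features.csv"))
  data.table::fwrite(
    data.table::data.table(label = ds$labels,
                           subject_id = ds$subject_id,
                           session_id = ds$session_id),
    file.path(path, "samples.csv"))
  meta <- list(n_samples = d[1L], n_channels = d[2L], n_bands = d[3L],
               channel_names = ds$channel_names, band_names = ds$band_names)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a feature dataset from an on-disk container
#'
#' Reads the directory layout written by [save_feature_dataset()] and
#' validates the result, normalizing the feature tensor to
#' samples x channels x bands axis order.
#'
#' @param path container directory.
#' @return a validated [feature_dataset()].
#' @export
load_feature_dataset <- function(path) {
  if (!dir.exists(path)) stop("container not found: ", path)
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) stop("missing meta.json in container: ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  need <- c("n_samples", "n_channels", "n_bands", "channel_names", "band_names")
  if (!all(need %in% names(meta)))
    stop("meta.json is missing fields: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  samp_file <- file.path(path, "samples.csv")
  if (!file.exists(samp_file)) stop("missing samples.csv in container: ", path)
  samples <- data.table::fread(samp_file, colClasses = list(
    character = c("subject_id", "session_id")))
  if (nrow(samples) != meta$n_samples)
    stop("samples.csv has ", nrow(samples), " rows but meta.json declares ",
         meta$n_samples, " samples")
  mat <- as.matrix(data.table::fread(file.path(path, "features.csv")))
  if (nrow(mat) != meta$n_samples ||
      ncol(mat) != meta$n_channels * meta$n_bands)
    stop("features.csv dimensions do not match meta.json")
  # channel-major / band-minor column order, the inverse of flatten_bands()
  feats <- array(NA_real_, c(meta$n_samples, meta$n_channels, meta$n_bands))
  for (b in seq_len(meta$n_bands))
    feats[, , b] <- mat[, (seq_len(meta$n_channels) - 1L) * meta$n_bands + b,
                        drop = FALSE]
  feature_dataset(feats, samples$label, samples$subject_id,
                  samples$session_id, meta$channel_names, meta$band_names)
}
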