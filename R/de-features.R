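#' Standard five-band specification
#'
#' The five EEG frequency bands used throughout: delta (1-3 Hz), theta
#' (4-7 Hz), alpha (8-13 Hz), beta (14-30 Hz) and gamma (31-50 Hz).
#'
#' @return a data.frame with columns `name`, `low_hz`, `high_hz`.
#' @export
de_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low_hz = c(1, 4, 8, 14, 31),
             high_hz = c(3, 7, 13, 30, 50))
}

# variance floor guarding log() on degenerate (constant) windows
.DE_VAR_FLOOR <- 1e-12

#' Differential entropy of a signal window
#'
#' Gaussian closed form in nats: `0.5 * log(2 * pi * e * var(x))`, with the
#' within-window sample variance (denominator n-1) floored at 1e-12 so a
#' constant window yields a large negative value rather than -Inf.
#'
#' @param x numeric vector (one window of a band-limited channel).
#' @return the differential entropy in nats.
#' @examples
#' differential_entropy(rnorm(200))          # ~ 0.5 * log(2 * pi * exp(1))
#' differential_entropy(rnorm(200, sd = 2))  # larger by ~ log(2)
#' @export
differential_entropy <- function(x) {
  0.5 * log(2 * pi * exp(1) * max(stats::var(x), .DE_VAR_FLOOR))
}

#' Extract windowed differential-entropy features from raw EEG
#'
#' Resamples the recording to 200 Hz if needed (polyphase resampling), applies
#' a zero-phase 5th-order Butterworth band-pass per band over the whole
#' recording (so filter transients are not windowed), segments each channel
#' into non-overlapping windows, and computes one differential-entropy value
#' per (window, channel, band).
#'
#' @param signal numeric matrix `[n_channels x n_timepoints]`.
#' @param sampling_rate sampling rate of `signal` in Hz.
#' @param channel_names electrode names, length `n_channels`.
#' @param bands data.frame with columns `name`, `low_hz`, `high_hz`; defaults
#'   to the five standard bands of [de_bands()].
#' @param window_s window length in seconds (default 1, no overlap).
#' @param target_rate rate to resample to before filtering (default 200 Hz).
#' @param subject_id,session_id metadata attached to every window.
#' @param filter if `FALSE`, skip band-pass filtering (each "band" then sees
#'   the broadband signal); used to validate the entropy estimator against its
#'   closed form.
#' @return a [feature_dataset()] with dimensions
#'   `n_windows x n_channels x nrow(bands)`; labels are `NA` (raw recordings
#'   carry no per-window labels).
#' @export
extract_de_features <- function(signal, sampling_rate, channel_names,
                                bands = de_bands(), window_s = 1,
                                target_rate = 200,
                                subject_id = "S01", session_id = "ses1",
                                filter = TRUE) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1L)
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (length(channel_names) != nrow(signal))
    stop("channel_names must match the channel axis of `signal`")
  nyq <- target_rate / 2
  if (filter && any(bands$low_hz <= 0 | bands$high_hz <= bands$low_hz |
                    bands$high_hz >= nyq))
    stop("each band must satisfy 0 < low_hz < high_hz < ", nyq, " Hz")

  if (sampling_rate != target_rate) {
    g <- .gcd(round(target_rate), round(sampling_rate))
    up <- round(target_rate) / g
    down <- round(sampling_rate) / g
    signal <- t(apply(signal, 1L, function(ch)
      signal::resample(ch, p = up, q = down)))
    sampling_rate <- target_rate
  }

  win <- round(window_s * sampling_rate)
  n_t <- ncol(signal)
  if (win > n_t)
    stop("window (", win, " samples) longer than recording (", n_t, ")")
  n_win <- n_t %/% win
  n_ch <- nrow(signal)
  n_b <- nrow(bands)

  feats <- array(NA_real_, c(n_win, n_ch, n_b))
  for (b in seq_len(n_b)) {
    if (filter) {
      bf <- signal::butter(5, c(bands$low_hz[b], bands$high_hz[b]) / nyq,
                           type = "pass")
      filt <- t(apply(signal, 1L, function(ch)
        signal::filtfilt(bf, ch)))
    } else filt <- signal
    for (w in seq_len(n_win)) {
      cols <- ((w - 1L) * win + 1L):(w * win)
      feats[w, , b] <- apply(filt[, cols, drop = FALSE], 1L,
                             differential_entropy)
    }
  }
  feature_dataset(feats, labels = rep(NA_integer_, n_win),
                  subject_id = rep(subject_id, n_win),
                  session_id = rep(session_id, n_win),
                  channel_names = channel_names,
                  band_names = bands$name)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Split a feature dataset into hemisphere datasets
#'
#' Drops midline channels and returns two sample-aligned datasets containing
#' only left- and right-hemisphere channels, reordered to follow the montage's
#' channel ordering.  Labels and metadata are unchanged.
#'
#' @param ds a [feature_dataset()] containing every montage electrode.
#' @param montage a [montage_config()]; defaults to the bundled 62-channel
#'   montage.
#' @return a list with elements `left` and `right`, each a `feature_dataset`.
#' @examples
#' \donttest{
#' pop <- generate_population(synthetic_spec(n_subjects = 2, d_channels = 2))
#' }
#' @export
split_hemispheres <- function(ds, montage = default_montage()) {
  validate_feature_dataset(ds)
  missing <- setdiff(c(montage$left, montage$right, montage$midline),
                     ds$channel_names)
  if (length(missing))
    stop("montage electrodes absent from dataset: ",
         paste(missing, collapse = ", "))
  take <- function(chs) {
    idx <- match(chs, ds$channel_names)
    feature_dataset(ds$features[, idx, , drop = FALSE],
                    ds$labels, ds$subject_id, ds$session_id,
                    chs, ds$band_names)
  }
  list(left = take(montage$left), right = take(montage$right))
}

#' Flatten the channel/band axes into a feature matrix
#'
#' Deterministic channel-major, band-minor flattening: for 27 channels and
#' the five standard bands each sample becomes a 135-dimensional vector.
#'
#' @param ds a [feature_dataset()].
#' @param band_subset band names to keep, in `ds$band_names` order; default
#'   all bands.
#' @return numeric matrix `[n_samples x (n_channels * length(band_subset))]`
#'   with column names `<channel>.<band>`.
#' @export
flatten_bands <- function(ds, band_subset = NULL) {
  validate_feature_dataset(ds)
  band_subset <- band_subset %||% ds$band_names
  unknown <- setdiff(band_subset, ds$band_names)
  if (length(unknown))
    stop("unknown band name(s): ", paste(unknown, collapse = ", "))
  bidx <- which(ds$band_names %in% band_subset)
  d <- dim(ds$features)
  n_ch <- d[2L]; n_b <- length(bidx)
  out <- matrix(NA_real_, d[1L], n_ch * n_b)
  cn <- character(n_ch * n_b)
  for (i in seq_len(n_ch)) for (j in seq_len(n_b)) {
    col <- (i - 1L) * n_b + j
    out[, col] <- ds$features[, i, bidx[j]]
    cn[col] <- paste(ds$channel_names[i], ds$band_names[bidx[j]], sep = ".")
  }
  colnames(out) <- cn
  out
}

#' Per-block z-score normalization
#'
#' Standardizes every feature dimension (channel x band) to zero mean and
#' unit variance within each block, where a block is all samples of one
#' subject (`scope = "subject"`) or of one subject-session pair
#' (`scope = "subject_session"`, the default).  No statistics are pooled
#' across blocks and labels are never used, so source and target domains can
#' be normalized without leakage.
#'
#' @param ds a [feature_dataset()].
#' @param scope `"subject_session"` or `"subject"`.
#' @return the normalized `feature_dataset`.  Dimensions with (near-)zero
#'   within-block variance are centred but left unscaled.
#' @export
normalize_per_block <- function(ds, scope = c("subject_session", "subject")) {
  scope <- match.arg(scope)
  validate_feature_dataset(ds)
  block <- if (scope == "subject") ds$subject_id
           else paste(ds$subject_id, ds$session_id, sep = "\r")
  feats <- ds$features
  d <- dim(feats)
  for (b in unique(block)) {
    idx <- which(block == b)
    if (length(idx) < 2L)
      stop("block '", gsub("\r", "/", b),
           "' has a single sample; within-block variance is undefined")
    sub <- matrix(feats[idx, , ], nrow = length(idx))
    mu <- colMeans(sub)
    sdv <- apply(sub, 2L, stats::sd)
    sdv[sdv < 1e-12] <- 1   # centred but unscaled for degenerate dimensions
    sub <- .mulrow(.addrow(sub, -mu), 1 / sdv)
    feats[idx, , ] <- array(sub, c(length(idx), d[2L], d[3L]))
  }
  feature_dataset(feats, ds$labels, ds$subject_id, ds$session_id,
                  ds$channel_names, ds$band_names)
}
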