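#' Specification for the synthetic feature generator
#'
#' Parameters of a generative model for hemisphere-paired, multi-subject,
#' multi-session differential-entropy-like feature populations.  Per
#' hemisphere, class means sit on a scaled simplex with equal pairwise
#' distance `class_separation` (times `asymmetry_factor` for the right
#' hemisphere) in units of the within-class standard deviation; each subject
#' carries a random affine domain shift (additive offset plus mild
#' multiplicative per-dimension scale jitter), and each session a smaller
#' additive offset.
#'
#' @param n_subjects number of subjects (default 10).
#' @param n_sessions recording sessions per subject (default 3).
#' @param n_classes number of emotion classes `C` (default 3, >= 2).
#' @param samples_per_class_per_session samples per class, subject and
#'   session (default 40).
#' @param d_channels channels per hemisphere (default 27).
#' @param n_bands frequency bands (default 5).
#' @param class_separation pairwise distance between class means, in
#'   within-class-sigma units (default 3).
#' @param subject_shift_scale sd of the per-subject additive offset per
#'   dimension; the log-scale jitter sd is `0.05 * subject_shift_scale` and
#'   the per-session offset sd is `subject_shift_scale / 2` (default 2).
#' @param asymmetry_factor multiplier on the right hemisphere's class
#'   separation (default 2, modelling stronger right-lateralized
#'   separability).
#' @param noise_sigma sd of additional isotropic feature noise (default 0;
#'   the within-class sd is already 1).
#' @param shift_mode `"isotropic"` (offsets drawn N(0, shift^2 I)) or
#'   `"class_confusion"` (each subject's offset is the between-class
#'   mean-difference vector of a random class pair plus small isotropic
#'   jitter, so marginal alignment is roughly preserved while classes are
#'   crossed -- the regime where a binary domain discriminator misleads
#'   adaptation).
#' @param seed integer seed; generation is a pure function of the spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 10, n_sessions = 3, n_classes = 3,
                           samples_per_class_per_session = 40,
                           d_channels = 27, n_bands = 5,
                           class_separation = 3, subject_shift_scale = 2,
                           asymmetry_factor = 2, noise_sigma = 0,
                           shift_mode = c("isotropic", "class_confusion"),
                           seed = 0) {
  shift_mode <- match.arg(shift_mode)
  stopifnot(.is_count(n_subjects), .is_count(n_sessions),
            .is_count(samples_per_class_per_session),
            .is_count(d_channels), .is_count(n_bands),
            subject_shift_scale >= 0, asymmetry_factor > 0, noise_sigma >= 0,
            class_separation != 0)
  if (!.is_count(n_classes) || n_classes < 2)
    stop("n_classes must be >= 2")
  structure(as.list(environment()), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d subjects x %d sessions x %d classes x %d/class, %d ch x %d bands\n",
    x$n_subjects, x$n_sessions, x$n_classes,
    x$samples_per_class_per_session, x$d_channels, x$n_bands))
  cat(sprintf(
    "  separation %g sd, subject shift %g sd, asymmetry %g, noise %g, mode %s, seed %d\n",
    x$class_separation, x$subject_shift_scale, x$asymmetry_factor,
    x$noise_sigma, x$shift_mode, x$seed))
  invisible(x)
}

# C points in R^d with equal pairwise distance `sep`, randomly rotated:
# scaled standard-basis simplex e_k * sep / sqrt(2) through a random
# orthogonal map (QR of a Gaussian matrix).
.class_means <- function(C, d, sep) {
  base <- diag(C) * sep / sqrt(2)
  base <- sweep(base, 2L, colMeans(base))  # centre the simplex
  rot <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  pts <- matrix(0, C, d)
  pts[, seq_len(C)] <- base
  pts %*% t(rot)
}

#' Generate a hemisphere-paired synthetic feature population
#'
#' Draws the full population described by a [synthetic_spec()]: per
#' hemisphere a set of equidistant class means (right-hemisphere separation
#' scaled by `asymmetry_factor`), per subject an affine domain shift, per
#' session a smaller offset, and unit-variance Gaussian samples around the
#' shifted class means.  Left and right datasets are sample-aligned with
#' identical labels, subject and session vectors.  Byte-identical across
#' calls with the same spec.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `left` and `right` [feature_dataset()]s.
#' @examples
#' pop <- generate_population(synthetic_spec(n_subjects = 2, n_sessions = 1,
#'                                           samples_per_class_per_session = 5,
#'                                           d_channels = 3, n_bands = 2))
#' pop$left
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  C <- spec$n_classes
  d <- spec$d_channels * spec$n_bands
  n_per <- spec$samples_per_class_per_session
  n_block <- C * n_per                       # samples per subject-session
  n_total <- n_block * spec$n_subjects * spec$n_sessions

  withr::with_seed(spec$seed, {
    means <- list(left = .class_means(C, d, spec$class_separation),
                  right = .class_means(C, d,
                                       spec$class_separation *
                                         spec$asymmetry_factor))
    sd_within <- sqrt(1 + spec$noise_sigma^2)
    log_jitter_sd <- 0.05 * spec$subject_shift_scale
    session_sd <- spec$subject_shift_scale / 2

    labels <- integer(n_total)
    subject <- character(n_total)
    session <- character(n_total)
    feats <- list(left = matrix(NA_real_, n_total, d),
                  right = matrix(NA_real_, n_total, d))
    row <- 0L
    for (sub in seq_len(spec$n_subjects)) {
      shift <- list(); scale <- list(); sess_shift <- list()
      for (h in c("left", "right")) {
        if (spec$shift_mode == "isotropic" || spec$subject_shift_scale == 0) {
          shift[[h]] <- stats::rnorm(d, 0, spec$subject_shift_scale)
        } else {
          # offset along a between-class mean-difference direction, at ~0.4 of
          # the between-class distance: large enough that marginal-only
          # alignment is tempted to cross classes, small enough that each
          # class's own mode stays nearest (the crossed solution remains
          # identifiable as wrong)
          pair <- sample.int(C, 2L)
          dir <- means[[h]][pair[1L], ] - means[[h]][pair[2L], ]
          shift[[h]] <- dir * 0.4 * exp(stats::rnorm(1, 0, 0.2)) +
            stats::rnorm(d, 0, 0.15 * spec$subject_shift_scale)
        }
        scale[[h]] <- exp(stats::rnorm(d, 0, log_jitter_sd))
        sess_shift[[h]] <- matrix(stats::rnorm(spec$n_sessions * d, 0,
                                               session_sd),
                                  spec$n_sessions, d)
      }
      for (ses in seq_len(spec$n_sessions)) {
        for (k in seq_len(C)) {
          idx <- row + seq_len(n_per)
          labels[idx] <- k
          subject[idx] <- sprintf("S%02d", sub)
          session[idx] <- sprintf("ses%d", ses)
          for (h in c("left", "right")) {
            centre <- means[[h]][k, ] + shift[[h]] + sess_shift[[h]][ses, ]
            x <- .addrow(matrix(stats::rnorm(n_per * d, 0, sd_within),
                                n_per, d), centre)
            feats[[h]][idx, ] <- .mulrow(x, scale[[h]])
          }
          row <- row + n_per
        }
      }
    }

    channel_names <- list(left = sprintf("L%02d", seq_len(spec$d_channels)),
                          right = sprintf("R%02d", seq_len(spec$d_channels)))
    band_names <- utils::head(c("delta", "theta", "alpha", "beta", "gamma",
                                sprintf("band%d", seq_len(spec$n_bands))),
                              spec$n_bands)
    mk <- function(h) {
      arr <- array(NA_real_, c(n_total, spec$d_channels, spec$n_bands))
      # feature columns are channel-major / band-minor, as in flatten_bands()
      for (i in seq_len(spec$d_channels)) for (b in seq_len(spec$n_bands))
        arr[, i, b] <- feats[[h]][, (i - 1L) * spec$n_bands + b]
      feature_dataset(arr, labels, subject, session,
                      channel_names[[h]], band_names)
    }
    list(left = mk("left"), right = mk("right"))
  })
}

#' Inject Gaussian feature noise
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation `sigma` to
#' every feature value; `sigma = 0` returns the dataset unchanged.  Used for
#' the noise-robustness sweeps.
#'
#' @param ds a [feature_dataset()].
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer seed (same seed, same noise realization).
#' @return the perturbed `feature_dataset`.
#' @export
inject_noise <- function(ds, sigma, seed = 1) {
  validate_feature_dataset(ds)
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(ds)
  feats <- withr::with_seed(seed,
    ds$features + array(stats::rnorm(length(ds$features), 0, sigma),
                        dim(ds$features)))
  feature_dataset(feats, ds$labels, ds$subject_id, ds$session_id,
                  ds$channel_names, ds$band_names)
}

#' Deterministic hand-checkable worked fixture
#'
#' A fixed 12-sample, 2-channels-per-hemisphere, 2-band, 3-class fixture for
#' documentation and exactness tests: small feature datasets plus fixed
#' discriminator output vectors, branch class probabilities, and the fusion
#' quantities (perplexities, weights, fused distribution, label) computed
#' from them by hand.  No randomness is involved.
#'
#' @return list with `left`/`right` [feature_dataset()]s, `disc_left`/
#'   `disc_right` (`12 x 4` discriminator logit matrices), `probs_left`/
#'   `probs_right` (`12 x 3` class probabilities), and `expected` (data.frame
#'   of per-sample perplexities, weights, fused probabilities and labels).
#' @export
toy_worked_fixture <- function() {
  n <- 12L; C <- 3L
  base <- outer(seq_len(n), c(1, -1, 0.5, -0.5)) / 10
  mk <- function(sign, chs) {
    arr <- array(sign * base, c(n, 2L, 2L))
    feature_dataset(arr, labels = rep(1:3, 4),
                    subject_id = rep(c("S01", "S02"), each = 6),
                    session_id = rep("ses1", n),
                    channel_names = chs, band_names = c("beta", "gamma"))
  }
  # fixed discriminator logits: left certain-of-target for odd samples,
  # right uniform; plus assorted hand-checkable rows
  zl <- matrix(rep(c(0, 0, 0, 2), each = n), n, 4)
  zl[seq(1, n, 2), 4] <- 0                    # uniform rows -> P = log(4)
  zr <- matrix(0, n, 4)                       # all uniform  -> P = log(4)
  pl <- matrix(rep(c(0.5, 0.3, 0.2), each = n), n, 3)
  pr <- matrix(rep(c(0.1, 0.8, 0.1), each = n), n, 3)

  p_left <- as.numeric(log(3 + exp(zl[, 4])) - zl[, 4])
  p_right <- rep(log(4), n)
  w <- hemisphere_weights(p_left, p_right)
  fused <- fuse_predictions(w$left, pl, w$right, pr)
  expected <- data.frame(perplexity_left = p_left,
                         perplexity_right = p_right,
                         weight_left = w$left, weight_right = w$right)
  expected <- .finish_fusion(expected, fused$probs, fused$label)
  list(left = mk(1, c("L01", "L02")), right = mk(-1, c("R01", "R02")),
       disc_left = zl, disc_right = zr,
       probs_left = pl, probs_right = pr, expected = expected)
}
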