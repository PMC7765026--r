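#' Repair missing samples in a signal segment
#'
#' Applies the two-part repair rule used throughout the pipeline: when more
#' than half of a segment's samples are missing the whole segment is set to
#' zero; otherwise each missing sample is replaced by the nearest preceding
#' observed value (a leading missing run takes the first observed value).
#'
#' @param segment numeric vector; missing samples are `NA`.
#' @return numeric vector with no `NA` values.
#' @export
fill_missing <- function(segment) {
  if (length(segment) == 0L) stop_glowsel("empty segment")
  miss <- is.na(segment)
  if (!any(miss)) return(segment)
  if (sum(miss) > length(segment) / 2) return(rep(0, length(segment)))
  # last-observation-carried-forward; leading NAs take the first observed value
  first_obs <- segment[which(!miss)[1L]]
  idx <- cumsum(!miss)                 # index of most recent observed sample
  filled <- c(first_obs, segment[!miss])[idx + 1L]
  filled
}

#' Segment a signal into overlapping sliding windows
#'
#' Windows of `window_seconds * sampling_rate` samples (rounded) start at
#' multiples of `hop = round(window * (1 - overlap))`; trailing partial
#' windows are discarded. A window longer than the signal yields an empty
#' result with a warning, not an error, so that short runs do not abort a
#' batch.
#'
#' @param signal numeric vector of samples.
#' @param window_seconds window length in seconds.
#' @param overlap fractional overlap between adjacent windows, in `[0, 1)`.
#' @param sampling_rate sampling rate in Hz.
#' @return a list of numeric windows (possibly empty).
#' @export
segment_windows <- function(signal, window_seconds, overlap, sampling_rate) {
  if (!(is_prob(overlap) && overlap < 1))
    stop_glowsel("overlap must lie in [0, 1)")
  w <- round(window_seconds * sampling_rate)
  if (w < 2L) stop_glowsel("window of %d samples is too short (need >= 2)", w)
  if (w > length(signal)) {
    warning("window longer than signal; returning no windows", call. = FALSE)
    return(list())
  }
  hop <- max(1L, round(w * (1 - overlap)))
  starts <- seq(1L, length(signal) - w + 1L, by = hop)
  lapply(starts, function(s) signal[s:(s + w - 1L)])
}

feature_names <- c("max", "min", "mean", "rms", "std", "skew", "kurt", "energy")

#' Extract the eight time-domain window features
#'
#' Computes, for a repaired window of N samples a_1..a_N: the maximum,
#' minimum, mean, root mean square `sqrt(mean(a^2))`, population standard
#' deviation `sigma = sqrt(mean((a - mean)^2))` (the 1/N form, not N-1),
#' skewness `S = mean((a - mean)^3) / sigma^3`, raw (non-excess) kurtosis
#' `K = mean((a - mean)^4) / sigma^4` (a Gaussian gives K near 3), and
#' signal energy `E = sum(a^2)`. For a constant window sigma is 0 and S and
#' K are defined as 0 rather than raising, because all-zero windows arise
#' from the missing-data repair rule.
#'
#' @param window numeric vector with no missing values, length >= 2.
#' @return named numeric vector with elements
#'   `max, min, mean, rms, std, skew, kurt, energy`.
#' @export
extract_features <- function(window) {
  if (anyNA(window)) stop_glowsel("window contains missing samples; repair first")
  n <- length(window)
  if (n < 2L) stop_glowsel("window must have at least 2 samples")
  m <- mean(window)
  d <- window - m
  sigma <- sqrt(mean(d^2))
  if (sigma > 0) {
    skew <- mean(d^3) / sigma^3
    kurt <- mean(d^4) / sigma^4
  } else {
    skew <- 0
    kurt <- 0
  }
  c(max = max(window), min = min(window), mean = m,
    rms = sqrt(mean(window^2)), std = sigma, skew = skew, kurt = kurt,
    energy = sum(abs(window)^2))
}

#' Build the per-window feature table for a whole dataset
#'
#' For every (subject, activity, sensor) series: slide windows, repair each
#' window with [fill_missing()] (the more-than-half-missing zero rule is
#' applied per window), and extract the eight features.
#'
#' @param dataset a `sensor_dataset`.
#' @param window_seconds,overlap windowing parameters
#'   (see [segment_windows()]).
#' @return a data frame of class `feature_table` with columns `subject`,
#'   `activity`, `sensor`, `window` and the eight feature columns.
#' @export
build_feature_table <- function(dataset, window_seconds = 0.5, overlap = 0.5) {
  rate <- attr(dataset, "sampling_rate")
  if (is.null(rate)) stop_glowsel("dataset has no sampling_rate attribute")
  ord <- order(dataset$subject, dataset$activity, dataset$sensor, dataset$sample_index)
  dataset <- dataset[ord, ]
  key <- interaction(dataset$subject, dataset$activity, dataset$sensor, drop = TRUE)
  groups <- split(seq_len(nrow(dataset)), key)
  rows <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    wins <- segment_windows(dataset$value[idx], window_seconds, overlap, rate)
    if (!length(wins)) next
    feats <- t(vapply(wins, function(w) extract_features(fill_missing(w)),
                      numeric(8L)))
    rows[[g]] <- data.frame(
      subject = dataset$subject[idx[1L]],
      activity = dataset$activity[idx[1L]],
      sensor = dataset$sensor[idx[1L]],
      window = seq_len(nrow(feats)),
      feats
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Min-max feature normalization fitted on training rows
#'
#' `fit_normalizer` learns per-feature (min, max) bounds from training rows
#' only; `apply_normalizer` maps each feature to `(x - min) / (max - min)`,
#' clipping values outside the training range to `[0, 1]`. A feature that is
#' constant in training maps to 0.
#'
#' @param train_rows a `feature_table` (or data frame containing the eight
#'   feature columns) of training rows.
#' @return `fit_normalizer`: an object of class `feature_normalizer`.
#' @export
fit_normalizer <- function(train_rows) {
  if (!all(feature_names %in% names(train_rows)))
    stop_glowsel("train_rows lacks the eight feature columns")
  X <- as.matrix(train_rows[feature_names])
  structure(list(min = apply(X, 2, min), max = apply(X, 2, max)),
            class = "feature_normalizer")
}

#' @rdname fit_normalizer
#' @param bounds a `feature_normalizer` from `fit_normalizer`.
#' @param rows feature rows to normalize.
#' @return `apply_normalizer`: `rows` with every feature column mapped into
#'   `[0, 1]`.
#' @export
apply_normalizer <- function(bounds, rows) {
  if (!inherits(bounds, "feature_normalizer"))
    stop_glowsel("bounds must come from fit_normalizer()")
  for (f in feature_names) {
    rng <- bounds$max[[f]] - bounds$min[[f]]
    z <- if (rng > 0) (rows[[f]] - bounds$min[[f]]) / rng else rep(0, nrow(rows))
    rows[[f]] <- pmin(1, pmax(0, z))
  }
  rows
}

#' Write a feature table as CSV
#'
#' Header `subject,activity,sensor,window,max,min,mean,rms,std,skew,kurt,energy`.
#'
#' @param features a `feature_table`.
#' @param path file path.
#' @export
write_feature_csv <- function(features, path) {
  write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}
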