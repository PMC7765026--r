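#' Specification for a synthetic multi-sensor activity recording
#'
#' Describes a multi-subject, multi-sensor recording in which a known subset
#' of sensor sources carries activity-discriminative signal and the rest are
#' pure noise. Informative sensors emit, for activity k (k = 1..n_activities),
#' a sinusoid of frequency `base_freq * k` Hz and amplitude `1 + 0.5*(k-1)`
#' plus Gaussian noise with standard deviation amplitude/snr, plus a constant
#' per-(subject, sensor) offset; non-informative sensors emit unit Gaussian
#' noise. Both the amplitude ladder and the frequency ladder separate the
#' classes, so time-domain statistics (standard deviation, RMS, extremes)
#' are discriminative.
#'
#' @param n_subjects number of subjects (>= 2; leave-one-subject-out needs 2).
#' @param n_sensors number of sensor sources M.
#' @param informative_ids integer vector of sensor ids (subset of
#'   `1:n_sensors`) that carry activity signal; may be empty.
#' @param n_activities number of activity classes (>= 2).
#' @param sampling_rate sampling rate in Hz.
#' @param duration_per_activity seconds of signal per subject-activity run.
#' @param snr amplitude-to-noise-sd ratio (dimensionless) for informative
#'   sensors.
#' @param subject_shift_sd standard deviation of the constant per-(subject,
#'   sensor) additive offset; creates the cross-subject shift that
#'   leave-one-subject-out evaluation is meant to measure.
#' @param base_freq base sinusoid frequency in Hz for activity 1.
#' @param seed RNG seed; identical spec + seed gives a bit-identical dataset.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(n_subjects = 5, n_sensors = 16,
                           informative_ids = 1:4, n_activities = 4,
                           sampling_rate = 25, duration_per_activity = 16,
                           snr = 10, subject_shift_sd = 0.5,
                           base_freq = 1, seed = 1) {
  if (!is_count(n_subjects, 2L))
    stop_glowsel("invalid spec: n_subjects must be an integer >= 2 (LOSO needs at least 2 subjects)")
  if (!is_count(n_activities, 2L))
    stop_glowsel("invalid spec: n_activities must be an integer >= 2")
  if (!is_count(n_sensors, 1L))
    stop_glowsel("invalid spec: n_sensors must be a positive integer")
  informative_ids <- sort(unique(as.integer(informative_ids)))
  if (length(informative_ids) && (min(informative_ids) < 1L || max(informative_ids) > n_sensors))
    stop_glowsel("invalid spec: informative_ids must be a subset of 1..n_sensors")
  if (!(is.numeric(snr) && snr > 0)) stop_glowsel("invalid spec: snr must be positive")
  structure(list(
    n_subjects = as.integer(n_subjects), n_sensors = as.integer(n_sensors),
    informative_ids = informative_ids, n_activities = as.integer(n_activities),
    sampling_rate = sampling_rate, duration_per_activity = duration_per_activity,
    snr = snr, subject_shift_sd = subject_shift_sd, base_freq = base_freq,
    seed = as.integer(seed)
  ), class = "generator_spec")
}

#' The bundled 16-sensor synthetic benchmark
#'
#' Five subjects, sixteen sensor sources of which sensors 1-4 are
#' informative, four activities, 25 Hz sampling, 16 s per subject-activity
#' run, amplitude-to-noise ratio 10. This is the package's standing test bed
#' for the full select-then-deploy pipeline.
#'
#' @param seed RNG seed for the generated recording.
#' @return a `generator_spec`.
#' @export
demo16_spec <- function(seed = 1) {
  generator_spec(n_subjects = 5, n_sensors = 16, informative_ids = 1:4,
                 n_activities = 4, sampling_rate = 25,
                 duration_per_activity = 16, snr = 10,
                 subject_shift_sd = 0.5, base_freq = 1, seed = seed)
}

#' Generate a synthetic multi-sensor activity dataset
#'
#' @param spec a [generator_spec()].
#' @return a data frame of class `sensor_dataset` in canonical long format
#'   with columns `subject`, `activity`, `sensor`, `sample_index`, `value`
#'   (missing samples are `NA`), plus attributes `sampling_rate` and
#'   `informative_ids` (the ground truth).
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "generator_spec")) spec <- do.call(generator_spec, spec)
  n_per_run <- round(spec$sampling_rate * spec$duration_per_activity)
  if (n_per_run < 4L) stop_glowsel("invalid spec: fewer than 4 samples per run")
  tt <- (seq_len(n_per_run) - 1L) / spec$sampling_rate

  grid <- expand.grid(sensor = seq_len(spec$n_sensors),
                      activity = seq_len(spec$n_activities),
                      subject = seq_len(spec$n_subjects))
  with_seed(spec$seed, {
    # constant per-(subject, sensor) baseline offsets
    offsets <- matrix(rnorm(spec$n_subjects * spec$n_sensors,
                            sd = spec$subject_shift_sd),
                      nrow = spec$n_subjects)
    values <- vector("list", nrow(grid))
    for (r in seq_len(nrow(grid))) {
      u <- grid$subject[r]; k <- grid$activity[r]; s <- grid$sensor[r]
      if (s %in% spec$informative_ids) {
        amp <- 1 + 0.5 * (k - 1)
        freq <- spec$base_freq * k
        phase <- runif(1, 0, 2 * pi)
        values[[r]] <- offsets[u, s] +
          amp * sin(2 * pi * freq * tt + phase) +
          rnorm(n_per_run, sd = amp / spec$snr)
      } else {
        values[[r]] <- rnorm(n_per_run)
      }
    }
  })

  out <- data.frame(
    subject = rep(grid$subject, each = n_per_run),
    activity = rep(grid$activity, each = n_per_run),
    sensor = rep(grid$sensor, each = n_per_run),
    sample_index = rep(seq_len(n_per_run), times = nrow(grid)),
    value = unlist(values)
  )
  attr(out, "sampling_rate") <- spec$sampling_rate
  attr(out, "informative_ids") <- spec$informative_ids
  attr(out, "n_activities") <- spec$n_activities
  class(out) <- c("sensor_dataset", "data.frame")
  out
}

#' Ground-truth informative sensors of a synthetic dataset
#'
#' @param dataset a `sensor_dataset` from [generate_dataset()].
#' @return integer vector of informative sensor ids.
#' @export
informative_ids <- function(dataset) attr(dataset, "informative_ids")

#' Inject bursty missing data into a dataset
#'
#' Replaces approximately `fraction` of the samples with the missing marker
#' (`NA`), in contiguous bursts of `burst_length` samples, independently per
#' (subject, activity, sensor) series. Each series is tiled into
#' `burst_length` blocks and a `fraction` share of blocks is knocked out, so
#' the realized missing fraction matches the request up to block rounding.
#'
#' @param dataset a `sensor_dataset`.
#' @param fraction proportion of samples to remove, in `[0, 1]`.
#' @param burst_length burst length in samples.
#' @param seed RNG seed.
#' @return the dataset with `NA` values injected; attributes preserved.
#' @export
inject_missing <- function(dataset, fraction, burst_length = 5, seed = 1) {
  if (!is_prob(fraction))
    stop_glowsel("invalid argument: fraction must lie in [0, 1]")
  if (!is_count(burst_length)) stop_glowsel("burst_length must be a positive integer")
  if (fraction == 0) return(dataset)
  key <- interaction(dataset$subject, dataset$activity, dataset$sensor, drop = TRUE)
  with_seed(seed, {
    for (idx in split(seq_len(nrow(dataset)), key)) {
      n <- length(idx)
      starts <- seq(1L, n, by = burst_length)
      n_out <- round(fraction * length(starts))
      if (fraction == 1) n_out <- length(starts)
      if (n_out == 0L) next
      chosen <- starts[sample.int(length(starts), n_out)]
      hit <- unlist(lapply(chosen, function(s) s:min(s + burst_length - 1L, n)))
      dataset$value[idx[hit]] <- NA_real_
    }
  })
  dataset
}

#' Write / read the canonical long-format sensor CSV
#'
#' Header `subject,activity,sensor,sample_index,value`; missing samples are
#' written as empty fields.
#'
#' @param dataset a `sensor_dataset`.
#' @param path file path.
#' @return `write_dataset_csv` returns `path` invisibly; `read_dataset_csv`
#'   returns a `sensor_dataset`.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- as.data.frame(dataset)
  write.csv(df, path, row.names = FALSE, na = "")
  meta <- list(sampling_rate = attr(dataset, "sampling_rate"),
               informative_ids = attr(dataset, "informative_ids"),
               n_activities = attr(dataset, "n_activities"))
  if (!is.null(meta$sampling_rate)) {
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_dataset_csv
#' @param sampling_rate sampling rate in Hz, used if no sidecar metadata
#'   file is present.
#' @export
read_dataset_csv <- function(path, sampling_rate = NULL) {
  df <- read.csv(path, na.strings = "")
  need <- c("subject", "activity", "sensor", "sample_index", "value")
  if (!all(need %in% names(df)))
    stop_glowsel("CSV must have columns %s", paste(need, collapse = ", "))
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(df, "sampling_rate") <- as.numeric(meta$sampling_rate)
    if (length(meta$informative_ids))
      attr(df, "informative_ids") <- as.integer(meta$informative_ids)
    attr(df, "n_activities") <- meta$n_activities
  }
  if (!is.null(sampling_rate)) attr(df, "sampling_rate") <- sampling_rate
  if (is.null(attr(df, "sampling_rate")))
    stop_glowsel("sampling_rate not given and no metadata sidecar found")
  class(df) <- c("sensor_dataset", "data.frame")
  df
}
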