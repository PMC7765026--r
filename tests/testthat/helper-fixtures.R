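# Shared fixtures and tiny independent oracles used across the suite.

# A small recording: 3 subjects, 4 sensors (2 informative), 3 activities.
tiny_spec <- function(seed = 11, ...) {
  args <- list(n_subjects = 3, n_sensors = 4, informative_ids = 1:2,
               n_activities = 3, sampling_rate = 25,
               duration_per_activity = 8, snr = 20, subject_shift_sd = 0.3,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(generator_spec, args)
}

# fast protocol settings for pipeline tests
tiny_protocol <- function(seed = 5, t_max = 30) {
  protocol_config(ibgso = ibgso_config(t_max = t_max, seed = 1), seed = seed)
}

# random lookup-table fitness over all non-empty masks of length M
lookup_fitness <- function(M, seed) {
  vals <- local({set.seed(seed); runif(2^M - 1)})
  function(mask) {
    if (!any(mask == 1L)) return(-Inf)
    vals[sum(mask * 2^(seq_along(mask) - 1L))]
  }
}

# independent second enumeration of all non-empty subsets (recursive,
# structured differently from exhaustive_oracle's intToBits loop)
enumerate_best_recursive <- function(fitness_fn, M) {
  best <- list(fitness = -Inf, mask = NULL)
  recurse <- function(prefix, k) {
    if (k > M) {
      if (any(prefix == 1L)) {
        f <- fitness_fn(prefix)
        if (f > best$fitness) best <<- list(fitness = f, mask = prefix)
      }
      return(invisible())
    }
    recurse(c(prefix, 0L), k + 1L)
    recurse(c(prefix, 1L), k + 1L)
  }
  recurse(integer(0), 1L)
  best
}

# mean leave-one-subject-out accuracy of a single-sensor ELM classifier
single_sensor_loso_acc <- function(spec, sensor = 1, hidden = 30) {
  ds <- generate_dataset(spec)
  ft <- build_feature_table(ds, 0.5, 0.5)
  accs <- vapply(loso_split(ft), function(fold) {
    tr <- ft[ft$subject %in% fold$train & ft$sensor == sensor, ]
    te <- ft[ft$subject == fold$test & ft$sensor == sensor, ]
    b <- fit_normalizer(tr)
    model <- train_elm(apply_normalizer(b, tr)[glowsel:::feature_names],
                       tr$activity, hidden = hidden, seed = spec$seed + 1)
    mean(predict(model, apply_normalizer(b, te)[glowsel:::feature_names]) ==
           as.character(te$activity))
  }, numeric(1))
  mean(accs)
}
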