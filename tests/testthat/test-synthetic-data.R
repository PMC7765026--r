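test_that("generation is deterministic and validates its spec", {
  spec <- tiny_spec(seed = 3)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a, b)
  expect_identical(informative_ids(a), 1:2)

  expect_error(generator_spec(n_subjects = 1), "n_subjects")
  expect_error(generator_spec(n_activities = 1), "n_activities")
  expect_error(generator_spec(informative_ids = c(1, 99), n_sensors = 4),
               "subset")
})

test_that("every sensor appears for every subject with balanced, contiguous runs", {
  ds <- generate_dataset(tiny_spec(seed = 7))
  tab <- table(ds$subject, ds$sensor)
  expect_true(all(tab == tab[1, 1]))
  # per (subject, activity): same number of samples everywhere
  per_sa <- table(ds$subject, ds$activity)
  expect_true(all(per_sa == per_sa[1, 1]))
  # contiguous sample_index per run
  one <- ds[ds$subject == 2 & ds$activity == 3 & ds$sensor == 4, ]
  expect_identical(one$sample_index, seq_len(nrow(one)))
})

test_that("a strongly separable sensor supports perfect within-subject classification", {
  # high snr, 2 activities with well-separated amplitudes: train and test an
  # ELM on windows of the informative sensor within one subject
  spec <- tiny_spec(seed = 21, n_activities = 2, snr = 50,
                    duration_per_activity = 12)
  ft <- build_feature_table(generate_dataset(spec), 0.5, 0.5)
  rows <- ft[ft$subject == 1 & ft$sensor == 1, ]
  odd <- seq_len(nrow(rows)) %% 2 == 1
  b <- fit_normalizer(rows[odd, ])
  model <- train_elm(apply_normalizer(b, rows[odd, ])[glowsel:::feature_names],
                     rows$activity[odd], hidden = 30, seed = 9)
  pred <- predict(model, apply_normalizer(b, rows[!odd, ])[glowsel:::feature_names])
  expect_equal(mean(pred == as.character(rows$activity[!odd])), 1.0)
})

test_that("with no informative sensors every classifier sits at chance level", {
  accs <- vapply(1:8, function(s) {
    spec <- tiny_spec(seed = 100 + s, informative_ids = integer(0),
                      n_sensors = 2, n_activities = 2,
                      duration_per_activity = 6)
    single_sensor_loso_acc(spec, sensor = 1)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("single-sensor separability is monotone in the signal-to-noise ratio", {
  mean_acc <- vapply(c(0.5, 2, 10), function(snr) {
    mean(vapply(1:5, function(s) {
      single_sensor_loso_acc(tiny_spec(seed = 200 + s, snr = snr,
                                       n_sensors = 2, informative_ids = 1L))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_acc) >= 0))
})

test_that("missing-data injection is bounded, bursty and deterministic", {
  spec <- tiny_spec(seed = 31, n_subjects = 2, n_sensors = 1,
                    informative_ids = 1L, n_activities = 2,
                    duration_per_activity = 100)
  ds <- generate_dataset(spec)   # 4 series x 2500 samples = 10000 samples
  expect_identical(nrow(ds), 10000L)
  expect_identical(inject_missing(ds, 0), ds)
  expect_true(all(is.na(inject_missing(ds, 1, seed = 2)$value)))

  out <- inject_missing(ds, 0.2, burst_length = 5, seed = 4)
  n_miss <- sum(is.na(out$value))
  band <- 2.576 * sqrt(10000 * 0.2 * 0.8)   # binomial 99% band around 2000
  expect_gt(n_miss, 2000 - band)
  expect_lt(n_miss, 2000 + band)
  expect_identical(inject_missing(ds, 0.2, burst_length = 5, seed = 4), out)
  expect_error(inject_missing(ds, 1.2), "fraction")
})

test_that("the long-format CSV round-trips, with missing values as empty fields", {
  ds <- inject_missing(generate_dataset(tiny_spec(seed = 41)), 0.1, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "\"subject\",\"activity\",\"sensor\",\"sample_index\",\"value\"")
  back <- read_dataset_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(ds))
  expect_identical(attr(back, "sampling_rate"), attr(ds, "sampling_rate"))
  expect_identical(informative_ids(back), informative_ids(ds))
})
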