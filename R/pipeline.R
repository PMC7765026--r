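#' Protocol configuration for the select-then-deploy evaluation
#'
#' Bundles the windowing, classifier and optimizer settings together with
#' the evaluation protocol: leave-one-subject-out folds and `n_repeats`
#' repeats per fold that re-randomize both the ELM input layers and the
#' swarm. All per-fold, per-repeat seeds are derived from the master seed
#' by a fixed counter scheme and recorded in the report.
#'
#' @param window_seconds,overlap sliding-window settings.
#' @param hidden,activation ELM settings shared by all pool members.
#' @param ibgso an [ibgso_config()]; its `seed` field is overridden by the
#'   derived per-run seeds.
#' @param n_repeats repeats per fold (>= 1).
#' @param seed master seed.
#' @return an object of class `protocol_config`.
#' @export
protocol_config <- function(window_seconds = 0.5, overlap = 0.5,
                            hidden = 50, activation = "sigmoid",
                            ibgso = ibgso_config(), n_repeats = 1, seed = 1) {
  if (!is_count(n_repeats)) stop_glowsel("n_repeats must be >= 1")
  structure(list(window_seconds = window_seconds, overlap = overlap,
                 hidden = hidden, activation = activation, ibgso = ibgso,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "protocol_config")
}

#' Leave-one-subject-out folds
#'
#' One fold per subject; each subject is the held-out test set exactly once.
#'
#' @param dataset a `sensor_dataset` (or any data frame with a `subject`
#'   column).
#' @return list of folds, each a list with `train` and `test` subject ids.
#' @export
loso_split <- function(dataset) {
  subjects <- sort(unique(dataset$subject))
  if (length(subjects) < 2L)
    stop_glowsel("leave-one-subject-out needs at least 2 subjects")
  lapply(subjects, function(s)
    list(train = setdiff(subjects, s), test = s))
}

#' Run the full select-then-deploy protocol
#'
#' For every leave-one-subject-out fold and repeat: extract and normalize
#' features (normalization bounds fitted on the training subjects only),
#' train the per-sensor ELM pool on the training subjects, search for the
#' best sensor subset with the binary glowworm swarm using the fitness
#' `omega * A_tr - (1 - omega) * m / M` (A_tr = resubstitution accuracy of
#' the masked majority vote on the training windows), then evaluate both
#' the pruned ensemble and the full "ensemble all" baseline on the held-out
#' subject.
#'
#' @param dataset a `sensor_dataset`.
#' @param config a [protocol_config()].
#' @return object of class `evaluation_report`: list with `runs` (one entry
#'   per fold x repeat: fold, repeat, test subject, seeds, selection result,
#'   pruned and full-ensemble metrics), `aggregate` (means over runs) and
#'   `config`.
#' @export
run_protocol <- function(dataset, config = protocol_config()) {
  if (!inherits(config, "protocol_config")) stop_glowsel("config must be a protocol_config")
  features <- build_feature_table(dataset, config$window_seconds, config$overlap)
  folds <- loso_split(features)
  M <- length(unique(features$sensor))

  runs <- list()
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    train_rows <- features[features$subject %in% fold$train, ]
    test_rows <- features[features$subject == fold$test, ]
    bounds <- fit_normalizer(train_rows)
    train_norm <- apply_normalizer(bounds, train_rows)
    test_norm <- apply_normalizer(bounds, test_rows)

    for (r in seq_len(config$n_repeats)) {
      run_id <- (f - 1L) * config$n_repeats + r
      pool_seed <- derive_seed(config$seed, 2L * run_id)
      swarm_seed <- derive_seed(config$seed, 2L * run_id + 1L)

      pool <- train_pool(train_norm, hidden = config$hidden,
                         activation = config$activation, seed = pool_seed)
      tr <- pool_predictions(pool, train_norm)
      fitness_fn <- function(mask) {
        fused <- majority_vote(tr$predictions, mask, tr$class_labels)
        a_tr <- mean(fused == tr$truth)
        list(fitness = subset_fitness(mask, a_tr, config$ibgso$omega),
             accuracy = a_tr)
      }
      cfg <- config$ibgso
      cfg$seed <- swarm_seed
      sel <- run_ibgso(fitness_fn, M, cfg)

      te <- pool_predictions(pool, test_norm)
      full_mask <- rep(1L, M)
      pruned <- compute_metrics(
        te$truth, majority_vote(te$predictions, sel$mask, te$class_labels),
        te$class_labels)
      full <- compute_metrics(
        te$truth, majority_vote(te$predictions, full_mask, te$class_labels),
        te$class_labels)

      runs[[length(runs) + 1L]] <- list(
        fold = f, rep = r, test_subject = fold$test,
        pool_seed = pool_seed, swarm_seed = swarm_seed,
        selection = sel,
        selected_sensors = pool$sensor_ids[sel$selected],
        pruned = pruned, full = full)
    }
  }

  agg <- function(fn) mean(vapply(runs, fn, numeric(1)))
  aggregate <- list(
    n_runs = length(runs),
    M = M,
    pruned_accuracy = agg(function(x) x$pruned$accuracy),
    pruned_macro_f1 = agg(function(x) x$pruned$macro_f1),
    full_accuracy = agg(function(x) x$full$accuracy),
    full_macro_f1 = agg(function(x) x$full$macro_f1),
    mean_size = agg(function(x) x$selection$selected_count),
    omega = config$ibgso$omega)
  structure(list(runs = runs, aggregate = aggregate, config = config),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(paste0(
    "leave-one-subject-out evaluation over %d run(s), pool of %d sensors ",
    "(omega = %.2f)\n",
    "  pruned ensemble : accuracy %.4f, macro-F1 %.4f, mean size %.1f\n",
    "  ensemble all    : accuracy %.4f, macro-F1 %.4f, size %d\n"),
    a$n_runs, a$M, a$omega, a$pruned_accuracy, a$pruned_macro_f1,
    a$mean_size, a$full_accuracy, a$full_macro_f1, a$M))
  invisible(x)
}

#' Selection quality against known informative sensors
#'
#' For synthetic data with known ground truth, measures how well the
#' selected sensor sets recover the informative set: per-run precision,
#' recall and Jaccard index, plus the same statistics for the pooled
#' (union) selection across runs.
#'
#' @param report an `evaluation_report`.
#' @param truth integer vector of informative sensor ids (non-empty).
#' @return list with `per_run` data frame (run, precision, recall,
#'   jaccard, size), `median_jaccard`, `mean_size` and `pooled`
#'   (statistics of the union of all selections).
#' @export
recover_informative <- function(report, truth) {
  if (!length(truth)) stop_glowsel("truth set is empty")
  truth <- unique(as.integer(truth))
  overlap_stats <- function(sel) {
    inter <- length(intersect(sel, truth))
    c(precision = if (length(sel)) inter / length(sel) else 0,
      recall = inter / length(truth),
      jaccard = inter / length(union(sel, truth)))
  }
  per <- do.call(rbind, lapply(seq_along(report$runs), function(i) {
    sel <- report$runs[[i]]$selected_sensors
    data.frame(run = i, t(overlap_stats(sel)), size = length(sel))
  }))
  pooled_sel <- sort(unique(unlist(lapply(report$runs, `[[`, "selected_sensors"))))
  list(per_run = per,
       median_jaccard = median(per$jaccard),
       mean_size = mean(per$size),
       pooled = as.list(overlap_stats(pooled_sel)))
}

#' Write an evaluation report to disk
#'
#' Emits `report.json` (runs, aggregates, config, seeds) plus one confusion
#' matrix CSV and one fitness-trace CSV per run, in `dir`.
#'
#' @param report an `evaluation_report`.
#' @param dir existing output directory.
#' @return the path of the JSON file, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) stop_glowsel("output directory '%s' does not exist", dir)
  payload <- list(
    aggregate = report$aggregate,
    config = report$config[setdiff(names(report$config), "ibgso")],
    ibgso = unclass(report$config$ibgso),
    runs = lapply(report$runs, function(run) list(
      fold = run$fold, rep = run$rep, test_subject = run$test_subject,
      pool_seed = run$pool_seed, swarm_seed = run$swarm_seed,
      mask = run$selection$mask,
      selected_sensors = run$selected_sensors,
      fitness = run$selection$fitness,
      training_accuracy = run$selection$training_accuracy,
      pruned_accuracy = run$pruned$accuracy,
      pruned_macro_f1 = run$pruned$macro_f1,
      full_accuracy = run$full$accuracy,
      full_macro_f1 = run$full$macro_f1)))
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  for (i in seq_along(report$runs)) {
    run <- report$runs[[i]]
    tag <- sprintf("fold%d_rep%d", run$fold, run$rep)
    write_confusion_csv(run$pruned, file.path(dir, sprintf("confusion_%s.csv", tag)))
    write_trace_csv(run$selection, file.path(dir, sprintf("trace_%s.csv", tag)))
  }
  invisible(json_path)
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  json_path <- file.path(dir, "report.json")
  if (!file.exists(json_path)) stop_glowsel("no report.json under '%s'", dir)
  jsonlite::read_json(json_path, simplifyVector = TRUE)
}
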