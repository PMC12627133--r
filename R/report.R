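#' Per-participant block accuracies
#'
#' Accuracy of each participant in each block of each task (training blocks
#' and the generalization test).
#'
#' @param trials A trial tibble.
#' @return A tibble: `participant_id`, `group`, `modality`, `task`,
#'   `block`, `accuracy`, `n_trials`.
#' @export
participant_block_accuracy <- function(trials) {
  trials |>
    dplyr::group_by(.data$participant_id, .data$group, .data$modality,
                    .data$task, .data$block) |>
    dplyr::summarise(accuracy = mean(.data$correct),
                     n_trials = dplyr::n(), .groups = "drop")
}

#' Blockwise learning curves
#'
#' Aggregates per-participant block accuracies to stratum (group x
#' modality x task x block) means with SD and standard error of the mean.
#'
#' @param trials A trial tibble.
#' @return A tibble: stratum keys, `mean_accuracy`, `sd`, `sem`, `n`
#'   (participants).
#' @export
blockwise_accuracy <- function(trials) {
  participant_block_accuracy(trials) |>
    dplyr::group_by(.data$group, .data$modality, .data$task, .data$block) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      sd = stats::sd(.data$accuracy),
      n = dplyr::n(),
      sem = .data$sd / sqrt(.data$n),
      .groups = "drop") |>
    dplyr::relocate("sem", .before = "n")
}

#' Generalization-transfer scores
#'
#' Transfer accuracy per participant and task: generalization-test accuracy
#' minus final training-block accuracy, in `[-1, 1]`.
#'
#' @param trials A trial tibble containing both block `"8"` and `"test"`
#'   records for every participant-task.
#' @return A tibble: `participant_id`, `group`, `modality`, `task`,
#'   `test_accuracy`, `final_accuracy`, `transfer`.
#' @export
transfer_scores <- function(trials) {
  acc <- participant_block_accuracy(trials)
  wide <- acc |>
    dplyr::filter(.data$block %in% c("8", "test")) |>
    dplyr::select(-"n_trials") |>
    tidyr::pivot_wider(names_from = "block", values_from = "accuracy")
  if (!all(c("8", "test") %in% names(wide)) || anyNA(wide[["test"]]) ||
      anyNA(wide[["8"]])) {
    stop("missing test or final training block for some participant-task",
         call. = FALSE)
  }
  dplyr::transmute(wide,
    .data$participant_id, .data$group, .data$modality, .data$task,
    test_accuracy = .data[["test"]], final_accuracy = .data[["8"]],
    transfer = .data[["test"]] - .data[["8"]])
}

#' Correlation between symptom severity and learning performance
#'
#' Pearson correlation between each participant's ASRS score and their
#' overall training performance — the unweighted mean of the 32
#' participant-task-block accuracies (8 training blocks x 2 modalities x 2
#' category types) — with a Fisher-z 95% confidence interval.
#'
#' @param participants Participant tibble with `participant_id`,
#'   `asrs_score`.
#' @param trials A trial tibble (training blocks are used).
#' @return An object of class `symptom_correlation`; [generics::tidy()]
#'   returns a one-row tibble with `estimate`, `conf.low`, `conf.high`,
#'   `statistic`, `df`, `p.value`, `n`.
#' @export
symptom_correlation <- function(participants, trials) {
  stopifnot(nrow(participants) >= 4)
  perf <- participant_block_accuracy(trials) |>
    dplyr::filter(.data$block != "test") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy), .groups = "drop")
  d <- dplyr::inner_join(participants, perf, by = "participant_id")
  if (stats::sd(d$asrs_score) == 0 || stats::sd(d$mean_accuracy) == 0) {
    stop("undefined correlation: zero variance in ASRS or accuracy",
         call. = FALSE)
  }
  ct <- stats::cor.test(d$asrs_score, d$mean_accuracy, method = "pearson")
  structure(list(test = ct, n = nrow(d), data = d),
            class = "symptom_correlation")
}

#' @export
print.symptom_correlation <- function(x, ...) {
  cat(sprintf("ASRS-accuracy correlation: r(%d) = %.3f, 95%% CI [%.3f, %.3f], p = %.2g\n",
              x$test$parameter, x$test$estimate, x$test$conf.int[1],
              x$test$conf.int[2], x$test$p.value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.symptom_correlation <- function(x, ...) {
  tibble::tibble(estimate = unname(x$test$estimate),
                 conf.low = x$test$conf.int[1],
                 conf.high = x$test$conf.int[2],
                 statistic = unname(x$test$statistic),
                 df = unname(x$test$parameter),
                 p.value = x$test$p.value,
                 n = x$n)
}

#' @exportS3Method generics::glance
glance.symptom_correlation <- function(x, ...) tidy(x)

#' Pipeline configuration
#'
#' Settings for the end-to-end driver [run_pipeline()].
#'
#' @param seed Master seed for the run.
#' @param n_per_group Participants per group.
#' @param cohort A [cohort_config()].
#' @param control A [fit_control()].
#' @param stimulus_seed Seed for the shared stimulus sets.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_per_group = 15,
                            cohort = cohort_config(),
                            control = fit_control(),
                            stimulus_seed = catbound_fixture_seed) {
  structure(list(seed = seed, n_per_group = n_per_group, cohort = cohort,
                 control = control, stimulus_seed = stimulus_seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Generate the four task stimulus sets, simulate a cohort, fit the
#' decision-bound models to every participant-block, derive the strategy
#' metrics and descriptive summaries, and write everything to `out_dir` as
#' CSV, with a JSON manifest recording the seeds, package version, config
#' hash, and per-stage row counts.  Reruns with the same config reproduce
#' identical CSVs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  conditions <- expand.grid(modality = c("auditory", "visual"),
                            task = c("RB", "II"), stringsAsFactors = FALSE)
  stimuli <- stage("stimuli", purrr::pmap_dfr(conditions, function(modality, task) {
    fixture_stimuli(modality, task, seed = config$stimulus_seed)
  }))
  write_stimuli(stimuli, file.path(out_dir, "stimuli.csv"))

  cohort <- stage("simulate", simulate_cohort(
    config$n_per_group, config$cohort, seed = config$seed,
    stimulus_seed = config$stimulus_seed))
  write_trials(cohort$trials, file.path(out_dir, "trials.csv"))
  readr::write_csv(cohort$participants, file.path(out_dir, "participants.csv"))

  fits <- stage("fit", fit_trials(cohort$trials, config$control))
  write_fits(fits, file.path(out_dir, "fits.csv"))

  metrics <- stage("metrics", strategy_metrics(fits, cohort$trials))
  readr::write_csv(metrics, file.path(out_dir, "strategy_metrics.csv"))

  summaries <- stage("report", {
    acc <- blockwise_accuracy(cohort$trials)
    readr::write_csv(acc, file.path(out_dir, "summary_accuracy.csv"))
    transfer <- transfer_scores(cohort$trials)
    readr::write_csv(transfer, file.path(out_dir, "transfer.csv"))
    corr <- tidy(symptom_correlation(cohort$participants, cohort$trials))
    readr::write_csv(corr, file.path(out_dir, "correlation.csv"))
    list(acc = acc, transfer = transfer, corr = corr)
  })

  manifest <- list(
    package = "catbound",
    version = as.character(utils::packageVersion("catbound")),
    seed = config$seed,
    stimulus_seed = config$stimulus_seed,
    n_per_group = config$n_per_group,
    config_hash = rlang::hash(config),
    rows = list(stimuli = nrow(stimuli), trials = nrow(cohort$trials),
                participants = nrow(cohort$participants), fits = nrow(fits),
                metrics = nrow(metrics),
                summary_accuracy = nrow(summaries$acc),
                transfer = nrow(summaries$transfer)),
    conditions = paste(conditions$modality, conditions$task)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
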