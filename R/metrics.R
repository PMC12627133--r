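#' Collapse model families into strategy labels
#'
#' Maps the nine fitted model variants onto the four reported strategy
#' labels: the GLC is the procedural (linear-integration) strategy marker,
#' unidimensional models keep their dimension regardless of response
#' assignment, and all guessing variants collapse to `"random"`.
#'
#' @param family Character vector of model families.
#' @return Character vector over
#'   `{"procedural", "uni_x", "uni_y", "random"}`.
#' @examples
#' collapse_family(c("glc", "guess_biased_A", "uni_x"))
#' @export
collapse_family <- function(family) {
  out <- dplyr::case_match(family,
    "glc" ~ "procedural",
    "uni_x" ~ "uni_x",
    "uni_y" ~ "uni_y",
    c("guess_fixed", "guess_biased_A", "guess_biased_B") ~ "random"
  )
  if (anyNA(out)) stop("unknown model family", call. = FALSE)
  out
}

#' The optimal strategy label for a task
#'
#' @param task `"RB"` or `"II"` (vectorized).
#' @return `"uni_x"` for RB (the relevant dimension), `"procedural"` for II.
#' @export
optimal_label <- function(task) {
  ifelse(task == "RB", "uni_x", "procedural")
}

#' Per-block strategy trajectories
#'
#' Collapses a best-model fit table into one strategy label per
#' participant-task-block (8 training blocks + test), with the task's
#' optimal label attached.
#'
#' @param fits Best-model fit tibble from [fit_trials()].
#' @return A tibble: `participant_id`, `group`, `modality`, `task`,
#'   `block`, `label`, `optimal_label`.
#' @export
strategy_trajectories <- function(fits) {
  if ("best_flag" %in% names(fits)) fits <- fits[fits$best_flag, ]
  dplyr::transmute(fits,
    .data$participant_id, .data$group, .data$modality, .data$task,
    .data$block,
    label = collapse_family(.data$family),
    optimal_label = optimal_label(.data$task))
}

#' First training block using the optimal strategy
#'
#' @param labels Character vector of training-block labels, in block order
#'   (test block excluded).
#' @param optimal The task's optimal label.
#' @param censor Value returned when the optimal strategy never appears
#'   during training (default `length(labels) + 1`, i.e. 9 for 8 blocks).
#' @return Integer block index.
#' @export
first_optimal_block <- function(labels, optimal,
                                censor = length(labels) + 1L) {
  hit <- which(labels == optimal)
  if (length(hit) == 0) as.integer(censor) else as.integer(hit[1])
}

#' @rdname first_optimal_block
#' @export
total_optimal_blocks <- function(labels, optimal) {
  sum(labels == optimal)
}

#' Strategy-use metrics per participant and task
#'
#' Derives the per-participant strategy measures from a best-model fit
#' table and the trial table: the first training block in which the
#' task-optimal strategy was used (coded `n_blocks + 1 = 9` if never
#' used), the total number of training blocks using it, the final
#' training-block label, and final-block accuracy among participants whose
#' final-block strategy was optimal (`NA`, i.e. excluded, otherwise).
#' The test block contributes to none of these counts.
#'
#' @param fits Best-model fit tibble from [fit_trials()].
#' @param trials Trial tibble (for final-block accuracy).
#' @param censor Censoring code for never-optimal trajectories.
#' @return A tibble: `participant_id`, `group`, `modality`, `task`,
#'   `first_optimal_block`, `total_optimal_blocks`, `final_block_label`,
#'   `accuracy_given_optimal`.
#' @export
strategy_metrics <- function(fits, trials, censor = 9L) {
  traj <- strategy_trajectories(fits)
  training <- dplyr::filter(traj, .data$block != "test")
  final_acc <- trials |>
    dplyr::filter(.data$block == "8") |>
    dplyr::group_by(.data$participant_id, .data$modality, .data$task) |>
    dplyr::summarise(final_accuracy = mean(.data$correct), .groups = "drop")
  training |>
    dplyr::group_by(.data$participant_id, .data$group, .data$modality,
                    .data$task) |>
    dplyr::arrange(as.integer(.data$block), .by_group = TRUE) |>
    dplyr::summarise(
      first_optimal_block = first_optimal_block(
        .data$label, .data$optimal_label[1], censor),
      total_optimal_blocks = total_optimal_blocks(
        .data$label, .data$optimal_label[1]),
      final_block_label = .data$label[.data$block == "8"],
      final_optimal = .data$final_block_label == .data$optimal_label[1],
      .groups = "drop") |>
    dplyr::left_join(final_acc,
                     by = c("participant_id", "modality", "task")) |>
    dplyr::mutate(accuracy_given_optimal =
                    ifelse(.data$final_optimal, .data$final_accuracy,
                           NA_real_)) |>
    dplyr::select(-"final_optimal", -"final_accuracy")
}

#' Strategy proportions by stratum
#'
#' Proportion of participants using each strategy label, per group x
#' modality x task x block (training blocks and test), with absent labels
#' filled as 0 so each stratum's proportions sum to 1.
#'
#' @param fits Best-model fit tibble from [fit_trials()].
#' @return A tibble: stratum keys, `label`, `n`, `proportion`.
#' @export
strategy_proportions <- function(fits) {
  traj <- strategy_trajectories(fits)
  if (nrow(traj) == 0) stop("empty stratum: no fits supplied", call. = FALSE)
  counts <- dplyr::count(traj, .data$group, .data$modality, .data$task,
                         .data$block, .data$label)
  strata <- dplyr::distinct(counts, .data$group, .data$modality, .data$task,
                            .data$block)
  tidyr::crossing(strata,
                  label = c("procedural", "uni_x", "uni_y", "random")) |>
    dplyr::left_join(counts,
                     by = c("group", "modality", "task", "block", "label")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::group_by(.data$group, .data$modality, .data$task, .data$block) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
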