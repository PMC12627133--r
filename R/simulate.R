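#' Learner profiles
#'
#' A learner profile bundles a participant's identity, group, ADHD-symptom
#' score (ASRS; screening threshold >= 51), and a per-block strategy
#' schedule: one [strategy()] for each of the 8 training blocks plus the
#' feedback-free `"test"` block.  Strategies are scheduled, not learned —
#' the simulator emulates observed strategy trajectories rather than a
#' trial-level learning process.
#'
#' @param participant_id Identifier string.
#' @param group `"control"` or `"ADHD"`.
#' @param asrs_score ASRS symptom score.  Scores >= 51 require
#'   `group = "ADHD"` (the screening rule).
#' @param schedule Named list of [strategy()] objects covering `"1"` ..
#'   `"8"` and `"test"`.
#' @param age Optional age in years.
#' @return An object of class `learner_profile`.
#' @export
learner_profile <- function(participant_id, group = c("control", "ADHD"),
                            asrs_score, schedule, age = NA_real_) {
  group <- match.arg(group)
  needed <- c(as.character(1:8), "test")
  missing <- setdiff(needed, names(schedule))
  if (length(missing) > 0) {
    stop("schedule is missing strategies for block(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (asrs_score >= 51 && group != "ADHD") {
    stop("asrs_score >= 51 implies group = \"ADHD\" under the screening rule",
         call. = FALSE)
  }
  stopifnot(all(vapply(schedule[needed], inherits, logical(1), "strategy")))
  structure(list(participant_id = participant_id, group = group,
                 asrs_score = asrs_score, schedule = schedule[needed],
                 age = age),
            class = "learner_profile")
}

#' The task-optimal strategy for a category structure
#'
#' Unidimensional rule on the relevant dimension for RB structures,
#' procedural (linear-integration) strategy on the discriminant bound for
#' II structures.
#'
#' @param dists Two-row tibble from [category_distributions()].
#' @param noise_sigma Noise SD in normalized units.
#' @param lapse_rate Lapse probability.
#' @return A [strategy()] object.
#' @export
optimal_strategy <- function(dists, noise_sigma, lapse_rate = 0) {
  bound <- optimal_boundary(dists)
  family <- if (dists$task[1] == "RB") {
    if (bound$b == 0) "uni_x" else "uni_y"
  } else "procedural"
  strategy(family, bound = bound, noise_sigma = noise_sigma,
           lapse_rate = lapse_rate)
}

# Deal the 200 training stimuli into blocks: within each half of training
# (blocks 1-4 and 5-8) each category's 100 stimuli are shuffled and dealt
# 25 per block, so each half exhausts the full set ("randomly but evenly").
.deal_blocks <- function(stimuli) {
  rows_A <- which(stimuli$category == "A")
  rows_B <- which(stimuli$category == "B")
  stopifnot(length(rows_A) == 100, length(rows_B) == 100)
  blocks <- vector("list", 8)
  for (half in 0:1) {
    a <- sample(rows_A)
    b <- sample(rows_B)
    for (j in 1:4) {
      idx <- c(a[(j - 1) * 25 + 1:25], b[(j - 1) * 25 + 1:25])
      blocks[[half * 4 + j]] <- sample(idx)
    }
  }
  blocks
}

#' Simulate one participant's session on one task
#'
#' Eight 50-trial training blocks (25 per category per block; each half of
#' training, blocks 1-4 and 5-8, presents every training stimulus exactly
#' once) with feedback, followed by a feedback-free generalization test on
#' the grid.  On each trial the response is drawn from
#' [response_prob()] under the block's scheduled strategy.
#'
#' @param profile A [learner_profile()].
#' @param stimuli Training stimulus tibble (200 stimuli, 100 per category).
#' @param grid Generalization grid tibble from [generalization_grid()].
#' @param seed Integer seed; the same seed reproduces the session exactly.
#' @return A trial tibble: `participant_id`, `group`, `modality`, `task`,
#'   `block` (`"1"` .. `"8"` or `"test"`), `trial_index`, `stimulus_id`,
#'   `x_norm`, `y_norm`, `true_category`, `response`, `correct`,
#'   `feedback_given` — 464 rows (400 training + 64 test).
#' @export
simulate_session <- function(profile, stimuli, grid, seed = NULL) {
  stopifnot(inherits(profile, "learner_profile"), nrow(stimuli) == 200)
  run <- function() {
    blocks <- .deal_blocks(stimuli)
    one_block <- function(block_name, rows, set, feedback) {
      strat <- profile$schedule[[block_name]]
      xs <- set$x_norm[rows]
      ys <- set$y_norm[rows]
      p <- pmin(pmax(response_prob(strat, xs, ys), 1e-10), 1 - 1e-10)
      resp <- ifelse(stats::runif(length(rows)) < p, "A", "B")
      tibble::tibble(
        participant_id = profile$participant_id, group = profile$group,
        modality = set$modality[rows], task = set$task[rows],
        block = block_name, trial_index = seq_along(rows),
        stimulus_id = set$id[rows],
        x_norm = xs, y_norm = ys,
        true_category = set$category[rows],
        response = resp, correct = resp == set$category[rows],
        feedback_given = feedback
      )
    }
    training <- purrr::map(1:8, function(b) {
      one_block(as.character(b), blocks[[b]], stimuli, TRUE)
    })
    test <- one_block("test", sample(nrow(grid)), grid, FALSE)
    dplyr::bind_rows(training, list(test))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Default cohort configuration
#'
#' Parameters of the synthetic two-group cohort.  ADHD-like learners adopt
#' the task-optimal strategy later (onset block uniform on 2..7 vs 1..4 for
#' controls), respond with more decision noise (sigma 0.12 vs 0.08
#' normalized units), and carry higher, more variable ASRS symptom scores
#' (Normal(60, 11.4) truncated at >= 51, vs Normal(35, 6.4) truncated below
#' 51 for controls, respecting the screening rule).  A small positive
#' `sigma_asrs_slope` ties individual noise to symptom severity so that the
#' symptom-performance association also holds within groups.  Before the
#' onset block, learners use either fixed guessing or a suboptimal
#' unidimensional rule, with equal probability.
#'
#' @param onset_blocks Named list of candidate first-optimal blocks per
#'   group (uniform draw).
#' @param noise_sigma Named numeric: baseline noise SD per group.
#' @param sigma_asrs_slope Added noise SD per ASRS point above the group
#'   mean.
#' @param asrs Named list of `c(mean, sd)` per group.
#' @param age Named list of `c(mean, sd)` per group.
#' @param lapse_rate Lapse probability for all strategies.
#' @return A named list of class `cohort_config`.
#' @export
cohort_config <- function(onset_blocks = list(control = 1:4, ADHD = 2:7),
                          noise_sigma = c(control = 0.08, ADHD = 0.12),
                          sigma_asrs_slope = 0.002,
                          asrs = list(control = c(mean = 35, sd = 6.4),
                                      ADHD = c(mean = 60, sd = 11.4)),
                          age = list(control = c(mean = 24.2, sd = 2.2),
                                     ADHD = c(mean = 26.2, sd = 3.4)),
                          lapse_rate = 0) {
  structure(list(onset_blocks = onset_blocks, noise_sigma = noise_sigma,
                 sigma_asrs_slope = sigma_asrs_slope, asrs = asrs,
                 age = age, lapse_rate = lapse_rate),
            class = "cohort_config")
}

# ASRS scores truncated at the screening threshold: controls < 51 <= ADHD.
.draw_asrs <- function(n, group, config) {
  pars <- config$asrs[[group]]
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * n, pars["mean"], pars["sd"])
    draw <- if (group == "ADHD") draw[draw >= 51] else draw[draw < 51]
    out <- c(out, draw)
  }
  out[seq_len(n)]
}

# Pre-onset (suboptimal) strategy: fair coin between fixed guessing and a
# unidimensional rule that is not the task-optimal one.
.suboptimal_strategy <- function(task, sigma, lapse) {
  if (stats::runif(1) < 0.5) {
    return(strategy("guess_fixed", lapse_rate = lapse))
  }
  axis <- if (task == "RB") "y" else sample(c("x", "y"), 1)
  side <- sample(c("high", "low"), 1)
  strategy(if (axis == "x") "uni_x" else "uni_y",
           bound = unidimensional_bound(axis, stats::runif(1, 0.3, 0.7), side),
           noise_sigma = sigma, lapse_rate = lapse)
}

#' Simulate a two-group cohort across all four tasks
#'
#' Simulates `n_per_group` control and `n_per_group` ADHD-like
#' participants, each completing all four tasks (auditory/visual x RB/II):
#' 8 training blocks of 50 trials plus a 64-trial generalization test per
#' task.  All participants see the same fixture stimulus sets, as in the
#' experiment being emulated.  Group differences arise solely from the
#' configuration: later optimal-strategy onset, larger noise, and higher
#' ASRS scores for the ADHD-like group.
#'
#' @param n_per_group Participants per group (>= 1).
#' @param config A [cohort_config()].
#' @param seed Integer seed for the whole cohort.
#' @param stimulus_seed Seed for the shared fixture stimulus sets.
#' @return A list with elements `trials` (one trial tibble, 464 rows per
#'   participant-task) and `participants` (`participant_id`, `group`,
#'   `asrs_score`, `age`).
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(2, seed = 1)
#' dplyr::count(cohort$trials, group, task)
#' }
#' @export
simulate_cohort <- function(n_per_group, config = cohort_config(), seed = NULL,
                            stimulus_seed = catbound_fixture_seed) {
  stopifnot(n_per_group >= 1)
  conditions <- expand.grid(modality = c("auditory", "visual"),
                            task = c("RB", "II"), stringsAsFactors = FALSE)
  sets <- purrr::pmap(conditions, function(modality, task) {
    dists <- category_distributions(modality, task)
    list(dists = dists,
         stimuli = fixture_stimuli(modality, task, seed = stimulus_seed),
         grid = generalization_grid(dists))
  })
  run <- function() {
    participants <- purrr::map_dfr(c("control", "ADHD"), function(grp) {
      pars_age <- config$age[[grp]]
      tibble::tibble(
        participant_id = sprintf("%s%03d", if (grp == "ADHD") "adhd" else "ctrl",
                                 seq_len(n_per_group)),
        group = grp,
        asrs_score = .draw_asrs(n_per_group, grp, config),
        age = round(stats::rnorm(n_per_group, pars_age["mean"], pars_age["sd"]), 1)
      )
    })
    trials <- purrr::map_dfr(seq_len(nrow(participants)), function(i) {
      p <- participants[i, ]
      sigma <- max(
        config$noise_sigma[[p$group]] +
          config$sigma_asrs_slope *
            (p$asrs_score - config$asrs[[p$group]]["mean"]),
        0.02)
      purrr::map_dfr(seq_along(sets), function(k) {
        s <- sets[[k]]
        onset <- sample(config$onset_blocks[[p$group]], 1)
        opt <- optimal_strategy(s$dists, sigma, config$lapse_rate)
        schedule <- lapply(1:8, function(b) {
          if (b >= onset) opt
          else .suboptimal_strategy(s$dists$task[1], sigma, config$lapse_rate)
        })
        names(schedule) <- as.character(1:8)
        schedule[["test"]] <- schedule[["8"]]
        profile <- learner_profile(p$participant_id, p$group, p$asrs_score,
                                   schedule, age = p$age)
        simulate_session(profile, s$stimuli, s$grid)
      })
    })
    list(trials = trials, participants = participants)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Read and write trial tables as CSV
#'
#' Header: `participant_id,group,modality,task,block,trial_index,`
#' `stimulus_id,x_norm,y_norm,true_category,response,correct,feedback_given`
#' with `block` in `"1"` .. `"8"` or `"test"`.
#'
#' @param trials A trial tibble.
#' @param path File path.
#' @return `read_trials()` returns the trial tibble; `write_trials()`
#'   returns `trials` invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- c("participant_id", "group", "modality", "task", "block",
            "trial_index", "stimulus_id", "x_norm", "y_norm",
            "true_category", "response", "correct", "feedback_given")
  readr::write_csv(trials[cols], path)
  invisible(trials)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(), group = readr::col_character(),
    modality = readr::col_character(), task = readr::col_character(),
    block = readr::col_character(), trial_index = readr::col_integer(),
    stimulus_id = readr::col_integer(), x_norm = readr::col_double(),
    y_norm = readr::col_double(), true_category = readr::col_character(),
    response = readr::col_character(), correct = readr::col_logical(),
    feedback_given = readr::col_logical()
  ))
}
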