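# Hand-built trial table: each participant-block is a run of known accuracy.
toy_trials <- function(spec) {
  purrr::pmap_dfr(spec, function(id, group, block, n_correct, n) {
    tibble::tibble(participant_id = id, group = group, modality = "auditory",
                   task = "RB", block = block, trial_index = seq_len(n),
                   correct = rep(c(TRUE, FALSE), c(n_correct, n - n_correct)))
  })
}

test_that("blockwise accuracy aggregates with exact SD and SEM", {
  tr <- toy_trials(tibble::tribble(
    ~id, ~group, ~block, ~n_correct, ~n,
    "p1", "control", "1", 40L, 50L,
    "p2", "control", "1", 30L, 50L,
    "p3", "control", "1", 40L, 50L))
  one <- blockwise_accuracy(tr[tr$participant_id == "p1", ])
  expect_equal(one$mean_accuracy, 0.8)
  expect_identical(one$n, 1L)

  two <- blockwise_accuracy(tr[tr$participant_id != "p3", ])
  expect_equal(two$mean_accuracy, 0.7)
  expect_equal(two$sd, sqrt((0.1^2 + 0.1^2) / 1), tolerance = 1e-12)  # 0.1414
  expect_equal(two$sem, two$sd / sqrt(2), tolerance = 1e-12)          # 0.10
  # equal trial counts: stratum mean equals the raw trial-level proportion
  all3 <- blockwise_accuracy(tr)
  expect_equal(all3$mean_accuracy, mean(tr$correct), tolerance = 1e-12)
})

test_that("transfer scores equal test-minus-final and cross-check blockwise output", {
  tr <- toy_trials(tibble::tribble(
    ~id, ~group, ~block, ~n_correct, ~n,
    "p1", "control", "8", 75L, 100L,
    "p1", "control", "test", 80L, 100L,
    "p2", "control", "8", 60L, 100L,
    "p2", "control", "test", 60L, 100L))
  ts <- transfer_scores(tr)
  expect_equal(ts$transfer[ts$participant_id == "p1"], 0.05)
  expect_equal(ts$transfer[ts$participant_id == "p2"], 0)
  # independent route through the aggregated accuracies
  acc <- participant_block_accuracy(tr)
  indep <- acc$accuracy[acc$block == "test"] - acc$accuracy[acc$block == "8"]
  expect_equal(sort(ts$transfer), sort(indep), tolerance = 1e-12)
  expect_error(transfer_scores(tr[tr$block == "8", ]), "missing")
})

test_that("a stationary strategy yields near-zero mean transfer", {
  d <- category_distributions("auditory", "II")
  set <- cached_fixture("auditory", "II")
  grid <- generalization_grid(d)
  prof <- uniform_schedule_profile(optimal_strategy(d, 0.12))
  transfers <- sapply(1:10, function(seed) {
    tr <- simulate_session(prof, set, grid, seed = seed)
    transfer_scores(tr)$transfer
  })
  expect_lt(abs(mean(transfers)), 0.04)
})

test_that("symptom correlation recovers exact and degenerate cases", {
  participants <- tibble::tibble(
    participant_id = paste0("p", 1:4), group = "control",
    asrs_score = c(10, 20, 30, 40))
  tr <- toy_trials(tibble::tibble(
    id = paste0("p", 1:4), group = "control", block = "1",
    n_correct = c(45L, 40L, 35L, 30L), n = 50L))
  sc <- symptom_correlation(participants, tr)
  td <- tidy(sc)
  expect_equal(td$estimate, -1, tolerance = 1e-12)
  expect_identical(td$n, 4L)
  expect_identical(tidy(sc), glance(sc))

  flat <- tr
  flat$correct <- TRUE
  expect_error(symptom_correlation(participants, flat), "zero variance")
  same_asrs <- participants
  same_asrs$asrs_score <- 30
  expect_error(symptom_correlation(same_asrs, tr), "zero variance")
})

test_that("the null symptom configuration shows no correlation bias", {
  # ASRS resampled independently of simulated accuracy: the correlation
  # should be centered on zero across seeds
  co <- simulate_cohort(10, seed = 77)
  rs <- sapply(1:12, function(seed) {
    p <- co$participants
    p$asrs_score <- withr::with_seed(seed, stats::rnorm(nrow(p), 45, 8))
    tidy(symptom_correlation(p, co$trials))$estimate
  })
  expect_lt(abs(mean(rs)), 0.3)
})

test_that("the pipeline writes every stage and reruns byte-identically", {
  cfg <- pipeline_config(seed = 3L, n_per_group = 2)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  m1 <- run_pipeline(cfg, out1)
  m2 <- run_pipeline(cfg, out2)
  files <- c("stimuli.csv", "trials.csv", "participants.csv", "fits.csv",
             "strategy_metrics.csv", "summary_accuracy.csv", "transfer.csv",
             "correlation.csv", "manifest.json")
  for (f in files) {
    expect_true(file.exists(file.path(out1, f)), label = f)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  expect_identical(m1$config_hash, m2$config_hash)
  expect_identical(m1$rows$trials, 2L * 2L * 4L * 464L)
  expect_identical(m1$rows$fits, 2L * 2L * 4L * 9L)
  expect_identical(m1$rows$stimuli, 4L * 200L)
})

test_that("plot builders return ggplot objects", {
  tr <- toy_trials(tibble::tribble(
    ~id, ~group, ~block, ~n_correct, ~n,
    "p1", "control", "1", 40L, 50L,
    "p1", "control", "8", 42L, 50L,
    "p1", "control", "test", 40L, 50L,
    "p2", "ADHD", "1", 30L, 50L,
    "p2", "ADHD", "8", 35L, 50L,
    "p2", "ADHD", "test", 33L, 50L))
  expect_s3_class(plot_learning_curves(blockwise_accuracy(tr)), "ggplot")
  expect_s3_class(plot_transfer(transfer_scores(tr)), "ggplot")
  set <- cached_fixture("auditory", "RB")
  b <- optimal_boundary(category_distributions("auditory", "RB"))
  expect_s3_class(plot_stimulus_space(set, b), "ggplot")
})
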