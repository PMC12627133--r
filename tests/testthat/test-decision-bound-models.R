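test_that("BIC follows its closed form", {
  l_guess <- 50 * log(0.5)
  expect_equal(bic(0, 50, l_guess), 100 * log(2))           # 69.315
  expect_equal(bic(2, 50, l_guess), 2 * log(50) + 100 * log(2))  # 77.139
  expect_identical(bic(0, 17, 0), 0)
})

test_that("model inventory carries the published free-parameter counts", {
  inv <- model_inventory()
  expect_identical(nrow(inv), 9L)
  expect_identical(inv$r[inv$family %in% c("uni_x", "uni_y")], rep(2L, 4))
  expect_identical(inv$r[inv$family == "glc"], rep(3L, 2))
  expect_identical(inv$r[inv$family == "guess_fixed"], 0L)
  expect_identical(inv$r[startsWith(inv$family, "guess_biased")], rep(1L, 2))
})

test_that("negative log-likelihood matches closed forms and handles edge cases", {
  withr::with_seed(2, {
    tr <- tibble::tibble(x_norm = runif(50), y_norm = runif(50),
                         response = sample(c("A", "B"), 50, TRUE))
  })
  expect_equal(model_nll("guess_fixed", NA, list(), tr), 50 * log(2))

  # a bound passing through every stimulus is indistinguishable from guessing
  tr0 <- tr
  tr0$x_norm <- 0.31
  expect_equal(model_nll("uni_x", "direct",
                         list(criterion = 0.31, sigma = 0.05), tr0),
               50 * log(2))

  # certainty limit under clamping
  trA <- tr
  trA$response <- "A"
  nll <- model_nll("guess_biased_A", NA, list(p_A = 1), trA)
  expect_lt(nll, 1e-7)
  expect_gte(nll, 0)

  expect_error(model_nll("uni_x", "direct",
                         list(criterion = 0.5, sigma = 0), tr), "sigma")
  expect_error(model_nll("guess_biased_A", NA, list(p_A = 1.5), tr), "p_A")
})

test_that("every fit satisfies the BIC identity to 1e-9", {
  withr::with_seed(11, blk <- make_strategy_block("uni_x", sigma = 0.05))
  fits <- fit_block(blk)
  expect_equal(fits$bic, fits$r * log(fits$n_trials) - 2 * fits$logL,
               tolerance = 1e-9)
  expect_true(all(fits$logL <= 0))
  expect_equal(fits$logL[fits$family == "guess_fixed"], 50 * log(0.5))
})

test_that("BIC selection breaks ties toward fewer parameters, then inventory order", {
  fits <- tibble::tibble(
    family = c("guess_fixed", "uni_x", "glc"),
    r = c(0L, 2L, 3L),
    bic = c(10, 10, 10))
  expect_identical(catbound:::.select_best(fits), 1L)
  fits$bic <- c(12, 10, 10 + 1e-8)   # uni and glc tied; guessing worse
  expect_identical(catbound:::.select_best(fits), 2L)
})

test_that("the GLC nests the unidimensional bounds in likelihood", {
  for (fam in c("uni_x", "uni_y")) {
    withr::with_seed(21, blk <- make_strategy_block(fam, sigma = 0.08))
    fits <- fit_block(blk)
    best_uni <- max(fits$logL[fits$family %in% c("uni_x", "uni_y")])
    glc <- fits$logL[fits$family == "glc"][1]
    expect_gte(glc, best_uni - 1e-4)
  }
})

test_that("all-A response blocks drive the biased-A guess to its bound", {
  tr <- tibble::tibble(x_norm = runif(50), y_norm = runif(50), response = "A")
  f <- fit_strategy_model(tr, "guess_biased_A")
  expect_equal(f$param1, 1)
  expect_gt(f$logL, -1e-7)
})

test_that("the optimizer matches an independent dense grid search", {
  d <- category_distributions("auditory", "RB")
  set <- cached_fixture("auditory", "RB")
  grid <- generalization_grid(d)
  prof <- uniform_schedule_profile(optimal_strategy(d, 0.07))
  tr <- simulate_session(prof, set, grid, seed = 31)
  for (b in c("2", "6")) {
    blk <- tr[tr$block == b, ]
    fitted <- fit_strategy_model(blk, "uni_x", "direct")
    oracle <- uni_grid_oracle(blk, n_grid = 200)
    expect_lt(2 * (-fitted$logL) - 2 * oracle, 0.5)
  }
})

test_that("parameters of a unidimensional generator are recovered", {
  withr::with_seed(41, {
    x <- runif(200); y <- runif(200)
    p <- pnorm((x - 0.5) / 0.05)
    tr <- tibble::tibble(x_norm = x, y_norm = y,
                         response = ifelse(runif(200) < p, "A", "B"))
  })
  f <- fit_strategy_model(tr, "uni_x", "direct")
  expect_lt(abs(f$param1 - 0.5), 0.05)
  expect_lt(abs(f$param2 - 0.05), 0.03)
  expect_true(f$converged)
})

test_that("fit_trials keys every participant-block and is deterministic", {
  d <- category_distributions("auditory", "RB")
  set <- cached_fixture("auditory", "RB")
  grid <- generalization_grid(d)
  two <- dplyr::bind_rows(
    simulate_session(uniform_schedule_profile(optimal_strategy(d, 0.1), id = "s1"),
                     set, grid, seed = 1),
    simulate_session(uniform_schedule_profile(strategy("guess_fixed"), id = "s2"),
                     set, grid, seed = 2))
  fits <- fit_trials(two)
  expect_identical(nrow(fits), 18L)      # 2 participants x 9 blocks
  expect_setequal(fits$block, c(as.character(1:8), "test"))
  expect_true(all(fits$best_flag))
  # optimal responder is read as uni_x, guesser as random
  expect_true(all(collapse_family(fits$family[fits$participant_id == "s1"]) == "uni_x"))
  expect_true(all(collapse_family(fits$family[fits$participant_id == "s2"]) == "random"))
  # full table keeps all nine fits per block
  all_fits <- fit_trials(two[two$participant_id == "s1" & two$block == "1", ],
                         keep_all = TRUE)
  expect_identical(nrow(all_fits), 9L)
  expect_identical(sum(all_fits$best_flag), 1L)
  # determinism
  expect_identical(fits, fit_trials(two))
  # degenerate inputs
  expect_identical(nrow(fit_trials(two[0, ])), 0L)
  short <- two[two$block == "1", ][1:5, ]
  expect_warning(out <- fit_trials(dplyr::bind_rows(two[two$block == "2", ], short)),
                 "only 5 trials")
  expect_identical(nrow(out), 2L)   # the two intact block-2 fits remain
})
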