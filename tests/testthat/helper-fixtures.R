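# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(modality, task) {
  key <- paste(modality, task)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- fixture_stimuli(modality, task)
  }
  .fixture_cache[[key]]
}

# 50-trial block with responses generated by a named strategy family on
# uniform stimuli (uses the current RNG stream).
make_strategy_block <- function(family, n = 50, sigma = 0.03) {
  x <- stats::runif(n)
  y <- stats::runif(n)
  p <- switch(family,
    uni_x = stats::pnorm((x - 0.5) / sigma),
    uni_y = stats::pnorm((y - 0.5) / sigma),
    glc   = stats::pnorm(((x + y - 1) / sqrt(2)) / sigma),
    guess = rep(0.5, n))
  tibble::tibble(x_norm = x, y_norm = y,
                 response = ifelse(stats::runif(n) < p, "A", "B"))
}

strategy_label_for <- function(family) {
  switch(family, glc = "procedural", uni_x = "uni_x", uni_y = "uni_y",
         guess = "random")
}

# Single-strategy learner profile covering all blocks and the test block.
uniform_schedule_profile <- function(strat, id = "p1", group = "control",
                                     asrs = 40) {
  sched <- stats::setNames(rep(list(strat), 9), c(as.character(1:8), "test"))
  learner_profile(id, group, asrs, sched)
}

# Dense grid-search oracle for the unidimensional model's NLL: minimum over
# an n_grid x n_grid (criterion, sigma) lattice, computed by brute force and
# independent of the package's optimizer.
uni_grid_oracle <- function(trials, n_grid = 400, sigma_range = c(0.01, 2),
                            criterion_range = c(-0.25, 1.25), eps = 1e-10) {
  respA <- as.numeric(trials$response == "A")
  crits <- seq(criterion_range[1], criterion_range[2], length.out = n_grid)
  sigmas <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                    length.out = n_grid))
  best <- Inf
  H <- outer(trials$x_norm, crits, "-")
  for (s in sigmas) {
    P <- stats::pnorm(H / s)
    P[P < eps] <- eps
    P[P > 1 - eps] <- 1 - eps
    nll <- -(crossprod(respA, log(P)) + crossprod(1 - respA, log1p(-P)))
    best <- min(best, min(nll))
  }
  best
}
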