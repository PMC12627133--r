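#' Optimizer settings for model fitting
#'
#' Maximum-likelihood fits of the boundary models run in two stages: a
#' dense coarse grid over the parameter space, scored in one vectorized
#' pass, followed by Nelder-Mead refinement from the `n_refine` best grid
#' points (optionally plus `n_random` seeded random starts).  Guessing
#' models have closed-form maximum-likelihood estimates and skip
#' optimization.  The default scheme is deterministic.
#'
#' @param n_refine Number of best grid points refined by Nelder-Mead.
#' @param n_random Extra random restarts (0 = fully deterministic).
#' @param seed Seed for the random restarts (unused when `n_random = 0`).
#' @param sigma_bounds Allowed noise-SD range, normalized units.  The lower
#'   bound (default 0.01, 1% of the stimulus range) keeps fits away from
#'   the degenerate zero-noise solution: on linearly separable blocks an
#'   unbounded probit likelihood is maximized by a separating bound with
#'   sigma -> 0 and log-likelihood -> 0, which makes the GLC absorb
#'   rule-based data and breaks model identifiability.
#' @param epsilon Likelihood clamp, as in [model_nll()].
#' @param criterion_grid,sigma_grid Coarse grid for unidimensional models.
#' @param theta_grid,offset_grid Coarse grid for the GLC bound
#'   (angle-offset parameterization of the unit-normal bound, which avoids
#'   the infinite-slope singularity of the slope/intercept form).
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(n_refine = 2, n_random = 0, seed = 1L,
                        sigma_bounds = c(0.01, 2),
                        epsilon = 1e-10,
                        criterion_grid = seq(-0.25, 1.25, length.out = 31),
                        sigma_grid = exp(seq(log(0.01), log(1), length.out = 11)),
                        theta_grid = seq(0, 2 * pi, length.out = 17)[-17],
                        offset_grid = seq(-0.9, 0.9, length.out = 9)) {
  structure(list(n_refine = n_refine, n_random = n_random, seed = seed,
                 sigma_bounds = sigma_bounds, epsilon = epsilon,
                 criterion_grid = criterion_grid, sigma_grid = sigma_grid,
                 theta_grid = theta_grid, offset_grid = offset_grid),
            class = "fit_control")
}

# Vectorized NLL for a matrix of P(A) columns (one candidate per column).
.nll_cols <- function(P, respA, eps) {
  P[P < eps] <- eps
  P[P > 1 - eps] <- 1 - eps
  -(as.numeric(crossprod(respA, log(P))) +
      as.numeric(crossprod(1 - respA, log1p(-P))))
}

# Scalar NLL for one P(A) vector; hot path inside Nelder-Mead.
.nll_vec <- function(p, respA, eps) {
  p[p < eps] <- eps
  p[p > 1 - eps] <- 1 - eps
  -sum(respA * log(p) + (1 - respA) * log1p(-p))
}

.clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

# Nelder-Mead refinement of an NLL objective over transformed parameters
# (sigma optimized on the log scale, clamped to bounds inside the objective).
.refine <- function(starts, objective) {
  best <- NULL
  converged <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[i, ]), objective,
                        method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-7))
    if (fit$convergence == 0) converged <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best$converged <- converged
  best
}

# Fit one unidimensional model (criterion + sigma) for both response
# assignments; the coarse grid is shared (flipping the assignment maps the
# per-candidate P(A) to 1 - P(A)).
.fit_uni_both <- function(axis, x, y, respA, control) {
  v <- if (axis == "x") x else y
  eps <- control$epsilon
  lo <- log(control$sigma_bounds[1]); hi <- log(control$sigma_bounds[2])
  H <- outer(v, control$criterion_grid, "-")
  pars <- as.matrix(expand.grid(crit = control$criterion_grid,
                                log_sigma = log(control$sigma_grid),
                                KEEP.OUT.ATTRS = FALSE))
  nll_d <- nll_f <- numeric(0)
  for (s in control$sigma_grid) {
    P <- stats::pnorm(H / s)
    nll_d <- c(nll_d, .nll_cols(P, respA, eps))
    nll_f <- c(nll_f, .nll_cols(1 - P, respA, eps))
  }
  one <- function(sgn, nll) {
    starts <- pars[order(nll)[seq_len(control$n_refine)], , drop = FALSE]
    if (control$n_random > 0) {
      extra <- withr::with_seed(control$seed, cbind(
        stats::runif(control$n_random, -0.25, 1.25),
        stats::runif(control$n_random, lo, min(hi, log(1)))))
      starts <- rbind(starts, extra)
    }
    slo <- control$sigma_bounds[1]; shi <- control$sigma_bounds[2]
    objective <- function(par) {
      s <- exp(par[2])
      if (s < slo) s <- slo else if (s > shi) s <- shi
      .nll_vec(stats::pnorm(sgn * (v - par[1]) / s), respA, eps)
    }
    best <- .refine(starts, objective)
    list(params = c(criterion = best$par[1],
                    sigma = exp(.clamp(best$par[2], lo, hi))),
         nll = best$value, converged = best$converged,
         n_starts = nrow(starts))
  }
  list(direct = one(1, nll_d), flipped = one(-1, nll_f))
}

# Fit the GLC (theta + offset + sigma).  Theta is free over [0, 2pi), so a
# single optimization covers both response assignments; the "flipped" row is
# derived analytically (theta -> theta + pi, offset -> -offset).
.fit_glc <- function(x, y, respA, control) {
  eps <- control$epsilon
  lo <- log(control$sigma_bounds[1]); hi <- log(control$sigma_bounds[2])
  sgrid <- control$sigma_grid[c(TRUE, FALSE)]
  sgrid <- sgrid[sgrid <= 0.8]
  n_off <- length(control$offset_grid)
  pars <- as.matrix(expand.grid(offset = control$offset_grid,
                                log_sigma = log(sgrid),
                                theta = control$theta_grid,
                                KEEP.OUT.ATTRS = FALSE))[, c(3, 1, 2)]
  colnames(pars) <- c("theta", "offset", "log_sigma")
  nll <- numeric(nrow(pars))
  k <- 0L
  for (th in control$theta_grid) {
    H <- outer(cos(th) * x + sin(th) * y, control$offset_grid, "+")
    for (sg in sgrid) {
      nll[k + seq_len(n_off)] <- .nll_cols(stats::pnorm(H / sg), respA, eps)
      k <- k + n_off
    }
  }
  grid <- cbind(pars, nll = nll)
  starts <- grid[order(grid[, "nll"])[seq_len(control$n_refine)], 1:3,
                 drop = FALSE]
  if (control$n_random > 0) {
    extra <- withr::with_seed(control$seed + 1L, cbind(
      stats::runif(control$n_random, 0, 2 * pi),
      stats::runif(control$n_random, -0.9, 0.9),
      stats::runif(control$n_random, lo, min(hi, log(0.8)))))
    starts <- rbind(starts, extra)
  }
  slo <- control$sigma_bounds[1]; shi <- control$sigma_bounds[2]
  objective <- function(par) {
    s <- exp(par[3])
    if (s < slo) s <- slo else if (s > shi) s <- shi
    h <- cos(par[1]) * x + sin(par[1]) * y + par[2]
    .nll_vec(stats::pnorm(h / s), respA, eps)
  }
  best <- .refine(starts, objective)
  theta <- best$par[1] %% (2 * pi)
  list(params = c(theta = theta, offset = best$par[2],
                  sigma = exp(.clamp(best$par[3], lo, hi))),
       nll = best$value, converged = best$converged,
       n_starts = nrow(starts))
}

# Slope/intercept form of the GLC bound where finite (near-vertical bounds
# are reported as NA slope/intercept).
.glc_slope_intercept <- function(theta, offset) {
  a <- cos(theta); b <- sin(theta)
  if (abs(b) < 1e-8) return(c(slope = NA_real_, intercept = NA_real_))
  c(slope = -a / b, intercept = -offset / b)
}

#' Fit one decision-bound model to one block of trials
#'
#' Maximum-likelihood fit of a single model from [model_inventory()] to the
#' trials of one participant-block, in normalized coordinates.
#'
#' @param trials Trial tibble for a single participant-block (`x_norm`,
#'   `y_norm`, `response`).
#' @param family Model family (see [model_inventory()]).
#' @param assignment Response assignment for boundary families.
#' @param control A [fit_control()].
#' @return A one-row tibble: `family`, `assignment`, `r`, `n_trials`,
#'   `param1`, `param2`, `param3`, `logL`, `bic`, `converged`,
#'   `n_starts_used`.  Parameter columns are family-specific: criterion and
#'   sigma for unidimensional models; slope, intercept, and sigma for the
#'   GLC; the response probability for biased guessing.
#' @export
fit_strategy_model <- function(trials, family,
                               assignment = NA_character_,
                               control = fit_control()) {
  stopifnot(nrow(trials) >= 10)
  inv <- model_inventory()
  row <- inv[inv$family == family &
               (is.na(inv$assignment) | inv$assignment %in% assignment), ]
  if (nrow(row) != 1) stop("unknown model: ", family, "/", assignment,
                           call. = FALSE)
  n <- nrow(trials)
  respA <- as.numeric(trials$response == "A")
  eps <- control$epsilon
  p1 <- p2 <- p3 <- NA_real_
  converged <- TRUE
  n_starts <- 0L
  if (family == "guess_fixed") {
    logL <- n * log(0.5)
  } else if (family %in% c("guess_biased_A", "guess_biased_B")) {
    # closed-form MLE projected into the constrained half-interval
    p_hat <- mean(respA)
    p_A <- if (family == "guess_biased_A") .clamp(p_hat, 0.5, 1)
           else .clamp(p_hat, 0, 0.5)
    logL <- -model_nll(family, NA, list(p_A = p_A), trials, eps)
    p1 <- p_A
  } else if (family %in% c("uni_x", "uni_y")) {
    f <- .fit_uni_both(substr(family, 5, 5),
                       trials$x_norm, trials$y_norm, respA, control)[[assignment]]
    logL <- -f$nll
    p1 <- f$params[["criterion"]]; p2 <- f$params[["sigma"]]
    converged <- f$converged; n_starts <- f$n_starts
  } else if (family == "glc") {
    f <- .fit_glc(trials$x_norm, trials$y_norm, respA, control)
    theta <- f$params[["theta"]]; offset <- f$params[["offset"]]
    if (assignment == "flipped") {
      theta <- (theta + pi) %% (2 * pi)
      offset <- -offset
    }
    si <- .glc_slope_intercept(theta, offset)
    logL <- -f$nll
    p1 <- si[["slope"]]; p2 <- si[["intercept"]]; p3 <- f$params[["sigma"]]
    converged <- f$converged; n_starts <- f$n_starts
  } else {
    stop("unknown model family: ", family, call. = FALSE)
  }
  tibble::tibble(family = family, assignment = row$assignment, r = row$r,
                 n_trials = n, param1 = p1, param2 = p2, param3 = p3,
                 logL = logL, bic = bic(row$r, n, logL),
                 converged = converged, n_starts_used = n_starts)
}

# BIC selection with deterministic tie-breaking: candidates within `tol` of
# the minimum BIC are tied; among ties the fewest free parameters wins,
# then the fixed inventory order (guessing < unidimensional < GLC).
.select_best <- function(fits, tol = 1e-6) {
  tied <- which(fits$bic - min(fits$bic) < tol)
  tied[order(fits$r[tied], tied)][1]
}

#' Fit all nine models to one participant-block and select by BIC
#'
#' Fits the full [model_inventory()] to one block of trials and flags the
#' best model by minimum BIC.  BIC ties (within 1e-6) are broken toward
#' fewer free parameters, then by the fixed inventory order.  The GLC's
#' flipped-assignment fit is derived analytically from the direct fit
#' (negating the bound leaves the likelihood surface unchanged), so its
#' log-likelihood always equals the direct fit's.
#'
#' @param trials Trial tibble for one participant-block (>= 10 trials).
#' @param control A [fit_control()].
#' @return A nine-row tibble of class `block_fits` (see
#'   [fit_strategy_model()] for columns) with an added logical
#'   `best_flag`; [generics::glance()] returns the best row.
#' @examples
#' \donttest{
#' dists <- category_distributions("auditory", "RB")
#' set <- fixture_stimuli("auditory", "RB")
#' s <- optimal_strategy(dists, 0.05)
#' tr <- dplyr::mutate(set[1:50, ],
#'   response = ifelse(runif(50) < response_prob(s, x_norm, y_norm), "A", "B"))
#' fit_block(tr)
#' }
#' @export
fit_block <- function(trials, control = fit_control()) {
  stopifnot(nrow(trials) >= 10)
  n <- nrow(trials)
  x <- trials$x_norm; y <- trials$y_norm
  respA <- as.numeric(trials$response == "A")
  eps <- control$epsilon
  inv <- model_inventory()
  na_fit <- list(params = c(NA_real_, NA_real_, NA_real_), nll = Inf,
                 converged = FALSE, n_starts = 0L)
  # guessing models: closed forms
  p_hat <- mean(respA)
  pA_bias_A <- .clamp(p_hat, 0.5, 1)
  pA_bias_B <- .clamp(p_hat, 0, 0.5)
  logL_bias <- function(p) {
    p <- .clamp(p, eps, 1 - eps)
    sum(respA) * log(p) + sum(1 - respA) * log(1 - p)
  }
  # boundary models: shared grid + refinement, errors demoted to NA rows
  ux <- tryCatch(.fit_uni_both("x", x, y, respA, control),
                 error = function(e) list(direct = na_fit, flipped = na_fit))
  uy <- tryCatch(.fit_uni_both("y", x, y, respA, control),
                 error = function(e) list(direct = na_fit, flipped = na_fit))
  g <- tryCatch(.fit_glc(x, y, respA, control), error = function(e) na_fit)
  uni_row <- function(f) c(f$params[[1]], f$params[[2]], NA_real_)
  glc_row <- function(f, flip) {
    if (!is.finite(f$nll)) return(c(NA_real_, NA_real_, NA_real_))
    theta <- f$params[["theta"]]; offset <- f$params[["offset"]]
    if (flip) { theta <- (theta + pi) %% (2 * pi); offset <- -offset }
    si <- .glc_slope_intercept(theta, offset)
    c(si[["slope"]], si[["intercept"]], f$params[["sigma"]])
  }
  params <- rbind(
    c(NA_real_, NA_real_, NA_real_),
    c(pA_bias_A, NA_real_, NA_real_),
    c(pA_bias_B, NA_real_, NA_real_),
    uni_row(ux$direct), uni_row(ux$flipped),
    uni_row(uy$direct), uni_row(uy$flipped),
    glc_row(g, FALSE), glc_row(g, TRUE))
  logL <- c(n * log(0.5), logL_bias(pA_bias_A), logL_bias(pA_bias_B),
            -ux$direct$nll, -ux$flipped$nll, -uy$direct$nll, -uy$flipped$nll,
            -g$nll, -g$nll)
  converged <- c(TRUE, TRUE, TRUE,
                 ux$direct$converged, ux$flipped$converged,
                 uy$direct$converged, uy$flipped$converged,
                 g$converged, g$converged)
  n_starts <- c(0L, 0L, 0L,
                ux$direct$n_starts, ux$flipped$n_starts,
                uy$direct$n_starts, uy$flipped$n_starts,
                g$n_starts, g$n_starts)
  fits <- tibble::tibble(
    family = inv$family, assignment = inv$assignment, r = inv$r,
    n_trials = n,
    param1 = params[, 1], param2 = params[, 2], param3 = params[, 3],
    logL = logL, bic = bic(inv$r, n, logL),
    converged = converged, n_starts_used = as.integer(n_starts))
  fits$bic[!is.finite(fits$logL)] <- Inf
  if (all(!is.finite(fits$bic))) stop("all model fits failed", call. = FALSE)
  fits$best_flag <- FALSE
  fits$best_flag[.select_best(fits)] <- TRUE
  class(fits) <- c("block_fits", class(fits))
  fits
}

#' @exportS3Method generics::tidy
tidy.block_fits <- function(x, ...) tibble::as_tibble(x)

#' @exportS3Method generics::glance
glance.block_fits <- function(x, ...) {
  tibble::as_tibble(x[x$best_flag, ])
}

#' Fit every participant-block in a trial table
#'
#' Batch driver over [fit_block()]: groups the trial table by participant,
#' modality, task, and block (training blocks and the generalization test
#' block alike), fits the full model inventory to each, and returns the
#' per-block fits keyed by those identifiers.  Blocks with fewer than 10
#' trials are skipped with a warning.  With the default deterministic
#' optimizer, rerunning yields an identical table.
#'
#' @param trials A trial tibble (from [simulate_cohort()],
#'   [simulate_session()], or [read_trials()]).
#' @param control A [fit_control()].
#' @param keep_all Keep all nine fits per block (`TRUE`) or only the
#'   BIC-best row per block (default).
#' @return A tibble keyed by `participant_id`, `group`, `modality`,
#'   `task`, `block`, with the fit columns of [fit_strategy_model()] plus
#'   `best_flag`.
#' @export
fit_trials <- function(trials, control = fit_control(), keep_all = FALSE) {
  if (nrow(trials) == 0) {
    return(tibble::tibble(participant_id = character(), group = character(),
                          modality = character(), task = character(),
                          block = character()))
  }
  keys <- dplyr::distinct(trials, .data$participant_id, .data$group,
                          .data$modality, .data$task, .data$block)
  keys <- dplyr::arrange(keys, .data$participant_id, .data$modality,
                         .data$task,
                         match(.data$block, c(as.character(1:8), "test")))
  purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    blk <- dplyr::semi_join(trials, k,
      by = c("participant_id", "modality", "task", "block"))
    if (nrow(blk) < 10) {
      warning(sprintf("skipping %s %s/%s block %s: only %d trials",
                      k$participant_id, k$modality, k$task, k$block,
                      nrow(blk)), call. = FALSE)
      return(NULL)
    }
    fits <- fit_block(blk, control)
    if (!keep_all) fits <- fits[fits$best_flag, ]
    dplyr::bind_cols(k[rep(1, nrow(fits)), ], tibble::as_tibble(fits))
  })
}

#' Write a fit table as CSV
#'
#' Header: `participant_id,modality,task,block,family,assignment,r,`
#' `n_trials,param1,param2,param3,logL,bic,best_flag,converged`.
#'
#' @param fits A fit tibble from [fit_trials()].
#' @param path File path.
#' @return `fits`, invisibly.
#' @export
write_fits <- function(fits, path) {
  cols <- c("participant_id", "modality", "task", "block", "family",
            "assignment", "r", "n_trials", "param1", "param2", "param3",
            "logL", "bic", "best_flag", "converged")
  readr::write_csv(fits[intersect(cols, names(fits))], path)
  invisible(fits)
}
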