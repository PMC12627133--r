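#' Bayesian information criterion
#'
#' `BIC = r * ln(N) - 2 * ln(L)`, where `r` is the number of free
#' parameters, `N` the number of trials in the block, and `L` the model
#' likelihood.  Lower is better.
#'
#' @param r Number of free parameters (>= 0).
#' @param n Number of trials (>= 1).
#' @param log_likelihood Maximized log-likelihood.
#' @return The BIC value.
#' @examples
#' bic(0, 50, 50 * log(0.5))  # fixed guessing on a 50-trial block
#' @export
bic <- function(r, n, log_likelihood) {
  stopifnot(all(n >= 1), all(r >= 0))
  r * log(n) - 2 * log_likelihood
}

#' The decision-bound model inventory
#'
#' The nine observer models fitted to every participant-block: the two
#' unidimensional rule (hypothesis-testing) models, each with both response
#' assignments (which side of the criterion is "A"); the general linear
#' classifier (GLC, the procedural-strategy marker) with both assignments;
#' fixed guessing (p = 0.5, no free parameters); and two biased-guessing
#' models (probability of responding "A" constrained to `[0.5, 1]` and
#' `[0, 0.5]` respectively).  Unidimensional models have 2 free parameters
#' (criterion, noise), the GLC 3 (slope, intercept, noise), biased guessing
#' 1 (response probability).
#'
#' @return A nine-row tibble with columns `family`, `assignment`, `r`,
#'   in the fixed order used for BIC tie-breaking (fewer parameters first).
#' @export
model_inventory <- function() {
  tibble::tribble(
    ~family,          ~assignment, ~r,
    "guess_fixed",    NA_character_, 0L,
    "guess_biased_A", NA_character_, 1L,
    "guess_biased_B", NA_character_, 1L,
    "uni_x",          "direct",      2L,
    "uni_x",          "flipped",     2L,
    "uni_y",          "direct",      2L,
    "uni_y",          "flipped",     2L,
    "glc",            "direct",      3L,
    "glc",            "flipped",     3L
  )
}

# Per-trial P(respond A) for a model family at given parameters.
# Boundary families use the shared response rule pnorm(h / sigma) with h the
# signed distance from the unit-normalized bound; "flipped" negates h.
.model_pA <- function(family, assignment, params, x, y) {
  if (family == "guess_fixed") return(rep(0.5, length(x)))
  if (family %in% c("guess_biased_A", "guess_biased_B")) {
    p <- params[["p_A"]]
    if (p < 0 || p > 1) stop("p_A outside [0, 1]", call. = FALSE)
    return(rep(p, length(x)))
  }
  sigma <- params[["sigma"]]
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  h <- switch(family,
    uni_x = x - params[["criterion"]],
    uni_y = y - params[["criterion"]],
    glc = cos(params[["theta"]]) * x + sin(params[["theta"]]) * y +
      params[["offset"]],
    stop("unknown model family: ", family, call. = FALSE)
  )
  if (identical(assignment, "flipped")) h <- -h
  stats::pnorm(h / sigma)
}

#' Negative log-likelihood of a decision-bound model
#'
#' `-sum(log P(response_i | stimulus_i))` over the trials of one
#' participant-block, with per-trial probabilities clamped to
#' `[epsilon, 1 - epsilon]` to keep the log finite.  The clamping is part
#' of the model and is applied identically in simulation and fitting.
#'
#' @param family One of the [model_inventory()] families.
#' @param assignment `"direct"`, `"flipped"`, or `NA` for guessing models.
#' @param params Named list/vector: `criterion`, `sigma` (unidimensional);
#'   `theta`, `offset`, `sigma` (GLC, angle-offset bound parameterization);
#'   `p_A` (biased guessing); empty for fixed guessing.
#' @param trials Trial tibble with `x_norm`, `y_norm`, `response`.
#' @param epsilon Probability clamp (default 1e-10).
#' @return The negative log-likelihood (a single number, >= 0).
#' @examples
#' tr <- tibble::tibble(x_norm = runif(50), y_norm = runif(50),
#'                      response = sample(c("A", "B"), 50, TRUE))
#' model_nll("guess_fixed", NA, list(), tr)  # 50 * log(2)
#' @export
model_nll <- function(family, assignment, params, trials, epsilon = 1e-10) {
  stopifnot(nrow(trials) > 0)
  p <- .model_pA(family, assignment, params, trials$x_norm, trials$y_norm)
  p <- pmin(pmax(p, epsilon), 1 - epsilon)
  -sum(log(ifelse(trials$response == "A", p, 1 - p)))
}
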