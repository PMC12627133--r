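#' Response strategies for simulated learners
#'
#' A strategy is the generative analogue of a decision-bound observer model:
#' either a boundary strategy (a linear bound plus Gaussian
#' perceptual/criterial noise) or a guessing strategy (stimulus-independent
#' response probability).  Boundary families: `uni_x` and `uni_y`
#' (unidimensional criterion rules) and `procedural` (arbitrary linear
#' bound).  Guessing families: `guess_fixed` (p = 0.5) and `guess_biased`.
#'
#' @param family Strategy family.
#' @param bound A [linear_bound()] object (boundary families only).  For
#'   `uni_x`/`uni_y` it must be unidimensional on the named dimension.
#' @param noise_sigma Perceptual + criterial noise SD in normalized units
#'   (boundary families only; > 0).
#' @param guess_p_A Probability of responding "A" (guessing families only).
#' @param lapse_rate Probability of a uniform-random lapse response, in
#'   `[0, 0.5]` (default 0).
#'
#' @return An object of class `strategy`.
#' @examples
#' strategy("uni_x", bound = unidimensional_bound("x", 0.5), noise_sigma = 0.1)
#' strategy("guess_fixed")
#' @export
strategy <- function(family = c("uni_x", "uni_y", "procedural",
                                "guess_fixed", "guess_biased"),
                     bound = NULL, noise_sigma = NULL,
                     guess_p_A = NULL, lapse_rate = 0) {
  family <- match.arg(family)
  stopifnot(lapse_rate >= 0, lapse_rate <= 0.5)
  if (family %in% c("guess_fixed", "guess_biased")) {
    if (family == "guess_fixed") guess_p_A <- 0.5
    stopifnot(!is.null(guess_p_A), guess_p_A >= 0, guess_p_A <= 1)
    bound <- NULL
    noise_sigma <- NULL
  } else {
    stopifnot(inherits(bound, "decision_bound"),
              !is.null(noise_sigma), noise_sigma > 0)
    if (family == "uni_x" && bound$a == 0)
      stop("uni_x strategy requires a bound on the x dimension", call. = FALSE)
    if (family == "uni_y" && bound$b == 0)
      stop("uni_y strategy requires a bound on the y dimension", call. = FALSE)
    if (family %in% c("uni_x", "uni_y") && bound$a != 0 && bound$b != 0)
      stop("unidimensional strategies require a unidimensional bound", call. = FALSE)
    guess_p_A <- NULL
  }
  structure(list(family = family, bound = bound, noise_sigma = noise_sigma,
                 guess_p_A = guess_p_A, lapse_rate = lapse_rate),
            class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  if (is.null(x$bound)) {
    cat(sprintf("<strategy %s> P(A) = %.3f, lapse = %.3f\n",
                x$family, x$guess_p_A, x$lapse_rate))
  } else {
    cat(sprintf("<strategy %s> sigma = %.3g, lapse = %.3f, bound: ",
                x$family, x$noise_sigma, x$lapse_rate))
    print(x$bound)
  }
  invisible(x)
}

#' Probability of responding "A" under a strategy
#'
#' Boundary strategies respond according to the stimulus's signed
#' perpendicular distance `h` from the bound, corrupted by Gaussian noise:
#' `P(A) = (1 - lapse) * pnorm(h / sigma) + lapse / 2`.  Guessing
#' strategies respond "A" with fixed probability regardless of the
#' stimulus.
#'
#' @param strat A [strategy()] object.
#' @param x,y Normalized stimulus coordinates (vectors).
#' @return Numeric vector of probabilities.
#' @examples
#' s <- strategy("uni_x", bound = unidimensional_bound("x", 0.5),
#'               noise_sigma = 0.1)
#' response_prob(s, 0.5, 0.3)  # on the bound: 0.5
#' @export
response_prob <- function(strat, x, y) {
  stopifnot(inherits(strat, "strategy"))
  n <- max(length(x), length(y))
  if (is.null(strat$bound)) {
    p <- rep(strat$guess_p_A, n)
  } else {
    h <- signed_distance(strat$bound, x, y)
    p <- stats::pnorm(h / strat$noise_sigma)
  }
  (1 - strat$lapse_rate) * p + strat$lapse_rate / 2
}
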