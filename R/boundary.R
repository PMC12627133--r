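#' Linear decision bounds
#'
#' A decision bound is the line `a*x + b*y + c = 0` in normalized
#' coordinates, with the unit-normal constraint `a^2 + b^2 = 1`.  The signed
#' perpendicular distance of a stimulus from the bound is
#' `h = a*x + b*y + c`; stimuli with `h >= 0` fall on the Category-A side
#' (points exactly on the bound are labeled A as a deterministic tie rule).
#'
#' `linear_bound()` builds a bound from raw coefficients (rescaled to unit
#' normal); `unidimensional_bound()` builds a criterion rule orthogonal to a
#' single dimension.
#'
#' @param a,b,c Line coefficients; `a` and `b` must not both be zero.
#' @param axis `"x"` or `"y"`: the dimension the criterion rule lives on.
#' @param criterion Criterion location in normalized units.
#' @param a_side Which side of the criterion is Category A: `"high"` (above
#'   the criterion) or `"low"`.
#'
#' @return An object of class `decision_bound`: a list with elements `a`,
#'   `b`, `c`.
#' @examples
#' unidimensional_bound("x", 0.5)
#' linear_bound(1, 1, -1)  # diagonal through (0.5, 0.5)
#' @export
linear_bound <- function(a, b, c) {
  nrm <- sqrt(a^2 + b^2)
  if (nrm == 0) stop("`a` and `b` cannot both be zero", call. = FALSE)
  structure(list(a = a / nrm, b = b / nrm, c = c / nrm),
            class = "decision_bound")
}

#' @rdname linear_bound
#' @export
unidimensional_bound <- function(axis = c("x", "y"), criterion,
                                 a_side = c("high", "low")) {
  axis <- match.arg(axis)
  a_side <- match.arg(a_side)
  s <- if (a_side == "high") 1 else -1
  if (axis == "x") {
    structure(list(a = s, b = 0, c = -s * criterion), class = "decision_bound")
  } else {
    structure(list(a = 0, b = s, c = -s * criterion), class = "decision_bound")
  }
}

#' @export
print.decision_bound <- function(x, ...) {
  kind <- if (x$a == 0 || x$b == 0) "unidimensional" else "linear"
  cat(sprintf("<decision_bound (%s)> %.6g*x + %.6g*y + %.6g = 0 (A side: h >= 0)\n",
              kind, x$a, x$b, x$c))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.decision_bound <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, c = x$c,
                 unidimensional = (x$a == 0 || x$b == 0))
}

#' Signed distance from a decision bound
#'
#' @param bound A [linear_bound()] object.
#' @param x,y Normalized coordinates.
#' @return Numeric vector of signed perpendicular distances (positive on
#'   the Category-A side).
#' @export
signed_distance <- function(bound, x, y) {
  bound$a * x + bound$b * y + bound$c
}

#' Optimal decision bound for a pair of category distributions
#'
#' For rule-based structures (category means differing on exactly one
#' dimension) the optimal bound is the unidimensional criterion at the
#' midpoint of the category means on the relevant dimension.  For
#' information-integration structures the bound is the pooled-covariance
#' Fisher linear discriminant; the small A/B differences in spread are
#' ignored and the boundary is kept linear, which is how the optimal II
#' strategy is conventionally described.  The bound is expressed in
#' normalized coordinates and oriented so Category A lies on the positive
#' side.
#'
#' @param dists A two-row distribution tibble from
#'   [category_distributions()].
#' @return A [linear_bound()] object.
#' @examples
#' optimal_boundary(category_distributions("auditory", "RB"))
#' @export
optimal_boundary <- function(dists) {
  stopifnot(nrow(dists) == 2, identical(sort(dists$label), c("A", "B")))
  nd <- .normalize_dists(dists)
  A <- nd[nd$label == "A", ]
  B <- nd[nd$label == "B", ]
  dx <- A$mean_x - B$mean_x
  dy <- A$mean_y - B$mean_y
  tol <- 1e-12
  if (abs(dx) < tol && abs(dy) < tol) {
    stop("degenerate distributions: category means are identical on both dimensions",
         call. = FALSE)
  }
  if (abs(dy) < tol) {       # means differ only on x: criterion on x
    crit <- (A$mean_x + B$mean_x) / 2
    return(unidimensional_bound("x", crit, if (dx > 0) "high" else "low"))
  }
  if (abs(dx) < tol) {       # means differ only on y
    crit <- (A$mean_y + B$mean_y) / 2
    return(unidimensional_bound("y", crit, if (dy > 0) "high" else "low"))
  }
  # Fisher linear discriminant with pooled covariance
  covA <- matrix(c(A$sd_x^2, A$covariance, A$covariance, A$sd_y^2), 2)
  covB <- matrix(c(B$sd_x^2, B$covariance, B$covariance, B$sd_y^2), 2)
  pooled <- (covA + covB) / 2
  w <- solve(pooled, c(dx, dy))
  mid <- c((A$mean_x + B$mean_x) / 2, (A$mean_y + B$mean_y) / 2)
  linear_bound(w[1], w[2], -sum(w * mid))
}

#' Classify stimuli with a decision bound
#'
#' `classify_stimuli()` appends the bound's predicted label for each
#' stimulus; `boundary_accuracy()` returns the proportion of stimuli whose
#' true category matches the prediction.
#'
#' @param stimuli A stimulus tibble with columns `x_norm`, `y_norm` and
#'   (for accuracy) `category`.
#' @param bound A [linear_bound()] object.
#'
#' @return `classify_stimuli()`: the input tibble with a `predicted` column
#'   (`"A"`/`"B"`).  `boundary_accuracy()`: a single proportion.
#' @export
classify_stimuli <- function(stimuli, bound) {
  stopifnot(nrow(stimuli) > 0)
  h <- signed_distance(bound, stimuli$x_norm, stimuli$y_norm)
  dplyr::mutate(stimuli, predicted = ifelse(h >= 0, "A", "B"))
}

#' @rdname classify_stimuli
#' @export
boundary_accuracy <- function(stimuli, bound) {
  cls <- classify_stimuli(stimuli, bound)
  mean(cls$predicted == cls$category)
}
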