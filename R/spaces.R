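#' Stimulus space for one modality
#'
#' The two-dimensional physical stimulus space in which category exemplars
#' live.  Auditory stimuli are spectrotemporal ripples parameterized by
#' temporal modulation (Hz) and spectral modulation (cycles/octave); visual
#' stimuli are Gabor patches parameterized by spatial frequency
#' (cycles/degree) and orientation (degrees).  Coordinates are also carried
#' in a normalized space, the unit square `[0, 1]^2`, mapped affinely onto
#' the physical ranges so that the two modalities are commensurate.
#'
#' @param modality `"auditory"` or `"visual"`.
#'
#' @return A one-row tibble with columns `modality`, `dim_x`, `dim_y`
#'   (dimension names), `unit_x`, `unit_y` (physical units), and the range
#'   bounds `x_lo`, `x_hi`, `y_lo`, `y_hi`.
#' @examples
#' stimulus_space("auditory")
#' @export
stimulus_space <- function(modality = c("auditory", "visual")) {
  modality <- match.arg(modality)
  if (modality == "auditory") {
    tibble::tibble(
      modality = "auditory",
      dim_x = "temporal modulation", dim_y = "spectral modulation",
      unit_x = "Hz", unit_y = "cycles/octave",
      x_lo = 2.0, x_hi = 14.8, y_lo = -0.38, y_hi = 2.67
    )
  } else {
    tibble::tibble(
      modality = "visual",
      dim_x = "spatial frequency", dim_y = "orientation",
      unit_x = "cycles/degree", unit_y = "degrees",
      x_lo = 0.04, x_hi = 0.072, y_lo = 10, y_hi = 104
    )
  }
}

# Table of category distribution parameters, physical units.
# One row per modality x task x category label.
.distribution_table <- function() {
  tibble::tribble(
    ~modality,  ~task, ~label, ~mean_x, ~sd_x,   ~mean_y, ~sd_y, ~covariance,
    "auditory", "II",  "A",    10.0,    2.13,    0.72,    0.49,  0.43,
    "auditory", "II",  "B",    6.62,    2.02,    1.53,    0.51,  0.43,
    "auditory", "RB",  "A",    10.42,   1.58,    1.14,    0.66,  0.062,
    "auditory", "RB",  "B",    5.59,    1.58,    1.14,    0.66,  -0.062,
    "visual",   "II",  "A",    0.060,   0.0054,  43.2,    15.0,  0.034,
    "visual",   "II",  "B",    0.051,   0.0051,  68.5,    15.8,  0.034,
    "visual",   "RB",  "A",    0.061,   0.0039,  56.7,    20.4,  0.0048,
    "visual",   "RB",  "B",    0.049,   0.0039,  56.7,    20.4,  -0.0048
  )
}

#' Bivariate-normal category distributions for one task
#'
#' Returns the parameters of the two category distributions (A and B) that
#' define a rule-based (RB) or information-integration (II) category
#' structure in one modality.  RB structures differ only along one dimension
#' (temporal modulation / spatial frequency) and are optimally separated by
#' a unidimensional criterion; II structures differ along both dimensions
#' with correlated variability and require a diagonal (linear-integration)
#' boundary.
#'
#' @param modality `"auditory"` or `"visual"`.
#' @param task `"RB"` (rule-based) or `"II"` (information-integration).
#'
#' @return A two-row tibble (labels `"A"`, `"B"`) with columns `modality`,
#'   `task`, `label`, `mean_x`, `sd_x`, `mean_y`, `sd_y`, `covariance`, in
#'   physical units.
#' @examples
#' category_distributions("auditory", "RB")
#' @export
category_distributions <- function(modality = c("auditory", "visual"),
                                   task = c("RB", "II")) {
  modality <- match.arg(modality)
  task <- match.arg(task)
  out <- dplyr::filter(.distribution_table(),
                       .data$modality == !!modality, .data$task == !!task)
  stopifnot(nrow(out) == 2, all(out$sd_x > 0), all(out$sd_y > 0),
            all(abs(out$covariance) <= out$sd_x * out$sd_y))
  out
}

.space_for <- function(dists) {
  modality <- unique(dists$modality)
  stopifnot(length(modality) == 1)
  stimulus_space(modality)
}

#' Convert between normalized and physical coordinates
#'
#' The normalized space is the unit square `[0, 1]^2`; the affine map sends
#' it onto the physical ranges of the given space.  `to_physical()` and
#' `to_normalized()` are exact inverses.
#'
#' @param space A one-row tibble from [stimulus_space()].
#' @param x,y Numeric vectors of coordinates.
#'
#' @return A tibble with columns `x` and `y` in the target coordinates.
#' @examples
#' sp <- stimulus_space("auditory")
#' to_physical(sp, 0, 0)    # range lower bounds
#' to_physical(sp, 1, 1)    # range upper bounds
#' @export
to_physical <- function(space, x, y) {
  tibble::tibble(x = space$x_lo + x * (space$x_hi - space$x_lo),
                 y = space$y_lo + y * (space$y_hi - space$y_lo))
}

#' @rdname to_physical
#' @export
to_normalized <- function(space, x, y) {
  tibble::tibble(x = (x - space$x_lo) / (space$x_hi - space$x_lo),
                 y = (y - space$y_lo) / (space$y_hi - space$y_lo))
}

# Distribution parameters mapped into normalized coordinates.
# Means shift+scale; SDs scale; covariance scales by both ranges.
.normalize_dists <- function(dists, space = .space_for(dists)) {
  rx <- space$x_hi - space$x_lo
  ry <- space$y_hi - space$y_lo
  dplyr::mutate(dists,
    mean_x = (.data$mean_x - space$x_lo) / rx,
    mean_y = (.data$mean_y - space$y_lo) / ry,
    sd_x = .data$sd_x / rx,
    sd_y = .data$sd_y / ry,
    covariance = .data$covariance / (rx * ry)
  )
}
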