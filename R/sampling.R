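#' Default seed used for the packaged fixture stimulus sets
#' @export
catbound_fixture_seed <- 20250925L

# Draw n points from one category's bivariate normal, rejecting draws that
# fall outside the physical ranges (hard stimulus limits -> truncation).
.sample_truncated <- function(dist_row, space, n) {
  mu <- c(dist_row$mean_x, dist_row$mean_y)
  sigma <- matrix(c(dist_row$sd_x^2, dist_row$covariance,
                    dist_row$covariance, dist_row$sd_y^2), 2)
  out <- matrix(NA_real_, nrow = 0, ncol = 2)
  while (nrow(out) < n) {
    draw <- MASS::mvrnorm(max(2 * (n - nrow(out)), 10), mu, sigma)
    ok <- draw[, 1] >= space$x_lo & draw[, 1] <= space$x_hi &
      draw[, 2] >= space$y_lo & draw[, 2] <= space$y_hi
    out <- rbind(out, draw[ok, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Sample a stimulus set from a pair of category distributions
#'
#' Draws `n_per_category` exemplars per category from the bivariate normal
#' distributions (out-of-range draws are rejected and redrawn, since the
#' stimulus ranges are hard limits), then optionally repairs the set so that
#' exactly `n_misclassified` stimuli fall on the wrong side of the
#' task-optimal boundary.  With the default 100 per category and 10
#' misclassified, the optimal bound classifies 190/200 stimuli correctly, a
#' performance ceiling of 95%.
#'
#' The repair is iterative: while the wrong-side count exceeds the target, a
#' random wrong-side stimulus is redrawn from its category distribution;
#' while it falls short, a random right-side stimulus is redrawn.  Each
#' redraw is itself range-truncated.  If the exact count is not reached
#' within `max_redraws`, an error reports the achieved count.
#'
#' @param dists Two-row tibble from [category_distributions()].
#' @param n_per_category Stimuli per category (training sets use 100).
#' @param n_misclassified Exact number of stimuli (out of `2 *
#'   n_per_category`) on the wrong side of the optimal bound, or `NULL` to
#'   skip the constraint.
#' @param seed Integer seed; the same seed reproduces the set exactly.
#' @param max_redraws Iteration cap for the overlap repair.
#'
#' @return A tibble with columns `id`, `task`, `modality`, `category`,
#'   `x_phys`, `y_phys`, `x_norm`, `y_norm`.
#' @examples
#' dists <- category_distributions("auditory", "RB")
#' set <- sample_stimuli(dists, seed = 1)
#' boundary_accuracy(set, optimal_boundary(dists))  # 0.95
#' @export
sample_stimuli <- function(dists, n_per_category = 100, n_misclassified = 10,
                           seed = NULL, max_redraws = 1e5) {
  stopifnot(n_per_category >= 1)
  if (!is.null(n_misclassified)) {
    stopifnot(n_misclassified >= 0, n_misclassified <= 2 * n_per_category)
  }
  space <- .space_for(dists)
  run <- function() {
    xy <- do.call(rbind, lapply(c("A", "B"), function(lab) {
      .sample_truncated(dists[dists$label == lab, ], space, n_per_category)
    }))
    category <- rep(c("A", "B"), each = n_per_category)
    if (!is.null(n_misclassified)) {
      bound <- optimal_boundary(dists)
      wrong <- function(m) {
        pred <- ifelse(signed_distance(bound,
          (m[, 1] - space$x_lo) / (space$x_hi - space$x_lo),
          (m[, 2] - space$y_lo) / (space$y_hi - space$y_lo)) >= 0, "A", "B")
        pred != category
      }
      w <- wrong(xy)
      redraws <- 0L
      while (sum(w) != n_misclassified) {
        if (redraws >= max_redraws) {
          stop(sprintf(
            "overlap constraint infeasible: %d misclassified after %d redraws (target %d)",
            sum(w), redraws, n_misclassified), call. = FALSE)
        }
        pool <- if (sum(w) > n_misclassified) which(w) else which(!w)
        i <- pool[sample.int(length(pool), 1)]
        xy[i, ] <- .sample_truncated(dists[dists$label == category[i], ], space, 1)
        w <- wrong(xy)
        redraws <- redraws + 1L
      }
    }
    nrm <- to_normalized(space, xy[, 1], xy[, 2])
    tibble::tibble(
      id = seq_len(2 * n_per_category),
      task = dists$task[1], modality = dists$modality[1],
      category = category,
      x_phys = xy[, 1], y_phys = xy[, 2],
      x_norm = nrm$x, y_norm = nrm$y
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Packaged fixture stimulus set for one task
#'
#' The fixed training set used throughout examples and tests: 200 stimuli
#' (100 per category) sampled with the packaged seed and the 10/200 overlap
#' constraint, so the optimal bound scores exactly 95%.
#'
#' @inheritParams category_distributions
#' @param seed Seed for the fixture draw (default [catbound_fixture_seed]).
#' @return A stimulus tibble (see [sample_stimuli()]).
#' @export
fixture_stimuli <- function(modality, task, seed = catbound_fixture_seed) {
  sample_stimuli(category_distributions(modality, task), 100, 10, seed = seed)
}

#' Generalization-test stimulus grid
#'
#' Builds the feedback-free generalization test set: `n_side^2` novel
#' stimuli evenly spaced in normalized coordinates over the full stimulus
#' ranges (the experiment used an 8x8 grid, shared with the AX
#' discrimination task).  True category labels are assigned by the task's
#' optimal bound, since grid stimuli were never trained.
#'
#' @param dists Two-row tibble from [category_distributions()].
#' @param n_side Grid points per side (>= 2; default 8).
#' @return A stimulus tibble with `n_side^2` rows.
#' @examples
#' nrow(generalization_grid(category_distributions("visual", "II")))  # 64
#' @export
generalization_grid <- function(dists, n_side = 8) {
  stopifnot(n_side >= 2)
  space <- .space_for(dists)
  bound <- optimal_boundary(dists)
  g <- seq(0, 1, length.out = n_side)
  pts <- expand.grid(x_norm = g, y_norm = g, KEEP.OUT.ATTRS = FALSE)
  phys <- to_physical(space, pts$x_norm, pts$y_norm)
  h <- signed_distance(bound, pts$x_norm, pts$y_norm)
  tibble::tibble(
    id = seq_len(nrow(pts)),
    task = dists$task[1], modality = dists$modality[1],
    category = ifelse(h >= 0, "A", "B"),
    x_phys = phys$x, y_phys = phys$y,
    x_norm = pts$x_norm, y_norm = pts$y_norm
  )
}

#' Read and write stimulus sets as CSV
#'
#' Plain comma-delimited UTF-8 files with header
#' `id,task,modality,category,x_phys,y_phys,x_norm,y_norm`, floats at full
#' precision.
#'
#' @param stimuli A stimulus tibble.
#' @param path File path.
#' @return `read_stimuli()` returns the stimulus tibble;
#'   `write_stimuli()` returns `stimuli` invisibly.
#' @export
write_stimuli <- function(stimuli, path) {
  cols <- c("id", "task", "modality", "category",
            "x_phys", "y_phys", "x_norm", "y_norm")
  readr::write_csv(stimuli[cols], path)
  invisible(stimuli)
}

#' @rdname write_stimuli
#' @export
read_stimuli <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    id = readr::col_integer(), task = readr::col_character(),
    modality = readr::col_character(), category = readr::col_character(),
    x_phys = readr::col_double(), y_phys = readr::col_double(),
    x_norm = readr::col_double(), y_norm = readr::col_double()
  ))
}
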