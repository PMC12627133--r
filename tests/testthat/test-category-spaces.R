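test_that("category distribution parameters match the published design", {
  aud_rb <- category_distributions("auditory", "RB")
  A <- aud_rb[aud_rb$label == "A", ]
  expect_equal(c(A$mean_x, A$sd_x, A$mean_y, A$sd_y, A$covariance),
               c(10.42, 1.58, 1.14, 0.66, 0.062))

  aud_ii <- category_distributions("auditory", "II")
  A <- aud_ii[aud_ii$label == "A", ]
  expect_equal(c(A$mean_x, A$sd_x, A$mean_y, A$sd_y, A$covariance),
               c(10.0, 2.13, 0.72, 0.49, 0.43))

  vis_rb <- category_distributions("visual", "RB")
  expect_equal(vis_rb$mean_x[vis_rb$label == "A"], 0.061)
  expect_equal(vis_rb$mean_x[vis_rb$label == "B"], 0.049)
  # orientation is irrelevant for the visual rule-based structure
  expect_equal(vis_rb$mean_y, c(56.7, 56.7))

  # every row is a valid bivariate normal
  for (m in c("auditory", "visual")) {
    for (tk in c("RB", "II")) {
      d <- category_distributions(m, tk)
      expect_true(all(d$sd_x > 0 & d$sd_y > 0))
      expect_true(all(abs(d$covariance) <= d$sd_x * d$sd_y))
    }
  }
  expect_error(category_distributions("tactile", "RB"))
  expect_error(category_distributions("auditory", "XX"))
})

test_that("normalized coordinates are an exact affine map of the physical ranges", {
  aud <- stimulus_space("auditory")
  expect_equal(as.numeric(to_physical(aud, 0, 0)), c(2.0, -0.38))
  expect_equal(as.numeric(to_physical(aud, 1, 1)), c(14.8, 2.67))
  vis <- stimulus_space("visual")
  expect_equal(as.numeric(to_physical(vis, 0, 0)), c(0.04, 10))
  expect_equal(as.numeric(to_physical(vis, 1, 1)), c(0.072, 104))

  withr::with_seed(7, {
    for (sp in list(aud, vis)) {
      xn <- runif(25); yn <- runif(25)
      phys <- to_physical(sp, xn, yn)
      back <- to_normalized(sp, phys$x, phys$y)
      expect_equal(back$x, xn, tolerance = 1e-12)
      expect_equal(back$y, yn, tolerance = 1e-12)
    }
  })
})

test_that("optimal boundaries sit at the category midpoints with unit normals", {
  b_aud <- optimal_boundary(category_distributions("auditory", "RB"))
  # criterion back in physical units: midpoint of 10.42 and 5.59
  expect_equal(2.0 + (-b_aud$c / b_aud$a) * (14.8 - 2.0), 8.005)
  expect_identical(b_aud$b, 0)

  b_vis <- optimal_boundary(category_distributions("visual", "RB"))
  expect_equal(0.04 + (-b_vis$c / b_vis$a) * (0.072 - 0.04), 0.055)

  for (m in c("auditory", "visual")) {
    for (tk in c("RB", "II")) {
      b <- optimal_boundary(category_distributions(m, tk))
      expect_equal(b$a^2 + b$b^2, 1, tolerance = 1e-12)
      # A side is the positive side at the A mean
      nd <- catbound:::.normalize_dists(category_distributions(m, tk))
      A <- nd[nd$label == "A", ]
      expect_gt(signed_distance(b, A$mean_x, A$mean_y), 0)
    }
  }

  degenerate <- category_distributions("auditory", "RB")
  degenerate$mean_x <- c(8, 8)
  expect_error(optimal_boundary(degenerate), "degenerate")
})

test_that("discriminant and midpoint bounds agree for rule-based pairs", {
  # independent pooled-covariance discriminant, computed directly
  for (m in c("auditory", "visual")) {
    d <- category_distributions(m, "RB")
    nd <- catbound:::.normalize_dists(d)
    A <- nd[nd$label == "A", ]; B <- nd[nd$label == "B", ]
    pooled <- (matrix(c(A$sd_x^2, A$covariance, A$covariance, A$sd_y^2), 2) +
               matrix(c(B$sd_x^2, B$covariance, B$covariance, B$sd_y^2), 2)) / 2
    w <- solve(pooled, c(A$mean_x - B$mean_x, A$mean_y - B$mean_y))
    mid <- c((A$mean_x + B$mean_x) / 2, (A$mean_y + B$mean_y) / 2)
    x_intercept <- (sum(w * mid)) / w[1]   # where the discriminant crosses y-slice at mid
    b <- optimal_boundary(d)
    expect_equal(-b$c / b$a, x_intercept, tolerance = 1e-9)
  }
})

test_that("sampling honors counts, hard ranges, and the exact overlap target", {
  d <- category_distributions("auditory", "RB")
  b <- optimal_boundary(d)
  sp <- stimulus_space("auditory")
  for (seed in 1:50) {
    s <- sample_stimuli(d, 100, 10, seed = seed)
    expect_identical(nrow(s), 200L)
    expect_identical(sum(s$category == "A"), 100L)
    expect_identical(sum(s$category == "B"), 100L)
    expect_true(all(s$x_phys >= sp$x_lo & s$x_phys <= sp$x_hi))
    expect_true(all(s$y_phys >= sp$y_lo & s$y_phys <= sp$y_hi))
    expect_equal(boundary_accuracy(s, b), 190 / 200)
    nrm <- to_normalized(sp, s$x_phys, s$y_phys)
    expect_equal(nrm$x, s$x_norm, tolerance = 1e-12)
  }
  # zero-overlap constraint and the other three conditions
  s0 <- sample_stimuli(d, 100, 0, seed = 3)
  expect_equal(boundary_accuracy(s0, b), 1)
  for (m in c("auditory", "visual")) {
    for (tk in c("RB", "II")) {
      di <- category_distributions(m, tk)
      si <- sample_stimuli(di, 100, 10, seed = 11)
      expect_equal(boundary_accuracy(si, optimal_boundary(di)), 0.95)
    }
  }
  # determinism
  expect_identical(sample_stimuli(d, 100, 10, seed = 5),
                   sample_stimuli(d, 100, 10, seed = 5))
})

test_that("sample moments track the generating distribution across seeds", {
  d <- category_distributions("auditory", "RB")
  A <- d[d$label == "A", ]
  n <- 100
  fail_mean <- fail_sd <- fail_cov <- 0
  for (seed in 1:50) {
    s <- sample_stimuli(d, n, n_misclassified = NULL, seed = seed)
    sa <- s[s$category == "A", ]
    se_mean <- A$sd_x / sqrt(n)
    se_sd <- A$sd_x / sqrt(2 * (n - 1))
    se_cov <- sqrt((A$sd_x^2 * A$sd_y^2 + A$covariance^2) / n)
    if (abs(mean(sa$x_phys) - A$mean_x) > 4 * se_mean) fail_mean <- fail_mean + 1
    if (abs(sd(sa$x_phys) - A$sd_x) > 4 * se_sd) fail_sd <- fail_sd + 1
    if (abs(cov(sa$x_phys, sa$y_phys) - A$covariance) > 4 * se_cov)
      fail_cov <- fail_cov + 1
  }
  expect_lte(fail_mean, 1)
  expect_lte(fail_sd, 1)
  expect_lte(fail_cov, 1)
})

test_that("bound classification follows the sign rule with ties labeled A", {
  b <- unidimensional_bound("x", 0.5)
  on_bound <- tibble::tibble(x_norm = 0.5, y_norm = 0.123, category = "B")
  expect_identical(classify_stimuli(on_bound, b)$predicted, "A")

  s <- cached_fixture("auditory", "RB")
  acc <- boundary_accuracy(s, optimal_boundary(category_distributions("auditory", "RB")))
  # complement under a region flip of the same line (no stimulus on the line)
  b0 <- optimal_boundary(category_distributions("auditory", "RB"))
  bf <- linear_bound(-b0$a, -b0$b, -b0$c)
  expect_equal(boundary_accuracy(s, bf), 1 - acc)
})

test_that("generalization grid spans the space and is labeled by the optimal bound", {
  d <- category_distributions("auditory", "RB")
  g <- generalization_grid(d)
  expect_identical(nrow(g), 64L)
  sp <- stimulus_space("auditory")
  expect_true(all(g$x_phys >= sp$x_lo & g$x_phys <= sp$x_hi))
  expect_true(all(g$y_phys >= sp$y_lo & g$y_phys <= sp$y_hi))
  b <- optimal_boundary(d)
  expect_identical(g$category,
                   ifelse(signed_distance(b, g$x_norm, g$y_norm) >= 0, "A", "B"))
  # grid stimuli are novel relative to the training fixture
  train <- cached_fixture("auditory", "RB")
  expect_false(any(paste(g$x_norm, g$y_norm) %in%
                     paste(train$x_norm, train$y_norm)))
  # 2x2 grid sits at the range corners
  g2 <- generalization_grid(d, n_side = 2)
  expect_setequal(paste(g2$x_norm, g2$y_norm), c("0 0", "1 0", "0 1", "1 1"))
  expect_setequal(g2$x_phys, c(2.0, 14.8))
})

test_that("stimulus CSV round-trips exactly", {
  s <- cached_fixture("visual", "II")
  path <- withr::local_tempfile(fileext = ".csv")
  write_stimuli(s, path)
  expect_identical(readLines(path, n = 1),
                   "id,task,modality,category,x_phys,y_phys,x_norm,y_norm")
  s2 <- read_stimuli(path)
  expect_equal(as.data.frame(s2), as.data.frame(s))
})
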