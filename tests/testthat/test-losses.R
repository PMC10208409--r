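test_that("calibration loss matches term-by-term arithmetic", {
  expect_equal(calibration_loss(1, 0.5), 1.0)
  expect_equal(calibration_loss(c(1, 0), c(0.9, 0.2)),
               (0.01 / 0.9 + 0.01 / 0.1) + (0.04 / 0.2 + 0.04 / 0.8))
  expect_equal(calibration_loss(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_error(calibration_loss(c(1, 2), c(0.5, 0.5)), "\\[0, 1\\]")
  expect_error(calibration_loss(1, c(0.5, 0.5)), "length")
})

test_that("euclidean distance: quadratic default, metric with sqrt flag", {
  expect_equal(euclidean_dist(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_dist(c(0, 0), c(3, 4)), 25)
  expect_equal(euclidean_dist(c(0, 0), c(3, 4), sqrt_form = TRUE), 5)
  set.seed(2)
  for (i in 1:20) {
    a <- runif(2); b <- runif(2)
    expect_equal(euclidean_dist(a, b), euclidean_dist(b, a))
  }
  expect_error(euclidean_dist(1:2, 1:3), "mismatch")
})

test_that("mahalanobis distance: explicit quadratic form and V scaling", {
  expect_equal(mahalanobis_dist(c(2, 0), c(0, 0), diag(c(4, 1))), 1.0)
  set.seed(7)
  a <- runif(2); b <- runif(2)
  V <- crossprod(matrix(rnorm(4), 2, 2)) + diag(2)
  expect_equal(mahalanobis_dist(a, b, 2 * V),
               mahalanobis_dist(a, b, V) / 2)
  expect_error(mahalanobis_dist(a, b, matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(mahalanobis_dist(a, b, matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("mahalanobis with identity V equals euclidean on random pairs", {
  set.seed(8)
  for (i in 1:1000) {
    a <- runif(2); b <- runif(2)
    expect_equal(mahalanobis_dist(a, b, diag(2)), euclidean_dist(a, b))
  }
})

test_that("minkowski distance: p = 1, p = 2 and the large-p limit", {
  expect_equal(minkowski_dist(c(0, 0), c(3, 4), p = 1), 7)
  expect_equal(minkowski_dist(c(0, 0), c(3, 4), p = 2),
               euclidean_dist(c(0, 0), c(3, 4), sqrt_form = TRUE))
  a <- c(0.1, 0.9); b <- c(0.7, 0.2)
  expect_equal(minkowski_dist(a, b, p = 64), max(abs(a - b)),
               tolerance = 1e-2)
  expect_error(minkowski_dist(a, b, p = 0), "positive")
})

test_that("distance loss sums per-bag distances and is additive", {
  spec <- loss_spec("vector_distance")
  y <- rbind(c(0.2, 0.1), c(0.5, 0.5))
  expect_equal(distance_loss(y, y, spec), 0)
  expect_equal(distance_loss(rbind(c(0.2, 0.1)), rbind(c(0.5, 0.5)), spec),
               0.09 + 0.16)
  o <- rbind(c(0.3, 0.3), c(0.6, 0.4))
  expect_equal(distance_loss(y, o, spec),
               distance_loss(y[1, , drop = FALSE], o[1, , drop = FALSE],
                             spec) +
               distance_loss(y[2, , drop = FALSE], o[2, , drop = FALSE],
                             spec))
  expect_error(distance_loss(y, o, loss_spec("mse")), "vector_distance")
})

test_that("baseline losses match closed forms and cel is minimized at y", {
  expect_equal(baseline_loss(1, 0.5, "mse"), 0.25)
  expect_equal(baseline_loss(1, 0.5, "cel"), log(2))
  grid <- seq(0.01, 0.99, by = 0.01)
  cel <- vapply(grid, function(o) baseline_loss(1, o, "cel"), numeric(1))
  expect_equal(grid[which.min(cel)], 0.99)  # monotone toward y = 1
  mixed <- vapply(grid, function(o)
    baseline_loss(c(1, 0), c(o, o), "cel"), numeric(1))
  expect_equal(grid[which.min(mixed)], 0.5) # balanced labels -> 0.5
  expect_error(baseline_loss(0.5, 0.5, "cel"), "\\{0, 1\\}")
})

test_that("losses are nonnegative and vanish only at the labels", {
  set.seed(10)
  for (i in 1:20) {
    y <- round(runif(3))
    o <- runif(3, 0.05, 0.95)
    expect_gte(calibration_loss(y, o), 0)
    expect_gte(baseline_loss(y, o, "mse"), 0)
    expect_gte(baseline_loss(y, o, "cel"), 0)
    yv <- matrix(runif(6), 3); ov <- matrix(runif(6), 3)
    expect_gte(distance_loss(yv, ov, loss_spec("vector_distance")), 0)
    expect_equal(distance_loss(yv, yv, loss_spec("vector_distance")), 0)
  }
  expect_equal(calibration_loss(c(0.4, 0.6), c(0.4, 0.6)), 0)
})

test_that("analytic loss gradients match central finite differences", {
  set.seed(12)
  eps <- 1e-6
  fd_check <- function(spec, y, o, n_m = NULL) {
    vg <- loss_value_grad(y, o, spec, n_m)
    g_fd <- o
    for (k in seq_along(o)) {
      op <- o; op[k] <- op[k] + eps
      om <- o; om[k] <- om[k] - eps
      g_fd[k] <- (loss_value_grad(y, op, spec, n_m)$value -
                  loss_value_grad(y, om, spec, n_m)$value) / (2 * eps)
    }
    expect_equal(as.vector(vg$grad), as.vector(g_fd), tolerance = 1e-5)
  }
  fd_check(loss_spec("category_calibration"), c(1, 0, 1),
           c(0.7, 0.3, 0.45))
  fd_check(loss_spec("category_calibration", weight_by_bag_size = TRUE),
           c(1, 0), c(0.6, 0.2), n_m = c(10, 25))
  fd_check(loss_spec("mse"), c(1, 0), c(0.7, 0.3))
  fd_check(loss_spec("cel"), c(1, 0), c(0.7, 0.3))
  V <- crossprod(matrix(rnorm(4), 2)) + diag(2)
  for (spec in list(loss_spec("vector_distance"),
                    loss_spec("vector_distance", sqrt_form = TRUE),
                    loss_spec("vector_distance", distance = "mahalanobis",
                              V = V),
                    loss_spec("vector_distance", distance = "minkowski",
                              p = 3)))
    fd_check(spec, matrix(runif(4), 2), matrix(runif(4, 0.2, 0.8), 2))
})
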