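#' Loss specification for multiple-instance training
#'
#' Bundles the label mode, bag aggregation metric, distance kind and
#' numerical guards selected for training or evaluation.  Modes:
#' `"category_calibration"` -- the calibration loss for category labels
#' (see [calibration_loss()]); `"vector_distance"` -- the distance loss for
#' `[pR, pT]` vector labels (see [distance_loss()]); `"mse"` and `"cel"` --
#' the baseline mean-square-error and cross-entropy losses.
#'
#' @param mode loss mode (see Details).
#' @param metric bag aggregation metric.
#' @param distance distance kind for `"vector_distance"`.
#' @param V 2x2 symmetric positive-definite covariance for the Mahalanobis
#'   distance (typically the sample covariance of the per-patient
#'   `(response, pT)` pairs).
#' @param p Minkowski order (> 0, default 2).
#' @param sqrt_form use the metric (square-root) form of the Euclidean /
#'   Mahalanobis distance instead of the default quadratic form.
#' @param eps clipping guard in `(0, 0.01]` applied before divisions and
#'   logarithms (default `1e-7`).
#' @param weight_by_bag_size multiply each bag's calibration term by its size
#'   `n_m`; this is the variant that coincides exactly with the
#'   Hosmer-Lemeshow statistic (default `FALSE`, the literal unweighted sum).
#' @return an object of class `"loss_spec"`.
#' @export
loss_spec <- function(mode = c("vector_distance", "category_calibration",
                               "mse", "cel"),
                      metric = c("median", "max", "min", "mean"),
                      distance = c("euclidean", "mahalanobis", "minkowski"),
                      V = NULL, p = 2, sqrt_form = FALSE, eps = 1e-7,
                      weight_by_bag_size = FALSE) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  distance <- match.arg(distance)
  stopifnot(eps > 0, eps <= 0.01, p > 0)
  if (distance == "mahalanobis" && mode == "vector_distance") {
    if (is.null(V)) stop("Mahalanobis distance requires a covariance 'V'")
    V <- .check_spd(V)
  }
  structure(list(mode = mode, metric = metric, distance = distance, V = V,
                 p = p, sqrt_form = sqrt_form, eps = eps,
                 weight_by_bag_size = weight_by_bag_size),
            class = "loss_spec")
}

.check_spd <- function(V, ridge = 1e-8) {
  V <- as.matrix(V)
  if (!isSymmetric(V, tol = 1e-10)) stop("covariance 'V' must be symmetric")
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("covariance 'V' is not positive definite (smallest eigenvalue ",
         format(min(ev)), ")")
  if (min(ev) / max(ev) < 1e-10) {
    warning("near-singular covariance 'V'; adding ridge ", ridge)
    V <- V + diag(ridge * max(ev), nrow(V))
  }
  V
}

.clip01 <- function(o, eps) pmin(pmax(o, eps), 1 - eps)

#' Calibration loss for category-labeled bags
#'
#' The global calibration loss of the network over `M` bags,
#' \deqn{E = \sum_m \frac{(y_m-\hat o_m)^2}{\hat o_m}
#'             + \frac{(y_m-\hat o_m)^2}{1-\hat o_m},}
#' a Pearson-style discrepancy between bag labels and aggregated bag outputs
#' whose minimisation optimises the model's goodness-of-fit: with mean
#' aggregation, labels taken as group event proportions and bag-size
#' weighting, it is exactly the Hosmer-Lemeshow statistic (see
#' [hosmer_lemeshow()]).
#'
#' @param y bag labels in `[0, 1]` (categories `{0,1}` or event
#'   proportions).
#' @param o_hat aggregated bag outputs in `(0, 1)`; clipped to
#'   `[eps, 1-eps]`.
#' @param spec a [loss_spec()] (only `eps` and `weight_by_bag_size` are
#'   used).
#' @param n_m bag sizes, required when `spec$weight_by_bag_size` is `TRUE`.
#' @return nonnegative scalar loss.
#' @examples
#' calibration_loss(1, 0.5)  # (0.25/0.5) + (0.25/0.5) = 1
#' @export
calibration_loss <- function(y, o_hat, spec = loss_spec("category_calibration"),
                             n_m = NULL) {
  stopifnot(length(y) == length(o_hat), length(y) >= 1)
  if (any(y < 0 | y > 1)) stop("calibration labels must lie in [0, 1]")
  o <- .clip01(o_hat, spec$eps)
  term <- (y - o)^2 / o + (y - o)^2 / (1 - o)
  if (isTRUE(spec$weight_by_bag_size)) {
    if (is.null(n_m)) stop("bag sizes 'n_m' required when weighting by size")
    term <- term * n_m
  }
  sum(term)
}

# d/do of the calibration term, on the clipped scale
.calibration_grad <- function(y, o_hat, spec, n_m = NULL) {
  o <- .clip01(o_hat, spec$eps)
  r <- y - o
  g <- (-2 * r * o - r^2) / o^2 + (-2 * r * (1 - o) + r^2) / (1 - o)^2
  if (isTRUE(spec$weight_by_bag_size)) g <- g * n_m
  g
}

#' Euclidean distance between endpoint vectors
#'
#' The printed quadratic form `(y1 - y2)(y1 - y2)^T` (squared Euclidean
#' distance), the default used in training; `sqrt_form = TRUE` yields the
#' metric form.
#'
#' @param y1,y2 numeric vectors of equal length.
#' @param sqrt_form return the square-root (metric) form.
#' @return nonnegative scalar.
#' @examples
#' euclidean_dist(c(0, 0), c(3, 4))            # 25
#' euclidean_dist(c(0, 0), c(3, 4), sqrt_form = TRUE)  # 5
#' @export
euclidean_dist <- function(y1, y2, sqrt_form = FALSE) {
  if (length(y1) != length(y2)) stop("dimension mismatch")
  q <- sum((y1 - y2)^2)
  if (sqrt_form) sqrt(q) else q
}

#' Mahalanobis distance between endpoint vectors
#'
#' The covariance-whitened quadratic form `(y1 - y2) V^{-1} (y1 - y2)^T`,
#' which accounts for the correlation between the ORR and TTE endpoints.
#' With `V` the identity it reduces to [euclidean_dist()].
#'
#' @param y1,y2 numeric vectors of equal length.
#' @param V symmetric positive-definite covariance between the endpoints.
#' @param sqrt_form return the square-root (metric) form.
#' @return nonnegative scalar.
#' @export
mahalanobis_dist <- function(y1, y2, V, sqrt_form = FALSE) {
  if (length(y1) != length(y2)) stop("dimension mismatch")
  V <- .check_spd(V)
  d <- y1 - y2
  q <- as.numeric(d %*% solve(V, d))
  if (sqrt_form) sqrt(q) else q
}

#' Minkowski distance between endpoint vectors
#'
#' The standard \eqn{\ell_p} form \eqn{(\sum_i |y_{1i}-y_{2i}|^p)^{1/p}};
#' `p = 2` coincides with the square-root Euclidean form and `p -> Inf`
#' approaches the maximum componentwise difference.
#'
#' @param y1,y2 numeric vectors of equal length.
#' @param p order, `> 0` (default 2).
#' @return nonnegative scalar.
#' @export
minkowski_dist <- function(y1, y2, p = 2) {
  if (length(y1) != length(y2)) stop("dimension mismatch")
  if (p <= 0) stop("Minkowski order 'p' must be positive")
  sum(abs(y1 - y2)^p)^(1 / p)
}

.dist_fun <- function(spec) {
  switch(spec$distance,
         euclidean = function(a, b) euclidean_dist(a, b, spec$sqrt_form),
         mahalanobis = function(a, b) {
           d <- a - b
           q <- as.numeric(d %*% solve(spec$V, d))
           if (spec$sqrt_form) sqrt(q) else q
         },
         minkowski = function(a, b) minkowski_dist(a, b, spec$p))
}

# gradient of dist(o, y) with respect to o (a k-vector)
.dist_grad <- function(o, y, spec) {
  d <- o - y
  switch(spec$distance,
    euclidean = {
      if (spec$sqrt_form) {
        nrm <- sqrt(sum(d^2))
        if (nrm < spec$eps) rep(0, length(d)) else d / nrm
      } else 2 * d
    },
    mahalanobis = {
      w <- as.numeric(solve(spec$V, d))
      if (spec$sqrt_form) {
        q <- sqrt(max(sum(d * w), 0))
        if (q < spec$eps) rep(0, length(d)) else w / q
      } else 2 * w
    },
    minkowski = {
      s <- sum(abs(d)^spec$p)
      if (s < spec$eps^spec$p) rep(0, length(d))
      else s^(1 / spec$p - 1) * abs(d)^(spec$p - 1) * sign(d)
    })
}

#' Distance loss for vector-labeled bags
#'
#' The global error over `M` bags with vector labels,
#' `E = sum_m dist(o_hat_m, y_m)`, with the distance selected in the
#' [loss_spec()] (quadratic Euclidean by default).
#'
#' @param y matrix of bag labels (bags x k, typically `k = 2` for
#'   `[pR, pT]`).
#' @param o_hat matrix of aggregated bag outputs, same shape.
#' @param spec a [loss_spec()] with `mode = "vector_distance"`.
#' @return nonnegative scalar loss.
#' @export
distance_loss <- function(y, o_hat, spec = loss_spec("vector_distance")) {
  if (spec$mode != "vector_distance")
    stop("'spec' mode must be \"vector_distance\"")
  y <- rbind(y); o_hat <- rbind(o_hat)
  if (!all(dim(y) == dim(o_hat))) stop("dimension mismatch")
  f <- .dist_fun(spec)
  sum(vapply(seq_len(nrow(y)), function(m) f(o_hat[m, ], y[m, ]), numeric(1)))
}

#' Baseline losses: mean square error and cross-entropy
#'
#' The two conventional machine-learning losses the calibration loss is
#' compared against: `mse = sum (y - o)^2` and
#' `cel = -sum [y log(o) + (1-y) log(1-o)]` (with eps clipping).
#'
#' @param y labels (`cel` requires `y` in `{0, 1}`).
#' @param o_hat predictions in `(0, 1)` for `cel`; unrestricted for `mse`.
#' @param kind `"mse"` or `"cel"`.
#' @param eps clipping guard for `cel` (default `1e-7`).
#' @return nonnegative scalar loss.
#' @export
baseline_loss <- function(y, o_hat, kind = c("mse", "cel"), eps = 1e-7) {
  kind <- match.arg(kind)
  stopifnot(length(y) == length(o_hat))
  if (kind == "mse") return(sum((y - o_hat)^2))
  if (!all(y %in% c(0, 1))) stop("cross-entropy requires labels in {0, 1}")
  o <- .clip01(o_hat, eps)
  -sum(y * log(o) + (1 - y) * log(1 - o))
}

#' Loss value and gradient at the bag level
#'
#' Evaluates the selected loss and its analytic gradient with respect to the
#' aggregated bag outputs.  Exposed so the gradient can be verified against
#' finite differences; training uses it internally.
#'
#' @param y bag labels: vector (scalar modes) or matrix (vector mode).
#' @param o_hat aggregated bag outputs, same shape as `y`.
#' @param spec a [loss_spec()].
#' @param n_m optional bag sizes (calibration weighting).
#' @return list with `value` (scalar) and `grad` (same shape as `o_hat`).
#' @export
loss_value_grad <- function(y, o_hat, spec, n_m = NULL) {
  switch(spec$mode,
    category_calibration = list(
      value = calibration_loss(y, o_hat, spec, n_m),
      grad = .calibration_grad(y, o_hat, spec, n_m)),
    vector_distance = {
      ym <- rbind(y); om <- rbind(o_hat)
      g <- t(vapply(seq_len(nrow(ym)),
                    function(m) .dist_grad(om[m, ], ym[m, ], spec),
                    numeric(ncol(ym))))
      list(value = distance_loss(ym, om, spec), grad = g)
    },
    mse = list(value = baseline_loss(y, o_hat, "mse"),
               grad = 2 * (o_hat - y)),
    cel = {
      o <- .clip01(o_hat, spec$eps)
      list(value = baseline_loss(y, o_hat, "cel", spec$eps),
           grad = (o - y) / (o * (1 - o)))
    })
}
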