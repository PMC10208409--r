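#' Fit the multiple-instance prognosis model
#'
#' The main fitting entry point: standardizes the burden features, builds a
#' multiple-instance regression network and trains it by full-batch gradient
#' descent to map patient burden vectors to subgroup-level prognosis labels.
#' With `mode = "probabilistic"` the labels are `[pR, pT]` pairs and the
#' model minimises a vector distance loss (quadratic Euclidean by default,
#' or Mahalanobis/Minkowski); with `mode = "category"` the labels are
#' `{0, 1}` categories and the model minimises the Hosmer-Lemeshow-style
#' calibration loss (or the MSE/CEL baselines).
#'
#' @param x numeric feature matrix, patients x d (e.g. from
#'   [tmb_matrix()] or [simulate_cohort()]).
#' @param bags factor (or vector) of subgroup ids, one per patient.
#' @param labels bag labels: numeric vector in `[0, 1]` for category mode,
#'   or a bags x 2 matrix of `[pR, pT]` for probabilistic mode; rows are
#'   matched to bag levels by name when named.
#' @param mode label mode; the default follows the shape of `labels`.
#' @param metric subgroup aggregation metric (default `"mean"`).
#' @param loss loss selection: `"auto"` picks the mode's canonical loss
#'   (distance for probabilistic, calibration for category); `"mse"`/`"cel"`
#'   select the baselines (category mode).
#' @param distance distance kind for probabilistic mode.
#' @param V Mahalanobis covariance; `NULL` uses the sample covariance of
#'   the per-patient `(response, pT)` pairs when a `clinical` frame is
#'   supplied, else the identity.
#' @param p Minkowski order.
#' @param sqrt_form use the metric (square-root) distance form.
#' @param hidden hidden-layer widths (default 16).
#' @param lr,max_epochs,tol,momentum gradient-descent settings, see
#'   [train_config()].
#' @param seed seed for weight initialisation.
#' @param scale standardize features before training (default `TRUE`).
#' @return an object of class `"tmbserval"`: the trained network, fitted
#'   scaler, loss specification, per-epoch loss trace, bag-level fitted
#'   values and residuals, accessible through `print()`, `summary()`,
#'   `coef()`, `predict()`, `fitted()`, `residuals()` and `plot()`.
#' @examples
#' cohort <- simulate_cohort(sim_config(scale = 0.2, seed = 1))
#' pT <- estimate_pT(cohort$features, cohort$clinical$time_days,
#'                   cohort$clinical$event)
#' lab <- probabilistic_label(cohort$bags, cohort$clinical$response, pT,
#'                            metric = "mean")
#' fit <- tmbserval(cohort$features, cohort$bags, lab, metric = "mean",
#'                  max_epochs = 500)
#' fit
#' @export
tmbserval <- function(x, bags, labels,
                      mode = c("auto", "probabilistic", "category"),
                      metric = c("mean", "median", "min", "max"),
                      loss = c("auto", "calibration", "distance", "mse",
                               "cel"),
                      distance = c("euclidean", "mahalanobis", "minkowski"),
                      V = NULL, p = 2, sqrt_form = FALSE,
                      hidden = 16, lr = 0.05, max_epochs = 5000, tol = 1e-3,
                      momentum = 0, seed = 1, scale = TRUE) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  loss <- match.arg(loss)
  distance <- match.arg(distance)
  x <- as.matrix(x)
  bags <- as.factor(bags)
  if (mode == "auto") mode <- if (is.null(dim(labels))) "category"
                              else "probabilistic"
  if (mode == "probabilistic" && distance == "mahalanobis" && is.null(V))
    V <- diag(2)
  spec_mode <- switch(loss,
    auto = if (mode == "probabilistic") "vector_distance"
           else "category_calibration",
    calibration = "category_calibration",
    distance = "vector_distance",
    mse = "mse", cel = "cel")
  spec <- loss_spec(spec_mode, metric = metric, distance = distance, V = V,
                    p = p, sqrt_form = sqrt_form)
  config <- train_config(lr = lr, max_epochs = max_epochs, tol = tol,
                         momentum = momentum, seed = seed)
  scaler <- if (scale) suppressWarnings(fit_scaler(x)) else NULL
  xs <- if (scale) predict(scaler, x) else x
  y <- .label_matrix(labels, levels(bags))
  out_dim <- if (spec_mode == "vector_distance") ncol(y) else 1L
  net <- init_network(ncol(x), hidden, out_dim, seed = seed)
  run <- mil_train(net, xs, bags, y, spec, config)
  fitted_bags <- rbind(run$o_hat)
  rownames(fitted_bags) <- levels(bags)
  structure(list(net = run$net, scaler = scaler, spec = spec,
                 config = config, trace = run$trace, loss = run$loss,
                 epochs = run$epochs, labels = y,
                 fitted_bags = fitted_bags, bags = bags, d = ncol(x),
                 mode = mode, call = match.call()),
            class = "tmbserval")
}

#' @export
#' @method print tmbserval
print.tmbserval <- function(x, ...) {
  cat("Multiple-instance TMB prognosis model\n")
  cat(sprintf("  %d bags, %d patients, %d burden dimensions\n",
              nlevels(x$bags), length(x$bags), x$d))
  cat(sprintf("  mode: %s | loss: %s | metric: %s%s\n", x$mode, x$spec$mode,
              x$spec$metric,
              if (x$spec$mode == "vector_distance")
                paste0(" | distance: ", x$spec$distance) else ""))
  cat(sprintf("  architecture: %s (%d parameters)\n",
              paste(x$net$dims, collapse = "-"), n_params(x$net)))
  cat(sprintf("  final training loss %.6g after %d epochs\n",
              x$loss, x$epochs))
  invisible(x)
}

#' @export
summary.tmbserval <- function(object, ...) {
  res <- residuals(object)
  tab <- data.frame(bag = levels(object$bags),
                    n = as.integer(table(object$bags)))
  tab <- cbind(tab, label = object$labels, fitted = object$fitted_bags,
               residual = res)
  out <- list(model = object, bag_table = tab)
  class(out) <- "summary.tmbserval"
  out
}

#' @export
#' @method print summary.tmbserval
print.summary.tmbserval <- function(x, digits = 4, ...) {
  print(x$model)
  cat("\nBag-level fit:\n")
  print(format(x$bag_table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.tmbserval <- function(object, ...) {
  list(W = object$net$W, b = object$net$b)
}

#' Predict instance- or bag-level prognosis
#'
#' @param object a fitted `"tmbserval"` model.
#' @param newdata feature matrix (patients x d); default: training features
#'   are not stored, so `newdata` is required.
#' @param bags optional bag ids for `type = "bag"`.
#' @param type `"instance"` for per-patient outputs, `"bag"` for aggregated
#'   subgroup predictions.
#' @param ... ignored.
#' @return matrix of instance outputs, or bags x output_dim matrix of
#'   aggregated predictions.
#' @export
predict.tmbserval <- function(object, newdata, bags = NULL,
                              type = c("instance", "bag"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (ncol(x) != object$d)
    stop("newdata has ", ncol(x), " feature dimensions; model expects ",
         object$d)
  xs <- if (!is.null(object$scaler)) predict(object$scaler, x) else x
  O <- forward(object$net, xs)
  if (type == "instance") return(O)
  if (is.null(bags)) stop("bag ids required for type = \"bag\"")
  bags <- droplevels(as.factor(bags))
  .aggregate_outputs(O, bags, object$spec$metric)$o_hat
}

#' @export
fitted.tmbserval <- function(object, ...) object$fitted_bags

#' @export
residuals.tmbserval <- function(object, ...) {
  y <- object$labels
  if (object$spec$mode == "vector_distance") y - object$fitted_bags
  else drop(y) - drop(object$fitted_bags)
}

#' Plot the training loss trace
#'
#' @param x a fitted `"tmbserval"` model.
#' @param ... passed to [graphics::plot()].
#' @export
#' @method plot tmbserval
plot.tmbserval <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "l",
                 xlab = "epoch", ylab = "training loss",
                 main = "Gradient-descent loss trace", ...)
  invisible(x)
}
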