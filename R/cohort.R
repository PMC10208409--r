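#' Aggregate instance values into a bag-level summary
#'
#' The four subgroup efficacy metrics -- median, maximum, minimum, mean --
#' applied to a vector of scalars or, componentwise, to the rows of a matrix
#' (e.g. per-patient `[pR, pT]` pairs).  The even-count median is the
#' midpoint of the central pair.
#'
#' @param values numeric vector, or matrix with one row per instance.
#' @param metric one of `"median"`, `"max"`, `"min"`, `"mean"`.
#' @return a scalar, or a vector with one entry per column of `values`.
#' @examples
#' aggregate_metric(c(0.1, 0.5, 0.9), "median")
#' aggregate_metric(rbind(c(0.2, 0.8), c(0.4, 0.6), c(0.6, 0.4)), "median")
#' @export
aggregate_metric <- function(values, metric = c("median", "max", "min", "mean")) {
  metric <- match.arg(metric)
  fun <- switch(metric, median = stats::median, max = max, min = min,
                mean = mean)
  if (is.matrix(values)) {
    if (nrow(values) == 0) stop("empty instance set")
    apply(values, 2, fun)
  } else {
    if (length(values) == 0) stop("empty instance set")
    if (!is.numeric(values)) stop("'values' must be numeric")
    fun(values)
  }
}

#' Expert-style category labels for patient subgroups
#'
#' Emulates clinician labeling of subgroup prognosis from tumor response
#' (RECIST: CR/PR = responder) and progression-free survival.  The two-class
#' rule labels a bag 1 when its responder proportion reaches
#' `response_threshold` *and* its median PFS exceeds `pfs_favorable_days`
#' (the conventional 6-month favorable-prognosis horizon); otherwise 0.  The
#' three-class rule grades bags satisfying exactly one clause as 0 and
#' neither as -1.  Such labeling is inherently subjective, so every rule
#' parameter is explicit.
#'
#' @param bags factor (or vector) of bag ids, one per patient.
#' @param response binary per-patient response indicator (CR/PR = 1).
#' @param time per-patient time-to-event in days.
#' @param response_threshold minimum responder proportion (default 0.5).
#' @param pfs_favorable_days PFS horizon in days (default 183, i.e. 6
#'   months).
#' @param three_class use the `{-1, 0, 1}` rule (default `FALSE`).
#' @return named numeric vector of bag labels, one per bag level.
#' @export
assign_category_label <- function(bags, response, time,
                                  response_threshold = 0.5,
                                  pfs_favorable_days = 183,
                                  three_class = FALSE) {
  bags <- as.factor(bags)
  stopifnot(length(response) == length(bags), length(time) == length(bags))
  if (anyNA(response) || anyNA(time))
    stop("missing clinical fields (response/time)")
  vapply(levels(bags), function(m) {
    i <- bags == m
    resp_ok <- mean(response[i]) >= response_threshold
    pfs_ok <- stats::median(time[i]) > pfs_favorable_days
    if (three_class) sum(resp_ok, pfs_ok) - 1 else as.numeric(resp_ok && pfs_ok)
  }, numeric(1))
}

#' Per-patient survival probability beyond a horizon via Cox PH
#'
#' Fits a Cox proportional-hazards model of time-to-event on the burden
#' features (partial likelihood, via \pkg{survival}), estimates the baseline
#' survival function, and returns each patient's predicted probability
#' `S_i(t0)` of surviving beyond the horizon `t0`.  These probabilities form
#' the `pT` component of the objective probabilistic subgroup labels.
#'
#' A rank-deficient design triggers a collinearity warning and a ridge-
#' penalized refit.
#'
#' @param x numeric feature matrix (patients x d).
#' @param time,event time-to-event in days and event indicator (1 = observed
#'   progression/death, 0 = censored).
#' @param t0 survival horizon in days (default 183).
#' @return numeric vector of survival probabilities in `[0, 1]`.
#' @export
estimate_pT <- function(x, time, event, t0 = 183) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(time), length(time) == length(event),
            t0 > 0, all(time > 0), all(event %in% c(0, 1)))
  if (sum(event) == 0)
    stop("all-censored cohort: no events to fit a proportional-hazards model")
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  df <- data.frame(time = time, event = event, x)
  form <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(colnames(x), collapse = " + ")))
  fit <- survival::coxph(form, data = df, x = TRUE)
  if (anyNA(stats::coef(fit))) {
    warning("collinear features in proportional-hazards fit; ",
            "refitting with a ridge penalty")
    form <- stats::as.formula(paste(
      "survival::Surv(time, event) ~ survival::ridge(",
      paste(colnames(x), collapse = ", "), ", theta = 1)"))
    fit <- survival::coxph(form, data = df, x = TRUE)
  }
  # product-limit (KM-style) baseline so a cohort failing entirely by t0
  # yields survival exactly 0
  sf <- survival::survfit(fit, newdata = df, stype = 1)
  s <- summary(sf, times = t0, extend = TRUE)$surv
  pmin(pmax(as.numeric(s), 0), 1)
}

#' Objective probabilistic subgroup label [pR, pT]
#'
#' Combines the two efficacy endpoints into a probability-scale bag label:
#' `pR` aggregates the member response values (with `metric = "mean"` this is
#' exactly the bag's objective response rate) and `pT` aggregates the member
#' Cox-derived survival probabilities from [estimate_pT()].
#'
#' @param bags factor (or vector) of bag ids, one per patient.
#' @param response per-patient response indicator or latent response
#'   probability in `[0, 1]`.
#' @param pT per-patient survival probability beyond the horizon.
#' @param metric aggregation metric (default `"median"`).
#' @return matrix with one row per bag (named) and columns `pR`, `pT`.
#' @export
probabilistic_label <- function(bags, response, pT,
                                metric = c("median", "max", "min", "mean")) {
  metric <- match.arg(metric)
  bags <- as.factor(bags)
  stopifnot(length(response) == length(bags), length(pT) == length(bags),
            all(response >= 0 & response <= 1), all(pT >= 0 & pT <= 1))
  lab <- t(vapply(levels(bags), function(m) {
    i <- bags == m
    c(aggregate_metric(response[i], metric), aggregate_metric(pT[i], metric))
  }, numeric(2)))
  colnames(lab) <- c("pR", "pT")
  lab
}

#' Fit a per-dimension feature standardizer
#'
#' Centers and scales each burden dimension on the training data; the fitted
#' scaler is reapplied unchanged to validation/test folds so no test
#' information leaks into the scaling.  Zero-variance dimensions are centered
#' only, with a warning.
#'
#' @param x numeric matrix (patients x d).
#' @return an object of class `"tmb_scaler"` with `center` and `scale`.
#' @seealso [predict.tmb_scaler()]
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  if (any(zero <- !is.finite(scale) | scale == 0)) {
    warning("zero-variance feature dimension(s) ",
            paste(which(zero), collapse = ", "), ": centered only")
    scale[zero] <- 1
  }
  structure(list(center = center, scale = scale), class = "tmb_scaler")
}

#' Apply (or invert) a fitted feature standardizer
#'
#' @param object a `"tmb_scaler"` from [fit_scaler()].
#' @param newdata numeric matrix to transform.
#' @param inverse undo the standardization (default `FALSE`).
#' @param ... ignored.
#' @return transformed matrix of the same shape.
#' @export
predict.tmb_scaler <- function(object, newdata, inverse = FALSE, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$center))
    stop("feature dimension mismatch: scaler expects ", length(object$center))
  if (inverse) sweep(sweep(x, 2, object$scale, "*"), 2, object$center, "+")
  else sweep(sweep(x, 2, object$center, "-"), 2, object$scale, "/")
}

#' Read a clinical endpoint table
#'
#' @param path TSV with columns `patient_id`, `response`, `time_days`,
#'   `event` and optionally `subgroup_id`.
#' @return data.frame with those columns.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "response", "time_days", "event")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("clinical table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(tab$time_days <= 0)) stop("time_days must be positive")
  if (!all(tab$event %in% c(0, 1))) stop("event must be 0/1")
  tab
}
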