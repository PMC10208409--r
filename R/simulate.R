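#' Configuration of the synthetic immunotherapy cohort generator
#'
#' The default preset emulates the study conditions of the reference
#' simulation at the burden-vector level: 660 patients in five prognosis
#' subgroups of sizes 90/212/64/202/92 with target `[pR, pT]` subgroup
#' labels (0.223,0.246), (0.326,0.397), (0.461,0.558), (0.654,0.733),
#' (0.908,0.922); three burden dimensions (SNV, INS, DEL) drawn from
#' overdispersed negative-binomial counts with subgroup-specific means; a
#' dichotomous-logistic response model; and exponential-baseline Cox
#' proportional-hazards progression-free-survival times with independent
#' exponential censoring.  Per-subgroup intercepts of the response and
#' hazard models are calibrated by root-finding so the subgroup mean latent
#' probabilities hit the target labels exactly.
#'
#' Slopes, subgroup feature means and dispersion are presets chosen to give
#' a monotone but non-uniform burden-benefit dependence (higher burden,
#' better prognosis); the reference coefficients are not published.
#'
#' @param subgroup_sizes positive integers, one per subgroup.
#' @param target_labels matrix (subgroups x 2) of `[pR, pT]` targets in
#'   `(0, 1)`.
#' @param feature_means matrix (subgroups x d) of negative-binomial mean
#'   counts per burden class.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param count_noise_sd standard deviation of the multiplicative lognormal
#'   measurement noise on counts (default 0.1), emulating assay measurement
#'   error.
#' @param logistic_slopes slopes of the response model on standardized
#'   features.
#' @param hazard_slopes log-hazard slopes on standardized features
#'   (negative: higher burden, lower hazard).
#' @param baseline_rate exponential baseline hazard rate per day.
#' @param censoring_rate target fraction of censored patients (default
#'   0.2); 0 disables censoring.
#' @param t0 survival horizon in days (default 183).
#' @param classes burden class names.
#' @param scale multiplies all subgroup sizes (convergence studies).
#' @param seed RNG seed (default 0).
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(subgroup_sizes = c(90, 212, 64, 202, 92),
                       target_labels = matrix(c(0.223, 0.246,
                                                0.326, 0.397,
                                                0.461, 0.558,
                                                0.654, 0.733,
                                                0.908, 0.922),
                                              ncol = 2, byrow = TRUE),
                       feature_means = matrix(c(30, 6, 5,
                                                45, 9, 7,
                                                60, 12, 10,
                                                80, 16, 13,
                                                110, 22, 18),
                                              ncol = 3, byrow = TRUE),
                       dispersion = 8,
                       count_noise_sd = 0.1,
                       logistic_slopes = c(0.6, 0.3, 0.3),
                       hazard_slopes = c(-0.4, -0.2, -0.2),
                       baseline_rate = log(2) / 180,
                       censoring_rate = 0.2,
                       t0 = 183,
                       classes = c("SNV", "INS", "DEL"),
                       scale = 1,
                       seed = 0) {
  target_labels <- as.matrix(target_labels)
  feature_means <- as.matrix(feature_means)
  subgroup_sizes <- as.integer(round(subgroup_sizes * scale))
  stopifnot(all(subgroup_sizes >= 1),
            nrow(target_labels) == length(subgroup_sizes),
            ncol(target_labels) == 2,
            all(target_labels > 0 & target_labels < 1),
            nrow(feature_means) == length(subgroup_sizes),
            ncol(feature_means) == length(classes),
            length(logistic_slopes) == length(classes),
            length(hazard_slopes) == length(classes),
            dispersion > 0, baseline_rate > 0, t0 > 0,
            censoring_rate >= 0, censoring_rate < 1, count_noise_sd >= 0)
  colnames(target_labels) <- c("pR", "pT")
  colnames(feature_means) <- classes
  structure(list(subgroup_sizes = subgroup_sizes,
                 target_labels = target_labels,
                 feature_means = feature_means, dispersion = dispersion,
                 count_noise_sd = count_noise_sd,
                 logistic_slopes = logistic_slopes,
                 hazard_slopes = hazard_slopes,
                 baseline_rate = baseline_rate,
                 censoring_rate = censoring_rate, t0 = t0,
                 classes = classes, seed = seed),
            class = "sim_config")
}

#' The default cohort preset
#'
#' Shorthand for [sim_config()] with all defaults: 660 patients, five
#' subgroups of sizes 90/212/64/202/92, three burden dimensions, the
#' printed target label pairs, `t0 = 183` days and seed 0.
#'
#' @return a `"sim_config"`.
#' @export
default_config <- function() sim_config()

# calibrate an intercept a so that mean(f(a + lp)) == target; f monotone
.calibrate_intercept <- function(lp, target, f, subgroup,
                                 bounds = c(-40, 40)) {
  obj <- function(a) mean(f(a + lp)) - target
  lo <- obj(bounds[1]); hi <- obj(bounds[2])
  if (is.na(lo) || is.na(hi) || lo * hi > 0)
    stop("calibration infeasible for subgroup ", subgroup,
         ": target ", target, " unreachable within intercept bounds")
  stats::uniroot(obj, bounds, tol = 1e-12)$root
}

#' Simulate a labeled immunotherapy cohort
#'
#' Draws, per subgroup: burden feature vectors from negative-binomial counts
#' with subgroup-specific means (plus multiplicative lognormal measurement
#' noise); a binary response from a logistic model whose intercept is
#' calibrated so the subgroup mean latent response probability equals the
#' target `pR`; and progression-free-survival times from an
#' exponential-baseline proportional-hazards model whose intercept is
#' calibrated so the subgroup mean latent probability of surviving beyond
#' `t0` equals the target `pT`.  Independent exponential censoring is
#' applied at a rate calibrated to the configured censoring fraction.
#' Latent probabilities and true event times are retained in the
#' ground-truth table.  Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return list of class `"tmb_cohort"` with `features` (matrix, patients x
#'   d), `clinical` (data.frame: `patient_id`, `response`, `time_days`,
#'   `event`), `bags` (factor), `labels` (target label matrix, rownames =
#'   bag ids), `truth` (data.frame with latent probabilities and true
#'   times), and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  M <- length(config$subgroup_sizes)
  d <- length(config$classes)
  N <- sum(config$subgroup_sizes)
  bag_ids <- paste0("G", seq_len(M))
  bags <- factor(rep(bag_ids, config$subgroup_sizes), levels = bag_ids)
  # burden counts with measurement noise
  X <- matrix(0, N, d, dimnames = list(NULL, config$classes))
  for (m in seq_len(M)) {
    i <- which(bags == bag_ids[m])
    for (j in seq_len(d))
      X[i, j] <- stats::rnbinom(length(i), size = config$dispersion,
                                mu = config$feature_means[m, j])
  }
  if (config$count_noise_sd > 0)
    X <- round(X * matrix(exp(stats::rnorm(N * d, 0,
                                           config$count_noise_sd)), N, d))
  # standardized linear predictors (cohort-level standardization)
  Z <- scale(X)
  lp_resp <- drop(Z %*% config$logistic_slopes)
  lp_haz <- drop(Z %*% config$hazard_slopes)
  p_resp <- h <- numeric(N)
  for (m in seq_len(M)) {
    i <- which(bags == bag_ids[m])
    a <- .calibrate_intercept(lp_resp[i], config$target_labels[m, "pR"],
                              stats::plogis, bag_ids[m])
    p_resp[i] <- stats::plogis(a + lp_resp[i])
    # survival beyond t0 under exponential baseline: S(t0) = exp(-h * t0)
    b <- .calibrate_intercept(lp_haz[i], config$target_labels[m, "pT"],
                              function(v) exp(-config$baseline_rate *
                                                exp(v) * config$t0),
                              bag_ids[m])
    h[i] <- config$baseline_rate * exp(b + lp_haz[i])
  }
  response <- stats::rbinom(N, 1, p_resp)
  t_true <- stats::rexp(N, rate = h)
  if (config$censoring_rate > 0) {
    rc <- stats::uniroot(function(r) mean(r / (r + h)) -
                           config$censoring_rate,
                         c(1e-10, 100), tol = 1e-12)$root
    cens <- stats::rexp(N, rate = rc)
  } else cens <- rep(Inf, N)
  time <- pmin(t_true, cens)
  event <- as.integer(t_true <= cens)
  ids <- sprintf("P%04d", seq_len(N))
  rownames(X) <- ids
  structure(list(
    features = X,
    clinical = data.frame(patient_id = ids, response = response,
                          time_days = time, event = event,
                          stringsAsFactors = FALSE),
    bags = bags,
    labels = structure(config$target_labels,
                       dimnames = list(bag_ids, c("pR", "pT"))),
    truth = data.frame(patient_id = ids, subgroup = as.character(bags),
                       p_response = p_resp, p_survive_t0 = exp(-h * config$t0),
                       true_time = t_true, hazard = h,
                       stringsAsFactors = FALSE),
    config = config), class = "tmb_cohort")
}

#' Write a simulated cohort to plain-text files
#'
#' Emits `features.tsv` (`patient_id` + one column per burden class),
#' `clinical.tsv`, `bags.tsv`, `truth.tsv` and `config.json` into `dir`;
#' the files round-trip through [read_cohort()].
#'
#' @param cohort a `"tmb_cohort"` from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tmb_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  feat <- data.frame(patient_id = rownames(cohort$features),
                     cohort$features, check.names = FALSE,
                     stringsAsFactors = FALSE)
  wt(feat, "features.tsv")
  wt(cohort$clinical, "clinical.tsv")
  wt(data.frame(patient_id = rownames(cohort$features),
                bag_id = as.character(cohort$bags)), "bags.tsv")
  wt(cohort$truth, "truth.tsv")
  cfg <- unclass(cohort$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding the cohort files.
#' @return a `"tmb_cohort"`.
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f),
                                      stringsAsFactors = FALSE)
  feat <- rd("features.tsv")
  X <- as.matrix(feat[, -1, drop = FALSE])
  rownames(X) <- feat$patient_id
  bag_tab <- rd("bags.tsv")
  bags <- factor(bag_tab$bag_id, levels = unique(bag_tab$bag_id))
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  config <- sim_config(
    subgroup_sizes = cfg_raw$subgroup_sizes,
    target_labels = matrix(unlist(cfg_raw$target_labels), ncol = 2,
                           byrow = !is.matrix(cfg_raw$target_labels)),
    feature_means = matrix(unlist(cfg_raw$feature_means),
                           ncol = length(cfg_raw$classes),
                           byrow = !is.matrix(cfg_raw$feature_means)),
    dispersion = cfg_raw$dispersion,
    count_noise_sd = cfg_raw$count_noise_sd,
    logistic_slopes = cfg_raw$logistic_slopes,
    hazard_slopes = cfg_raw$hazard_slopes,
    baseline_rate = cfg_raw$baseline_rate,
    censoring_rate = cfg_raw$censoring_rate,
    t0 = cfg_raw$t0, classes = cfg_raw$classes, seed = cfg_raw$seed)
  labels <- config$target_labels
  dimnames(labels) <- list(levels(bags), c("pR", "pT"))
  structure(list(features = X, clinical = rd("clinical.tsv"), bags = bags,
                 labels = labels, truth = rd("truth.tsv"), config = config),
            class = "tmb_cohort")
}
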