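#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Sorts subjects by predicted probability, partitions them into `g`
#' near-equal-count groups (ties kept together, so degenerate predictions can
#' yield fewer groups), and computes
#' \deqn{\chi^2 = \sum_g \frac{(O_g - n_g\bar p_g)^2}{n_g\bar p_g}
#'   + \frac{((n_g-O_g) - n_g(1-\bar p_g))^2}{n_g(1-\bar p_g)},}
#' referred to a chi-square distribution with `g - 2` degrees of freedom
#' (upper tail).  The two conventional reporting regimes are `g = 10`
#' (df = 8) and `g = 20` (df = 18).
#'
#' @param y binary observed outcomes (0/1).
#' @param p predicted probabilities in `(0, 1)`.
#' @param g number of risk groups (default 10).
#' @param eps guard for degenerate groups with mean prediction 0 or 1.
#' @return an object of classes `"hl_test"` and `"htest"` with `statistic`,
#'   `parameter` (df), `p.value`, and the per-group `table` (`n`, `observed`,
#'   `expected`, `p_mean`).
#' @export
hosmer_lemeshow <- function(y, p, g = 10, eps = 1e-7) {
  stopifnot(length(y) == length(p), all(y %in% c(0, 1)))
  if (g < 3) stop("'g' must be at least 3")
  if (length(y) < g) stop("need at least g observations")
  qs <- unique(stats::quantile(p, probs = seq(0, 1, length.out = g + 1),
                               type = 2))
  if (length(qs) < 3) stop("predictions too degenerate to form risk groups")
  grp <- cut(p, breaks = qs, include.lowest = TRUE)
  tab <- do.call(rbind, lapply(levels(grp), function(lv) {
    i <- grp == lv
    data.frame(n = sum(i), observed = sum(y[i]),
               expected = sum(i) * mean(p[i]), p_mean = mean(p[i]))
  }))
  g_eff <- nrow(tab)
  pbar <- tab$p_mean
  if (any(pbar <= 0 | pbar >= 1)) {
    warning("degenerate risk group with mean prediction 0 or 1; eps-guarded")
    pbar <- pmin(pmax(pbar, eps), 1 - eps)
  }
  stat <- sum((tab$observed - tab$n * pbar)^2 / (tab$n * pbar) +
              ((tab$n - tab$observed) - tab$n * (1 - pbar))^2 /
                (tab$n * (1 - pbar)))
  df <- g_eff - 2
  if (df < 1) stop("fewer than 3 distinct risk groups")
  structure(list(statistic = c(`X-squared` = stat),
                 parameter = c(df = df),
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 method = "Hosmer-Lemeshow goodness-of-fit test",
                 data.name = deparse(substitute(p)),
                 table = tab, groups = g_eff),
            class = c("hl_test", "htest"))
}

#' Compare calibration-loss, MSE, CEL and SVM learners by goodness-of-fit
#'
#' Trains four learners predicting patient response probability on identical
#' splits and reports, for each, the Hosmer-Lemeshow statistic and p-value
#' of its per-patient predicted probabilities against the observed binary
#' responses, on the training set, the test set and the full cohort, at
#' `g = 10` and `g = 20` risk groups.
#'
#' Each loss is trained on the supervision its domain admits: the
#' calibration-loss and MSE multiple-instance learners on the bag response
#' proportions of the training split (mean aggregation, so the bag output
#' is the mean predicted response probability); the CEL multiple-instance
#' learner on binary category bag labels (cross-entropy requires labels in
#' `{0, 1}`); and the SVM instance-level on binary responses with Platt
#' probability outputs (bag structure unused).
#'
#' @param x raw feature matrix (patients x d).
#' @param bags factor of bag ids.
#' @param bag_labels binary bag labels in `{0, 1}` for the CEL learner
#'   (e.g. from [assign_category_label()]).
#' @param response per-patient binary outcome the calibration is judged
#'   against.
#' @param config a [train_config()].
#' @param hidden hidden widths for the MIL learners.
#' @param fraction training fraction of the split (default 0.7).
#' @param seed seed for the split and the learner initialisations.
#' @return data.frame with one row per learner x data slice x group setting
#'   (4 x 3 x 2 = 24 rows): `learner`, `slice`, `g`, `statistic`, `df`,
#'   `p_value`.
#' @export
compare_learners <- function(x, bags, bag_labels, response,
                             config = train_config(lr = 0.01,
                                                   max_epochs = 600),
                             hidden = 16, fraction = 0.7, seed = 1) {
  x <- as.matrix(x)
  bags <- as.factor(bags)
  stopifnot(all(bag_labels %in% c(0, 1)), all(response %in% c(0, 1)))
  sp <- split_train_test(bags, fraction, seed = seed)
  sc <- suppressWarnings(fit_scaler(x[sp$train, , drop = FALSE]))
  xs <- predict(sc, x)
  prop_lab <- vapply(levels(bags), function(m)
    mean(response[intersect(sp$train, which(bags == m))]), numeric(1))
  train_one <- function(mode, labels) {
    net <- init_network(ncol(x), hidden, 1, seed = seed)
    fit <- mil_train(net, xs[sp$train, , drop = FALSE], bags[sp$train],
                     labels, loss_spec(mode, metric = "mean"), config)
    drop(forward(fit$net, xs))
  }
  preds <- list(
    category_calibration = train_one("category_calibration", prop_lab),
    mse = train_one("mse", prop_lab),
    cel = train_one("cel", bag_labels))
  set.seed(seed)
  sv <- e1071::svm(xs[sp$train, , drop = FALSE],
                   factor(response[sp$train], levels = c(0, 1)),
                   probability = TRUE)
  pr <- attr(stats::predict(sv, xs, probability = TRUE), "probabilities")
  preds[["svm"]] <- pr[, "1"]
  learner_names <- c(category_calibration = "calibration", mse = "mse",
                     cel = "cel", svm = "svm")
  slices <- list(train = sp$train, test = sp$test,
                 all = seq_along(bags))
  out <- list()
  for (ln in names(preds)) for (sl in names(slices)) for (g in c(10, 20)) {
    i <- slices[[sl]]
    hl <- suppressWarnings(hosmer_lemeshow(response[i], preds[[ln]][i], g))
    out[[length(out) + 1L]] <- data.frame(
      learner = learner_names[[ln]], slice = sl, g = g,
      statistic = unname(hl$statistic), df = unname(hl$parameter),
      p_value = hl$p.value, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
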