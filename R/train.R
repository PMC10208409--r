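#' Training configuration for full-batch gradient descent
#'
#' @param lr learning rate (> 0, default 0.05).
#' @param max_epochs maximum number of full-batch epochs (default 5000).
#' @param tol stopping tolerance `delta`: descent stops once the global loss
#'   `E <= tol` (default `1e-3`).
#' @param momentum classical momentum coefficient in `[0, 1)` (default 0,
#'   plain gradient descent).
#' @param grad_clip componentwise bound on the bag-level loss gradient
#'   before backpropagation (default 10).  The calibration loss's
#'   denominators make its gradient grow like `1/o^2` when an aggregate
#'   nears 0 or 1; clipping keeps single descent steps bounded without
#'   altering the loss landscape away from the boundary.
#' @param seed seed used when (re)initialising the network inside
#'   higher-level drivers.
#' @return list of class `"train_config"`.
#' @export
train_config <- function(lr = 0.05, max_epochs = 5000, tol = 1e-3,
                         momentum = 0, grad_clip = 10, seed = 1) {
  stopifnot(lr > 0, max_epochs >= 1, tol >= 0, momentum >= 0, momentum < 1,
            grad_clip > 0)
  structure(list(lr = lr, max_epochs = max_epochs, tol = tol,
                 momentum = momentum, grad_clip = grad_clip, seed = seed),
            class = "train_config")
}

# labels as a bags x output_dim matrix with rownames = bag levels
.label_matrix <- function(labels, bag_levels) {
  y <- if (is.null(dim(labels))) matrix(labels, ncol = 1,
                                        dimnames = list(names(labels), NULL))
       else as.matrix(labels)
  if (nrow(y) != length(bag_levels))
    stop("need one label (row) per bag: got ", nrow(y), " for ",
         length(bag_levels), " bags")
  if (!is.null(rownames(y))) {
    if (!all(bag_levels %in% rownames(y)))
      stop("label rownames do not cover all bag ids")
    y <- y[bag_levels, , drop = FALSE]
  } else rownames(y) <- bag_levels
  y
}

#' Train a multiple-instance network by full-batch gradient descent
#'
#' Implements the descent loop of the decision framework: each epoch runs
#' the instance-level forward pass over the whole cohort, aggregates instance
#' outputs per bag under the configured metric, evaluates the selected loss
#' between aggregated outputs and bag labels, and backpropagates through the
#' aggregation (mean spreads the gradient over all members; median/extreme
#' metrics route it to the selecting member(s)).  Descent stops when
#' `E <= tol` or `max_epochs` is reached.  Deterministic for a fixed
#' initial network and data order.
#'
#' @param net a `"mil_network"` from [init_network()].
#' @param x scaled feature matrix (patients x d).
#' @param bags factor of bag ids, one per patient.
#' @param labels bag labels: numeric vector (scalar modes) or bags x 2
#'   matrix (vector mode); rows matched to bag levels by rowname when named.
#' @param spec a [loss_spec()].
#' @param config a [train_config()].
#' @return list with the trained `net`, the per-epoch loss `trace`, final
#'   `loss`, number of `epochs` run, and the final bag `o_hat`.
#' @export
mil_train <- function(net, x, bags, labels, spec = loss_spec(),
                      config = train_config()) {
  x <- as.matrix(x)
  bags <- as.factor(bags)
  stopifnot(nrow(x) == length(bags))
  y <- .label_matrix(labels, levels(bags))
  if (ncol(y) != net$dims[length(net$dims)])
    stop("label dimension ", ncol(y), " does not match network output ",
         net$dims[length(net$dims)])
  n_m <- as.numeric(table(bags))
  scalar_mode <- spec$mode != "vector_distance"
  vel <- list(W = lapply(net$W, function(w) w * 0),
              b = lapply(net$b, function(b) b * 0))
  trace <- numeric(0)
  agg <- NULL
  for (epoch in seq_len(config$max_epochs)) {
    A <- .forward_full(net, x)
    O <- A[[length(A)]]
    agg <- .aggregate_outputs(O, bags, spec$metric)
    vg <- loss_value_grad(if (scalar_mode) drop(y) else y,
                          if (scalar_mode) drop(agg$o_hat) else agg$o_hat,
                          spec, n_m)
    E <- vg$value
    if (!is.finite(E)) {
      per_bag <- rowSums(rbind(agg$o_hat))
      bad <- which(!is.finite(per_bag))[1]
      stop("non-finite loss at epoch ", epoch, " (bag ",
           levels(bags)[if (length(bad)) bad else 1], ")")
    }
    trace[epoch] <- E
    if (E <= config$tol) break
    G <- if (scalar_mode) matrix(vg$grad, ncol = 1)
         else rbind(vg$grad)               # bags x output_dim
    G <- pmin(pmax(G, -config$grad_clip), config$grad_clip)
    dO <- agg$Wagg * G[as.integer(bags), , drop = FALSE]
    gr <- .backward(net, A, dO)
    for (l in seq_along(net$W)) {
      vel$W[[l]] <- config$momentum * vel$W[[l]] - config$lr * gr$W[[l]]
      vel$b[[l]] <- config$momentum * vel$b[[l]] - config$lr * gr$b[[l]]
      net$W[[l]] <- net$W[[l]] + vel$W[[l]]
      net$b[[l]] <- net$b[[l]] + vel$b[[l]]
    }
  }
  list(net = net, trace = trace, loss = trace[length(trace)],
       epochs = length(trace), o_hat = agg$o_hat)
}

# evaluate the configured loss of a net on (x, bags, labels); 'labels' must
# be a rownamed bags x k matrix (see .label_matrix)
.eval_loss <- function(net, x, bags, labels, spec) {
  bags <- droplevels(as.factor(bags))
  y <- labels[levels(bags), , drop = FALSE]
  O <- forward(net, x)
  agg <- .aggregate_outputs(O, bags, spec$metric)
  n_m <- as.numeric(table(bags))
  scalar <- spec$mode != "vector_distance"
  loss_value_grad(if (scalar) drop(y) else y,
                  if (scalar) drop(agg$o_hat) else agg$o_hat,
                  spec, n_m)$value
}

#' Stratified train/test split
#'
#' Splits patients into two disjoint cohorts preserving each bag's
#' proportion (within rounding), under a seed.
#'
#' @param bags factor of bag ids, one per patient.
#' @param fraction fraction allocated to the first (training) side,
#'   strictly between 0 and 1 (default 0.7).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(bags, fraction = 0.7, seed = 1) {
  stopifnot(fraction > 0, fraction < 1)
  bags <- as.factor(bags)
  set.seed(seed)
  train <- integer(0)
  for (m in levels(bags)) {
    i <- which(bags == m)
    n_tr <- round(fraction * length(i))
    n_tr <- min(max(n_tr, 1L), length(i) - 1L)
    train <- c(train, sample(i, n_tr))
  }
  train <- sort(train)
  test <- setdiff(seq_along(bags), train)
  if (!length(train) || !length(test))
    stop("split fraction leaves one side empty")
  list(train = train, test = test)
}

# fold ids: shuffle within bags, then deal 1..k round-robin across the
# concatenated sequence, so every fold is populated (k = N gives
# leave-one-out) and bags spread evenly over folds.
.fold_ids <- function(bags, k, seed) {
  bags <- as.factor(bags)
  n <- length(bags)
  if (k < 2 || k > n) stop("'k' must be in [2, N]; lower k for this cohort")
  set.seed(seed)
  ord <- unlist(lapply(levels(bags), function(m) sample(which(bags == m))))
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(k), n)
  fold
}

#' k-fold cross-validation of the multiple-instance learner
#'
#' Folds are drawn *within* bags (each fold sees every bag with roughly
#' `1/k` of its members), because the bag labels are the supervision: with
#' only a handful of bags, splitting whole bags would leave folds without
#' usable labels.  The feature scaler is refit on each fold's training split
#' only.
#'
#' @param x raw feature matrix (patients x d).
#' @param bags factor of bag ids.
#' @param labels bag labels (vector or matrix, see [mil_train()]).
#' @param k number of folds (default 10).
#' @param spec a [loss_spec()].
#' @param config a [train_config()].
#' @param hidden hidden-layer widths for the fold networks.
#' @param seed seed controlling fold assignment and fold-network
#'   initialisation.
#' @return list with `fold_losses`, their `mean`, and the fold assignment.
#' @export
kfold_cv <- function(x, bags, labels, k = 10, spec = loss_spec(),
                     config = train_config(), hidden = 16, seed = 1) {
  x <- as.matrix(x)
  bags <- as.factor(bags)
  fold <- .fold_ids(bags, k, seed)
  labels <- .label_matrix(labels, levels(bags))
  out_dim <- ncol(labels)
  losses <- numeric(k)
  for (j in seq_len(k)) {
    tr <- fold != j; va <- fold == j
    sc <- suppressWarnings(fit_scaler(x[tr, , drop = FALSE]))
    net <- init_network(ncol(x), hidden, out_dim, seed = seed + j)
    fit <- mil_train(net, predict(sc, x[tr, , drop = FALSE]), bags[tr],
                     labels, spec, config)
    losses[j] <- .eval_loss(fit$net, predict(sc, x[va, , drop = FALSE]),
                            bags[va], labels, spec)
  }
  list(fold_losses = losses, mean = mean(losses), fold = fold)
}

#' Learning curve of the multiple-instance learner
#'
#' For each requested training-set size, subsamples the training cohort
#' (bag proportions preserved), trains, and records the training loss and
#' the loss on a held-out validation split, averaged over repeats.
#'
#' @param x raw feature matrix.
#' @param bags factor of bag ids.
#' @param labels bag labels.
#' @param sizes increasing vector of training-set sizes (patients).
#' @param spec a [loss_spec()].
#' @param config a [train_config()].
#' @param repeats number of repeated splits averaged (default 3).
#' @param val_fraction fraction held out for validation (default 0.3).
#' @param hidden hidden widths.
#' @param seed base seed; repeat `r` uses `seed + r`.
#' @return data.frame with columns `size`, `train_loss`, `val_loss`.
#' @export
learning_curve <- function(x, bags, labels, sizes, spec = loss_spec(),
                           config = train_config(), repeats = 3,
                           val_fraction = 0.3, hidden = 16, seed = 1) {
  x <- as.matrix(x)
  bags <- as.factor(bags)
  sizes <- sort(unique(as.integer(sizes)))
  labels <- .label_matrix(labels, levels(bags))
  out_dim <- ncol(labels)
  tr_loss <- va_loss <- matrix(NA_real_, length(sizes), repeats)
  for (r in seq_len(repeats)) {
    sp <- split_train_test(bags, 1 - val_fraction, seed = seed + r)
    pool <- sp$train
    if (max(sizes) > length(pool))
      stop("largest size ", max(sizes), " exceeds available training pool (",
           length(pool), ")")
    for (s in seq_along(sizes)) {
      set.seed(seed + 1000 * r + s)
      sub <- unlist(lapply(levels(bags), function(m) {
        i <- intersect(pool, which(bags == m))
        take <- max(1L, round(sizes[s] * length(i) / length(pool)))
        sample(i, min(take, length(i)))
      }))
      sc <- suppressWarnings(fit_scaler(x[sub, , drop = FALSE]))
      net <- init_network(ncol(x), hidden, out_dim, seed = seed + r)
      fit <- mil_train(net, predict(sc, x[sub, , drop = FALSE]), bags[sub],
                       labels, spec, config)
      tr_loss[s, r] <- .eval_loss(fit$net, predict(sc, x[sub, , drop = FALSE]),
                                  bags[sub], labels, spec)
      va_loss[s, r] <- .eval_loss(fit$net,
                                  predict(sc, x[sp$test, , drop = FALSE]),
                                  bags[sp$test], labels, spec)
    }
  }
  data.frame(size = sizes, train_loss = rowMeans(tr_loss),
             val_loss = rowMeans(va_loss))
}
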