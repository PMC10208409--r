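#' Initialise a multiple-instance regression network
#'
#' A small fully connected network with `d` input units, optional hidden
#' layers (tanh activation) and a logistic output layer squashing every
#' component into `(0, 1)`.  `output_dim = 1` serves category labels,
#' `output_dim = 2` the `[pR, pT]` probabilistic labels.  With
#' `hidden = integer(0)` the model degenerates to logistic regression.
#' Weights are drawn from a symmetric uniform distribution scaled by fan-in
#' and fan-out (Glorot-style) under the given seed, so identical seeds give
#' identical initial parameters.
#'
#' @param d input dimension (number of burden classes).
#' @param hidden integer vector of hidden-layer widths (default 16).
#' @param output_dim 1 or 2.
#' @param seed RNG seed for the draw (default 1).
#' @return an object of class `"mil_network"`.
#' @export
init_network <- function(d, hidden = 16, output_dim = 1, seed = 1) {
  stopifnot(d >= 1, output_dim %in% c(1, 2))
  hidden <- as.integer(hidden)
  if (any(hidden <= 0)) stop("hidden widths must be positive")
  dims <- c(d, hidden, output_dim)
  set.seed(seed)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    s <- sqrt(6 / (dims[l] + dims[l + 1L]))
    W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -s, s),
                     dims[l], dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  structure(list(dims = dims, W = W, b = b, seed = seed),
            class = "mil_network")
}

#' Number of trainable parameters
#' @param net a `"mil_network"`.
#' @return integer parameter count (weights plus biases).
#' @export
n_params <- function(net) {
  sum(vapply(net$W, length, integer(1))) +
    sum(vapply(net$b, length, integer(1)))
}

# forward pass keeping layer activations for backprop
.forward_full <- function(net, X) {
  X <- rbind(X)
  if (ncol(X) != net$dims[1]) stop("input dimension mismatch: expected ",
                                   net$dims[1], ", got ", ncol(X))
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) tanh(Z) else stats::plogis(Z)
  }
  A
}

#' Instance-level forward pass
#'
#' Evaluates the network on one or more feature vectors; outputs are
#' strictly inside `(0, 1)` per component.
#'
#' @param net a `"mil_network"`.
#' @param x a d-vector or an `n x d` matrix.
#' @return an `n x output_dim` matrix of outputs.
#' @export
forward <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  A <- .forward_full(net, x)
  A[[length(A)]]
}

# Aggregation weights: for a vector v, the weight each instance contributes
# to the aggregate (weights sum to 1).  Subgradient conventions: mean spreads
# uniformly; max/min select the extreme (ties averaged); the even-count
# median splits 0.5/0.5 between the central pair (ties within each half
# averaged).
.agg_weights <- function(v, metric) {
  n <- length(v)
  if (metric == "mean") return(rep(1 / n, n))
  w <- numeric(n)
  if (metric %in% c("max", "min")) {
    sel <- if (metric == "max") which(v == max(v)) else which(v == min(v))
    w[sel] <- 1 / length(sel)
    return(w)
  }
  ord <- order(v)
  if (n %% 2L == 1L) {
    mid <- v[ord[(n + 1L) %/% 2L]]
    sel <- which(v == mid)
    w[sel] <- 1 / length(sel)
  } else {
    lo <- v[ord[n %/% 2L]]
    hi <- v[ord[n %/% 2L + 1L]]
    if (lo == hi) {
      sel <- which(v == lo)
      w[sel] <- 1 / length(sel)
    } else {
      sl <- which(v == lo); sh <- which(v == hi)
      w[sl] <- 0.5 / length(sl)
      w[sh] <- 0.5 / length(sh)
    }
  }
  w
}

# bag aggregates and the instance weight matrix used for backprop
.aggregate_outputs <- function(O, bags, metric) {
  bags <- as.factor(bags)
  M <- nlevels(bags)
  k <- ncol(O)
  o_hat <- matrix(NA_real_, M, k, dimnames = list(levels(bags), colnames(O)))
  Wagg <- matrix(0, nrow(O), k)
  for (m in seq_len(M)) {
    i <- which(bags == levels(bags)[m])
    for (j in seq_len(k)) {
      w <- .agg_weights(O[i, j], metric)
      Wagg[i, j] <- w
      o_hat[m, j] <- sum(w * O[i, j])
    }
  }
  list(o_hat = o_hat, Wagg = Wagg)
}

#' Bag-level prediction
#'
#' Runs the instance-level forward pass over a bag's members and aggregates
#' the outputs with the chosen subgroup metric.
#'
#' @param net a `"mil_network"`.
#' @param x feature matrix of the bag members (`n_m x d`), `n_m >= 1`.
#' @param metric aggregation metric.
#' @return list with `instance_outputs` (`n_m x output_dim`), `aggregated`
#'   (length-`output_dim` vector) and `metric`.
#' @export
predict_bag <- function(net, x, metric = c("median", "max", "min", "mean")) {
  metric <- match.arg(metric)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(x) == 0) stop("empty bag")
  O <- forward(net, x)
  list(instance_outputs = O,
       aggregated = aggregate_metric(O, metric),
       metric = metric)
}

# backprop: dO is n x output_dim gradient of the loss wrt instance outputs
.backward <- function(net, A, dO) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  Out <- A[[L + 1L]]
  delta <- dO * Out * (1 - Out)           # through the logistic output
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * (1 - A[[l]]^2)  # through tanh
    }
  }
  list(W = gW, b = gb)
}
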