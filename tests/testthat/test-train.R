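test_that("gradient descent reduces the loss on separable data", {
  tc <- tiny_cohort()
  net <- init_network(3, 8, 2, seed = 1)
  spec <- loss_spec("vector_distance", metric = "mean")
  fit <- mil_train(net, scale(tc$x), tc$bags, tc$labels_vec, spec,
                   train_config(lr = 0.1, max_epochs = 800, tol = 0))
  expect_lt(fit$loss, fit$trace[1])
  expect_lt(fit$loss, 0.05)
})

test_that("zero-ish learning rate leaves weights unchanged", {
  tc <- tiny_cohort()
  net <- init_network(3, 8, 2, seed = 1)
  fit <- mil_train(net, scale(tc$x), tc$bags, tc$labels_vec,
                   loss_spec("vector_distance", metric = "mean"),
                   train_config(lr = 1e-300, max_epochs = 5, tol = 0))
  expect_equal(fit$net$W, net$W)
  expect_equal(fit$net$b, net$b)
})

test_that("duplicating every bag doubles the loss and gradient", {
  tc <- tiny_cohort()
  xs <- scale(tc$x)
  spec <- loss_spec("vector_distance", metric = "mean")
  net <- init_network(3, 8, 2, seed = 2)
  x2 <- rbind(xs, xs)
  bags2 <- factor(c(as.character(tc$bags), paste0(tc$bags, "2")),
                  levels = c("lo", "hi", "lo2", "hi2"))
  labels2 <- rbind(tc$labels_vec,
                   `rownames<-`(tc$labels_vec, c("lo2", "hi2")))
  f1 <- mil_train(net, xs, tc$bags, tc$labels_vec, spec,
                  train_config(lr = 0.05, max_epochs = 40, tol = 0))
  f2 <- mil_train(net, x2, bags2, labels2, spec,
                  train_config(lr = 0.025, max_epochs = 40, tol = 0))
  # halving the learning rate on the duplicated cohort retraces the same
  # trajectory, with every loss doubled (gradient proportionality)
  expect_equal(f2$trace, 2 * f1$trace, tolerance = 1e-10)
  expect_equal(f2$net$W, f1$net$W, tolerance = 1e-8)
})

test_that("training aborts with a diagnostic on non-finite loss", {
  tc <- tiny_cohort()
  net <- init_network(3, 8, 2, seed = 1)
  net$W[[1]][1] <- Inf
  expect_error(
    mil_train(net, scale(tc$x), tc$bags, tc$labels_vec,
              loss_spec("vector_distance", metric = "mean"),
              train_config(max_epochs = 3)),
    "non-finite")
})

test_that("training never increases its own loss at small learning rate", {
  co <- small_sim(seed = 5)
  fit <- tmbserval(co$features, co$bags, co$labels, metric = "mean",
                   lr = 1e-3, max_epochs = 300, tol = 0, seed = 3)
  expect_lte(fit$trace[length(fit$trace)], fit$trace[1])
  cat_lab <- assign_category_label(co$bags, co$clinical$response,
                                   co$clinical$time_days)
  fitc <- tmbserval(co$features, co$bags, cat_lab, metric = "mean",
                    lr = 1e-3, max_epochs = 300, tol = 0, seed = 3)
  expect_lte(fitc$trace[length(fitc$trace)], fitc$trace[1])
})

test_that("train/test splits are disjoint, exhaustive and bag-balanced", {
  co <- simulate_cohort(sim_config(seed = 1))
  sp <- split_train_test(co$bags, fraction = 0.5, seed = 2)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(co$bags))
  expect_equal(length(sp$train), 330, tolerance = 3)
  for (m in levels(co$bags)) {
    n_m <- sum(co$bags == m)
    n_tr <- sum(co$bags[sp$train] == m)
    expect_lte(abs(n_tr - 0.5 * n_m), 1)
  }
  expect_error(split_train_test(co$bags, 0), "fraction")
})

test_that("fold assignment partitions the cohort and is seed-stable", {
  bags <- factor(rep(c("a", "b", "c"), each = 4))
  f1 <- TMBserval:::.fold_ids(bags, 12, seed = 3)
  expect_equal(sort(unique(f1)), 1:12)           # k = N gives leave-one-out
  expect_equal(as.integer(table(f1)), rep(1L, 12))
  f2 <- TMBserval:::.fold_ids(bags, 4, seed = 9)
  expect_equal(TMBserval:::.fold_ids(bags, 4, seed = 9), f2)
  expect_equal(sum(table(f2)), 12)
  expect_error(TMBserval:::.fold_ids(bags, 13, seed = 1), "lower k")
})

test_that("k-fold cross-validation returns one loss per fold", {
  co <- small_sim(seed = 6)
  cv <- kfold_cv(co$features, co$bags, co$labels, k = 4,
                 loss_spec("vector_distance", metric = "mean"),
                 train_config(lr = 0.05, max_epochs = 150), seed = 4)
  expect_length(cv$fold_losses, 4)
  expect_true(all(is.finite(cv$fold_losses)))
  expect_equal(cv$mean, mean(cv$fold_losses))
  cv2 <- kfold_cv(co$features, co$bags, co$labels, k = 4,
                  loss_spec("vector_distance", metric = "mean"),
                  train_config(lr = 0.05, max_epochs = 150), seed = 4)
  expect_equal(cv$fold_losses, cv2$fold_losses)   # seed-reproducible
})

test_that("learning_curve covers the requested sizes and matches a plain
           run at full size", {
  co <- small_sim(seed = 7)
  spec <- loss_spec("vector_distance", metric = "mean")
  cfg <- train_config(lr = 0.05, max_epochs = 150)
  lc <- learning_curve(co$features, co$bags, co$labels, sizes = c(30, 80),
                       spec, cfg, repeats = 1, seed = 2)
  expect_equal(lc$size, c(30, 80))
  expect_true(all(is.finite(lc$train_loss)) && all(is.finite(lc$val_loss)))
  expect_error(
    learning_curve(co$features, co$bags, co$labels, sizes = 5000,
                   spec, cfg, repeats = 1, seed = 2),
    "exceeds")
})
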