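# Loss, optimiser, training loop, metrics and LOSO integrity.

test_that("composite loss reduces to cross-entropy and adds the penalty", {
  logits <- matrix(0, 4, 3)
  labels <- c(0L, 1L, 2L, 0L)
  expect_equal(composite_loss(logits, labels, list(), 0), log(3),
               tolerance = 1e-12)
  # alpha = 1 everywhere: penalty exactly zero
  expect_equal(composite_loss(logits, labels, list(a = rep(1, 4)), 5),
               log(3), tolerance = 1e-12)
  # one indicator with alpha = (0.5, 1.5), lambda = 0.1: penalty 0.025
  l2 <- composite_loss(matrix(0, 2, 3), c(0L, 1L), list(a = c(0.5, 1.5)),
                       0.1)
  expect_equal(l2 - log(3), 0.025, tolerance = 1e-12)
  expect_error(composite_loss(matrix(0, 0, 3), integer(0), list(), 0),
               "empty")
})

test_that("lambda = 0 equals plain mean cross-entropy on random logits", {
  set.seed(31)
  for (i in 1:20) {
    logits <- matrix(rnorm(15), 5, 3)
    labels <- sample(0:2, 5, replace = TRUE)
    p <- exp(logits) / rowSums(exp(logits))
    ce <- -mean(log(p[cbind(1:5, labels + 1)]))
    expect_equal(composite_loss(logits, labels,
                                list(a = rnorm(5)), 0), ce,
                 tolerance = 1e-12)
  }
})

test_that("RMSprop follows its recurrence and optimises a quadratic", {
  # zero gradient: parameters unchanged, accumulator decayed
  st <- list(w = 0.4)
  up <- rmsprop_step(list(w = 2), list(w = 0), st, eta = 0.1)
  expect_equal(up$params$w, 2)
  expect_equal(up$state$w, 0.36)
  # one step on f(w) = w^2 from w = 1 moves toward 0
  up2 <- rmsprop_step(list(w = 1), list(w = 2), list(), eta = 0.05)
  expect_lt(up2$params$w, 1)
  # 200 steps on a 2-d convex quadratic reach loss < 1e-3, and the whole
  # trajectory matches the stated recurrence written as a plain loop
  params <- list(w = c(1, -2))
  state <- list()
  w_oracle <- c(1, -2); v_oracle <- c(0, 0)
  for (i in 1:200) {
    g <- 0.4 * params$w                    # f(w) = 0.2 (w1^2 + w2^2)
    up <- rmsprop_step(params, list(w = g), state, eta = 0.05)
    params <- up$params; state <- up$state
    g2 <- 0.4 * w_oracle
    v_oracle <- 0.9 * v_oracle + 0.1 * g2^2
    w_oracle <- w_oracle - 0.05 * g2 / (sqrt(v_oracle) + 1e-8)
  }
  expect_equal(params$w, w_oracle, tolerance = 1e-12)
  expect_lt(0.2 * sum(params$w^2), 1e-3)
})

test_that("backpropagation matches central finite differences", {
  fs <- random_feature_set(xi = 6, seed = 44, labels = c(0L, 1L, 2L, 0L, 1L, 2L))
  m <- calibrate_norms(init_model(model_config(contrib_hidden = 6,
                                               affect_hidden = 6,
                                               analyser_hidden = 4, seed = 3),
                                  fs$manifest), list(fs))
  tr <- forward_subject(m, fs)
  bw <- affectsig:::backward_subject(m, tr, fs$labels, lambda = 0.05)
  p0 <- flatten_params(m)
  lossf <- function(params) {
    t2 <- forward_subject(affectsig:::set_params(m, params), fs)
    composite_loss(t2$logits, fs$labels,
                   lapply(t2$per, function(p) p$contrib$alpha), 0.05)
  }
  set.seed(9)
  for (nm in names(p0)) {
    i <- sample(length(p0[[nm]]), 1)
    h <- 1e-5
    pp <- p0; pp[[nm]][i] <- pp[[nm]][i] + h
    pm <- p0; pm[[nm]][i] <- pm[[nm]][i] - h
    fd <- (lossf(pp) - lossf(pm)) / (2 * h)
    expect_lt(abs(bw$grads[[nm]][i] - fd), 1e-7 + 1e-4 * abs(fd))
  }
})

test_that("a training epoch visits each subject once and learns", {
  set.seed(77)
  # separable synthetic features: one EDA column encodes the label
  mk <- function(seed) {
    fs <- random_feature_set(xi = 12, seed = seed,
                             labels = rep(0:2, each = 4))
    fs$B$EDA[, 1] <- fs$labels * 2 + rnorm(12, 0, 0.1)
    fs$PF[, colnames(fs$B$EDA)[1]] <- fs$B$EDA[, 1]
    fs
  }
  feats <- lapply(1:2, mk)
  m <- calibrate_norms(init_model(model_config(contrib_hidden = 10,
                                               affect_hidden = 10,
                                               analyser_hidden = 8, seed = 1),
                                  feats[[1]]$manifest), feats)
  tc <- train_config(lambda = 0, lr = 0.01, seed = 5)
  p_before <- flatten_params(m)
  losses <- numeric(50)
  st <- list()
  for (ep in 1:50) {
    te <- train_epoch(m, feats, tc, st, lr = 0.01, epoch_seed = ep)
    m <- te$model; st <- te$state; losses[ep] <- te$loss
  }
  expect_false(identical(p_before, flatten_params(m)))
  expect_lt(losses[50], 0.5 * losses[1])
  # the epoch order is a permutation of the subjects
  ord <- affectsig:::with_local_seed(3L, sample(seq_along(feats)))
  expect_setequal(ord, seq_along(feats))
})

test_that("fit honours the learning-rate schedule and patience settings", {
  feats <- lapply(1:2, function(s)
    random_feature_set(xi = 9, seed = s, labels = rep(0:2, each = 3)))
  tc <- train_config(max_epochs = 8, patience = 0, val_fraction = 0,
                     lr_step = 3, seed = 2)
  fit <- affect_fit(feats, model_config(contrib_hidden = 4, affect_hidden = 4,
                                        analyser_hidden = 4, seed = 1), tc)
  expect_identical(nrow(fit$history), 8L)   # patience 0 disables early stop
  expect_equal(fit$history$lr, 1e-4 * 0.5^((0:7) %/% 3))
  expect_true(all(diff(fit$history$lr) <= 0))
  expect_error(affect_fit(feats[1], model_config(), tc), "2 subjects")
})

test_that("metrics match a hand evaluation of the formulas", {
  y_true <- c(0L, 0L, 1L, 1L, 2L, 2L)
  y_pred <- c(0L, 1L, 1L, 1L, 2L, 0L)
  m <- compute_metrics(y_true, y_pred)
  expect_equal(m$acc, 4 / 6, tolerance = 1e-12)
  expect_equal(unname(m$f1_per_class), c(0.5, 0.8, 2 / 3), tolerance = 1e-12)
  expect_equal(m$f1_macro, mean(c(0.5, 0.8, 2 / 3)), tolerance = 1e-12)
  expect_equal(m$mse, 5 / 6, tolerance = 1e-12)
  expect_identical(sum(m$confusion), 6L)

  perfect <- compute_metrics(0:2, 0:2)
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$f1_macro, 1)
  expect_equal(perfect$mse, 0)

  skew <- compute_metrics(rep(0:2, each = 2), rep(0L, 6))
  expect_equal(unname(skew$f1_per_class[2:3]), c(0, 0))
})

test_that("confusion rows sum to the per-class truth counts", {
  set.seed(55)
  for (i in 1:25) {
    yt <- sample(0:2, 30, replace = TRUE)
    yp <- sample(0:2, 30, replace = TRUE)
    cm <- confusion_matrix(yt, yp)
    expect_identical(unname(rowSums(cm)),
                     vapply(0:2, function(c) sum(yt == c), numeric(1)))
    expect_equal(compute_metrics(yt, yp)$acc, sum(diag(cm)) / 30)
  }
})

test_that("LOSO holds the test subject out of training and validation", {
  feats <- lapply(1:3, function(s)
    random_feature_set(xi = 9, seed = s, labels = rep(0:2, each = 3)))
  mc <- model_config(contrib_hidden = 4, affect_hidden = 4,
                     analyser_hidden = 4, seed = 1)
  tc <- train_config(max_epochs = 3, patience = 0, val_fraction = 0, seed = 9)
  cv <- loso_cv(feats, mc, tc)
  expect_identical(cv$n_folds, 3L)
  for (i in seq_along(cv$folds)) {
    f <- cv$folds[[i]]
    expect_false(f$test_subject %in% f$train_subjects)
    expect_identical(sort(c(f$test_subject, f$train_subjects)),
                     sort(vapply(feats, `[[`, "", "subject_id")))
  }
  expect_error(loso_cv(feats[1], mc, tc), "2 subjects")
  # reproducibility: the whole run is a deterministic function of the seed
  cv2 <- loso_cv(feats, mc, tc)
  expect_identical(cv$pooled$confusion, cv2$pooled$confusion)
})
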