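# Training: composite loss, exact backpropagation through the whole
# architecture (including the causal embedding), RMSprop, sequential
# per-subject epochs, early stopping with a StepLR schedule, and
# leave-one-subject-out cross-validation.

#' Composite training loss
#'
#' Mean cross-entropy over windows plus `lambda` times the mean over
#' indicators of the mean over windows of `(alpha - 1)^2` — the contribution
#' regulariser that keeps window contributions near 1.
#'
#' @param logits windows x 3 matrix.
#' @param labels integer vector in {0,1,2}.
#' @param alphas list (one per indicator) of per-window contribution vectors.
#' @param lambda regularisation coefficient.
#' @return scalar loss.
#' @export
composite_loss <- function(logits, labels, alphas, lambda = 0) {
  if (!length(labels)) stop_data("composite_loss: empty window set")
  ce <- mean(cross_entropy_rows(logits, labels))
  pen <- if (lambda > 0 && length(alphas))
    lambda * mean(vapply(alphas, function(a) mean((a - 1)^2), numeric(1)))
  else 0
  ce + pen
}

# Per-row cross-entropy, numerically stable.
cross_entropy_rows <- function(logits, labels) {
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  lse - logits[cbind(seq_along(labels), labels + 1L)]
}

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

revcumsum_rows <- function(M) {
  n <- nrow(M)
  res <- apply(M[n:1, , drop = FALSE], 2, cumsum)
  if (is.null(dim(res))) res <- matrix(res, nrow = 1)
  res[n:1, , drop = FALSE]
}

# ---- parameter flattening ----------------------------------------------------

flatten_params <- function(model) {
  out <- list()
  for (ind in model$indicators) {
    cn <- model$contrib[[ind]]
    out[[paste0("contrib.", ind, ".W1")]] <- cn$W1
    out[[paste0("contrib.", ind, ".b1")]] <- cn$b1
    out[[paste0("contrib.", ind, ".w2")]] <- cn$w2
    out[[paste0("contrib.", ind, ".b2")]] <- cn$b2
    ly <- model$affect[[ind]]$layers
    for (l in seq_along(ly)) {
      out[[paste0("affect.", ind, ".W", l)]] <- ly[[l]]$W
      out[[paste0("affect.", ind, ".b", l)]] <- ly[[l]]$b
    }
  }
  out[["analyser.G1"]] <- model$analyser$G1
  out[["analyser.c1"]] <- model$analyser$c1
  out[["analyser.G2"]] <- model$analyser$G2
  out[["analyser.c2"]] <- model$analyser$c2
  out[["baseline.u"]] <- model$u
  out
}

set_params <- function(model, params) {
  for (ind in model$indicators) {
    model$contrib[[ind]]$W1 <- params[[paste0("contrib.", ind, ".W1")]]
    model$contrib[[ind]]$b1 <- params[[paste0("contrib.", ind, ".b1")]]
    model$contrib[[ind]]$w2 <- params[[paste0("contrib.", ind, ".w2")]]
    model$contrib[[ind]]$b2 <- params[[paste0("contrib.", ind, ".b2")]]
    for (l in seq_along(model$affect[[ind]]$layers)) {
      model$affect[[ind]]$layers[[l]]$W <-
        params[[paste0("affect.", ind, ".W", l)]]
      model$affect[[ind]]$layers[[l]]$b <-
        params[[paste0("affect.", ind, ".b", l)]]
    }
  }
  model$analyser$G1 <- params[["analyser.G1"]]
  model$analyser$c1 <- params[["analyser.c1"]]
  model$analyser$G2 <- params[["analyser.G2"]]
  model$analyser$c2 <- params[["analyser.c2"]]
  model$u <- params[["baseline.u"]]
  model
}

# ---- backpropagation ---------------------------------------------------------

# Exact gradients of the composite loss for one subject. `mask` selects the
# windows whose cross-entropy terms enter the loss (validation windows are
# excluded during training); the alpha penalty runs over all windows.
backward_subject <- function(model, trace, labels, mask = NULL,
                             lambda = 0) {
  xi <- nrow(trace$logits)
  if (is.null(mask)) mask <- rep(TRUE, xi)
  nm <- sum(mask)
  if (nm == 0) stop_data("no training windows in mask")
  probs <- softmax_rows(trace$logits)
  onehot <- matrix(0, xi, ncol(trace$logits))
  onehot[cbind(seq_len(xi), labels + 1L)] <- 1
  dlogits <- (probs - onehot) / nm
  dlogits[!mask, ] <- 0

  g <- list()
  an <- model$analyser
  g[["analyser.G2"]] <- t(dlogits) %*% trace$Hmid
  g[["analyser.c2"]] <- colSums(dlogits)
  dH <- dlogits %*% an$G2
  g[["analyser.G1"]] <- t(dH) %*% trace$Phi
  g[["analyser.c1"]] <- colSums(dH)
  dPhi <- dH %*% an$G1
  g[["baseline.u"]] <- colSums(dPhi)

  M <- length(model$indicators)
  for (j in seq_along(model$indicators)) {
    ind <- model$indicators[j]
    p <- trace$per[[ind]]
    dtheta <- dPhi[, j]
    aff <- model$affect[[ind]]
    L <- length(aff$layers)
    delta <- matrix(dtheta, ncol = 1)
    dgamman <- NULL
    for (l in L:1) {
      g[[paste0("affect.", ind, ".W", l)]] <- t(delta) %*% p$affect$acts[[l]]
      g[[paste0("affect.", ind, ".b", l)]] <- colSums(delta)
      back <- delta %*% aff$layers[[l]]$W
      if (l > 1) delta <- back * (p$affect$acts[[l]] > 0)
      else dgamman <- back
    }
    dgamma <- sweep(dgamman, 2, p$affect$sd, "/")
    k <- model$k
    mj <- ncol(p$beta)
    dbeta <- dgamma[, k + seq_len(mj), drop = FALSE]
    Rv <- revcumsum_rows(dbeta)
    B <- trace$per[[ind]]$PF_j[, k + seq_len(mj), drop = FALSE]
    dalpha <- rowSums(Rv * B)
    if (lambda > 0)
      dalpha <- dalpha + lambda * 2 * (p$contrib$alpha - 1) / (M * xi)
    cn <- model$contrib[[ind]]
    H1 <- p$contrib$h1
    g[[paste0("contrib.", ind, ".w2")]] <- as.numeric(t(H1) %*% dalpha)
    g[[paste0("contrib.", ind, ".b2")]] <- sum(dalpha)
    dH1 <- (dalpha %o% cn$w2) * (H1 > 0)
    g[[paste0("contrib.", ind, ".W1")]] <- t(dH1) %*% p$contrib$Pn
    g[[paste0("contrib.", ind, ".b1")]] <- colSums(dH1)
  }
  loss <- composite_loss(trace$logits[mask, , drop = FALSE], labels[mask],
                         lapply(trace$per, function(p) p$contrib$alpha),
                         lambda)
  list(grads = g, loss = loss)
}

#' One RMSprop update
#'
#' Per-parameter accumulator `v <- 0.9 v + 0.1 g^2`, update
#' `phi <- phi - eta * g / (sqrt(v) + 1e-8)`.
#'
#' @param params named list of parameter arrays.
#' @param grads matching named list of gradients.
#' @param state accumulator list (empty list for the first call).
#' @param eta learning rate.
#' @param decay accumulator decay (0.9).
#' @param eps stabiliser (1e-8).
#' @return list `params`, `state`.
#' @export
rmsprop_step <- function(params, grads, state, eta, decay = 0.9,
                         eps = 1e-8) {
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    v <- state[[nm]]
    if (is.null(v)) v <- gr * 0
    v <- decay * v + (1 - decay) * gr^2
    state[[nm]] <- v
    params[[nm]] <- params[[nm]] - eta * gr / (sqrt(v) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' @param lambda contribution-regularisation coefficient.
#' @param lr initial learning rate.
#' @param max_epochs maximum number of epochs.
#' @param patience early-stopping patience on validation loss (0 disables
#'   early stopping).
#' @param lr_step,lr_gamma StepLR schedule: lr = lr0 * gamma^floor(t/step)
#'   with t the 0-based epoch index.
#' @param rmsprop_decay,rmsprop_eps RMSprop accumulator parameters.
#' @param val_fraction fraction of training windows held out (per subject)
#'   for validation.
#' @param seed integer seed for subject shuffling and the validation split.
#' @return object of class `train_config`.
#' @export
train_config <- function(lambda = 0.01, lr = 1e-4, max_epochs = 150,
                         patience = 15, lr_step = 30, lr_gamma = 0.5,
                         rmsprop_decay = 0.9, rmsprop_eps = 1e-8,
                         val_fraction = 0.1, seed = 1L) {
  if (lambda < 0) stop_config("lambda must be >= 0")
  if (lr <= 0) stop_config("lr must be positive")
  if (patience >= max_epochs) stop_config("patience must be < max_epochs")
  structure(list(lambda = lambda, lr = lr, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr_step = as.integer(lr_step),
                 lr_gamma = lr_gamma, rmsprop_decay = rmsprop_decay,
                 rmsprop_eps = rmsprop_eps, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' One training epoch
#'
#' Visits the subjects in a seeded shuffled order and performs one RMSprop
#' step per subject on that subject's full window set.
#'
#' @param model an `affect_model`.
#' @param features_list list of `feature_set`s (the training subjects).
#' @param config a [train_config()].
#' @param state RMSprop accumulator state.
#' @param lr learning rate for this epoch.
#' @param masks optional list of logical training masks per subject.
#' @param epoch_seed seed for the subject shuffle.
#' @return list `model`, `state`, `loss` (mean per-subject loss).
#' @export
train_epoch <- function(model, features_list, config, state = list(),
                        lr = config$lr, masks = NULL, epoch_seed = 0L) {
  ord <- with_local_seed(epoch_seed, sample(seq_along(features_list)))
  losses <- numeric(0)
  for (i in ord) {
    fs <- features_list[[i]]
    trace <- forward_subject(model, fs)
    bw <- backward_subject(model, trace, fs$labels,
                           mask = if (is.null(masks)) NULL else masks[[i]],
                           lambda = config$lambda)
    params <- flatten_params(model)
    up <- rmsprop_step(params, bw$grads, state, lr,
                       config$rmsprop_decay, config$rmsprop_eps)
    model <- set_params(model, up$params)
    state <- up$state
    losses <- c(losses, bw$loss)
  }
  list(model = model, state = state, loss = mean(losses))
}

validation_loss <- function(model, features_list, masks, lambda) {
  tot <- 0; n <- 0
  for (i in seq_along(features_list)) {
    vm <- !masks[[i]]
    if (!any(vm)) next
    fs <- features_list[[i]]
    trace <- forward_subject(model, fs)
    ce <- cross_entropy_rows(trace$logits, fs$labels)
    tot <- tot + sum(ce[vm]); n <- n + sum(vm)
  }
  if (n == 0) NA_real_ else tot / n
}

#' Fit the affect classifier
#'
#' Trains the full architecture on a list of featurized subjects with
#' sequential per-subject RMSprop updates, a StepLR schedule, and early
#' stopping on a held-in validation split (a seeded 10% of training windows
#' per subject; never test data). Returns the best-validation checkpoint.
#'
#' @param features_list list of `feature_set`s (>= 2 subjects).
#' @param mconfig a [model_config()].
#' @param tconfig a [train_config()].
#' @param verbose print one line per epoch.
#' @return object of class `affect_fit` with the trained model, the fit
#'   history (per-epoch training loss, validation loss, learning rate), the
#'   stopping epoch, and the configurations.
#' @export
affect_fit <- function(features_list, mconfig = model_config(),
                       tconfig = train_config(), verbose = FALSE) {
  if (length(features_list) < 2)
    stop_data("affect_fit needs at least 2 subjects")
  manifest <- features_list[[1]]$manifest
  model <- init_model(mconfig, manifest)
  model <- calibrate_norms(model, features_list)
  seeds <- derive_seeds(tconfig$seed, 2L + tconfig$max_epochs)
  use_val <- tconfig$patience > 0 && tconfig$val_fraction > 0
  masks <- with_local_seed(seeds[1], lapply(features_list, function(fs) {
    xi <- length(fs$labels)
    m <- rep(TRUE, xi)
    if (use_val) {
      nv <- floor(tconfig$val_fraction * xi)
      if (nv > 0 && nv < xi) m[sample(xi, nv)] <- FALSE
    }
    m
  }))
  state <- list()
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))
  best_val <- Inf; best_params <- flatten_params(model)
  best_model <- model; best_epoch <- 0L; wait <- 0L
  stopped <- tconfig$max_epochs
  for (epoch in seq_len(tconfig$max_epochs)) {
    lr <- tconfig$lr * tconfig$lr_gamma^((epoch - 1) %/% tconfig$lr_step)
    te <- train_epoch(model, features_list, tconfig, state, lr,
                      masks = masks, epoch_seed = seeds[2 + epoch])
    model <- te$model; state <- te$state
    vl <- if (use_val)
      validation_loss(model, features_list, masks, tconfig$lambda)
    else NA_real_
    history <- rbind(history, data.frame(epoch = epoch, train_loss = te$loss,
                                         val_loss = vl, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %s  lr %.2e", epoch,
                      te$loss, ifelse(is.na(vl), "NA", sprintf("%.4f", vl)),
                      lr))
    if (use_val) {
      if (vl < best_val - 1e-12) {
        best_val <- vl; best_model <- model; best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tconfig$patience) { stopped <- epoch; break }
      }
    } else {
      best_model <- model; best_epoch <- epoch
    }
  }
  structure(list(model = best_model, history = history,
                 stopped_epoch = stopped, best_epoch = best_epoch,
                 mconfig = mconfig, tconfig = tconfig,
                 n_subjects = length(features_list)),
            class = "affect_fit")
}

# ---- metrics -----------------------------------------------------------------

#' 3x3 confusion matrix
#'
#' @param y_true,y_pred integer vectors in {0,1,2}.
#' @return 3x3 integer matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  cm <- matrix(0L, 3, 3, dimnames = list(true = 0:2, pred = 0:2))
  for (i in seq_along(y_true))
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  cm
}

#' Classification metrics
#'
#' Accuracy, per-class F1 (with 0/0 defined as 0), macro F1 (unweighted
#' mean), and mean squared error on the integer class codes.
#'
#' @inheritParams confusion_matrix
#' @return object of class `affect_metrics`: `confusion`, `acc`,
#'   `f1_per_class`, `f1_macro`, `mse`, `n`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  cm <- confusion_matrix(y_true, y_pred)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  f1 <- vapply(1:3, function(c) {
    tp <- cm[c, c]; fp <- sum(cm[-c, c]); fn <- sum(cm[c, -c])
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  structure(list(confusion = cm, acc = acc, f1_per_class = f1,
                 f1_macro = mean(f1),
                 mse = mean((as.numeric(y_true) - as.numeric(y_pred))^2),
                 n = n),
            class = "affect_metrics")
}

#' Leave-one-subject-out cross-validation
#'
#' N folds for N subjects: fold i trains on all subjects except subject i
#' (validation split drawn only from training subjects) and tests on
#' subject i. Per-fold seeds derive deterministically from the master seed.
#'
#' @param features_list list of `feature_set`s (>= 2).
#' @param mconfig a [model_config()].
#' @param tconfig a [train_config()]; its seed is the master seed.
#' @param verbose print per-fold progress.
#' @return object of class `affect_loso`: `folds` (per-fold metrics,
#'   test subject, train subject ids), `pooled` metrics over the
#'   concatenated predictions, and `per_fold_acc`.
#' @export
loso_cv <- function(features_list, mconfig = model_config(),
                    tconfig = train_config(), verbose = FALSE) {
  N <- length(features_list)
  if (N < 2) stop_data("LOSO needs at least 2 subjects")
  fold_seeds <- derive_seeds(tconfig$seed, N)
  all_true <- integer(0); all_pred <- integer(0)
  folds <- vector("list", N)
  for (i in seq_len(N)) {
    train_fs <- features_list[-i]
    test_fs <- features_list[[i]]
    tc <- tconfig; tc$seed <- fold_seeds[i]
    mc <- mconfig; mc$seed <- fold_seeds[i]
    fit <- affect_fit(train_fs, mc, tc)
    trace <- forward_subject(fit$model, test_fs)
    m <- compute_metrics(test_fs$labels, trace$pred)
    folds[[i]] <- list(test_subject = test_fs$subject_id,
                       train_subjects = vapply(train_fs, `[[`, "",
                                               "subject_id"),
                       metrics = m, fit_epochs = fit$stopped_epoch)
    all_true <- c(all_true, test_fs$labels)
    all_pred <- c(all_pred, trace$pred)
    if (verbose)
      message(sprintf("fold %d/%d (%s): acc %.3f", i, N,
                      test_fs$subject_id, m$acc))
  }
  structure(list(folds = folds, pooled = compute_metrics(all_true, all_pred),
                 per_fold_acc = vapply(folds, function(f) f$metrics$acc,
                                       numeric(1)),
                 n_folds = N, seed = tconfig$seed),
            class = "affect_loso")
}
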