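# S3 methods for the fitted-model objects.

#' @export
print.affect_model <- function(x, ...) {
  cat("Affective-state classifier\n")
  cat("  indicators:", paste(x$indicators, collapse = ", "), "\n")
  cat("  attributes:", x$k, " encoded columns\n")
  cat(sprintf("  contribution nets: %d hidden; affect nets: %d hidden x %d layers\n",
              x$config$contrib_hidden, x$config$affect_hidden,
              x$config$affect_depth))
  np <- sum(vapply(flatten_params(x), length, numeric(1)))
  cat("  parameters:", np, "\n")
  invisible(x)
}

#' @export
print.affect_fit <- function(x, ...) {
  print(x$model)
  h <- x$history
  cat(sprintf("Trained on %d subjects; stopped at epoch %d (best epoch %d)\n",
              x$n_subjects, x$stopped_epoch, x$best_epoch))
  cat(sprintf("  final train loss %.4f", tail(h$train_loss, 1)))
  if (!all(is.na(h$val_loss)))
    cat(sprintf(", best val loss %.4f", min(h$val_loss, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @export
summary.affect_fit <- function(object, ...) {
  print(object)
  cat("\nFit history (last 5 epochs):\n")
  print(tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' Predict affective state for new subjects
#'
#' @param object an `affect_fit`.
#' @param newdata a `feature_set` or list of them.
#' @param type `"class"` (integer codes), `"prob"` (softmax matrix) or
#'   `"trace"` (full forward traces).
#' @param ... unused.
#' @return depends on `type`; for a list input, results are concatenated
#'   (`"trace"` returns one trace per subject).
#' @export
predict.affect_fit <- function(object, newdata,
                               type = c("class", "prob", "trace"), ...) {
  type <- match.arg(type)
  data <- as_feature_list(newdata)
  traces <- lapply(data, function(fs)
    forward_subject(object$model, fs))
  switch(type,
         class = unlist(lapply(traces, `[[`, "pred")),
         prob = do.call(rbind, lapply(traces, function(t)
           softmax_rows(t$logits))),
         trace = if (inherits(newdata, "feature_set")) traces[[1]] else traces)
}

#' @export
coef.affect_fit <- function(object, ...) flatten_params(object$model)

#' @export
plot.affect_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", ...)
  if (!all(is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   bty = "n")
  invisible(x)
}

#' @export
print.affect_metrics <- function(x, ...) {
  cat(sprintf("acc %.4f  macro-F1 %.4f  MSE %.4f  (n = %d)\n",
              x$acc, x$f1_macro, x$mse, x$n))
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
print.affect_loso <- function(x, ...) {
  cat(sprintf("Leave-one-subject-out over %d folds (seed %d)\n",
              x$n_folds, x$seed))
  cat("per-fold accuracy:",
      paste(sprintf("%.3f", x$per_fold_acc), collapse = " "), "\n")
  cat("pooled: ")
  print(x$pooled)
  invisible(x)
}

#' @export
summary.affect_loso <- function(object, ...) {
  print(object)
  cat(sprintf("\nmean fold accuracy %.4f (sd %.4f)\n",
              mean(object$per_fold_acc), stats::sd(object$per_fold_acc)))
  invisible(object)
}

#' @export
print.pareto_front <- function(x, ...) {
  cat("Complexity-loss front:\n")
  for (l in x)
    cat(sprintf("  %2d  %.6g  %s\n", l$complexity, l$fit_loss, l$expression))
  invisible(x)
}

#' @export
plot.pareto_front <- function(x, ...) {
  cx <- vapply(x, `[[`, numeric(1), "complexity")
  ls <- vapply(x, `[[`, numeric(1), "fit_loss")
  graphics::plot(cx, ls, type = "b", xlab = "complexity",
                 ylab = "loss (MAE)", ...)
  invisible(x)
}

#' @export
print.distillation <- function(x, ...) {
  cat(sprintf("Symbolic law for %s (n = %d windows)\n", x$indicator,
              x$n_samples))
  cat("  ", x$law$expression, "\n")
  cat(sprintf("  complexity %d, fit loss %.5g, R^2 %.4f\n",
              x$law$complexity, x$law$fit_loss, x$r2))
  cat("  variables:", paste(x$law$variables_used, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.distillation <- function(x, ...) {
  graphics::plot(x$complexity_loss$complexity, x$complexity_loss$loss,
                 type = "b", xlab = "complexity", ylab = "loss (MAE)",
                 main = x$indicator, ...)
  invisible(x)
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Feature importance for", x$indicator, "\n")
  s <- sort(x$scores, decreasing = TRUE)
  print(round(head(s, 10), 4))
  invisible(x)
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("Subject %s: %d channels, %.0f s\n", x$subject_id,
              length(x$channels),
              length(x$labels$codes) / x$labels$sampling_rate))
  invisible(x)
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("Feature set %s: %d windows x %d columns (%d indicators)\n",
              x$subject_id, nrow(x$PF), ncol(x$PF), length(x$B)))
  invisible(x)
}
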