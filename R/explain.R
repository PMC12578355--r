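# Symbolic distillation: gradient-magnitude feature importance over an
# indicator's raw inputs, top-k feature selection, and per-indicator law
# extraction by symbolic regression against the affect-network output.

# Exact gradient of S = sum_q theta_q with respect to the indicator's raw
# input matrix X = [A | B_j], through both paths: the affect network (gamma's
# attribute columns and, via the causal embedding, B and alpha) and the
# contribution network (alpha's dependence on the full input).
input_gradient <- function(model, trace, indicator) {
  p <- trace$per[[indicator]]
  aff <- model$affect[[indicator]]
  xi <- length(p$contrib$alpha)
  L <- length(aff$layers)
  delta <- matrix(1, xi, 1)
  for (l in L:1) {
    back <- delta %*% aff$layers[[l]]$W
    if (l > 1) delta <- back * (p$affect$acts[[l]] > 0)
    else dgamman <- back
  }
  dgamma <- sweep(dgamman, 2, p$affect$sd, "/")
  k <- model$k
  mj <- ncol(p$beta)
  dbeta <- dgamma[, k + seq_len(mj), drop = FALSE]
  Rv <- revcumsum_rows(dbeta)
  B <- p$PF_j[, k + seq_len(mj), drop = FALSE]
  dalpha <- rowSums(Rv * B)
  dB <- Rv * p$contrib$alpha
  cn <- model$contrib[[indicator]]
  dH1 <- (dalpha %o% cn$w2) * (p$contrib$h1 > 0)
  dP <- sweep(dH1 %*% cn$W1, 2, p$contrib$sd, "/")
  dX <- dP
  dX[, seq_len(k)] <- dX[, seq_len(k)] + dgamma[, seq_len(k), drop = FALSE]
  dX[, k + seq_len(mj)] <- dX[, k + seq_len(mj)] + dB
  colnames(dX) <- colnames(p$PF_j)
  dX
}

as_feature_list <- function(data) {
  if (inherits(data, "feature_set")) list(data) else data
}

model_of <- function(object) {
  if (inherits(object, "affect_fit")) object$model else object
}

#' Gradient-based feature importance for one indicator
#'
#' Sums the indicator's affect-network output over all windows
#' (`S = sum_q theta_q`), takes the absolute gradient of S with respect to
#' the indicator's raw inputs (attributes plus its own features), and
#' normalises the per-feature gradient mass to relative importance scores
#' that sum to 1.
#'
#' @param object an `affect_fit` or `affect_model`.
#' @param indicator indicator name.
#' @param data a `feature_set` or list of them.
#' @param top_k how many features to preselect.
#' @return object of class `importance_report`: `indicator`, `scores`
#'   (named, sums to 1), `G` (stacked absolute gradient matrix), `selected`
#'   (top-k feature names).
#' @export
indicator_importance <- function(object, indicator, data, top_k = 10) {
  model <- model_of(object)
  data <- as_feature_list(data)
  G <- do.call(rbind, lapply(data, function(fs) {
    trace <- forward_subject(model, fs)
    abs(input_gradient(model, trace, indicator))
  }))
  tot <- sum(G)
  if (tot <= 0) {
    warning("all-zero gradients for ", indicator, "; uniform importance")
    scores <- rep(1 / ncol(G), ncol(G))
    names(scores) <- colnames(G)
  } else {
    scores <- colSums(G) / tot
  }
  rep <- structure(list(indicator = indicator, scores = scores, G = G),
                   class = "importance_report")
  rep$selected <- select_top_features(rep, top_k)
  rep
}

#' Select the top-k features from an importance report
#'
#' Highest importance scores win; ties break by manifest (column) order.
#'
#' @param report an `importance_report`.
#' @param top_k number of features (default 10).
#' @return character vector of feature names.
#' @export
select_top_features <- function(report, top_k = 10) {
  s <- report$scores
  ord <- order(-s, seq_along(s))
  names(s)[ord[seq_len(min(top_k, length(s)))]]
}

#' Distill one indicator into a symbolic law
#'
#' Chains gradient importance, top-k feature selection, symbolic regression
#' with the indicator's affect-network output (theta) as target, law
#' selection on the complexity-loss front, and R-squared evaluation. Inputs
#' are standardised (z-score) before the search; the transform is recorded
#' with the law so it can be applied to new data.
#'
#' @param object an `affect_fit` or `affect_model`.
#' @param indicator indicator name.
#' @param data a `feature_set` or list of them.
#' @param params [sr_params()].
#' @param top_k number of candidate features for the search.
#' @return object of class `distillation`: `importance`, `front`, `law`,
#'   `r2`, `complexity_loss` (data.frame), `standardization`, `target`.
#' @export
distill_indicator <- function(object, indicator, data,
                              params = sr_params(), top_k = 10) {
  model <- model_of(object)
  data <- as_feature_list(data)
  imp <- indicator_importance(object, indicator, data, top_k = top_k)
  X <- do.call(rbind, lapply(data, function(fs)
    indicator_input(fs, indicator)))
  theta <- unlist(lapply(data, function(fs)
    forward_subject(model, fs)$Theta[, indicator]))
  Xs <- as.data.frame(X[, imp$selected, drop = FALSE])
  mu <- vapply(Xs, mean, numeric(1))
  sdv <- vapply(Xs, stats::sd, numeric(1))
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  Xstd <- as.data.frame(mapply(function(col, m, s) (col - m) / s,
                               Xs, mu, sdv, SIMPLIFY = FALSE))
  front <- symbolic_regress(theta, Xstd, params)
  law <- select_law(front)
  r2 <- law_r2(law, Xstd, theta)
  cl <- data.frame(
    complexity = vapply(front, `[[`, numeric(1), "complexity"),
    loss = vapply(front, `[[`, numeric(1), "fit_loss"))
  structure(list(indicator = indicator, importance = imp, front = front,
                 law = law, r2 = r2, complexity_loss = cl,
                 standardization = list(mean = mu, sd = sdv),
                 n_samples = length(theta)),
            class = "distillation")
}

#' Distill every indicator of a fitted model
#'
#' @inheritParams distill_indicator
#' @return named list of `distillation` objects, one per indicator.
#' @export
distill_all <- function(object, data, params = sr_params(), top_k = 10) {
  model <- model_of(object)
  out <- lapply(model$indicators, function(ind)
    distill_indicator(object, ind, data, params, top_k))
  names(out) <- model$indicators
  out
}
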