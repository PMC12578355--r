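# The classifier architecture. Per indicator b_j:
#   contribution network:  alpha_q = w2 . ReLU(W1 norm(PF_j[q,]) + b1) + b2
#   causal embedding:      beta[q, f] = sum_{t <= q} alpha_t * B_j[t, f]
#   affect network:        theta_q = MLP_l(norm([A, beta[q,]]))  (scalar)
# Fusion: Theta = [theta_1 ... theta_M], Phi = Theta + u (learnable baseline),
# logits = G2 (G1 Phi[q,] + c1) + c2 (no nonlinearity in the analyser).
#
# "Normalization" is feature-wise standardisation whose statistics are
# calibrated once from the pooled training windows (see calibrate_norms) and
# frozen thereafter; gradients treat the statistics as constants. Globally
# constant columns get unit scale so they pass through centred.

#' Model configuration
#'
#' @param contrib_hidden hidden width of each contribution network
#'   (default 100, the setting that performed best in sensitivity runs).
#' @param affect_hidden hidden width of each affect network (default 100).
#' @param affect_depth number of weight layers in the affect network
#'   (>= 2, default 3).
#' @param analyser_hidden hidden width of the fusion analyser.
#' @param n_classes number of affective states (3).
#' @param seed integer seed for weight initialisation.
#' @return object of class `model_config`.
#' @export
model_config <- function(contrib_hidden = 100, affect_hidden = 100,
                         affect_depth = 3, analyser_hidden = 32,
                         n_classes = 3, seed = 1L) {
  if (contrib_hidden < 1 || affect_hidden < 1)
    stop_config("hidden widths must be >= 1")
  if (affect_depth < 2) stop_config("affect_depth must be >= 2")
  structure(list(contrib_hidden = as.integer(contrib_hidden),
                 affect_hidden = as.integer(affect_hidden),
                 affect_depth = as.integer(affect_depth),
                 analyser_hidden = as.integer(analyser_hidden),
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = "model_config")
}

# Scaled-uniform initialisation: U(-s, s) with s = sqrt(6 / (fan_in+fan_out)).
init_mat <- function(nrow, ncol) {
  s <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -s, s), nrow, ncol)
}

new_norm <- function(p) list(mean = rep(0, p), var = rep(1, p),
                             initialized = FALSE)

norm_stats <- function(X) {
  v <- apply(X, 2, function(c) mean((c - mean(c))^2))
  v[v < 1e-12] <- 1   # constant columns: centre only
  list(mean = colMeans(X), var = v, initialized = TRUE)
}

norm_apply <- function(norm, X) {
  sdv <- sqrt(norm$var)
  Xn <- sweep(sweep(X, 2, norm$mean, "-"), 2, sdv, "/")
  list(X = Xn, sd = sdv)
}

#' Initialise the model parameters
#'
#' Builds one contribution network and one affect network per indicator in
#' the manifest, the fusion analyser, and the zero-initialised baseline
#' vector u. Deterministic given `config$seed`.
#'
#' @param config a [model_config()].
#' @param manifest feature manifest: `list(attributes=, indicators=)` as
#'   produced by [assemble_feature_tensors()].
#' @return object of class `affect_model`.
#' @export
init_model <- function(config, manifest) {
  k <- length(manifest$attributes)
  inds <- names(manifest$indicators)
  M <- length(inds)
  with_local_seed(config$seed, {
    contrib <- list(); affect <- list()
    for (ind in inds) {
      mj <- length(manifest$indicators[[ind]])
      p <- k + mj
      H <- config$contrib_hidden
      # b2 starts at 1: the embedding begins as a plain cumulative sum
      # (alpha = 1), the state the regulariser pulls toward.
      contrib[[ind]] <- list(
        W1 = init_mat(H, p), b1 = rep(0, H),
        w2 = as.numeric(init_mat(1, H)), b2 = 1,
        norm = new_norm(p))
      Ha <- config$affect_hidden
      dims <- c(p, rep(Ha, config$affect_depth - 1), 1)
      layers <- lapply(seq_len(config$affect_depth), function(l)
        list(W = init_mat(dims[l + 1], dims[l]), b = rep(0, dims[l + 1])))
      affect[[ind]] <- list(layers = layers, norm = new_norm(p))
    }
    h <- config$analyser_hidden
    analyser <- list(G1 = init_mat(h, M), c1 = rep(0, h),
                     G2 = init_mat(config$n_classes, h),
                     c2 = rep(0, config$n_classes))
    structure(list(config = config, manifest = manifest,
                   indicators = inds, k = k,
                   contrib = contrib, affect = affect,
                   analyser = analyser, u = rep(0, M)),
              class = "affect_model")
  })
}

# Indicator input matrix: [A columns | that indicator's feature columns].
indicator_input <- function(features, ind) {
  cbind(features$PF[, features$manifest$attributes, drop = FALSE],
        features$B[[ind]])
}

#' Contribution-network forward pass
#'
#' @param model an `affect_model`.
#' @param indicator indicator name.
#' @param PF_j windows x (k + m_j) input matrix (attributes | own features).
#' @return list `alpha` (one scalar per window), `h1` (hidden activations),
#'   `Pn` (normalised input), `sd` (normalisation scale).
#' @export
contrib_forward <- function(model, indicator, PF_j) {
  cn <- model$contrib[[indicator]]
  if (ncol(PF_j) != ncol(cn$W1))
    stop_data("contribution network input width mismatch for ", indicator)
  na <- norm_apply(cn$norm, PF_j)
  Z1 <- na$X %*% t(cn$W1)
  Z1 <- sweep(Z1, 2, cn$b1, "+")
  H1 <- pmax(Z1, 0)
  alpha <- as.numeric(H1 %*% cn$w2) + cn$b2
  list(alpha = alpha, h1 = H1, Pn = na$X, sd = na$sd)
}

#' Causal upper-triangular temporal embedding
#'
#' `beta[q, f] = sum_{t <= q} alpha_t * B[t, f]`: each window's embedded
#' features are a contribution-weighted cumulative sum of the past, so row q
#' never depends on rows after q.
#'
#' @param B_j windows x m_j feature matrix.
#' @param alpha contribution scalar per window.
#' @return embedded matrix of the same shape.
#' @export
temporal_embed <- function(B_j, alpha) {
  if (nrow(B_j) != length(alpha)) stop_data("alpha length != window count")
  res <- apply(B_j * alpha, 2, cumsum)
  if (is.null(dim(res)))
    res <- matrix(res, nrow = 1, dimnames = list(NULL, colnames(B_j)))
  res
}

#' Affect-network forward pass
#'
#' @param model an `affect_model`.
#' @param indicator indicator name.
#' @param gamma_j windows x (k + m_j) matrix `[A | beta]`.
#' @return list `theta` (scalar per window), layer activations.
#' @export
affect_forward <- function(model, indicator, gamma_j) {
  an <- model$affect[[indicator]]
  na <- norm_apply(an$norm, gamma_j)
  acts <- list(na$X)
  L <- length(an$layers)
  H <- na$X
  for (l in seq_len(L)) {
    Z <- sweep(H %*% t(an$layers[[l]]$W), 2, an$layers[[l]]$b, "+")
    H <- if (l < L) pmax(Z, 0) else Z
    acts[[l + 1]] <- H
  }
  list(theta = as.numeric(H), acts = acts, sd = na$sd)
}

#' Fusion analyser forward pass
#'
#' Adds the learnable baseline u to the stacked affect levels and applies
#' the two linear layers. Predicted class is the argmax with ties broken
#' toward the lowest class index.
#'
#' @param model an `affect_model`.
#' @param Theta windows x M matrix of per-indicator affect levels.
#' @return list `logits` (windows x n_classes), `Phi`, `Hmid`.
#' @export
analyser_forward <- function(model, Theta) {
  Phi <- sweep(Theta, 2, model$u, "+")
  an <- model$analyser
  Hmid <- sweep(Phi %*% t(an$G1), 2, an$c1, "+")
  logits <- sweep(Hmid %*% t(an$G2), 2, an$c2, "+")
  list(logits = logits, Phi = Phi, Hmid = Hmid)
}

#' Full forward pass for one subject
#'
#' Runs the whole architecture and retains all intermediates (the forward
#' trace) for loss, backpropagation and explanation.
#'
#' @param model an `affect_model`.
#' @param features a `feature_set`.
#' @return object of class `forward_trace`: per-indicator `alpha`, `beta`,
#'   `gamma`, `theta` and activations, plus `Theta`, `Phi`, `logits` and
#'   `pred`.
#' @export
forward_subject <- function(model, features) {
  if (!identical(names(features$manifest$indicators), model$indicators))
    stop_data("feature manifest does not match the model's indicator set")
  xi <- nrow(features$PF)
  per <- list()
  Theta <- matrix(0, xi, length(model$indicators),
                  dimnames = list(NULL, model$indicators))
  for (ind in model$indicators) {
    PF_j <- indicator_input(features, ind)
    cf <- contrib_forward(model, ind, PF_j)
    beta <- temporal_embed(features$B[[ind]], cf$alpha)
    gamma <- cbind(PF_j[, seq_len(model$k), drop = FALSE], beta)
    af <- affect_forward(model, ind, gamma)
    Theta[, ind] <- af$theta
    per[[ind]] <- list(PF_j = PF_j, contrib = cf, beta = beta,
                       gamma = gamma, affect = af)
  }
  anf <- analyser_forward(model, Theta)
  pred <- max.col(anf$logits, ties.method = "first") - 1L
  structure(list(per = per, Theta = Theta, Phi = anf$Phi,
                 Hmid = anf$Hmid, logits = anf$logits, pred = pred),
            class = "forward_trace")
}

#' Calibrate normalisation statistics from training data
#'
#' Sets each network's standardisation statistics from the pooled windows of
#' the given subjects: the contribution networks from the raw indicator
#' inputs, the affect networks from the embedded inputs computed with the
#' freshly calibrated contribution networks. Statistics are frozen
#' afterwards; globally constant columns get unit scale.
#'
#' @param model an `affect_model`.
#' @param features_list list of `feature_set`s.
#' @return the calibrated model.
#' @export
calibrate_norms <- function(model, features_list) {
  features_list <- as_feature_list(features_list)
  for (ind in model$indicators) {
    PF_all <- do.call(rbind, lapply(features_list, indicator_input, ind))
    model$contrib[[ind]]$norm <- norm_stats(PF_all)
    gam_all <- do.call(rbind, lapply(features_list, function(fs) {
      PF_j <- indicator_input(fs, ind)
      cf <- contrib_forward(model, ind, PF_j)
      beta <- temporal_embed(fs$B[[ind]], cf$alpha)
      cbind(PF_j[, seq_len(model$k), drop = FALSE], beta)
    }))
    model$affect[[ind]]$norm <- norm_stats(gam_all)
  }
  model
}
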