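# Shared fixtures, all generated in code and memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# Small wrist-style cohort: 2 subjects, 3 x 120 s blocks.
small_cohort <- function() memo("small_cohort", function() {
  generate_cohort(cohort_config(
    n_subjects = 2,
    state_schedule = data.frame(state = 0:2, duration_s = c(120, 120, 120)),
    seed = 301))
})

small_feats <- function() memo("small_feats", function() {
  featurize_cohort(small_cohort(), window_s = 30)
})

# A tiny random feature set (not from signals) for model-level tests.
random_feature_set <- function(xi = 6, mj = c(ACC = 3, EDA = 2), k = 2,
                               seed = 1, labels = NULL) {
  set.seed(seed)
  A <- stats::setNames(round(runif(k, 1, 10), 2), paste0("a", seq_len(k)))
  B <- lapply(names(mj), function(ind)
    matrix(rnorm(xi * mj[[ind]]), xi, mj[[ind]],
           dimnames = list(NULL, paste0(ind, "_f", seq_len(mj[[ind]])))))
  names(B) <- names(mj)
  PF <- cbind(matrix(A, xi, k, byrow = TRUE, dimnames = list(NULL, names(A))),
              do.call(cbind, B))
  structure(list(subject_id = paste0("R", seed), B = B, A = A, PF = PF,
                 labels = labels %||% sample(0:2, xi, replace = TRUE),
                 manifest = list(attributes = names(A),
                                 indicators = lapply(B, colnames))),
            class = "feature_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split each subject's feature set into single-window sequences (so the
# causal embedding is the identity).
split_windows <- function(features_list) {
  unlist(lapply(features_list, function(fs) {
    lapply(seq_along(fs$labels), function(q) {
      structure(list(subject_id = paste0(fs$subject_id, "_", q),
                     B = lapply(fs$B, function(m) m[q, , drop = FALSE]),
                     A = fs$A, PF = fs$PF[q, , drop = FALSE],
                     labels = fs$labels[q], manifest = fs$manifest),
                class = "feature_set")
    })
  }), recursive = FALSE)
}

# Model whose affect network for `indicator` passes through exactly one
# feature column (a +/-ReLU identity pair) and whose contribution networks
# output alpha = 1 everywhere. On single-window sequences theta equals the
# standardised planted feature exactly.
planted_model <- function(manifest, indicator, feature, data) {
  k <- length(manifest$attributes)
  col <- k + which(manifest$indicators[[indicator]] == feature)
  stopifnot(length(col) == 1)
  m <- init_model(model_config(contrib_hidden = 4, affect_hidden = 4,
                               analyser_hidden = 4, seed = 1), manifest)
  for (j in m$indicators) {
    m$contrib[[j]]$W1[] <- 0; m$contrib[[j]]$b1[] <- 0
    m$contrib[[j]]$w2[] <- 0; m$contrib[[j]]$b2 <- 1
  }
  m$affect[[indicator]]$layers[[1]]$W[] <- 0
  m$affect[[indicator]]$layers[[1]]$W[1, col] <- 1
  m$affect[[indicator]]$layers[[1]]$W[2, col] <- -1
  m$affect[[indicator]]$layers[[1]]$b[] <- 0
  m$affect[[indicator]]$layers[[2]]$W[] <- 0
  m$affect[[indicator]]$layers[[2]]$W[1, 1] <- 1
  m$affect[[indicator]]$layers[[2]]$W[2, 2] <- 1
  m$affect[[indicator]]$layers[[2]]$b[] <- 0
  m$affect[[indicator]]$layers[[3]]$W[] <- 0
  m$affect[[indicator]]$layers[[3]]$W[1, 1] <- 1
  m$affect[[indicator]]$layers[[3]]$W[1, 2] <- -1
  m$affect[[indicator]]$layers[[3]]$b[] <- 0
  calibrate_norms(m, data)
}

# Finite-difference gradient of a scalar function of one feature-set entry.
# The step scales with the feature's spread so features of very different
# magnitudes (e.g. temperature slopes ~1e-4) stay in the locally linear
# regime of the ReLU network.
fd_input_grad <- function(model, fs, indicator, q, feature, h = NULL) {
  h <- h %||% (1e-4 * max(stats::sd(fs$B[[indicator]][, feature]), 1e-3))
  bump <- function(s) {
    f2 <- fs
    if (feature %in% colnames(f2$B[[indicator]])) {
      f2$B[[indicator]][q, feature] <- f2$B[[indicator]][q, feature] + s * h
    } else {
      stop("attribute perturbation not supported here")
    }
    sum(forward_subject(model, f2)$Theta[, indicator])
  }
  (bump(1) - bump(-1)) / (2 * h)
}
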