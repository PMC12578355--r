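# Architecture: initialisation, forward contracts, the causal embedding,
# and checkpoint round trips.

test_that("initialisation is deterministic and sized by the manifest", {
  fs <- random_feature_set()
  mc <- model_config(contrib_hidden = 7, affect_hidden = 5, seed = 10)
  m1 <- init_model(mc, fs$manifest)
  m2 <- init_model(mc, fs$manifest)
  expect_identical(flatten_params(m1), flatten_params(m2))
  mc2 <- mc; mc2$seed <- 11L
  expect_false(identical(flatten_params(m1),
                         flatten_params(init_model(mc2, fs$manifest))))
  # contribution-net parameter count: H*(k+mj) + H + H + 1
  k <- length(fs$manifest$attributes)
  mj <- length(fs$manifest$indicators$ACC)
  cn <- m1$contrib$ACC
  expect_identical(length(cn$W1) + length(cn$b1) + length(cn$w2) + 1L,
                   7L * (k + mj) + 7L + 7L + 1L)
})

test_that("contribution network forward matches an explicit loop", {
  fs <- random_feature_set(xi = 5, seed = 2)
  m <- init_model(model_config(contrib_hidden = 6, seed = 3), fs$manifest)
  m <- calibrate_norms(m, list(fs))
  PF_j <- cbind(fs$PF[, fs$manifest$attributes, drop = FALSE], fs$B$ACC)
  out <- contrib_forward(m, "ACC", PF_j)
  expect_length(out$alpha, 5)
  cn <- m$contrib$ACC
  for (q in 1:5) {
    xn <- (PF_j[q, ] - cn$norm$mean) / sqrt(cn$norm$var)
    a_hand <- sum(cn$w2 * pmax(cn$W1 %*% xn + cn$b1, 0)) + cn$b2
    expect_equal(out$alpha[q], a_hand, tolerance = 1e-6)
  }
  # w2 = 0 collapses alpha to the output bias
  m0 <- m; m0$contrib$ACC$w2[] <- 0
  expect_equal(contrib_forward(m0, "ACC", PF_j)$alpha,
               rep(m0$contrib$ACC$b2, 5))
  expect_error(contrib_forward(m, "ACC", PF_j[, 1:3]), "width mismatch")
})

test_that("temporal embedding is the alpha-weighted cumulative sum", {
  B <- matrix(c(1, 2, 3), ncol = 1)
  expect_equal(temporal_embed(B, c(1, 1, 1)), matrix(c(1, 3, 6), ncol = 1))
  expect_equal(temporal_embed(B, c(2, 0, 1)), matrix(c(2, 2, 5), ncol = 1))
  # perturbing the last row leaves earlier rows bit-identical
  set.seed(4)
  B2 <- matrix(rnorm(12), 4, 3)
  a <- rnorm(4)
  b1 <- temporal_embed(B2, a)
  B3 <- B2; B3[4, ] <- B3[4, ] + 100
  b2 <- temporal_embed(B3, a)
  expect_identical(b1[1:3, ], b2[1:3, ])
})

test_that("affect network forward matches an explicit layer loop", {
  fs <- random_feature_set(xi = 4, seed = 6)
  m <- init_model(model_config(affect_hidden = 5, affect_depth = 3, seed = 8),
                  fs$manifest)
  m <- calibrate_norms(m, list(fs))
  tr <- forward_subject(m, fs)
  gam <- tr$per$EDA$gamma
  an <- m$affect$EDA
  for (q in 1:4) {
    h <- (gam[q, ] - an$norm$mean) / sqrt(an$norm$var)
    for (l in seq_along(an$layers)) {
      z <- an$layers[[l]]$W %*% h + an$layers[[l]]$b
      h <- if (l < length(an$layers)) pmax(z, 0) else z
    }
    expect_equal(tr$per$EDA$affect$theta[q], as.numeric(h), tolerance = 1e-6)
  }
  # all-zero weights collapse theta to the final bias
  m0 <- m
  for (l in 1:3) m0$affect$EDA$layers[[l]]$W[] <- 0
  m0$affect$EDA$layers[[3]]$b <- 0.7
  tr0 <- forward_subject(m0, fs)
  expect_equal(tr0$per$EDA$affect$theta, rep(0.7, 4))
})

test_that("analyser adds the baseline and applies two linear layers", {
  fs <- random_feature_set(xi = 3, seed = 9)
  m <- init_model(model_config(seed = 5), fs$manifest)
  m <- calibrate_norms(m, list(fs))
  Theta <- matrix(rnorm(6), 3, 2)
  # u = 0: Phi equals Theta
  out0 <- analyser_forward(m, Theta)
  expect_identical(out0$Phi, Theta)
  # shifting one baseline coordinate shifts exactly that Phi column
  m$u[2] <- 0.25
  out1 <- analyser_forward(m, Theta)
  expect_equal(out1$Phi[, 2], Theta[, 2] + 0.25)
  expect_identical(out1$Phi[, 1], Theta[, 1])
  # zero weight matrices leave only the output bias
  m0 <- m
  m0$analyser$G1[] <- 0; m0$analyser$G2[] <- 0; m0$analyser$c2 <- c(1, 2, 3)
  outz <- analyser_forward(m0, Theta)
  expect_true(all(apply(outz$logits, 1, function(r) all(r == c(1, 2, 3)))))
})

test_that("the forward trace has the documented shapes and is causal", {
  fs <- random_feature_set(xi = 6, seed = 12)
  m <- calibrate_norms(init_model(model_config(seed = 2), fs$manifest),
                       list(fs))
  tr <- forward_subject(m, fs)
  expect_identical(dim(tr$logits), c(6L, 3L))
  expect_identical(dim(tr$Theta), c(6L, 2L))
  expect_identical(tr$Phi, sweep(tr$Theta, 2, m$u, "+"))
  for (ind in m$indicators) {
    expect_length(tr$per[[ind]]$contrib$alpha, 6)
    expect_length(tr$per[[ind]]$affect$theta, 6)
  }
  # evaluation determinism: repeated forwards are bit-identical
  expect_identical(tr$logits, forward_subject(m, fs)$logits)
  # perturbing any feature in the last window leaves earlier logits alone
  fs2 <- fs
  fs2$B$ACC[6, ] <- fs2$B$ACC[6, ] + 50
  fs2$PF[6, colnames(fs2$B$ACC)] <- fs2$B$ACC[6, ]
  tr2 <- forward_subject(m, fs2)
  expect_identical(tr$logits[1:5, ], tr2$logits[1:5, ])
  expect_false(identical(tr$logits[6, ], tr2$logits[6, ]))
  # indicator-set mismatch is a descriptive error
  fs3 <- fs
  names(fs3$manifest$indicators) <- c("ACC", "XYZ")
  expect_error(forward_subject(m, fs3), "manifest")
})

test_that("checkpoints round-trip bit-exactly and reject corruption", {
  fs <- random_feature_set(xi = 5, seed = 20)
  m <- calibrate_norms(init_model(model_config(seed = 7), fs$manifest),
                       list(fs))
  # make the stored parameters non-trivial
  m$u <- c(pi, exp(1)) * 1e-3
  path <- tempfile(fileext = ".json")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(forward_subject(m, fs)$logits,
                   forward_subject(m2, fs)$logits)
  expect_identical(flatten_params(m), flatten_params(m2))
  # truncated file: explicit load error, not silent corruption
  txt <- readLines(path, warn = FALSE)
  writeLines(substr(paste(txt, collapse = ""), 1, 200), path)
  expect_error(load_checkpoint(path), "checkpoint")
  # version mismatch
  path2 <- tempfile(fileext = ".json")
  doc <- jsonlite::fromJSON(save_checkpoint(m, path2) |> readLines() |>
                              paste(collapse = ""), simplifyVector = FALSE)
  doc$version <- "other-0"
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path2)
  expect_error(load_checkpoint(path2), "version")
})
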