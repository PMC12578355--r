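# Expression trees, protected evaluation, the GP search and law selection.

test_that("expressions parse, evaluate and report structure", {
  inputs <- data.frame(x1 = c(0, 1, -2), x2 = c(pi / 2, 0, pi))
  expect_equal(evaluate_expression("x1", inputs), inputs$x1)
  expect_equal(evaluate_expression("2*x1 + sin(x2)", inputs),
               2 * inputs$x1 + sin(inputs$x2), tolerance = 1e-12)
  e <- parse_expression("2*x1 + sin(x2)")
  expect_identical(expression_complexity(e), 6L)  # +, *, 2, x1, sin, x2
  expect_setequal(expression_variables(e), c("x1", "x2"))
  expect_identical(expression_complexity(parse_expression("x1")), 1L)
  expect_error(evaluate_expression("x9", inputs), "x9")
})

test_that("protected operators always return finite values", {
  inputs <- data.frame(x1 = c(0, -4, 1e6))
  lg <- evaluate_expression("log(x1)", inputs)
  expect_equal(lg[1], log(1e-12))
  expect_equal(lg[2], log(4 + 1e-12))
  ex <- evaluate_expression("exp(x1)", inputs)
  expect_true(all(is.finite(ex)))
  expect_equal(ex[3], exp(50))                    # clipped argument
  pw <- evaluate_expression("pow(x1, x1)", inputs)
  expect_true(all(is.finite(pw)))
  # negative bases are sign-safe
  expect_true(all(is.finite(evaluate_expression("pow(x1, 0.5)",
                                                data.frame(x1 = -3)))))
})

test_that("the front finds exact and constant targets at complexity 1", {
  set.seed(60)
  inputs <- data.frame(x1 = runif(50, -2, 2), x2 = runif(50, -2, 2))
  fr <- symbolic_regress(inputs$x1, inputs,
                         sr_params(population = 200, generations = 5,
                                   seed = 1))
  c1 <- Filter(function(l) l$complexity == 1, fr)
  expect_true(length(c1) >= 1)
  expect_lte(c1[[1]]$fit_loss, 1e-9)
  expect_identical(c1[[1]]$expression, "x1")

  frc <- symbolic_regress(rep(3.5, 50), inputs,
                          sr_params(population = 100, generations = 3,
                                    seed = 2))
  cc <- Filter(function(l) l$complexity == 1, frc)
  expect_lte(abs(3.5 - evaluate_expression(cc[[1]]$expr,
                                           inputs[1, , drop = FALSE])), 1e-6)
})

test_that("the search is deterministic and the front monotone", {
  set.seed(61)
  inputs <- data.frame(x1 = runif(60, -2, 2), x2 = runif(60, -2, 2))
  target <- inputs$x1 * inputs$x2 + 0.5
  p <- sr_params(population = 150, generations = 8, seed = 42)
  f1 <- symbolic_regress(target, inputs, p)
  f2 <- symbolic_regress(target, inputs, p)
  expect_identical(lapply(f1, `[[`, "expression"),
                   lapply(f2, `[[`, "expression"))
  cx <- vapply(f1, `[[`, numeric(1), "complexity")
  ls <- vapply(f1, `[[`, numeric(1), "fit_loss")
  expect_true(all(diff(cx) > 0))
  expect_true(all(diff(ls) <= 1e-15))
  expect_true(all(cx <= 15))
})

test_that("law selection walks the convergence rule as documented", {
  mk <- function(cx, loss, vars) list(expr = e_var("x"), expression = "x",
                                      complexity = cx, fit_loss = loss,
                                      variables_used = vars)
  front <- structure(list(mk(1, 1.0, "a"), mk(3, 0.2, "a"),
                          mk(5, 0.19, c("a", "b")),
                          mk(7, 0.189, c("a", "b"))),
                     class = "pareto_front")
  # converged set {5, 7}; equal variable counts -> lower complexity wins
  expect_identical(select_law(front)$complexity, 5)
  # fewest variables among converged wins
  front2 <- structure(list(mk(1, 1.0, "a"), mk(3, 0.2, "a"),
                           mk(5, 0.199, c("a", "b", "c")),
                           mk(7, 0.198, c("a", "b"))),
                      class = "pareto_front")
  expect_identical(select_law(front2)$complexity, 7)
  # single-entry front returns that entry
  single <- structure(list(mk(3, 0.4, "a")), class = "pareto_front")
  expect_identical(select_law(single)$complexity, 3)
  # still-falling curve: nothing converged, lowest loss returned
  front3 <- structure(list(mk(1, 1.0, "a"), mk(3, 0.2, "a"),
                           mk(5, 0.02, "b")),
                      class = "pareto_front")
  expect_identical(select_law(front3)$complexity, 5)
})

test_that("law R-squared follows its definition including edge cases", {
  inputs <- data.frame(x1 = seq(-2, 2, length.out = 40))
  target <- 3 * inputs$x1
  exact <- parse_expression("3 * x1")
  expect_equal(law_r2(exact, inputs, target), 1)
  # the mean-constant law scores 0
  cm <- e_const(mean(target))
  expect_equal(law_r2(cm, inputs, target), 0, tolerance = 1e-12)
  # worse-than-mean laws may score below 0 and are reported as such
  bad <- parse_expression("-3 * x1")
  expect_lt(law_r2(bad, inputs, target), 0)
  # zero-variance target: 1 when residuals vanish, else 0
  expect_equal(law_r2(e_const(2), inputs, rep(2, 40)), 1)
  expect_equal(law_r2(e_const(5), inputs, rep(2, 40)), 0)
})

test_that("degenerate targets and inputs are rejected or handled", {
  inputs <- data.frame(x1 = runif(30))
  expect_error(symbolic_regress(rnorm(10), data.frame(x1 = runif(10))),
               ">= 20")
  fr <- symbolic_regress(rep(1.25, 30), inputs,
                         sr_params(population = 80, generations = 2,
                                   seed = 3))
  expect_lte(fr[[1]]$fit_loss, 1e-6)
})
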