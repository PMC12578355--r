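# Genetic-programming symbolic regression: tournament selection, subtree
# crossover, point and subtree mutation, a complexity cap, per-complexity
# Pareto archive (the complexity-loss front), and deterministic
# coordinate-descent constant optimisation on front candidates.

#' Symbolic-regression search parameters
#'
#' @param population population size.
#' @param generations number of generations.
#' @param tournament_k tournament size.
#' @param p_crossover,p_subtree_mut,p_point_mut operator probabilities
#'   (remainder reproduces the parent unchanged).
#' @param max_complexity maximum expression node count.
#' @param p_var probability a random leaf is a variable (vs constant).
#' @param const_sd scale of freshly drawn constants.
#' @param n_const_opt how many archive candidates get constant optimisation
#'   per generation.
#' @param seed integer seed; the whole search is deterministic given it.
#' @return list of parameters.
#' @export
sr_params <- function(population = 500, generations = 40, tournament_k = 5,
                      p_crossover = 0.65, p_subtree_mut = 0.2,
                      p_point_mut = 0.1, max_complexity = 15, p_var = 0.8,
                      const_sd = 2, n_const_opt = 6, seed = 1L) {
  list(population = population, generations = generations,
       tournament_k = tournament_k, p_crossover = p_crossover,
       p_subtree_mut = p_subtree_mut, p_point_mut = p_point_mut,
       max_complexity = max_complexity, p_var = p_var, const_sd = const_sd,
       n_const_opt = n_const_opt, seed = as.integer(seed))
}

random_leaf <- function(vars, p_var, const_sd) {
  if (length(vars) && runif(1) < p_var) e_var(sample(vars, 1))
  else e_const(round(rnorm(1, 0, const_sd), 3))
}

random_tree <- function(depth, vars, p_var, const_sd, full = FALSE) {
  if (depth <= 0 || (!full && runif(1) < 0.3))
    return(random_leaf(vars, p_var, const_sd))
  op <- sample(c(SR_BINARY, SR_UNARY), 1,
               prob = c(3, 2, 3, 0.7, 1.5, 1, 0.7, 0.7))
  if (op %in% SR_BINARY)
    e_call(op, random_tree(depth - 1, vars, p_var, const_sd, full),
           random_tree(depth - 1, vars, p_var, const_sd, full))
  else
    e_call(op, random_tree(depth - 1, vars, p_var, const_sd, full))
}

point_mutate <- function(expr, vars, const_sd) {
  paths <- node_paths(expr)
  p <- paths[[sample(length(paths), 1)]]
  node <- get_node(expr, p)
  new <- switch(node$op,
    const = e_const(node$value + rnorm(1, 0, 0.5 * (abs(node$value) + 1))),
    var = if (length(vars) > 1) e_var(sample(setdiff(vars, node$name), 1))
          else e_const(round(rnorm(1, 0, const_sd), 3)),
    {
      pool <- if (node$op %in% SR_BINARY) SR_BINARY else SR_UNARY
      node$op <- sample(pool, 1)
      node
    })
  set_node(expr, p, new)
}

subtree_mutate <- function(expr, vars, p_var, const_sd) {
  paths <- node_paths(expr)
  p <- paths[[sample(length(paths), 1)]]
  set_node(expr, p, random_tree(2, vars, p_var, const_sd))
}

crossover <- function(a, b) {
  pa <- node_paths(a); pb <- node_paths(b)
  set_node(a, pa[[sample(length(pa), 1)]],
           get_node(b, pb[[sample(length(pb), 1)]]))
}

mae <- function(pred, target) mean(abs(pred - target))

# Deterministic constant refinement: golden-section search on each constant
# in turn, two sweeps.
optimise_constants <- function(expr, inputs, target, sweeps = 2) {
  cps <- const_paths(expr)
  if (!length(cps)) return(expr)
  for (s in seq_len(sweeps)) {
    for (p in cps) {
      v0 <- get_node(expr, p)$value
      span <- 2 * abs(v0) + 2
      f <- function(v) mae(evaluate_expression(set_node(expr, p, e_const(v)),
                                               inputs), target)
      opt <- stats::optimize(f, lower = v0 - span, upper = v0 + span,
                             tol = 1e-6)
      if (opt$objective < f(v0)) expr <- set_node(expr, p, e_const(opt$minimum))
    }
  }
  expr
}

archive_update <- function(archive, expr, loss) {
  cx <- expression_complexity(expr)
  key <- as.character(cx)
  cur <- archive[[key]]
  if (is.null(cur) || loss < cur$loss - 1e-15)
    archive[[key]] <- list(expr = expr, loss = loss, complexity = cx)
  archive
}

# Reduce the archive to a monotone front: ascending complexity,
# non-increasing loss (ties kept: the best law at a higher complexity may
# match, but never exceed, the loss of a simpler one).
archive_front <- function(archive) {
  if (!length(archive)) return(list())
  entries <- archive[order(as.integer(names(archive)))]
  front <- list(); best <- Inf
  for (e in entries) {
    if (e$loss <= best + 1e-15) {
      front[[length(front) + 1]] <- e
      best <- min(best, e$loss)
    }
  }
  front
}

#' Symbolic regression by genetic programming
#'
#' Minimises mean absolute error between the expression and the target over
#' the operator set \{+, -, x, sin, cos, log, exp, pow\}, keeping the best
#' expression found at each complexity level (node count) up to the cap.
#' Deterministic given `params$seed`.
#'
#' @param target numeric response vector (>= 20 samples).
#' @param inputs data.frame of candidate input features (>= 1 column).
#' @param params see [sr_params()].
#' @return object of class `pareto_front`: list of laws, each with `expr`,
#'   `expression` (infix string), `complexity`, `fit_loss`,
#'   `variables_used`; complexities strictly increase and losses strictly
#'   decrease along the front.
#' @export
symbolic_regress <- function(target, inputs, params = sr_params()) {
  if (length(target) < 20) stop_data("symbolic regression needs >= 20 samples")
  if (!ncol(as.data.frame(inputs))) stop_data("needs >= 1 input feature")
  inputs <- as.data.frame(inputs)
  vars <- colnames(inputs)
  with_local_seed(params$seed, {
    fitness <- function(e) mae(evaluate_expression(e, inputs), target)
    archive <- list()
    # Seeds: the target mean (complexity-1 constant) and each bare variable.
    seeds <- c(list(e_const(mean(target))), lapply(vars, e_var))
    pop <- vector("list", params$population)
    for (i in seq_along(pop)) {
      pop[[i]] <- if (i <= length(seeds)) seeds[[i]]
      else random_tree(sample(2:4, 1), vars, params$p_var, params$const_sd,
                       full = runif(1) < 0.5)
    }
    fit <- vapply(pop, fitness, numeric(1))
    for (i in seq_along(pop)) archive <- archive_update(archive, pop[[i]],
                                                        fit[i])
    for (gen in seq_len(params$generations)) {
      # constant optimisation on the current front's most promising entries
      fr <- archive_front(archive)
      if (length(fr)) {
        pick <- head(fr[order(vapply(fr, `[[`, numeric(1), "loss"))],
                     params$n_const_opt)
        for (e in pick) {
          if (length(const_paths(e$expr))) {
            e2 <- optimise_constants(e$expr, inputs, target)
            archive <- archive_update(archive, e2, fitness(e2))
          }
        }
      }
      best_loss <- min(vapply(archive, `[[`, numeric(1), "loss"))
      if (best_loss < 1e-10) break
      newpop <- vector("list", params$population)
      tourn <- function() {
        idx <- sample(length(pop), params$tournament_k)
        idx[which.min(fit[idx])]
      }
      # elitism: re-inject the front
      n_elite <- min(length(fr), params$population - 1L)
      for (i in seq_len(n_elite)) newpop[[i]] <- fr[[i]]$expr
      for (i in seq(n_elite + 1, params$population)) {
        r <- runif(1)
        parent <- pop[[tourn()]]
        child <- if (r < params$p_crossover)
          crossover(parent, pop[[tourn()]])
        else if (r < params$p_crossover + params$p_subtree_mut)
          subtree_mutate(parent, vars, params$p_var, params$const_sd)
        else if (r < params$p_crossover + params$p_subtree_mut +
                 params$p_point_mut)
          point_mutate(parent, vars, params$const_sd)
        else parent
        if (expression_complexity(child) > params$max_complexity)
          child <- parent
        newpop[[i]] <- child
      }
      pop <- newpop
      fit <- vapply(pop, fitness, numeric(1))
      for (i in seq_along(pop)) archive <- archive_update(archive, pop[[i]],
                                                          fit[i])
    }
    # final constant polish on the front
    fr <- archive_front(archive)
    for (e in fr) {
      if (length(const_paths(e$expr))) {
        e2 <- optimise_constants(e$expr, inputs, target, sweeps = 3)
        archive <- archive_update(archive, e2, fitness(e2))
      }
    }
    front <- lapply(archive_front(archive), function(e) {
      list(expr = e$expr, expression = format_expression(e$expr),
           complexity = e$complexity, fit_loss = e$loss,
           variables_used = expression_variables(e$expr))
    })
    structure(front, class = "pareto_front")
  })
}

#' Select the reported law from a complexity-loss front
#'
#' The converged set is the maximal suffix of the complexity-loss curve in
#' which every step improves the loss by at most `convergence_tol` (measured
#' against the larger of the previous loss and 1, so the rule behaves
#' absolutely for small losses): the region where the curve has flattened
#' and the fit is stable. Among converged laws the one with the fewest
#' distinct variables wins; ties break to lower complexity, then lower
#' loss. A single-entry front returns that entry; if the curve is still
#' falling at its end nothing has converged and the lowest-loss law is
#' returned.
#'
#' @param front a `pareto_front`.
#' @param convergence_tol convergence threshold (default 0.01).
#' @return one law (list with `expr`, `expression`, `complexity`,
#'   `fit_loss`, `variables_used`).
#' @export
select_law <- function(front, convergence_tol = 0.01) {
  if (!length(front)) stop_data("empty front")
  if (length(front) == 1) return(front[[1]])
  losses <- vapply(front, `[[`, numeric(1), "fit_loss")
  n <- length(front)
  small <- vapply(2:n, function(i)
    (losses[i - 1] - losses[i]) <=
      convergence_tol * max(losses[i - 1], 1) + 1e-12,
    logical(1))
  # maximal all-small suffix: entries after the last sizeable improvement
  last_big <- if (any(!small)) max(which(!small)) else 0L
  cand <- if (last_big < length(small)) seq(last_big + 2L, n) else integer(0)
  if (!length(cand)) return(front[[which.min(losses)]])
  nvars <- vapply(front, function(l) length(l$variables_used), numeric(1))
  cx <- vapply(front, `[[`, numeric(1), "complexity")
  ord <- cand[order(nvars[cand], cx[cand], losses[cand])]
  front[[ord[1]]]
}

#' Goodness of fit of a law against the surrogate target
#'
#' `1 - SS_res / SS_tot` with `SS_tot` about the target mean. A
#' zero-variance target gives 1 when residuals are (numerically) zero and 0
#' otherwise. Values below 0 (worse than the mean) are reported as is.
#'
#' @param law a law from [select_law()] (or any expression tree).
#' @param inputs data.frame of inputs.
#' @param target numeric surrogate target.
#' @return R-squared.
#' @export
law_r2 <- function(law, inputs, target) {
  expr <- if (!is.null(law$expr)) law$expr else law
  pred <- evaluate_expression(expr, inputs)
  ss_res <- sum((target - pred)^2)
  ss_tot <- sum((target - mean(target))^2)
  if (ss_tot <= 1e-24) return(if (ss_res <= 1e-18) 1 else 0)
  1 - ss_res / ss_tot
}
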