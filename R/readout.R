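# The decision neuron: an L2-regularized logistic classifier trained on
# 0-vs-180 degree discrimination, read out as generalization curves over
# the full direction circle.
#
# Cost: sum_i [log(1 + exp(z_i)) - y_i z_i] + (lambda/2) ||w||^2, with
# z = Xw + b, rightward (0 deg) coded as the positive class, and the bias
# left out of the penalty. Minimized by damped Newton iterations (exact
# Hessian + step halving), which is deterministic and drives the gradient
# norm to the requested tolerance in a handful of steps.

sigmoid <- function(z) 1 / (1 + exp(-z))

logistic_cost <- function(theta, X, y, lambda) {
  z <- drop(X %*% theta)
  # numerically stable log(1 + exp(z)) - y z
  ce <- sum(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
  pen <- theta
  pen[1] <- 0
  ce + lambda / 2 * sum(pen^2)
}

logistic_grad <- function(theta, X, y, lambda) {
  p <- sigmoid(drop(X %*% theta))
  g <- drop(crossprod(X, p - y))
  pen <- theta
  pen[1] <- 0
  g + lambda * pen
}

#' Train the decision neuron on a two-direction discrimination
#'
#' Fits a logistic readout of the population response to discriminate the
#' two training directions (rightward, 0 degrees, is the positive class).
#' The cost is the summed cross-entropy plus an L2 penalty
#' `(lambda/2) * ||weights||^2` on the cell weights (bias unpenalized),
#' minimized by damped Newton iteration to gradient norm `<= tol`. The L2
#' term doubles as a homeostatic constraint on total synaptic strength.
#'
#' @param responses A `response_set` from [sample_responses()] holding
#'   balanced trials of exactly two stimulus directions, 0 and 180.
#' @param lambda L2 regularization strength (>= 0).
#' @param tol Convergence tolerance on the gradient norm.
#' @param max_iter Maximum Newton iterations.
#' @return A `plaid_readout` object: `weights` (one per cell), `bias`,
#'   `cells`, `train_kind`, `lambda`, `converged`, `n_iter`,
#'   `final_grad_norm`, `train_accuracy`.
#' @seealso [generalization_curve()], [tidy.plaid_readout()],
#'   [prune_by_quantile()]
#' @examples
#' cells <- sample_population(population_config(24, k = 7, baseline = 0.1,
#'                                              trial_noise_sd = 0.25))
#' rs <- sample_responses(cells, stimulus_spec("plaid", c(0, 180)),
#'                        n_reps = 50, noise_sd = 0.25, seed = 1)
#' model <- train_readout(rs, lambda = 1)
#' glance(model)
#' @export
train_readout <- function(responses, lambda = 1, tol = 1e-8,
                          max_iter = 200L) {
  stopifnot(inherits(responses, "response_set"))
  if (lambda < 0) abort("lambda must be non-negative")
  dirs <- sort(unique(responses$stimuli$direction))
  if (!identical(dirs, c(0, 180))) {
    abort("training responses must contain exactly the directions 0 and 180")
  }
  if (length(unique(responses$stimuli$kind)) != 1) {
    abort("training responses must be of a single stimulus kind")
  }
  y <- as.numeric(responses$stimuli$direction == 0)
  if (sum(y) != sum(1 - y)) abort("training classes must be balanced")
  X <- cbind(1, responses$values)
  n_par <- ncol(X)
  theta <- numeric(n_par)
  pen_mask <- c(0, rep(1, n_par - 1))
  converged <- FALSE
  iter <- 0L
  g <- logistic_grad(theta, X, y, lambda)
  while (iter < max_iter) {
    gnorm <- sqrt(sum(g^2))
    if (gnorm <= tol) {
      converged <- TRUE
      break
    }
    iter <- iter + 1L
    p <- sigmoid(drop(X %*% theta))
    s <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X * s, X) + lambda * diag(pen_mask)
    step <- tryCatch(solve(H, g), error = function(e) g / max(s))
    # step halving keeps the iteration stable when far from the optimum
    f0 <- logistic_cost(theta, X, y, lambda)
    alpha <- 1
    repeat {
      theta_new <- theta - alpha * step
      if (logistic_cost(theta_new, X, y, lambda) <= f0 || alpha < 1e-10) break
      alpha <- alpha / 2
    }
    theta <- theta_new
    g <- logistic_grad(theta, X, y, lambda)
  }
  gnorm <- sqrt(sum(g^2))
  if (!converged && gnorm > tol) {
    warn(sprintf(
      "readout training stopped at max_iter = %d with gradient norm %.3g",
      max_iter, gnorm
    ))
  } else {
    converged <- TRUE
  }
  pred <- sigmoid(drop(X %*% theta)) > 0.5
  structure(
    list(
      weights = theta[-1],
      bias = theta[1],
      cells = responses$cells,
      train_kind = responses$stimuli$kind[1],
      lambda = lambda,
      tol = tol,
      converged = converged,
      n_iter = iter,
      final_grad_norm = gnorm,
      train_accuracy = mean(pred == (y == 1))
    ),
    class = "plaid_readout"
  )
}

#' @export
print.plaid_readout <- function(x, ...) {
  cat(sprintf(
    "<plaid_readout> %d inputs, trained on %ss (lambda = %g)\n",
    length(x$weights), x$train_kind, x$lambda
  ))
  cat(sprintf("  training accuracy %.3f, ||w|| = %.3f, %s in %d iterations\n",
              x$train_accuracy, sqrt(sum(x$weights^2)),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Pre-sigmoid evidence and predicted class for a response matrix
#'
#' @param object A `plaid_readout`.
#' @param newdata A trials x cells numeric matrix or a `response_set`.
#' @param type `"evidence"` (weighted input `Xw + b`), `"prob"` (sigmoid of
#'   evidence) or `"class"` (`TRUE` = rightward).
#' @param ... Unused.
#' @return A numeric (or logical) vector, one element per trial.
#' @export
predict.plaid_readout <- function(object, newdata,
                                  type = c("evidence", "prob", "class"),
                                  ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "response_set")) newdata$values else newdata
  if (ncol(X) != length(object$weights)) {
    abort("newdata has a different number of cells than the readout")
  }
  ev <- drop(X %*% object$weights) + object$bias
  switch(type,
    evidence = ev,
    prob = sigmoid(ev),
    class = ev > 0
  )
}

#' Tidy the decision neuron's weights
#'
#' @param x A `plaid_readout`.
#' @param ... Unused.
#' @return One row per input cell: `cell_id`, `cell_class`,
#'   `pref_direction`, `weight`.
#' @export
tidy.plaid_readout <- function(x, ...) {
  tibble(
    cell_id = x$cells$cell_id %||% seq_along(x$weights),
    cell_class = x$cells$cell_class,
    pref_direction = x$cells$pref_direction,
    weight = x$weights
  )
}

#' One-row model summary of a fitted readout
#'
#' @param x A `plaid_readout`.
#' @param ... Unused.
#' @return A one-row tibble: `train_kind`, `lambda`, `n_inputs`,
#'   `train_accuracy`, `weight_norm`, `bias`, `converged`, `n_iter`.
#' @export
glance.plaid_readout <- function(x, ...) {
  tibble(
    train_kind = x$train_kind,
    lambda = x$lambda,
    n_inputs = length(x$weights),
    train_accuracy = x$train_accuracy,
    weight_norm = weight_norm(x),
    bias = x$bias,
    converged = x$converged,
    n_iter = x$n_iter
  )
}

#' Classification accuracy on freshly sampled held-out trials
#'
#' @param model A `plaid_readout`.
#' @param responses A `response_set` of 0/180-degree trials.
#' @return Fraction of trials classified correctly.
#' @export
readout_accuracy <- function(model, responses) {
  stopifnot(inherits(responses, "response_set"))
  pred <- predict(model, responses, type = "class")
  mean(pred == (responses$stimuli$direction == 0))
}

#' Generalization curve of a trained readout over the direction circle
#'
#' For each direction on the grid, samples `n_test_reps` noisy population
#' responses to the test stimulus and reports the fraction of trials the
#' readout classifies as rightward (predicted probability > 0.5). Test
#' trials carry the same response noise as training trials. This is the
#' model counterpart of a behavioral priming curve.
#'
#' @param model A `plaid_readout`.
#' @param cells The cell tibble the model reads out (defaults to the cells
#'   it was trained on).
#' @param stimulus_kind `"grating"` or `"plaid"`.
#' @param directions Degree grid (default 0 to 345 in steps of 15).
#' @param n_test_reps Test trials per direction.
#' @param noise_sd Response noise SD for test trials.
#' @param seed Integer seed.
#' @param cross_angle Plaid cross-angle, degrees.
#' @return A tibble of class `generalization_curve`: `direction`,
#'   `stimulus_kind`, `prop_rightward`, `n`.
#' @examples
#' \donttest{
#' cells <- sample_population(population_config(24, k = 7, baseline = 0.1))
#' rs <- sample_responses(cells, stimulus_spec("plaid", c(0, 180)),
#'                        n_reps = 100, noise_sd = 0.25, seed = 1)
#' model <- train_readout(rs)
#' generalization_curve(model, stimulus_kind = "plaid", n_test_reps = 100,
#'                      noise_sd = 0.25, seed = 2)
#' }
#' @export
generalization_curve <- function(model, cells = model$cells,
                                 stimulus_kind = c("plaid", "grating"),
                                 directions = seq(0, 345, by = 15),
                                 n_test_reps = 500,
                                 noise_sd = 0.25,
                                 seed = NULL,
                                 cross_angle = 120) {
  stimulus_kind <- match.arg(stimulus_kind)
  if (length(directions) == 0) abort("direction grid must be non-empty")
  cells <- validate_cells(cells)
  if (nrow(cells) != length(model$weights)) {
    abort("cells and model have incompatible dimensions")
  }
  stim <- stimulus_spec(stimulus_kind, directions, cross_angle)
  rs <- sample_responses(cells, stim, n_reps = n_test_reps,
                         noise_sd = noise_sd, seed = seed)
  right <- predict(model, rs, type = "class")
  prop <- tapply(right, factor(rs$stimuli$direction, levels = directions),
                 mean)
  out <- tibble(
    direction = directions,
    stimulus_kind = stimulus_kind,
    prop_rightward = as.numeric(prop),
    n = n_test_reps
  )
  class(out) <- c("generalization_curve", class(out))
  out
}

#' Mean absolute divergence between two generalization curves
#'
#' Averages the absolute differences between the proportions of rightward
#' choices of two curves across all tested directions - the statistic used
#' to quantify how differently a representation generalizes to gratings
#' versus plaids.
#'
#' @param curve_a,curve_b Tibbles from [generalization_curve()] sharing the
#'   same direction grid.
#' @return A scalar in `[0, 1]`; zero iff the curves are identical.
#' @export
curve_divergence <- function(curve_a, curve_b) {
  if (!identical(curve_a$direction, curve_b$direction)) {
    abort("curves must share the same direction grid")
  }
  mean(abs(curve_a$prop_rightward - curve_b$prop_rightward))
}
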