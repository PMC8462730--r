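# The logistic decision neuron and its generalization curves

test_that("the newton solver matches independent optimizers on the same
           cost", {
  cells <- small_population()[1:4, ]
  rs <- sample_responses(cells, stimulus_spec("plaid", c(0, 180)),
                         n_reps = 30, noise_sd = 0.4, seed = 5)
  model <- train_readout(rs, lambda = 2)
  X <- cbind(1, rs$values)
  y <- as.numeric(rs$stimuli$direction == 0)
  # oracle 1: quasi-Newton (BFGS) minimization of the identical cost
  cost <- function(th) {
    z <- drop(X %*% th)
    sum(log(1 + exp(z)) - y * z) + 1 * sum(th[-1]^2)
  }
  fit <- optim(rep(0, 5), cost, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(c(model$bias, model$weights), fit$par, tolerance = 1e-5)
  # oracle 2: glmnet's penalized logistic likelihood, matched scaling
  # ((1/N) * deviance/2 + (lambda_glmnet/2) ||w||^2 has the same argmin)
  g <- glmnet::glmnet(rs$values, y, family = "binomial", alpha = 0,
                      lambda = 2 / nrow(X), standardize = FALSE,
                      thresh = 1e-14)
  expect_equal(model$weights, as.numeric(g$beta), tolerance = 1e-3)
  expect_equal(model$bias, as.numeric(g$a0), tolerance = 1e-3)
  expect_true(model$converged)
  expect_lte(model$final_grad_norm, model$tol)
})

test_that("heavy regularization shrinks the weights toward zero", {
  cells <- small_population()
  rs <- sample_responses(cells, stimulus_spec("plaid", c(0, 180)),
                         n_reps = 50, noise_sd = 0.25, seed = 1)
  strong <- train_readout(rs, lambda = 1e6)
  weak <- train_readout(rs, lambda = 1)
  expect_lt(weight_norm(strong), 1e-2)
  expect_gt(weight_norm(weak), 10 * weight_norm(strong))
})

test_that("training input is validated", {
  cells <- small_population()
  rs <- sample_responses(cells, stimulus_spec("plaid", c(0, 90)),
                         n_reps = 5, noise_sd = 0.1, seed = 1)
  expect_error(train_readout(rs), "0 and 180")
  mixed <- sample_responses(cells, stimulus_spec(c("plaid", "grating"),
                                                 c(0, 180)),
                            n_reps = 5, noise_sd = 0.1, seed = 1)
  expect_error(train_readout(mixed), "single stimulus kind")
})

test_that("plaid training over component cells puts large weights at
           +/- 60 degrees off the training axis", {
  cells <- small_population("component")
  model <- train_small_readout(cells, "plaid")
  expect_equal(model$train_accuracy, 1)
  w <- tidy(model)
  expect_setequal(w$pref_direction[order(-w$weight)[1:2]], c(60, 300))
  expect_setequal(w$pref_direction[order(w$weight)[1:2]], c(120, 240))
})

test_that("generalization curves are antisymmetric around 180 degrees for
           a symmetric design", {
  cells <- small_population("component")
  model <- train_small_readout(cells, "plaid")
  curve <- generalization_curve(model, cells, "plaid", n_test_reps = 500,
                                noise_sd = 0.25, seed = 31)
  # rotating the stimulus by 180 degrees swaps the two choices ...
  opposite <- curve$prop_rightward[match(
    wrap_direction(curve$direction + 180), curve$direction
  )]
  resid <- curve$prop_rightward + opposite - 1
  expect_lt(max(abs(resid)), 0.1)
  expect_lt(mean(abs(resid)), 0.04)
  # ... and reflecting it about the horizontal axis changes nothing
  mirrored <- curve$prop_rightward[match(
    wrap_direction(360 - curve$direction), curve$direction
  )]
  expect_lt(max(abs(curve$prop_rightward - mirrored)), 0.1)
})

test_that("more training data never hurts held-out accuracy in
           expectation", {
  cells <- small_population()[seq(1, 24, by = 6), ]   # 4 cells, hard task
  acc <- sapply(c(4, 40, 400), function(n_train) {
    mean(sapply(1:12, function(s) {
      seeds <- s * 100 + 1:2
      rs <- sample_responses(cells, stimulus_spec("plaid", c(0, 180)),
                             n_reps = n_train, noise_sd = 1.5,
                             seed = seeds[1])
      m <- train_readout(rs, lambda = 1)
      held <- sample_responses(cells, stimulus_spec("plaid", c(0, 180)),
                               n_reps = 200, noise_sd = 1.5,
                               seed = seeds[2])
      readout_accuracy(m, held)
    }))
  })
  expect_true(all(diff(acc) > -0.02))
  expect_gt(acc[3], acc[1])
})

test_that("curve divergence is the mean absolute gap", {
  a <- tibble::tibble(direction = seq(0, 345, 15), prop_rightward = 0.2,
                      stimulus_kind = "plaid", n = 10)
  b <- dplyr::mutate(a, prop_rightward = 0.6, stimulus_kind = "grating")
  expect_equal(curve_divergence(a, a), 0)
  expect_equal(curve_divergence(a, b), 0.4)
  short <- a[1:10, ]
  expect_error(curve_divergence(a, short), "grid")
  expect_error(generalization_curve(train_small_readout(small_population()),
                                    directions = numeric(0)), "non-empty")
})
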