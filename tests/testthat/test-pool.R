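# Decoding-pool pruning, norms, and evidence curves

test_that("quantile pruning zeroes the weakest weights with exact survivor
           counts", {
  cells <- cell_tuning(cell_class = rep("component", 4))
  m <- manual_readout(c(1, 2, 3, 4), cells)
  expect_equal(prune_by_quantile(m, 0)$weights, c(1, 2, 3, 4))
  expect_equal(prune_by_quantile(m, 0.5)$weights, c(0, 0, 3, 4))
  expect_equal(prune_by_quantile(m, 0.75)$weights, c(0, 0, 0, 4))
  # magnitude, not sign, decides survival
  neg <- manual_readout(c(-5, 2, -3, 4), cells)
  expect_equal(prune_by_quantile(neg, 0.5)$weights, c(-5, 0, 0, 4))
  # ties: the later index survives
  tie <- manual_readout(c(1, 1, 1, 1), cells)
  expect_equal(prune_by_quantile(tie, 0.5)$weights, c(0, 0, 1, 1))
  big <- manual_readout(rnorm(1000), cell_tuning(
    cell_class = rep("component", 1000)
  ))
  expect_equal(sum(prune_by_quantile(big, 0.9)$weights != 0), 100)
  expect_error(prune_by_quantile(m, 1), "quantile")
})

test_that("pruning is idempotent and nested across quantiles", {
  set.seed(1)
  m <- manual_readout(rnorm(200),
                      cell_tuning(cell_class = rep("pattern", 200)))
  for (q in c(0.2, 0.5, 0.8)) {
    once <- prune_by_quantile(m, q)
    twice <- prune_by_quantile(once, q)
    expect_identical(once$weights, twice$weights)
  }
  alive <- function(q) which(prune_by_quantile(m, q)$weights != 0)
  qs <- seq(0, 0.9, by = 0.1)
  for (i in seq_along(qs)[-1]) {
    expect_true(all(alive(qs[i]) %in% alive(qs[i - 1])))
  }
})

test_that("class fractions reflect the surviving pool", {
  cells <- cell_tuning(cell_class = rep(c("component", "pattern"),
                                        c(8, 2)))
  m <- manual_readout(seq(0.1, 1, by = 0.1), cells)
  f <- class_fractions(m)
  expect_equal(f$fraction_component, 0.8)
  expect_equal(f$fraction_pattern, 0.2)
  expect_equal(f$fraction_component + f$fraction_pattern, 1)
  zero <- manual_readout(rep(0, 10), cells)
  expect_error(class_fractions(zero), "empty")
  prof <- pruning_profile(m, c(0, 0.5))
  expect_s3_class(prof, "pruning_profile")
  expect_equal(prof$n_pool, c(10, 5))
})

test_that("weight norm is the euclidean norm without the bias", {
  cells <- cell_tuning(cell_class = rep("pattern", 2))
  expect_equal(weight_norm(manual_readout(c(3, 4), cells, bias = 99)), 5)
  expect_equal(weight_norm(manual_readout(c(0, 0), cells)), 0)
})

test_that("input norms track cross-orientation suppression", {
  pat <- cortical_population(n_cells = 300, fraction_component = 0,
                             pattern_plaid_suppression = 0.25, seed = 2)
  norms <- input_population_norms(pat, n_reps = 100, noise_sd = 2,
                                  seed = 4)
  expect_gt(norms$mean_norm[norms$kind == "grating"],
            norms$mean_norm[norms$kind == "plaid"])
  # without suppression (and without broadening) the norms coincide
  even <- cortical_population(n_cells = 300, fraction_component = 0,
                              pattern_plaid_suppression = 1,
                              pattern_plaid_k_divisor = 1, seed = 2)
  n2 <- input_population_norms(even, n_reps = 400, noise_sd = 2, seed = 4)
  expect_equal(n2$mean_norm[1], n2$mean_norm[2], tolerance = 0.01)
  # one-cell, zero-noise case: the norm is the response itself
  cell <- cell_tuning("pattern", pref_direction = 0, k = 7, amplitude = 8,
                      baseline = 2)
  n1 <- input_population_norms(cell, kinds = "grating", n_reps = 5,
                               noise_sd = 0, seed = 1)
  expect_equal(n1$mean_norm,
               mean(abs(drop(grating_tuning(cell, c(0, 180))))))
})

test_that("evidence curves average the weighted input", {
  cells <- cell_tuning(cell_class = rep("pattern", 3), k = 7,
                       amplitude = 1, baseline = 0.1,
                       pref_direction = c(0, 120, 240))
  # degenerate model: zero weights give a flat curve at the bias
  flat <- evidence_curve(manual_readout(c(0, 0, 0), cells, bias = 1.5),
                         cells, "grating", noise_sd = 1, n_reps = 20,
                         seed = 2)
  expect_true(all(flat$evidence == 1.5))
  # zero noise: evidence equals the deterministic weighted tuning
  m <- manual_readout(c(1, -2, 0.5), cells, bias = 0.25)
  ev <- evidence_curve(m, cells, "grating", directions = c(0, 90),
                       noise_sd = 0, n_reps = 3, seed = 1)
  mu <- grating_tuning(cells, c(0, 90))
  expect_equal(ev$evidence, drop(mu %*% c(1, -2, 0.5)) + 0.25)
  expect_error(evidence_curve(m, small_population(), "grating"),
               "incompatible")
})
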