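# The synthetic cohort generator and its ground truth

test_that("configurations are validated at construction time", {
  expect_error(sim_rat_config("r", "G", base_accuracy = 0.5), "base_accuracy")
  expect_error(sim_rat_config("r", "G", base_accuracy = 0.9,
                              identity_gain = 0.2), "inconsistent")
  expect_error(sim_rat_config("r", "G", lapse_rate = 0.5), "rates")
  expect_error(sim_rat_config("r", "X"))
})

test_that("generation is deterministic under the seed", {
  cfg <- dplyr::bind_rows(
    sim_rat_config("r1", "G", n_sessions = 2, trials_per_session = 100),
    sim_rat_config("r2", "P", n_sessions = 2, trials_per_session = 100)
  )
  a <- simulate_cohort(cfg, seed = 5)
  b <- simulate_cohort(cfg, seed = 5)
  expect_identical(a$trials, b$trials)
  c2 <- simulate_cohort(cfg, seed = 6)
  expect_false(identical(a$trials, c2$trials))
  expect_equal(nrow(a$trials), 400)
  expect_equal(unique(a$trials$phase), "priming")
})

test_that("trial tables round-trip through CSV unchanged", {
  cfg <- sim_rat_config("r1", "P", n_sessions = 1, trials_per_session = 60)
  sim <- simulate_cohort(cfg, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(sim$trials, path)
  back <- read_trials(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$trials))
  # empty cohort: header-only file
  write_trials(sim$trials[0, ], path)
  expect_equal(nrow(read_trials(path)), 0)
  expect_equal(names(read_trials(path)), names(sim$trials))
})

test_that("injected invalid-trial counts match the validity filter
           exactly", {
  cfg <- dplyr::bind_rows(
    sim_rat_config("r1", "G", too_fast_rate = 0.05, ignored_rate = 0.08,
                   n_sessions = 3, trials_per_session = 400),
    sim_rat_config("r2", "G", too_fast_rate = 0.02, ignored_rate = 0.01,
                   n_sessions = 3, trials_per_session = 400)
  )
  sim <- simulate_cohort(cfg, seed = 9)
  filt <- filter_trials(sim$trials)
  inj <- sim$truth$injected_invalid
  expect_equal(filt$exclusions$n[filt$exclusions$reason == "too_fast"],
               sum(inj$too_fast))
  expect_equal(filt$exclusions$n[filt$exclusions$reason == "ignored"],
               sum(inj$ignored))
  expect_equal(filt$exclusions$n[filt$exclusions$reason == "malformed"], 0)
})

test_that("the full design is covered in a long run", {
  cfg <- sim_rat_config("r1", "P", n_sessions = 2,
                        trials_per_session = 5000)
  sim <- simulate_cohort(cfg, seed = 13)
  combos <- dplyr::distinct(sim$trials, prime_direction, prime_kind,
                            target_direction)
  expect_equal(nrow(combos), 19 * 2 * 2)
})

test_that("expected curves follow the configured bias shape and lapse", {
  cfg <- sim_rat_config("r1", "P", base_accuracy = 0.8,
                        identity_gain = 0.15, cross_gain = 0.05,
                        bias_shape = "linear", lapse_rate = 0.1)
  curves <- expected_priming_curve(cfg)
  ident <- curves[curves$condition == "identity", ]
  expect_equal(ident$expected_accuracy[ident$distance == 0],
               0.9 * (0.8 + 0.15) + 0.05)
  expect_equal(ident$expected_accuracy[ident$distance == 90],
               0.9 * 0.8 + 0.05)
  expect_equal(ident$expected_accuracy[ident$distance == 180],
               0.9 * (0.8 - 0.15) + 0.05)
  # sigmoid shape is anchored at the same three points
  sig <- sim_rat_config("r2", "P", bias_shape = "sigmoid", lapse_rate = 0)
  sc <- expected_priming_curve(sig)
  si <- sc[sc$condition == "identity", ]
  expect_equal(si$expected_accuracy[si$distance == 0], 0.8 + 0.15)
  expect_equal(si$expected_accuracy[si$distance == 90], 0.8)
  expect_equal(si$expected_accuracy[si$distance == 180], 0.8 - 0.15)
  expect_equal(expected_priming_magnitude(sig, "identity"),
               expected_priming_magnitude(sig, "cross"))
})

test_that("a null generator produces only the sampling-floor magnitude", {
  cfg <- dplyr::bind_rows(
    sim_rat_config("r1", "G", identity_gain = 0, cross_gain = 0,
                   lapse_rate = 0, too_fast_rate = 0, ignored_rate = 0,
                   n_sessions = 5, trials_per_session = 1200),
    sim_rat_config("r2", "G", identity_gain = 0, cross_gain = 0,
                   lapse_rate = 0, too_fast_rate = 0, ignored_rate = 0,
                   n_sessions = 5, trials_per_session = 1200)
  )
  sim <- simulate_cohort(cfg, seed = 17)
  inc <- animal_inclusion(sim$trials)
  # analytic floor: |accuracy difference| of two binomial bins folds to
  # E|N(0, sd_diff)| = sd_diff * sqrt(2/pi); bins hold ~ n/19 trials each
  n_bin <- 0.5 * 5 * 1200 / 19
  sd_diff <- sqrt(2 * 0.8 * 0.2 / n_bin)
  floor_bound <- 3 * sd_diff * sqrt(2 / pi)    # generous 3x margin
  expect_lt(mean(inc$identity_magnitude), floor_bound)
  expect_lt(mean(inc$identity_magnitude), 0.05)
})

test_that("group phenotypes mirror the study design", {
  # G-like rat: identity priming only; P-like rat: both conditions equal
  cfg <- dplyr::bind_rows(
    sim_rat_config("g1", "G", identity_gain = 0.15, cross_gain = 0,
                   lapse_rate = 0, n_sessions = 6,
                   trials_per_session = 1500),
    sim_rat_config("p1", "P", identity_gain = 0.15, cross_gain = 0.15,
                   lapse_rate = 0, n_sessions = 6,
                   trials_per_session = 1500)
  )
  sim <- simulate_cohort(cfg, seed = 23)
  mags <- purrr::map_dfr(split(sim$trials, sim$trials$animal_id),
                         function(df) {
    cond <- prime_condition(df$group, df$prime_kind)
    tibble::tibble(
      animal_id = df$animal_id[1],
      identity = priming_magnitude(priming_curve(df[cond == "identity", ])),
      cross = priming_magnitude(priming_curve(df[cond == "cross", ]))
    )
  })
  g <- mags[mags$animal_id == "g1", ]
  p <- mags[mags$animal_id == "p1", ]
  expect_gt(g$identity, 3 * g$cross)
  expect_lt(abs(p$identity - p$cross), 0.05)
  expect_gt(p$cross, 0.10)
})

test_that("training-session simulation ramps to the asymptote", {
  s <- simulate_training_sessions("r1", n_sessions = 40,
                                  start_accuracy = 0.5, asymptote = 0.82,
                                  rate = 0.2, trials_per_session = 500,
                                  seed = 3)
  m <- learning_metrics(s)
  expect_true(m$summary$reached)
  expect_equal(m$summary$asymptotic, 0.82, tolerance = 0.03)
  expect_lt(mean(s$accuracy[1:3]), mean(s$accuracy[35:40]))
})
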