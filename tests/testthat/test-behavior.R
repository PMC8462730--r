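# Trial filtering, learning metrics, priming curves and group statistics

test_that("the priming-phase response window is (300, 1000] ms", {
  tr <- tibble::tibble(
    phase = "priming",
    reaction_time = c(250, 500, 1200, NA, 300, 1000)
  )
  out <- filter_trials(tr)
  expect_equal(out$trials$reaction_time, c(500, 300, 1000))
  expect_equal(out$exclusions$n[out$exclusions$reason == "too_fast"], 1)
  expect_equal(out$exclusions$n[out$exclusions$reason == "ignored"], 1)
  expect_equal(out$exclusions$n[out$exclusions$reason == "malformed"], 1)
})

test_that("training-phase trials may run 2 s past stimulus offset", {
  tr <- tibble::tibble(
    phase = "training",
    reaction_time = c(250, 1500, 3800, 4200)
  )
  out <- filter_trials(tr)
  expect_equal(out$trials$reaction_time, c(1500, 3800))
  expect_equal(out$exclusions$n,
               c(too_fast = 1, ignored = 1, malformed = 0),
               ignore_attr = TRUE)
})

test_that("learning metrics find the criterion run and asymptote", {
  s <- tibble::tibble(animal_id = "r1", session = 1:6,
                      accuracy = c(0.60, 0.65, 0.72, 0.71, 0.73, 0.74))
  m <- learning_metrics(s)
  expect_equal(m$summary$criterion_session, 3L)
  expect_equal(m$summary$asymptotic, mean(c(0.72, 0.71, 0.73, 0.74)))
  expect_true(m$summary$reached)
  # the smoothed curve uses a size-3 window with shrunk edges
  expect_equal(m$curves$smoothed[1], mean(c(0.60, 0.65)))
  expect_equal(m$curves$smoothed[3], mean(c(0.65, 0.72, 0.71)))
  expect_equal(m$curves$smoothed[6], mean(c(0.73, 0.74)))
  # the criterion is a strict >= 0.70 over four consecutive sessions
  never <- tibble::tibble(animal_id = "r2", session = 1:6, accuracy = 0.69)
  m2 <- learning_metrics(never)
  expect_false(m2$summary$reached)
  expect_true(is.na(m2$summary$criterion_session))
  expect_true(is.na(m2$summary$asymptotic))
  # a dip restarts the required four-session run
  broken <- tibble::tibble(
    animal_id = "r3", session = 1:7,
    accuracy = c(0.72, 0.71, 0.69, 0.73, 0.74, 0.75, 0.76)
  )
  expect_equal(learning_metrics(broken)$summary$criterion_session, 4L)
  expect_error(learning_metrics(s[1:3, ]), "at least 4")
})

test_that("priming curves pool targets by angular distance", {
  tr <- tibble::tibble(
    prime_direction = c(0, 180, 90, 90, 180, 0),
    target_direction = c(0, 180, 0, 180, 0, 180),
    correct = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  pc <- priming_curve(tr)
  expect_equal(pc$distance, seq(0, 180, 10))
  expect_equal(pc$accuracy[pc$distance == 0], 1)      # both coherent trials
  expect_equal(pc$accuracy[pc$distance == 90], 0.5)   # neutral, either target
  expect_equal(pc$accuracy[pc$distance == 180], 0)    # both incoherent
  expect_equal(pc$n_trials[pc$distance == 0], 2)
  # empty bins are missing, not zero
  expect_true(all(is.na(pc$accuracy[!pc$distance %in% c(0, 90, 180)])))
  # invariance to relabeling the two targets
  flipped <- dplyr::mutate(tr, target_direction = 180 - target_direction,
                           prime_direction = 180 - prime_direction)
  expect_equal(priming_curve(flipped)$accuracy, pc$accuracy)
})

test_that("priming magnitude is the mean absolute deviation of the curve
           extremes from the neutral point", {
  curve <- tibble::tibble(
    distance = seq(0, 180, 10),
    accuracy = c(rep(0.9, 4), rep(0.7, 11), rep(0.5, 4))
  )
  expect_equal(priming_magnitude(curve), 0.2)
  expect_equal(priming_magnitude(dplyr::mutate(curve, accuracy = 0.8)), 0)
  no_neutral <- dplyr::mutate(curve,
                              accuracy = replace(accuracy, 10, NA))
  expect_error(priming_magnitude(no_neutral), "neutral")
})

test_that("the 5% identity-priming inclusion criterion separates flat
           animals", {
  with_seed_local <- function(code) withr::with_seed(99, code)
  strong <- with_seed_local(design_trials(
    "strong", "P", n_sessions = 40,
    p_correct = function(d, cond) 0.8 + 0.15 * (90 - d) / 90
  ))
  flat <- with_seed_local(design_trials(
    "flat", "P", n_sessions = 40,
    p_correct = function(d, cond) 0.8
  ))
  inc <- animal_inclusion(dplyr::bind_rows(strong, flat))
  expect_true(inc$included[inc$animal_id == "strong"])
  expect_gt(inc$identity_magnitude[inc$animal_id == "strong"], 0.05)
})

test_that("a deterministic animal yields zero-width bootstrap intervals", {
  tr <- dplyr::bind_rows(design_trials("r1", "P", 3),
                         design_trials("r2", "P", 3))
  boot <- bootstrap_group_curves(tr, n_reps = 10, seed = 1)
  expect_true(all(boot$curves$accuracy == 1))
  expect_true(all(boot$curves$boot_sd == 0))
  expect_equal(boot$curves$ci_low, boot$curves$ci_high)
  expect_true(all(boot$magnitudes$magnitude == 0))
})

test_that("bonferroni correction widens curve-point intervals", {
  p_fun <- function(d, cond) 0.75 + 0.1 * (90 - d) / 90
  tr <- withr::with_seed(5, dplyr::bind_rows(
    design_trials("r1", "G", 8, p_fun), design_trials("r2", "G", 8, p_fun)
  ))
  wide <- bootstrap_group_curves(tr, n_reps = 30, bonferroni_m = 19,
                                 seed = 2)
  narrow <- bootstrap_group_curves(tr, n_reps = 30, bonferroni_m = 1,
                                   seed = 2)
  expect_identical(wide$curves$boot_sd, narrow$curves$boot_sd)
  w_wide <- wide$curves$ci_high - wide$curves$ci_low
  w_narrow <- narrow$curves$ci_high - narrow$curves$ci_low
  expect_true(all(w_wide > w_narrow | w_narrow == 0))
  # the expected ratio is the ratio of critical values
  expect_equal(mean((w_wide / w_narrow)[w_narrow > 0]),
               qnorm(1 - 0.025 / 19) / qnorm(0.975), tolerance = 1e-8)
  # a single-session animal is flagged
  single <- design_trials("solo", "G", 1)
  expect_warning(
    bootstrap_group_curves(dplyr::bind_rows(tr, single), n_reps = 3,
                           seed = 1),
    "single session"
  )
})

test_that("bootstrap SDs stabilize as replicates grow", {
  p_fun <- function(d, cond) 0.8 + 0.12 * (90 - d) / 90
  tr <- withr::with_seed(11, dplyr::bind_rows(
    design_trials("r1", "P", 10, p_fun),
    design_trials("r2", "P", 10, p_fun)
  ))
  b1 <- bootstrap_group_curves(tr, n_reps = 500, seed = 21)
  b2 <- bootstrap_group_curves(tr, n_reps = 500, seed = 22)
  m1 <- b1$magnitudes$boot_sd[b1$magnitudes$condition == "identity"]
  m2 <- b2$magnitudes$boot_sd[b2$magnitudes$condition == "identity"]
  expect_lt(abs(m1 - m2) / m1, 0.1)
})

test_that("group comparison reproduces the pooled-variance t statistic", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 3),
                      v = c(70, 72, 74, 80, 82, 84))
  res <- group_comparison(d, "v", "g")
  # hand-computed: diff -10, pooled var 4, se = 2 * sqrt(2/3)
  expect_equal(res$t, -10 / (2 * sqrt(2 / 3)), tolerance = 1e-6)
  expect_equal(res$t, -6.124, tolerance = 1e-3)
  expect_equal(res$df, 4)
  same <- tibble::tibble(g = rep(c("a", "b"), each = 3), v = rep(1:3, 2))
  res2 <- group_comparison(same, "v", "g")
  expect_equal(res2$t, 0)
  expect_equal(res2$p_value, 1)
  # degenerate: both groups constant
  constant <- tibble::tibble(g = rep(c("a", "b"), each = 2),
                             v = c(1, 1, 1, 1))
  res3 <- group_comparison(constant, "v", "g")
  expect_true(res3$degenerate)
  expect_equal(res3$p_value, 1)
  expect_error(group_comparison(d[1:3, ], "v", "g"), "two levels")
})
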