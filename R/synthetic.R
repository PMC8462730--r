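# Synthetic two-alternative forced-choice trial generator. Emulates the
# priming experiment's statistical structure - two groups (G: grating
# targets, P: plaid targets), 19 prime directions x {grating, plaid}
# primes, a direction-dependent priming bias, lapses and invalid-trial
# contamination, and a session structure that is the unit of bootstrap
# resampling - and carries its exact expected priming curves as ground
# truth.

# priming bias b(distance): +1 at 0, -1 at 180, 0 at 90
bias_shape_fun <- function(shape, slope = 20) {
  switch(shape,
    linear = function(d) (90 - d) / 90,
    sigmoid = function(d) {
      f <- function(x) 1 / (1 + exp((x - 90) / slope)) - 0.5
      f(d) / f(0)
    },
    abort("bias_shape must be 'sigmoid' or 'linear'")
  )
}

#' Configure one simulated rat
#'
#' @param animal_id Identifier string.
#' @param group `"G"` (grating targets) or `"P"` (plaid targets).
#' @param base_accuracy Accuracy under the neutral (90-degree) prime, in
#'   `(0.5, 1)`.
#' @param identity_gain Priming bias amplitude (fraction) when the prime is
#'   of the trained stimulus kind: accuracy is
#'   `base_accuracy + gain * b(distance)` with `b` running from +1
#'   (coherent) through 0 (neutral) to -1 (incoherent).
#' @param cross_gain Same, for primes of the other kind.
#' @param bias_shape `"sigmoid"` (scaled logistic in angular distance,
#'   centered at 90 degrees) or `"linear"`.
#' @param bias_slope Logistic slope in degrees (sigmoid shape only).
#' @param lapse_rate Probability a response is replaced by a coin flip.
#' @param too_fast_rate,ignored_rate Rates of injected invalid trials
#'   (reaction time below 300 ms / above 1000 ms).
#' @param n_sessions,trials_per_session Session structure.
#' @return A one-row tibble of configuration fields.
#' @seealso [simulate_cohort()]
#' @export
sim_rat_config <- function(animal_id,
                           group = c("G", "P"),
                           base_accuracy = 0.80,
                           identity_gain = 0.15,
                           cross_gain = identity_gain,
                           bias_shape = c("sigmoid", "linear"),
                           bias_slope = 20,
                           lapse_rate = 0.05,
                           too_fast_rate = 0.03,
                           ignored_rate = 0.03,
                           n_sessions = 10L,
                           trials_per_session = 300L) {
  group <- match.arg(group)
  bias_shape <- match.arg(bias_shape)
  if (base_accuracy <= 0.5 || base_accuracy >= 1) {
    abort("base_accuracy must lie in (0.5, 1)")
  }
  gains <- c(identity_gain, cross_gain)
  if (any(base_accuracy + gains > 1) || any(base_accuracy - gains < 0)) {
    abort("inconsistent probabilities: base_accuracy +/- gain outside [0, 1]")
  }
  rates <- c(lapse_rate, too_fast_rate, ignored_rate)
  if (any(rates < 0 | rates > 0.2)) {
    abort("lapse/too-fast/ignored rates must lie in [0, 0.2]")
  }
  tibble(
    animal_id = as.character(animal_id), group = group,
    base_accuracy = base_accuracy, identity_gain = identity_gain,
    cross_gain = cross_gain, bias_shape = bias_shape,
    bias_slope = bias_slope, lapse_rate = lapse_rate,
    too_fast_rate = too_fast_rate, ignored_rate = ignored_rate,
    n_sessions = as.integer(n_sessions),
    trials_per_session = as.integer(trials_per_session)
  )
}

#' Expected priming curve implied by a rat configuration
#'
#' The exact accuracy the generator targets at each prime-target distance,
#' including the flattening effect of lapses:
#' `(1 - lapse) * (base + gain * b(d)) + lapse / 2`.
#'
#' @param config A one-row tibble from [sim_rat_config()].
#' @return A tibble: `condition` (identity/cross), `distance`,
#'   `expected_accuracy`.
#' @export
expected_priming_curve <- function(config) {
  b <- bias_shape_fun(config$bias_shape, config$bias_slope)(DISTANCE_GRID)
  purrr::map_dfr(c(identity = "identity", cross = "cross"), function(cond) {
    gain <- if (cond == "identity") config$identity_gain else
      config$cross_gain
    p <- config$base_accuracy + gain * b
    tibble(
      condition = cond, distance = DISTANCE_GRID,
      expected_accuracy = (1 - config$lapse_rate) * p +
        config$lapse_rate / 2
    )
  })
}

#' Expected priming magnitude implied by a rat configuration
#'
#' The magnitude statistic ([priming_magnitude()]) evaluated on the exact
#' expected curve.
#'
#' @inheritParams expected_priming_curve
#' @param condition `"identity"` or `"cross"`.
#' @return A scalar fraction.
#' @export
expected_priming_magnitude <- function(config,
                                       condition = c("identity", "cross")) {
  condition <- match.arg(condition)
  curve <- dplyr::filter(expected_priming_curve(config),
                         .data$condition == !!condition)
  priming_magnitude(dplyr::rename(curve, accuracy = "expected_accuracy"))
}

#' Simulate a cohort of rats in the priming paradigm
#'
#' Generates one trial table for all configured animals. Per trial: target
#' direction uniform on {0, 180}; prime kind uniform on {grating, plaid};
#' prime direction uniform on the 19-point grid; the choice is correct with
#' probability `base_accuracy + gain * b(distance)` (gain by condition),
#' lapses replace the response with a coin flip, and too-fast/ignored
#' trials are injected at the configured rates with reaction times outside
#' the valid 300-1000 ms window. Deterministic under the seed.
#'
#' @param configs A tibble of rat configurations ([sim_rat_config()] rows).
#' @param seed Integer master seed (per-animal streams are derived from
#'   it).
#' @return A list with `trials` (the cohort trial table, priming phase) and
#'   `truth` (per-animal expected curves and magnitudes, the exact injected
#'   invalid-trial counts, and the configs).
#' @examples
#' cohort <- dplyr::bind_rows(
#'   sim_rat_config("r1", "G", n_sessions = 2, trials_per_session = 50),
#'   sim_rat_config("r2", "G", n_sessions = 2, trials_per_session = 50)
#' )
#' sim <- simulate_cohort(cohort, seed = 1)
#' nrow(sim$trials)
#' @export
simulate_cohort <- function(configs, seed = NULL) {
  stopifnot(is.data.frame(configs), nrow(configs) >= 1)
  seeds <- child_seeds(seed, nrow(configs))
  per_animal <- lapply(seq_len(nrow(configs)), function(i) {
    cfg <- configs[i, ]
    with_seed(if (is.null(seed)) NULL else seeds[i], {
      n <- cfg$n_sessions * cfg$trials_per_session
      target <- sample(c(0, 180), n, replace = TRUE)
      prime_kind <- sample(c("grating", "plaid"), n, replace = TRUE)
      prime_dir <- sample(DISTANCE_GRID, n, replace = TRUE)
      d <- angular_distance(prime_dir, target)
      b <- bias_shape_fun(cfg$bias_shape, cfg$bias_slope)(d)
      cond <- prime_condition(cfg$group, prime_kind)
      gain <- ifelse(cond == "identity", cfg$identity_gain, cfg$cross_gain)
      p_correct <- cfg$base_accuracy + gain * b
      correct <- runif(n) < p_correct
      lapse <- runif(n) < cfg$lapse_rate
      correct[lapse] <- runif(sum(lapse)) < 0.5
      # invalid-trial contamination, disjoint reaction-time ranges
      u <- runif(n)
      status <- ifelse(u < cfg$too_fast_rate, "too_fast",
                       ifelse(u < cfg$too_fast_rate + cfg$ignored_rate,
                              "ignored", "valid"))
      rt <- runif(n, 320, 980)
      rt[status == "too_fast"] <- runif(sum(status == "too_fast"), 100, 290)
      rt[status == "ignored"] <- runif(sum(status == "ignored"), 1050, 2000)
      right_is_correct <- target == 0
      choice <- ifelse(xor(right_is_correct, !correct), "right", "left")
      list(
        trials = tibble(
          animal_id = cfg$animal_id, group = cfg$group,
          session = rep(seq_len(cfg$n_sessions),
                        each = cfg$trials_per_session),
          phase = "priming", prime_kind = prime_kind,
          prime_direction = prime_dir, target_direction = target,
          choice = choice, reaction_time = rt, correct = correct
        ),
        injected = tibble(
          animal_id = cfg$animal_id,
          too_fast = sum(status == "too_fast"),
          ignored = sum(status == "ignored")
        )
      )
    })
  })
  trials <- purrr::map_dfr(per_animal, "trials")
  truth <- list(
    injected_invalid = purrr::map_dfr(per_animal, "injected"),
    configs = as_tibble(configs),
    expected_curves = purrr::map_dfr(seq_len(nrow(configs)), function(i) {
      dplyr::mutate(expected_priming_curve(configs[i, ]),
                    animal_id = configs$animal_id[i], .before = 1)
    }),
    expected_magnitudes = purrr::map_dfr(seq_len(nrow(configs)),
                                         function(i) {
      tibble(
        animal_id = configs$animal_id[i],
        identity = expected_priming_magnitude(configs[i, ], "identity"),
        cross = expected_priming_magnitude(configs[i, ], "cross")
      )
    }),
    seed = seed
  )
  list(trials = trials, truth = truth)
}

#' Write a trial table to CSV
#'
#' Round-trips losslessly through [read_trials()].
#'
#' @param trials A trial tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}

#' Simulate training-phase session accuracies with a learning curve
#'
#' Optional learning-curve mode of the generator: session accuracy ramps
#' exponentially from a starting level toward an asymptote, with binomial
#' trial noise, to exercise the learning-curve metrics.
#'
#' @param animal_id Identifier.
#' @param n_sessions Number of training sessions.
#' @param start_accuracy,asymptote Accuracy at session 1 and at
#'   convergence.
#' @param rate Exponential learning rate per session.
#' @param trials_per_session Trials per session (binomial sampling).
#' @param seed Integer seed.
#' @return A tibble: `animal_id`, `session`, `accuracy`.
#' @export
simulate_training_sessions <- function(animal_id, n_sessions = 30L,
                                       start_accuracy = 0.5,
                                       asymptote = 0.8, rate = 0.15,
                                       trials_per_session = 300L,
                                       seed = NULL) {
  with_seed(seed, {
    s <- seq_len(n_sessions)
    p <- asymptote - (asymptote - start_accuracy) * exp(-rate * (s - 1))
    tibble(
      animal_id = as.character(animal_id), session = s,
      accuracy = stats::rbinom(n_sessions, trials_per_session, p) /
        trials_per_session
    )
  })
}
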