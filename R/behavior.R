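# Behavioral pipeline: trial validity filtering, learning-curve metrics,
# priming curves, the priming-magnitude statistic with its 5% inclusion
# criterion, session-level bootstrap confidence intervals, and group
# comparisons.

DISTANCE_GRID <- seq(0, 180, by = 10)

trial_cols <- function() {
  readr::cols(
    animal_id = readr::col_character(),
    group = readr::col_character(),
    session = readr::col_integer(),
    phase = readr::col_character(),
    prime_kind = readr::col_character(),
    prime_direction = readr::col_double(),
    target_direction = readr::col_double(),
    choice = readr::col_character(),
    reaction_time = readr::col_double(),
    correct = readr::col_logical()
  )
}

#' Read a behavioral trial table from CSV
#'
#' One row per trial with the columns `animal_id`, `group` (G or P),
#' `session`, `phase` (training or priming), `prime_kind` (grating, plaid
#' or none), `prime_direction` (degrees, 0-180 grid, NA in training),
#' `target_direction` (0 or 180), `choice` (left, right or none),
#' `reaction_time` (ms from target onset) and `correct` (logical).
#'
#' @param path CSV file path (header mandatory).
#' @return A tibble of trials.
#' @seealso [write_trials()], [filter_trials()]
#' @export
read_trials <- function(path) {
  readr::read_csv(path, col_types = trial_cols(), progress = FALSE)
}

#' Filter behavioral trials by response-window validity
#'
#' Applies the task's trial-validity rules. In the priming phase the
#' allowed response window runs from 300 to 1000 ms after target onset:
#' reaction times below 300 ms are "too fast" (aborted) and those above
#' 1000 ms are "ignored". In the training phase the too-fast bound is the
#' same but a trial counts as ignored only when the response comes more
#' than 2 s after stimulus offset (stimulus duration 2 s, so 4000 ms after
#' onset). Trials with a missing reaction time are excluded as malformed.
#'
#' @param trials A trial tibble (see [read_trials()]).
#' @param stimulus_duration_ms Training-phase stimulus duration.
#' @return A list with `trials` (the valid subset) and `exclusions`, a
#'   tibble of counts per reason (`too_fast`, `ignored`, `malformed`).
#' @examples
#' tr <- tibble::tibble(phase = "priming", reaction_time = c(250, 500, 1200))
#' filter_trials(tr)$exclusions
#' @export
filter_trials <- function(trials, stimulus_duration_ms = 2000) {
  stopifnot(all(c("phase", "reaction_time") %in% names(trials)))
  rt <- trials$reaction_time
  reason <- rep(NA_character_, nrow(trials))
  reason[is.na(rt)] <- "malformed"
  ok <- is.na(reason)
  too_fast <- ok & rt < 300
  reason[too_fast] <- "too_fast"
  ok <- is.na(reason)
  priming <- trials$phase == "priming"
  ignored <- ok & ((priming & rt > 1000) |
                     (!priming & rt > stimulus_duration_ms + 2000))
  reason[ignored] <- "ignored"
  counts <- vapply(c("too_fast", "ignored", "malformed"),
                   function(r) sum(reason == r, na.rm = TRUE), integer(1))
  list(
    trials = as_tibble(trials[is.na(reason), , drop = FALSE]),
    exclusions = tibble(reason = names(counts), n = unname(counts))
  )
}

#' Learning-curve metrics from session-by-session accuracies
#'
#' Smooths each animal's session accuracies with a size-3 moving average
#' (edge windows shrunk to the available sessions), finds the criterion
#' session - the first session opening a run of four consecutive sessions
#' with raw accuracy at or above the criterion - and computes the
#' asymptotic performance as the mean raw accuracy from the criterion
#' session onward.
#'
#' @param sessions A tibble with `animal_id`, `session` and `accuracy`
#'   (fractions), at least 4 sessions per animal.
#' @param criterion Accuracy criterion (default 0.70).
#' @param run_length Consecutive sessions required at criterion.
#' @return A list with `curves` (per session: raw and `smoothed` accuracy)
#'   and `summary` (per animal: `criterion_session`, `asymptotic`,
#'   `reached`; `criterion_session` is NA when the criterion was never
#'   met).
#' @examples
#' s <- tibble::tibble(animal_id = "r1", session = 1:6,
#'                     accuracy = c(0.60, 0.65, 0.72, 0.71, 0.73, 0.74))
#' learning_metrics(s)$summary
#' @export
learning_metrics <- function(sessions, criterion = 0.70, run_length = 4L) {
  stopifnot(all(c("animal_id", "session", "accuracy") %in% names(sessions)))
  sessions <- dplyr::arrange(as_tibble(sessions), .data$animal_id,
                             .data$session)
  per_animal <- split(sessions, sessions$animal_id)
  curves <- purrr::map_dfr(per_animal, function(df) {
    n <- nrow(df)
    if (n < run_length) abort("each animal needs at least 4 sessions")
    acc <- df$accuracy
    df$smoothed <- vapply(seq_len(n), function(i) {
      mean(acc[max(1, i - 1):min(n, i + 1)])
    }, numeric(1))
    df
  })
  summary <- purrr::map_dfr(per_animal, function(df) {
    acc <- df$accuracy
    n <- length(acc)
    hit <- acc >= criterion
    crit_idx <- NA_integer_
    for (i in seq_len(n - run_length + 1L)) {
      if (all(hit[i:(i + run_length - 1L)])) {
        crit_idx <- i
        break
      }
    }
    tibble(
      animal_id = df$animal_id[1],
      criterion_session = if (is.na(crit_idx)) NA_integer_ else
        df$session[crit_idx],
      asymptotic = if (is.na(crit_idx)) NA_real_ else mean(acc[crit_idx:n]),
      reached = !is.na(crit_idx)
    )
  })
  list(curves = curves, summary = summary)
}

# fast accuracy-by-distance on the 19-point grid; returns acc (NA for
# empty bins) and n
curve_counts <- function(distance, correct) {
  idx <- match(distance, DISTANCE_GRID)
  n <- tabulate(idx, nbins = length(DISTANCE_GRID))
  k <- tabulate(idx[correct], nbins = length(DISTANCE_GRID))
  acc <- ifelse(n > 0, k / n, NA_real_)
  list(accuracy = acc, n = n)
}

#' Priming curve of one set of trials
#'
#' Bins trials by the angular distance between prime and target drift
#' directions (0 to 180 degrees in steps of 10; both targets pooled, so
#' distance 0 is the coherent condition, 180 the incoherent one and 90 the
#' neutral vertical prime) and reports the fraction of correct choices per
#' bin. Empty bins propagate as `NA`, never as zero.
#'
#' @param trials Valid priming-phase trials of one animal and one prime
#'   kind (filter beforehand; the function uses all rows it is given).
#' @return A tibble of class `priming_curve`: `distance`, `accuracy`,
#'   `n_trials`.
#' @seealso [priming_magnitude()], [bootstrap_group_curves()]
#' @export
priming_curve <- function(trials) {
  stopifnot(all(c("prime_direction", "target_direction", "correct")
                %in% names(trials)))
  d <- angular_distance(trials$prime_direction, trials$target_direction)
  cc <- curve_counts(d, trials$correct)
  out <- tibble(distance = DISTANCE_GRID, accuracy = cc$accuracy,
                n_trials = cc$n)
  class(out) <- c("priming_curve", class(out))
  out
}

#' Priming magnitude of a curve
#'
#' The mean, over the four most-coherent (distances 0-30) and four
#' most-incoherent (150-180) points of the curve, of the absolute
#' difference between the point's accuracy and the animal's own
#' neutral-condition (90-degree) accuracy. Animals whose identity-priming
#' magnitude falls below 0.05 (5 percentage points) are excluded from group
#' analyses.
#'
#' @param curve A tibble from [priming_curve()] (or any tibble with
#'   `distance` and `accuracy`); the neutral bin and all eight extreme
#'   points must be defined.
#' @return The magnitude as a fraction (non-negative).
#' @export
priming_magnitude <- function(curve) {
  acc <- curve$accuracy[match(DISTANCE_GRID, curve$distance)]
  neutral <- acc[DISTANCE_GRID == 90]
  if (is.na(neutral)) abort("neutral (90-degree) bin is undefined")
  extremes <- acc[DISTANCE_GRID <= 30 | DISTANCE_GRID >= 150]
  if (any(is.na(extremes))) {
    abort("priming magnitude needs all four extreme points on each side")
  }
  mean(abs(extremes - neutral))
}

# identity/cross condition of a prime given the animal's trained target
prime_condition <- function(group, prime_kind) {
  target_kind <- ifelse(group == "G", "grating", "plaid")
  ifelse(prime_kind == target_kind, "identity", "cross")
}

#' Per-animal identity-priming magnitudes and the inclusion criterion
#'
#' @param trials Valid priming trials with `animal_id`, `group`,
#'   `prime_kind` columns.
#' @param threshold Inclusion threshold on the identity-priming magnitude
#'   (default 0.05, i.e. 5 percentage points).
#' @return A tibble: `animal_id`, `group`, `identity_magnitude`,
#'   `included`.
#' @export
animal_inclusion <- function(trials, threshold = 0.05) {
  trials <- dplyr::mutate(as_tibble(trials),
                          condition = prime_condition(.data$group,
                                                      .data$prime_kind))
  ident <- dplyr::filter(trials, .data$condition == "identity")
  purrr::map_dfr(split(ident, ident$animal_id), function(df) {
    tibble(
      animal_id = df$animal_id[1],
      group = df$group[1],
      identity_magnitude = priming_magnitude(priming_curve(df)),
      included = NA
    )
  }) %>%
    dplyr::mutate(included = .data$identity_magnitude >= threshold)
}

# per-animal curves and magnitudes for one (possibly resampled) trial set;
# trials must carry precomputed `distance` and `condition`
animal_curves_magnitudes <- function(d, correct, condition) {
  out <- list()
  for (cond in c("identity", "cross")) {
    sel <- condition == cond
    cc <- curve_counts(d[sel], correct[sel])
    neutral <- cc$accuracy[DISTANCE_GRID == 90]
    ext <- cc$accuracy[DISTANCE_GRID <= 30 | DISTANCE_GRID >= 150]
    out[[cond]] <- list(
      accuracy = cc$accuracy,
      magnitude = if (is.na(neutral) || any(is.na(ext))) NA_real_ else
        mean(abs(ext - neutral)),
      neutral = neutral
    )
  }
  out
}

#' Session-level bootstrap of group priming curves and magnitudes
#'
#' For each bootstrap replicate, every animal's sessions are independently
#' resampled with replacement, the animal's identity- and cross-priming
#' curves and magnitudes are recomputed from the resampled trials, and
#' animals are averaged with equal weights into group curves. Bootstrap
#' standard deviations then give normal confidence intervals
#' (`mean +/- z * SD`): for the 19 curve points the critical value is
#' Bonferroni-adjusted over `bonferroni_m` comparisons, while scalar
#' magnitudes use the unadjusted value. With two groups present, the
#' between-group differences in identity-priming magnitude and neutral
#' accuracy are also estimated from the bootstrap distribution of
#' differences.
#'
#' Confidence bounds are reported as computed - normal CIs on accuracies
#' may exceed `[0, 1]`; they are flagged, not clipped.
#'
#' @param trials Valid priming trials (`animal_id`, `group`, `session`,
#'   `prime_kind`, `prime_direction`, `target_direction`, `correct`), at
#'   least 2 animals.
#' @param n_reps Bootstrap replicates (default 50).
#' @param ci_level Confidence level (default 0.95).
#' @param bonferroni_m Number of comparisons for curve-point CIs (default
#'   19, one per curve point).
#' @param seed Integer seed.
#' @return A `priming_bootstrap` list: `curves` (group, condition,
#'   distance, accuracy, boot_sd, ci_low, ci_high), `magnitudes` (group,
#'   condition, magnitude, boot_sd, ci_low, ci_high), `condition_diff`
#'   (identity minus cross magnitude per group, with CI), `group_diff`
#'   (between-group differences, when two groups are present), `settings`,
#'   and `ci_out_of_bounds` (flag).
#' @export
bootstrap_group_curves <- function(trials, n_reps = 50, ci_level = 0.95,
                                   bonferroni_m = 19L, seed = NULL) {
  if (n_reps < 2) abort("n_reps must be at least 2")
  trials <- as_tibble(trials)
  trials$distance <- angular_distance(trials$prime_direction,
                                      trials$target_direction)
  trials$condition <- prime_condition(trials$group, trials$prime_kind)
  groups <- sort(unique(trials$group))
  animals <- unique(trials[, c("animal_id", "group")])
  if (nrow(animals) < 2) abort("bootstrap needs at least 2 animals")

  # per-animal precomputation: session -> trial rows
  per_animal <- lapply(seq_len(nrow(animals)), function(i) {
    df <- trials[trials$animal_id == animals$animal_id[i], ]
    sess <- split(seq_len(nrow(df)), df$session)
    if (length(sess) < 2) {
      warn(sprintf("animal %s has a single session: resampling degenerates",
                   animals$animal_id[i]))
    }
    list(d = df$distance, correct = df$correct, condition = df$condition,
         sessions = sess, group = animals$group[i])
  })

  alpha <- 1 - ci_level
  z_curve <- qnorm(1 - alpha / (2 * bonferroni_m))
  z_scalar <- qnorm(1 - alpha / 2)
  n_pt <- length(DISTANCE_GRID)

  point <- lapply(per_animal, function(a) {
    animal_curves_magnitudes(a$d, a$correct, a$condition)
  })

  seeds <- child_seeds(seed, n_reps)
  boot <- lapply(seq_len(n_reps), function(r) {
    with_seed(if (is.null(seed)) NULL else seeds[r], {
      lapply(per_animal, function(a) {
        take <- unlist(a$sessions[sample.int(length(a$sessions),
                                             length(a$sessions),
                                             replace = TRUE)],
                       use.names = FALSE)
        animal_curves_magnitudes(a$d[take], a$correct[take],
                                 a$condition[take])
      })
    })
  })

  group_stat <- function(res_list, grp, cond, what) {
    vals <- vapply(which(animals$group == grp), function(i) {
      v <- res_list[[i]][[cond]][[what]]
      if (what == "accuracy") v else as.numeric(v)
    }, if (what == "accuracy") numeric(n_pt) else numeric(1))
    if (what == "accuracy") rowMeans(as.matrix(vals), na.rm = TRUE)
    else mean(vals, na.rm = TRUE)
  }

  curves <- list()
  mags <- list()
  cdiff <- list()
  boot_store <- list()
  for (grp in groups) {
    for (cond in c("identity", "cross")) {
      est <- group_stat(point, grp, cond, "accuracy")
      bmat <- vapply(boot, group_stat, numeric(n_pt), grp = grp,
                     cond = cond, what = "accuracy")
      bsd <- apply(bmat, 1, sd)
      curves[[paste(grp, cond)]] <- tibble(
        group = grp, condition = cond, distance = DISTANCE_GRID,
        accuracy = est, boot_sd = bsd,
        ci_low = est - z_curve * bsd, ci_high = est + z_curve * bsd
      )
      mag_est <- group_stat(point, grp, cond, "magnitude")
      mag_boot <- vapply(boot, group_stat, numeric(1), grp = grp,
                         cond = cond, what = "magnitude")
      mags[[paste(grp, cond)]] <- tibble(
        group = grp, condition = cond, magnitude = mag_est,
        boot_sd = sd(mag_boot),
        ci_low = mag_est - z_scalar * sd(mag_boot),
        ci_high = mag_est + z_scalar * sd(mag_boot)
      )
      boot_store[[paste(grp, cond, "mag")]] <- mag_boot
      boot_store[[paste(grp, cond, "neutral")]] <-
        vapply(boot, group_stat, numeric(1), grp = grp, cond = cond,
               what = "neutral")
    }
    dd <- boot_store[[paste(grp, "identity", "mag")]] -
      boot_store[[paste(grp, "cross", "mag")]]
    est_d <- group_stat(point, grp, "identity", "magnitude") -
      group_stat(point, grp, "cross", "magnitude")
    cdiff[[grp]] <- tibble(
      group = grp, difference = est_d, boot_sd = sd(dd),
      ci_low = est_d - z_scalar * sd(dd),
      ci_high = est_d + z_scalar * sd(dd)
    )
  }

  group_diff <- NULL
  if (length(groups) == 2) {
    g1 <- groups[1]
    g2 <- groups[2]
    mk <- function(what) {
      d_boot <- boot_store[[paste(g1, "identity", what)]] -
        boot_store[[paste(g2, "identity", what)]]
      est <- if (what == "mag") {
        group_stat(point, g1, "identity", "magnitude") -
          group_stat(point, g2, "identity", "magnitude")
      } else {
        group_stat(point, g1, "identity", "neutral") -
          group_stat(point, g2, "identity", "neutral")
      }
      tibble(
        quantity = if (what == "mag") "identity_magnitude" else
          "neutral_accuracy",
        comparison = paste(g1, "-", g2), estimate = est,
        boot_sd = sd(d_boot), ci_low = est - z_scalar * sd(d_boot),
        ci_high = est + z_scalar * sd(d_boot)
      )
    }
    group_diff <- bind_rows(mk("mag"), mk("neutral"))
  }

  curves <- bind_rows(curves)
  out <- structure(
    list(
      curves = curves,
      magnitudes = bind_rows(mags),
      condition_diff = bind_rows(cdiff),
      group_diff = group_diff,
      settings = list(n_reps = n_reps, ci_level = ci_level,
                      bonferroni_m = bonferroni_m, seed = seed),
      ci_out_of_bounds = any(curves$ci_low < 0 | curves$ci_high > 1,
                             na.rm = TRUE)
    ),
    class = "priming_bootstrap"
  )
  out
}

#' @export
print.priming_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<priming_bootstrap> %d replicates, %d group(s), %.0f%% normal CIs (Bonferroni m = %d on curve points)\n",
    x$settings$n_reps, length(unique(x$curves$group)),
    100 * x$settings$ci_level, x$settings$bonferroni_m
  ))
  print(x$magnitudes)
  invisible(x)
}

#' Unpaired two-tailed t-test between two groups of animals
#'
#' Pooled-variance (equal-variance) unpaired t-test on a per-animal metric
#' such as sessions-to-criterion or asymptotic performance. Degenerate
#' inputs (both groups constant) are reported with an infinite or NaN
#' statistic and flagged rather than raising.
#'
#' @param data A tibble with one row per animal.
#' @param value Column name (string) of the metric.
#' @param group Column name (string) of the group label (two levels).
#' @return A one-row tibble: group means, `t`, `df`, `p_value`,
#'   `degenerate`.
#' @examples
#' d <- tibble::tibble(g = rep(c("G", "P"), each = 3),
#'                     v = c(70, 72, 74, 80, 82, 84))
#' group_comparison(d, "v", "g")
#' @export
group_comparison <- function(data, value, group) {
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) != 2) abort("group column must have exactly two levels")
  if (any(table(g) < 2)) abort("each group needs at least 2 animals")
  v1 <- v[g == levels(g)[1]]
  v2 <- v[g == levels(g)[2]]
  res <- tryCatch(
    t.test(v1, v2, var.equal = TRUE),
    error = function(e) NULL
  )
  if (is.null(res)) {
    diff <- mean(v1) - mean(v2)
    t_stat <- if (diff == 0) NaN else sign(diff) * Inf
    return(tibble(
      mean_1 = mean(v1), mean_2 = mean(v2), t = t_stat,
      df = length(v) - 2, p_value = if (diff == 0) 1 else 0,
      degenerate = TRUE
    ))
  }
  tibble(
    mean_1 = mean(v1), mean_2 = mean(v2),
    t = unname(res$statistic), df = unname(res$parameter),
    p_value = res$p.value, degenerate = FALSE
  )
}
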