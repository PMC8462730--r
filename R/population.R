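# Population construction: selectivity indices, calibration of the Von
# Mises concentration to target OSI/DSI distributions, and seeded sampling
# of mixed component/pattern populations.

#' Orientation and direction selectivity of simulated cells
#'
#' OSI contrasts the evoked response at the preferred direction with the
#' mean evoked response at the two orthogonal directions (pref +/- 90);
#' DSI contrasts preferred with opposite (pref + 180):
#' `OSI = (R_pref - R_orth) / (R_pref + R_orth)`,
#' `DSI = (R_pref - R_null) / (R_pref + R_null)`.
#' Both are computed on the noise-free, baseline-subtracted (evoked)
#' grating tuning, the convention under which a sharply tuned cell
#' approaches 1 regardless of its background rate. An untuned cell
#' (zero evoked amplitude but positive baseline) has OSI = DSI = 0; a cell
#' with no response at all is degenerate and raises an error.
#'
#' @inheritParams grating_tuning
#' @return A tibble with one row per cell: `osi`, `dsi`, both in `[0, 1]`
#'   when `anti_pref_amplitude <= amplitude`.
#' @examples
#' compute_osi_dsi(cell_tuning(k = 7, amplitude = 1, baseline = 0.1))
#' @export
compute_osi_dsi <- function(cells) {
  cells <- validate_cells(cells)
  if (any(cells$amplitude == 0 & cells$baseline == 0)) {
    abort("degenerate cell: zero response everywhere, selectivity undefined")
  }
  x2 <- vm_lobe(180, cells$k)          # exp(-2k)
  x1 <- vm_lobe(90, cells$k)           # exp(-k)
  a_main <- cells$amplitude
  a_anti <- cells$anti_pref_amplitude
  r_pref <- a_main + a_anti * x2
  r_orth <- (a_main + a_anti) * x1
  r_null <- a_anti + a_main * x2
  osi <- ifelse(r_pref + r_orth > 0, (r_pref - r_orth) / (r_pref + r_orth), 0)
  dsi <- ifelse(r_pref + r_null > 0, (r_pref - r_null) / (r_pref + r_null), 0)
  tibble(osi = osi, dsi = dsi)
}

# OSI/DSI of a (k, anti-ratio r) pair in closed form; x = exp(-k)
osi_of <- function(k, r) {
  x <- exp(-k)
  num <- 1 + r * x^2 - (1 + r) * x
  den <- 1 + r * x^2 + (1 + r) * x
  num / den
}
dsi_of <- function(k, r) {
  x2 <- exp(-2 * k)
  ((1 - r) * (1 - x2)) / ((1 + r) * (1 + x2))
}

#' Solve for tuning parameters matching target selectivity indices
#'
#' Numerically inverts [compute_osi_dsi()]: finds the concentration `k` and
#' the anti-preferred lobe amplitude such that a cell attains the requested
#' OSI and DSI. A single Von Mises lobe cannot set both indices
#' independently, so the secondary lobe at `pref + 180` (amplitude ratio
#' started at `(1 - DSI) / (1 + DSI)` and refined) carries the DSI degree of
#' freedom. Root finding alternates a bisection for `k` (OSI is strictly
#' increasing in `k`) with the closed-form ratio update until both indices
#' match within `tol`.
#'
#' When a DSI target exceeds what the solved tuning width allows
#' (`(1 - exp(-2k)) / (1 + exp(-2k))`, approached as the anti-lobe vanishes),
#' the cell is returned at the maximum achievable DSI with `feasible = FALSE`
#' and a warning.
#'
#' @param osi_target,dsi_target Numeric vectors (recycled): OSI in `(0, 1)`,
#'   DSI in `[0, 1)`.
#' @param amplitude,baseline Cell amplitude and baseline used to scale the
#'   returned anti-lobe amplitude (the indices themselves depend only on
#'   tuning shape).
#' @param tol Convergence tolerance on both indices.
#' @return A tibble with one row per target pair: `k`,
#'   `anti_pref_amplitude`, `osi_achieved`, `dsi_achieved`, `feasible`.
#' @examples
#' calibrate_k(0.7, 0.6, amplitude = 8, baseline = 2)
#' @export
calibrate_k <- function(osi_target, dsi_target, amplitude = 1, baseline = 0,
                        tol = 1e-6) {
  n <- max(length(osi_target), length(dsi_target), length(amplitude))
  osi_target <- rep_len(osi_target, n)
  dsi_target <- rep_len(dsi_target, n)
  amplitude <- rep_len(amplitude, n)
  if (any(osi_target <= 0 | osi_target >= 1)) {
    abort("osi_target must lie strictly in (0, 1)")
  }
  if (any(dsi_target < 0 | dsi_target >= 1)) {
    abort("dsi_target must lie in [0, 1)")
  }
  one <- function(o, d) {
    r <- (1 - d) / (1 + d)
    k <- NA_real_
    feasible <- TRUE
    for (i in seq_len(100)) {
      k <- uniroot(function(kk) osi_of(kk, r) - o,
                   lower = 1e-8, upper = 500, tol = 1e-12)$root
      q <- dsi_of(k, 0)                 # max DSI at this width
      if (q < d) {
        feasible <- FALSE
        r_new <- 0
      } else {
        r_new <- (q - d) / (q + d)
      }
      if (abs(r_new - r) < tol / 10) {
        r <- r_new
        break
      }
      r <- r_new
    }
    k <- uniroot(function(kk) osi_of(kk, r) - o,
                 lower = 1e-8, upper = 500, tol = 1e-12)$root
    c(k = k, r = r, osi = osi_of(k, r), dsi = dsi_of(k, r),
      feasible = as.numeric(feasible))
  }
  res <- t(vapply(seq_len(n), function(i) one(osi_target[i], dsi_target[i]),
                  numeric(5)))
  if (any(res[, "feasible"] == 0)) {
    warn(sprintf(
      "%d target(s) infeasible: DSI capped at the maximum achievable value",
      sum(res[, "feasible"] == 0)
    ))
  }
  tibble(
    k = unname(res[, "k"]),
    anti_pref_amplitude = unname(res[, "r"]) * amplitude,
    osi_achieved = unname(res[, "osi"]),
    dsi_achieved = unname(res[, "dsi"]),
    feasible = unname(res[, "feasible"]) == 1
  )
}

#' Configure a simulated population of direction-tuned cells
#'
#' Two parameterization modes are supported. With a fixed `k`, every cell
#' shares the same tuning width and has no anti-preferred lobe (the 24-cell
#' representation: equispaced preferred directions, peak 1, peak-to-baseline
#' ratio 10). With OSI/DSI targets, each cell's width and anti-lobe are
#' calibrated so the population's selectivity indices follow the requested
#' Gaussians (the 1000-cell representation: uniform-random preferred
#' directions, amplitudes N(8, 1) spikes/s, baseline 2 spikes/s).
#'
#' @param n_cells Number of cells (>= 2).
#' @param fraction_component Fraction of component cells in `[0, 1]`; the
#'   rest are pattern cells.
#' @param pref_direction_scheme `"equispaced"` (360/n apart, starting at 0)
#'   or `"uniform_random"`.
#' @param amplitude Length-1 (fixed) or length-2 `(mean, sd)` normal
#'   specification of peak evoked response, truncated at 0.
#' @param baseline Background response, same units.
#' @param trial_noise_sd Standard deviation of per-trial Gaussian response
#'   noise, carried along for [sample_responses()].
#' @param k Fixed concentration, or `NULL` to calibrate from targets.
#' @param osi_target,dsi_target Length-2 `(mean, sd)` Gaussian targets for
#'   the selectivity indices (used when `k` is `NULL`).
#' @param component_plaid_suppression,pattern_plaid_suppression
#'   Cross-orientation suppression factors by class (1 = none).
#' @param pattern_plaid_k_divisor Broadening of pattern-cell plaid tuning.
#' @param seed Integer seed for [sample_population()].
#' @return A `population_config` list.
#' @export
population_config <- function(n_cells,
                              fraction_component = 1,
                              pref_direction_scheme = c("equispaced",
                                                        "uniform_random"),
                              amplitude = 1,
                              baseline = 0,
                              trial_noise_sd = 0,
                              k = NULL,
                              osi_target = c(0.7, 0.1),
                              dsi_target = c(0.6, 0.2),
                              component_plaid_suppression = 1,
                              pattern_plaid_suppression = 1,
                              pattern_plaid_k_divisor = 1,
                              seed = NULL) {
  pref_direction_scheme <- match.arg(pref_direction_scheme)
  if (n_cells < 2) abort("a population needs at least 2 cells")
  if (fraction_component < 0 || fraction_component > 1) {
    abort("fraction_component must lie in [0, 1]")
  }
  if (trial_noise_sd < 0) abort("trial_noise_sd must be non-negative")
  structure(
    list(
      n_cells = as.integer(n_cells),
      fraction_component = fraction_component,
      pref_direction_scheme = pref_direction_scheme,
      amplitude = amplitude,
      baseline = baseline,
      trial_noise_sd = trial_noise_sd,
      k = k,
      osi_target = osi_target,
      dsi_target = dsi_target,
      component_plaid_suppression = component_plaid_suppression,
      pattern_plaid_suppression = pattern_plaid_suppression,
      pattern_plaid_k_divisor = pattern_plaid_k_divisor,
      seed = seed
    ),
    class = "population_config"
  )
}

#' Draw a population of cells from a configuration
#'
#' Deterministic under the config's seed: the same configuration always
#' yields the same population. Class labels are assigned at random (so
#' class and preferred direction are uncorrelated), with counts matching
#' `fraction_component * n_cells` after rounding.
#'
#' @param config A [population_config()].
#' @return A cell tibble (one row per cell) with `cell_id`, tuning fields,
#'   and - in calibrated mode - the achieved `osi`/`dsi`. The config is
#'   attached as attribute `"config"`.
#' @examples
#' cfg <- population_config(24, k = 7, amplitude = 1, baseline = 0.1)
#' sample_population(cfg)
#' @export
sample_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n_cells
  n_comp <- round(config$fraction_component * n)
  with_seed(config$seed, {
    classes <- rep("pattern", n)
    classes[sample.int(n, n_comp)] <- "component"
    prefs <- switch(config$pref_direction_scheme,
      equispaced = seq(0, 360 - 360 / n, by = 360 / n),
      uniform_random = runif(n, 0, 360)
    )
    amp_spec <- config$amplitude
    if (length(amp_spec) == 1) {
      amps <- rep(amp_spec, n)
    } else {
      amps <- rnorm(n, amp_spec[1], amp_spec[2])
      while (any(amps <= 0)) {          # truncate the normal at zero
        bad <- amps <= 0
        amps[bad] <- rnorm(sum(bad), amp_spec[1], amp_spec[2])
      }
    }
    if (!is.null(config$k)) {
      k <- rep(config$k, n)
      anti <- rep(0, n)
    } else {
      osi <- pmin(pmax(rnorm(n, config$osi_target[1], config$osi_target[2]),
                       0.02), 0.98)
      dsi <- pmin(pmax(rnorm(n, config$dsi_target[1], config$dsi_target[2]),
                       0), 0.98)
      cal <- calibrate_k(osi, dsi, amplitude = amps)
      k <- cal$k
      anti <- cal$anti_pref_amplitude
    }
    cells <- tibble(
      cell_id = seq_len(n),
      cell_class = classes,
      pref_direction = wrap_direction(prefs),
      k = k,
      amplitude = amps,
      baseline = config$baseline,
      anti_pref_amplitude = anti,
      plaid_k_divisor = ifelse(classes == "pattern",
                               config$pattern_plaid_k_divisor, 1),
      plaid_suppression = ifelse(classes == "component",
                                 config$component_plaid_suppression,
                                 config$pattern_plaid_suppression)
    )
    cells <- validate_cells(cells)
    attr(cells, "config") <- config
    cells
  })
}
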