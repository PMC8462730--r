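# Config-driven scenario recipes. Each scenario reproduces one complete
# simulation or analysis end to end - population construction, readout
# training, test curves, derived statistics - as a named, seeded,
# overridable run that emits tabular results plus a JSON-able summary and
# a reproducibility manifest.

SCENARIOS <- c(
  "component_readout",        # 24 equispaced component cells, plaid-trained
  "pattern_readout",          # 24 equispaced pattern cells, plaid-trained
  "tuning_width_sweep",       # component readout across k values
  "grating_trained_readout",  # both 24-cell representations, grating-trained
  "mixed_pool_pruning",       # 1000-cell mixed pool, suppression + pruning
  "pruning_no_suppression",   # control: same pool without suppression
  "homeostatic_norm",         # pattern-only pool, L2 homeostasis analysis
  "behavior_synthetic",       # generate a synthetic priming cohort
  "behavior_analysis"         # full behavioral pipeline on a trial table
)

#' Default parameters of a named scenario
#'
#' @param scenario One of `"component_readout"`, `"pattern_readout"`,
#'   `"tuning_width_sweep"`, `"grating_trained_readout"`,
#'   `"mixed_pool_pruning"`, `"pruning_no_suppression"`,
#'   `"homeostatic_norm"`, `"behavior_synthetic"`, `"behavior_analysis"`.
#' @return A named list of parameters that [run_scenario()] will use; any
#'   element can be overridden.
#' @export
scenario_defaults <- function(scenario) {
  scenario <- match.arg(scenario, SCENARIOS)
  small <- list(
    n_cells = 24L, k = 7, amplitude = 1, baseline = 0.1,
    noise_sd = 0.25, cross_angle = 120, lambda = 1,
    n_train = 500L, n_test_reps = 500L,
    directions = seq(0, 345, by = 15)
  )
  cortical <- list(
    n_cells = 1000L, fraction_component = 0.8,
    amplitude = c(8, 1), baseline = 2, noise_sd = 2,
    osi_target = c(0.7, 0.1), dsi_target = c(0.6, 0.2),
    component_plaid_suppression = 0.5, pattern_plaid_suppression = 1,
    pattern_plaid_k_divisor = 4, cross_angle = 120, lambda = 1,
    n_train = 200L, n_heldout = 200L,
    quantiles = seq(0, 0.9, by = 0.1)
  )
  switch(scenario,
    component_readout = c(small, list(cell_class = "component",
                                      train_kind = "plaid")),
    pattern_readout = c(small, list(cell_class = "pattern",
                                    train_kind = "plaid")),
    tuning_width_sweep = c(small, list(cell_class = "component",
                                       train_kind = "plaid",
                                       k_values = c(0.5, 1, 3, 5, 7, 9, 11))),
    grating_trained_readout = c(small, list(train_kind = "grating")),
    mixed_pool_pruning = c(cortical, list(train_kind = "plaid")),
    pruning_no_suppression = utils::modifyList(
      c(cortical, list(train_kind = "plaid")),
      list(component_plaid_suppression = 1)
    ),
    homeostatic_norm = utils::modifyList(
      cortical,
      list(fraction_component = 0, pattern_plaid_suppression = 0.25,
           n_evidence_reps = 200L, directions = seq(0, 345, by = 15))
    ),
    behavior_synthetic = list(
      n_g = 11L, n_p = 10L, base_accuracy = 0.80,
      identity_gain = 0.15, cross_gain_g = 0.01, cross_gain_p = 0.15,
      lapse_rate = 0.05, too_fast_rate = 0.03, ignored_rate = 0.03,
      n_sessions = 10L, trials_per_session = 300L
    ),
    behavior_analysis = list(
      trials = NULL, trials_path = NULL,
      n_boot = 50L, ci_level = 0.95, bonferroni_m = 19L,
      inclusion_threshold = 0.05
    )
  )
}

# one 24-cell equispaced representation + trained readout + both test
# curves; shared by the small-population scenarios
run_small_readout <- function(p, cell_class, train_kind, seed) {
  seeds <- child_seeds(seed, 4)
  cfg <- population_config(
    n_cells = p$n_cells, fraction_component = as.numeric(cell_class ==
                                                           "component"),
    pref_direction_scheme = "equispaced", amplitude = p$amplitude,
    baseline = p$baseline, trial_noise_sd = p$noise_sd, k = p$k,
    seed = seeds[1]
  )
  cells <- sample_population(cfg)
  train <- sample_responses(cells, stimulus_spec(train_kind, c(0, 180),
                                                 p$cross_angle),
                            n_reps = p$n_train, noise_sd = p$noise_sd,
                            seed = seeds[2])
  model <- train_readout(train, lambda = p$lambda)
  curves <- bind_rows(
    generalization_curve(model, cells, "plaid", p$directions,
                         p$n_test_reps, p$noise_sd, seed = seeds[3],
                         cross_angle = p$cross_angle),
    generalization_curve(model, cells, "grating", p$directions,
                         p$n_test_reps, p$noise_sd, seed = seeds[4])
  )
  list(cells = cells, model = model, curves = curves)
}

curve_of <- function(curves, kind) {
  curves[curves$stimulus_kind == kind, , drop = FALSE]
}

# direction of the local maximum of the plaid curve strictly inside
# (60, 180) on the test grid
local_max_direction <- function(curve, lower = 60, upper = 180) {
  inside <- curve$direction > lower & curve$direction < upper
  curve$direction[inside][which.max(curve$prop_rightward[inside])]
}

#' Run a named simulation or analysis scenario
#'
#' Executes one complete recipe with seeded determinism: the same
#' `scenario`, `overrides` and `seed` always produce the same result
#' bundle. When `out_dir` is given, tabular results are written as CSV,
#' the summary as JSON, and a manifest (configuration hash, seed, package
#' version) sufficient to reproduce the bundle.
#'
#' @param scenario Scenario name; see [scenario_defaults()].
#' @param overrides Named list of parameter overrides.
#' @param seed Integer seed driving every random draw in the run.
#' @param out_dir Optional output directory.
#' @return A list of class `scenario_result`: the scenario's tables and
#'   fitted objects, a `summary` list of its headline numbers, and the
#'   `manifest`.
#' @examples
#' \donttest{
#' res <- run_scenario("pattern_readout", seed = 1)
#' res$summary$divergence_grating_plaid
#' }
#' @export
run_scenario <- function(scenario, overrides = list(), seed = 1,
                         out_dir = NULL) {
  scenario <- match.arg(scenario, SCENARIOS)
  p <- scenario_defaults(scenario)
  unknown <- setdiff(names(overrides), c(names(p), "trials", "trials_path"))
  if (length(unknown) > 0) {
    abort(paste0("unknown override(s) for ", scenario, ": ",
                 paste(unknown, collapse = ", ")))
  }
  p <- utils::modifyList(p, overrides)
  res <- switch(scenario,
    component_readout = ,
    pattern_readout = {
      cell_class <- p$cell_class
      r <- run_small_readout(p, cell_class, p$train_kind, seed)
      plaid <- curve_of(r$curves, "plaid")
      grating <- curve_of(r$curves, "grating")
      w <- tidy(r$model)
      r$summary <- list(
        cell_class = cell_class,
        train_accuracy = r$model$train_accuracy,
        prop_rightward_plaid_0 = plaid$prop_rightward[plaid$direction == 0],
        prop_rightward_plaid_60 = plaid$prop_rightward[plaid$direction == 60],
        local_max_direction = local_max_direction(plaid),
        divergence_grating_plaid = curve_divergence(plaid, grating),
        top_positive_pref = sort(w$pref_direction[order(-w$weight)[1:2]]),
        top_negative_pref = sort(w$pref_direction[order(w$weight)[1:2]])
      )
      r
    },
    tuning_width_sweep = {
      seeds <- child_seeds(seed, length(p$k_values))
      sweep_tbl <- purrr::map_dfr(seq_along(p$k_values), function(i) {
        pk <- utils::modifyList(p, list(k = p$k_values[i]))
        r <- run_small_readout(pk, p$cell_class, p$train_kind, seeds[i])
        tibble(
          k = p$k_values[i],
          fwhm = fwhm_von_mises(p$k_values[i]),
          divergence = curve_divergence(curve_of(r$curves, "plaid"),
                                        curve_of(r$curves, "grating"))
        )
      })
      list(sweep = sweep_tbl,
           summary = list(
             k_values = sweep_tbl$k,
             divergences = sweep_tbl$divergence,
             divergence_at_max_k = sweep_tbl$divergence[nrow(sweep_tbl)],
             divergence_at_min_k = sweep_tbl$divergence[1]
           ))
    },
    grating_trained_readout = {
      seeds <- child_seeds(seed, 2)
      out <- lapply(c(component = "component", pattern = "pattern"),
                    function(cl) {
        i <- if (cl == "component") 1 else 2
        run_small_readout(p, cl, "grating", seeds[i])
      })
      list(
        component = out$component, pattern = out$pattern,
        summary = list(
          component_divergence = curve_divergence(
            curve_of(out$component$curves, "plaid"),
            curve_of(out$component$curves, "grating")
          ),
          pattern_divergence = curve_divergence(
            curve_of(out$pattern$curves, "plaid"),
            curve_of(out$pattern$curves, "grating")
          ),
          component_plaid_peak = local_max_direction(
            curve_of(out$component$curves, "plaid"), 0, 120
          )
        )
      )
    },
    mixed_pool_pruning = ,
    pruning_no_suppression = {
      seeds <- child_seeds(seed, 3)
      cfg <- population_config(
        n_cells = p$n_cells, fraction_component = p$fraction_component,
        pref_direction_scheme = "uniform_random", amplitude = p$amplitude,
        baseline = p$baseline, trial_noise_sd = p$noise_sd,
        osi_target = p$osi_target, dsi_target = p$dsi_target,
        component_plaid_suppression = p$component_plaid_suppression,
        pattern_plaid_suppression = p$pattern_plaid_suppression,
        pattern_plaid_k_divisor = p$pattern_plaid_k_divisor,
        seed = seeds[1]
      )
      cells <- sample_population(cfg)
      train <- sample_responses(cells,
                                stimulus_spec(p$train_kind, c(0, 180),
                                              p$cross_angle),
                                n_reps = p$n_train, noise_sd = p$noise_sd,
                                seed = seeds[2])
      model <- train_readout(train, lambda = p$lambda)
      heldout <- sample_responses(cells,
                                  stimulus_spec(p$train_kind, c(0, 180),
                                                p$cross_angle),
                                  n_reps = p$n_heldout,
                                  noise_sd = p$noise_sd, seed = seeds[3])
      profile <- pruning_profile(model, p$quantiles)
      reversal <- profile$quantile[profile$fraction_pattern >=
                                     profile$fraction_component]
      list(
        cells = cells, model = model, profile = profile,
        summary = list(
          train_accuracy = model$train_accuracy,
          heldout_accuracy = readout_accuracy(model, heldout),
          reversal_quantile = if (length(reversal) > 0) min(reversal) else
            NA_real_,
          max_component_fraction_shift = max(abs(
            profile$fraction_component - p$fraction_component
          ))
        )
      )
    },
    homeostatic_norm = {
      seeds <- child_seeds(seed, 8)
      cfg <- population_config(
        n_cells = p$n_cells, fraction_component = 0,
        pref_direction_scheme = "uniform_random", amplitude = p$amplitude,
        baseline = p$baseline, trial_noise_sd = p$noise_sd,
        osi_target = p$osi_target, dsi_target = p$dsi_target,
        pattern_plaid_suppression = p$pattern_plaid_suppression,
        pattern_plaid_k_divisor = p$pattern_plaid_k_divisor,
        seed = seeds[1]
      )
      cells <- sample_population(cfg)
      models <- lapply(c(grating = "grating", plaid = "plaid"),
                       function(kind) {
        i <- if (kind == "grating") 2 else 3
        train <- sample_responses(cells,
                                  stimulus_spec(kind, c(0, 180),
                                                p$cross_angle),
                                  n_reps = p$n_train,
                                  noise_sd = p$noise_sd, seed = seeds[i])
        train_readout(train, lambda = p$lambda)
      })
      norms <- input_population_norms(cells, n_reps = p$n_train,
                                      noise_sd = p$noise_sd,
                                      seed = seeds[4],
                                      cross_angle = p$cross_angle)
      combos <- expand.grid(train = c("grating", "plaid"),
                            test = c("grating", "plaid"),
                            stringsAsFactors = FALSE)
      evidence <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
        evidence_curve(models[[combos$train[i]]], cells,
                       test_kind = combos$test[i],
                       directions = p$directions, noise_sd = p$noise_sd,
                       n_reps = p$n_evidence_reps, seed = seeds[4 + i],
                       cross_angle = p$cross_angle)
      })
      mean_abs_ev <- function(tr, te) {
        mean(abs(evidence$evidence[evidence$train_kind == tr &
                                     evidence$test_kind == te]))
      }
      list(
        cells = cells, models = models, input_norms = norms,
        evidence = evidence,
        summary = list(
          input_norm_grating = norms$mean_norm[norms$kind == "grating"],
          input_norm_plaid = norms$mean_norm[norms$kind == "plaid"],
          weight_norm_grating_trained = weight_norm(models$grating),
          weight_norm_plaid_trained = weight_norm(models$plaid),
          weight_norm_ratio = weight_norm(models$plaid) /
            weight_norm(models$grating),
          evidence_grating_on_grating = mean_abs_ev("grating", "grating"),
          evidence_grating_on_plaid = mean_abs_ev("grating", "plaid"),
          evidence_plaid_on_plaid = mean_abs_ev("plaid", "plaid"),
          evidence_plaid_on_grating = mean_abs_ev("plaid", "grating")
        )
      )
    },
    behavior_synthetic = {
      configs <- bind_rows(
        purrr::map_dfr(seq_len(p$n_g), function(i) {
          sim_rat_config(sprintf("G%02d", i), "G",
                         base_accuracy = p$base_accuracy,
                         identity_gain = p$identity_gain,
                         cross_gain = p$cross_gain_g,
                         lapse_rate = p$lapse_rate,
                         too_fast_rate = p$too_fast_rate,
                         ignored_rate = p$ignored_rate,
                         n_sessions = p$n_sessions,
                         trials_per_session = p$trials_per_session)
        }),
        purrr::map_dfr(seq_len(p$n_p), function(i) {
          sim_rat_config(sprintf("P%02d", i), "P",
                         base_accuracy = p$base_accuracy,
                         identity_gain = p$identity_gain,
                         cross_gain = p$cross_gain_p,
                         lapse_rate = p$lapse_rate,
                         too_fast_rate = p$too_fast_rate,
                         ignored_rate = p$ignored_rate,
                         n_sessions = p$n_sessions,
                         trials_per_session = p$trials_per_session)
        })
      )
      sim <- simulate_cohort(configs, seed = seed)
      sim$summary <- list(
        n_trials = nrow(sim$trials),
        n_animals = nrow(configs),
        n_groups = length(unique(configs$group))
      )
      sim
    },
    behavior_analysis = {
      trials <- p$trials
      if (is.null(trials) && !is.null(p$trials_path)) {
        trials <- read_trials(p$trials_path)
      }
      if (is.null(trials)) {
        trials <- run_scenario("behavior_synthetic",
                               seed = child_seeds(seed, 2)[1])$trials
      }
      filt <- filter_trials(trials)
      inclusion <- animal_inclusion(filt$trials,
                                    threshold = p$inclusion_threshold)
      kept <- inclusion$animal_id[inclusion$included]
      included_trials <- filt$trials[filt$trials$animal_id %in% kept, ]
      boot <- bootstrap_group_curves(included_trials, n_reps = p$n_boot,
                                     ci_level = p$ci_level,
                                     bonferroni_m = p$bonferroni_m,
                                     seed = child_seeds(seed, 2)[2])
      mag <- boot$magnitudes
      list(
        exclusions = filt$exclusions, inclusion = inclusion,
        bootstrap = boot,
        summary = c(
          list(n_valid_trials = nrow(filt$trials),
               n_included_animals = length(kept)),
          stats::setNames(
            as.list(mag$magnitude),
            paste0("magnitude_", mag$group, "_", mag$condition)
          )
        )
      )
    }
  )
  res$manifest <- list(
    scenario = scenario,
    config_hash = rlang::hash(list(scenario = scenario, params = p,
                                   seed = seed)),
    seed = seed,
    package_version = as.character(utils::packageVersion("plaidpercept"))
  )
  res$scenario <- scenario
  res$config <- p
  class(res) <- "scenario_result"
  if (!is.null(out_dir)) write_scenario(res, out_dir)
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s (seed %s)\n", x$scenario,
              x$manifest$seed))
  utils::str(x$summary, give.attr = FALSE)
  invisible(x)
}

write_scenario <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res)) {
    obj <- res[[nm]]
    if (is.data.frame(obj)) {
      readr::write_csv(obj, file.path(out_dir, paste0(nm, ".csv")),
                       progress = FALSE)
    }
  }
  jsonlite::write_json(res$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(res$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Read a scenario configuration file
#'
#' Reads a YAML or JSON file with fields `scenario`, optional `overrides`,
#' `seed` and `out_dir`, ready to splice into [run_scenario()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_scenario_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$scenario)) abort("config file must name a scenario")
  cfg
}
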