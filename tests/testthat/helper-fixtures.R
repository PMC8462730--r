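# Shared fixture builders. Everything is generated in code at test time.

# the 24-cell equispaced representation (peak 1, peak:background 10)
small_population <- function(cell_class = "component", k = 7, seed = 1) {
  sample_population(population_config(
    n_cells = 24, fraction_component = as.numeric(cell_class == "component"),
    pref_direction_scheme = "equispaced", amplitude = 1, baseline = 0.1,
    trial_noise_sd = 0.25, k = k, seed = seed
  ))
}

# the 1000-cell mixed cortical-like population
cortical_population <- function(n_cells = 1000, fraction_component = 0.8,
                                component_plaid_suppression = 0.5,
                                pattern_plaid_suppression = 1,
                                pattern_plaid_k_divisor = 4,
                                seed = 1) {
  suppressWarnings(sample_population(population_config(
    n_cells = n_cells, fraction_component = fraction_component,
    pref_direction_scheme = "uniform_random", amplitude = c(8, 1),
    baseline = 2, trial_noise_sd = 2,
    osi_target = c(0.7, 0.1), dsi_target = c(0.6, 0.2),
    component_plaid_suppression = component_plaid_suppression,
    pattern_plaid_suppression = pattern_plaid_suppression,
    pattern_plaid_k_divisor = pattern_plaid_k_divisor,
    seed = seed
  )))
}

train_small_readout <- function(cells, train_kind = "plaid", n_train = 500,
                                noise_sd = 0.25, lambda = 1, seed = 2) {
  rs <- sample_responses(cells, stimulus_spec(train_kind, c(0, 180)),
                         n_reps = n_train, noise_sd = noise_sd, seed = seed)
  train_readout(rs, lambda = lambda)
}

# hand-built readout over given cells (for pruning/evidence unit tests)
manual_readout <- function(weights, cells, bias = 0, train_kind = "plaid") {
  structure(
    list(weights = weights, bias = bias, cells = cells,
         train_kind = train_kind, lambda = 1, converged = TRUE,
         n_iter = 0L, final_grad_norm = 0, train_accuracy = NA_real_),
    class = "plaid_readout"
  )
}

# a deterministic priming trial table covering the full design once per
# session: every prime direction x prime kind x target, all correct unless
# given an accuracy function p(distance, condition) in [0, 1]
design_trials <- function(animal_id = "r1", group = "P", n_sessions = 2,
                          p_correct = NULL) {
  grid <- expand.grid(
    prime_direction = seq(0, 180, 10),
    prime_kind = c("grating", "plaid"),
    target_direction = c(0, 180),
    stringsAsFactors = FALSE
  )
  out <- purrr::map_dfr(seq_len(n_sessions), function(s) {
    df <- tibble::as_tibble(grid)
    df$animal_id <- animal_id
    df$group <- group
    df$session <- s
    df$phase <- "priming"
    df$reaction_time <- 500
    d <- angular_distance(df$prime_direction, df$target_direction)
    cond <- ifelse(
      df$prime_kind == ifelse(group == "G", "grating", "plaid"),
      "identity", "cross"
    )
    df$correct <- if (is.null(p_correct)) TRUE else
      runif(nrow(df)) < p_correct(d, cond)
    df$choice <- ifelse(xor(df$target_direction == 0, !df$correct),
                        "right", "left")
    df
  })
  out
}
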