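# Decoding-pool analyses: quantile pruning of the decision neuron's
# inputs, class composition of the surviving pool, and the input/weight
# norm and evidence-curve quantities of the homeostatic scenario.

#' Prune the weakest readout weights by magnitude quantile
#'
#' Sets to zero every weight whose magnitude falls below the given quantile
#' of the weight-magnitude distribution (computed over all inputs,
#' including already-zero weights), emulating a sparsity constraint on the
#' decision neuron's connectivity. Exactly `ceiling((1 - quantile) * n)`
#' inputs survive; ties in magnitude are broken by dropping the
#' earlier-indexed weight first.
#'
#' @param model A `plaid_readout`.
#' @param quantile Pruning level in `[0, 1)`; 0 leaves the model unchanged.
#' @return The pruned `plaid_readout` (weights zeroed, everything else
#'   untouched).
#' @examples
#' m <- structure(list(weights = c(1, 2, 3, 4), bias = 0,
#'                     cells = cell_tuning()[rep(1, 4), ]),
#'                class = "plaid_readout")
#' prune_by_quantile(m, 0.5)$weights
#' @export
prune_by_quantile <- function(model, quantile) {
  stopifnot(inherits(model, "plaid_readout"))
  if (quantile < 0 || quantile >= 1) abort("quantile must lie in [0, 1)")
  w <- model$weights
  n <- length(w)
  n_keep <- ceiling((1 - quantile) * n)
  ord <- order(abs(w), seq_len(n))     # ties: earlier index dropped first
  drop_idx <- ord[seq_len(n - n_keep)]
  w[drop_idx] <- 0
  model$weights <- w
  model$pruned_quantile <- quantile
  model
}

#' Class composition of the surviving decoding pool
#'
#' Fractions of component and pattern cells among the inputs with nonzero
#' weight.
#'
#' @param model A `plaid_readout` (possibly pruned).
#' @return A one-row tibble: `n_pool`, `fraction_component`,
#'   `fraction_pattern` (summing to 1).
#' @export
class_fractions <- function(model) {
  stopifnot(inherits(model, "plaid_readout"))
  alive <- model$weights != 0
  if (!any(alive)) abort("empty decoding pool: all weights are zero")
  cls <- model$cells$cell_class[alive]
  tibble(
    n_pool = sum(alive),
    fraction_component = mean(cls == "component"),
    fraction_pattern = mean(cls == "pattern")
  )
}

#' Pool composition across a grid of pruning levels
#'
#' Applies [prune_by_quantile()] at each quantile and records the class
#' composition of the surviving pool - the curve that reveals whether one
#' cell class takes over the decoding pool as connectivity is made sparser.
#'
#' @param model A `plaid_readout`.
#' @param quantiles Pruning grid in `[0, 1)` (default 0 to 0.9 step 0.1).
#' @return A tibble of class `pruning_profile`: `quantile`, `n_pool`,
#'   `fraction_component`, `fraction_pattern`.
#' @export
pruning_profile <- function(model, quantiles = seq(0, 0.9, by = 0.1)) {
  out <- purrr::map_dfr(quantiles, function(q) {
    dplyr::bind_cols(tibble(quantile = q),
                     class_fractions(prune_by_quantile(model, q)))
  })
  class(out) <- c("pruning_profile", class(out))
  out
}

#' L2 norm of the readout weight vector
#'
#' @param model A `plaid_readout`; the bias is excluded.
#' @return The Euclidean norm of the weights.
#' @export
weight_norm <- function(model) {
  stopifnot(inherits(model, "plaid_readout"))
  sqrt(sum(model$weights^2))
}

#' Mean L2 norm of the input population vectors, per stimulus kind
#'
#' Samples noisy population responses to the two training stimuli (0- and
#' 180-degree drift) for each requested kind and averages the Euclidean
#' norm of the per-trial response vector. Cross-orientation suppression
#' makes the plaid input norm smaller than the grating norm.
#'
#' @inheritParams sample_responses
#' @param kinds Stimulus kinds to measure.
#' @param directions Training directions (default `c(0, 180)`).
#' @param cross_angle Plaid cross-angle, degrees.
#' @return A tibble: `kind`, `mean_norm`, `n_trials`.
#' @export
input_population_norms <- function(cells, kinds = c("grating", "plaid"),
                                   directions = c(0, 180),
                                   n_reps = 200, noise_sd = 2, seed = NULL,
                                   cross_angle = 120) {
  cells <- validate_cells(cells)
  seeds <- child_seeds(seed, length(kinds))
  purrr::map_dfr(seq_along(kinds), function(i) {
    rs <- sample_responses(cells, stimulus_spec(kinds[i], directions,
                                                cross_angle),
                           n_reps = n_reps, noise_sd = noise_sd,
                           seed = if (is.null(seed)) NULL else seeds[i])
    tibble(
      kind = kinds[i],
      mean_norm = mean(sqrt(rowSums(rs$values^2))),
      n_trials = nrow(rs$values)
    )
  })
}

#' Evidence curve: mean weighted input over the direction circle
#'
#' For each direction, the mean pre-sigmoid activation of the decision
#' neuron (`weights . response + bias`) across noisy test trials. Unlike
#' the generalization curve, this retains the magnitude of the sensory
#' evidence, which is what the homeostatic (L2) constraint acts on.
#'
#' @inheritParams generalization_curve
#' @param test_kind Stimulus kind presented at test.
#' @param n_reps Trials per direction.
#' @return A tibble of class `evidence_curve`: `direction`, `train_kind`,
#'   `test_kind`, `evidence`.
#' @export
evidence_curve <- function(model, cells = model$cells,
                           test_kind = c("grating", "plaid"),
                           directions = seq(0, 345, by = 15),
                           noise_sd = 2, n_reps = 200, seed = NULL,
                           cross_angle = 120) {
  test_kind <- match.arg(test_kind)
  cells <- validate_cells(cells)
  if (nrow(cells) != length(model$weights)) {
    abort("cells and model have incompatible dimensions")
  }
  rs <- sample_responses(cells, stimulus_spec(test_kind, directions,
                                              cross_angle),
                         n_reps = n_reps, noise_sd = noise_sd, seed = seed)
  ev <- predict(model, rs, type = "evidence")
  m <- tapply(ev, factor(rs$stimuli$direction, levels = directions), mean)
  out <- tibble(
    direction = directions,
    train_kind = model$train_kind %||% NA_character_,
    test_kind = test_kind,
    evidence = as.numeric(m)
  )
  class(out) <- c("evidence_curve", class(out))
  out
}
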