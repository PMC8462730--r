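# Noisy trial responses. The trials x cells array is kept as a matrix
# inside a light `response_set` container (long tibbles with millions of
# rows would be wasteful for the linear-algebra steps); `tidy()` /
# `as_tibble()` give the long tabular view.

#' Sample noisy population responses to a set of stimuli
#'
#' Each trial response is the noise-free tuning value plus zero-mean
#' Gaussian noise of standard deviation `noise_sd` (the rate-noise model);
#' alternatively, `noise = "poisson"` draws spike counts with the tuning
#' value as the Poisson mean. Negative Gaussian samples are left
#' untruncated by default (a linear readout is unaffected); set
#' `clip_negative = TRUE` to clamp responses at zero.
#'
#' @inheritParams grating_tuning
#' @param stimuli A stimulus tibble from [stimulus_spec()].
#' @param n_reps Trials per stimulus (>= 1).
#' @param noise_sd Gaussian noise standard deviation (>= 0); ignored for
#'   Poisson noise.
#' @param seed Integer seed; same seed gives identical responses.
#' @param noise `"gaussian"` or `"poisson"`.
#' @param clip_negative Clamp Gaussian responses at zero.
#' @return A `response_set`: list with `values` (trials x cells matrix),
#'   `stimuli` (one row per trial: `trial`, `kind`, `direction`) and
#'   `cells` (the cell tibble).
#' @examples
#' cells <- sample_population(population_config(24, k = 7, baseline = 0.1))
#' rs <- sample_responses(cells, stimulus_spec("plaid", c(0, 180)),
#'                        n_reps = 5, noise_sd = 0.25, seed = 1)
#' dim(rs$values)
#' @export
sample_responses <- function(cells, stimuli, n_reps, noise_sd, seed = NULL,
                             noise = c("gaussian", "poisson"),
                             clip_negative = FALSE) {
  noise <- match.arg(noise)
  cells <- validate_cells(cells)
  if (n_reps < 1) abort("n_reps must be at least 1")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  mu <- stimulus_tuning(cells, stimuli)
  idx <- rep(seq_len(nrow(stimuli)), each = n_reps)
  mu_trials <- mu[idx, , drop = FALSE]
  values <- with_seed(seed, {
    if (noise == "gaussian") {
      v <- mu_trials + rnorm(length(mu_trials), 0, noise_sd)
      if (clip_negative) v <- pmax(v, 0)
      v
    } else {
      matrix(rpois(length(mu_trials), pmax(mu_trials, 0)),
             nrow = nrow(mu_trials))
    }
  })
  trial_stimuli <- stimuli[idx, , drop = FALSE]
  trial_stimuli$trial <- seq_along(idx)
  structure(
    list(values = values,
         stimuli = as_tibble(trial_stimuli[, c("trial", "kind", "direction")]),
         cells = cells),
    class = "response_set"
  )
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf("<response_set> %d trials x %d cells (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$stimuli$kind), collapse = "/")))
  invisible(x)
}

#' @rdname sample_responses
#' @param x A `response_set`.
#' @param ... Unused.
#' @return `as_tibble()`/`tidy()`: a long tibble with one row per trial and
#'   cell (`trial`, `kind`, `direction`, `cell_id`, `cell_class`,
#'   `response`).
#' @export
as_tibble.response_set <- function(x, ...) {
  n_tr <- nrow(x$values)
  n_ce <- ncol(x$values)
  tibble(
    trial = rep(x$stimuli$trial, times = n_ce),
    kind = rep(x$stimuli$kind, times = n_ce),
    direction = rep(x$stimuli$direction, times = n_ce),
    cell_id = rep(x$cells$cell_id %||% seq_len(n_ce), each = n_tr),
    cell_class = rep(x$cells$cell_class, each = n_tr),
    response = as.vector(x$values)
  )
}

#' @export
tidy.response_set <- function(x, ...) as_tibble.response_set(x, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
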