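#' Generate synthetic soil samples
#'
#' Draws soils spanning the property ranges of the European incubation
#' study: pH 2.98--7.52, organic carbon 0.41--23.32 % w/w, with aging
#' temperatures around temperate annual means and incubation times from
#' days to decades. pH, organic carbon and temperature are sampled
#' uniformly and independently; time is sampled log-uniformly so that
#' short- and long-term aging are both represented.
#'
#' @param n Number of soils (>= 0).
#' @param ph_range,corg_range,temp_range Numeric `c(low, high)` ranges for
#'   pH, organic carbon (% w/w) and temperature (kelvin).
#' @param time_range Range of incubation times in days, sampled
#'   log-uniformly.
#' @param seed Integer seed; the output is a pure function of `seed` and
#'   the configuration. `NULL` uses the current RNG state.
#' @return Data frame with columns `sample_id`, `ph`, `corg`,
#'   `temperature`, `time`.
#' @examples
#' soils <- generate_soils(5, seed = 1)
#' @export
generate_soils <- function(n, ph_range = c(2.98, 7.52),
                           corg_range = c(0.41, 23.32),
                           temp_range = c(278, 298),
                           time_range = c(1, 30000), seed = NULL) {
  stopifnot(n >= 0, ph_range[1] <= ph_range[2],
            corg_range[1] <= corg_range[2],
            temp_range[1] <= temp_range[2],
            time_range[1] > 0, time_range[1] <= time_range[2])
  gen <- function() {
    data.frame(
      sample_id = sprintf("soil_%04d", seq_len(n)),
      ph = runif(n, ph_range[1], ph_range[2]),
      corg = runif(n, corg_range[1], corg_range[2]),
      temperature = runif(n, temp_range[1], temp_range[2]),
      time = exp(runif(n, log(time_range[1]), log(time_range[2]))),
      stringsAsFactors = FALSE
    )
  }
  if (n == 0)
    return(data.frame(sample_id = character(), ph = numeric(),
                      corg = numeric(), temperature = numeric(),
                      time = numeric(), stringsAsFactors = FALSE))
  with_seed(seed, gen)
}

#' Simulate noisy E-value observations
#'
#' Evaluates the aging model on each soil and adds independent Gaussian
#' noise on the E fraction, clipped to [0, 1]. The number of clipped values
#' is attached as attribute `n_clipped` (boundary censoring is informative
#' when the noise scale is large relative to the predicted fraction).
#'
#' @param soils Data frame as from [generate_soils()].
#' @param params An [aging_params()] object (truth for the simulation).
#' @param noise_sd Standard deviation of the additive observation noise on
#'   the E fraction; 0 reproduces the model predictions exactly.
#' @param seed Integer seed for the noise draws (`NULL`: current RNG).
#' @return The soil table with an `e_add_obs` column (and attribute
#'   `n_clipped`).
#' @export
simulate_observations <- function(soils, params = aging_params(),
                                  noise_sd = 0.05, seed = NULL) {
  stopifnot(noise_sd >= 0)
  params <- as_aging_params(params)
  pred <- e_add_quiet(soils, params)
  raw <- if (noise_sd == 0) pred else
    with_seed(seed, function() pred + rnorm(length(pred), 0, noise_sd))
  obs <- soils
  obs$e_add_obs <- pmin(1, pmax(0, raw))
  attr(obs, "n_clipped") <- sum(raw < 0 | raw > 1)
  obs
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates soils, simulates noisy observations from a known
#' parameter set, and refits the model, reporting per-parameter bias,
#' relative RMSE of the estimates, and boundary-hit counts. This is the
#' package's internal check that the fitting machinery can recover the
#' model under its own assumptions at realistic noise.
#'
#' @param truth An [aging_params()] object used to simulate.
#' @param n Soils per replicate.
#' @param noise_sd Observation noise sd on the E fraction.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer master seed; replicate r uses `seed + r` for
#'   generation and `seed + 10000 + r` for noise.
#' @param free Parameters to estimate (the rest fixed at truth).
#' @param multistart,... Passed to [fit_aging_model()].
#' @return Object of class `recovery_report`: list with `estimates` (one
#'   row per converged replicate), `summary` (per-parameter truth, mean
#'   estimate, bias, relative RMSE, boundary hits), `n_converged`,
#'   `n_reps`, `n`, `noise_sd`.
#' @examples
#' \donttest{
#' rec <- recovery_experiment(n = 60, noise_sd = 0.02, n_reps = 2,
#'                            seed = 1, multistart = 2)
#' rec$summary
#' }
#' @export
recovery_experiment <- function(truth = aging_params(), n = 200,
                                noise_sd = 0.02, n_reps = 1, seed = 1,
                                free = c("B", "C", "N", "F", "G"),
                                multistart = 4, ...) {
  stopifnot(n_reps >= 1)
  truth <- as_aging_params(truth)
  est <- matrix(NA_real_, n_reps, length(free),
                dimnames = list(NULL, free))
  converged <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    soils <- generate_soils(n, seed = seed + r)
    obs <- simulate_observations(soils, truth, noise_sd,
                                 seed = seed + 10000 + r)
    fit <- tryCatch(
      fit_aging_model(obs, start = truth, free = free,
                      multistart = multistart, seed = seed + 20000 + r,
                      ...),
      error = function(e) NULL)
    if (!is.null(fit)) {
      est[r, ] <- unlist(fit$params[free])
      converged[r] <- fit$converged
    }
  }
  done <- !apply(est, 1, function(z) any(is.na(z)))
  tv <- unlist(truth[free])
  mean_est <- colMeans(est[done, , drop = FALSE])
  bias <- mean_est - tv
  rel_rmse <- sqrt(colMeans(
    (est[done, , drop = FALSE] - rep(tv, each = sum(done)))^2)) /
    ifelse(tv != 0, abs(tv), 1)
  boundary <- colSums(est[done, , drop = FALSE] <=
                        rep(param_lower[free] + 1e-8, each = sum(done)))
  structure(list(
    estimates = est,
    summary = data.frame(param = free, truth = tv, mean_estimate = mean_est,
                         bias = bias, rel_rmse = rel_rmse,
                         boundary_hits = boundary, row.names = NULL),
    n_converged = sum(converged), n_reps = n_reps, n = n,
    noise_sd = noise_sd, seed = seed
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "Parameter recovery: %d rep(s), %d soils each, noise sd %.3g\n",
    x$n_reps, x$n, x$noise_sd))
  cat(sprintf("  converged fits: %d / %d\n", x$n_converged, x$n_reps))
  print(x$summary, digits = 4)
  invisible(x)
}
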