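#' Default sampling times emulating a multi-decade campaign
#'
#' The historical campaign dates are not public, so the default design is a
#' deterministic irregular grid: `n` times between `first` and `last` years
#' after the accident, spaced by a mild power law so early campaigns are
#' denser, as post-accident monitoring programmes usually are.
#'
#' @param n number of campaigns (default 24).
#' @param first,last first and last sampling times in years (defaults 1.2
#'   and 37).
#' @return Strictly increasing numeric vector of length `n`.
#' @export
default_sample_times <- function(n = 24, first = 1.2, last = 37) {
  stopifnot(n >= 2, first > 0, last > first)
  u <- (seq_len(n) - 1) / (n - 1)
  first + (last - first) * u^1.3
}

#' Configuration of the synthetic campaign generator
#'
#' Bundles the ground-truth parameters of a simulated soil-sampling series:
#' the chain transfer rate(s), initial fractions, sampling design, the
#' multiplicative measurement noise (the study's combined standard
#' uncertainty is about 10% at coverage factor 1), soil density, the total
#' deposition backdated to the accident date, and the nuclide half-life.
#'
#' @param k_true transfer rate in 1/y (scalar for the equal-rate chain, or
#'   one rate per compartment). Default 0.024.
#' @param init initial fractions (default [chernobyl_init_fractions()]).
#' @param sample_times strictly increasing positive times in years
#'   (default [default_sample_times()]).
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise (default 0.10).
#' @param noise_model `"gaussian"` (factor `max(0, 1 + cv * eps)`, eps
#'   standard normal) or `"lognormal"` (mean-1 lognormal with the same CV).
#' @param density bulk soil density in g/cm3 (default 1.3).
#' @param deposition_0 total deposition backdated to the accident date, in
#'   kBq/m2 (default 18.6).
#' @param thickness_cm layer thickness in cm (default 5).
#' @param half_life nuclide half-life in years.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(k_true = 0.024,
                             init = chernobyl_init_fractions(),
                             sample_times = default_sample_times(),
                             noise_cv = 0.10,
                             noise_model = c("gaussian", "lognormal"),
                             density = 1.3,
                             deposition_0 = 18.6,
                             thickness_cm = 5,
                             half_life = cs137_half_life()) {
  noise_model <- match.arg(noise_model)
  if (inherits(init, "fraction_vector")) init <- init$r
  model <- chain_model(k_true, init)   # validates rates and init
  if (any(sample_times <= 0) || any(diff(sample_times) <= 0)) {
    stop("sample_times must be strictly increasing and positive", call. = FALSE)
  }
  if (!is.numeric(noise_cv) || noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (density <= 0 || deposition_0 < 0 || thickness_cm <= 0 || half_life <= 0) {
    stop("density, deposition_0, thickness_cm and half_life must be positive", call. = FALSE)
  }
  structure(list(model = model, sample_times = as.numeric(sample_times),
                 noise_cv = noise_cv, noise_model = noise_model,
                 density = density, deposition_0 = deposition_0,
                 thickness_cm = thickness_cm, half_life = half_life),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_config> %d campaigns over %.3g-%.3g y, ",
                     "rates %s 1/y, noise CV %.3g (%s)\n"),
              length(x$sample_times), min(x$sample_times), max(x$sample_times),
              paste(signif(unique(x$model$rates), 4), collapse = "/"),
              x$noise_cv, x$noise_model))
  invisible(x)
}

# one multiplicative noise factor per (time, layer); mean 1, sd = cv
noise_factors <- function(config, n_times) {
  n <- config$model$n
  cv <- config$noise_cv
  if (cv == 0) return(matrix(1, n_times, n))
  if (config$noise_model == "gaussian") {
    matrix(pmax(0, 1 + cv * stats::rnorm(n_times * n)), n_times, n)
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    matrix(stats::rlnorm(n_times * n, meanlog = -sdlog^2 / 2, sdlog = sdlog),
           n_times, n)
  }
}

#' Simulate a measured fraction series
#'
#' Propagates the chain to each sampling time, perturbs every layer with an
#' independent multiplicative noise factor, and (by default) renormalizes
#' each sampled vector to sum 1 -- measured fractional contributions are
#' ratios of measured activities, so they sum to 1 by construction. Set
#' `renormalize = FALSE` to obtain the noisy raw model fractions instead
#' (whose surface layer is exactly exponential in expectation).
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; mandatory whenever `noise_cv > 0`.
#' @param renormalize renormalize each sampled vector to sum 1 (default
#'   `TRUE`).
#' @return A data.frame with columns `t_years` and one fraction column per
#'   layer (R5, R10, ...).
#' @export
simulate_fraction_series <- function(config, seed = NULL, renormalize = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$noise_cv > 0 && is.null(seed)) {
    stop("a seed is mandatory for any stochastic call", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  clean <- propagate_chain(config$model, config$sample_times)
  cols <- layer_names(config$model$n)
  noisy <- as.matrix(clean[cols]) * noise_factors(config, length(config$sample_times))
  if (renormalize) noisy <- noisy / rowSums(noisy)
  out <- data.frame(t_years = config$sample_times)
  out[cols] <- as.data.frame(noisy)
  out
}

#' Simulate a series of measured soil profiles
#'
#' Converts the (noisy, renormalized) fraction series into raw per-layer
#' mass activities: the sampled fractions are scaled so that the noiseless
#' deposition backdated to the accident date equals `deposition_0`, then
#' forward radioactive decay is applied to each sampling date. The output
#' is directly consumable by [fractional_contributions()],
#' [total_deposition()] and [read_profiles()]/[write_profiles()].
#'
#' @inheritParams simulate_fraction_series
#' @param ref reference (accident) date from which sampling dates are
#'   offset.
#' @return A list of [soil_profile()] objects, one per sampling time.
#' @export
simulate_profile_series <- function(config, seed = NULL, ref = chernobyl_date()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$noise_cv > 0 && is.null(seed)) {
    stop("a seed is mandatory for any stochastic call", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  clean <- propagate_chain(config$model, config$sample_times)
  cols <- layer_names(config$model$n)
  frac <- as.matrix(clean[cols]) / clean$sum       # renormalized model state
  factors <- noise_factors(config, length(config$sample_times))
  thick_m <- config$thickness_cm / 100
  mass_loading <- config$density * 1000 * thick_m  # kg/m2 per layer
  lapply(seq_along(config$sample_times), function(i) {
    t <- config$sample_times[i]
    areal_0 <- config$deposition_0 * 1000 * frac[i, ] * factors[i, ]  # Bq/m2 at t=0
    areal_t <- areal_0 * 2^(-t / config$half_life)                    # forward decay
    soil_profile(ref + round(t * 365.25),
                 activity = areal_t / mass_loading,
                 top_cm = (seq_along(cols) - 1) * config$thickness_cm,
                 bottom_cm = seq_along(cols) * config$thickness_cm,
                 rel_sigma = config$noise_cv,
                 density = config$density,
                 half_life = config$half_life)
  })
}
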