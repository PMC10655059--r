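#' Fit the transfer rate k to a surface-layer time series
#'
#' Least-squares fit of the single-parameter exponential
#' `R5(t) = R5(0) * exp(-k t)` with the intercept *fixed* at its value at
#' the reference date (0.71 for the study site) -- only k is estimated.
#' The loss is ordinary (unweighted) least squares by default; supplying
#' per-point standard deviations switches to `1/sigma^2` weights.
#'
#' The deterministic starting value is `log(r5_0 / last value) / last time`
#' clipped to `[1e-4, 1]`; the minimum is then located by golden-section /
#' parabolic search on the one-dimensional residual sum of squares.
#'
#' The reported standard error is the asymptotic one-parameter
#' Gauss-Newton value `sqrt(RSS/(n-1) / sum(J^2))` with
#' `J_i = -t_i r5_0 exp(-k t_i)`; `se_method = "bootstrap"` instead
#' resamples residuals (seeded) and refits.
#'
#' @param times sampling times in years since the reference date; all `> 0`.
#' @param r5_values observed surface-layer fractions at `times`.
#' @param r5_0 fixed fraction at t = 0 (default 0.71).
#' @param sigma optional per-point standard deviations; when given, the fit
#'   minimises the `1/sigma^2`-weighted sum of squares.
#' @param se_method `"asymptotic"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed seed for the bootstrap; required when
#'   `se_method = "bootstrap"`.
#' @return A `fit_result`: list with `k_hat`, `k_se`, `rss`, `n_points`,
#'   `residuals`, `fixed_r5_0`, `method`.
#' @examples
#' t <- seq(1.2, 37, length.out = 20)
#' fit_k(t, 0.71 * exp(-0.024 * t))$k_hat
#' @export
fit_k <- function(times, r5_values, r5_0 = 0.71, sigma = NULL,
                  se_method = c("asymptotic", "bootstrap"),
                  n_boot = 1000, seed = NULL) {
  se_method <- match.arg(se_method)
  times <- as.numeric(times)
  r5_values <- as.numeric(r5_values)
  if (length(times) != length(r5_values)) stop("times and values differ in length", call. = FALSE)
  n <- length(times)
  if (n < 3L) stop("fit failure: need at least 3 points", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(r5_values))) {
    stop("fit failure: non-finite inputs", call. = FALSE)
  }
  if (any(times <= 0)) stop("fit failure: times must be positive", call. = FALSE)
  if (all(r5_values <= 0)) stop("fit failure: no positive observations", call. = FALSE)
  if (!is.numeric(r5_0) || r5_0 <= 0) stop("r5_0 must be positive", call. = FALSE)
  w <- if (is.null(sigma)) rep(1, n) else {
    if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
    1 / sigma^2
  }
  rss_fun <- function(k) sum(w * (r5_values - r5_0 * exp(-k * times))^2)
  last_pos <- r5_values[n]
  k0 <- if (last_pos > 0) log(r5_0 / last_pos) / times[n] else 1
  k0 <- min(max(k0, 1e-4), 1)
  # bracket around the deterministic start, then polish
  opt <- stats::optimize(rss_fun, interval = c(1e-6, max(10 * k0, 1)), tol = 1e-12)
  k_hat <- opt$minimum
  rss <- opt$objective
  fitted <- r5_0 * exp(-k_hat * times)
  resid <- r5_values - fitted
  J <- -times * r5_0 * exp(-k_hat * times) * sqrt(w)
  sigma2 <- rss / max(n - 1, 1)
  k_se_asym <- sqrt(sigma2 / sum(J^2))
  if (se_method == "bootstrap") {
    if (is.null(seed)) stop("bootstrap standard error requires a seed", call. = FALSE)
    set.seed(seed)
    k_boot <- vapply(seq_len(n_boot), function(b) {
      y <- fitted + sample(resid, n, replace = TRUE)
      rb <- function(k) sum(w * (y - r5_0 * exp(-k * times))^2)
      stats::optimize(rb, interval = c(1e-6, max(10 * k0, 1)), tol = 1e-10)$minimum
    }, numeric(1))
    k_se <- stats::sd(k_boot)
  } else {
    k_se <- k_se_asym
  }
  structure(list(k_hat = k_hat, k_se = k_se, rss = rss, n_points = n,
                 residuals = resid, fixed_r5_0 = r5_0,
                 method = sprintf("fixed-intercept 1-parameter %s LS, %s SE",
                                  if (is.null(sigma)) "ordinary" else "weighted",
                                  se_method)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> k = %.4f +/- %.4f 1/y (n = %d, RSS = %.5g)\n",
              x$k_hat, x$k_se, x$n_points, x$rss))
  cat(sprintf("  %s, R5(0) fixed at %.3g\n", x$method, x$fixed_r5_0))
  invisible(x)
}

#' Write a fit result as a JSON report
#'
#' @param fit a `fit_result` from [fit_k()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(
    list(k_hat = fit$k_hat, k_se = fit$k_se, rss = fit$rss,
         n_points = fit$n_points, method = fit$method, r5_0 = fit$fixed_r5_0),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Compare the equal-rate model against increasing-rate variants
#'
#' Ranks candidate models of the 5-10 cm layer by residual sum of squares
#' against an observed `R10` series. The candidates are the equal-rate
#' chain curve at rate `k1` and, for each entry of `k2_list`, the two-rate
#' chain in which the second compartment drains faster (`k2 > k1`, the
#' diffusion-like case). `k1` is held at the value fitted from the surface
#' layer, since the surface-layer solution is the same in both models.
#'
#' @param times sampling times in years.
#' @param r10_values observed 5-10 cm fractions at `times`.
#' @param k1 surface-layer transfer rate in 1/y.
#' @param k2_list candidate second-link rates in 1/y; values below `k1`
#'   trigger a warning (the variant is meant for increasing rates) but are
#'   still evaluated.
#' @param init initial fractions; only the first two entries are used.
#' @return A data.frame sorted by RSS with columns `model`, `k2`, `rss`,
#'   `rank`.
#' @export
compare_rate_models <- function(times, r10_values, k1, k2_list,
                                init = chernobyl_init_fractions()) {
  if (inherits(init, "fraction_vector")) init <- init$r
  init <- as.numeric(init)
  if (length(times) != length(r10_values)) stop("times and values differ in length", call. = FALSE)
  if (!is.numeric(k1) || k1 <= 0) stop("'k1' must be positive", call. = FALSE)
  if (any(k2_list < k1)) {
    warning("some k2 < k1: the two-rate variant is intended for increasing rates")
  }
  r10_curve <- function(rates) {
    m <- chain_model(rates, init[1:2])
    solver <- if (uniform_rates(m)) equal_rate_solution else general_chain_solution
    vapply(times, function(t) solver(m, t)$r[[2L]], numeric(1))
  }
  cand <- c(list(`equal-rate` = c(k1, k1)),
            stats::setNames(lapply(k2_list, function(k2) c(k1, k2)),
                            sprintf("two-rate k2=%.4g", k2_list)))
  out <- data.frame(
    model = names(cand),
    k2 = vapply(cand, `[[`, numeric(1), 2L),
    rss = vapply(cand, function(rates) sum((r10_values - r10_curve(rates))^2),
                 numeric(1)),
    row.names = NULL
  )
  out <- out[order(out$rss), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
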