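#' Hydrotime model parameters
#'
#' Container for the three parameters of the hydrotime threshold model of
#' seed germination. Each seed in the population germinates once its
#' accumulated hydrotime \eqn{[\Psi - \Psi_b] t} reaches the constant
#' \eqn{\theta_H}; the per-seed base water potential \eqn{\Psi_b} is
#' normally distributed across the seed lot with median `psi_b50` and
#' standard deviation `sigma`.
#'
#' @param psi_b50 Median base water potential \eqn{\Psi_b(50)} in MPa
#'   (typically negative; seeds whose base potential exceeds the ambient
#'   water potential never germinate).
#' @param sigma Standard deviation \eqn{\sigma_{\Psi b}} of the base water
#'   potential distribution, in MPa. Must be positive.
#' @param theta_h Hydrotime constant \eqn{\theta_H} in MPa h. Must be
#'   positive; larger values mean slower germination at a given driving
#'   potential.
#'
#' @return An object of class `hydrotime_params`.
#' @examples
#' hydrotime_params(psi_b50 = -1.073, sigma = 0.339, theta_h = 43.054)
#' @export
hydrotime_params <- function(psi_b50, sigma, theta_h) {
  stopifnot(is.numeric(psi_b50), length(psi_b50) == 1L, is.finite(psi_b50))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive finite number (MPa)", call. = FALSE)
  if (!is.numeric(theta_h) || length(theta_h) != 1L || !is.finite(theta_h) || theta_h <= 0)
    stop("`theta_h` must be a single positive finite number (MPa h)", call. = FALSE)
  structure(
    list(psi_b50 = as.numeric(psi_b50), sigma = as.numeric(sigma),
         theta_h = as.numeric(theta_h)),
    class = "hydrotime_params"
  )
}

#' @export
print.hydrotime_params <- function(x, ...) {
  cat("Hydrotime model parameters\n")
  cat(sprintf("  psi_b50 : %8.4f MPa\n", x$psi_b50))
  cat(sprintf("  sigma   : %8.4f MPa\n", x$sigma))
  cat(sprintf("  theta_H : %8.4f MPa h\n", x$theta_h))
  invisible(x)
}

#' Probit transformation
#'
#' Inverse standard-normal cumulative distribution function, used to
#' linearise cumulative germination fractions under a normal threshold
#' model. Boundary fractions (0 and 1) map to infinite probits and are
#' rejected; callers must exclude them before fitting.
#'
#' @param g Numeric vector of fractions, each strictly inside (0, 1).
#' @return Standard-normal quantiles `z` with `pnorm(z) == g`.
#' @examples
#' probit(0.5)     # 0
#' probit(0.8413)  # about 1
#' @export
probit <- function(g) {
  if (!is.numeric(g) || any(!is.finite(g)))
    stop("`g` must be finite numeric", call. = FALSE)
  if (any(g <= 0 | g >= 1))
    stop("probit is defined only on the open interval (0, 1); exclude boundary fractions",
         call. = FALSE)
  stats::qnorm(g)
}

#' Predicted cumulative germination fraction
#'
#' Forward prediction of the hydrotime model: the expected fraction of the
#' seed population germinated by time `t` at water potential `psi` is
#' \deqn{g(t) = \Phi\left(\frac{\Psi - \theta_H / t - \Psi_b(50)}{\sigma}\right).}
#'
#' @param params A [hydrotime_params()] object.
#' @param psi Water potential in MPa (vectorised).
#' @param t Time since imbibition in hours, strictly positive (vectorised).
#' @return Expected cumulative germinated fraction(s) in (0, 1),
#'   non-decreasing in both `t` and `psi`.
#' @examples
#' p <- hydrotime_params(-1.073, 0.339, 43.054)
#' predict_fraction(p, psi = 0, t = 168)
#' @export
predict_fraction <- function(params, psi, t) {
  stopifnot(inherits(params, "hydrotime_params"))
  if (any(!is.finite(t)) || any(t <= 0))
    stop("`t` must be positive and finite (hours)", call. = FALSE)
  stats::pnorm((psi - params$theta_h / t - params$psi_b50) / params$sigma)
}

#' Germination time of an individual seed
#'
#' Inverts the hydrotime accumulation rule for a single seed with base
#' water potential `psi_b_seed`: germination occurs when
#' \eqn{(\Psi - \Psi_b) t = \theta_H}, i.e. at
#' \eqn{t = \theta_H / (\Psi - \Psi_b)}. A seed whose base potential is at
#' or above the ambient potential accumulates no hydrotime and never
#' germinates; this is reported as `Inf`, a value, not an error.
#'
#' @param params A [hydrotime_params()] object.
#' @param psi_b_seed Base water potential(s) of individual seeds, MPa.
#' @param psi Ambient water potential, MPa.
#' @return Germination time(s) in hours; `Inf` for non-germinating seeds.
#' @export
seed_germination_time <- function(params, psi_b_seed, psi) {
  stopifnot(inherits(params, "hydrotime_params"))
  drive <- psi - psi_b_seed
  ifelse(drive > 0, params$theta_h / drive, Inf)
}

# Probit regression for one theta candidate: regress probit(g) on
# x = psi - theta/t. Returns r.squared, slope, intercept.
probit_fit_for_theta <- function(theta, psi, t, probit_g) {
  x <- psi - theta / t
  fit <- stats::lm.fit(cbind(1, x), probit_g)
  res <- fit$residuals
  tss <- sum((probit_g - mean(probit_g))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  list(r_squared = r2, intercept = fit$coefficients[[1]],
       slope = fit$coefficients[[2]])
}

#' Fit the hydrotime model by repeated probit regression
#'
#' Estimates \eqn{\Psi_b(50)}, \eqn{\sigma_{\Psi b}} and \eqn{\theta_H}
#' from cumulative germination fractions observed at two or more water
#' potentials. For each candidate \eqn{\theta_H} the observations are
#' linearised as \eqn{x_i = \Psi_i - \theta_H / t_i} and
#' \eqn{\mathrm{probit}(g_i)} is regressed on \eqn{x_i} by ordinary least
#' squares, pooled across all water-potential levels; the candidate
#' maximising \eqn{R^2} is selected by a 1-D Brent search refined to
#' `tol`. At the optimum, \eqn{\sigma = 1/\mathrm{slope}} and
#' \eqn{\Psi_b(50) = -\mathrm{intercept} \cdot \sigma}.
#'
#' Cumulative fractions at exactly 0 or 1 carry infinite probits and are
#' dropped before fitting; fractions are relative to seeds sown, with
#' non-germination absorbed by the base-water-potential distribution.
#'
#' @param data A data frame with columns `psi` (MPa), `time_h` (hours)
#'   and `fraction` (cumulative germinated fraction of seeds sown), one
#'   row per observation, or a dataset returned by
#'   [simulate_germination()] (its `observations` element is used, with
#'   replicates pooled by summing counts).
#' @param theta_range Search interval for \eqn{\theta_H} in MPa h.
#' @param tol Absolute tolerance of the \eqn{\theta_H} search.
#' @return An object of class `hydrotime_fit`: a list with elements
#'   `params` ([hydrotime_params()]), `r_squared`, `n_points`,
#'   `theta_grid_best` (equal to `params$theta_h`), `slope` and
#'   `intercept` of the final probit regression.
#' @examples
#' truth <- hydrotime_params(-1.0, 0.3, 40)
#' grid <- expand.grid(psi = c(0, -0.5), time_h = seq(12, 144, by = 12))
#' grid$fraction <- predict_fraction(truth, grid$psi, grid$time_h)
#' fit_hydrotime(grid)
#' @export
fit_hydrotime <- function(data, theta_range = c(0.1, 500), tol = 1e-3) {
  df <- as_fraction_table(data)
  usable <- df$fraction > 0 & df$fraction < 1
  df <- df[usable, , drop = FALSE]
  if (nrow(df) < 3L)
    stop("hydrotime fit is under-determined: fewer than 3 observations with ",
         "0 < fraction < 1", call. = FALSE)
  if (length(unique(df$psi)) < 2L)
    stop("hydrotime fit is under-determined: a single water-potential level ",
         "cannot separate theta_H from psi_b(50)", call. = FALSE)
  pg <- probit(df$fraction)
  if (stats::var(pg) == 0)
    stop("degenerate hydrotime fit: all usable fractions are identical",
         call. = FALSE)
  objective <- function(theta)
    probit_fit_for_theta(theta, df$psi, df$time_h, pg)$r_squared
  opt <- stats::optimize(objective, interval = theta_range,
                         maximum = TRUE, tol = tol)
  best <- probit_fit_for_theta(opt$maximum, df$psi, df$time_h, pg)
  if (!is.finite(best$slope) || best$slope <= 0)
    stop("degenerate hydrotime fit: non-positive probit slope at the optimal ",
         "theta_H (no usable dose-response signal)", call. = FALSE)
  sigma <- 1 / best$slope
  psi_b50 <- -best$intercept * sigma
  structure(
    list(
      params = hydrotime_params(psi_b50, sigma, opt$maximum),
      r_squared = best$r_squared,
      n_points = nrow(df),
      theta_grid_best = opt$maximum,
      slope = best$slope,
      intercept = best$intercept
    ),
    class = "hydrotime_fit"
  )
}

#' @export
print.hydrotime_fit <- function(x, ...) {
  cat("Hydrotime model fit (repeated probit regression)\n")
  print(x$params)
  cat(sprintf("  R^2     : %.6f on %d observations\n", x$r_squared, x$n_points))
  invisible(x)
}

# Coerce fit input to a (psi, time_h, fraction) table. Accepts the list
# returned by simulate_germination(), a germination observation table
# with counts (replicates pooled by summing), or a ready-made fraction
# table.
as_fraction_table <- function(data) {
  if (is.list(data) && !is.data.frame(data) && !is.null(data$observations))
    data <- data$observations
  if (!is.data.frame(data))
    stop("`data` must be a data frame or a simulate_germination() result",
         call. = FALSE)
  if (all(c("psi", "time_h", "fraction") %in% names(data)))
    return(tibble::as_tibble(data[, c("psi", "time_h", "fraction")]))
  cols <- c("psi", "time_h", "n_germ_cum", "n_total")
  if (all(cols %in% names(data))) {
    pooled <- dplyr::summarise(
      dplyr::group_by(data, .data$psi, .data$time_h),
      n_germ_cum = sum(.data$n_germ_cum),
      n_total = sum(.data$n_total),
      .groups = "drop"
    )
    pooled$fraction <- pooled$n_germ_cum / pooled$n_total
    return(pooled[, c("psi", "time_h", "fraction")])
  }
  stop("`data` must have columns (psi, time_h, fraction) or ",
       "(psi, time_h, n_germ_cum, n_total)", call. = FALSE)
}
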