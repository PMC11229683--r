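#' Pool replicate germination series into a cumulative curve
#'
#' Aggregates daily germination scoring for one water-potential treatment
#' into a single cumulative curve. Replicates are pooled by summing
#' germinated and sown counts at matching observation times, so the curve
#' is count-weighted; the germinated fraction is taken relative to seeds
#' sown, not to the final germinated count.
#'
#' @param observations Data frame with columns `psi` (one value), `replicate`,
#'   `time_h`, `n_germ_cum` (cumulative germinated count) and `n_total`
#'   (seeds sown), one row per replicate x observation time.
#' @return An object of class `germination_curve`: a tibble with columns
#'   `time_h` (strictly increasing) and `fraction`, plus attributes
#'   `psi`, `n_total` (pooled seeds sown) and `max_fraction` (final
#'   plateau fraction).
#' @examples
#' obs <- data.frame(psi = 0, replicate = "r1", time_h = c(24, 48),
#'                   n_germ_cum = c(10, 25), n_total = 50)
#' build_curve(obs)
#' @export
build_curve <- function(observations) {
  req <- c("psi", "time_h", "n_germ_cum", "n_total")
  if (!is.data.frame(observations) || nrow(observations) == 0L)
    stop("`observations` must be a non-empty data frame", call. = FALSE)
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols))
    stop("`observations` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  obs <- tibble::as_tibble(observations)
  if (!"replicate" %in% names(obs)) obs$replicate <- "r1"
  if (length(unique(obs$psi)) != 1L)
    stop("all observations must share one water potential; got psi = ",
         paste(sort(unique(obs$psi)), collapse = ", "), call. = FALSE)
  if (any(obs$n_germ_cum > obs$n_total))
    stop("cumulative germinated count exceeds seeds sown", call. = FALSE)
  if (any(obs$n_germ_cum < 0) || any(obs$n_total <= 0))
    stop("counts must satisfy 0 <= n_germ_cum <= n_total, n_total > 0",
         call. = FALSE)

  # each replicate series must be observed on the same time grid and be
  # individually monotone
  grids <- split(obs$time_h, obs$replicate)
  ref_grid <- sort(unique(obs$time_h))
  bad <- vapply(grids, function(g) !identical(sort(g), ref_grid), logical(1))
  if (any(bad)) {
    offending <- lapply(grids[bad], function(g) {
      sort(unique(c(setdiff(ref_grid, g), setdiff(g, ref_grid))))
    })
    stop("replicate time grids do not match at times: ",
         paste(unique(unlist(offending)), collapse = ", "), call. = FALSE)
  }
  for (r in names(grids)) {
    series <- obs[obs$replicate == r, ]
    series <- series[order(series$time_h), ]
    if (is.unsorted(series$n_germ_cum))
      stop("replicate '", r, "' has a decreasing cumulative count", call. = FALSE)
  }

  pooled <- dplyr::summarise(
    dplyr::group_by(obs, .data$time_h),
    n_germ_cum = sum(.data$n_germ_cum),
    n_total = sum(.data$n_total),
    .groups = "drop"
  )
  pooled <- pooled[order(pooled$time_h), ]
  curve <- tibble::tibble(
    time_h = pooled$time_h,
    fraction = pooled$n_germ_cum / pooled$n_total
  )
  structure(curve,
            class = c("germination_curve", class(curve)),
            psi = obs$psi[[1]],
            n_total = pooled$n_total[[1]],
            max_fraction = curve$fraction[[nrow(curve)]])
}

#' @export
print.germination_curve <- function(x, ...) {
  cat(sprintf("Germination curve at psi = %g MPa (%d seeds pooled, final fraction %.3f)\n",
              attr(x, "psi"), attr(x, "n_total"), attr(x, "max_fraction")))
  NextMethod()
}

# Earliest time at which the curve reaches `level`, linearly interpolating
# on the fraction scale between the bracketing observations. If the level
# equals an observed fraction the observed time is returned; if the level
# is already met at the first observation (nothing to bracket, as with a
# single-step curve) the interpolation degenerates to that observation
# time.
crossing_time <- function(time_h, fraction, level) {
  hit <- which(fraction >= level)
  if (!length(hit)) return(NA_real_)
  i <- hit[[1]]
  if (fraction[[i]] == level || i == 1L) return(time_h[[i]])
  t0 <- time_h[[i - 1L]]
  f0 <- fraction[[i - 1L]]
  t0 + (level - f0) / (fraction[[i]] - f0) * (time_h[[i]] - t0)
}

#' Germination-curve summary metrics
#'
#' Computes the three curve summaries used to compare seed lots across
#' drought treatments: `t50_h`, the time to reach 50% of maximum
#' germination; `u7525_h`, the time span between 25% and 75% of maximum
#' germination (a uniformity measure); and `auc`, the trapezoidal area
#' under the germination-percentage curve (0-100 scale) over
#' `[0, auc_window_h]` hours. Crossing times are linearly interpolated
#' between adjacent observations; for the area, the curve is held at 0
#' before the first observation and at its last value beyond the final
#' one.
#'
#' @param curve A [build_curve()] result, or any data frame with columns
#'   `time_h` and `fraction`.
#' @param auc_window_h Upper limit of the area window, hours.
#' @return A one-row tibble with columns `t50_h`, `u7525_h`, `auc`
#'   (percent hours) and `max_fraction`. When nothing germinated, `t50_h`
#'   and `u7525_h` are `NA` and `auc` is 0.
#' @examples
#' crv <- build_curve(data.frame(psi = 0, replicate = "r1",
#'                               time_h = c(24, 48, 72),
#'                               n_germ_cum = c(10, 25, 40), n_total = 50))
#' germination_metrics(crv)
#' @export
germination_metrics <- function(curve, auc_window_h = 72) {
  if (!is.data.frame(curve) || nrow(curve) == 0L)
    stop("`curve` must be a non-empty data frame", call. = FALSE)
  stopifnot(all(c("time_h", "fraction") %in% names(curve)))
  tm <- curve$time_h
  fr <- curve$fraction
  if (is.unsorted(tm, strictly = TRUE))
    stop("`time_h` must be strictly increasing", call. = FALSE)
  if (is.unsorted(fr) || any(fr < 0) || any(fr > 1))
    stop("`fraction` must be non-decreasing within [0, 1]", call. = FALSE)
  max_fraction <- fr[[length(fr)]]

  if (max_fraction == 0) {
    return(tibble::tibble(t50_h = NA_real_, u7525_h = NA_real_,
                          auc = 0, max_fraction = 0))
  }
  t50 <- crossing_time(tm, fr, 0.50 * max_fraction)
  t25 <- crossing_time(tm, fr, 0.25 * max_fraction)
  t75 <- crossing_time(tm, fr, 0.75 * max_fraction)

  # trapezoid on the percentage scale over [0, auc_window_h]; extend with
  # the plateau value if scoring stopped early, clip at the window if not
  grid_t <- c(0, tm)
  grid_f <- c(0, fr) * 100
  if (grid_t[[length(grid_t)]] < auc_window_h) {
    grid_t <- c(grid_t, auc_window_h)
    grid_f <- c(grid_f, grid_f[[length(grid_f)]])
  }
  keep <- grid_t <= auc_window_h
  inside_t <- grid_t[keep]
  inside_f <- grid_f[keep]
  if (max(inside_t) < auc_window_h) {
    f_at_window <- stats::approx(grid_t, grid_f, xout = auc_window_h)$y
    inside_t <- c(inside_t, auc_window_h)
    inside_f <- c(inside_f, f_at_window)
  }
  k <- length(inside_t)
  auc <- sum(diff(inside_t) * (inside_f[-k] + inside_f[-1]) / 2)

  tibble::tibble(t50_h = t50, u7525_h = t75 - t25, auc = auc,
                 max_fraction = max_fraction)
}

#' Read a germination scoring table
#'
#' Reads the CSV layout used for germination experiments: one row per
#' replicate x observation time with columns `psi_mpa`, `replicate`,
#' `time_h`, `n_germ_cum`, `n_total` (an optional `cultivar` column is
#' carried through).
#'
#' @param path CSV file path.
#' @return A tibble with `psi` (renamed from `psi_mpa`) and the remaining
#'   columns.
#' @export
read_germination_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"psi_mpa" %in% names(df))
    stop("germination CSV must have a `psi_mpa` column", call. = FALSE)
  dplyr::rename(df, psi = "psi_mpa")
}

#' Metrics for every treatment in a germination table
#'
#' Convenience wrapper: groups a scoring table by water potential (and
#' cultivar when present), builds each pooled curve and computes its
#' summary metrics.
#'
#' @inheritParams germination_metrics
#' @param observations Table as returned by [read_germination_csv()].
#' @return A tibble with one row per treatment and the metric columns of
#'   [germination_metrics()].
#' @export
germination_metrics_table <- function(observations, auc_window_h = 72) {
  keys <- intersect(c("cultivar", "psi"), names(observations))
  if (!"psi" %in% keys) stop("`observations` needs a `psi` column", call. = FALSE)
  groups <- dplyr::group_split(dplyr::group_by(observations,
                                               dplyr::across(dplyr::all_of(keys))))
  rows <- lapply(groups, function(g) {
    m <- germination_metrics(build_curve(g), auc_window_h = auc_window_h)
    dplyr::bind_cols(unique(g[, keys, drop = FALSE]), m)
  })
  dplyr::bind_rows(rows)
}
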