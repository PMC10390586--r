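#' Total activity series and its moments
#'
#' `total_activity()` sums a conflated activity raster over nodes,
#' \eqn{A(t) = \sum_i s_i(t)}. `activity_stats()` returns the time-mean
#' \eqn{\langle A \rangle} and the population standard deviation
#' \eqn{\sigma_A} (divisor \eqn{t_{sim}}, not \eqn{t_{sim} - 1}).
#'
#' @param raster n_nodes x t_sim matrix with entries 0/1, or an
#'   `activity_raster`.
#' @return `total_activity()`: numeric series of length t_sim.
#' @export
total_activity <- function(raster) {
  if (inherits(raster, "activity_raster")) raster <- raster$raster
  if (length(raster) == 0L) stop("empty raster")
  colSums(raster)
}

#' @rdname total_activity
#' @param a numeric activity series.
#' @return `activity_stats()`: named vector `c(mean = , sd = )`.
#' @export
activity_stats <- function(a) {
  if (length(a) < 1L) stop("empty activity series")
  m <- mean(a)
  c(mean = m, sd = sqrt(mean((a - m)^2)))
}

#' Lag-1 autocorrelation of an activity series
#'
#' Standard lag-1 estimator with the overall mean and population variance:
#' \deqn{\rho(1) = \frac{\sum_{t=1}^{T-1}(A_t - \bar A)(A_{t+1} - \bar A)}
#' {\sum_{t=1}^{T}(A_t - \bar A)^2}.}
#' Returns 0 by convention when the series has zero variance. Near a
#' continuous transition the activity becomes temporally correlated, so
#' \eqn{\rho(1)} peaks together with the other criticality indicators.
#'
#' @param a numeric series of length >= 2.
#' @return scalar in \[-1, 1\].
#' @export
autocorr1 <- function(a) {
  if (length(a) < 2L) stop("series must have at least 2 points")
  m <- mean(a)
  denom <- sum((a - m)^2)
  if (denom == 0) return(0)
  tt <- length(a)
  sum((a[-tt] - m) * (a[-1L] - m)) / denom
}

#' Variance of the largest-cluster series
#'
#' Population variance of \eqn{S_1(t)}; like \eqn{\sigma_A} it peaks near
#' the transition.
#'
#' @param series a `cluster_series` (or numeric S1 series).
#' @return scalar variance.
#' @export
var_largest_cluster <- function(series) {
  s1 <- if (inherits(series, "cluster_series")) series$s1 else as.numeric(series)
  if (length(s1) < 1L) stop("empty series")
  mean((s1 - mean(s1))^2)
}

#' Indicator curve over a control-parameter grid
#'
#' @param grid strictly ascending control-parameter values (threshold or
#'   temperature).
#' @param values indicator values, same length as `grid`.
#' @param name indicator identifier.
#' @return object of class `indicator_curve`.
#' @export
indicator_curve <- function(grid, values, name = "indicator") {
  grid <- as.numeric(grid); values <- as.numeric(values)
  if (length(grid) != length(values)) stop("grid and values lengths differ")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly ascending")
  structure(list(grid = grid, values = values, name = name),
            class = "indicator_curve")
}

#' @export
print.indicator_curve <- function(x, ...) {
  cat("<indicator_curve> ", x$name, ": ", length(x$grid), " points on [",
      min(x$grid), ", ", max(x$grid), "]\n", sep = "")
  invisible(x)
}

#' Area under an indicator curve
#'
#' Trapezoidal integral over the sampled grid; for the second-largest cluster
#' curve this is \eqn{I_2 = \int S_2 \, d\mathcal{T}}, the scalar summary that
#' captures the loss of the critical peak (high \eqn{S_2} at low threshold
#' inflates it). Comparisons across conditions must share one grid.
#'
#' @param curve an `indicator_curve` with >= 2 points.
#' @return scalar area.
#' @export
area_under_s2 <- function(curve) {
  if (!inherits(curve, "indicator_curve")) stop("expected an indicator_curve")
  g <- curve$grid; v <- curve$values
  if (length(g) < 2L) stop("need at least 2 grid points")
  sum(diff(g) * (utils::head(v, -1L) + utils::tail(v, -1L)) / 2)
}

#' Grid location of a curve's maximum
#'
#' Argmax over the sampled grid (ties broken towards the smaller grid
#' value). `is_interior` is `FALSE` when the maximum sits on either grid
#' boundary - the operational signature of a "lost" critical peak.
#'
#' @param curve an `indicator_curve` with >= 3 points.
#' @return list with `value` (grid location), `index`, and `is_interior`.
#' @export
peak_location <- function(curve) {
  if (!inherits(curve, "indicator_curve")) stop("expected an indicator_curve")
  if (length(curve$grid) < 3L) stop("need at least 3 grid points")
  k <- which.max(curve$values)
  list(value = curve$grid[k], index = k,
       is_interior = k > 1L && k < length(curve$grid))
}

#' Mean-field critical threshold of the excitable automaton
#'
#' \deqn{\mathcal{T}_c = \langle w^{in} \rangle \frac{r_2}{1 + 2 r_2},}
#' with \eqn{\langle w^{in} \rangle} the average in-strength. For an
#' in-strength-normalized network \eqn{\langle w^{in} \rangle = 1}.
#'
#' @param net a `weighted_network`.
#' @param r2 refractory release probability in (0, 1\].
#' @return scalar threshold estimate.
#' @examples
#' lat <- build_lattice(lattice_spec(3, 3))
#' mean_field_tc(lat$network, r2 = 0.3)
#' @export
mean_field_tc <- function(net, r2) {
  stopifnot_network(net)
  mean_w_in <- mean(Matrix::rowSums(net$weights))
  mean_w_in * r2 / (1 + 2 * r2)
}

#' Normalize a curve to its maximum
#'
#' @param curve an `indicator_curve` with positive maximum.
#' @return the curve scaled so its maximum is exactly 1.
#' @export
normalize_to_max <- function(curve) {
  if (!inherits(curve, "indicator_curve")) stop("expected an indicator_curve")
  mx <- max(curve$values)
  if (mx <= 0) stop("cannot normalize: curve maximum is not positive")
  indicator_curve(curve$grid, curve$values / mx, paste0(curve$name, "_norm"))
}

#' Relative change with respect to an unmodified baseline
#'
#' \eqn{A(\mathrm{norm.}) = (A - A^0) / A^0}: zero for the unmodified
#' system, positive/negative for quantities that grew/shrank after the
#' modification.
#'
#' @param value measured quantity after modification.
#' @param baseline value \eqn{A^0} in the unmodified system (nonzero).
#' @return scalar relative change.
#' @export
normalized_change <- function(value, baseline) {
  if (length(baseline) != 1L || baseline == 0) {
    stop("baseline must be a single nonzero value")
  }
  (value - baseline) / baseline
}

#' Sweep result container
#'
#' Bundles the indicator curves and (optionally) per-step cluster series
#' produced by [threshold_sweep()] or [temperature_sweep()]. Use
#' [as.data.frame.sweep_result()] for a tidy one-row-per-grid-point table and
#' [get_curve()] to extract a single `indicator_curve`.
#'
#' @param grid control-parameter grid.
#' @param rows per-grid-point summaries (internal layout).
#' @param control `"threshold"` or `"temperature"`.
#' @param params the base parameter object.
#' @param seeds per-grid-point sub-seeds.
#' @return object of class `sweep_result`.
#' @export
sweep_result <- function(grid, rows, control, params, seeds) {
  structure(list(grid = grid, rows = rows, control = control,
                 params = params, seeds = seeds),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", length(x$grid), " ", x$control, " values on [",
      min(x$grid), ", ", max(x$grid), "]\n", sep = "")
  pk <- peak_location(get_curve(x, "S2"))
  cat("  S2 peak at ", x$control, " = ", signif(pk$value, 4),
      if (pk$is_interior) " (interior)" else " (boundary)", "\n", sep = "")
  invisible(x)
}

#' Extract one indicator curve from a sweep result
#'
#' @param sweep a `sweep_result`.
#' @param name one of `"S1"`, `"S2"`, `"mean_A"`, `"sd_A"`, `"rho1"`,
#'   `"var_S1"`, or `"S1:<label>"` / `"S2:<label>"` for subsystem averages.
#' @return an `indicator_curve`.
#' @export
get_curve <- function(sweep, name) {
  if (!inherits(sweep, "sweep_result")) stop("expected a sweep_result")
  if (grepl(":", name, fixed = TRUE)) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1L]]
    stat <- parts[1L]; label <- parts[2L]
    vals <- vapply(sweep$rows, function(r) {
      if (is.null(r$sub_avg) || is.null(r$sub_avg[[label]])) {
        stop("no subsystem averages for label ", label)
      }
      r$sub_avg[[label]][[stat]]
    }, numeric(1))
  } else {
    vals <- vapply(sweep$rows, function(r) {
      if (is.null(r[[name]])) stop("unknown indicator: ", name)
      r[[name]]
    }, numeric(1))
  }
  indicator_curve(sweep$grid, vals, name)
}

#' @export
as.data.frame.sweep_result <- function(x, ...) {
  base <- data.frame(
    control = x$grid,
    S1 = vapply(x$rows, `[[`, numeric(1), "S1"),
    S2 = vapply(x$rows, `[[`, numeric(1), "S2"),
    mean_A = vapply(x$rows, `[[`, numeric(1), "mean_A"),
    sd_A = vapply(x$rows, `[[`, numeric(1), "sd_A"),
    rho1 = vapply(x$rows, `[[`, numeric(1), "rho1"),
    var_S1 = vapply(x$rows, `[[`, numeric(1), "var_S1"),
    seed = x$seeds
  )
  names(base)[1L] <- x$control
  sub <- x$rows[[1L]]$sub_avg
  if (!is.null(sub)) {
    for (lb in names(sub)) {
      base[[paste0("S1_", lb)]] <-
        vapply(x$rows, function(r) r$sub_avg[[lb]][["S1"]], numeric(1))
      base[[paste0("S2_", lb)]] <-
        vapply(x$rows, function(r) r$sub_avg[[lb]][["S2"]], numeric(1))
    }
  }
  base
}

#' Export a sweep result as TSV
#'
#' One row per grid point with all indicator columns (and subsystem averages
#' when present).
#' @param sweep a `sweep_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sweep_tsv <- function(sweep, path) {
  utils::write.table(as.data.frame(sweep), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
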