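#' Sweep one model parameter against a target PSD
#'
#' The practical-identifiability workhorse: vary a single model parameter
#' over a set of values, simulate the compartment at each value and record
#' the energy distance to a fixed target. On a sectional grid, step-location
#' parameters only change the model output when they cross a representative
#' size, so the resulting distance profile is a staircase; the plateau
#' structure (and how much of it falls below the measurement-error
#' threshold) quantifies how well the parameter can be estimated.
#'
#' @param template List with elements `inlet` (a `psd`) and `comp` (a
#'   [compartment()]); all parameters other than the swept one are taken
#'   from the template.
#' @param target Target `psd` on the same grid.
#' @param param_name Name of a kernel or breakage parameter (e.g. `"R2"`,
#'   `"step"`, `"R"`, `"beta0"`, `"S0"`).
#' @param values Numeric vector (length >= 2) of values to sweep.
#' @param flat_tol Plateau tolerance on the min-max normalized profile
#'   (default `1e-3`).
#' @param threshold Optional measurement-error threshold (same units as the
#'   distance) for the uniqueness diagnostics.
#' @return An object of class `pbm_sweep`: list with `param`, `values`,
#'   `distance`, `normalized` (min-max to [0, 1]), `failed` (per-point
#'   simulation failures), `plateaus`, and when a threshold is given
#'   `threshold`, `below_threshold` (count) and `below_idx`.
#' @export
sweep_parameter <- function(template, target, param_name, values,
                            flat_tol = 1e-3, threshold = NULL) {
  if (!is.list(template) || !inherits(template$inlet, "psd") ||
      !inherits(template$comp, "compartment")) {
    stop("template must be a list with a 'psd' inlet and a 'compartment' comp",
         call. = FALSE)
  }
  stopifnot(inherits(target, "psd"))
  if (!is.numeric(values) || length(values) < 2 || any(!is.finite(values))) {
    stop("values must be a finite numeric vector of length >= 2", call. = FALSE)
  }
  dist <- rep(NA_real_, length(values))
  for (k in seq_along(values)) {
    comp <- set_compartment_param(template$comp, param_name, values[k])
    out <- tryCatch(integrate_compartment(template$inlet, comp),
                    error = function(e) NULL)
    if (!is.null(out)) dist[k] <- energy_distance(out, target)
  }
  failed <- is.na(dist)
  if (all(failed)) stop("simulation failed at every swept value", call. = FALSE)
  ok <- dist[!failed]
  rng <- range(ok)
  normalized <- if (diff(rng) > 0) (dist - rng[1]) / diff(rng) else dist * 0
  res <- structure(
    list(param = param_name, values = values, distance = dist,
         normalized = normalized, failed = failed,
         plateaus = NULL, threshold = threshold,
         below_threshold = NULL, below_idx = NULL),
    class = "pbm_sweep"
  )
  res$plateaus <- detect_plateaus(res, flat_tol)
  if (!is.null(threshold)) {
    u <- uniqueness_below_threshold(res, threshold)
    res$below_threshold <- u$count
    res$below_idx <- u$idx
  }
  res
}

#' Detect plateaus in a sweep profile
#'
#' Splits the swept points into maximal runs in which consecutive normalized
#' distances vary by less than `flat_tol`; the boundaries between runs are
#' the step locations of the staircase.
#'
#' @param sweep A `pbm_sweep`.
#' @param flat_tol Positive tolerance on the normalized profile.
#' @return Data frame with one row per plateau: `start`, `end` (indices into
#'   `sweep$values`), `length` and mean normalized `level`.
#' @export
detect_plateaus <- function(sweep, flat_tol = 1e-3) {
  stopifnot(inherits(sweep, "pbm_sweep"))
  if (!is.finite(flat_tol) || flat_tol <= 0) {
    stop("flat_tol must be > 0", call. = FALSE)
  }
  z <- sweep$normalized
  n <- length(z)
  brk <- c(TRUE, abs(diff(z)) >= flat_tol | is.na(diff(z)))
  run_id <- cumsum(brk)
  starts <- which(brk)
  ends <- c(starts[-1] - 1L, n)
  data.frame(
    start = starts, end = ends, length = ends - starts + 1L,
    level = vapply(split(z, run_id), mean, 1, na.rm = TRUE),
    row.names = NULL
  )
}

#' Count swept values below a distance threshold
#'
#' A swept parameter is practically identifiable at a given measurement
#' error when exactly one swept value produces a model-target distance below
#' the threshold; several values below means the data cannot distinguish
#' them, none means the model cannot reach the data at all.
#'
#' @param sweep A `pbm_sweep`.
#' @param threshold Positive distance threshold (raw distance units, e.g.
#'   from [measurement_error_threshold()]).
#' @return List with `count`, `idx` (indices below), and `identifiable`
#'   (`TRUE` iff `count == 1`).
#' @export
uniqueness_below_threshold <- function(sweep, threshold) {
  stopifnot(inherits(sweep, "pbm_sweep"))
  if (!is.finite(threshold) || threshold <= 0) {
    stop("threshold must be > 0", call. = FALSE)
  }
  idx <- which(!sweep$failed & sweep$distance < threshold)
  list(count = length(idx), idx = idx, identifiable = length(idx) == 1L)
}

#' Count intermediate discretized levels of the double-step kernel
#'
#' On the sectional grid, the smooth step of the double-step kernel is only
#' evaluated at representative sizes, so for a given step location `R2` the
#' kernel multiplier takes at most a handful of values strictly between its
#' low and high plateaus. This diagnostic fixes one partner size, evaluates
#' the multiplier at every representative size for each swept `R2`, counts
#' the values strictly inside the plateau gap (beyond 1% of the gap from
#' either plateau) and returns the maximum count over the sweep. A sharp
#' smoother on the default grid yields at most two such intermediate levels;
#' a smoother wide relative to the bin spacing yields many.
#'
#' @param kernel_spec A `tanh_double_step` [aggregation_kernel()].
#' @param grid A `size_grid`.
#' @param fixed_size Volume (\eqn{\mu m^3}) of the fixed partner particle
#'   (normally a representative volume).
#' @param sweep_values_for_R2 Numeric vector of `R2` values (\eqn{\mu m}).
#' @return Maximum number of intermediate levels over the sweep.
#' @export
discretized_step_levels <- function(kernel_spec, grid, fixed_size,
                                    sweep_values_for_R2) {
  stopifnot(inherits(kernel_spec, "aggregation_kernel"),
            inherits(grid, "size_grid"))
  if (kernel_spec$variant != "tanh_double_step") {
    stop("discretized_step_levels applies to the tanh_double_step kernel only",
         call. = FALSE)
  }
  if (!is.finite(fixed_size) || fixed_size <= 0) {
    stop("fixed_size must be a positive volume", call. = FALSE)
  }
  v <- grid$representative_volumes
  gap <- kernel_spec$top1 - kernel_spec$top2
  tol <- 0.01 * gap
  max_count <- 0L
  for (R2 in sweep_values_for_R2) {
    spec <- kernel_spec
    spec$R2 <- R2
    mult <- kernel_value(spec, v, rep(fixed_size, length(v))) /
      (v^(1 / 3) * fixed_size^(1 / 3))
    inter <- mult > kernel_spec$top2 + tol & mult < kernel_spec$top1 - tol
    max_count <- max(max_count, sum(inter))
  }
  max_count
}

#' @export
print.pbm_sweep <- function(x, ...) {
  ok <- !x$failed
  cat(sprintf(
    "Sweep of '%s': %d values (%d failed), distance %.4g-%.4g, %d plateau(s)\n",
    x$param, length(x$values), sum(x$failed),
    min(x$distance[ok]), max(x$distance[ok]), nrow(x$plateaus)
  ))
  if (!is.null(x$threshold)) {
    cat(sprintf("  threshold %.4g: %d value(s) below -> %s\n", x$threshold,
                x$below_threshold,
                if (x$below_threshold == 1) "identifiable at this error level"
                else if (x$below_threshold == 0) "optimum not attainable"
                else "not uniquely identifiable"))
  }
  invisible(x)
}

#' @export
plot.pbm_sweep <- function(x, ..., normalized = TRUE) {
  y <- if (normalized) x$normalized else x$distance
  graphics::plot(x$values, y, type = "s", xlab = x$param,
                 ylab = if (normalized) "normalized distance" else "distance",
                 ...)
  if (!is.null(x$threshold) && !normalized) {
    graphics::abline(h = x$threshold, lty = 2)
  }
  invisible(x)
}
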