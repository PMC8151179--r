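#' Equivalent-sphere volume of a particle diameter
#'
#' The internal coordinate of the population balance is particle volume
#' (\eqn{\mu m^3}); sizes are reported as equivalent-sphere diameters
#' (\eqn{\mu m}). `volume_of_diameter()` and `diameter_of_volume()` convert
#' between the two via \eqn{v = (\pi/6) d^3}.
#'
#' @param d Particle diameter(s) in \eqn{\mu m}; must be positive.
#' @return Particle volume(s) in \eqn{\mu m^3}.
#' @examples
#' volume_of_diameter(100)            # ~5.236e5
#' diameter_of_volume(pi / 6)         # 1
#' @export
volume_of_diameter <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("diameters must be positive and finite", call. = FALSE)
  }
  (pi / 6) * d^3
}

#' @rdname volume_of_diameter
#' @param v Particle volume(s) in \eqn{\mu m^3}; must be positive.
#' @export
diameter_of_volume <- function(v) {
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("volumes must be positive and finite", call. = FALSE)
  }
  (6 * v / pi)^(1 / 3)
}

#' Build a geometric size grid over particle volume
#'
#' Constructs the sectional discretization used by the solver: `n_bins`
#' representative particle volumes spaced geometrically between
#' `volume_of_diameter(d_min)` and `volume_of_diameter(d_max)`, with bin edges
#' at the geometric midpoints between adjacent representatives and outer edges
#' extended by half a ratio step. The grid is fixed within any one analysis;
#' the default working grid of 35 bins over 1--4000 \eqn{\mu m} keeps every
#' representative diameter well below 7000 \eqn{\mu m}, so particles cannot
#' aggregate out of the system through the upper step of the double-step
#' kernel.
#'
#' @param n_bins Number of size classes (>= 2).
#' @param d_min,d_max Diameters (\eqn{\mu m}) of the smallest and largest
#'   representative size; `0 < d_min < d_max`.
#' @return An object of class `size_grid`: a list with `n_bins`,
#'   `representative_volumes`, `bin_edges` (length `n_bins + 1`),
#'   `representative_diameters` and the geometric `ratio`.
#' @examples
#' g <- build_geometric_grid(35, 1, 4000)
#' max(g$representative_diameters)  # 4000
#' @export
build_geometric_grid <- function(n_bins = 35, d_min = 1, d_max = 4000) {
  if (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins < 2 ||
      n_bins != round(n_bins)) {
    stop("n_bins must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(d_min) || !is.numeric(d_max) || length(d_min) != 1 ||
      length(d_max) != 1 || !is.finite(d_min) || !is.finite(d_max) ||
      d_min <= 0 || d_max <= d_min) {
    stop("diameter bounds must satisfy 0 < d_min < d_max", call. = FALSE)
  }
  if (d_max >= 7000) {
    # keeps every representative below the invisible upper kernel step, so
    # particles cannot aggregate out of the system
    stop("d_max must stay below 7000 um", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  v_min <- volume_of_diameter(d_min)
  v_max <- volume_of_diameter(d_max)
  # geometric spacing in volume
  lv <- seq(log(v_min), log(v_max), length.out = n_bins)
  vols <- exp(lv)
  half <- (lv[2] - lv[1]) / 2
  edges <- exp(c(lv[1] - half, lv + half))
  grid <- structure(
    list(
      n_bins = n_bins,
      representative_volumes = vols,
      bin_edges = edges,
      representative_diameters = diameter_of_volume(vols),
      ratio = exp(lv[2] - lv[1])
    ),
    class = "size_grid"
  )
  grid
}

#' @export
print.size_grid <- function(x, ...) {
  cat(sprintf(
    "Geometric size grid: %d bins, representative diameters %.4g-%.4g um (ratio %.6g in volume)\n",
    x$n_bins, min(x$representative_diameters),
    max(x$representative_diameters), x$ratio
  ))
  invisible(x)
}

# internal: grids are equal when their defining representatives agree
same_grid <- function(a, b, tol = 1e-12) {
  a$n_bins == b$n_bins &&
    all(abs(a$representative_volumes - b$representative_volumes) <=
          tol * b$representative_volumes)
}

# internal: index of the representative size nearest a diameter (ties to the
# smaller size)
nearest_representative <- function(grid, d) {
  dist <- abs(grid$representative_diameters - d)
  which(dist <= min(dist) + 0)[1]
}
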