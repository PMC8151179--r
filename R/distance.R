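#' Energy distance between two particle size distributions
#'
#' The calibration objective: the energy distance (equivalently, a maximum
#' mean discrepancy)
#' \deqn{D(u,v) = \big(2\,E|X-Y| - E|X-X'| - E|Y-Y'|\big)^{1/2}}
#' between the volume-fraction distributions of two PSDs on the same grid,
#' with `X, X'` drawn from `u` and `Y, Y'` from `v`. On a sectional grid with
#' weights `p`, `q` over support points `s` (the representative diameters in
#' \eqn{\mu m}, or their logarithms when `support = "log-diameter"`):
#' \deqn{D = \Big(2\sum_{ij} p_i q_j |s_i - s_j|
#'   - \sum_{ij} p_i p_j |s_i - s_j|
#'   - \sum_{ij} q_i q_j |s_i - s_j|\Big)^{1/2}.}
#' `D` is a metric on the normalized distributions: zero iff they agree,
#' symmetric, and satisfying the triangle inequality.
#'
#' @param u,v `psd` objects on the same grid.
#' @param support `"diameter"` (default, matching how measured PSDs are
#'   compared) or `"log-diameter"`.
#' @return Non-negative scalar distance.
#' @examples
#' g <- build_geometric_grid(10, 10, 1000)
#' a <- psd(g, c(1, rep(0, 9)))
#' b <- psd(g, c(rep(0, 9), 1))
#' energy_distance(a, b)
#' @export
energy_distance <- function(u, v, support = c("diameter", "log-diameter")) {
  stopifnot(inherits(u, "psd"), inherits(v, "psd"))
  support <- match.arg(support)
  if (!same_grid(u$grid, v$grid)) {
    stop("PSDs must share a grid", call. = FALSE)
  }
  p <- to_volume_fraction(u)
  q <- to_volume_fraction(v)
  s <- u$grid$representative_diameters
  if (support == "log-diameter") s <- log(s)
  A <- abs(outer(s, s, "-"))
  # grouped so the result is exactly symmetric in (u, v) in floating point
  cross <- (drop(p %*% A %*% q) + drop(q %*% A %*% p)) / 2
  d2 <- 2 * cross - (drop(p %*% A %*% p) + drop(q %*% A %*% q))
  sqrt(max(d2, 0))
}

#' Measurement-error threshold from repeated measurements
#'
#' The practical-identifiability workflow needs to know which model-data
#' distances are meaningful: the median of all unordered pairwise energy
#' distances among repeated PSD measurements (repeats of one measurement
#' and/or repeated experiments) gives the magnitude of distance that
#' measurement noise alone produces. The median is used rather than the mean
#' for robustness to outliers. Parameter values whose sweep distance falls
#' below this threshold cannot be distinguished from the optimum by the
#' available data.
#'
#' @param repeats List of at least two `psd` objects on a common grid.
#' @param support Passed to [energy_distance()].
#' @return Scalar threshold (median pairwise distance).
#' @export
measurement_error_threshold <- function(repeats,
                                        support = c("diameter", "log-diameter")) {
  support <- match.arg(support)
  if (!is.list(repeats) || length(repeats) < 2) {
    stop("need at least two repeated measurements", call. = FALSE)
  }
  k <- length(repeats)
  pairs <- utils::combn(k, 2)
  d <- apply(pairs, 2, function(idx) {
    energy_distance(repeats[[idx[1]]], repeats[[idx[2]]], support = support)
  })
  stats::median(d)
}
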