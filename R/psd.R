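#' Particle size distribution on a size grid
#'
#' A PSD is a vector of non-negative particle numbers per bin (per unit of a
#' fixed reference volume of material) attached to a [build_geometric_grid()]
#' grid. The volume-fraction view ([to_volume_fraction()]) is what the
#' granulation literature plots and what the energy distance compares.
#'
#' @param grid A `size_grid`.
#' @param number_per_bin Non-negative numeric vector of length
#'   `grid$n_bins`.
#' @return An object of class `psd`.
#' @export
psd <- function(grid, number_per_bin) {
  if (!inherits(grid, "size_grid")) stop("grid must be a size_grid", call. = FALSE)
  if (!is.numeric(number_per_bin) || length(number_per_bin) != grid$n_bins) {
    stop("number_per_bin must be numeric of length grid$n_bins", call. = FALSE)
  }
  if (any(!is.finite(number_per_bin)) || any(number_per_bin < 0)) {
    stop("number_per_bin must be finite and non-negative", call. = FALSE)
  }
  structure(list(grid = grid, number_per_bin = as.numeric(number_per_bin)),
            class = "psd")
}

#' Total particle volume of a PSD
#' @param x A `psd`.
#' @return Scalar total volume (\eqn{\mu m^3}).
#' @export
total_volume <- function(x) {
  stopifnot(inherits(x, "psd"))
  sum(x$number_per_bin * x$grid$representative_volumes)
}

#' Volume-fraction view of a PSD
#'
#' `fraction_i = n_i v_i / sum_j n_j v_j`; the fractions sum to one whenever
#' the PSD holds any material.
#'
#' @param x A `psd`.
#' @return Numeric vector of per-bin volume fractions.
#' @export
to_volume_fraction <- function(x) {
  stopifnot(inherits(x, "psd"))
  w <- x$number_per_bin * x$grid$representative_volumes
  tot <- sum(w)
  if (tot <= 0) stop("degenerate PSD: total volume is zero", call. = FALSE)
  w / tot
}

#' @export
print.psd <- function(x, ...) {
  occ <- sum(x$number_per_bin > 0)
  cat(sprintf(
    "PSD on %d-bin grid: total number %.6g, total volume %.6g um^3, %d occupied bins\n",
    x$grid$n_bins, sum(x$number_per_bin), total_volume(x), occ
  ))
  invisible(x)
}

#' @export
as.data.frame.psd <- function(x, ...) {
  data.frame(
    diameter_um = x$grid$representative_diameters,
    number = x$number_per_bin,
    volume_fraction = if (total_volume(x) > 0) to_volume_fraction(x) else 0
  )
}

#' @export
plot.psd <- function(x, ..., log = "x", type = "b",
                     xlab = "diameter (um)", ylab = "volume fraction") {
  graphics::plot(x$grid$representative_diameters, to_volume_fraction(x),
                 log = log, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Read and write PSD tables
#'
#' PSD tables are plain comma-separated text with a mandatory header and
#' columns `diameter_um` plus one of `number` or `volume_fraction`. The
#' diameters must form a geometric grid (constant ratio); volume fractions are
#' converted to numbers through the representative bin volumes.
#'
#' @param path File path.
#' @return `read_psd_table()` returns a `psd`; `write_psd_table()` invisibly
#'   returns `path`.
#' @export
read_psd_table <- function(path) {
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (!("diameter_um" %in% names(tab))) {
    stop("PSD table must have a 'diameter_um' column", call. = FALSE)
  }
  value_col <- intersect(c("number", "volume_fraction"), names(tab))
  if (length(value_col) == 0) {
    stop("PSD table must have a 'number' or 'volume_fraction' column",
         call. = FALSE)
  }
  value_col <- value_col[1]
  d <- tab$diameter_um
  val <- tab[[value_col]]
  if (any(!is.finite(d)) || any(d <= 0)) {
    bad <- which(!is.finite(d) | d <= 0)[1]
    stop(sprintf("invalid diameter in row %d", bad), call. = FALSE)
  }
  if (any(diff(d) <= 0)) {
    bad <- which(diff(d) <= 0)[1] + 1
    stop(sprintf("diameters not strictly increasing at row %d", bad),
         call. = FALSE)
  }
  if (any(!is.finite(val)) || any(val < 0)) {
    bad <- which(!is.finite(val) | val < 0)[1]
    stop(sprintf("negative or missing %s in row %d", value_col, bad),
         call. = FALSE)
  }
  n <- length(d)
  if (n < 2) stop("PSD table needs at least two rows", call. = FALSE)
  ratios <- d[-1] / d[-n]
  if (max(ratios) / min(ratios) - 1 > 1e-6) {
    stop("diameters do not form a geometric grid", call. = FALSE)
  }
  grid <- build_geometric_grid(n, d[1], d[n])
  if (value_col == "number") {
    psd(grid, val)
  } else {
    # volume fraction -> numbers via bin volumes (arbitrary unit total volume)
    psd(grid, val / grid$representative_volumes)
  }
}

#' @rdname read_psd_table
#' @param x A `psd`.
#' @export
write_psd_table <- function(x, path) {
  stopifnot(inherits(x, "psd"))
  tab <- data.frame(
    diameter_um = formatC(x$grid$representative_diameters, digits = 15,
                          format = "g"),
    number = formatC(x$number_per_bin, digits = 15, format = "g")
  )
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Locate the depletion point of a bimodal PSD
#'
#' The depletion point is the size at which the first (fines) peak of a
#' bimodal volume-fraction PSD dies out towards larger sizes: the first local
#' minimum after the first local maximum of the (lightly smoothed)
#' volume-fraction curve. Because it marks where un-granulated material ends,
#' it estimates the critical size `R` of the square-step aggregation kernel
#' directly from data, removing `R` from the calibration problem.
#'
#' A centred moving average of width 3 is applied before the extremum scan;
#' ties are broken toward the smaller size. The returned diameter is snapped
#' to the representative size of the valley bin.
#'
#' @param x A `psd`.
#' @return An object of class `depletion_point`: list with `found` (logical),
#'   `diameter` (\eqn{\mu m}, `NA` if not found), `bin` (index, `NA` if not
#'   found).
#' @export
estimate_depletion_size <- function(x) {
  stopifnot(inherits(x, "psd"))
  w <- to_volume_fraction(x)
  n <- length(w)
  # centred moving average width 3, partial windows at the ends
  sm <- w
  if (n >= 3) {
    sm[2:(n - 1)] <- (w[1:(n - 2)] + w[2:(n - 1)] + w[3:n]) / 3
    sm[1] <- (w[1] + w[2]) / 2
    sm[n] <- (w[n - 1] + w[n]) / 2
  }
  no_point <- structure(list(found = FALSE, diameter = NA_real_,
                             bin = NA_integer_), class = "depletion_point")
  # first local maximum: first k whose successor does not exceed it and that
  # exceeds its predecessor (k = 1 allowed)
  kmax <- NA_integer_
  for (k in seq_len(n - 1)) {
    if (sm[k + 1] < sm[k] && (k == 1 || sm[k] > sm[k - 1])) {
      kmax <- k
      break
    }
  }
  if (is.na(kmax)) return(no_point)
  # first turning point after the maximum: curve decreases, then rises again;
  # on a flat valley the tie goes to the smaller size
  for (k in seq(kmax + 1, length.out = max(0, n - kmax - 1))) {
    if (sm[k + 1] > sm[k] && sm[k] < sm[kmax]) {
      while (k > kmax + 1 && sm[k - 1] <= sm[k]) k <- k - 1
      return(structure(
        list(found = TRUE,
             diameter = x$grid$representative_diameters[k],
             bin = as.integer(k)),
        class = "depletion_point"
      ))
    }
  }
  no_point
}

#' @export
print.depletion_point <- function(x, ...) {
  if (x$found) {
    cat(sprintf("Depletion point: %.4g um (bin %d)\n", x$diameter, x$bin))
  } else {
    cat("No depletion point (PSD has no interior valley after its first peak)\n")
  }
  invisible(x)
}
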