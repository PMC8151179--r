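# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Measurement-noise specification
#'
#' Multiplicative log-normal perturbation per bin, emulating laser
#' diffraction / image analysis repeatability. The per-bin log-scale grows
#' linearly with bin index (measurements of granule PSDs get noisier for
#' larger particles): bin `i` of `N` uses
#' `sd_i = scale * (1 + growth * (i - 1) / (N - 1))`.
#'
#' @param scale Base log-scale of the perturbation (>= 0).
#' @param growth Linear growth factor toward the large-particle end
#'   (default 1: the last bin is twice as noisy as the first).
#' @param seed Integer seed for reproducible replicates.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(scale, growth = 1, seed = 1L) {
  if (!is.finite(scale) || scale < 0) stop("scale must be >= 0", call. = FALSE)
  if (!is.finite(growth) || growth < 0) stop("growth must be >= 0", call. = FALSE)
  structure(list(scale = scale, growth = growth, seed = as.integer(seed)),
            class = "noise_spec")
}

# internal: one noisy replicate (total volume preserved)
perturb_psd <- function(x, noise) {
  n <- x$grid$n_bins
  sd_i <- noise$scale * (1 + noise$growth * (seq_len(n) - 1) / (n - 1))
  num <- x$number_per_bin * exp(stats::rnorm(n, 0, sd_i))
  tot <- total_volume(x)
  out <- psd(x$grid, num)
  if (tot > 0 && total_volume(out) > 0) {
    out$number_per_bin <- out$number_per_bin * tot / total_volume(out)
  }
  out
}

#' Generate a synthetic preblend PSD
#'
#' Deterministic stand-in for a measured raw-material (preblend) PSD: a
#' log-normal number distribution in diameter, evaluated on the log-spaced
#' representative sizes (density in log-diameter, so number per bin is
#' `dlnorm(d_i) * d_i` up to scale) and scaled to `total_number` particles.
#' The volume-fraction view is unimodal with mode near
#' `median_diameter * exp(3 * log(geometric_sd)^2)`.
#'
#' @param grid A `size_grid`.
#' @param median_diameter Number-median diameter (\eqn{\mu m}); must lie
#'   inside the grid span.
#' @param geometric_sd Geometric standard deviation (> 1).
#' @param total_number Total particle count per reference volume of
#'   material. The default (5e7) puts the paper-scale aggregation
#'   efficiency `beta0 ~ 7e-12` in the partial-granulation regime over one
#'   dimensionless residence time.
#' @param seed Ignored (generation is deterministic); accepted so callers
#'   can treat all generators uniformly.
#' @return A `psd`.
#' @export
generate_preblend <- function(grid, median_diameter = 50, geometric_sd = 1.6,
                              total_number = 5e7, seed = NULL) {
  stopifnot(inherits(grid, "size_grid"))
  if (!is.finite(geometric_sd) || geometric_sd <= 1) {
    stop("geometric_sd must be > 1", call. = FALSE)
  }
  d <- grid$representative_diameters
  if (median_diameter < min(d) || median_diameter > max(d)) {
    stop("median_diameter lies outside the grid span", call. = FALSE)
  }
  if (!is.finite(total_number) || total_number <= 0) {
    stop("total_number must be > 0", call. = FALSE)
  }
  w <- stats::dlnorm(d, meanlog = log(median_diameter),
                     sdlog = log(geometric_sd)) * d
  if (!is.finite(sum(w)) || sum(w) <= 0) {
    stop("preblend degenerate on this grid: geometric_sd too narrow for the bin spacing",
         call. = FALSE)
  }
  psd(grid, w / sum(w) * total_number)
}

#' Generate noisy compartment targets from a forward simulation
#'
#' Stands in for PSDs sampled along the granulator barrel: simulates the
#' compartment chain from the preblend (the noise-free truth), then applies
#' one multiplicative noise realization per compartment outlet. The
#' generating chain is recorded so parameter-recovery studies can compare
#' calibrated values against the truth.
#'
#' @param preblend Inlet `psd`.
#' @param compartments List of [compartment()] objects.
#' @param noise A [noise_spec()]; `scale = 0` returns the truth unchanged.
#' @return List with `targets` (named list of noisy per-compartment `psd`s),
#'   `truth` (the noise-free `chain_result`) and `parameters` (the
#'   generating compartment list).
#' @export
generate_compartment_targets <- function(preblend, compartments, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  truth <- simulate_chain(preblend, compartments)
  targets <- with_seed(noise$seed, lapply(truth$outlets, perturb_psd, noise = noise))
  list(targets = targets, truth = truth, parameters = compartments)
}

#' Generate repeated noisy measurements of one PSD
#'
#' Independent multiplicative perturbations of a single PSD, the input for
#' [measurement_error_threshold()].
#'
#' @param x A `psd`.
#' @param noise A [noise_spec()].
#' @param k Number of replicates (>= 2).
#' @return List of `k` perturbed `psd` objects.
#' @export
generate_repeated_measurements <- function(x, noise, k) {
  stopifnot(inherits(x, "psd"), inherits(noise, "noise_spec"))
  if (!is.numeric(k) || length(k) != 1 || k < 2 || k != round(k)) {
    stop("k must be an integer >= 2", call. = FALSE)
  }
  with_seed(noise$seed, replicate(k, perturb_psd(x, noise), simplify = FALSE))
}
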