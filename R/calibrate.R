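#' Fix R, mu and sigma from wetting-zone measurements
#'
#' The parameter-reduction protocol: the depletion point of the bimodal
#' wetting-zone PSD sits in the same size class across liquid-to-solid
#' ratios for a given formulation, so the critical size `R` of the
#' square-step kernel can be read off the data instead of calibrated
#' (majority vote across measurements, ties toward the smaller size). The
#' erosion-fragment mean is then tied to the same size, `mu = R`, and the
#' spread fixed at `sigma = 50` (neither high nor low dispersion). This
#' leaves exactly two free parameters in the wetting zone (`step`, `beta0`)
#' and three in the kneading zones (`beta0`, `S0`, `fprim`).
#'
#' @param wetting_psd_measurements List of one or more wetting-zone `psd`
#'   objects (e.g. at different liquid-to-solid ratios).
#' @param formulation_label Optional label carried into the result.
#' @param sigma Fixed erosion spread (default 50 \eqn{\mu m}).
#' @return An object of class `parameter_reduction`: list with `R`, `mu`,
#'   `sigma`, `bin`, per-measurement `votes`, `free_wetting` and
#'   `free_kneading` parameter names.
#' @export
reduce_parameters <- function(wetting_psd_measurements, formulation_label = "",
                              sigma = 50) {
  if (inherits(wetting_psd_measurements, "psd")) {
    wetting_psd_measurements <- list(wetting_psd_measurements)
  }
  if (!is.list(wetting_psd_measurements) || length(wetting_psd_measurements) < 1) {
    stop("need at least one wetting-zone PSD", call. = FALSE)
  }
  dps <- lapply(wetting_psd_measurements, estimate_depletion_size)
  bins <- vapply(dps, function(d) if (d$found) d$bin else NA_integer_, 1L)
  if (all(is.na(bins))) {
    stop(paste("no depletion point found in any wetting-zone measurement;",
               "R cannot be fixed from data and must be calibrated"),
         call. = FALSE)
  }
  votes <- table(bins[!is.na(bins)])
  # majority vote; ties broken toward the smaller size (names sort ascending)
  winners <- as.integer(names(votes)[votes == max(votes)])
  bin <- min(winners)
  R <- wetting_psd_measurements[[1]]$grid$representative_diameters[bin]
  structure(
    list(R = R, mu = R, sigma = sigma, bin = bin, votes = bins,
         formulation = formulation_label,
         free_wetting = c("step", "beta0"),
         free_kneading = c("beta0", "S0", "fprim")),
    class = "parameter_reduction"
  )
}

#' @export
print.parameter_reduction <- function(x, ...) {
  cat(sprintf(
    "Parameter reduction%s: R = %.4g um (bin %d), mu = %.4g, sigma = %g\n",
    if (nzchar(x$formulation)) paste0(" [", x$formulation, "]") else "",
    x$R, x$bin, x$mu, x$sigma
  ))
  cat(sprintf("  free wetting parameters:  %s\n",
              paste(x$free_wetting, collapse = ", ")))
  cat(sprintf("  free kneading parameters: %s\n",
              paste(x$free_kneading, collapse = ", ")))
  invisible(x)
}

# default calibration bounds; beta0 is searched on a log10 scale
default_bounds <- function() {
  list(step = c(1, 1e4), beta0 = c(1e-16, 1e-6), S0 = c(0, 100),
       fprim = c(0, 1))
}

kernel_par_names <- c("beta0", "top1", "top2", "R1", "R2", "delta1", "delta2",
                      "R", "step", "p")
breakage_par_names <- c("S0", "mu", "sigma", "fprim")

# set a single model parameter inside a compartment template
set_compartment_param <- function(comp, name, value) {
  value <- unname(value)
  if (name %in% kernel_par_names) {
    comp$kernel[[name]] <- value
  } else if (name %in% breakage_par_names) {
    if (is.null(comp$breakage)) {
      stop(sprintf("parameter '%s' needs a breakage spec in the template", name),
           call. = FALSE)
    }
    comp$breakage[[name]] <- value
  } else {
    stop(sprintf("unknown model parameter '%s'", name), call. = FALSE)
  }
  comp
}

#' Define a per-compartment calibration problem
#'
#' Bundles everything one particle-swarm calibration needs: the compartment
#' template (with all fixed parameters set), the free-parameter names and
#' bounds, inlet and target PSDs, and the swarm settings. The objective is
#' the energy distance between the simulated compartment outlet and the
#' target.
#'
#' @param inlet,target `psd` objects on a common grid.
#' @param comp A [compartment()] template.
#' @param free Character vector of free-parameter names.
#' @param lower,upper Named bounds; defaults from the package
#'   (`step` in [1, 1e4], `beta0` in [1e-16, 1e-6], `S0` in [0, 100],
#'   `fprim` in [0, 1]). `beta0`, and `step` whenever its lower bound is
#'   positive, are searched on a log10 scale: both span several decades, and
#'   a linear search stalls in the `step * beta0` compensation valley.
#' @param swarm,iterations,inertia,cognitive,social Swarm settings
#'   (constriction-type defaults: 30 particles, 250 iterations, inertia
#'   0.72, cognitive = social = 1.49; the iteration budget is sized so the
#'   swarm fully converges on noise-free recovery problems).
#' @param seed Integer seed recorded in the result.
#' @return An object of class `calibration_problem`.
#' @export
calibration_problem <- function(inlet, target, comp, free,
                                lower = NULL, upper = NULL,
                                swarm = 30L, iterations = 250L,
                                inertia = 0.72, cognitive = 1.49,
                                social = 1.49, seed = 1L) {
  stopifnot(inherits(inlet, "psd"), inherits(target, "psd"),
            inherits(comp, "compartment"))
  if (!same_grid(inlet$grid, target$grid)) {
    stop("inlet and target must share a grid", call. = FALSE)
  }
  if (length(free) < 1) stop("need at least one free parameter", call. = FALSE)
  db <- default_bounds()
  lo <- vapply(free, function(p) {
    if (!is.null(lower) && p %in% names(lower)) lower[[p]]
    else if (p %in% names(db)) db[[p]][1]
    else stop(sprintf("no bounds for parameter '%s'", p), call. = FALSE)
  }, 1)
  hi <- vapply(free, function(p) {
    if (!is.null(upper) && p %in% names(upper)) upper[[p]]
    else db[[p]][2]
  }, 1)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(hi < lo)) {
    stop("free-parameter bounds must be finite with upper >= lower", call. = FALSE)
  }
  structure(
    list(inlet = inlet, target = target, comp = comp, free = free,
         lower = lo, upper = hi, swarm = as.integer(swarm),
         iterations = as.integer(iterations), inertia = inertia,
         cognitive = cognitive, social = social, seed = as.integer(seed)),
    class = "calibration_problem"
  )
}

# shared PSO driver for the per-compartment calibrations
calibrate_compartment <- function(problem, allowed_free) {
  stopifnot(inherits(problem, "calibration_problem"))
  if (!all(problem$free %in% allowed_free)) {
    stop(sprintf("free parameters must be a subset of {%s}",
                 paste(allowed_free, collapse = ", ")), call. = FALSE)
  }
  # parameters with collapsed bounds are pinned at that value, not searched
  pinned <- problem$lower == problem$upper
  if (any(pinned)) {
    for (k in which(pinned)) {
      problem$comp <- set_compartment_param(problem$comp, problem$free[k],
                                            problem$lower[k])
    }
    pinned_par <- stats::setNames(as.numeric(problem$lower[pinned]),
                                  problem$free[pinned])
    problem$free <- problem$free[!pinned]
    problem$lower <- problem$lower[!pinned]
    problem$upper <- problem$upper[!pinned]
    if (length(problem$free) == 0) {
      stop("all free parameters have collapsed bounds; nothing to calibrate",
           call. = FALSE)
    }
  } else {
    pinned_par <- stats::setNames(numeric(0), character(0))
  }
  log_scaled <- problem$free == "beta0" |
    (problem$free == "step" & problem$lower > 0)
  lo <- ifelse(log_scaled, log10(problem$lower), problem$lower)
  hi <- ifelse(log_scaled, log10(problem$upper), problem$upper)

  natural <- function(u) ifelse(log_scaled, 10^u, u)
  objective <- function(u) {
    pars <- natural(u)
    comp <- problem$comp
    for (k in seq_along(problem$free)) {
      comp <- set_compartment_param(comp, problem$free[k], pars[k])
    }
    out <- tryCatch(integrate_compartment(problem$inlet, comp),
                    error = function(e) NULL)
    # a crashed simulation (integrator over budget at an extreme parameter
    # combination) is penalized with a finite value far above any physical
    # distance on the working grid, so the swarm retreats from it instead of
    # the whole run aborting
    if (is.null(out)) return(1e3)
    energy_distance(out, problem$target)
  }
  fit <- pso_minimize(objective, lo, hi, swarm = problem$swarm,
                      iterations = problem$iterations,
                      inertia = problem$inertia,
                      cognitive = problem$cognitive, social = problem$social,
                      seed = problem$seed)
  best <- stats::setNames(as.numeric(natural(fit$par)), problem$free)
  structure(
    list(par = best, pinned = pinned_par, objective = fit$value,
         trace = fit$trace, seed = problem$seed, problem = problem,
         evals = fit$evals),
    class = "pbm_calibration"
  )
}

#' Calibrate the wetting zone
#'
#' Particle swarm calibration of the pure-aggregation wetting compartment:
#' free parameters are (a subset of) the step-kernel multiplier `step` and
#' the aggregation efficiency `beta0` (log-scale search); the critical size
#' `R` is fixed beforehand via [reduce_parameters()]. Deterministic given the
#' problem seed.
#'
#' @param problem A [calibration_problem()] whose compartment is
#'   pure aggregation.
#' @return A `pbm_calibration` object: best parameters ([coef()]), objective
#'   value, per-iteration trace and seed.
#' @export
calibrate_wetting <- function(problem) {
  if (!is.null(problem$comp$breakage)) {
    stop("wetting calibration expects a pure-aggregation compartment",
         call. = FALSE)
  }
  calibrate_compartment(problem, c("step", "beta0"))
}

#' Calibrate a kneading zone
#'
#' As [calibrate_wetting()], for an aggregation-plus-breakage compartment:
#' free parameters are (a subset of) `beta0`, `S0` and `fprim`; the erosion
#' parameters `mu` and `sigma` are fixed beforehand via
#' [reduce_parameters()].
#'
#' @param problem A [calibration_problem()] whose compartment carries a
#'   breakage spec.
#' @return A `pbm_calibration` object.
#' @export
calibrate_kneading <- function(problem) {
  if (is.null(problem$comp$breakage)) {
    stop("kneading calibration expects an aggregation+breakage compartment",
         call. = FALSE)
  }
  calibrate_compartment(problem, c("beta0", "S0", "fprim"))
}

#' @export
coef.pbm_calibration <- function(object, ...) object$par

#' @export
print.pbm_calibration <- function(x, ...) {
  cat(sprintf("PBM calibration (%s, seed %d): objective %.6g after %d evaluations\n",
              x$problem$comp$name, x$seed, x$objective, x$evals))
  for (k in seq_along(x$par)) {
    cat(sprintf("  %-6s = %.6g\n", names(x$par)[k], x$par[k]))
  }
  invisible(x)
}

#' @export
plot.pbm_calibration <- function(x, ..., log = "y") {
  tr <- x$trace
  if (any(tr <= 0)) log <- ""
  graphics::plot(seq_along(tr), tr, type = "l", log = log,
                 xlab = "iteration", ylab = "best objective (energy distance)",
                 ...)
  invisible(x)
}
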