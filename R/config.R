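# Run configuration: structured-text (JSON) mapping with full validation.
# Every validation error is collected (with its key path) before failing, so
# a bad file is diagnosed in one pass.

kernel_allowed_keys <- list(
  tanh_double_step = c("variant", "beta0", "top1", "top2", "R1", "R2",
                       "delta1", "delta2"),
  circle_step = c("variant", "beta0", "R", "step"),
  square_step = c("variant", "beta0", "R", "step"),
  square_step_power = c("variant", "beta0", "R", "step", "p")
)

#' Load and validate a run configuration
#'
#' Configuration files are structured-text (JSON) mappings with sections
#' `grid` (`n_bins`, `d_min_um`, `d_max_um`; defaults 35, 1, 4000),
#' `compartments` (ordered list, each with `name`, `kernel`, optionally
#' `breakage` and `integration_time`), and optional `calibration`
#' (`swarm`, `iterations`, `seed`) and `seeds` sections. Unknown keys are
#' rejected; a kernel section may only carry the parameters of its
#' `variant`; all violations are reported together with their key paths.
#'
#' @param path Path to a configuration file.
#' @return An object of class `run_config`: the validated configuration
#'   with defaults filled, plus `grid_object` (a `size_grid`) and
#'   `compartment_objects` (list of [compartment()]s).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path), call. = FALSE)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE),
                  error = function(e) stop(sprintf("cannot parse config: %s",
                                                   conditionMessage(e)),
                                           call. = FALSE))
  errors <- character()
  note <- function(fmt, ...) errors <<- c(errors, sprintf(fmt, ...))

  top_allowed <- c("grid", "compartments", "calibration", "sweep", "seeds")
  for (k in setdiff(names(raw), top_allowed)) note("unknown key '%s'", k)

  # grid section with defaults
  grid_cfg <- if (is.null(raw$grid)) list() else raw$grid
  for (k in setdiff(names(grid_cfg), c("n_bins", "d_min_um", "d_max_um"))) {
    note("unknown key 'grid.%s'", k)
  }
  n_bins <- if (is.null(grid_cfg$n_bins)) 35 else grid_cfg$n_bins
  d_min <- if (is.null(grid_cfg$d_min_um)) 1 else grid_cfg$d_min_um
  d_max <- if (is.null(grid_cfg$d_max_um)) 4000 else grid_cfg$d_max_um
  if (!is.numeric(n_bins) || n_bins < 2) note("'grid.n_bins' must be >= 2")
  if (!is.numeric(d_min) || !is.numeric(d_max) || d_min <= 0 || d_max <= d_min) {
    note("'grid' diameter bounds must satisfy 0 < d_min_um < d_max_um")
  }

  # compartments
  comps_cfg <- raw$compartments
  comp_objects <- list()
  if (!is.null(comps_cfg)) {
    if (!is.list(comps_cfg)) {
      note("'compartments' must be a list")
      comps_cfg <- list()
    }
    for (ci in seq_along(comps_cfg)) {
      cc <- comps_cfg[[ci]]
      pfx <- sprintf("compartments[%d]", ci)
      allowed <- c("name", "mechanisms", "kernel", "breakage", "integration_time")
      for (k in setdiff(names(cc), allowed)) note("unknown key '%s.%s'", pfx, k)
      if (is.null(cc$name)) note("'%s.name' is required", pfx)
      if (is.null(cc$kernel)) {
        note("'%s.kernel' is required", pfx)
        next
      }
      kc <- cc$kernel
      variant <- kc$variant
      if (is.null(variant) || !variant %in% names(kernel_allowed_keys)) {
        note("'%s.kernel.variant' must be one of %s", pfx,
             paste(names(kernel_allowed_keys), collapse = ", "))
        next
      }
      for (k in setdiff(names(kc), kernel_allowed_keys[[variant]])) {
        note("key '%s.kernel.%s' is not a parameter of variant '%s'",
             pfx, k, variant)
      }
      bc <- cc$breakage
      if (!is.null(bc)) {
        for (k in setdiff(names(bc), c("S0", "mu_um", "sigma_um", "fprim"))) {
          note("unknown key '%s.breakage.%s'", pfx, k)
        }
        if (is.null(bc$S0)) note("'%s.breakage.S0' is required", pfx)
        if (is.null(bc$mu_um)) note("'%s.breakage.mu_um' is required", pfx)
      }
    }
  }

  # calibration section
  cal_cfg <- if (is.null(raw$calibration)) list() else raw$calibration
  for (k in setdiff(names(cal_cfg), c("swarm", "iterations", "seed"))) {
    note("unknown key 'calibration.%s'", k)
  }

  # sweep section
  sw_cfg <- if (is.null(raw$sweep)) list() else raw$sweep
  for (k in setdiff(names(sw_cfg), c("param", "from", "to", "step"))) {
    note("unknown key 'sweep.%s'", k)
  }

  if (length(errors) > 0) {
    stop(paste0("invalid configuration:\n  ",
                paste(errors, collapse = "\n  ")), call. = FALSE)
  }

  grid <- build_geometric_grid(n_bins, d_min, d_max)
  if (!is.null(comps_cfg)) {
    comp_objects <- lapply(comps_cfg, function(cc) {
      kc <- cc$kernel
      kargs <- kc
      kargs$variant <- NULL
      kern <- do.call(aggregation_kernel,
                      c(list(variant = kc$variant), kargs))
      brk <- NULL
      if (!is.null(cc$breakage)) {
        bc <- cc$breakage
        brk <- breakage_spec(
          S0 = bc$S0, mu = bc$mu_um,
          sigma = if (is.null(bc$sigma_um)) 50 else bc$sigma_um,
          fprim = if (is.null(bc$fprim)) 0.5 else bc$fprim
        )
      }
      compartment(cc$name, kern, brk,
                  mechanisms = if (is.null(cc$mechanisms)) NULL else cc$mechanisms,
                  integration_time = if (is.null(cc$integration_time)) 1
                                     else cc$integration_time)
    })
  }

  structure(
    list(
      grid = list(n_bins = as.integer(n_bins), d_min_um = d_min,
                  d_max_um = d_max),
      compartments = comps_cfg,
      calibration = list(
        swarm = if (is.null(cal_cfg$swarm)) 30L else as.integer(cal_cfg$swarm),
        iterations = if (is.null(cal_cfg$iterations)) 150L
                     else as.integer(cal_cfg$iterations),
        seed = if (is.null(cal_cfg$seed)) 1L else as.integer(cal_cfg$seed)
      ),
      sweep = sw_cfg,
      seeds = raw$seeds,
      grid_object = grid,
      compartment_objects = comp_objects
    ),
    class = "run_config"
  )
}

#' Write a run configuration back to structured text
#'
#' Dumps the user-level sections of a `run_config` (not the derived grid and
#' compartment objects) so that a dump-then-load round trip reproduces the
#' configuration.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(grid = config$grid, compartments = config$compartments,
              calibration = config$calibration)
  if (length(config$sweep) > 0) out$sweep <- config$sweep
  if (!is.null(config$seeds)) out$seeds <- config$seeds
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run configuration: %d-bin grid (%g-%g um), %d compartment(s)\n",
              x$grid$n_bins, x$grid$d_min_um, x$grid$d_max_um,
              length(x$compartment_objects)))
  invisible(x)
}
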