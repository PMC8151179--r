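#' Compartment specification
#'
#' A compartment of the twin-screw granulator, modelled as a well-mixed
#' aggregation(-breakage) reactor integrated over one dimensionless residence
#' time. The wetting zone (conveying elements, low shear) is pure
#' aggregation; kneading zones and the outlet combine aggregation and
#' breakage. Rates (`beta0`, `S0`) absorb the true residence time, so the
#' integration horizon defaults to 1.
#'
#' @param name Compartment label (e.g. `"C1"`, `"C3"`, `"C5"`, `"C6"`).
#' @param kernel An [aggregation_kernel()] (carries `beta0`).
#' @param breakage A [breakage_spec()] or `NULL` for pure aggregation.
#' @param mechanisms Character vector; inferred from `breakage` when omitted.
#'   Wetting-type compartments (`"aggregation"` only) must not carry a
#'   breakage spec.
#' @param integration_time Dimensionless duration (default 1).
#' @return An object of class `compartment`.
#' @export
compartment <- function(name, kernel, breakage = NULL, mechanisms = NULL,
                        integration_time = 1) {
  stopifnot(inherits(kernel, "aggregation_kernel"))
  if (!is.null(breakage)) stopifnot(inherits(breakage, "breakage_spec"))
  if (is.null(mechanisms)) {
    mechanisms <- if (is.null(breakage)) "aggregation" else c("aggregation", "breakage")
  }
  mechanisms <- match.arg(mechanisms, c("aggregation", "breakage"),
                          several.ok = TRUE)
  if (!("breakage" %in% mechanisms) && !is.null(breakage)) {
    stop("a pure-aggregation (wetting) compartment cannot carry a breakage spec",
         call. = FALSE)
  }
  if ("breakage" %in% mechanisms && is.null(breakage)) {
    stop("mechanisms include breakage but no breakage spec was given",
         call. = FALSE)
  }
  if (!is.finite(integration_time) || integration_time < 0) {
    stop("integration_time must be >= 0", call. = FALSE)
  }
  structure(list(name = name, mechanisms = mechanisms, kernel = kernel,
                 breakage = breakage, integration_time = integration_time),
            class = "compartment")
}

#' @export
print.compartment <- function(x, ...) {
  cat(sprintf("Compartment %s: %s (t = %g)\n", x$name,
              paste(x$mechanisms, collapse = " + "), x$integration_time))
  print(x$kernel)
  if (!is.null(x$breakage)) print(x$breakage)
  invisible(x)
}

# internal: fixed-pivot pair structure for aggregation on a geometric grid.
# For each unordered bin pair (i <= j) whose aggregate volume stays on the
# grid, precompute the event-rate coefficient (beta0 * kernel entry, halved
# on the diagonal) and the pivot split of the newborn between the bracketing
# representatives (conserving number and mass). Pairs that would aggregate
# past the largest representative are dropped entirely: they neither give
# birth nor consume particles, so nothing flows over the top of the grid.
build_pair_structure <- function(grid, kernel_matrix, beta0) {
  v <- grid$representative_volumes
  n <- grid$n_bins
  ij <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  i <- ij[, 1]
  j <- ij[, 2]
  vnew <- v[i] + v[j]
  keep <- vnew <= v[n] * (1 + 1e-12)
  i <- i[keep]; j <- j[keep]; vnew <- pmin(vnew[keep], v[n])
  k <- findInterval(vnew, v)
  lo <- k
  hi <- pmin(k + 1, n)
  flo <- ifelse(hi > lo, (v[hi] - vnew) / (v[hi] - v[lo]), 1)
  coef <- beta0 * kernel_matrix[cbind(i, j)] * ifelse(i == j, 0.5, 1)
  list(pi = as.integer(i - 1L), pj = as.integer(j - 1L), coef = coef,
       lo = as.integer(lo - 1L), hi = as.integer(hi - 1L), flo = flo)
}

no_breakage <- function(n) list(selection = numeric(n),
                                redistribution = matrix(0, n, n))

#' Aggregation right-hand side of the population balance
#'
#' Time derivative of `number_per_bin` under pure aggregation with the fixed
#' pivot sectional scheme: birth from every allowed pair `(i, j)` at rate
#' `beta0 * K[i, j] * n_i * n_j` (counted once per unordered pair, with the
#' 1/2 factor on the diagonal), the newborn volume `v_i + v_j` split between
#' the bracketing representatives so that number and mass are both conserved;
#' matching death terms; pairs that would leave the grid are not formed.
#'
#' @param x A `psd`.
#' @param kernel_matrix Matrix from [build_kernel_matrix()] on the same grid.
#' @param beta0 Aggregation efficiency (1/time).
#' @return Numeric vector `dn/dt`.
#' @export
aggregation_rhs <- function(x, kernel_matrix, beta0) {
  stopifnot(inherits(x, "psd"))
  n <- x$grid$n_bins
  if (!is.matrix(kernel_matrix) || !all(dim(kernel_matrix) == n)) {
    stop("kernel matrix does not match the PSD grid", call. = FALSE)
  }
  ps <- build_pair_structure(x$grid, kernel_matrix, beta0)
  pbm_rhs_cpp(x$number_per_bin, ps$pi, ps$pj, ps$coef, ps$lo, ps$hi, ps$flo,
              numeric(n), matrix(0, n, n), FALSE)
}

#' Breakage right-hand side of the population balance
#'
#' `dn_i/dt = sum_j M[i, j] S_j n_j - S_i n_i` with operators from
#' [build_breakage_operator()].
#'
#' @param x A `psd`.
#' @param selection_vector Per-bin selection rates.
#' @param redistribution_matrix Daughter redistribution matrix.
#' @return Numeric vector `dn/dt`.
#' @export
breakage_rhs <- function(x, selection_vector, redistribution_matrix) {
  stopifnot(inherits(x, "psd"))
  n <- x$grid$n_bins
  if (length(selection_vector) != n || !is.matrix(redistribution_matrix) ||
      !all(dim(redistribution_matrix) == n)) {
    stop("breakage operators do not match the PSD grid", call. = FALSE)
  }
  sn <- selection_vector * x$number_per_bin
  as.numeric(redistribution_matrix %*% sn) - sn
}

#' Integrate one compartment
#'
#' Adaptive explicit (Dormand-Prince 5(4)) integration of the combined
#' aggregation-breakage right-hand side over `[0, integration_time]`. The
#' output is checked for mass conservation (relative drift must stay below
#' `1e-6`) and non-negativity: undershoots beyond `-abs_tol` abort with an
#' error, smaller ones are clipped to zero and reported in the diagnostics.
#'
#' @param x Inlet `psd`.
#' @param comp A [compartment()].
#' @param rel_tol,abs_tol Integrator tolerances; `abs_tol` defaults to
#'   `1e-10` times the inlet total number.
#' @param max_steps Step budget before the integrator gives up.
#' @return Outlet `psd` with a `diagnostics` attribute (list: `steps`,
#'   `rejected`, `mass_drift`, `number_change`, `clipped`).
#' @export
integrate_compartment <- function(x, comp, rel_tol = 1e-8, abs_tol = NULL,
                                  max_steps = 100000L) {
  stopifnot(inherits(x, "psd"), inherits(comp, "compartment"))
  if (!is.finite(rel_tol) || rel_tol <= 0) stop("rel_tol must be > 0", call. = FALSE)
  n0 <- x$number_per_bin
  if (is.null(abs_tol)) abs_tol <- 1e-10 * max(sum(n0), 1)
  if (!is.finite(abs_tol) || abs_tol <= 0) stop("abs_tol must be > 0", call. = FALSE)

  grid <- x$grid
  kmat <- build_kernel_matrix(comp$kernel, grid)
  ps <- build_pair_structure(grid, kmat, comp$kernel$beta0)
  brk <- if (!is.null(comp$breakage)) {
    build_breakage_operator(comp$breakage, grid)
  } else {
    no_breakage(grid$n_bins)
  }

  res <- pbm_integrate_cpp(n0, comp$integration_time, ps$pi, ps$pj, ps$coef,
                           ps$lo, ps$hi, ps$flo, brk$selection,
                           brk$redistribution, !is.null(comp$breakage),
                           rel_tol, abs_tol, as.integer(max_steps))
  if (res$status != 0) {
    stop(sprintf("compartment %s: integrator failed (status %d after %d steps)",
                 comp$name, res$status, res$steps), call. = FALSE)
  }
  state <- res$state
  if (res$min_state < -abs_tol) {
    stop(sprintf("compartment %s: negative number density %.3g beyond tolerance",
                 comp$name, res$min_state), call. = FALSE)
  }
  clipped <- sum(state < 0)
  state[state < 0] <- 0

  v <- grid$representative_volumes
  mass_in <- sum(n0 * v)
  mass_out <- sum(state * v)
  drift <- if (mass_in > 0) abs(mass_out - mass_in) / mass_in else 0
  if (drift > 1e-6) {
    stop(sprintf("compartment %s: relative mass drift %.3g exceeds 1e-6",
                 comp$name, drift), call. = FALSE)
  }
  out <- psd(grid, state)
  attr(out, "diagnostics") <- list(
    steps = res$steps, rejected = res$rejected, mass_drift = drift,
    number_change = sum(state) - sum(n0), clipped = clipped
  )
  out
}

#' Simulate a compartment chain
#'
#' Feeds the preblend through an ordered sequence of compartments (wetting
#' zone, kneading zones, outlet); each compartment's outlet is the next
#' compartment's inlet.
#'
#' @param preblend Inlet `psd`.
#' @param compartments List of [compartment()] objects (>= 1).
#' @param ... Passed to [integrate_compartment()].
#' @return An object of class `chain_result`: list with `inlet`, `outlets`
#'   (named list of per-compartment `psd`s) and `diagnostics` (named list).
#' @export
simulate_chain <- function(preblend, compartments, ...) {
  stopifnot(inherits(preblend, "psd"))
  if (inherits(compartments, "compartment")) compartments <- list(compartments)
  if (length(compartments) < 1) stop("need at least one compartment", call. = FALSE)
  outlets <- list()
  diags <- list()
  cur <- preblend
  for (comp in compartments) {
    cur <- tryCatch(
      integrate_compartment(cur, comp, ...),
      error = function(e) stop(sprintf("in compartment %s: %s", comp$name,
                                       conditionMessage(e)), call. = FALSE)
    )
    outlets[[comp$name]] <- cur
    diags[[comp$name]] <- attr(cur, "diagnostics")
  }
  structure(list(inlet = preblend, outlets = outlets, diagnostics = diags),
            class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf("Compartment chain: %d compartment(s)\n", length(x$outlets)))
  for (nm in names(x$outlets)) {
    d <- x$diagnostics[[nm]]
    cat(sprintf("  %s: %d steps, mass drift %.2e, number change %.4g\n",
                nm, d$steps, d$mass_drift, d$number_change))
  }
  invisible(x)
}

#' @export
plot.chain_result <- function(x, ..., log = "x") {
  nser <- length(x$outlets) + 1
  cols <- grDevices::hcl.colors(nser, "viridis")
  d <- x$inlet$grid$representative_diameters
  all_f <- cbind(to_volume_fraction(x$inlet),
                 vapply(x$outlets, to_volume_fraction, numeric(length(d))))
  graphics::matplot(d, all_f, type = "l", lty = 1, col = cols, log = log,
                    xlab = "diameter (um)", ylab = "volume fraction", ...)
  graphics::legend("topright", legend = c("inlet", names(x$outlets)),
                   col = cols, lty = 1, bty = "n")
  invisible(x)
}
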