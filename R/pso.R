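# Constriction-type particle swarm optimizer (internal).
#
# No PSO package ships with the supported environment, so a standard
# global-best swarm is implemented here: inertia 0.72, cognitive = social =
# 1.49 (Clerc-style constriction values), reflecting bound handling, velocity
# clamped to the box width. Deterministic given `seed`.
#
# fn: objective over a numeric vector (lower <= x <= upper); non-finite
# values are treated as +Inf. Returns list(par, value, trace, evals).
pso_minimize <- function(fn, lower, upper, swarm = 30L, iterations = 150L,
                         inertia = 0.72, cognitive = 1.49, social = 1.49,
                         seed = 1L) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  d <- length(lower)
  span <- upper - lower
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  pos <- matrix(stats::runif(swarm * d, rep(lower, each = swarm),
                             rep(upper, each = swarm)), swarm, d)
  vel <- matrix(stats::runif(swarm * d, -rep(span, each = swarm),
                             rep(span, each = swarm)) / 4, swarm, d)

  evaluate <- function(p) {
    val <- fn(p)
    if (!is.finite(val)) Inf else val
  }
  fit <- apply(pos, 1, evaluate)
  if (sum(is.infinite(fit)) > swarm / 2) {
    stop("objective non-finite over most of the initial swarm; check bounds",
         call. = FALSE)
  }
  pbest <- pos
  pbest_fit <- fit
  g <- which.min(fit)
  gbest <- pos[g, ]
  gbest_fit <- fit[g]
  trace <- numeric(iterations)

  for (it in seq_len(iterations)) {
    r1 <- matrix(stats::runif(swarm * d), swarm, d)
    r2 <- matrix(stats::runif(swarm * d), swarm, d)
    vel <- inertia * vel +
      cognitive * r1 * (pbest - pos) +
      social * r2 * (matrix(gbest, swarm, d, byrow = TRUE) - pos)
    vmax <- matrix(span, swarm, d, byrow = TRUE)
    vel <- pmin(pmax(vel, -vmax), vmax)
    pos <- pos + vel
    # reflecting bounds
    for (k in seq_len(d)) {
      below <- pos[, k] < lower[k]
      pos[below, k] <- pmin(2 * lower[k] - pos[below, k], upper[k])
      vel[below, k] <- -vel[below, k]
      above <- pos[, k] > upper[k]
      pos[above, k] <- pmax(2 * upper[k] - pos[above, k], lower[k])
      vel[above, k] <- -vel[above, k]
    }
    fit <- apply(pos, 1, evaluate)
    improved <- fit < pbest_fit
    pbest[improved, ] <- pos[improved, , drop = FALSE]
    pbest_fit[improved] <- fit[improved]
    g <- which.min(pbest_fit)
    if (pbest_fit[g] < gbest_fit) {
      gbest_fit <- pbest_fit[g]
      gbest <- pbest[g, ]
    }
    trace[it] <- gbest_fit
  }
  list(par = gbest, value = gbest_fit, trace = trace,
       evals = swarm * (iterations + 1L))
}
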