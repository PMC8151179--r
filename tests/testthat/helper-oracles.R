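# Independent brute-force oracles, deliberately written as plain double
# loops so they share no code path with the package implementations.

# aggregation right-hand side: direct double sum over all bin pairs with
# fixed-pivot splitting of the newborn volume
brute_aggregation_rhs <- function(x, kmat, beta0) {
  v <- x$grid$representative_volumes
  n <- x$number_per_bin
  N <- length(n)
  dn <- numeric(N)
  for (i in seq_len(N)) {
    for (j in i:N) {
      vnew <- v[i] + v[j]
      if (vnew > v[N] * (1 + 1e-12)) next
      rate <- beta0 * kmat[i, j] * n[i] * n[j] * (if (i == j) 0.5 else 1)
      dn[i] <- dn[i] - rate
      dn[j] <- dn[j] - rate
      vnew <- min(vnew, v[N])
      k <- max(which(v <= vnew * (1 + 1e-15)))
      if (k == N) {
        dn[N] <- dn[N] + rate
      } else {
        a <- (v[k + 1] - vnew) / (v[k + 1] - v[k])
        dn[k] <- dn[k] + rate * a
        dn[k + 1] <- dn[k + 1] + rate * (1 - a)
      }
    }
  }
  dn
}

# breakage right-hand side: explicit loops over mother and daughter bins
brute_breakage_rhs <- function(x, svec, M) {
  n <- x$number_per_bin
  N <- length(n)
  dn <- numeric(N)
  for (i in seq_len(N)) {
    acc <- -svec[i] * n[i]
    for (j in seq_len(N)) acc <- acc + M[i, j] * svec[j] * n[j]
    dn[i] <- acc
  }
  dn
}

# energy distance: three explicit double sums over bins
brute_energy_distance <- function(u, v) {
  p <- to_volume_fraction(u)
  q <- to_volume_fraction(v)
  s <- u$grid$representative_diameters
  N <- length(s)
  spq <- spp <- sqq <- 0
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      a <- abs(s[i] - s[j])
      spq <- spq + p[i] * q[j] * a
      spp <- spp + p[i] * p[j] * a
      sqq <- sqq + q[i] * q[j] * a
    }
  }
  sqrt(max(2 * spq - spp - sqq, 0))
}

# random strictly positive PSD on a grid
random_psd <- function(grid, seed) {
  set.seed(seed)
  psd(grid, stats::runif(grid$n_bins, 0.1, 10))
}

# standard working grid and the representative size used as the critical
# size anchor in recovery scenarios (nearest representative to 168.35 um)
default_grid <- function() build_geometric_grid(35, 1, 4000)

anchor_bin <- 22L
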