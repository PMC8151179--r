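scenario9 <- function() {
  g <- default_grid()
  pre <- generate_preblend(g)
  kern <- aggregation_kernel("tanh_double_step", beta0 = 7e-12, R2 = 500,
                             top1 = 10, top2 = 1, R1 = 7000,
                             delta1 = 10, delta2 = 10)
  comp <- compartment("C1", kern)
  list(grid = g, pre = pre, comp = comp,
       target = integrate_compartment(pre, comp))
}

test_that("a sweep through the generating value bottoms out at zero there", {
  sc <- scenario9()
  values <- c(460, 480, 500, 520, 540)
  sw <- sweep_parameter(list(inlet = sc$pre, comp = sc$comp), sc$target,
                        "R2", values)
  expect_s3_class(sw, "pbm_sweep")
  # the generating value attains the global minimum (which may extend over
  # a plateau of equivalent discretized kernels)
  expect_lt(sw$distance[3], 1e-12)
  expect_equal(min(sw$distance), sw$distance[3])
  expect_true(all(sw$distance >= 0))
  expect_equal(range(sw$normalized), c(0, 1))
})

test_that("square-step sweeps are piecewise constant between representatives", {
  g <- default_grid()
  pre <- generate_preblend(g)
  d <- g$representative_diameters
  comp <- compartment("C1", aggregation_kernel("square_step", beta0 = 7e-12,
                                               R = d[anchor_bin], step = 10))
  target <- integrate_compartment(pre, comp)
  # several R values strictly between consecutive representatives give
  # identical distances; crossing a representative changes the distance
  inside_a <- seq(d[20] * 1.01, d[21] * 0.99, length.out = 4)
  inside_b <- seq(d[21] * 1.01, d[22] * 0.99, length.out = 4)
  sw <- sweep_parameter(list(inlet = pre, comp = comp), target, "R",
                        c(inside_a, inside_b))
  expect_equal(diff(sw$distance[1:4]), rep(0, 3))
  expect_equal(diff(sw$distance[5:8]), rep(0, 3))
  expect_false(sw$distance[1] == sw$distance[5])
})

test_that("sweeps are pure: repeated invocation yields identical profiles", {
  sc <- scenario9()
  values <- seq(480, 520, by = 10)
  tpl <- list(inlet = sc$pre, comp = sc$comp)
  s1 <- sweep_parameter(tpl, sc$target, "R2", values)
  s2 <- sweep_parameter(tpl, sc$target, "R2", values)
  expect_identical(s1$distance, s2$distance)
})

test_that("adjacent representative R values always change the kernel matrix", {
  g <- default_grid()
  d <- g$representative_diameters
  mats <- lapply(d, function(R) {
    build_kernel_matrix(aggregation_kernel("square_step", R = R, step = 10), g)
  })
  for (i in seq_len(34)) {
    expect_false(identical(mats[[i]], mats[[i + 1]]))
  }
})

test_that("plateau detection splits profiles at steps", {
  fake <- structure(
    list(param = "x", values = 1:5, distance = c(0.5, 0.5, 0.5, 0.1, 0.1),
         normalized = c(1, 1, 1, 0, 0), failed = rep(FALSE, 5)),
    class = "pbm_sweep"
  )
  pl <- detect_plateaus(fake, 1e-3)
  expect_equal(nrow(pl), 2L)
  expect_equal(pl$start, c(1L, 4L))
  expect_equal(pl$end, c(3L, 5L))
  # strictly monotone profile with spacing above flat_tol: all singletons
  mono <- structure(
    list(param = "x", values = 1:6, distance = seq(0, 1, length.out = 6),
         normalized = seq(0, 1, length.out = 6), failed = rep(FALSE, 6)),
    class = "pbm_sweep"
  )
  pl2 <- detect_plateaus(mono, 1e-3)
  expect_equal(nrow(pl2), 6L)
  expect_true(all(pl2$length == 1L))
  expect_error(detect_plateaus(mono, 0), "flat_tol")
})

test_that("a noisy 5-level staircase yields exactly 5 plateaus", {
  set.seed(42)
  flat_tol <- 1e-3
  levels <- c(0, 0.3, 0.45, 0.8, 1)
  z <- rep(levels, each = 8)
  z <- z + runif(length(z), -flat_tol / 4, flat_tol / 4)
  fake <- structure(
    list(param = "x", values = seq_along(z), distance = z, normalized = z,
         failed = rep(FALSE, length(z))),
    class = "pbm_sweep"
  )
  expect_equal(nrow(detect_plateaus(fake, flat_tol)), 5L)
})

test_that("uniqueness counting below a threshold", {
  fake <- structure(
    list(param = "x", values = 1:3, distance = c(0.5, 0.1, 0.4),
         normalized = c(1, 0, 0.75), failed = rep(FALSE, 3)),
    class = "pbm_sweep"
  )
  u <- uniqueness_below_threshold(fake, 0.2)
  expect_equal(u$count, 1L)
  expect_equal(u$idx, 2L)
  expect_true(u$identifiable)
  u0 <- uniqueness_below_threshold(fake, 0.05)
  expect_equal(u0$count, 0L)
  expect_false(u0$identifiable)
  expect_error(uniqueness_below_threshold(fake, -1), "threshold")
})

test_that("discretized step levels: sharp smoother none, wide smoother many", {
  g <- default_grid()
  v_fix <- g$representative_volumes[5]
  sharp <- aggregation_kernel("tanh_double_step", top1 = 10, top2 = 1,
                              R1 = 7000, R2 = 500,
                              delta1 = 1e-9, delta2 = 1e-9)
  expect_equal(
    discretized_step_levels(sharp, g, v_fix, seq(400, 600, by = 10)), 0L
  )
  # smoother spanning many bins: far more than two intermediate levels
  wide <- aggregation_kernel("tanh_double_step", top1 = 10, top2 = 1,
                             R1 = 7000, R2 = 500,
                             delta1 = 1e9, delta2 = 1e9)
  expect_gt(
    discretized_step_levels(wide, g, v_fix, seq(400, 600, by = 10)), 2
  )
  expect_error(
    discretized_step_levels(aggregation_kernel("square_step"), g, v_fix, 500),
    "tanh"
  )
})

test_that("failed sweep points are recorded without killing the sweep", {
  g <- default_grid()
  pre <- generate_preblend(g)
  comp <- compartment("C1", aggregation_kernel("square_step", beta0 = 7e-12,
                                               R = 168, step = 10))
  target <- integrate_compartment(pre, comp)
  # a negative step is an invalid kernel: that point fails, others succeed
  sw <- sweep_parameter(list(inlet = pre, comp = comp), target, "step",
                        c(-5, 5, 10, 20))
  expect_identical(sw$failed, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(is.na(sw$distance[1]))
})
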