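test_that("square step without a step is the pure product kernel", {
  sq1 <- aggregation_kernel("square_step", R = 500, step = 1)
  set.seed(3)
  x <- runif(20, 1, 1e9)
  e <- runif(20, 1, 1e9)
  expect_equal(kernel_value(sq1, x, e), x^(1 / 3) * e^(1 / 3),
               tolerance = 1e-14)
  # both sizes below R: (1000 * 1000)^(1/3) = 100 exactly
  sq <- aggregation_kernel("square_step", R = 500, step = 10)
  expect_equal(kernel_value(sq, 1000, 1000), 100, tolerance = 1e-12)
  # above R on either side the step multiplier applies
  vR <- volume_of_diameter(500)
  expect_equal(kernel_value(sq, 2 * vR, 1000), 10 * (2 * vR * 1000)^(1 / 3),
               tolerance = 1e-12)
})

test_that("the power variant at p = 1/3 reproduces the square step everywhere", {
  g <- default_grid()
  sq <- aggregation_kernel("square_step", R = 300, step = 25)
  sqp <- aggregation_kernel("square_step_power", R = 300, step = 25, p = 1 / 3)
  expect_equal(build_kernel_matrix(sqp, g), build_kernel_matrix(sq, g),
               tolerance = 1e-14)
})

test_that("the sharp-smoother double step converges to the circle step", {
  g <- default_grid()
  step <- 7
  R <- 400
  tanh_sharp <- aggregation_kernel("tanh_double_step", top1 = step, top2 = 1,
                                   R1 = 7000, R2 = R,
                                   delta1 = 1e-6, delta2 = 1e-6)
  circ <- aggregation_kernel("circle_step", R = R, step = step)
  v <- g$representative_volumes
  s <- sqrt(outer(v^2, v^2, "+"))
  away <- abs(s - R^3) / R^3 > 1e-6  # exclude the step locus itself
  mt <- build_kernel_matrix(tanh_sharp, g)
  mc <- build_kernel_matrix(circ, g)
  expect_lt(max(abs(mt[away] / mc[away] - 1)), 1e-6)
})

test_that("every kernel variant is symmetric in its size arguments", {
  set.seed(9)
  specs <- list(
    aggregation_kernel("square_step", R = runif(1, 50, 1000), step = runif(1, 1, 50)),
    aggregation_kernel("square_step_power", R = 200, step = 5, p = 2 / 5),
    aggregation_kernel("circle_step", R = 650, step = 12),
    aggregation_kernel("tanh_double_step", R2 = 500, top1 = 10, top2 = 1,
                       R1 = 7000, delta1 = 10, delta2 = 10)
  )
  x <- runif(50, 1, 3e10)
  e <- runif(50, 1, 3e10)
  for (spec in specs) {
    expect_equal(kernel_value(spec, x, e), kernel_value(spec, e, x),
                 tolerance = 1e-14)
    m <- build_kernel_matrix(spec, default_grid())
    expect_identical(m, t(m))
    expect_true(all(m >= 0))
  }
})

test_that("square step with step >= 1 is monotone in each size argument", {
  sq <- aggregation_kernel("square_step", R = 300, step = 40)
  x <- sort(exp(seq(log(1), log(3e10), length.out = 100)))
  for (e_fixed in c(10, volume_of_diameter(300), 1e9)) {
    vals <- kernel_value(sq, x, rep(e_fixed, length(x)))
    expect_true(all(diff(vals) >= -1e-12 * vals[-1]))
  }
})

test_that("kernel matrix collapses to scaled product kernel at extreme R", {
  g <- default_grid()
  prod_m <- build_kernel_matrix(aggregation_kernel("square_step", R = 1000,
                                                   step = 1), g)
  below <- aggregation_kernel("square_step", R = 0.5, step = 13)
  expect_equal(build_kernel_matrix(below, g), 13 * prod_m, tolerance = 1e-14)
  above <- aggregation_kernel("square_step", R = 4500, step = 13)
  expect_equal(build_kernel_matrix(above, g), prod_m, tolerance = 1e-14)
})

test_that("double-step plateaus have the top1/top2 multiplier ratio", {
  # reference scenario: R2 = 500, top1 = 10 (low plateau top2 = 1)
  g <- default_grid()
  k9 <- aggregation_kernel("tanh_double_step", R2 = 500, top1 = 10, top2 = 1,
                           R1 = 7000, delta1 = 10, delta2 = 10)
  v <- g$representative_volumes
  mult <- build_kernel_matrix(k9, g) / outer(v^(1 / 3), v^(1 / 3))
  s <- sqrt(outer(v^2, v^2, "+"))
  low <- s < 500^3 * 0.99
  high <- s > 500^3 * 1.01
  expect_equal(max(mult[high]) / max(mult[low]), 10, tolerance = 1e-9)
  expect_equal(unique(round(mult[low], 9)), 1)
})

test_that("sweeping R changes the square-step matrix only at representative crossings", {
  g <- default_grid()
  d <- g$representative_diameters
  # continuous sweep spanning three representatives (bins 20..22)
  Rvals <- seq(d[20] * 0.99, d[23] * 0.99, length.out = 60)
  mats <- lapply(Rvals, function(R) {
    build_kernel_matrix(aggregation_kernel("square_step", R = R, step = 10), g)
  })
  distinct <- Reduce(function(acc, m) {
    if (!any(vapply(acc, identical, TRUE, m))) c(acc, list(m)) else acc
  }, mats[-1], list(mats[[1]]))
  spanned <- sum(d >= min(Rvals) & d <= max(Rvals))
  expect_equal(length(distinct), spanned + 1L)
  # changes happen exactly when R crosses a representative
  crossings <- vapply(seq_len(length(Rvals) - 1), function(i) {
    !identical(mats[[i]], mats[[i + 1]])
  }, TRUE)
  expected <- vapply(seq_len(length(Rvals) - 1), function(i) {
    any(d > Rvals[i] & d <= Rvals[i + 1])
  }, TRUE)
  expect_identical(crossings, expected)
})

test_that("kernel relative difference masks agreement and scales correctly", {
  a <- matrix(1:9, 3, 3) * 1.0
  expect_true(all(is.na(kernel_relative_difference(a, a))))
  expect_equal(unique(as.vector(kernel_relative_difference(a, 2 * a))), 1)
  expect_error(kernel_relative_difference(a, matrix(0, 2, 2)), "shape")
})

test_that("sharp double-step vs square step differ only at straddling pairs", {
  g <- default_grid()
  R <- g$representative_diameters[anchor_bin]
  tanh_sharp <- aggregation_kernel("tanh_double_step", top1 = 10, top2 = 1,
                                   R1 = 7000, R2 = R,
                                   delta1 = 1e-6, delta2 = 1e-6)
  sq <- aggregation_kernel("square_step", R = R, step = 10)
  mt <- build_kernel_matrix(tanh_sharp, g)
  ms <- build_kernel_matrix(sq, g)
  v <- g$representative_volumes
  # independent classification of every pair under the two step geometries
  circle_low <- sqrt(outer(v^2, v^2, "+")) <= R^3
  dd <- g$representative_diameters
  square_low <- outer(dd < R, dd < R, "&")
  disagree <- xor(circle_low, square_low)
  differs <- abs(mt - ms) > 1e-9 * ms
  expect_identical(differs, disagree)
})

test_that("invalid kernel arguments are rejected", {
  expect_error(aggregation_kernel("square_step", R = -1), "R")
  expect_error(aggregation_kernel("square_step", step = 0), "step")
  expect_error(aggregation_kernel("square_step_power", p = 1.5), "p")
  expect_error(aggregation_kernel("tanh_double_step", R1 = 100, R2 = 500),
               "R1 > R2")
  sq <- aggregation_kernel("square_step")
  expect_error(kernel_value(sq, -1, 10), "positive")
})
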