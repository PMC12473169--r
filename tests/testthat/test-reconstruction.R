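test_that("section fits recover exact polynomials after unscaling", {
  xs <- c(-1, -0.5, 0, 0.5, 1)
  f <- fit_section(radial_section(0, xs, xs^2), order_n = 2)
  expect_equal(section_fit_coeffs_raw(f), c(0, 0, 1), tolerance = 1e-9)
  expect_lt(f$rms_residual, 1e-12)

  f7 <- fit_section(radial_section(0, seq(-2, 2, length.out = 5), rep(7, 5)),
                    order_n = 3)
  expect_equal(section_fit_coeffs_raw(f7), c(7, 0, 0, 0), tolerance = 1e-9)

  expect_error(fit_section(radial_section(0, xs, xs), order_n = 5),
               "underdetermined")
})

test_that("section fits equal the normal-equations oracle", {
  set.seed(21)
  for (rep in 1:5) {
    x <- sort(runif(50, -3, 3))
    z <- rnorm(50)
    fit <- fit_section(radial_section(0.3, x, z), order_n = 4)
    expect_equal(section_fit_coeffs_raw(fit), ls_oracle(x, z, 4),
                 tolerance = 1e-8)
  }
})

test_that("matrix A rows are per-section fits ordered by angle", {
  # angle-invariant surface: all rows equal
  ss <- make_sections(function(x, a) 1 - x^2, n_sections = 6)
  A <- build_matrix_A(ss, order_n = 2)
  expect_equal(dim(A$values), c(6L, 3L))
  for (k in 2:6) expect_equal(A$values[k, ], A$values[1, ], tolerance = 1e-12)
  # unscaled row reads (1, 0, -1)
  expect_equal(poly_unscale_test(A$values[1, ], A$x_scale),
               c(1, 0, -1), tolerance = 1e-9)

  # shape contract at order 1 with two sections
  ss2 <- make_sections(function(x, a) x, n_sections = 2)
  expect_equal(dim(build_matrix_A(ss2, 1)$values), c(2L, 2L))

  # constant column reproduces the section parameter
  ssy <- make_sections(function(x, a) a + x^2, n_x = 9)
  Ay <- build_matrix_A(ssy, order_n = 2)
  raw <- t(apply(Ay$values, 1, poly_unscale_test, Ay$x_scale))
  expect_equal(raw[, 1], Ay$angles, tolerance = 1e-9)

  # a failing section is reported with its index
  bad <- section_set(list(radial_section(0, c(-1, 0, 1), c(0, 1, 0)),
                          radial_section(1, c(-1, 1), c(0, 0))))
  expect_error(build_matrix_A(bad, 2), "section 2")
})

test_that("second-layer fits reproduce structured coefficient matrices", {
  ss <- make_sections(function(x, a) 1 - x^2)
  A <- build_matrix_A(ss, 2)

  # constant columns -> B rows (c_i, 0, ..., 0)
  m0 <- fit_coefficient_curves(A, order_m = 3)
  expect_equal(dim(m0$B), c(3L, 4L))
  expect_equal(m0$B[, 2:4], matrix(0, 3, 3), tolerance = 1e-9)

  # linear-in-y columns recovered exactly at order 1
  ssl <- make_sections(function(x, a) a * (1 + x), n_x = 9)
  Al <- build_matrix_A(ssl, 2)
  ml <- fit_coefficient_curves(Al, order_m = 1)
  yh <- (Al$angles - ml$y_scale[1]) / ml$y_scale[2]
  recon <- ml$B %*% rbind(1, yh)   # a_i(y_k)
  expect_equal(t(recon), Al$values, tolerance = 1e-10)

  expect_error(fit_coefficient_curves(A, order_m = 6), "underdetermined")
})

test_that("second-layer fit equals an independent per-row oracle", {
  set.seed(33)
  angles <- sort(runif(7, 0, pi - 0.1))
  ss <- section_set(lapply(angles, function(a) {
    radial_section(a, seq(-1, 1, length.out = 9), rnorm(9))
  }))
  A <- build_matrix_A(ss, 3)
  m <- fit_coefficient_curves(A, order_m = 3)
  yh <- (angles - m$y_scale[1]) / m$y_scale[2]
  for (i in seq_len(nrow(m$B))) {
    expect_equal(m$B[i, ], ls_oracle(yh, A$values[, i], 3), tolerance = 1e-8)
  }
})

test_that("surface evaluation matches the term-by-term double sum", {
  set.seed(9)
  B <- matrix(rnorm(12), 4, 3)
  model <- structure(list(B = B, order_n = 3L, order_m = 2L,
                          x_scale = c(0.5, 2), y_scale = c(1, 1.5),
                          frame = "section-space"),
                     class = "surface_model")
  x <- runif(40, -1.5, 2.5)
  y <- runif(40, -0.5, 2.5)
  xh <- (x - 0.5) / 2
  yh <- (y - 1) / 1.5
  expect_equal(eval_surface(model, x, y), double_sum_oracle(B, xh, yh),
               tolerance = 1e-12)

  # constant-only matrix
  Bc <- matrix(0, 4, 3); Bc[1, 1] <- 4.2
  mc <- structure(list(B = Bc, order_n = 3L, order_m = 2L,
                       x_scale = c(0, 1), y_scale = c(0, 1),
                       frame = "section-space"), class = "surface_model")
  expect_equal(eval_surface(mc, c(-1, 0, 2), c(0, 1, 3)), rep(4.2, 3))
})

test_that("reconstruction recovers polynomial surfaces exactly", {
  f <- function(x, a) 2 + a - x^2
  ss <- make_sections(f, n_sections = 6, n_x = 15)
  model <- reconstruct_surface(ss, order_n = 12, order_m = 5)
  xs <- seq(-1, 1, length.out = 15)
  for (s in ss$sections) {
    expect_lt(max(abs(eval_surface(model, xs, rep(s$angle, 15)) - f(xs, s$angle))),
              1e-8)
  }
  expect_lt(attr(model, "global_rms"), 1e-8)
})

test_that("coefficient-matrix shape follows the polynomial orders", {
  surf <- analytic_surface("hemisphere", R = 10)
  ss <- sample_sections(surf, acquisition_plan(noise_sd = 0))
  expect_equal(dim(reconstruct_surface(ss, 12, 5)$B), c(13L, 6L))
  expect_equal(dim(reconstruct_surface(ss, 8, 5)$B), c(9L, 6L))
  # 3 sections cannot support a degree-5 second layer
  ss3 <- make_sections(function(x, a) 1 - x^2, n_sections = 3)
  expect_error(reconstruct_surface(ss3, 4, 5), "underdetermined")
})

test_that("in-sample RMS never increases with polynomial order", {
  set.seed(14)
  xs <- seq(-1, 1, length.out = 31)
  z <- sin(3 * xs) + rnorm(31, 0, 0.05)
  s <- radial_section(0, xs, z)
  rms <- vapply(2:10, function(n) fit_section(s, n)$rms_residual, numeric(1))
  expect_true(all(diff(rms) <= 1e-12))
})

test_that("model save/load round-trips through CSV plus sidecar", {
  ss <- make_sections(function(x, a) 1 + a * x - x^2, n_x = 11)
  model <- reconstruct_surface(ss, 4, 3)
  d <- withr::local_tempdir()
  p <- file.path(d, "B.csv")
  save_surface_model(model, p)
  back <- load_surface_model(p)
  expect_identical(back$B, model$B)
  expect_equal(back$x_scale, model$x_scale)
  expect_equal(back$y_scale, model$y_scale)
  x <- seq(-1, 1, 0.25)
  expect_identical(eval_surface(back, x, x + 0.5),
                   eval_surface(model, x, x + 0.5))
})

test_that("boundary polynomials evaluate with the additive correction", {
  expect_equal(eval_boundary_poly(boundary_poly(3), 0), 0.023)
  expect_equal(eval_boundary_poly(boundary_poly(5), 0), 0.011)
  expect_equal(eval_boundary_poly(boundary_poly(3, G = 1), 0), 1.023)
  # spot value against direct arithmetic
  x <- 0.1
  expect_equal(eval_boundary_poly(boundary_poly(3), x),
               896.436 * x^3 - 64.994 * x^2 + 1.206 * x + 0.023)
  expect_equal(eval_boundary_poly(boundary_poly(5), x),
               9617.999 * x^5 - 847.094 * x^4 - 104.9966 * x^3 +
                 15.369 * x^2 - 0.661 * x + 0.011)
})
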