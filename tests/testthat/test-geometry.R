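test_that("cylindrical/Cartesian transforms match the axis cases", {
  expect_equal(cyl_to_cart(1, 0, 5), list(x = 1, y = 0, z = 5))
  expect_equal(cyl_to_cart(2, pi / 2, 1)$y, 2)
  expect_equal(cyl_to_cart(2, pi / 2, 1)$x, 0, tolerance = 1e-15)
  expect_equal(cyl_to_cart(1, pi, 0)$x, -1)

  c1 <- cart_to_cyl(0, 2, 1)
  expect_equal(c(c1$r, c1$phi, c1$z), c(2, pi / 2, 1))
  # degenerate axis convention
  c0 <- cart_to_cyl(0, 0, 3)
  expect_equal(c(c0$r, c0$phi, c0$z), c(0, 0, 3))
  c2 <- cart_to_cyl(-1, -1, 0)
  expect_equal(c(c2$r, c2$phi), c(sqrt(2), -3 * pi / 4))
})

test_that("transform round-trips are the identity to 1e-12 mm", {
  set.seed(11)
  r <- runif(200, 0.01, 50)
  phi <- runif(200, -pi + 1e-6, pi)
  z <- runif(200, -10, 10)
  p <- cyl_to_cart(r, phi, z)
  back <- cart_to_cyl(p$x, p$y, p$z)
  expect_lt(max(abs(back$r - r)), 1e-12)
  expect_lt(max(abs(back$phi - phi)), 1e-12)

  x <- runif(200, -20, 20); y <- runif(200, -20, 20)
  cc <- cart_to_cyl(x, y, z)
  p2 <- cyl_to_cart(cc$r, cc$phi, cc$z)
  expect_lt(max(abs(p2$x - x)), 1e-12)
  expect_lt(max(abs(p2$y - y)), 1e-12)
})

test_that("tangent frames match analytic partials on simple surfaces", {
  # flat plane
  pl <- parametric_surface(function(u, v) list(x = u, y = v, z = 0 * u),
                           domain = c(-1, 1, -1, 1))
  fr <- tangent_frame(pl, 0.2, -0.3)
  expect_equal(fr$ru, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fr$rv, c(0, 1, 0), tolerance = 1e-9)
  expect_equal(fr$normal, c(0, 0, 1), tolerance = 1e-9)

  # graph surface z = u^2: normal at (0,0) = (0,0,1); at (1,0) prop (-2,0,1)
  gr <- parametric_surface(function(u, v) list(x = u, y = v, z = u^2),
                           domain = c(-2, 2, -2, 2))
  f0 <- tangent_frame(gr, 0, 0)
  expect_equal(f0$normal / sqrt(sum(f0$normal^2)), c(0, 0, 1),
               tolerance = 1e-6)
  f1 <- tangent_frame(gr, 1, 0)
  n1 <- f1$normal / sqrt(sum(f1$normal^2))
  expect_equal(n1, c(-2, 0, 1) / sqrt(5), tolerance = 1e-6)

  # sphere: normal parallel to the radius vector at an equatorial point
  sp <- sphere_surface(1)
  fe <- tangent_frame(sp, 0, 0.7)
  p <- fe$p
  cosang <- sum(fe$normal * p) / sqrt(sum(fe$normal^2) * sum(p^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-6)
})

test_that("normal is orthogonal to both tangents on random surfaces", {
  set.seed(3)
  sp <- sphere_surface(2.5)
  for (i in 1:20) {
    u <- runif(1, -1.2, 1.2)
    v <- runif(1, -2.5, 2.5)
    fr <- tangent_frame(sp, u, v)
    scale <- sqrt(sum(fr$normal^2)) *
      max(sqrt(sum(fr$ru^2)), sqrt(sum(fr$rv^2)))
    expect_lt(abs(sum(fr$normal * fr$ru)), 1e-9 * scale)
    expect_lt(abs(sum(fr$normal * fr$rv)), 1e-9 * scale)
  }
})

test_that("finite differences converge to analytic partials at O(h^2)", {
  f <- function(u, v) list(x = u, y = v, z = sin(2 * u) * cos(v))
  err_at <- function(h) {
    s <- parametric_surface(f, domain = c(-2, 2, -2, 2), step = h)
    fr <- tangent_frame(s, 0.4, -0.6)
    ru_true <- c(1, 0, 2 * cos(0.8) * cos(-0.6))
    max(abs(fr$ru - ru_true))
  }
  e1 <- err_at(1e-2)
  e2 <- err_at(5e-3)
  expect_lt(e2, e1 / 3)  # ~factor 4 expected for O(h^2)
})

test_that("regularity rank classifies frames by singular values", {
  pl <- parametric_surface(function(u, v) list(x = u, y = v, z = 0 * u),
                           domain = c(-1, 1, -1, 1))
  expect_identical(regularity_rank(tangent_frame(pl, 0, 0)), 2L)

  degen <- structure(list(ru = c(1, 0, 0), rv = c(1, 0, 0),
                          normal = c(0, 0, 0)), class = "tangent_frame")
  expect_identical(regularity_rank(degen), 1L)
  zero <- structure(list(ru = c(0, 0, 0), rv = c(0, 0, 0),
                         normal = c(0, 0, 0)), class = "tangent_frame")
  expect_identical(regularity_rank(zero), 0L)
})

test_that("tangent planes pass through the point and recover known planes", {
  # plane surface recovers its own equation
  pl <- parametric_surface(function(u, v) list(x = u, y = v, z = 0 * u),
                           domain = c(-1, 1, -1, 1))
  tp <- tangent_plane_at(pl, 0.1, 0.2)
  expect_equal(plane_value(tp, 5, -3, 0), 0, tolerance = 1e-9)

  # graph z = u^2 at (1, 0): -2(x - 1) + (z - 1) = 0 up to scale
  gr <- parametric_surface(function(u, v) list(x = u, y = v, z = u^2),
                           domain = c(-2, 2, -2, 2))
  tp2 <- tangent_plane_at(gr, 1, 0)
  expect_equal(plane_value(tp2, tp2$p0[1], tp2$p0[2], tp2$p0[3]), 0,
               tolerance = 1e-9)
  n <- tp2$normal / tp2$normal[3]
  expect_equal(n, c(-2, 0, 1), tolerance = 1e-5)

  # sphere: plane perpendicular to the radius
  sp <- sphere_surface(1)
  tp3 <- tangent_plane_at(sp, 0.5, 0.3)
  expect_equal(plane_value(tp3, tp3$p0[1], tp3$p0[2], tp3$p0[3]), 0,
               tolerance = 1e-9)

  # degenerate point is refused
  degen_s <- parametric_surface(function(u, v) list(x = u, y = u, z = 0 * u),
                                domain = c(-1, 1, -1, 1))
  expect_error(tangent_plane_at(degen_s, 0, 0), "not regular")
})

test_that("sphere parametrisation satisfies the implicit equation", {
  sp <- sphere_surface(2)
  expect_equal(unlist(sp$eval(0, 0)), c(x = 2, y = 0, z = 0))
  expect_equal(unlist(sp$eval(pi / 2, 1.3))[["z"]], 2)
  set.seed(5)
  u <- runif(50, -pi / 2, pi / 2)
  v <- runif(50, -pi, pi)
  p <- sp$eval(u, v)
  expect_lt(max(abs(p$x^2 + p$y^2 + p$z^2 - 4)), 1e-9 * 4)
  expect_error(sphere_surface(-1), "> 0")
})
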