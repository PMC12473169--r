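flat_unit_square <- function(h = 0.5, z = 0) {
  mesh_from_model(function(x, y) rep(z, length(x)),
                  rect_domain(c(0, 1), c(0, 1)), h, frame = "cartesian")
}

hemisphere_mesh <- function(R = 1, h = 0.05) {
  s <- analytic_surface("hemisphere", R = R)
  mesh_from_model(function(x, y) s$height(x, y), disc_domain(R), h,
                  frame = "section-space")
}

test_that("structured rectangle meshing has deterministic counts", {
  m <- flat_unit_square(0.5)
  expect_equal(nrow(m$vertices), 9L)
  expect_equal(nrow(m$faces), 8L)
  m2 <- flat_unit_square(0.5)
  expect_identical(m$vertices, m2$vertices)
  expect_identical(m$faces, m2$faces)
  expect_error(flat_unit_square(10), "element_size larger")
})

test_that("surface area sums triangles and scales by the elasticity k", {
  m <- flat_unit_square(0.5)
  a <- surface_area(m, k = 1)
  expect_equal(a$area_geometric, 1)
  expect_equal(a$area_corrected, 1)
  a2 <- surface_area(m, k = 1.1)
  expect_equal(a2$area_geometric, 1)
  expect_equal(a2$area_corrected, 1.1)
  expect_error(surface_area(m, k = 0), "> 0")
})

test_that("hemisphere mesh reproduces closed-form area and volume", {
  m <- hemisphere_mesh(R = 1, h = 0.02)
  a <- surface_area(m)$area_geometric
  expect_lt(abs(a / (2 * pi) - 1), 0.01)
  v <- volume_under_surface(m, 0, method = "both")
  expect_lt(abs(v["prism"] / (2 * pi / 3) - 1), 0.01)
  expect_lt(abs(v["prism"] / v["divergence"] - 1), 0.001)
})

test_that("volume handles flat and degenerate-height fixtures", {
  expect_equal(volume_under_surface(flat_unit_square(0.5, z = 1), 0), 1)
  expect_equal(volume_under_surface(flat_unit_square(0.5, z = 0), 0), 0)
  # dual routes agree on a non-flat graph too
  m <- mesh_from_model(function(x, y) 1 + 0.3 * x + 0.2 * y^2,
                       rect_domain(c(0, 2), c(0, 1)), 0.1,
                       frame = "cartesian")
  v <- volume_under_surface(m, 0, "both")
  expect_lt(abs(v["prism"] / v["divergence"] - 1), 1e-3)
})

test_that("area and volume are invariant under rigid rotation", {
  m <- hemisphere_mesh(R = 1, h = 0.1)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m2 <- tri_mesh(m$vertices %*% t(Rz), m$faces, m$element_size)
  expect_equal(surface_area(m2)$area_geometric,
               surface_area(m)$area_geometric, tolerance = 1e-9)
  expect_equal(volume_under_surface(m2, 0), volume_under_surface(m, 0),
               tolerance = 1e-9)
})

test_that("volume error shrinks as the element size halves", {
  v_true <- 2 * pi / 3
  errs <- vapply(c(0.1, 0.05), function(h) {
    abs(volume_under_surface(hemisphere_mesh(1, h), 0) - v_true)
  }, numeric(1))
  expect_lt(errs[2], errs[1] * 1.05)
})

test_that("mass, centroid and mean density follow the density field", {
  slab <- flat_unit_square(0.1, z = 1)
  mc <- mass_and_centroid(slab, density = density_field(2))
  expect_equal(mc$mass, 2, tolerance = 1e-12)
  expect_equal(unname(mc$centroid), c(0.5, 0.5, 0.5), tolerance = 1e-9)
  expect_equal(mc$mean_density, 2, tolerance = 1e-12)
  expect_equal(mc$mean_density, mc$mass / mc$volume)  # identity

  # hemisphere centroid z -> 3R/8
  mh <- mass_and_centroid(hemisphere_mesh(1, 0.02))
  expect_lt(abs(mh$centroid[["z"]] / (3 / 8) - 1), 0.02)

  # depth-proportional density: mass 1/2, centroid z = 2/3
  mz <- mass_and_centroid(slab, density = density_field(function(x, y, z) z))
  expect_equal(mz$mass, 0.5, tolerance = 1e-12)
  expect_equal(mz$centroid[["z"]], 2 / 3, tolerance = 5e-3)

  expect_error(
    mass_and_centroid(slab, density = density_field(function(x, y, z) z - 1)),
    "non-positive")
})

test_that("measure_report combines the measures consistently", {
  rep <- measure_report(hemisphere_mesh(1, 0.05), k = 1.2,
                        density = density_field(2))
  expect_equal(rep$area_corrected, 1.2 * rep$area_geometric)
  expect_equal(rep$mean_density, rep$mass / rep$volume, tolerance = 1e-9)
  expect_equal(rep$k_elasticity, 1.2)
  expect_lt(abs(rep$volume / rep$volume_divergence - 1), 1e-3)
  expect_gt(rep$n_elements, 0)
})

test_that("two-point resection measures distances and depths", {
  m <- flat_unit_square(0.5, z = 1)
  r <- resection_measure(m, c(0, 0, 1), c(1, 1, 1), base_z = 0)
  expect_equal(r$euclidean_mm, sqrt(2))
  expect_gte(r$surface_path_mm, r$euclidean_mm - 1e-12)
  expect_equal(r$depth1_mm, 1)
  expect_equal(r$surface_path_mm,
               dijkstra_oracle(m$vertices, m$faces, r$vertex1, r$vertex2),
               tolerance = 1e-12)

  same <- resection_measure(m, c(0, 0, 1), c(0, 0, 1))
  expect_equal(same$euclidean_mm, 0)
  expect_equal(same$surface_path_mm, 0)
  expect_equal(same$depth1_mm, same$depth2_mm)

  expect_error(resection_measure(m, c(5, 5, 5), c(0, 0, 1)), "farther")

  # edge path >= euclidean over sampled vertex pairs
  set.seed(8)
  hm <- hemisphere_mesh(1, 0.2)
  for (i in 1:5) {
    ij <- sample(nrow(hm$vertices), 2)
    p1 <- hm$vertices[ij[1], ]; p2 <- hm$vertices[ij[2], ]
    rr <- resection_measure(hm, p1, p2)
    expect_gte(rr$surface_path_mm + 1e-12, rr$euclidean_mm)
  }
})

test_that("mesh writers emit well-formed deterministic ASCII files", {
  m <- flat_unit_square(0.5, z = 1)
  d <- withr::local_tempdir()
  obj <- file.path(d, "m.obj")
  write_mesh(m, obj)
  lines <- readLines(obj)
  expect_equal(sum(startsWith(lines, "v ")), nrow(m$vertices))
  expect_equal(sum(startsWith(lines, "f ")), nrow(m$faces))
  write_mesh(m, file.path(d, "m2.obj"))
  expect_identical(readLines(file.path(d, "m2.obj")), lines)

  ply <- file.path(d, "m.ply")
  write_mesh(m, ply)
  pl <- readLines(ply)
  expect_equal(pl[1], "ply")
  expect_true(sprintf("element vertex %d", nrow(m$vertices)) %in% pl)

  stl <- file.path(d, "m.stl")
  write_mesh(m, stl)
  sl <- readLines(stl)
  expect_equal(sum(grepl("^  facet normal", sl)), nrow(m$faces))
})

test_that("mesh constructor validates faces and element size", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(tri_mesh(v, rbind(c(1, 2, 4)), 1), "out of range")
  expect_error(tri_mesh(v, rbind(c(1, 2, 3)), -1), "element_size")
  expect_error(tri_mesh(rbind(v, c(0.5, 0, 0)), rbind(c(1, 2, 4)), 1),
               "degenerate")
})
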