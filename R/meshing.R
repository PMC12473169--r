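#' Triangular surface mesh
#'
#' Container for a triangulated surface in Cartesian mm used by the
#' area/volume/centroid integrators. Faces are triples of 1-based vertex
#' indices, oriented with upward (positive z) normals by construction of
#' the built-in meshers.
#'
#' @param vertices Numeric `n x 3` matrix of (x, y, z), mm.
#' @param faces Integer `m x 3` matrix of vertex indices.
#' @param element_size Target linear element size, mm.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, element_size) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop_input("vertices must be n x 3")
  if (!all(is.finite(vertices))) stop_input("non-finite vertex coordinate")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop_input("face index out of range")
  }
  if (!is_scalar_num(element_size) || element_size <= 0) {
    stop_input("element_size must be > 0")
  }
  a <- triangle_areas(vertices, faces)
  if (any(a <= 1e-12)) stop_input("degenerate (zero-area) face in mesh")
  structure(list(vertices = vertices, faces = faces,
                 element_size = element_size),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces, element_size %g mm\n",
              nrow(x$vertices), nrow(x$faces), x$element_size))
  invisible(x)
}

face_cross <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - v1
  e2 <- vertices[faces[, 3], , drop = FALSE] - v1
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

triangle_areas <- function(vertices, faces) {
  cr <- face_cross(vertices, faces)
  0.5 * sqrt(rowSums(cr^2))
}

#' Rectangular and disc mesh domains
#'
#' @param xlim,ylim Parameter ranges for a rectangle.
#' @param radius Disc radius, mm.
#' @return A domain descriptor for [mesh_from_model()].
#' @export
rect_domain <- function(xlim, ylim) {
  stopifnot(length(xlim) == 2, length(ylim) == 2,
            xlim[2] > xlim[1], ylim[2] > ylim[1])
  list(type = "rect", xlim = as.numeric(xlim), ylim = as.numeric(ylim))
}

#' @rdname rect_domain
#' @export
disc_domain <- function(radius) {
  stopifnot(is_scalar_num(radius), radius > 0)
  list(type = "disc", radius = radius)
}

# Structured mesh over a rectangle in (u, v) parameter space.
# map: function(u, v) -> n x 3 matrix of Cartesian vertices.
mesh_rect_grid <- function(map, xlim, ylim, element_size) {
  dx <- diff(xlim); dy <- diff(ylim)
  if (element_size > dx || element_size > dy) {
    stop_input("element_size larger than the domain extent")
  }
  nx <- ceiling(dx / element_size)
  ny <- ceiling(dy / element_size)
  us <- seq(xlim[1], xlim[2], length.out = nx + 1)
  vs <- seq(ylim[1], ylim[2], length.out = ny + 1)
  g <- expand.grid(u = us, v = vs)                  # u varies fastest
  verts <- map(g$u, g$v)
  idx <- function(i, j) (j - 1L) * (nx + 1L) + i
  i <- rep(seq_len(nx), ny)
  j <- rep(seq_len(ny), each = nx)
  v00 <- idx(i, j); v10 <- idx(i + 1L, j)
  v01 <- idx(i, j + 1L); v11 <- idx(i + 1L, j + 1L)
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  list(vertices = verts, faces = faces)
}

# Structured ring/fan mesh over a disc: J rings of n_theta vertices plus a
# centre vertex; all faces counter-clockwise seen from above.
mesh_disc_grid <- function(hfun_cyl, radius, element_size) {
  if (element_size > radius) stop_input("element_size larger than the domain extent")
  J <- ceiling(radius / element_size)
  ntheta <- max(8L, ceiling(2 * pi * radius / element_size))
  phi <- (seq_len(ntheta) - 1) * 2 * pi / ntheta
  rr <- radius * seq_len(J) / J
  g_r <- rep(rr, each = ntheta)
  g_phi <- rep(phi, J)
  z <- c(hfun_cyl(0, 0), hfun_cyl(g_r, g_phi))
  verts <- rbind(c(0, 0, z[1]),
                 cbind(g_r * cos(g_phi), g_r * sin(g_phi), z[-1]))
  idx <- function(j, t) 1L + (j - 1L) * ntheta + ((t - 1L) %% ntheta) + 1L
  t <- seq_len(ntheta)
  faces <- cbind(1L, idx(1L, t), idx(1L, t + 1L))
  if (J > 1L) {
    for (j in 2:J) {
      a <- idx(j - 1L, t); b <- idx(j - 1L, t + 1L)
      c2 <- idx(j, t + 1L); d <- idx(j, t)
      faces <- rbind(faces, cbind(a, d, c2), cbind(a, c2, b))
    }
  }
  list(vertices = verts, faces = faces)
}

#' Triangulate a reconstructed surface model
#'
#' Builds a structured triangular mesh of the model's height field over a
#' rectangle or a disc. In `section-space` frame a parameter point
#' `(x, y)` maps to the Cartesian vertex `(x cos y, x sin y, z(x, y))` and
#' the disc is the natural domain (the angle is wrapped onto the fitted
#' half-turn using the signed-x symmetry `z(r, phi + pi) = z(-r, phi)`);
#' in `cartesian` frame the vertex is `(x, y, z(x, y))`. The construction
#' is deterministic: the same model, domain and element size always give
#' identical vertex and face arrays.
#'
#' @param model A `surface_model`, or any function `(x, y) -> z`.
#' @param domain [rect_domain()] or [disc_domain()].
#' @param element_size Target edge length, mm.
#' @param frame Overrides the model frame (`"section-space"` or
#'   `"cartesian"`); required when `model` is a bare function.
#' @return A [tri_mesh()].
#' @export
mesh_from_model <- function(model, domain, element_size, frame = NULL) {
  if (inherits(model, "surface_model")) {
    hfun <- function(x, y) eval_surface(model, x, y)
    if (is.null(frame)) frame <- model$frame
  } else if (is.function(model)) {
    hfun <- model
    if (is.null(frame)) stop_input("'frame' is required for a bare height function")
  } else {
    stop_input("'model' must be a surface_model or a function")
  }
  frame <- match.arg(frame, c("section-space", "cartesian"))
  if (domain$type == "disc") {
    if (frame != "section-space") {
      stop_input("disc domains require the section-space frame")
    }
    # wrap full-turn angle onto the fitted half-turn with signed x
    hcyl <- function(r, phi) {
      phi <- phi %% (2 * pi)
      x <- ifelse(phi < pi, r, -r)
      y <- ifelse(phi < pi, phi, phi - pi)
      hfun(x, y)
    }
    gm <- mesh_disc_grid(hcyl, domain$radius, element_size)
  } else {
    map <- if (frame == "section-space") {
      function(u, v) cbind(u * cos(v), u * sin(v), hfun(u, v))
    } else {
      function(u, v) cbind(u, v, hfun(u, v))
    }
    gm <- mesh_rect_grid(map, domain$xlim, domain$ylim, element_size)
  }
  tri_mesh(gm$vertices, gm$faces, element_size)
}

# Faces re-ordered so the projected (z-component) normal is >= 0.
orient_up <- function(mesh) {
  cr <- face_cross(mesh$vertices, mesh$faces)
  flip <- cr[, 3] < 0
  f <- mesh$faces
  f[flip, ] <- f[flip, c(1, 3, 2)]
  f
}

#' Geometric and elasticity-corrected surface area
#'
#' The geometric area is the sum of triangle areas (half cross-product
#' magnitude). The corrected skin area multiplies by the dimensionless
#' skin-elasticity coefficient `k`, accounting for the stretch of skin
#' over the raised lesion (k depends on patient age; no standard table is
#' bundled, so it is a user input, default 1).
#'
#' @param mesh A [tri_mesh()].
#' @param k Skin-elasticity coefficient (> 0).
#' @return List with `area_geometric` and `area_corrected`, mm^2.
#' @export
surface_area <- function(mesh, k = 1) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (!is_scalar_num(k) || k <= 0) stop_input("'k' must be > 0")
  a <- sum(triangle_areas(mesh$vertices, mesh$faces))
  list(area_geometric = a, area_corrected = k * a)
}

# Directed boundary edges of an up-oriented face set (edges used once).
boundary_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[key %in% names(which(table(key) == 1L)), , drop = FALSE]
}

#' Volume between the mesh and a base plane
#'
#' Two independent integration routes are provided. `"prism"` sums, per
#' triangle, the projected area times the mean vertex height above
#' `base_z`. `"divergence"` closes the mesh with vertical walls and a base
#' cap and evaluates the divergence-theorem signed volume
#' `sum(det(v1, v2, v3)) / 6`. The two must agree closely on any
#' graph-like mesh; `"both"` returns both for cross-checking.
#'
#' @param mesh A [tri_mesh()].
#' @param base_z Base plane height, mm.
#' @param method `"prism"`, `"divergence"` or `"both"`.
#' @param tol Tolerance (mm) for vertices below the base plane.
#' @return Volume in mm^3 (named vector of both when `method = "both"`).
#' @export
volume_under_surface <- function(mesh, base_z = 0,
                                 method = c("prism", "divergence", "both"),
                                 tol = 1e-9) {
  stopifnot(inherits(mesh, "tri_mesh"))
  method <- match.arg(method)
  if (any(mesh$vertices[, 3] < base_z - max(tol, 1e-9 * mesh$element_size))) {
    warning("mesh extends below the base plane; inverted regions truncated into the volume signs")
  }
  faces <- orient_up(mesh)
  V <- mesh$vertices
  prism <- function() {
    cr <- face_cross(V, faces)
    a_proj <- cr[, 3] / 2
    hbar <- (V[faces[, 1], 3] + V[faces[, 2], 3] + V[faces[, 3], 3]) / 3 - base_z
    sum(a_proj * hbar)
  }
  divergence <- function() {
    nV <- nrow(V)
    Vb <- V
    Vb[, 3] <- base_z
    verts <- rbind(V, Vb)
    base_faces <- faces[, c(1, 3, 2)] + nV        # cap, outward-down
    be <- boundary_edges(faces)
    wall_faces <- rbind(cbind(be[, 1], be[, 1] + nV, be[, 2] + nV),
                        cbind(be[, 1], be[, 2] + nV, be[, 2]))
    all_faces <- rbind(faces, base_faces, wall_faces)
    v1 <- verts[all_faces[, 1], , drop = FALSE]
    v2 <- verts[all_faces[, 2], , drop = FALSE]
    v3 <- verts[all_faces[, 3], , drop = FALSE]
    dets <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
      v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
      v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
    # closed outward surface: the det sum is origin-independent
    abs(sum(dets) / 6)
  }
  switch(method,
         prism = prism(),
         divergence = divergence(),
         both = c(prism = prism(), divergence = divergence()))
}

#' Density field
#'
#' @param value Either a single positive number (uniform density, g/mm^3)
#'   or a function `(x, y, z) -> density`.
#' @return An object of class `density_field`.
#' @export
density_field <- function(value = 1) {
  if (is.function(value)) {
    structure(list(mode = "callable", fn = value), class = "density_field")
  } else {
    if (!is_scalar_num(value) || value <= 0) stop_input("density must be > 0")
    structure(list(mode = "uniform", value = value), class = "density_field")
  }
}

density_at <- function(d, x, y, z) {
  if (d$mode == "uniform") rep(d$value, length(x)) else d$fn(x, y, z)
}

#' Mass, centroid and mean density of the enclosed body
#'
#' Integrates the density field over the region between the surface and
#' the base plane. Each triangle defines a vertical prism, subdivided into
#' vertical layers of at most `element_size` height; the density and the
#' coordinate moments are evaluated at each layer's midpoint (midpoint
#' quadrature, O(h^2) error). With a uniform density the mass reduces to
#' density times the prism volume exactly.
#'
#' @param mesh A [tri_mesh()].
#' @param base_z Base plane height, mm.
#' @param density A [density_field()] (or a number / function coerced to one).
#' @return List with `mass` (g), `centroid` (x, y, z mm), `mean_density`
#'   (g/mm^3) and `volume` (mm^3).
#' @export
mass_and_centroid <- function(mesh, base_z = 0, density = density_field(1)) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (!inherits(density, "density_field")) density <- density_field(density)
  faces <- orient_up(mesh)
  V <- mesh$vertices
  cr <- face_cross(V, faces)
  a_proj <- cr[, 3] / 2
  zbar <- (V[faces[, 1], 3] + V[faces[, 2], 3] + V[faces[, 3], 3]) / 3
  hbar <- pmax(zbar - base_z, 0)
  xc <- (V[faces[, 1], 1] + V[faces[, 2], 1] + V[faces[, 3], 1]) / 3
  yc <- (V[faces[, 1], 2] + V[faces[, 2], 2] + V[faces[, 3], 2]) / 3
  n_layers <- pmax(1L, ceiling(hbar / mesh$element_size))
  mass <- 0; mx <- 0; my <- 0; mz <- 0
  for (l in seq_len(max(n_layers))) {
    act <- which(n_layers >= l)
    if (!length(act)) break
    dz <- hbar[act] / n_layers[act]
    zmid <- base_z + (l - 0.5) * dz
    mu <- density_at(density, xc[act], yc[act], zmid)
    if (any(mu <= 0)) stop_input("non-positive density sample")
    dv <- a_proj[act] * dz
    dm <- mu * dv
    mass <- mass + sum(dm)
    mx <- mx + sum(xc[act] * dm)
    my <- my + sum(yc[act] * dm)
    mz <- mz + sum(zmid * dm)
  }
  vol <- sum(a_proj * hbar)
  list(mass = mass,
       centroid = c(x = mx, y = my, z = mz) / mass,
       mean_density = if (vol > 0) mass / vol else NA_real_,
       volume = vol)
}

#' Full geometric measure report
#'
#' Convenience wrapper computing area (geometric and elasticity-corrected),
#' volume (with the dual-route cross-check), mass, mean density and
#' centroid in one pass.
#'
#' @inheritParams mass_and_centroid
#' @param k Skin-elasticity coefficient.
#' @return An object of class `measure_report` (a named list).
#' @export
measure_report <- function(mesh, base_z = 0, k = 1, density = density_field(1)) {
  ar <- surface_area(mesh, k)
  vol <- volume_under_surface(mesh, base_z, method = "both")
  mc <- mass_and_centroid(mesh, base_z, density)
  structure(list(area_geometric = ar$area_geometric,
                 area_corrected = ar$area_corrected,
                 k_elasticity = k,
                 volume = unname(vol["prism"]),
                 volume_divergence = unname(vol["divergence"]),
                 mass = mc$mass,
                 mean_density = mc$mean_density,
                 centroid = mc$centroid,
                 n_elements = nrow(mesh$faces)),
            class = "measure_report")
}

#' @export
print.measure_report <- function(x, ...) {
  cat(sprintf(paste0(
    "measure_report (%d elements)\n",
    "  area: %.4g mm^2 (corrected %.4g, k=%.3g)\n",
    "  volume: %.4g mm^3   mass: %.4g g   mean density: %.4g g/mm^3\n",
    "  centroid: (%.4g, %.4g, %.4g) mm\n"),
    x$n_elements, x$area_geometric, x$area_corrected, x$k_elasticity,
    x$volume, x$mass, x$mean_density,
    x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Two-point resection measurement
#'
#' The operator places two points on the model; each is snapped to the
#' nearest mesh vertex (within one element size). Reported are the
#' straight-line distance between the placed points, the shortest path
#' between the snapped vertices along mesh edges (Dijkstra; an upper bound
#' on the true surface geodesic), and the depth of each point above the
#' base plane.
#'
#' @param mesh A [tri_mesh()].
#' @param p1,p2 Numeric length-3 points (x, y, z), mm.
#' @param base_z Base plane height, mm.
#' @return List with `euclidean_mm`, `surface_path_mm`, `depth1_mm`,
#'   `depth2_mm` and the snapped vertex indices.
#' @export
resection_measure <- function(mesh, p1, p2, base_z = 0) {
  stopifnot(inherits(mesh, "tri_mesh"))
  snap <- function(p) {
    d2 <- colSums((t(mesh$vertices) - p)^2)
    i <- which.min(d2)
    if (sqrt(d2[i]) > mesh$element_size) {
      stop_input("point (", paste(signif(p, 4), collapse = ", "),
                 ") is farther than one element size from every vertex")
    }
    i
  }
  i1 <- snap(p1); i2 <- snap(p2)
  euclid <- sqrt(sum((p1 - p2)^2))
  if (i1 == i2) {
    path <- 0
  } else {
    f <- mesh$faces
    e <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
    e <- t(apply(e, 1, sort))
    e <- unique(e)
    w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    path <- igraph::distances(g, v = i1, to = i2, weights = w)[1, 1]
  }
  list(euclidean_mm = euclid, surface_path_mm = unname(path),
       depth1_mm = unname(mesh$vertices[i1, 3]) - base_z,
       depth2_mm = unname(mesh$vertices[i2, 3]) - base_z,
       vertex1 = unname(i1), vertex2 = unname(i2))
}

fmt9 <- function(x) sprintf("%.9g", x)

#' Write a mesh to an ASCII file
#'
#' Supports Wavefront OBJ (default), ASCII PLY and ASCII STL. Coordinates
#' are printed with 9 significant digits so outputs are reproducible
#' across platforms.
#'
#' @param mesh A [tri_mesh()].
#' @param path Output path; the format is inferred from the extension
#'   unless `format` is given.
#' @param format `"obj"`, `"ply"` or `"stl"`.
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("obj", "ply", "stl"))
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "obj") {
    writeLines(sprintf("v %s %s %s", fmt9(V[, 1]), fmt9(V[, 2]), fmt9(V[, 3])), con)
    writeLines(sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3]), con)
  } else if (format == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(V)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(F)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%s %s %s", fmt9(V[, 1]), fmt9(V[, 2]), fmt9(V[, 3])), con)
    writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  } else {
    cr <- face_cross(V, F)
    nrm <- cr / pmax(sqrt(rowSums(cr^2)), .Machine$double.xmin)
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(F))) {
      writeLines(c(sprintf("  facet normal %s %s %s",
                           fmt9(nrm[i, 1]), fmt9(nrm[i, 2]), fmt9(nrm[i, 3])),
                   "    outer loop",
                   sprintf("      vertex %s %s %s",
                           fmt9(V[F[i, ], 1]), fmt9(V[F[i, ], 2]),
                           fmt9(V[F[i, ], 3])),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}
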