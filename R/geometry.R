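#' Cylindrical to Cartesian coordinates
#'
#' @param r Radius, mm (vectorised).
#' @param phi Azimuth, radians.
#' @param z Height, mm.
#' @return A list with numeric vectors `x`, `y`, `z`:
#'   `x = r cos(phi)`, `y = r sin(phi)`, `z = z`.
#' @export
cyl_to_cart <- function(r, phi, z) {
  if (any(r < 0)) stop_input("cylindrical radius must be >= 0")
  list(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Cartesian to cylindrical coordinates
#'
#' The radius is `sqrt(x^2 + y^2)`; `phi` is the two-argument arctangent of `(y, x)`
#' in `(-pi, pi]`, with the convention `phi = 0` at the axis (`x = y = 0`).
#'
#' @param x,y,z Cartesian coordinates, mm (vectorised).
#' @return A list with numeric vectors `r`, `phi`, `z`.
#' @export
cart_to_cyl <- function(x, y, z) {
  r <- sqrt(x^2 + y^2)
  phi <- atan2(y, x)
  phi[r == 0] <- 0
  list(r = r, phi = phi, z = z)
}

#' Parametric surface
#'
#' Wraps smooth coordinate functions `x(u,v), y(u,v), z(u,v)` over a
#' rectangular parameter domain, with optional analytic partial
#' derivatives. Partials default to central finite differences.
#'
#' @param eval Function `(u, v) -> list(x, y, z)` (vectorised).
#' @param domain Numeric vector `c(u_min, u_max, v_min, v_max)`.
#' @param step Finite-difference step as a fraction of the domain span
#'   of each parameter.
#' @param deriv Optional function `(u, v) -> list(ru = c(x,y,z), rv = c(x,y,z))`
#'   giving analytic partials.
#' @return An object of class `parametric_surface`.
#' @export
parametric_surface <- function(eval, domain, step = 1e-5, deriv = NULL) {
  stopifnot(is.function(eval), length(domain) == 4, step > 0)
  if (domain[2] <= domain[1] || domain[4] <= domain[3]) {
    stop_input("degenerate parameter domain")
  }
  structure(list(eval = eval, domain = as.numeric(domain), step = step,
                 deriv = deriv),
            class = "parametric_surface")
}

surface_point <- function(s, u, v) {
  p <- s$eval(u, v)
  c(p$x, p$y, p$z)
}

#' Tangent frame of a parametric surface
#'
#' Computes the tangent vectors `ru = dr/du`, `rv = dr/dv` and the normal
#' `N = ru x rv` at an interior parameter point. Partials are analytic when
#' the surface supplies them, otherwise second-order central differences.
#'
#' @param s A [parametric_surface()].
#' @param u,v Parameter values strictly inside the domain.
#' @return A list of class `tangent_frame` with 3-vectors `ru`, `rv`,
#'   `normal` and the point `p`.
#' @export
tangent_frame <- function(s, u, v) {
  stopifnot(inherits(s, "parametric_surface"))
  d <- s$domain
  hu <- s$step * (d[2] - d[1])
  hv <- s$step * (d[4] - d[3])
  if (u - hu < d[1] || u + hu > d[2] || v - hv < d[3] || v + hv > d[4]) {
    stop_input("(u, v) too close to the domain boundary for central differences")
  }
  if (!is.null(s$deriv)) {
    dv <- s$deriv(u, v)
    ru <- dv$ru
    rv <- dv$rv
  } else {
    ru <- (surface_point(s, u + hu, v) - surface_point(s, u - hu, v)) / (2 * hu)
    rv <- (surface_point(s, u, v + hv) - surface_point(s, u, v - hv)) / (2 * hv)
  }
  normal <- c(ru[2] * rv[3] - ru[3] * rv[2],
              ru[3] * rv[1] - ru[1] * rv[3],
              ru[1] * rv[2] - ru[2] * rv[1])
  structure(list(ru = ru, rv = rv, normal = normal, p = surface_point(s, u, v)),
            class = "tangent_frame")
}

#' Rank of the surface Jacobian at a point
#'
#' The 2x3 Jacobian `[ru; rv]` has rank 2 exactly at regular points, where
#' the tangent plane is non-degenerate. Rank is counted as the number of
#' singular values above `tol` times the largest singular value.
#'
#' @param frame A [tangent_frame()].
#' @param tol Relative singular-value threshold.
#' @return Integer 0, 1 or 2.
#' @export
regularity_rank <- function(frame, tol = 1e-10) {
  J <- rbind(frame$ru, frame$rv)
  sv <- svd(J, nu = 0, nv = 0)$d
  if (max(sv) == 0) return(0L)
  sum(sv > tol * max(sv))
}

#' Tangent plane at a regular surface point
#'
#' Returns the plane `Nx (x - x0) + Ny (y - y0) + Nz (z - z0) = 0` through
#' the surface point with the cross-product normal.
#'
#' @inheritParams tangent_frame
#' @param tol Regularity tolerance passed to [regularity_rank()].
#' @return A list of class `tangent_plane` with fields `normal` (`Nx, Ny,
#'   Nz`) and `p0` (`x0, y0, z0`).
#' @export
tangent_plane_at <- function(s, u, v, tol = 1e-10) {
  fr <- tangent_frame(s, u, v)
  if (regularity_rank(fr, tol) < 2L) {
    stop_input("surface is not regular at (u, v); tangent plane undefined")
  }
  structure(list(normal = fr$normal, p0 = fr$p), class = "tangent_plane")
}

#' Evaluate a tangent-plane equation at a point
#'
#' @param plane A `tangent_plane`.
#' @param x,y,z Cartesian point, mm.
#' @return The (signed) value of the plane form; 0 on the plane.
#' @export
plane_value <- function(plane, x, y, z) {
  plane$normal[1] * (x - plane$p0[1]) +
    plane$normal[2] * (y - plane$p0[2]) +
    plane$normal[3] * (z - plane$p0[3])
}

#' Sphere as a parametric surface
#'
#' Standard spherical parametrisation `x = R cos(u) cos(v)`,
#' `y = R cos(u) sin(v)`, `z = R sin(u)` with `u` the latitude and `v` the
#' longitude; every point satisfies `x^2 + y^2 + z^2 = R^2`. Used as a
#' smooth fixture with known differential geometry.
#'
#' @param R Radius, mm (> 0).
#' @return A [parametric_surface()] with analytic partial derivatives.
#' @export
sphere_surface <- function(R) {
  if (!is_scalar_num(R) || R <= 0) stop_input("sphere radius must be > 0")
  parametric_surface(
    eval = function(u, v) {
      list(x = R * cos(u) * cos(v), y = R * cos(u) * sin(v), z = R * sin(u))
    },
    domain = c(-pi / 2, pi / 2, -pi, pi),
    deriv = function(u, v) {
      list(ru = c(-R * sin(u) * cos(v), -R * sin(u) * sin(v), R * cos(u)),
           rv = c(-R * cos(u) * sin(v), R * cos(u) * cos(v), 0))
    })
}
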