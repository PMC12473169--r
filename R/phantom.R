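#' Analytic phantom surfaces
#'
#' Synthetic stand-ins for the physical calibration phantom: analytic
#' height fields `z(x, angle)` with closed-form geometry, used to exercise
#' and validate the whole acquisition/reconstruction pipeline.
#'
#' Kinds:
#' \describe{
#'   \item{`hemisphere`}{`z = sqrt(R^2 - x^2)` at every angle; every
#'     measure has a closed form (`area = 2 pi R^2`,
#'     `volume = 2/3 pi R^3`, centroid height `3R/8`).}
#'   \item{`gaussian-bumps`}{Sum of Gaussian bumps
#'     `A_i exp(-d_i^2 / (2 w_i^2))` at planar centres, the "complex"
#'     irregular case.}
#'   \item{`ellipsoid-cap`}{Upper half of an ellipsoid with semi-axes
#'     `(a, b, c)`.}
#' }
#'
#' @param kind One of `"hemisphere"`, `"gaussian-bumps"`, `"ellipsoid-cap"`.
#' @param R Hemisphere radius, mm.
#' @param centers For bumps: `n x 2` matrix of planar centres, mm.
#' @param amplitudes,widths For bumps: per-bump heights and Gaussian
#'   widths, mm.
#' @param semi_axes For the ellipsoid cap: `c(a, b, c)`, mm.
#' @return An object of class `analytic_surface` with fields `kind`,
#'   `height(x, angle)` and `support_radius` (mm).
#' @export
analytic_surface <- function(kind = c("hemisphere", "gaussian-bumps",
                                      "ellipsoid-cap"),
                             R = 10,
                             centers = NULL, amplitudes = NULL, widths = NULL,
                             semi_axes = c(10, 8, 5)) {
  kind <- match.arg(kind)
  if (kind == "hemisphere") {
    if (!is_scalar_num(R) || R <= 0) stop_input("hemisphere radius must be > 0")
    height <- function(x, angle) sqrt(pmax(R^2 - x^2, 0))
    support <- R
  } else if (kind == "gaussian-bumps") {
    if (is.null(centers)) {
      # default 3-bump irregular surface within a 10 mm footprint
      centers <- rbind(c(0, 0), c(4, 2), c(-3, 3))
      amplitudes <- c(5, 3, 2)
      widths <- c(3, 2, 1.5)
    }
    centers <- matrix(as.numeric(centers), ncol = 2)
    stopifnot(length(amplitudes) == nrow(centers),
              length(widths) == nrow(centers), all(widths > 0),
              all(amplitudes > 0))
    height <- function(x, angle) {
      px <- x * cos(angle)
      py <- x * sin(angle)
      z <- 0
      for (i in seq_len(nrow(centers))) {
        d2 <- (px - centers[i, 1])^2 + (py - centers[i, 2])^2
        z <- z + amplitudes[i] * exp(-d2 / (2 * widths[i]^2))
      }
      z
    }
    support <- max(sqrt(rowSums(centers^2)) + 4 * widths)
  } else {
    stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
    a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
    height <- function(x, angle) {
      px <- x * cos(angle)
      py <- x * sin(angle)
      cc * sqrt(pmax(1 - (px / a)^2 - (py / b)^2, 0))
    }
    support <- max(a, b)
  }
  structure(list(kind = kind, height = height, support_radius = support),
            class = "analytic_surface")
}

#' Rotational acquisition plan
#'
#' Describes the virtual acquisition: `n_sections` sections at
#' `angle_step` intervals covering a half-turn (signed x makes the second
#' half-turn redundant), `n_samples` equally spaced signed-x samples per
#' section, and additive Gaussian height noise. The defaults emulate the
#' reference acquisition: six sections at 30 degree intervals.
#'
#' @param n_sections Number of sections (>= 2).
#' @param angle_step Angular step, radians; default `pi / 6` (30 degrees).
#' @param n_samples Samples per section.
#' @param noise_sd Gaussian noise SD on z, mm (>= 0).
#' @param seed RNG seed for the noise.
#' @return An object of class `acquisition_plan`.
#' @export
acquisition_plan <- function(n_sections = 6, angle_step = pi / 6,
                             n_samples = 41, noise_sd = 0.1, seed = 1L) {
  if (n_sections < 2) stop_input("need at least 2 sections")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  if (n_sections * angle_step > pi + 1e-9) {
    stop_input("plan exceeds a half-turn; signed-x sections cover [0, pi)")
  }
  structure(list(n_sections = as.integer(n_sections), angle_step = angle_step,
                 n_samples = as.integer(n_samples), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "acquisition_plan")
}

#' Virtually acquire radial sections from an analytic surface
#'
#' Sections are taken at angles `0, step, ..., (n-1) step`; each samples
#' the closed-form height at `n_samples` equally spaced signed x across
#' the support, plus seeded Gaussian noise. Identical seeds give
#' bit-identical output.
#'
#' @param surf An [analytic_surface()].
#' @param plan An [acquisition_plan()].
#' @return A [section_set()].
#' @export
sample_sections <- function(surf, plan = acquisition_plan()) {
  stopifnot(inherits(surf, "analytic_surface"),
            inherits(plan, "acquisition_plan"))
  angles <- (seq_len(plan$n_sections) - 1) * plan$angle_step
  xs <- seq(-surf$support_radius, surf$support_radius,
            length.out = plan$n_samples)
  with_seed(plan$seed, {
    secs <- lapply(angles, function(a) {
      z <- surf$height(xs, a)
      if (plan$noise_sd > 0) z <- z + stats::rnorm(length(z), 0, plan$noise_sd)
      radial_section(a, xs, z)
    })
    section_set(secs, meta = list(phantom = surf$kind,
                                  noise_sd = plan$noise_sd,
                                  seed = plan$seed))
  })
}

#' Render a binary silhouette of an analytic surface
#'
#' Produces the image the virtual camera would capture at one rotation
#' angle: a light object on a dark background whose column-wise upper
#' envelope equals the analytic profile to within one pixel. Feeds the
#' imaging module for end-to-end tests.
#'
#' @param surf An [analytic_surface()].
#' @param angle Rotation angle, radians.
#' @param px Image width in pixels.
#' @param mm_per_px Physical pixel size, mm.
#' @return A [silhouette_image()] with `polarity = "light-object"`.
#' @export
render_silhouette <- function(surf, angle, px = 256, mm_per_px = 0.1) {
  stopifnot(inherits(surf, "analytic_surface"))
  half_width <- px * mm_per_px / 2
  if (surf$support_radius > half_width) {
    stop_input("support exceeds the image frame; increase px or mm_per_px")
  }
  xs <- (seq_len(px) - (px + 1) / 2) * mm_per_px
  z <- surf$height(xs, angle)
  zpx <- round(z / mm_per_px)
  nr <- max(zpx) + 2L            # margin so the object never touches the top
  pix <- matrix(0, nr, px)
  for (j in seq_len(px)) {
    if (zpx[j] >= 1L) pix[(nr - zpx[j] + 1L):nr, j] <- 1
  }
  silhouette_image(pix, mm_per_px, angle, polarity = "light-object")
}
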