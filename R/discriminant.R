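#' Per-parameter group statistics for discriminant screening
#'
#' Means and standard deviations of candidate resection parameters in the
#' normal state (Theta0) versus the pathological state (Theta1).
#'
#' @param names Parameter labels.
#' @param m0,m1 Means in states Theta0 and Theta1.
#' @param s0,s1 Standard deviations in the two states (> 0).
#' @return An object of class `group_stats`.
#' @export
group_stats <- function(names, m0, m1, s0, s1) {
  n <- length(names)
  if (!all(lengths(list(m0, m1, s0, s1)) == n)) {
    stop_input("all fields must have the same length")
  }
  if (any(s0 <= 0) || any(s1 <= 0)) stop_input("standard deviations must be > 0")
  structure(list(names = as.character(names),
                 m0 = as.numeric(m0), m1 = as.numeric(m1),
                 s0 = as.numeric(s0), s1 = as.numeric(s1)),
            class = "group_stats")
}

#' Mahalanobis separation of the two states
#'
#' Per parameter, the conservative SD `sigma_i = max(s0_i, s1_i)` is used.
#' The default `"squared"` mode is the standard squared Mahalanobis
#' distance `delta = sum((m0 - m1)^2 / sigma^2)`; the `"as-printed"` mode
#' is the signed variant `sum((m0 - m1) / sigma^2)` retained for
#' comparison with legacy reports that omit the square.
#'
#' @param g A [group_stats()].
#' @param mode `"squared"` (default) or `"as-printed"`.
#' @return Unitless distance `delta` (nonnegative in squared mode).
#' @export
mahalanobis_delta <- function(g, mode = c("squared", "as-printed")) {
  stopifnot(inherits(g, "group_stats"))
  mode <- match.arg(mode)
  sigma <- pmax(g$s0, g$s1)
  if (any(sigma == 0)) stop_input("zero standard deviation")
  if (mode == "squared") {
    sum(((g$m0 - g$m1) / sigma)^2)
  } else {
    sum((g$m0 - g$m1) / sigma^2)
  }
}

#' Decision-error probability bound
#'
#' Upper bound `P_err <= 1 - Phi(delta / 2)`. With the default
#' `"normal-cdf"` convention, `Phi` is the standard normal distribution
#' function (bound <= 0.5 for delta >= 0). The `"laplace"` convention uses
#' the textbook Laplace function `Phi0 = Phi - 1/2`, giving
#' `1 - Phi0(delta/2)` capped into `[0, 1]`; it is selectable because some
#' published tables report bounds above 0.5 that are only consistent with
#' this reading.
#'
#' @param delta Nonnegative separation from [mahalanobis_delta()].
#' @param phi_convention `"normal-cdf"` (default) or `"laplace"`.
#' @return Probability bound in `[0, 1]`.
#' @export
error_probability_bound <- function(delta,
                                    phi_convention = c("normal-cdf", "laplace")) {
  phi_convention <- match.arg(phi_convention)
  if (any(delta < 0)) stop_input("delta must be >= 0")
  p <- if (phi_convention == "normal-cdf") {
    1 - stats::pnorm(delta / 2)
  } else {
    1 - (stats::pnorm(delta / 2) - 0.5)
  }
  pmin(pmax(p, 0), 1)
}

#' Reference table of resection-parameter discriminant characteristics
#'
#' The five parameters screened for influence on resection outcome, with
#' their group means in the normal (Theta0) and pathological (Theta1)
#' states and the separation / error-bound values reported for them:
#' skin-elasticity coefficient, tumor volume (mm^3), tumor weight (g),
#' tumor density (g/mm^3), and the shape/size correction factor P. The
#' underlying standard deviations were not published, so the delta and
#' P_err columns are reference data for comparison only; they cannot be
#' recomputed from the means alone and are not produced by
#' [mahalanobis_delta()].
#'
#' @return A data frame with columns `name`, `label`, `theta0`, `theta1`,
#'   `delta_reported`, `p_err_bound_reported`.
#' @export
resection_reference_table <- function() {
  data.frame(
    name = paste0("X", 1:5),
    label = c("skin elasticity coefficient", "tumor volume (mm^3)",
              "tumor weight (g)", "tumor density (g/mm^3)",
              "P shape/size correction factor"),
    theta0 = c(1.1, 4, 0, 11, 0.67),
    theta1 = c(0.8, 1, 17.5, 9, 0.97),
    delta_reported = c(2.1, 2.5, 6.40, 7.3, 8.11),
    p_err_bound_reported = c(0.81, 0.69, 0.45, 0.4, 0.31),
    stringsAsFactors = FALSE)
}

#' Discriminant screening of a parameter set
#'
#' Computes the cumulative separation and error bound as parameters are
#' added one at a time, mirroring the question "can any parameter be
#' dropped without degrading the decision".
#'
#' @inheritParams mahalanobis_delta
#' @inheritParams error_probability_bound
#' @return A data frame with one row per parameter: `name`,
#'   `delta_single` (that parameter alone), `delta_cumulative`,
#'   `p_err_bound_cumulative`.
#' @export
discriminant_screen <- function(g, mode = c("squared", "as-printed"),
                                phi_convention = c("normal-cdf", "laplace")) {
  stopifnot(inherits(g, "group_stats"))
  mode <- match.arg(mode)
  phi_convention <- match.arg(phi_convention)
  n <- length(g$names)
  single <- vapply(seq_len(n), function(i) {
    mahalanobis_delta(group_stats(g$names[i], g$m0[i], g$m1[i],
                                  g$s0[i], g$s1[i]), mode)
  }, numeric(1))
  cum <- cumsum(single)
  data.frame(name = g$names,
             delta_single = single,
             delta_cumulative = cum,
             p_err_bound_cumulative = error_probability_bound(
               pmax(cum, 0), phi_convention),
             stringsAsFactors = FALSE)
}
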