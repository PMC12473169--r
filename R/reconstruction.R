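#' Fit one radial section by a polynomial
#'
#' Least-squares fit of `z(x)` by a degree-`order_n` polynomial. Before
#' fitting, x is affinely rescaled to `[-1, 1]` (the stored `x_scale`), which
#' keeps the Vandermonde design matrix well conditioned at the high orders
#' (12-13) this method uses; the scaling is carried in the result so the
#' fitted surface is unchanged. The system is solved by QR decomposition.
#'
#' @param s A [radial_section()].
#' @param order_n Polynomial degree N (fit has N+1 coefficients).
#' @param x_scale Optional shared scaling `c(center, halfwidth)`; defaults to
#'   the section's own x range.
#' @param raw If `TRUE`, fit on unscaled x (numerically unstable at high
#'   order; provided for comparison only).
#' @return An object of class `section_fit` with fields `angle`, `coeffs`
#'   (ascending powers of scaled x), `order_n`, `x_scale`, `rms_residual`.
#' @export
fit_section <- function(s, order_n, x_scale = NULL, raw = FALSE) {
  stopifnot(inherits(s, "radial_section"))
  if (!is_scalar_num(order_n) || order_n < 0) stop_input("'order_n' must be >= 0")
  order_n <- as.integer(order_n)
  if (length(s$xs) < order_n + 1L) {
    stop_input("underdetermined fit: ", length(s$xs), " points for order ",
               order_n)
  }
  if (is.null(x_scale)) {
    x_scale <- c(center = mean(range(s$xs)), halfwidth = diff(range(s$xs)) / 2)
  }
  if (x_scale[2] <= 0) stop_input("x_scale halfwidth must be > 0")
  xh <- if (raw) s$xs else (s$xs - x_scale[1]) / x_scale[2]
  V <- outer(xh, 0:order_n, `^`)
  qrV <- qr(V)
  if (qrV$rank < order_n + 1L) {
    stop_input("rank-deficient design matrix in section fit")
  }
  coeffs <- qr.coef(qrV, s$zs)
  res <- s$zs - drop(V %*% coeffs)
  structure(list(angle = s$angle, coeffs = unname(coeffs), order_n = order_n,
                 x_scale = unname(x_scale), raw = raw,
                 rms_residual = sqrt(mean(res^2))),
            class = "section_fit")
}

#' Unscale a section fit to raw-x polynomial coefficients
#'
#' @param fit A [fit_section()] result.
#' @return Numeric vector of coefficients of `z(x)` in ascending powers of
#'   the original (mm) x coordinate.
#' @export
section_fit_coeffs_raw <- function(fit) {
  stopifnot(inherits(fit, "section_fit"))
  if (isTRUE(fit$raw)) return(fit$coeffs)
  poly_unscale(fit$coeffs, fit$x_scale[1], fit$x_scale[2])
}

#' Build the per-section coefficient matrix A
#'
#' Row k of A holds the polynomial coefficients of section k (ordered by
#' angle), all fitted with a single shared x scaling covering every
#' section, so coefficients are comparable across rows.
#'
#' @param ss A [section_set()].
#' @param order_n Polynomial degree N per section.
#' @param raw Fit on unscaled x (see [fit_section()]).
#' @return An object of class `coeff_matrix_A` with fields `values`
#'   (`(M+1) x (N+1)` matrix), `angles`, `x_scale`, `order_n`,
#'   `rms_residuals` (per section).
#' @export
build_matrix_A <- function(ss, order_n, raw = FALSE) {
  stopifnot(inherits(ss, "section_set"))
  all_x <- unlist(lapply(ss$sections, `[[`, "xs"))
  x_scale <- c(mean(range(all_x)), diff(range(all_x)) / 2)
  fits <- vector("list", length(ss$sections))
  for (k in seq_along(ss$sections)) {
    fits[[k]] <- tryCatch(
      fit_section(ss$sections[[k]], order_n, x_scale = x_scale, raw = raw),
      error = function(e) stop_input("section ", k, " (angle ",
                                     signif(ss$sections[[k]]$angle, 4),
                                     " rad) failed to fit: ",
                                     conditionMessage(e)))
  }
  A <- do.call(rbind, lapply(fits, `[[`, "coeffs"))
  structure(list(values = A, angles = section_angles(ss), x_scale = x_scale,
                 order_n = as.integer(order_n), raw = raw,
                 rms_residuals = vapply(fits, `[[`, numeric(1), "rms_residual")),
            class = "coeff_matrix_A")
}

#' Second-layer fit: coefficients as polynomials of the section parameter
#'
#' Each column i of A (the values of coefficient `a_i` across sections) is
#' fitted by a degree-`order_m` polynomial in the section parameter y
#' (rescaled to `[-1, 1]`). Row i of the resulting matrix B holds
#' `b_i0 ... b_iM`, so the surface is
#' `z(x, y) = sum_i sum_k B[i, k] yhat^k xhat^i`.
#'
#' @param A A [build_matrix_A()] result.
#' @param order_m Polynomial degree M across sections.
#' @return A `surface_model` object; see [eval_surface()].
#' @export
fit_coefficient_curves <- function(A, order_m) {
  stopifnot(inherits(A, "coeff_matrix_A"))
  order_m <- as.integer(order_m)
  n_sec <- nrow(A$values)
  if (n_sec < order_m + 1L) {
    stop_input("underdetermined second-layer fit: ", n_sec,
               " sections for order ", order_m)
  }
  y <- A$angles
  y_scale <- c(mean(range(y)), diff(range(y)) / 2)
  yh <- (y - y_scale[1]) / y_scale[2]
  Vy <- outer(yh, 0:order_m, `^`)
  qrV <- qr(Vy)
  if (qrV$rank < order_m + 1L) {
    stop_input("rank-deficient second-layer design matrix")
  }
  # columns of A are the responses; solve all at once
  Bt <- qr.coef(qrV, A$values)          # (M+1) x (N+1)
  B <- t(Bt)                            # row i = b_i0..b_iM
  structure(list(B = unname(B), order_n = A$order_n, order_m = order_m,
                 x_scale = A$x_scale, y_scale = unname(y_scale),
                 frame = "section-space"),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("surface_model: B %d x %d (N=%d, M=%d), frame=%s\n",
              nrow(x$B), ncol(x$B), x$order_n, x$order_m, x$frame))
  invisible(x)
}

#' Evaluate the reconstructed surface
#'
#' Computes `z(x, y) = sum_i sum_k b_ik yhat^k xhat^i` where `xhat`, `yhat`
#' are the model's stored affine rescalings of the inputs. Vectorised;
#' `x` and `y` are recycled to a common length.
#'
#' @param model A `surface_model`.
#' @param x Signed in-section coordinate(s), mm.
#' @param y Section parameter value(s) (rotation angle, radians).
#' @param warn_extrapolation Warn when evaluating outside the fitted
#'   parameter rectangle.
#' @return Numeric vector of heights z, mm.
#' @export
eval_surface <- function(model, x, y, warn_extrapolation = FALSE) {
  stopifnot(inherits(model, "surface_model"))
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  xh <- (x - model$x_scale[1]) / model$x_scale[2]
  yh <- (y - model$y_scale[1]) / model$y_scale[2]
  if (warn_extrapolation && any(abs(xh) > 1 + 1e-9 | abs(yh) > 1 + 1e-9)) {
    warning("evaluating surface model outside the fitted domain")
  }
  Xp <- outer(xh, 0:model$order_n, `^`)   # n x (N+1)
  Yp <- outer(yh, 0:model$order_m, `^`)   # n x (M+1)
  rowSums((Xp %*% model$B) * Yp)
}

#' Reconstruct a surface model from a section set
#'
#' The complete two-layer pipeline: per-section polynomial fits assembled
#' into matrix A, then per-coefficient fits across the section parameter
#' giving matrix B. Defaults N = 12, M = 5 give a 13 x 6 coefficient
#' matrix from six sections.
#'
#' @param ss A [section_set()].
#' @param order_n Per-section polynomial degree N (default 12).
#' @param order_m Cross-section polynomial degree M (default 5).
#' @param raw Fit on unscaled coordinates (unstable at high order).
#' @return A `surface_model` with attributes `section_rms` (per-section
#'   first-layer residual RMS) and `global_rms` (RMS of the final model
#'   against all input samples).
#' @export
reconstruct_surface <- function(ss, order_n = 12, order_m = 5, raw = FALSE) {
  A <- build_matrix_A(ss, order_n, raw = raw)
  model <- fit_coefficient_curves(A, order_m)
  resid2 <- 0
  n_tot <- 0
  for (s in ss$sections) {
    zhat <- eval_surface(model, s$xs, rep(s$angle, length(s$xs)))
    resid2 <- resid2 + sum((zhat - s$zs)^2)
    n_tot <- n_tot + length(s$xs)
  }
  attr(model, "section_rms") <- A$rms_residuals
  attr(model, "global_rms") <- sqrt(resid2 / n_tot)
  model
}

#' Save / load a surface model
#'
#' The coefficient matrix B goes to a headered CSV (see
#' [write_coeff_matrix()]) and the orders, scalings and frame to a JSON
#' sidecar `<stem>.json`.
#'
#' @param model A `surface_model`.
#' @param path Path of the coefficient CSV; the sidecar uses the same stem.
#' @return Invisibly, `path`.
#' @export
save_surface_model <- function(model, path) {
  stopifnot(inherits(model, "surface_model"))
  write_coeff_matrix(coeff_matrix(model$B, kind = "B"), path)
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  # scalings as %.17g strings so reloaded models evaluate bit-identically
  jsonlite::write_json(
    list(order_n = model$order_n, order_m = model$order_m,
         x_scale = sprintf("%.17g", model$x_scale),
         y_scale = sprintf("%.17g", model$y_scale),
         frame = model$frame),
    side, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_surface_model
#' @export
load_surface_model <- function(path) {
  m <- read_coeff_matrix(path)
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(side)) stop_input("model sidecar not found: ", side)
  meta <- jsonlite::fromJSON(side)
  structure(list(B = m$values, order_n = as.integer(meta$order_n),
                 order_m = as.integer(meta$order_m),
                 x_scale = as.numeric(meta$x_scale),
                 y_scale = as.numeric(meta$y_scale), frame = meta$frame),
            class = "surface_model")
}

#' Fixed boundary polynomials with correction factor
#'
#' Degree-3 and degree-5 polynomials approximating, respectively, the
#' concave and convex parts of a lesion boundary projected onto a plane,
#' plus an additive correction factor `G`:
#' degree 3: `z = 896.436 x^3 - 64.994 x^2 + 1.206 x + 0.023 + G`;
#' degree 5: `z = 9617.999 x^5 - 847.094 x^4 - 104.9966 x^3 + 15.369 x^2 -
#' 0.661 x + 0.011 + G`.
#'
#' @param degree 3 or 5.
#' @param G Additive correction factor.
#' @return An object of class `boundary_poly` with `coeffs` (ascending
#'   powers) and `G`.
#' @export
boundary_poly <- function(degree = c(3, 5), G = 0) {
  degree <- match.arg(as.character(degree[1]), c("3", "5"))
  coeffs <- if (degree == "3") {
    c(0.023, 1.206, -64.994, 896.436)
  } else {
    c(0.011, -0.661, 15.369, -104.9966, -847.094, 9617.999)
  }
  structure(list(coeffs = coeffs, G = G, degree = as.integer(degree)),
            class = "boundary_poly")
}

#' Evaluate a boundary polynomial
#'
#' @param p A [boundary_poly()].
#' @param x Coordinate(s) along the projected boundary.
#' @return `z` value(s): polynomial plus `G`.
#' @export
eval_boundary_poly <- function(p, x) {
  stopifnot(inherits(p, "boundary_poly"))
  poly_eval(p$coeffs, x) + p$G
}
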