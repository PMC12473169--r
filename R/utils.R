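# Internal helpers shared across modules.

# Evaluate RNG-dependent code under a given seed, restoring the caller's
# RNG state afterwards so library calls have no global side effects.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Multiply two polynomials given as coefficient vectors (ascending powers).
poly_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# Rewrite p(xhat), xhat = (x - center)/halfwidth, as a polynomial in raw x.
# Coefficients ascending; used to report fits on the original mm scale.
poly_unscale <- function(coeffs, center, halfwidth) {
  lin <- c(-center / halfwidth, 1 / halfwidth)  # xhat as polynomial in x
  out <- numeric(1)
  pw <- 1  # lin^0
  for (i in seq_along(coeffs)) {
    term <- coeffs[i] * pw
    n <- max(length(out), length(term))
    out <- c(out, numeric(n - length(out))) + c(term, numeric(n - length(term)))
    pw <- poly_mul(pw, lin)
  }
  out[seq_len(length(coeffs))]
}

poly_eval <- function(coeffs, x) {
  # Horner, ascending coefficients
  z <- rep(0, length(x))
  for (i in rev(seq_along(coeffs))) z <- z * x + coeffs[i]
  z
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("rs_input_error", "error")))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
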