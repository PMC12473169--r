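# Independent oracles and fixture builders, deliberately brute-force and
# separate from the package's code paths.

# Polynomial least squares by explicit normal equations: solve V'V a = V'z.
ls_oracle <- function(x, z, degree) {
  V <- outer(x, 0:degree, `^`)
  solve(crossprod(V), crossprod(V, z))[, 1]
}

# Otsu threshold by exhaustive search over the 256 candidate cuts; flat
# maxima (empty gap between modes) resolved by the plateau midpoint.
otsu_oracle <- function(values, nbins = 256L) {
  h <- tabulate(pmin(pmax(floor(values * nbins) + 1L, 1L), nbins), nbins)
  p <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  s <- rep(-Inf, nbins - 1L)
  for (t in seq_len(nbins - 1L)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:t] * mids[1:t]) / w0
    m1 <- sum(p[(t + 1):nbins] * mids[(t + 1):nbins]) / w1
    s[t] <- w0 * w1 * (m0 - m1)^2
  }
  mean(which(s >= max(s) * (1 - 1e-12))) / nbins
}

# Term-by-term double-sum evaluation of a bivariate coefficient matrix on
# already-scaled coordinates.
double_sum_oracle <- function(B, xh, yh) {
  z <- 0
  for (i in seq_len(nrow(B))) {
    for (k in seq_len(ncol(B))) {
      z <- z + B[i, k] * yh^(k - 1) * xh^(i - 1)
    }
  }
  z
}

# Sections of an analytic z(x, angle) at evenly spaced angles over a
# half-turn, sampled on a fixed signed-x grid.
make_sections <- function(f, n_sections = 6, n_x = 15, x_max = 1) {
  angles <- (seq_len(n_sections) - 1) * pi / n_sections
  xs <- seq(-x_max, x_max, length.out = n_x)
  section_set(lapply(angles, function(a) radial_section(a, xs, f(xs, a))))
}

# Shortest-path oracle by exhaustive Bellman-Ford relaxation on a small
# vertex set.
dijkstra_oracle <- function(vertices, faces, from, to) {
  n <- nrow(vertices)
  e <- unique(rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)]))
  d <- rep(Inf, n)
  d[from] <- 0
  for (iter in seq_len(n)) {
    for (r in seq_len(nrow(e))) {
      a <- e[r, 1]; b <- e[r, 2]
      w <- sqrt(sum((vertices[a, ] - vertices[b, ])^2))
      if (d[a] + w < d[b]) d[b] <- d[a] + w
      if (d[b] + w < d[a]) d[a] <- d[b] + w
    }
  }
  d[to]
}

# Convert coefficients in scaled x to raw-x coefficients by sampling the
# fitted polynomial and re-solving a Vandermonde system.
poly_unscale_test <- function(coeffs, x_scale) {
  deg <- length(coeffs) - 1L
  x <- seq(-1, 1, length.out = deg + 1L) * x_scale[2] + x_scale[1]
  xh <- (x - x_scale[1]) / x_scale[2]
  z <- drop(outer(xh, 0:deg, `^`) %*% coeffs)
  solve(outer(x, 0:deg, `^`), z)
}
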