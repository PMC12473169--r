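#' Silhouette image of a rotated object
#'
#' A grayscale photograph of the object against a contrasting background,
#' taken at one rotation angle. Pixel values are in `[0, 1]`; `polarity`
#' says whether the object is darker (`"dark-object"`) or lighter
#' (`"light-object"`) than the background. Row 1 is the top of the image.
#'
#' @param pixels Numeric matrix in `[0, 1]`.
#' @param mm_per_px Physical pixel size, mm (> 0).
#' @param angle Rotation angle, radians.
#' @param polarity `"dark-object"` or `"light-object"`.
#' @return An object of class `silhouette_image`.
#' @export
silhouette_image <- function(pixels, mm_per_px, angle = 0,
                             polarity = c("dark-object", "light-object")) {
  polarity <- match.arg(polarity)
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(!is.finite(pixels)) ||
      any(pixels < 0) || any(pixels > 1)) {
    stop_input("pixel values must be finite and in [0, 1]")
  }
  if (!is_scalar_num(mm_per_px) || mm_per_px <= 0) {
    stop_input("mm_per_px must be > 0")
  }
  structure(list(pixels = pixels, mm_per_px = mm_per_px, angle = angle,
                 polarity = polarity),
            class = "silhouette_image")
}

#' Read a PNG or TIFF silhouette image
#'
#' Color images are collapsed to luminance with the Rec.\ 601 weights
#' (0.299, 0.587, 0.114); an alpha channel is ignored.
#'
#' @param path Image path (`.png`, `.tif`, `.tiff`).
#' @inheritParams silhouette_image
#' @return A [silhouette_image()].
#' @export
read_silhouette <- function(path, mm_per_px, angle = 0,
                            polarity = "dark-object") {
  if (!file.exists(path)) stop_input("image not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop_input("unsupported image format: .", ext))
  px <- if (length(dim(arr)) == 3L) {
    w <- c(0.299, 0.587, 0.114)
    arr[, , 1] * w[1] + arr[, , 2] * w[2] + arr[, , 3] * w[3]
  } else {
    arr
  }
  silhouette_image(px, mm_per_px, angle, polarity)
}

#' Otsu threshold
#'
#' Classic histogram threshold maximising the between-class variance, on a
#' fixed 256-bin histogram of `[0, 1]`. With well-separated modes the
#' between-class variance is flat across the empty gap, so the midpoint of
#' the maximising plateau is returned.
#'
#' @param values Numeric vector (or matrix) of intensities in `[0, 1]`.
#' @param nbins Number of histogram bins.
#' @return Threshold in `[0, 1]`.
#' @export
otsu_threshold <- function(values, nbins = 256L) {
  v <- as.numeric(values)
  if (any(v < 0 | v > 1)) stop_input("intensities must be in [0, 1]")
  h <- tabulate(pmin(pmax(floor(v * nbins) + 1L, 1L), nbins), nbins)
  p <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[nbins]
  w1 <- 1 - w0
  # between-class variance for threshold after bin t
  num <- (mt * w0 - m0)^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  sigma_b <- sigma_b[-nbins]
  plateau <- which(sigma_b >= max(sigma_b) * (1 - 1e-12))
  mean(plateau) / nbins
}

#' Binarise a silhouette image
#'
#' Normalises polarity so the object is bright, thresholds (Otsu by
#' default), and keeps the largest 4-connected foreground component (ties
#' broken by the leftmost bounding box).
#'
#' @param img A [silhouette_image()].
#' @param threshold Numeric threshold in `[0, 1]`, or `"auto"` for Otsu.
#' @return A logical foreground mask with attribute `threshold_used`.
#' @export
binarize <- function(img, threshold = "auto") {
  stopifnot(inherits(img, "silhouette_image"))
  fg <- if (img$polarity == "dark-object") 1 - img$pixels else img$pixels
  thr <- if (identical(threshold, "auto")) {
    otsu_threshold(fg)
  } else {
    if (!is_scalar_num(threshold) || threshold < 0 || threshold > 1) {
      stop_input("threshold must be in [0, 1]")
    }
    threshold
  }
  mask <- fg > thr
  if (!any(mask)) stop_input("empty foreground after thresholding")
  lab <- label_components4(mask)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # leftmost bounding box wins
    left <- vapply(best, function(b) min(col(lab)[lab == b]), numeric(1))
    best <- best[which.min(left)]
  }
  out <- lab == best
  attr(out, "threshold_used") <- thr
  out
}

# 4-connected component labelling by iterative minimum-label propagation.
label_components4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  shift_min <- function(l) {
    m <- l
    m[-1, ] <- pmin(m[-1, ], ifelse(l[-nr, ] > 0L, l[-nr, ], .Machine$integer.max))
    m[-nr, ] <- pmin(m[-nr, ], ifelse(l[-1, ] > 0L, l[-1, ], .Machine$integer.max))
    m[, -1] <- pmin(m[, -1], ifelse(l[, -nc] > 0L, l[, -nc], .Machine$integer.max))
    m[, -nc] <- pmin(m[, -nc], ifelse(l[, -1] > 0L, l[, -1], .Machine$integer.max))
    m[!mask] <- 0L
    m
  }
  repeat {
    new <- shift_min(lab)
    if (identical(new, lab)) break
    lab <- new
  }
  # compact labels
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

#' Extract a radial-section profile from a silhouette
#'
#' After binarisation, each pixel column intersecting the mask contributes
#' one profile sample: the topmost foreground row defines the height `z`
#' (measured from the bottom image row, in pixels times `mm_per_px`), and
#' the signed coordinate `x` is measured from the vertical symmetry axis
#' (by default the foreground centroid column). An object touching the top
#' image border is rejected as clipped.
#'
#' @param img A [silhouette_image()].
#' @param threshold Passed to [binarize()].
#' @param axis_col Symmetry-axis column (fractional pixels); default is the
#'   foreground centroid column.
#' @return A list of class `profile_extract` with fields `section`
#'   (a [radial_section()]), `threshold_used`, `n_foreground_px`.
#' @export
extract_profile <- function(img, threshold = "auto", axis_col = NULL) {
  stopifnot(inherits(img, "silhouette_image"))
  mask <- binarize(img, threshold)
  if (any(mask[1, ])) stop_input("object touches the top image border (clipped)")
  nr <- nrow(mask)
  cols <- which(colSums(mask) > 0)
  top <- vapply(cols, function(j) which(mask[, j])[1], numeric(1))
  if (is.null(axis_col)) axis_col <- mean(col(mask)[mask])
  xs <- (cols - axis_col) * img$mm_per_px
  zs <- (nr - top + 1) * img$mm_per_px
  structure(list(section = radial_section(img$angle, xs, zs),
                 threshold_used = attr(mask, "threshold_used"),
                 n_foreground_px = sum(mask)),
            class = "profile_extract")
}
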