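#' Radial cross-section profile
#'
#' A radial section is the diametral height profile `z(x)` of a raised
#' surface measured in the vertical plane at one rotation angle of the
#' object. `x` is the signed in-plane distance (mm) from the rotation axis,
#' so one section covers both sides of the object; `z` is height above the
#' healthy-skin base plane (mm).
#'
#' @param angle Section angle in radians, in `[0, pi)`.
#' @param xs Signed in-section coordinates, mm; must be strictly increasing
#'   after sorting (duplicates are an error).
#' @param zs Heights, mm; same length as `xs`.
#' @return An object of class `radial_section` with fields `angle`, `xs`,
#'   `zs` (sorted by `xs`).
#' @examples
#' radial_section(0, c(-1, 0, 1), c(0, 1, 0))
#' @export
radial_section <- function(angle, xs, zs) {
  if (!is_scalar_num(angle)) stop_input("'angle' must be a single finite number")
  xs <- as.numeric(xs)
  zs <- as.numeric(zs)
  if (length(xs) != length(zs)) stop_input("'xs' and 'zs' must have equal length")
  if (length(xs) < 2L) stop_input("a radial section needs at least 2 samples")
  if (!all(is.finite(xs)) || !all(is.finite(zs))) {
    stop_input("section coordinates must all be finite")
  }
  ord <- order(xs)
  xs <- xs[ord]
  zs <- zs[ord]
  if (any(diff(xs) == 0)) stop_input("duplicate x values in section")
  structure(list(angle = angle, xs = xs, zs = zs), class = "radial_section")
}

#' Set of radial sections
#'
#' Bundles the sections of one rotational acquisition. Angles must be
#' strictly increasing and distinct modulo pi (a half-turn suffices because
#' each section carries signed x).
#'
#' @param sections List of [radial_section()] objects (at least 2).
#' @param meta Optional named list of free-form provenance strings.
#' @return An object of class `section_set` with fields `sections`,
#'   `units` (always `"mm"`) and `meta`.
#' @export
section_set <- function(sections, meta = list()) {
  if (!is.list(sections) || length(sections) < 2L) {
    stop_input("need at least 2 sections")
  }
  ok <- vapply(sections, inherits, logical(1), "radial_section")
  if (!all(ok)) stop_input("all elements must be radial_section objects")
  ang <- vapply(sections, `[[`, numeric(1), "angle")
  ord <- order(ang)
  sections <- sections[ord]
  ang <- ang[ord]
  if (any(diff(ang) <= 0)) stop_input("section angles must be strictly increasing")
  amod <- ang %% pi
  if (any(abs(outer(amod, amod, "-"))[lower.tri(diag(length(amod)))] < 1e-12)) {
    stop_input("section angles must be distinct modulo pi")
  }
  structure(list(sections = sections, units = "mm", meta = meta),
            class = "section_set")
}

#' @export
print.section_set <- function(x, ...) {
  ang <- vapply(x$sections, `[[`, numeric(1), "angle")
  cat(sprintf("section_set: %d sections at %s deg\n", length(x$sections),
              paste(signif(ang * 180 / pi, 4), collapse = ", ")))
  invisible(x)
}

section_angles <- function(ss) vapply(ss$sections, `[[`, numeric(1), "angle")

detect_delim <- function(path) {
  head <- readLines(path, n = 5L, warn = FALSE)
  head <- head[!grepl("^\\s*#", head) & nzchar(trimws(head))]
  if (!length(head)) stop_input("file has no data rows: ", path)
  for (d in c(",", "\t", ";")) {
    if (all(grepl(d, head, fixed = TRUE))) return(d)
  }
  stop_input("could not detect delimiter (comma/tab/semicolon) in ", path)
}

#' Read one radial-section file
#'
#' Section files are two-column delimited text (`x_mm, z_mm`); the delimiter
#' is auto-detected among comma, tab and semicolon, and lines starting with
#' `#` are comments. Rows are sorted by x; duplicate x values are rejected.
#'
#' @param path Path to the section file.
#' @param angle Section angle in radians (the file itself carries no angle;
#'   it comes from the filename convention or the manifest).
#' @return A [radial_section()].
#' @export
read_section_file <- function(path, angle) {
  if (!file.exists(path)) stop_input("section file not found: ", path)
  delim <- detect_delim(path)
  df <- tryCatch(
    utils::read.table(path, sep = delim, comment.char = "#",
                      colClasses = "numeric", col.names = c("x", "z")),
    error = function(e) stop_input("could not parse '", path, "': ",
                                   conditionMessage(e)))
  if (nrow(df) < 2L) stop_input("fewer than 2 rows in ", path)
  radial_section(angle, df$x, df$z)
}

#' Read a section set from a manifest
#'
#' The manifest is a JSON array of `{"file": <name>, "angle_deg": <number>}`
#' entries; file names are resolved relative to the manifest's directory.
#' Angles are converted to radians and sections sorted by angle.
#'
#' @param manifest Path to the manifest JSON.
#' @return A [section_set()].
#' @export
read_section_set <- function(manifest) {
  if (!file.exists(manifest)) stop_input("manifest not found: ", manifest)
  entries <- jsonlite::fromJSON(manifest, simplifyDataFrame = TRUE)
  if (is.null(dim(entries)) || nrow(entries) == 0L) {
    stop_input("empty manifest: ", manifest)
  }
  if (!all(c("file", "angle_deg") %in% names(entries))) {
    stop_input("manifest entries need 'file' and 'angle_deg' fields")
  }
  if (anyDuplicated(entries$angle_deg)) stop_input("repeated angle in manifest")
  dir <- dirname(manifest)
  secs <- lapply(seq_len(nrow(entries)), function(i) {
    read_section_file(file.path(dir, entries$file[i]),
                      entries$angle_deg[i] * pi / 180)
  })
  section_set(secs, meta = list(manifest = manifest))
}

#' Write a section set as CSV files plus a manifest
#'
#' @param ss A [section_set()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix for the per-section CSVs.
#' @return Invisibly, the manifest path.
#' @export
write_section_set <- function(ss, dir, prefix = "section") {
  stopifnot(inherits(ss, "section_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ang_deg <- section_angles(ss) * 180 / pi
  files <- sprintf("%s_%03ddeg.csv", prefix, round(ang_deg))
  for (i in seq_along(files)) {
    s <- ss$sections[[i]]
    utils::write.table(data.frame(x = s$xs, z = s$zs),
                       file.path(dir, files[i]), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    data.frame(file = files, angle_deg = ang_deg),
    manifest, auto_unbox = FALSE, digits = NA)
  invisible(manifest)
}

#' Coefficient-matrix container
#'
#' On-disk representation of the per-section coefficient matrix A or the
#' bivariate surface coefficient matrix B.
#'
#' @param values Numeric matrix.
#' @param kind `"A"` or `"B"`.
#' @return An object of class `coeff_matrix`.
#' @export
coeff_matrix <- function(values, kind = c("B", "A")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop_input("coefficient matrix entries must be finite numbers")
  }
  structure(list(values = values, kind = kind), class = "coeff_matrix")
}

#' Write a coefficient matrix to CSV
#'
#' The file has a one-line header `# kind=<A|B> rows=<r> cols=<c>` followed
#' by one CSV row per matrix row, printed with full precision so that
#' [read_coeff_matrix()] round-trips bit-identically.
#'
#' @param m A [coeff_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coeff_matrix <- function(m, path) {
  stopifnot(inherits(m, "coeff_matrix"))
  v <- m$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s rows=%d cols=%d", m$kind, nrow(v), ncol(v)), con)
  for (i in seq_len(nrow(v))) {
    writeLines(paste(sprintf("%.17g", v[i, ]), collapse = ","), con)
  }
  invisible(path)
}

#' Read a coefficient matrix written by [write_coeff_matrix()]
#'
#' @param path Path to the CSV file.
#' @return A [coeff_matrix()].
#' @export
read_coeff_matrix <- function(path) {
  if (!file.exists(path)) stop_input("coefficient file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- regmatches(lines[1],
                    regexec("^# kind=([AB]) rows=(\\d+) cols=(\\d+)$", lines[1]))[[1]]
  if (length(hdr) != 4L) stop_input("malformed coefficient-file header in ", path)
  rows <- as.integer(hdr[3]); cols <- as.integer(hdr[4])
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  if (length(body) != rows) stop_input("row count mismatch in ", path)
  vals <- t(vapply(strsplit(body, ","), function(r) as.numeric(r), numeric(cols)))
  vals <- matrix(as.numeric(vals), nrow = rows, ncol = cols)
  if (!all(is.finite(vals))) stop_input("non-numeric cell in ", path)
  coeff_matrix(vals, kind = hdr[2])
}
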