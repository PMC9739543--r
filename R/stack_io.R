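#' Image stacks
#'
#' An `image_stack` is a 3D grayscale volume with axis order `(z, y, x)`,
#' 1-based indices and non-negative voxel intensities. `stack$voxels[z, , ]`
#' is the y-by-x matrix of optical section `z`. The dtype records the storage
#' scale: `"uint8"` (0..255), `"uint16"` (0..65535) or `"float"` (0..1).
#'
#' @param voxels 3D numeric array `(z, y, x)`, or a single y-by-x matrix
#'   which is treated as a depth-1 stack.
#' @param dtype One of `"uint8"`, `"uint16"`, `"float"`; guessed from the
#'   value range when missing.
#' @param source Provenance string (file path or generator description).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, dtype = NULL, source = NA_character_) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  assert_that(is.array(voxels) && length(dim(voxels)) == 3L,
              "voxels must be a (z, y, x) array")
  assert_that(all(dim(voxels) >= 1L), "all stack dimensions must be >= 1")
  assert_that(all(is.finite(voxels)) && min(voxels) >= 0,
              "voxel intensities must be finite and non-negative")
  if (is.null(dtype)) {
    mx <- max(voxels)
    dtype <- if (mx <= 1 && any(voxels %% 1 != 0)) "float"
             else if (mx <= 255) "uint8" else "uint16"
  }
  dtype <- match.arg(dtype, c("uint8", "uint16", "float"))
  structure(list(voxels = voxels, dtype = dtype, source = source),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d x %d (z, y, x), dtype %s, source: %s\n",
              d[1], d[2], d[3], x$dtype, x$source))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Maximum representable intensity of a stack's dtype
#' @param stack An `image_stack`.
#' @return 255, 65535 or 1.
#' @export
dtype_max <- function(stack) {
  switch(stack$dtype, uint8 = 255, uint16 = 65535, float = 1)
}

#' Binary label masks
#'
#' A `label_mask` is a 3D binary volume aligned to an [image_stack()]:
#' same `(z, y, x)` shape, values in \{0, 1\}. Used both for ground-truth
#' annotations and for segmentation output.
#'
#' @param voxels 3D array (or matrix, treated as depth 1) of 0/1 or logical.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(voxels) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  assert_that(is.array(voxels) && length(dim(voxels)) == 3L,
              "mask must be a (z, y, x) array")
  v <- voxels * 1
  assert_that(all(v %in% c(0, 1)), "mask values must be 0 or 1")
  structure(list(voxels = v), class = "label_mask")
}

#' @export
dim.label_mask <- function(x) dim(x$voxels)

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_mask> %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

#' Read a multi-page TIFF into an image stack
#'
#' Pages become z-slices in file order. Integer TIFFs (8/16-bit) are read
#' bit-exactly; float TIFFs are kept on their native 0..1 scale.
#'
#' @param path Path to a single- or multi-page grayscale TIFF.
#' @return An [image_stack()].
#' @export
read_stack <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop(sprintf(
                      "cannot read '%s' as TIFF: %s", path, conditionMessage(e)),
                      call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  assert_that(length(pages) >= 1L, "TIFF has no pages: %s", path)
  for (p in pages) {
    assert_that(length(dim(p)) == 2L,
                "only single-channel grayscale TIFFs are supported: %s", path)
  }
  d1 <- dim(pages[[1]])
  same <- vapply(pages, function(p) identical(dim(p), d1), logical(1))
  assert_that(all(same), "pages of '%s' have inconsistent dimensions", path)
  vox <- array(0, c(length(pages), d1))
  for (i in seq_along(pages)) vox[i, , ] <- pages[[i]]
  bits <- attr(pages[[1]], "bits.per.sample")
  dtype <- if (any(vox %% 1 != 0)) "float"
           else if (!is.null(bits) && bits == 8) "uint8"
           else if (!is.null(bits) && bits == 16) "uint16"
           else if (max(vox) <= 255) "uint8" else "uint16"
  image_stack(vox, dtype = dtype, source = path)
}

#' Write an image stack as a multi-page TIFF
#'
#' Integer dtypes round-trip bit-exactly through [read_stack()].
#'
#' @param stack An [image_stack()] (or [label_mask()], written as 8-bit 0/1).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (inherits(stack, "label_mask")) {
    stack <- image_stack(stack$voxels, dtype = "uint8", source = "mask")
  }
  assert_that(inherits(stack, "image_stack"), "stack must be an image_stack")
  mx <- dtype_max(stack)
  bits <- switch(stack$dtype, uint8 = 8L, uint16 = 16L, float = 32L)
  d <- dim(stack$voxels)
  pages <- lapply(seq_len(d[1]), function(z) stack$voxels[z, , ] / mx)
  ok <- tryCatch({
    tiff::writeTIFF(pages, where = path, bits.per.sample = bits)
    TRUE
  }, error = function(e) FALSE)
  assert_that(ok, "cannot write TIFF to '%s'", path)
  invisible(path)
}

#' Read a binary mask from a TIFF
#'
#' Any strictly positive intensity is foreground, so masks stored as 0/1 or
#' 0/255 both load correctly.
#'
#' @param path TIFF path.
#' @return A [label_mask()].
#' @export
read_mask <- function(path) {
  s <- read_stack(path)
  label_mask((s$voxels > 0) * 1)
}

#' Rasterize per-slice polygon ROIs into a truth mask
#'
#' A mask voxel is set iff its pixel center `(y, x)` (integer coordinates)
#' lies inside, or exactly on the boundary of, a polygon annotated on that
#' slice. Slices without ROIs stay zero. ROIs extending past the image are
#' clipped with a warning.
#'
#' @param rois A [roi_set()].
#' @param shape Integer vector `c(z, y, x)`.
#' @return A [label_mask()] of the given shape.
#' @export
rasterize_rois <- function(rois, shape) {
  assert_that(inherits(rois, "roi_set"), "rois must be a roi_set")
  assert_that(length(shape) == 3L && all(shape >= 1), "shape must be c(z, y, x)")
  mask <- array(0, shape)
  for (rec in rois$records) {
    assert_that(rec$z >= 1 && rec$z <= shape[1],
                "ROI slice index %d outside stack depth %d", rec$z, shape[1])
    filled <- fill_polygon(rec$x, rec$y, ny = shape[2], nx = shape[3])
    if (attr(filled, "clipped")) {
      warning(sprintf("ROI on slice %d extends outside the image; clipped", rec$z),
              call. = FALSE)
    }
    mask[rec$z, , ] <- pmax(mask[rec$z, , ], filled)
  }
  label_mask(mask)
}

# Fill a closed polygon (vertices in pixel-center coordinates, 1-based) on an
# ny x nx raster; boundary pixels count as inside.  Interior via even-odd
# scanline crossings with a half-open vertex rule; lattice points lying
# exactly on an edge are added in a second pass.
fill_polygon <- function(xs, ys, ny, nx) {
  assert_that(length(xs) >= 3 && length(xs) == length(ys),
              "polygon needs >= 3 vertices")
  out <- matrix(0, ny, nx)
  clipped <- any(xs < 1 | xs > nx | ys < 1 | ys > ny)
  n <- length(xs)
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  eps <- 1e-9

  y_lo <- max(1L, ceiling(min(ys) - eps))
  y_hi <- min(ny, floor(max(ys) + eps))
  for (yy in seq_len(max(0L, y_hi - y_lo + 1L)) + y_lo - 1L) {
    cross <- numeric(0)
    for (e in seq_len(n)) {
      ya <- ys[e]; yb <- y2[e]
      if (ya == yb) next
      # half-open: count the edge on [min(ya,yb), max(ya,yb))
      if ((yy >= min(ya, yb) - eps) && (yy < max(ya, yb) - eps)) {
        t <- (yy - ya) / (yb - ya)
        cross <- c(cross, xs[e] + t * (x2[e] - xs[e]))
      }
    }
    cross <- sort(cross)
    k <- 1L
    while (k + 1L <= length(cross)) {
      a <- cross[k]; b <- cross[k + 1L]
      xa <- max(1L, ceiling(a - eps)); xb <- min(nx, floor(b + eps))
      if (xb >= xa) out[yy, xa:xb] <- 1
      k <- k + 2L
    }
  }

  # boundary pass: integer lattice points exactly on an edge are inside
  for (e in seq_len(n)) {
    xa <- xs[e]; ya <- ys[e]; xb <- x2[e]; yb <- y2[e]
    dx <- xb - xa; dy <- yb - ya
    len2 <- dx * dx + dy * dy
    if (len2 < eps) next
    mark <- function(px, py) {
      if (px >= 1 && px <= nx && py >= 1 && py <= ny) out[py, px] <<- 1
    }
    if (abs(dy) > eps) {
      for (yy in seq(max(1L, ceiling(min(ya, yb) - eps)),
                     min(ny, floor(max(ya, yb) + eps)))) {
        t <- (yy - ya) / dy
        if (t < -eps || t > 1 + eps) next
        px <- xa + t * dx
        if (abs(px - round(px)) < 1e-7) mark(as.integer(round(px)), yy)
      }
    }
    if (abs(dx) > eps) {
      for (xx in seq(max(1L, ceiling(min(xa, xb) - eps)),
                     min(nx, floor(max(xa, xb) + eps)))) {
        t <- (xx - xa) / dx
        if (t < -eps || t > 1 + eps) next
        py <- ya + t * dy
        if (abs(py - round(py)) < 1e-7) mark(xx, as.integer(round(py)))
      }
    }
  }
  attr(out, "clipped") <- clipped
  out
}
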