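#' Per-slice morphological opening of a binary stack
#'
#' Erosion then dilation with a disc structuring element, applied to each
#' z-slice in 2D (the segmentation itself is produced slice-by-slice).
#' Removes structures smaller than the disc, e.g. speckle.
#'
#' @param binary_stack [label_mask()] or 3D binary array.
#' @param radius Disc radius in pixels (>= 0; 0 is a no-op).
#' @return Object of the same type as the input.
#' @export
open_binary <- function(binary_stack, radius = 1L) {
  assert_that(radius >= 0, "radius must be >= 0")
  was_mask <- inherits(binary_stack, "label_mask")
  vox <- if (was_mask) binary_stack$voxels else binary_stack * 1
  if (radius > 0 && sum(vox) > 0) {
    kern <- disc_kernel(radius)
    for (z in seq_len(dim(vox)[1])) {
      sl <- vox[z, , ]
      if (sum(sl) == 0) next
      vox[z, , ] <- EBImage::dilate(EBImage::erode(sl, kern), kern)
    }
  }
  if (was_mask) label_mask(vox) else vox
}

# disc structuring element: offsets with dy^2 + dx^2 <= r^2
disc_kernel <- function(radius) {
  r <- as.integer(radius)
  side <- 2L * r + 1L
  d <- outer((-r:r)^2, (-r:r)^2, "+")
  matrix(as.numeric(d <= radius^2), side, side)
}

#' Assemble 3D objects from a binary stack
#'
#' Labels 3D connected components (26- or 6-neighborhood) and measures each
#' one: voxel count, occupied z-slices, and the per-slice 2D centroid (mean
#' pixel position of the component's voxels on each slice).
#'
#' @param binary_stack [label_mask()] or 3D binary array `(z, y, x)`.
#' @param connectivity 26 (default) or 6.
#' @return List of `bleb_object` records (fields `id`, `voxel_count`,
#'   `span`, `z_slices`, `centroids` (z, cy, cx matrix), `bbox`, `coords`);
#'   the stack dimensions are attached as attribute `dim`.
#' @export
assemble_objects <- function(binary_stack, connectivity = 26L) {
  vox <- if (inherits(binary_stack, "label_mask")) binary_stack$voxels
         else binary_stack
  d <- dim(vox)
  labs <- label_components_3d(as.logical(vox), as.integer(d),
                              as.integer(connectivity))
  objs <- list()
  if (any(labs > 0)) {
    coords <- which(array(labs, d) > 0, arr.ind = TRUE)
    lv <- labs[labs > 0]
    ord <- order(lv)
    coords <- coords[ord, , drop = FALSE]
    lv <- lv[ord]
    idx_by <- split(seq_len(nrow(coords)), lv)
    objs <- lapply(seq_along(idx_by), function(i) {
      co <- coords[idx_by[[i]], , drop = FALSE]
      colnames(co) <- c("z", "y", "x")
      zs <- sort(unique(co[, "z"]))
      cen <- t(vapply(zs, function(z) {
        sel <- co[, "z"] == z
        c(z, mean(co[sel, "y"]), mean(co[sel, "x"]))
      }, numeric(3)))
      colnames(cen) <- c("z", "cy", "cx")
      structure(list(id = i, voxel_count = nrow(co), span = length(zs),
                     z_slices = zs, centroids = cen,
                     bbox = apply(co, 2, range), coords = co),
                class = "bleb_object")
    })
  }
  attr(objs, "stack_dim") <- d
  objs
}

#' @export
print.bleb_object <- function(x, ...) {
  cat(sprintf("<bleb_object #%d> %d voxels over %d slice(s) [z %d..%d]\n",
              x$id, x$voxel_count, x$span, min(x$z_slices), max(x$z_slices)))
  invisible(x)
}

keep_objects <- function(objects, keep) {
  out <- objects[keep]
  attr(out, "stack_dim") <- attr(objects, "stack_dim")
  out
}

#' Slice-thickness filter
#'
#' A real bleb must persist through a minimum number of z-slices; objects
#' spanning fewer are discarded. Default minimum: 5 slices.
#'
#' @param objects Output of [assemble_objects()].
#' @param min_slices Minimum slice span (kept iff `span >= min_slices`).
#' @return Filtered object list.
#' @export
filter_slice_thickness <- function(objects, min_slices = 5L) {
  assert_that(min_slices >= 1, "min_slices must be >= 1")
  keep_objects(objects, vapply(objects, function(o) o$span >= min_slices,
                               logical(1)))
}

#' Travelling-vector elimination
#'
#' Bright axonal segments appear to shift through the z-stack as neighbouring
#' segments come into focus, whereas blebs stay put. The Euclidean distance
#' between an object's centroids on consecutive occupied slices is measured;
#' if any such displacement exceeds `max_shift` the whole object is
#' eliminated. Default threshold: 15 px (a 15 px shift is kept, 16 px is
#' removed).
#'
#' @param objects Output of [assemble_objects()].
#' @param max_shift Largest tolerated consecutive-slice centroid shift (px).
#' @return Filtered object list.
#' @export
filter_travelling <- function(objects, max_shift = 15) {
  assert_that(max_shift >= 0, "max_shift must be >= 0")
  keep_objects(objects, vapply(objects, function(o) {
    max_centroid_step(o) <= max_shift
  }, logical(1)))
}

#' Largest consecutive-slice centroid displacement of an object
#' @param object A `bleb_object`.
#' @return Displacement in px (0 for single-slice objects).
#' @export
max_centroid_step <- function(object) {
  cen <- object$centroids
  if (nrow(cen) < 2) return(0)
  max(sqrt(diff(cen[, "cy"])^2 + diff(cen[, "cx"])^2))
}

#' Size filter
#'
#' Discards small objects; applied after morphological opening in the full
#' pipeline. Default: objects with fewer than 100 voxels are eliminated
#' (exactly 100 is kept).
#'
#' @param objects Output of [assemble_objects()].
#' @param min_size Minimum 3D voxel count (kept iff `voxel_count >= min_size`).
#' @return Filtered object list.
#' @export
filter_size <- function(objects, min_size = 100L) {
  assert_that(min_size >= 1, "min_size must be >= 1")
  keep_objects(objects, vapply(objects, function(o) o$voxel_count >= min_size,
                               logical(1)))
}

#' Paint a set of objects back into a binary stack
#'
#' @param objects Object list carrying a `dim` attribute.
#' @param dims Stack dimensions; defaults to the attribute.
#' @return 3D binary array.
#' @export
objects_to_mask <- function(objects, dims = attr(objects, "stack_dim")) {
  out <- array(0, dims)
  for (o in objects) {
    lin <- o$coords[, "z"] + (o$coords[, "y"] - 1) * dims[1] +
      (o$coords[, "x"] - 1) * dims[1] * dims[2]
    out[lin] <- 1
  }
  out
}

#' Count blebs in a binary segmentation
#'
#' The full 3D post-processing pipeline, in a fixed order:
#' (1) assemble 3D connected components and drop those spanning fewer than
#' `min_slices` z-slices; (2) eliminate objects whose per-slice centroid
#' shifts more than `max_shift` px between consecutive slices (travelling
#' bright segments); (3) apply a per-slice morphological opening, re-assemble,
#' and drop objects smaller than `min_size` voxels. The surviving objects are
#' the counted blebs.
#'
#' @param binary_stack [label_mask()] or 3D binary array from the model (or
#'   any other source, e.g. a ground-truth mask).
#' @param config Post-processing configuration (see
#'   [default_config()]`$postprocess`); missing entries take defaults.
#' @return A `bleb_catalog`: `objects` (survivors), `n` (total count),
#'   `eliminated` (per-filter elimination counts), `config`, `dim`.
#' @export
count_blebs <- function(binary_stack, config = list()) {
  cfg <- utils::modifyList(default_config()$postprocess, config)
  objs <- assemble_objects(binary_stack, cfg$connectivity)
  n0 <- length(objs)
  o1 <- filter_slice_thickness(objs, cfg$min_slices)
  o2 <- filter_travelling(o1, cfg$max_shift)
  m2 <- objects_to_mask(o2, attr(objs, "stack_dim"))
  m3 <- open_binary(m2, cfg$opening_radius)
  o3 <- assemble_objects(m3, cfg$connectivity)
  o4 <- filter_size(o3, cfg$min_size)
  eliminated <- c(slice_thickness = n0 - length(o1),
                  travelling = length(o1) - length(o2),
                  opening_and_size = length(o3) - length(o4))
  bk_log("count_blebs: %d objects -> %d survivors (eliminated: %d thin, %d travelling, %d small)",
         n0, length(o4), eliminated[1], eliminated[2], eliminated[3])
  structure(list(objects = o4, n = length(o4), eliminated = eliminated,
                 config = cfg, dim = attr(objs, "stack_dim")),
            class = "bleb_catalog")
}

#' @export
print.bleb_catalog <- function(x, ...) {
  cat(sprintf("<bleb_catalog> %d bleb(s); eliminated: %s\n", x$n,
              paste(sprintf("%s %d", names(x$eliminated), x$eliminated),
                    collapse = ", ")))
  invisible(x)
}

#' Export a bleb catalog
#'
#' Writes `catalog.csv` (one row per bleb: id, span, voxel count, z range,
#' start/end centroid, largest centroid step), `provenance.json` (the
#' thresholds used and per-filter elimination counts) and `survivors.tif`
#' (binary mask of the surviving objects).
#'
#' @param catalog A `bleb_catalog`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_catalog <- function(catalog, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- catalog_df(catalog)
  utils::write.csv(df, file.path(dir, "catalog.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_blebs = catalog$n, eliminated = as.list(catalog$eliminated),
         config = catalog$config),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  write_stack(label_mask(objects_to_mask(catalog$objects, catalog$dim)),
              file.path(dir, "survivors.tif"))
  invisible(dir)
}

#' One-row-per-bleb data frame view of a catalog
#' @param catalog A `bleb_catalog`.
#' @return data.frame.
#' @export
catalog_df <- function(catalog) {
  if (length(catalog$objects) == 0) {
    return(data.frame(id = integer(), slice_span = integer(),
                      voxel_count = integer(), z0 = integer(), z1 = integer(),
                      cy = numeric(), cx = numeric(), max_step = numeric()))
  }
  do.call(rbind, lapply(catalog$objects, function(o) {
    data.frame(id = o$id, slice_span = o$span, voxel_count = o$voxel_count,
               z0 = min(o$z_slices), z1 = max(o$z_slices),
               cy = mean(o$centroids[, "cy"]), cx = mean(o$centroids[, "cx"]),
               max_step = max_centroid_step(o))
  }))
}
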