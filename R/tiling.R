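#' Tiling configuration
#'
#' Fixed-size square tiles with fractional overlap. Defaults: 320 px tiles
#' with 5% overlap, i.e. a stride of `floor(320 * 0.95) = 304` px.
#'
#' @param tile_side Tile side in pixels.
#' @param overlap_fraction Overlap as a fraction of the tile side, in `[0, 1)`.
#' @return A `tiling_config` list.
#' @export
tiling_config <- function(tile_side = 320L, overlap_fraction = 0.05) {
  assert_that(tile_side >= 1, "tile_side must be >= 1")
  assert_that(overlap_fraction >= 0 && overlap_fraction < 1,
              "overlap_fraction must be in [0, 1)")
  structure(list(tile_side = as.integer(tile_side),
                 overlap_fraction = overlap_fraction),
            class = "tiling_config")
}

#' Plan a tile grid over a 2D slice
#'
#' Tile origins advance by `stride = floor(side * (1 - overlap))` per axis;
#' the last origin per axis is clamped so the final tile abuts the border
#' (duplicates removed). Slices smaller than the tile side are planned over
#' a zero-padded canvas, so every source pixel is always covered by at least
#' one tile.
#'
#' @param slice_shape `c(y, x)` of the slice.
#' @param config A [tiling_config()].
#' @return A `tile_grid`: origins matrix (`y`, `x`, 1-based, one row per
#'   tile), tile side, stride, source and padded shapes.
#' @export
plan_tiles <- function(slice_shape, config = tiling_config()) {
  assert_that(length(slice_shape) == 2L && all(slice_shape >= 1),
              "slice_shape must be c(y, x), both >= 1")
  side <- config$tile_side
  stride <- max(1L, as.integer(floor(side * (1 - config$overlap_fraction))))
  padded <- pmax(as.integer(slice_shape), side)
  axis_origins <- function(dim) {
    last <- dim - side + 1L
    os <- seq.int(1L, last, by = stride)
    sort(unique(c(os, last)))
  }
  oy <- axis_origins(padded[1])
  ox <- axis_origins(padded[2])
  origins <- as.matrix(expand.grid(y = oy, x = ox))
  structure(list(origins = origins, side = side, stride = stride,
                 slice_shape = as.integer(slice_shape), padded_shape = padded),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d tiles of %dx%d (stride %d) over %dx%d slice\n",
              nrow(x$origins), x$side, x$side, x$stride,
              x$slice_shape[1], x$slice_shape[2]))
  invisible(x)
}

#' Extract the tiles of a planned grid
#'
#' @param slice_image 2D matrix matching the grid's source shape.
#' @param grid A `tile_grid` from [plan_tiles()].
#' @return List of side-by-side matrices; zero in padded regions.
#' @export
extract_tiles <- function(slice_image, grid) {
  assert_that(identical(dim(slice_image), as.integer(grid$slice_shape)) ||
                identical(dim(slice_image), grid$slice_shape),
              "slice shape does not match the planned grid")
  canvas <- matrix(0, grid$padded_shape[1], grid$padded_shape[2])
  canvas[seq_len(nrow(slice_image)), seq_len(ncol(slice_image))] <- slice_image
  side <- grid$side
  lapply(seq_len(nrow(grid$origins)), function(i) {
    oy <- grid$origins[i, "y"]; ox <- grid$origins[i, "x"]
    canvas[oy:(oy + side - 1L), ox:(ox + side - 1L)]
  })
}

#' Stitch per-tile maps back into a slice map
#'
#' Overlapping pixels take the per-pixel maximum over all covering tiles
#' (seam-robust and sensitivity-favouring); padded margins are cropped away.
#'
#' @param tile_maps List of side-by-side matrices, one per grid tile.
#' @param grid The `tile_grid` the maps were predicted on.
#' @return Matrix of the grid's source slice shape.
#' @export
stitch_tiles <- function(tile_maps, grid) {
  assert_that(length(tile_maps) == nrow(grid$origins),
              "need exactly one map per tile (%d expected, %d given)",
              nrow(grid$origins), length(tile_maps))
  side <- grid$side
  canvas <- matrix(-Inf, grid$padded_shape[1], grid$padded_shape[2])
  for (i in seq_along(tile_maps)) {
    m <- tile_maps[[i]]
    assert_that(identical(dim(m), c(side, side)) ||
                  identical(dim(m), as.integer(c(side, side))),
                "tile map %d has the wrong shape", i)
    oy <- grid$origins[i, "y"]; ox <- grid$origins[i, "x"]
    ys <- oy:(oy + side - 1L); xs <- ox:(ox + side - 1L)
    canvas[ys, xs] <- pmax(canvas[ys, xs], m)
  }
  canvas[seq_len(grid$slice_shape[1]), seq_len(grid$slice_shape[2]), drop = FALSE]
}
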