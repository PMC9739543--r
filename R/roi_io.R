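#' ROI annotation sets
#'
#' A `roi_set` holds per-slice closed polygon annotations: each record has a
#' 1-based slice index `z`, vertex vectors `x` and `y` in pixel-center
#' coordinates, and an optional `label`. A bleb annotated on several slices
#' appears as several records; 3D identity is recovered later by object
#' assembly.
#'
#' @param records List of records, each `list(z =, x =, y =, label =)`.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(records = list()) {
  for (rec in records) {
    assert_that(length(rec$x) >= 3 && length(rec$x) == length(rec$y),
                "each ROI polygon needs >= 3 vertices")
    assert_that(is.numeric(rec$z) && rec$z >= 1, "ROI slice index must be >= 1")
  }
  structure(list(records = records), class = "roi_set")
}

#' @export
length.roi_set <- function(x) length(x$records)

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROI record(s)\n", length(x$records)))
  invisible(x)
}

# ---- ImageJ .roi binary format -------------------------------------------
# 64-byte header ("Iout", version, type, bounds, n, stack position at byte
# 56), then n shorts of x offsets and n shorts of y offsets relative to the
# top-left bound.  Coordinates on disk are 0-based; in memory blebkit uses
# 1-based pixel centers, converted at this boundary.

ROI_TYPE_POLYGON <- 0L
ROI_TYPE_RECT <- 1L
ROI_TYPE_FREEHAND <- 7L
ROI_TYPE_TRACED <- 8L

encode_roi <- function(rec) {
  x0 <- as.integer(round(rec$x)) - 1L   # to 0-based
  y0 <- as.integer(round(rec$y)) - 1L
  left <- min(x0); top <- min(y0)
  right <- max(x0) + 1L; bottom <- max(y0) + 1L
  n <- length(x0)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(charToRaw("Iout"), con)
  writeBin(c(228L), con, size = 2, endian = "big")            # version
  writeBin(as.raw(c(ROI_TYPE_POLYGON, 0L)), con)              # type, pad
  writeBin(as.integer(c(top, left, bottom, right, n)), con,
           size = 2, endian = "big")
  writeBin(raw(38), con)                                      # bytes 18..55
  writeBin(as.integer(rec$z), con, size = 4, endian = "big")  # position
  writeBin(0L, con, size = 4, endian = "big")                 # header2 offset
  writeBin(x0 - left, con, size = 2, endian = "big")
  writeBin(y0 - top, con, size = 2, endian = "big")
  rawConnectionValue(con)
}

decode_roi <- function(bytes, label = NA_character_) {
  assert_that(length(bytes) >= 64, "ROI record too short")
  assert_that(identical(rawToChar(bytes[1:4]), "Iout"),
              "not an ImageJ ROI record (bad magic)")
  rd_short <- function(off) {
    v <- as.integer(bytes[off + 1L]) * 256L + as.integer(bytes[off + 2L])
    if (v >= 32768L) v - 65536L else v
  }
  rd_int <- function(off) {
    as.integer(sum(as.numeric(bytes[off + 1:4]) * c(16777216, 65536, 256, 1)))
  }
  type <- as.integer(bytes[7])
  top <- rd_short(8); left <- rd_short(10)
  bottom <- rd_short(12); right <- rd_short(14)
  n <- rd_short(16)
  pos <- rd_int(56)
  z <- as.integer(if (pos > 0) pos else 1L)
  if (type == ROI_TYPE_RECT) {
    # rectangle pixels span x in [left, right-1], y in [top, bottom-1]
    # (0-based); as 1-based pixel-center corners:
    return(list(z = z, x = c(left + 1L, right, right, left + 1L),
                y = c(top + 1L, top + 1L, bottom, bottom), label = label))
  }
  if (!type %in% c(ROI_TYPE_POLYGON, ROI_TYPE_FREEHAND, ROI_TYPE_TRACED)) {
    stop(sprintf("unsupported ROI type %d (no polygon representation)", type),
         call. = FALSE)
  }
  assert_that(n >= 3, "polygon ROI with fewer than 3 vertices")
  assert_that(length(bytes) >= 64 + 4 * n, "truncated polygon ROI record")
  xs <- integer(n); ys <- integer(n)
  for (i in seq_len(n)) {
    xs[i] <- rd_short(64L + 2L * (i - 1L)) + left
    ys[i] <- rd_short(64L + 2L * n + 2L * (i - 1L)) + top
  }
  list(z = z, x = xs + 1L, y = ys + 1L, label = label)
}

#' Read ImageJ ROI annotations
#'
#' Accepts a single `.roi` file, a `.zip` container of ROIs (the RoiSet
#' format), or a directory of `.roi` files. Rectangle ROIs become 4-vertex
#' polygons; polygon, freehand and traced ROIs keep their vertex lists.
#'
#' @param path `.roi` file, `.zip` RoiSet, or directory.
#' @return A [roi_set()].
#' @export
read_rois <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  files <- NULL
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.roi$", full.names = TRUE)
  } else if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    head4 <- readBin(path, "raw", 4)
    if (identical(head4, as.raw(c(0x50, 0x4b, 0x05, 0x06)))) {
      return(roi_set())  # bare end-of-directory record: zero entries
    }
    ex <- file.path(tempfile("roiset"), "x")
    dir.create(ex, recursive = TRUE)
    utils::unzip(path, exdir = ex)
    files <- list.files(ex, pattern = "\\.roi$", full.names = TRUE,
                        recursive = TRUE)
  } else {
    files <- path
  }
  files <- sort(files)
  recs <- lapply(files, function(f) {
    decode_roi(readBin(f, "raw", file.size(f)),
               label = sub("\\.roi$", "", basename(f)))
  })
  roi_set(recs)
}

#' Write ROI annotations as an ImageJ-compatible container
#'
#' Writes a `.zip` of `.roi` records (paths ending in `.zip`) or a single
#' `.roi` file (single-record sets only).
#'
#' @param rois A [roi_set()].
#' @param path Destination (`.zip` or `.roi`).
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  assert_that(inherits(rois, "roi_set"), "rois must be a roi_set")
  if (grepl("\\.roi$", path, ignore.case = TRUE)) {
    assert_that(length(rois) == 1L, "a .roi file holds exactly one ROI")
    writeBin(encode_roi(rois$records[[1]]), path)
    return(invisible(path))
  }
  entries <- list()
  for (i in seq_along(rois$records)) {
    rec <- rois$records[[i]]
    nm <- if (!is.null(rec$label) && !is.na(rec$label)) rec$label
          else sprintf("%04d-%04d", rec$z, i)
    entries[[paste0(nm, ".roi")]] <- encode_roi(rec)
  }
  write_zip_stored(entries, path)
  invisible(path)
}

# ---- minimal ZIP writer (store method, no compression) -------------------
# Enough of PKZIP for ImageJ RoiSet containers: local file headers, central
# directory, end record.  CRC-32 comes from the compiled helper.

write_zip_stored <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) {
    v <- as.numeric(v)
    lo <- v %% 65536; hi <- (v - lo) / 65536
    w16(lo); w16(hi)
  }
  offsets <- numeric(length(entries))
  names_v <- names(entries)
  crcs <- numeric(length(entries))
  pos <- 0
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    nm <- charToRaw(names_v[i])
    crcs[i] <- crc32_raw(data)
    offsets[i] <- pos
    w32(0x04034b50); w16(20); w16(0); w16(0); w16(0); w16(0x21)
    w32(crcs[i]); w32(length(data)); w32(length(data))
    w16(length(nm)); w16(0)
    writeBin(nm, con); writeBin(data, con)
    pos <- pos + 30 + length(nm) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    nm <- charToRaw(names_v[i])
    w32(0x02014b50); w16(20); w16(20); w16(0); w16(0); w16(0); w16(0x21)
    w32(crcs[i]); w32(length(data)); w32(length(data))
    w16(length(nm)); w16(0); w16(0); w16(0); w16(0)
    w32(0); w32(offsets[i])
    writeBin(nm, con)
    pos <- pos + 46 + length(nm)
  }
  w32(0x06054b50); w16(0); w16(0)
  w16(length(entries)); w16(length(entries))
  w32(pos - cd_start); w32(cd_start); w16(0)
  invisible(path)
}
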