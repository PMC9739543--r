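options(blebkit.quiet = TRUE)

# ---- brute-force oracles, kept deliberately naive and independent of the
# ---- implementation paths they check

# 3D connected-component labeling by queue-based flood fill
flood_fill_label <- function(vox, connectivity = 26) {
  d <- dim(vox)
  lab <- array(0L, d)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6) {
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  }
  cur <- 0L
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (vox[z, y, x] == 0 || lab[z, y, x] != 0) next
    cur <- cur + 1L
    queue <- list(c(z, y, x))
    lab[z, y, x] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        q <- p + c(offs$dz[k], offs$dy[k], offs$dx[k])
        if (any(q < 1) || any(q > d)) next
        if (vox[q[1], q[2], q[3]] != 0 && lab[q[1], q[2], q[3]] == 0) {
          lab[q[1], q[2], q[3]] <- cur
          queue <- c(queue, list(q))
        }
      }
    }
  }
  lab
}

# even-odd ray casting with explicit on-segment test, one pixel at a time
point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  for (e in seq_len(n)) {  # boundary counts as inside
    ax <- xs[e]; ay <- ys[e]; bx <- x2[e]; by <- y2[e]
    len2 <- (bx - ax)^2 + (by - ay)^2
    if (len2 == 0) next
    t <- ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / len2
    t <- min(max(t, 0), 1)
    if ((px - (ax + t * (bx - ax)))^2 + (py - (ay + t * (by - ay)))^2 < 1e-14) {
      return(TRUE)
    }
  }
  inside <- FALSE
  for (e in seq_len(n)) {
    ay <- ys[e]; by <- y2[e]
    if ((ay > py) != (by > py)) {
      xint <- xs[e] + (py - ay) / (by - ay) * (x2[e] - xs[e])
      if (px < xint) inside <- !inside
    }
  }
  inside
}

# erosion/dilation by direct neighborhood min/max scans
brute_morph <- function(m, offsets, op = c("erode", "dilate")) {
  op <- match.arg(op)
  d <- dim(m)
  out <- matrix(0, d[1], d[2])
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    vals <- numeric(0)
    for (k in seq_len(nrow(offsets))) {
      yy <- y + offsets[k, 1]; xx <- x + offsets[k, 2]
      v <- if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2]) 0 else m[yy, xx]
      vals <- c(vals, v)
    }
    out[y, x] <- if (op == "erode") min(vals) else max(vals)
  }
  out
}

disc_offsets <- function(radius) {
  g <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  as.matrix(g[g$dy^2 + g$dx^2 <= radius^2, ])
}

# construct a synthetic bleb_object record directly (unit-testing filters
# without going through a mask)
make_object <- function(id, coords, dims) {
  colnames(coords) <- c("z", "y", "x")
  zs <- sort(unique(coords[, "z"]))
  cen <- t(vapply(zs, function(z) {
    sel <- coords[, "z"] == z
    c(z, mean(coords[sel, "y"]), mean(coords[sel, "x"]))
  }, numeric(3)))
  colnames(cen) <- c("z", "cy", "cx")
  structure(list(id = as.integer(id), voxel_count = nrow(coords),
                 span = length(zs),
                 z_slices = zs, centroids = cen,
                 bbox = apply(coords, 2, range), coords = coords),
            class = "bleb_object")
}

object_list <- function(objects, dims) {
  attr(objects, "stack_dim") <- dims
  objects
}

# axis-aligned solid box as coordinate matrix
box_coords <- function(z0, z1, y0, y1, x0, x1) {
  as.matrix(expand.grid(z = z0:z1, y = y0:y1, x = x0:x1))
}

# a stack of stacked discs: one disc of radius r per slice z0..z1 whose
# center moves by (dy, dx) per slice; returns a binary array
disc_track_mask <- function(dims, z0, z1, y_start, x_start, r, dy = 0, dx = 0) {
  vox <- array(0, dims)
  for (t in 0:(z1 - z0)) {
    cy <- y_start + t * dy; cx <- x_start + t * dx
    for (y in floor(cy - r):ceiling(cy + r)) {
      for (x in floor(cx - r):ceiling(cx + r)) {
        if ((y - cy)^2 + (x - cx)^2 <= r^2 &&
            y >= 1 && y <= dims[2] && x >= 1 && x <= dims[3]) {
          vox[z0 + t, y, x] <- 1
        }
      }
    }
  }
  vox
}
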