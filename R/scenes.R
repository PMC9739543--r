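#' Specify a synthetic optic-nerve scene
#'
#' Describes a 3D test volume emulating a neurofilament-labelled nerve:
#' bright tubular axons running along the x (nerve) axis, ellipsoidal blebs
#' whose centroids stay put across slices, bright disc segments whose centre
#' translates a fixed distance per slice (the appearance of bright axonal
#' segments coming into focus through the stack), and small single-slice
#' speckle artifacts, all over Gaussian background noise on an 8-bit scale.
#'
#' Distractor classes for exercising the post-processing filters are
#' available through `n_sub_span_blebs` (blebs spanning fewer slices than the
#' thickness filter keeps) and `n_small_blebs` (blebs with fewer voxels than
#' the size filter keeps).
#'
#' @param shape `c(z, y, x)` volume dimensions.
#' @param n_axons Number of axon tubes (image only, never in the truth mask).
#' @param axon_intensity,bleb_intensity Intensity ranges (8-bit scale).
#' @param n_blebs Number of qualifying blebs.
#' @param bleb_radius In-plane radius range (px).
#' @param bleb_span Slice-span range for qualifying blebs.
#' @param n_sub_span_blebs Blebs with span 3-4 slices (fail the 5-slice rule
#'   but exceed the size threshold).
#' @param n_small_blebs Blebs with radius 2 (pass the span rule but fall
#'   under the 100-voxel size threshold).
#' @param n_travel Number of travelling bright segments.
#' @param travel_shift Per-slice centroid displacement (px) of travelling
#'   segments; their disc radius is enlarged to at least `shift/2 + 2` so
#'   consecutive discs stay 26-connected.
#' @param travel_radius Nominal disc radius of travelling segments.
#' @param travel_span Slice-span range for travelling segments.
#' @param n_specks Single-slice speckle artifacts.
#' @param speck_size Voxel-count range for specks.
#' @param background `c(mean, sd)` of the Gaussian background.
#' @param seed Integer seed; scenes are deterministic given the seed.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(shape = c(20L, 128L, 128L),
                       n_axons = 10L,
                       axon_intensity = c(90, 130),
                       n_blebs = 6L,
                       bleb_intensity = c(150, 230),
                       bleb_radius = c(4, 6),
                       bleb_span = c(6, 10),
                       n_sub_span_blebs = 0L,
                       n_small_blebs = 0L,
                       n_travel = 0L,
                       travel_shift = 20,
                       travel_radius = 4,
                       travel_span = c(5, 6),
                       n_specks = 0L,
                       speck_size = c(2L, 8L),
                       background = c(mean = 40, sd = 8),
                       seed = 1L) {
  spec <- list(shape = as.integer(shape), n_axons = as.integer(n_axons),
               axon_intensity = axon_intensity, n_blebs = as.integer(n_blebs),
               bleb_intensity = bleb_intensity, bleb_radius = bleb_radius,
               bleb_span = as.integer(bleb_span),
               n_sub_span_blebs = as.integer(n_sub_span_blebs),
               n_small_blebs = as.integer(n_small_blebs),
               n_travel = as.integer(n_travel), travel_shift = travel_shift,
               travel_radius = travel_radius, travel_span = as.integer(travel_span),
               n_specks = as.integer(n_specks), speck_size = as.integer(speck_size),
               background = background, seed = as.integer(seed))
  assert_that(length(spec$shape) == 3L && all(spec$shape >= 1L),
              "shape must be c(z, y, x), all >= 1")
  counts <- c(spec$n_axons, spec$n_blebs, spec$n_sub_span_blebs,
              spec$n_small_blebs, spec$n_travel, spec$n_specks)
  assert_that(all(counts >= 0L), "all object counts must be >= 0")
  assert_that(all(spec$bleb_radius > 0) && spec$travel_shift >= 0,
              "radii must be > 0 and shift >= 0")
  if (spec$n_blebs > 0) {
    assert_that(max(spec$bleb_span) <= spec$shape[1],
                "bleb slice span exceeds stack depth")
  }
  if (spec$n_travel > 0) {
    assert_that(max(spec$travel_span) <= spec$shape[1],
                "travel slice span exceeds stack depth")
  }
  structure(spec, class = "scene_spec")
}

#' Generate a synthetic scene with exact ground truth
#'
#' Deterministic given `spec$seed`. Objects are placed by rejection sampling
#' so that no two catalogued objects touch (2-voxel clearance), which keeps
#' the catalog in one-to-one correspondence with 3D connected components.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `bleb_scene`:
#'   * `stack` — [image_stack()] (uint8);
#'   * `mask` — [label_mask()] marking bleb-class voxels only (training truth);
#'   * `labels` — integer `(z, y, x)` array of object ids for all planted
#'     objects (blebs, travelling segments, specks);
#'   * `catalog` — data.frame, one row per planted object: `id`, `class`,
#'     `z0`, `z1`, `span`, `size` (painted voxel count), `max_step` (largest
#'     consecutive-slice centroid displacement), `qualifies_as_bleb`, plus a
#'     `centroids` list-column of per-slice `(z, cy, cx)` matrices;
#'   * `voxel_sum` — total image intensity, for round-trip checks.
#' @export
generate_scene <- function(spec) {
  assert_that(inherits(spec, "scene_spec"), "spec must be a scene_spec")
  with_seed(spec$seed, {
    nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
    img <- array(clip(round(rnorm(nz * ny * nx, spec$background[1],
                                  spec$background[2])), 0, 255),
                 c(nz, ny, nx))
    labels <- array(0L, c(nz, ny, nx))

    # axons: straight bright tubes along x (image only)
    if (spec$n_axons > 0) {
      for (a in seq_len(spec$n_axons)) {
        zc <- runif(1, 1.5, nz - 0.5)
        yc <- runif(1, 3, ny - 2)
        r <- runif(1, 1.0, 1.8)
        inten <- runif(1, spec$axon_intensity[1], spec$axon_intensity[2])
        zi <- seq_len(nz); yi <- seq_len(ny)
        d2 <- outer((zi - zc)^2, (yi - yc)^2, "+")
        hit <- which(d2 <= r^2, arr.ind = TRUE)
        if (nrow(hit) == 0) next
        for (k in seq_len(nrow(hit))) {
          img[hit[k, 1], hit[k, 2], ] <-
            pmax(img[hit[k, 1], hit[k, 2], ],
                 clip(round(inten + rnorm(nx, 0, 5)), 0, 255))
        }
      }
    }

    cat_rows <- list()
    centroid_list <- list()
    next_id <- 0L

    place <- function(coords_fun, class, tries = 300L) {
      # coords_fun() proposes a list(coords = matrix(z, y, x), meta = ...)
      for (t in seq_len(tries)) {
        prop <- coords_fun()
        co <- prop$coords
        if (is.null(co) || nrow(co) == 0) next
        if (min(co) < 1 || any(co[, 1] > nz) || any(co[, 2] > ny) ||
            any(co[, 3] > nx)) next
        z0 <- max(1L, min(co[, 1]) - 2L); z1 <- min(nz, max(co[, 1]) + 2L)
        y0 <- max(1L, min(co[, 2]) - 2L); y1 <- min(ny, max(co[, 2]) + 2L)
        x0 <- max(1L, min(co[, 3]) - 2L); x1 <- min(nx, max(co[, 3]) + 2L)
        if (any(labels[z0:z1, y0:y1, x0:x1] > 0)) next
        next_id <<- next_id + 1L
        lin <- co[, 1] + (co[, 2] - 1L) * nz + (co[, 3] - 1L) * nz * ny
        labels[lin] <<- next_id
        inten <- runif(1, spec$bleb_intensity[1], spec$bleb_intensity[2])
        img[lin] <<- pmax(img[lin], clip(round(inten + rnorm(length(lin), 0, 8)),
                                         0, 255))
        zs <- sort(unique(co[, 1]))
        cen <- t(vapply(zs, function(z) {
          sel <- co[, 1] == z
          c(z, mean(co[sel, 2]), mean(co[sel, 3]))
        }, numeric(3)))
        colnames(cen) <- c("z", "cy", "cx")
        steps <- if (nrow(cen) > 1) {
          sqrt(diff(cen[, "cy"])^2 + diff(cen[, "cx"])^2)
        } else 0
        cat_rows[[next_id]] <<- data.frame(
          id = next_id, class = class, z0 = min(zs), z1 = max(zs),
          span = length(zs), size = nrow(co), max_step = max(steps),
          stringsAsFactors = FALSE)
        centroid_list[[next_id]] <<- cen
        return(TRUE)
      }
      stop(sprintf("could not place a '%s' object; scene too crowded or too small",
                   class), call. = FALSE)
    }

    ellipsoid_coords <- function(r, span) {
      zc0 <- sample(seq_len(nz - span + 1L), 1)
      zc <- zc0 + (span - 1) / 2
      rz <- max((span - 1) / 2, 1e-6)
      yc <- sample(seq.int(ceiling(r + 3), floor(ny - r - 2)), 1)
      xc <- sample(seq.int(ceiling(r + 3), floor(nx - r - 2)), 1)
      zi <- zc0:(zc0 + span - 1L)
      grid <- expand.grid(z = zi,
                          y = floor(yc - r):ceiling(yc + r),
                          x = floor(xc - r):ceiling(xc + r))
      keep <- ((grid$z - zc) / rz)^2 + ((grid$y - yc) / r)^2 +
        ((grid$x - xc) / r)^2 <= 1 + 1e-9
      list(coords = as.matrix(grid[keep, , drop = FALSE]))
    }

    # travelling segments first: their footprint (disc path) is by far the
    # largest, so they must claim space before the blebs do
    if (spec$n_travel > 0) {
      rr <- max(spec$travel_radius, spec$travel_shift / 2 + 2)
      for (b in seq_len(spec$n_travel)) {
        place(function() {
          span <- sample(seq.int(spec$travel_span[1], spec$travel_span[2]), 1)
          theta <- runif(1, 0, 2 * pi)
          dy <- spec$travel_shift * sin(theta)
          dx <- spec$travel_shift * cos(theta)
          ext_y <- abs(dy) * (span - 1); ext_x <- abs(dx) * (span - 1)
          lo_y <- rr + 3 + max(0, -dy * (span - 1))
          hi_y <- ny - rr - 2 - max(0, dy * (span - 1))
          lo_x <- rr + 3 + max(0, -dx * (span - 1))
          hi_x <- nx - rr - 2 - max(0, dx * (span - 1))
          if (hi_y <= lo_y || hi_x <= lo_x) return(list(coords = NULL))
          y0 <- runif(1, lo_y, hi_y); x0 <- runif(1, lo_x, hi_x)
          z0 <- sample(seq_len(nz - span + 1L), 1)
          rows <- vector("list", span)
          for (t in seq_len(span)) {
            cy <- y0 + (t - 1) * dy; cx <- x0 + (t - 1) * dx
            yy <- floor(cy - rr):ceiling(cy + rr)
            xx <- floor(cx - rr):ceiling(cx + rr)
            g <- expand.grid(z = z0 + t - 1L, y = yy, x = xx)
            keep <- (g$y - cy)^2 + (g$x - cx)^2 <= rr^2
            rows[[t]] <- as.matrix(g[keep, , drop = FALSE])
          }
          list(coords = do.call(rbind, rows))
        }, "travel_segment")
      }
    }

    if (spec$n_blebs > 0) {
      for (b in seq_len(spec$n_blebs)) {
        place(function() {
          r <- runif(1, spec$bleb_radius[1], spec$bleb_radius[2])
          span <- sample(seq.int(spec$bleb_span[1], spec$bleb_span[2]), 1)
          ellipsoid_coords(r, span)
        }, "bleb")
      }
    }
    if (spec$n_sub_span_blebs > 0) {
      for (b in seq_len(spec$n_sub_span_blebs)) {
        place(function() ellipsoid_coords(6, sample(3:4, 1)), "bleb")
      }
    }
    if (spec$n_small_blebs > 0) {
      for (b in seq_len(spec$n_small_blebs)) {
        place(function() ellipsoid_coords(2, sample(6:7, 1)), "bleb")
      }
    }

    if (spec$n_specks > 0) {
      for (b in seq_len(spec$n_specks)) {
        place(function() {
          sz <- sample(seq.int(spec$speck_size[1], spec$speck_size[2]), 1)
          z <- sample(nz, 1)
          y <- sample(seq.int(4, ny - 3), 1)
          x <- sample(seq.int(4, nx - 3), 1)
          pts <- matrix(c(z, y, x), 1)
          while (nrow(pts) < sz) {
            base <- pts[sample(nrow(pts), 1), ]
            step <- base + c(0L, sample(c(-1L, 0L, 1L), 1), sample(c(-1L, 0L, 1L), 1))
            pts <- unique(rbind(pts, step))
          }
          colnames(pts) <- c("z", "y", "x")
          list(coords = pts)
        }, "speck")
      }
    }

    catalog <- if (length(cat_rows)) do.call(rbind, cat_rows) else
      data.frame(id = integer(), class = character(), z0 = integer(),
                 z1 = integer(), span = integer(), size = integer(),
                 max_step = numeric(), stringsAsFactors = FALSE)
    pp <- default_config()$postprocess
    catalog$qualifies_as_bleb <- catalog$class == "bleb" &
      catalog$span >= pp$min_slices & catalog$size >= pp$min_size
    catalog$centroids <- I(centroid_list[seq_len(nrow(catalog))])

    bleb_ids <- catalog$id[catalog$class == "bleb"]
    mask <- array(0, c(nz, ny, nx))
    mask[labels %in% bleb_ids & labels > 0] <- 1

    structure(list(
      stack = image_stack(img, dtype = "uint8",
                          source = sprintf("synthetic seed %d", spec$seed)),
      mask = label_mask(mask),
      labels = labels,
      catalog = catalog,
      voxel_sum = sum(img),
      spec = spec
    ), class = "bleb_scene")
  })
}

#' Apply random augmentation to an image/mask pair
#'
#' Draws a random subset of \{x-flip, y-flip, intensity rescale, additive
#' Gaussian noise, Gaussian blur, multiplicative bias field\} (each included
#' with probability 1/2). Geometric transforms are applied identically to
#' image and mask; intensity transforms touch the image only. With
#' `apply = FALSE` the pair is returned unchanged.
#'
#' @param image 2D numeric matrix on a 0..1 scale.
#' @param mask 2D binary matrix, same shape.
#' @param seed Integer seed.
#' @param apply Apply any transforms at all?
#' @return `list(image, mask, ops)` where `ops` names the transforms used.
#' @export
augment_pair <- function(image, mask, seed, apply = TRUE) {
  assert_that(identical(dim(image), dim(mask)),
              "image and mask must have the same 2D shape")
  if (!apply) return(list(image = image, mask = mask, ops = character(0)))
  with_seed(seed, {
    all_ops <- c("flip_x", "flip_y", "rescale", "noise", "blur", "bias")
    ops <- all_ops[runif(6) < 0.5]
    for (op in ops) {
      if (op == "flip_x") {
        image <- image[, rev(seq_len(ncol(image))), drop = FALSE]
        mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
      } else if (op == "flip_y") {
        image <- image[rev(seq_len(nrow(image))), , drop = FALSE]
        mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
      } else if (op == "rescale") {
        image <- clip(image * runif(1, 0.7, 1.3), 0, 1)
      } else if (op == "noise") {
        image <- clip(image + matrix(rnorm(length(image), 0, 0.03),
                                     nrow(image)), 0, 1)
      } else if (op == "blur") {
        image <- gaussian_blur(image, runif(1, 0.5, 1.2))
      } else if (op == "bias") {
        u <- matrix(seq(0, 1, length.out = nrow(image)), nrow(image),
                    ncol(image))
        v <- matrix(seq(0, 1, length.out = ncol(image)), nrow(image),
                    ncol(image), byrow = TRUE)
        a <- runif(3, -0.3, 0.3)
        gain <- 1 + a[1] * (u - 0.5) + a[2] * (v - 0.5) +
          a[3] * (u - 0.5) * (v - 0.5)
        image <- clip(image * gain, 0, 1)
      }
    }
    list(image = image, mask = mask, ops = ops)
  })
}

# separable Gaussian blur with edge renormalization
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  band <- function(n) {
    B <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - r):min(n, i + r)
      B[j, i] <- k[j - i + r + 1L]
      B[, i] <- B[, i] / sum(B[, i])
    }
    B
  }
  if (nrow(m) < 2 || ncol(m) < 2) return(m)
  t(band(nrow(m))) %*% m %*% band(ncol(m))
}

#' Select an exact fraction of a dataset for augmentation
#'
#' Marks exactly `round(fraction * n)` items, chosen by a seeded shuffle,
#' rather than per-item coin flips, so the augmented share is exact.
#'
#' @param n Number of items (or a vector/list, whose length is used).
#' @param fraction Fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return Sorted integer indices of the selected items.
#' @export
select_augmented <- function(n, fraction, seed) {
  if (!is.numeric(n) || length(n) != 1) n <- length(n)
  assert_that(fraction >= 0 && fraction <= 1, "fraction must be in [0, 1]")
  k <- round(fraction * n)
  if (k == 0) return(integer(0))
  with_seed(seed, sort(sample.int(n, k)))
}
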