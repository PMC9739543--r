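test_that("opening removes speckle and matches the brute-force min/max scan", {
  empty <- array(0, c(2, 10, 10))
  expect_equal(sum(open_binary(empty, 1)), 0)

  # isolated pixel is smaller than the radius-1 disc
  v <- array(0, c(1, 9, 9)); v[1, 5, 5] <- 1
  expect_equal(sum(open_binary(v, 1)), 0)

  # large solid disc: interior preserved, result equals erosion-then-dilation
  # by direct neighborhood scan
  m <- matrix(0, 21, 21)
  for (y in 1:21) for (x in 1:21) if ((y - 11)^2 + (x - 11)^2 <= 49) m[y, x] <- 1
  v2 <- array(m, c(1, 21, 21))
  opened <- open_binary(v2, 1)
  offs <- disc_offsets(1)
  oracle <- brute_morph(brute_morph(m, offs, "erode"), offs, "dilate")
  expect_identical(opened[1, , ], oracle)
  expect_equal(opened[1, 11, 11], 1)
  expect_error(open_binary(v2, -1), "radius")
})

test_that("object assembly matches flood-fill labeling on random volumes", {
  set.seed(20)
  for (rep in 1:5) {
    v <- array(rbinom(6 * 14 * 14, 1, 0.18), c(6, 14, 14))
    for (conn in c(26L, 6L)) {
      objs <- assemble_objects(v, conn)
      ref <- flood_fill_label(v, conn)
      expect_equal(length(objs), max(ref))
      # identical partition of foreground voxels
      got_sizes <- sort(vapply(objs, function(o) o$voxel_count, numeric(1)))
      ref_sizes <- sort(as.vector(table(ref[ref > 0])))
      expect_equal(got_sizes, as.numeric(ref_sizes))
    }
  }
})

test_that("a solid cube assembles into one static object", {
  v <- array(0, c(6, 10, 10))
  v[2:4, 3:5, 4:6] <- 1
  objs <- assemble_objects(v)
  expect_length(objs, 1L)
  o <- objs[[1]]
  expect_equal(o$voxel_count, 27)
  expect_equal(o$span, 3L)
  expect_equal(unname(o$centroids[, "cy"]), rep(4, 3))
  expect_equal(max_centroid_step(o), 0)

  # two blobs separated by > 1 voxel in every axis
  v[6, 9:10, 9:10] <- 1
  expect_length(assemble_objects(v), 2L)
  expect_length(assemble_objects(array(0, c(2, 4, 4))), 0L)
})

test_that("slice-thickness filter keeps span 5 and removes span 4 at defaults", {
  dims <- c(12L, 30L, 30L)
  objs <- object_list(lapply(1:10, function(s) {
    make_object(s, box_coords(1, s, 2 + 2 * s, 3 + 2 * s, 5, 8), dims)
  }), dims)  # spans 1..10
  kept <- filter_slice_thickness(objs, 5L)
  expect_identical(vapply(kept, function(o) o$span, integer(1)), 5:10)
  expect_length(filter_slice_thickness(objs, 1L), 10L)
  # idempotent and monotone in min_slices
  expect_identical(vapply(filter_slice_thickness(kept, 5L),
                          function(o) o$id, integer(1)),
                   vapply(kept, function(o) o$id, integer(1)))
  expect_lte(length(filter_slice_thickness(objs, 10L)), length(kept))
})

test_that("travelling filter: 15 px shift kept, 16 px removed, diagonal 12,12 removed", {
  dims <- c(8L, 200L, 200L)
  mk_shift <- function(id, dy, dx) {
    rows <- lapply(0:4, function(t) {
      box_coords(1 + t, 1 + t, 50 + t * dy, 52 + t * dy, 50 + t * dx, 52 + t * dx)
    })
    make_object(id, do.call(rbind, rows), dims)
  }
  static <- mk_shift(1, 0, 0)
  s15 <- mk_shift(2, 0, 15)
  s16 <- mk_shift(3, 0, 16)
  diag12 <- mk_shift(4, 12, 12)   # sqrt(288) = 16.97 > 15
  objs <- object_list(list(static, s15, s16, diag12), dims)
  kept <- filter_travelling(objs, 15)
  expect_identical(vapply(kept, function(o) o$id, integer(1)), c(1L, 2L))
  expect_equal(max_centroid_step(diag12), sqrt(12^2 + 12^2))
  # monotone in max_shift: a larger tolerance never removes more
  expect_length(filter_travelling(objs, 17), 4L)
  expect_length(filter_travelling(objs, 0), 1L)
})

test_that("size filter keeps 100 voxels and removes 99 at defaults", {
  dims <- c(10L, 60L, 60L)
  sizes <- c(50, 99, 100, 101, 150)
  objs <- object_list(lapply(seq_along(sizes), function(i) {
    n <- sizes[i]
    # 5 slices of n/5-ish voxels: a 5 x k x m box plus remainder voxels
    co <- box_coords(1, 5, 1 + 10 * (i - 1), 3 + 10 * (i - 1), 1, 10)[seq_len(n), ]
    make_object(i, co, dims)
  }), dims)
  kept <- filter_size(objs, 100L)
  expect_identical(vapply(kept, function(o) o$voxel_count, integer(1)),
                   as.integer(c(100, 101, 150)))
  expect_length(filter_size(objs, 1L), 5L)
  expect_identical(filter_size(filter_size(objs, 100L), 100L), kept)
})

test_that("count_blebs recovers exactly the qualifying planted blebs", {
  sc <- generate_scene(scene_spec(shape = c(14L, 160L, 160L), n_axons = 0L,
                                  n_blebs = 5L, n_travel = 2L,
                                  n_sub_span_blebs = 2L, n_small_blebs = 2L,
                                  n_specks = 6L, seed = 42L))
  catalog <- count_blebs((sc$labels > 0) * 1)
  n_qual <- sum(sc$catalog$qualifies_as_bleb)
  expect_equal(catalog$n, n_qual)
  # survivors coincide voxel-wise with the qualifying planted blebs
  qual_ids <- sc$catalog$id[sc$catalog$qualifies_as_bleb]
  ref <- array(0, dim(sc$labels)); ref[sc$labels %in% qual_ids] <- 1
  m <- match_objects(catalog, assemble_objects(ref))
  expect_equal(m$tp, n_qual)
  expect_equal(m$fp, 0L)
  expect_equal(m$fn, 0L)
  # eliminations are attributed to the expected filters
  expect_equal(unname(catalog$eliminated["travelling"]), 2)
  expect_gte(unname(catalog$eliminated["slice_thickness"]), 2)

  # raising min_slices can only lower the count
  stricter <- count_blebs((sc$labels > 0) * 1, list(min_slices = 10L))
  expect_lte(stricter$n, catalog$n)
  # empty input counts zero
  expect_equal(count_blebs(array(0, c(3, 16, 16)))$n, 0)
})

test_that("catalog export writes csv, provenance and survivor mask", {
  sc <- generate_scene(scene_spec(shape = c(10L, 96L, 96L), n_blebs = 3L,
                                  seed = 3L))
  catalog <- count_blebs(sc$mask)
  d <- tempfile("catalog")
  write_catalog(catalog, d)
  expect_true(file.exists(file.path(d, "catalog.csv")))
  expect_true(file.exists(file.path(d, "provenance.json")))
  expect_true(file.exists(file.path(d, "survivors.tif")))
  df <- read.csv(file.path(d, "catalog.csv"))
  expect_equal(nrow(df), catalog$n)
  prov <- jsonlite::read_json(file.path(d, "provenance.json"))
  expect_equal(prov$config$min_slices, 5)
  expect_equal(prov$config$max_shift, 15)
  expect_equal(prov$config$min_size, 100)
  surv <- read_mask(file.path(d, "survivors.tif"))
  expect_equal(sum(surv$voxels),
               sum(vapply(catalog$objects, function(o) o$voxel_count,
                          numeric(1))))
})
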