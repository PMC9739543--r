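test_that("the default architecture matches its contract", {
  net <- build_network(architecture_spec(), seed = 1)
  s <- network_summary(net)
  expect_equal(s$n_down, 3L)
  expect_equal(s$down_filters, c(10L, 20L, 30L))
  expect_equal(s$up_filters, c(30L, 20L, 10L))
  expect_equal(s$kernel, 5L)
  expect_equal(s$stride, 2L)
  expect_equal(s$n_classes, 2L)
  expect_equal(s$head_kernel, 1L)
  expect_equal(s$threshold, 0.5)
  # layer shapes: encoder 1->10->20->30; decoder with skip concatenations
  expect_equal(vapply(net$params, function(p) p$cin, integer(1),
                      USE.NAMES = FALSE), c(1L, 10L, 20L, 30L, 50L, 30L, 10L))
  expect_equal(vapply(net$params, function(p) p$cout, integer(1),
                      USE.NAMES = FALSE), c(10L, 20L, 30L, 30L, 20L, 10L, 2L))
})

test_that("seeded builds are reproducible and distinct across seeds", {
  a <- build_network(seed = 5)
  b <- build_network(seed = 5)
  c <- build_network(seed = 6)
  x <- matrix(runif(24 * 24), 24, 24)
  expect_identical(predict_tile(a, x), predict_tile(b, x))
  expect_false(identical(predict_tile(a, x), predict_tile(c, x)))
})

test_that("softmax normalization holds at every pixel", {
  net <- build_network(seed = 2)
  for (side in c(16L, 40L)) {
    p <- predict_tile(net, matrix(runif(side * side), side, side))
    expect_identical(dim(p), c(side, side, 2L))
    expect_true(all(abs(p[, , 1] + p[, , 2] - 1) < 1e-5))
    expect_true(all(p >= 0 & p <= 1))
  }
  # zero input is valid and deterministic
  z1 <- predict_tile(net, matrix(0, 16, 16))
  z2 <- predict_tile(net, matrix(0, 16, 16))
  expect_identical(z1, z2)
})

test_that("tiles with sides not divisible by 8 are rejected", {
  net <- build_network(seed = 1)
  expect_error(predict_tile(net, matrix(0, 30, 30)), "divisible by 8")
})

test_that("binarization thresholds the bleb channel with ties as foreground", {
  h <- 10; w <- 10
  pm <- array(0, c(h, w, 2))
  pm[, , 2] <- 0; pm[, , 1] <- 1
  expect_true(all(binarize(pm) == 0))

  pm[, , 2] <- 0.5; pm[, , 1] <- 0.5
  expect_true(all(binarize(pm) == 1))  # tie rule: exactly 0.5 is foreground

  # ramp sweep: first foreground value is the configured threshold
  vals <- seq(0, 1, by = 0.01)
  ramp <- array(0, c(1, length(vals), 2))
  ramp[1, , 2] <- vals; ramp[1, , 1] <- 1 - vals
  for (thr in c(0.3, 0.5, 0.77)) {
    bin <- binarize(ramp, thr)
    first_fg <- vals[which(bin[1, ] == 1)[1]]
    expect_equal(first_fg, min(vals[vals >= thr]))
  }
  expect_error(binarize(ramp, 1.5), "threshold")
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  net <- build_network(architecture_spec(down_filters = c(3L, 4L, 5L)),
                       seed = 3)
  H <- 16L
  x <- matrix(runif(H * H), H, H)
  mask <- matrix(rbinom(H * H, 1, 0.3), H, H)
  wmap <- matrix(runif(H * H, 0.5, 2), H, H)
  loss_fn <- function(n) {
    weighted_cross_entropy(blebkit:::unet_forward(n, x)$prob, mask, wmap)
  }
  fw <- blebkit:::unet_forward(net, x, keep = TRUE)
  fg <- mask > 0
  dlog <- array(0, dim(fw$prob))
  dlog[, , 1] <- (fw$prob[, , 1] - !fg) * wmap / length(wmap)
  dlog[, , 2] <- (fw$prob[, , 2] - fg) * wmap / length(wmap)
  g <- blebkit:::unet_backward(net, fw, dlog)
  eps <- 1e-6
  for (nm in names(net$params)) {
    idx <- sample(length(net$params[[nm]]$W), 3)
    for (i in idx) {
      n2 <- net
      n2$params[[nm]]$W[i] <- net$params[[nm]]$W[i] + eps
      lp <- loss_fn(n2)
      n2$params[[nm]]$W[i] <- net$params[[nm]]$W[i] - eps
      lm <- loss_fn(n2)
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - g[[nm]]$dW[i]) /
                  max(1e-6, abs(num) + abs(g[[nm]]$dW[i])), 1e-4)
    }
  }
})

test_that("stack prediction equals the manual tile-wise composition", {
  net <- build_network(seed = 4)
  set.seed(10)
  v <- array(sample(0:255, 3 * 40 * 56, replace = TRUE), c(3, 40, 56))
  stk <- image_stack(v, dtype = "uint8")
  cfg <- tiling_config(32L, 0.1)
  pred <- predict_stack(net, stk, cfg)
  expect_identical(dim(pred$voxels), dim(v))
  grid <- plan_tiles(c(40L, 56L), cfg)
  for (z in 1:3) {
    tiles <- extract_tiles(v[z, , ] / 255, grid)
    maps <- lapply(tiles, function(tl) predict_tile(net, tl)[, , 2])
    manual <- binarize(stitch_tiles(maps, grid), 0.5)
    expect_identical(pred$voxels[z, , ], manual)
  }
})

test_that("slices are segmented independently: permuting z permutes output", {
  net <- build_network(seed = 4)
  set.seed(11)
  v <- array(sample(0:255, 4 * 32 * 32, replace = TRUE), c(4, 32, 32))
  cfg <- tiling_config(32L, 0)
  a <- predict_stack(net, image_stack(v, dtype = "uint8"), cfg)
  perm <- c(3, 1, 4, 2)
  b <- predict_stack(net, image_stack(v[perm, , ], dtype = "uint8"), cfg)
  expect_identical(b$voxels, a$voxels[perm, , ])
  # depth-1 stacks work
  one <- predict_stack(net, image_stack(v[1, , , drop = FALSE],
                                        dtype = "uint8"), cfg)
  expect_identical(dim(one$voxels), c(1L, 32L, 32L))
})

test_that("checkpoints round-trip through save and load", {
  net <- build_network(seed = 9)
  p <- tempfile(fileext = ".rds")
  save_network(net, p)
  back <- load_network(p)
  x <- matrix(runif(16 * 16), 16, 16)
  expect_identical(predict_tile(back, x), predict_tile(net, x))
  bad <- tempfile(fileext = ".rds")
  saveRDS(1:3, bad)
  expect_error(load_network(bad), "not a network checkpoint")
})
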