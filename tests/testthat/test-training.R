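test_that("dataset splitting is an exact seeded 90/10 partition", {
  items <- letters[1:10]
  sp <- split_dataset(items, 0.9, seed = 2)
  expect_length(sp$train, 9L)
  expect_length(sp$validation, 1L)
  expect_setequal(c(sp$train, sp$validation), items)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_identical(split_dataset(items, 0.9, seed = 2), sp)
  # default fraction puts 90% in training for larger n too
  sp2 <- split_dataset(seq_len(200), seed = 5)
  expect_length(sp2$train, 180L)
  expect_error(split_dataset(1:5, 0.999, seed = 1), "empty partition")
})

test_that("weight maps: empty mask, disabled boost, strict positivity", {
  empty <- matrix(0, 12, 12)
  w <- make_weight_map(empty, w0 = 10, sigma = 5, class_weights = c(1.5, 4))
  expect_true(all(w == 1.5))

  set.seed(6)
  m <- matrix(rbinom(144, 1, 0.2), 12, 12)
  w0off <- make_weight_map(m, w0 = 0, class_weights = c(1, 7))
  expect_identical(w0off, ifelse(m > 0, 7, 1))
  expect_true(all(make_weight_map(m, w0 = 10, sigma = 5) > 0))
  expect_error(make_weight_map(m, sigma = 0), "sigma")
})

test_that("border boost between two discs matches the exhaustive distance scan", {
  m <- matrix(0, 24, 24)
  # two discs 6 px apart (edge to edge) on one row
  for (y in 1:24) for (x in 1:24) {
    if ((y - 12)^2 + (x - 6)^2 <= 4 || (y - 12)^2 + (x - 18)^2 <= 4) {
      m[y, x] <- 1
    }
  }
  w <- make_weight_map(m, w0 = 10, sigma = 5, class_weights = c(1, 3))
  # oracle: exhaustive nearest/second-nearest distances from pixel centers
  # to the two connected objects found by flood fill
  lab3 <- flood_fill_label(array(m, c(1, 24, 24)))
  nobj <- max(lab3)
  expect_equal(nobj, 2L)
  oracle <- matrix(0, 24, 24)
  for (y in 1:24) for (x in 1:24) {
    dists <- vapply(seq_len(nobj), function(i) {
      co <- which(lab3[1, , ] == i, arr.ind = TRUE)
      sqrt(min((co[, 1] - y)^2 + (co[, 2] - x)^2))
    }, numeric(1))
    ds <- sort(dists)
    oracle[y, x] <- ifelse(m[y, x] > 0, 3, 1) +
      10 * exp(-(ds[1] + ds[2])^2 / (2 * 25))
  }
  expect_equal(w, oracle, tolerance = 1e-6)
  # boost is maximal in the gap between the discs, vanishing far away
  expect_gt(w[12, 12], w[1, 1])
})

test_that("weighted cross-entropy matches hand arithmetic on a 2x2 toy", {
  prob <- array(0, c(2, 2, 2))
  pb <- matrix(c(0.9, 0.2, 0.6, 0.5), 2, 2)   # bleb-channel probabilities
  prob[, , 2] <- pb; prob[, , 1] <- 1 - pb
  truth <- matrix(c(1, 0, 0, 1), 2, 2)
  wmap <- matrix(c(2, 1, 1, 4), 2, 2)
  hand <- mean(c(2 * -log(0.9), 1 * -log(0.8), 1 * -log(0.4), 4 * -log(0.5)))
  expect_equal(weighted_cross_entropy(prob, truth, wmap), hand, tolerance = 1e-12)

  # uniform weights reduce to unweighted cross-entropy
  expect_equal(weighted_cross_entropy(prob, truth),
               mean(-log(c(0.9, 0.8, 0.4, 0.5))), tolerance = 1e-12)

  # a perfect one-hot prediction is at the clipping floor
  perfect <- array(0, c(2, 2, 2))
  perfect[, , 2] <- truth; perfect[, , 1] <- 1 - truth
  expect_lt(weighted_cross_entropy(perfect, truth), 1e-5)
  expect_error(weighted_cross_entropy(prob, matrix(0, 3, 3)), "mismatch")
})

test_that("Jaccard index follows set arithmetic", {
  a <- matrix(0, 4, 4); b <- matrix(0, 4, 4)
  expect_equal(jaccard_index(a, b), 1)      # both empty
  a[1, 1:3] <- 1
  expect_equal(jaccard_index(a, a), 1)
  b[3, 1:2] <- 1
  expect_equal(jaccard_index(a, b), 0)      # disjoint
  b <- matrix(0, 4, 4); b[1, 3:4] <- 1      # |A|=3, |B|=2, overlap 1
  expect_equal(jaccard_index(a, b), 1 / 4)
})

test_that("early stopping fires on a crafted rising-loss sequence", {
  st <- blebkit:::stop_epoch(c(1.0, 0.9, 0.95, 1.0), patience = 2)
  expect_equal(st$stop_at, 4L)
  expect_equal(st$best, 2L)   # epoch-2 weights are kept
  st2 <- blebkit:::stop_epoch(c(1.0, 0.9, 0.8), patience = 2)
  expect_true(is.na(st2$stop_at))
  expect_equal(st2$best, 3L)
  # a recovery resets the patience counter
  st3 <- blebkit:::stop_epoch(c(1.0, 1.1, 0.9, 1.0, 1.05), patience = 2)
  expect_equal(st3$stop_at, 5L)
  expect_equal(st3$best, 3L)
})

test_that("a short seeded run learns a tiny separable problem deterministically", {
  # 20 tiny tiles: bright centered square = bleb, dim noise = background
  set.seed(77)
  dataset <- lapply(1:20, function(i) {
    img <- matrix(runif(256, 0, 0.25), 16, 16)
    msk <- matrix(0, 16, 16)
    if (i %% 2 == 0) {
      y <- sample(5:9, 1); x <- sample(5:9, 1)
      img[y:(y + 3), x:(x + 3)] <- runif(16, 0.7, 1)
      msk[y:(y + 3), x:(x + 3)] <- 1
    }
    list(image = img, mask = msk)
  })
  cfg <- list(max_epochs = 10L, batch_size = 5L, learning_rate = 3e-3,
              seed = 13L, patience = 5L)
  net <- build_network(architecture_spec(down_filters = c(4L, 6L, 8L)),
                       seed = 2)
  fit <- train_network(net, dataset, cfg)
  lg <- fit$log
  expect_lt(tail(lg$train_loss, 1), lg$train_loss[1])
  expect_gte(tail(lg$val_ji, 1), lg$val_ji[1])
  expect_true(all(diff(lg$steps) > 0))
  # identical rerun gives an identical log
  fit2 <- train_network(build_network(architecture_spec(
    down_filters = c(4L, 6L, 8L)), seed = 2), dataset, cfg)
  expect_identical(fit2$log, lg)
})
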