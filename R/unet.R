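#' Reduced UNet architecture specification
#'
#' A small encoder-decoder segmentation network: three down-sampling
#' convolutional layers of 5 x 5 filters (10, 20, 30 filters) with stride 2
#' (convolution and pooling combined in one step), a mirrored up-sampling arm
#' (30, 20, 10 filters) whose stages concatenate the same-resolution encoder
#' features, and a 1 x 1 two-channel softmax head whose bleb channel is
#' thresholded at 0.5 for a binary segmentation. All convolutions use "same"
#' padding and rectified-linear activations, so output maps match the input
#' size.
#'
#' @param down_filters Filter counts of the down arm; the up arm mirrors them.
#' @param kernel Convolution kernel side.
#' @param stride Down-sampling stride.
#' @param n_classes Output channels (background, bleb).
#' @param threshold Binarization threshold on the bleb channel.
#' @return An `architecture_spec` list.
#' @export
architecture_spec <- function(down_filters = c(10L, 20L, 30L), kernel = 5L,
                              stride = 2L, n_classes = 2L, threshold = 0.5) {
  assert_that(length(down_filters) >= 1 && all(down_filters >= 1),
              "down_filters must be positive")
  assert_that(n_classes == 2L, "the head is a two-channel categorical output")
  assert_that(threshold >= 0 && threshold <= 1, "threshold must be in [0, 1]")
  structure(list(down_filters = as.integer(down_filters),
                 up_filters = rev(as.integer(down_filters)),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 n_classes = as.integer(n_classes), threshold = threshold),
            class = "architecture_spec")
}

#' Build a seeded network
#'
#' He-initialized weights; two builds with the same seed produce identical
#' parameters (and hence identical outputs).
#'
#' @param spec An [architecture_spec()].
#' @param seed Integer seed for the initializer.
#' @return A `bleb_unet` object.
#' @export
build_network <- function(spec = architecture_spec(), seed = 1L) {
  assert_that(inherits(spec, "architecture_spec"),
              "spec must be an architecture_spec")
  f <- spec$down_filters
  nd <- length(f)
  k <- spec$kernel
  layer_dims <- list()
  cin <- 1L
  for (i in seq_len(nd)) {                # encoder
    layer_dims[[paste0("d", i)]] <- c(cin, f[i])
    cin <- f[i]
  }
  for (i in seq_len(nd)) {                # decoder (+ skip concatenations)
    cout <- spec$up_filters[i]
    layer_dims[[paste0("u", i)]] <- c(cin, cout)
    skip <- if (i < nd) f[nd - i] else 0L    # concat same-resolution encoder map
    cin <- cout + skip
  }
  layer_dims[["head"]] <- c(cin, spec$n_classes)
  params <- with_seed(seed, {
    lapply(seq_along(layer_dims), function(i) {
      dims <- layer_dims[[i]]
      kk <- if (names(layer_dims)[i] == "head") 1L else k
      K <- kk * kk * dims[1]
      list(W = matrix(rnorm(K * dims[2], sd = sqrt(2 / K)), K, dims[2]),
           b = numeric(dims[2]), cin = dims[1], cout = dims[2], k = kk)
    })
  })
  names(params) <- names(layer_dims)
  structure(list(spec = spec, params = params, seed = seed),
            class = "bleb_unet")
}

#' @export
print.bleb_unet <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<bleb_unet> down (%s) / up (%s), %dx%d kernels, stride %d, %d-class softmax head\n",
              paste(s$down_filters, collapse = ", "),
              paste(s$up_filters, collapse = ", "),
              s$kernel, s$kernel, s$stride, s$n_classes))
  invisible(x)
}

#' Introspect a network's architecture
#'
#' @param net A `bleb_unet`.
#' @return List with `n_down`, `n_up`, `down_filters`, `up_filters`,
#'   `kernel`, `stride`, `n_classes`, `head_kernel`, `threshold` and the
#'   total parameter count.
#' @export
network_summary <- function(net) {
  s <- net$spec
  list(n_down = length(s$down_filters), n_up = length(s$up_filters),
       down_filters = s$down_filters, up_filters = s$up_filters,
       kernel = s$kernel, stride = s$stride, n_classes = s$n_classes,
       head_kernel = 1L, threshold = s$threshold,
       n_params = sum(vapply(net$params,
                             function(p) length(p$W) + length(p$b), numeric(1))))
}

# ---- layer primitives ----------------------------------------------------

pad_same <- function(k) (k - 1L) %/% 2L

conv_forward <- function(x, par, stride, keep = FALSE) {
  d <- dim(x)
  k <- par$k
  pad <- pad_same(k)
  hp <- d[1] + 2L * pad; wp <- d[2] + 2L * pad
  xp <- array(0, c(hp, wp, d[3]))
  if (pad > 0) xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x else xp[] <- x
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  P <- ho * wo
  K <- nrow(par$W)
  if (keep || P * as.numeric(K) <= 4e6) {
    xcol <- im2col_range(xp, k, stride, ho, wo, 0L, P)
    y <- xcol %*% par$W
    y <- y + rep(par$b, each = P)
    out <- array(y, c(ho, wo, par$cout))
    cache <- if (keep) list(xcol = xcol, dimx = d, hp = hp, wp = wp,
                            ho = ho, wo = wo, pad = pad, stride = stride) else NULL
  } else {
    # inference on large maps: bounded-memory chunks of output rows
    chunk <- max(1L, as.integer(floor(4e6 / K)))
    y <- matrix(0, P, par$cout)
    p0 <- 0L
    while (p0 < P) {
      p1 <- min(P, p0 + chunk)
      xc <- im2col_range(xp, k, stride, ho, wo, p0, p1)
      y[(p0 + 1L):p1, ] <- xc %*% par$W
      p0 <- p1
    }
    y <- y + rep(par$b, each = P)
    out <- array(y, c(ho, wo, par$cout))
    cache <- NULL
  }
  list(out = out, cache = cache)
}

conv_backward <- function(dout, par, cache) {
  P <- cache$ho * cache$wo
  dY <- matrix(dout, P, par$cout)
  dW <- crossprod(cache$xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(par$W)
  dxp <- col2im_acc(dXcol, cache$hp, cache$wp, cache$dimx[3], par$k,
                    cache$stride, cache$ho, cache$wo)
  pad <- cache$pad
  dx <- if (pad > 0) {
    dxp[pad + seq_len(cache$dimx[1]), pad + seq_len(cache$dimx[2]), ,
        drop = FALSE]
  } else dxp
  list(dW = dW, db = db, dx = array(dx, cache$dimx))
}

relu <- function(x) pmax(x, 0)

upsample2 <- function(x) {
  d <- dim(x)
  out <- array(0, c(2L * d[1], 2L * d[2], d[3]))
  out[seq.int(1L, 2L * d[1], 2L), seq.int(1L, 2L * d[2], 2L), ] <- x
  out
}

upsample2_back <- function(g) {
  d <- dim(g)
  g[seq.int(1L, d[1], 2L), seq.int(1L, d[2], 2L), , drop = FALSE]
}

cat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

# Full forward pass; keep = TRUE retains every im2col cache for the backward
# pass (training); keep = FALSE runs in bounded memory (inference).
unet_forward <- function(net, x, keep = FALSE) {
  s <- net$spec
  p <- net$params
  stride <- s$stride
  x3 <- array(x, c(dim(x), 1L))
  c1 <- conv_forward(x3, p$d1, stride, keep); a1 <- relu(c1$out)
  c2 <- conv_forward(a1, p$d2, stride, keep); a2 <- relu(c2$out)
  c3 <- conv_forward(a2, p$d3, stride, keep); a3 <- relu(c3$out)
  u1in <- upsample2(a3)
  c4 <- conv_forward(u1in, p$u1, 1L, keep); a4 <- relu(c4$out)
  m1 <- cat3(a4, a2)
  u2in <- upsample2(m1)
  c5 <- conv_forward(u2in, p$u2, 1L, keep); a5 <- relu(c5$out)
  m2 <- cat3(a5, a1)
  u3in <- upsample2(m2)
  c6 <- conv_forward(u3in, p$u3, 1L, keep); a6 <- relu(c6$out)
  ch <- conv_forward(a6, p$head, 1L, keep)
  logits <- ch$out
  mx <- pmax(logits[, , 1], logits[, , 2])
  e1 <- exp(logits[, , 1] - mx); e2 <- exp(logits[, , 2] - mx)
  ssum <- e1 + e2
  prob <- array(c(e1 / ssum, e2 / ssum), dim(logits))
  out <- list(prob = prob, logits = logits)
  if (keep) {
    out$caches <- list(c1 = c1$cache, c2 = c2$cache, c3 = c3$cache,
                       c4 = c4$cache, c5 = c5$cache, c6 = c6$cache,
                       head = ch$cache)
    out$acts <- list(a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5, a6 = a6)
  }
  out
}

# Backward pass from d(loss)/d(logits); returns per-parameter gradients.
unet_backward <- function(net, fw, dlogits) {
  p <- net$params
  cc <- fw$caches
  aa <- fw$acts
  g <- list()
  bh <- conv_backward(dlogits, p$head, cc$head)
  g$head <- bh[c("dW", "db")]
  d6 <- bh$dx * (aa$a6 > 0)
  b6 <- conv_backward(d6, p$u3, cc$c6)
  g$u3 <- b6[c("dW", "db")]
  dm2 <- upsample2_back(b6$dx)
  n5 <- dim(aa$a5)[3]
  d5 <- dm2[, , seq_len(n5), drop = FALSE] * (aa$a5 > 0)
  d1_skip <- dm2[, , -seq_len(n5), drop = FALSE]
  b5 <- conv_backward(d5, p$u2, cc$c5)
  g$u2 <- b5[c("dW", "db")]
  dm1 <- upsample2_back(b5$dx)
  n4 <- dim(aa$a4)[3]
  d4 <- dm1[, , seq_len(n4), drop = FALSE] * (aa$a4 > 0)
  d2_skip <- dm1[, , -seq_len(n4), drop = FALSE]
  b4 <- conv_backward(d4, p$u1, cc$c4)
  g$u1 <- b4[c("dW", "db")]
  d3 <- upsample2_back(b4$dx) * (aa$a3 > 0)
  b3 <- conv_backward(d3, p$d3, cc$c3)
  g$d3 <- b3[c("dW", "db")]
  d2 <- (b3$dx + d2_skip) * (aa$a2 > 0)
  b2 <- conv_backward(d2, p$d2, cc$c2)
  g$d2 <- b2[c("dW", "db")]
  d1 <- (b2$dx + d1_skip) * (aa$a1 > 0)
  b1 <- conv_backward(d1, p$d1, cc$c1)
  g$d1 <- b1[c("dW", "db")]
  g[names(p)]
}

#' Predict the class-probability map of one tile
#'
#' @param net A `bleb_unet`.
#' @param tile Square single-channel matrix, intensities on a 0..1 scale,
#'   side divisible by `stride^n_down` (8 for the default architecture).
#' @return `(side, side, 2)` array; channels (background, bleb) sum to 1 at
#'   every pixel.
#' @export
predict_tile <- function(net, tile) {
  assert_that(is.matrix(tile), "tile must be a 2D matrix")
  div <- net$spec$stride^length(net$spec$down_filters)
  assert_that(nrow(tile) %% div == 0 && ncol(tile) %% div == 0,
              "tile sides must be divisible by %d", div)
  unet_forward(net, tile, keep = FALSE)$prob
}

#' Threshold a probability map into a binary segmentation
#'
#' A pixel is foreground iff its bleb-channel probability is greater than or
#' equal to the threshold (ties count as foreground).
#'
#' @param prob_map `(h, w, 2)` probability array (or a bleb-channel matrix).
#' @param threshold Value in `[0, 1]`; default 0.5.
#' @return Binary matrix.
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  assert_that(threshold >= 0 && threshold <= 1, "threshold must be in [0, 1]")
  bleb <- if (length(dim(prob_map)) == 3) {
    matrix(prob_map[, , 2], dim(prob_map)[1], dim(prob_map)[2])
  } else prob_map
  (bleb >= threshold) * 1
}

#' Segment a whole z-stack slice-by-slice
#'
#' Each optical section is independently normalized (by the stack's dtype
#' maximum), tiled, predicted, stitched (per-pixel maximum over overlapping
#' tiles) and binarized, so stacks of any depth are handled.
#'
#' @param net A `bleb_unet`.
#' @param stack An [image_stack()].
#' @param config A [tiling_config()]; the tile side must be divisible by 8
#'   for the default architecture.
#' @param threshold Binarization threshold (defaults to the architecture's).
#' @return A [label_mask()] of the stack's shape.
#' @export
predict_stack <- function(net, stack, config = tiling_config(),
                          threshold = net$spec$threshold) {
  assert_that(inherits(stack, "image_stack"), "stack must be an image_stack")
  div <- net$spec$stride^length(net$spec$down_filters)
  assert_that(config$tile_side %% div == 0,
              "tile side must be divisible by %d", div)
  d <- dim(stack$voxels)
  mx <- dtype_max(stack)
  out <- array(0, d)
  grid <- plan_tiles(d[2:3], config)
  for (z in seq_len(d[1])) {
    slice <- stack$voxels[z, , ] / mx
    tiles <- extract_tiles(slice, grid)
    maps <- lapply(tiles, function(tl) unet_forward(net, tl)$prob[, , 2])
    out[z, , ] <- binarize(stitch_tiles(maps, grid), threshold)
  }
  label_mask(out)
}

#' Save / load a network checkpoint
#'
#' @param net A `bleb_unet`.
#' @param path Checkpoint path (RDS).
#' @return `path` (save) or the restored `bleb_unet` (load).
#' @export
save_network <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  assert_that(inherits(net, "bleb_unet"), "'%s' is not a network checkpoint", path)
  net
}
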