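#' Split a dataset into training and validation parts
#'
#' Seeded shuffle, then an exact `round(train_fraction * n)` split; the two
#' parts are disjoint and exhaustive. Default split is 90/10.
#'
#' @param items Vector or list of items.
#' @param train_fraction Fraction assigned to training.
#' @param seed Integer seed.
#' @return `list(train =, validation =)`.
#' @export
split_dataset <- function(items, train_fraction = 0.9, seed = 1L) {
  n <- length(items)
  assert_that(n >= 2, "need at least 2 items to split")
  n_train <- round(train_fraction * n)
  assert_that(n_train >= 1 && n_train < n,
              "train_fraction %.3f yields an empty partition for n = %d",
              train_fraction, n)
  idx <- with_seed(seed, sample.int(n))
  list(train = items[idx[seq_len(n_train)]],
       validation = items[idx[(n_train + 1L):n]])
}

#' Per-pixel loss weight map
#'
#' Class-balance weights plus a border boost concentrated in the gaps
#' between nearby objects:
#' `w = w_class + w0 * exp(-(d1 + d2)^2 / (2 * sigma^2))`,
#' where `d1` and `d2` are the Euclidean distances to the nearest and
#' second-nearest connected foreground object. With fewer than two objects
#' the boost term is zero everywhere (there are no inter-object gaps); with
#' `w0 = 0` the map reduces to pure class-balance weights.
#'
#' @param truth_mask Binary 2D matrix.
#' @param w0 Border boost amplitude (>= 0).
#' @param sigma Boost length scale in pixels (> 0).
#' @param class_weights `c(background, foreground)` base weights.
#' @return Positive matrix of the mask's shape.
#' @export
make_weight_map <- function(truth_mask, w0 = 10, sigma = 5,
                            class_weights = c(1, 5)) {
  assert_that(sigma > 0, "sigma must be > 0")
  assert_that(all(class_weights > 0), "class weights must be > 0")
  m <- truth_mask * 1
  w <- ifelse(m > 0, class_weights[2], class_weights[1])
  if (w0 > 0) {
    labs <- EBImage::bwlabel(m)
    nobj <- max(labs)
    if (nobj >= 2) {
      dmaps <- vapply(seq_len(nobj), function(i) {
        EBImage::distmap((labs != i) * 1)
      }, matrix(0, nrow(m), ncol(m)))
      two_smallest <- apply(dmaps, c(1, 2), function(v) sum(sort(v)[1:2]))
      w <- w + w0 * exp(-two_smallest^2 / (2 * sigma^2))
    }
  }
  w
}

#' Spatially weighted per-pixel categorical cross-entropy
#'
#' `mean(weight * -log p_true)` over pixels, probabilities clipped at 1e-7.
#' Uniform weights recover plain categorical cross-entropy.
#'
#' @param prob_map `(h, w, 2)` probability array.
#' @param truth_mask Binary matrix (1 = bleb).
#' @param weight_map Positive matrix, or `NULL` for uniform weights.
#' @return Non-negative scalar loss.
#' @export
weighted_cross_entropy <- function(prob_map, truth_mask, weight_map = NULL) {
  d <- dim(prob_map)
  assert_that(identical(d[1:2], dim(truth_mask)) ||
                all(d[1:2] == dim(truth_mask)), "shape mismatch")
  if (is.null(weight_map)) weight_map <- matrix(1, d[1], d[2])
  p_true <- ifelse(truth_mask > 0, prob_map[, , 2], prob_map[, , 1])
  p_true <- pmax(p_true, 1e-7)
  mean(weight_map * -log(p_true))
}

#' Jaccard index of two binary masks
#'
#' Intersection over union; defined as 1 when both masks are empty.
#'
#' @param a,b Binary arrays of the same shape.
#' @return Value in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  assert_that(all(dim(a) == dim(b)), "shape mismatch")
  ai <- a > 0; bi <- b > 0
  u <- sum(ai | bi)
  if (u == 0) return(1)
  sum(ai & bi) / u
}

# Early-stopping rule: validation loss is "rising" in an epoch where it
# exceeds the best seen so far; `patience` consecutive rising epochs stop
# the run.  Returns the stopping epoch (NA if never triggered) and the
# best (checkpointed) epoch.
stop_epoch <- function(val_losses, patience) {
  best <- Inf; best_at <- NA_integer_; rising <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]; best_at <- e; rising <- 0L
    } else {
      rising <- rising + 1L
      if (rising >= patience) {
        return(list(stop_at = e, best = best_at))
      }
    }
  }
  list(stop_at = NA_integer_, best = best_at)
}

# one Adam update; state carries first/second moments and the step count
adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in c("W", "b")) {
    gname <- paste0("d", nm)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad[[gname]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad[[gname]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

#' Train a network on image/mask tile pairs
#'
#' Splits the dataset 90/10 into training and validation groups (seeded),
#' augments an exact fraction of the training items (augmented copies are
#' appended, enlarging the set), and minimizes spatially weighted per-pixel
#' categorical cross-entropy with Adam. After every epoch the validation
#' loss and Jaccard index are logged; training stops at `max_epochs` or
#' after `patience` consecutive epochs of validation loss above its best,
#' whichever comes first, and the best-validation parameters are restored.
#'
#' @param net A `bleb_unet` (e.g. from [build_network()]).
#' @param dataset List of `list(image =, mask =)` pairs: square matrices,
#'   images on a 0..1 scale, sides divisible by 8.
#' @param config Training configuration (see [default_config()]`$training`);
#'   missing entries take defaults.
#' @return `list(network, log, stopped_epoch, reason)`; `log` is a
#'   data.frame with one row per completed epoch
#'   (`epoch`, `train_loss`, `val_loss`, `val_ji`, `steps`).
#' @export
train_network <- function(net, dataset, config = list()) {
  cfg <- utils::modifyList(default_config()$training, config)
  assert_that(length(dataset) >= 2, "dataset must hold at least 2 tile pairs")

  parts <- split_dataset(seq_along(dataset), cfg$train_fraction, cfg$seed)
  train_items <- dataset[parts$train]
  val_items <- dataset[parts$validation]

  aug_idx <- select_augmented(length(train_items), cfg$augment_fraction,
                              cfg$seed + 1L)
  if (length(aug_idx) > 0) {
    aug <- lapply(seq_along(aug_idx), function(i) {
      it <- train_items[[aug_idx[i]]]
      a <- augment_pair(it$image, it$mask, seed = cfg$seed + 100L + i)
      list(image = a$image, mask = a$mask)
    })
    train_items <- c(train_items, aug)
  }
  bk_log("training on %d tiles (%d augmented copies), validating on %d",
         length(train_items), length(aug_idx), length(val_items))

  wmaps <- lapply(train_items, function(it) {
    make_weight_map(it$mask, cfg$w0, cfg$sigma, cfg$class_weights)
  })

  states <- lapply(net$params, function(p) {
    list(m = list(W = p$W * 0, b = p$b * 0),
         v = list(W = p$W * 0, b = p$b * 0), t = 0L)
  })

  eval_validation <- function(params) {
    net$params <- params
    losses <- numeric(length(val_items)); jis <- numeric(length(val_items))
    for (i in seq_along(val_items)) {
      it <- val_items[[i]]
      fw <- unet_forward(net, it$image)
      losses[i] <- weighted_cross_entropy(fw$prob, it$mask)
      jis[i] <- jaccard_index(binarize(fw$prob, net$spec$threshold), it$mask)
    }
    c(loss = mean(losses), ji = mean(jis))
  }

  params <- net$params
  log_rows <- list()
  val_losses <- numeric(0)
  best_params <- params
  total_steps <- 0L
  reason <- "max_epochs"

  with_seed(cfg$seed + 7L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(length(train_items))
      batch_losses <- numeric(0)
      b0 <- 1L
      while (b0 <= length(ord)) {
        bidx <- ord[b0:min(length(ord), b0 + cfg$batch_size - 1L)]
        b0 <- b0 + cfg$batch_size
        grads <- NULL
        bl <- 0
        for (ii in bidx) {
          it <- train_items[[ii]]
          net$params <- params
          fw <- unet_forward(net, it$image, keep = TRUE)
          wmap <- wmaps[[ii]]
          npx <- length(wmap)
          onehot_fg <- it$mask > 0
          dlog <- array(0, dim(fw$prob))
          dlog[, , 1] <- (fw$prob[, , 1] - !onehot_fg) * wmap / npx
          dlog[, , 2] <- (fw$prob[, , 2] - onehot_fg) * wmap / npx
          g <- unet_backward(net, fw, dlog)
          bl <- bl + weighted_cross_entropy(fw$prob, it$mask, wmap)
          if (is.null(grads)) {
            grads <- g
          } else {
            for (nm in names(g)) {
              grads[[nm]]$dW <- grads[[nm]]$dW + g[[nm]]$dW
              grads[[nm]]$db <- grads[[nm]]$db + g[[nm]]$db
            }
          }
        }
        nb <- length(bidx)
        bl <- bl / nb
        if (!is.finite(bl)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
               call. = FALSE)
        }
        for (nm in names(grads)) {
          grads[[nm]]$dW <- grads[[nm]]$dW / nb
          grads[[nm]]$db <- grads[[nm]]$db / nb
          upd <- adam_step(params[[nm]], grads[[nm]], states[[nm]],
                           cfg$learning_rate)
          params[[nm]] <- upd$par
          states[[nm]] <- upd$state
        }
        total_steps <- total_steps + 1L
        batch_losses <- c(batch_losses, bl)
      }
      vm <- eval_validation(params)
      val_losses <- c(val_losses, vm["loss"])
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, train_loss = mean(batch_losses),
        val_loss = unname(vm["loss"]), val_ji = unname(vm["ji"]),
        steps = total_steps)
      st <- stop_epoch(val_losses, cfg$patience)
      if (!is.na(st$stop_at) || st$best == epoch) {
        if (st$best == epoch) best_params <- params
      }
      bk_log("epoch %d: train loss %.4f, val loss %.4f, val JI %.4f",
             epoch, mean(batch_losses), vm["loss"], vm["ji"])
      if (!is.na(st$stop_at)) {
        reason <- "early_stop"
        break
      }
    }
  })

  net$params <- best_params
  list(network = net, log = do.call(rbind, log_rows),
       stopped_epoch = length(val_losses), reason = reason)
}
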