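#' Object-level matching of two segmentations
#'
#' Greedy one-to-one matching of predicted against reference objects by
#' descending voxel overlap (ties broken by predicted then reference id); a
#' pair matches iff it shares at least `min_overlap` voxels. Matched pairs
#' are true positives, unmatched predicted objects false positives,
#' unmatched reference objects false negatives.
#'
#' @param predicted,reference Object lists from [assemble_objects()] (or
#'   `bleb_catalog`s), sharing the same stack geometry.
#' @param min_overlap Minimum shared voxels for a candidate match.
#' @return `list(tp, fp, fn, pairs)`; `pairs` is a data.frame of matched
#'   (pred_id, ref_id, overlap).
#' @export
match_objects <- function(predicted, reference, min_overlap = 1L) {
  pred <- as_object_list(predicted)
  ref <- as_object_list(reference)
  dp <- attr(pred, "stack_dim"); dr <- attr(ref, "stack_dim")
  assert_that(!is.null(dp) && !is.null(dr) && all(dp == dr),
              "catalogs refer to different stack geometries")
  refvol <- integer(prod(dr))
  for (o in ref) {
    lin <- o$coords[, "z"] + (o$coords[, "y"] - 1) * dr[1] +
      (o$coords[, "x"] - 1) * dr[1] * dr[2]
    refvol[lin] <- o$id
  }
  cand <- list()
  for (o in pred) {
    lin <- o$coords[, "z"] + (o$coords[, "y"] - 1) * dr[1] +
      (o$coords[, "x"] - 1) * dr[1] * dr[2]
    hits <- refvol[lin]
    hits <- hits[hits > 0]
    if (length(hits) == 0) next
    tb <- table(hits)
    cand[[length(cand) + 1L]] <- data.frame(
      pred_id = o$id, ref_id = as.integer(names(tb)),
      overlap = as.integer(tb))
  }
  pairs <- if (length(cand)) do.call(rbind, cand) else
    data.frame(pred_id = integer(), ref_id = integer(), overlap = integer())
  pairs <- pairs[pairs$overlap >= min_overlap, , drop = FALSE]
  pairs <- pairs[order(-pairs$overlap, pairs$pred_id, pairs$ref_id), ,
                 drop = FALSE]
  used_p <- integer(0); used_r <- integer(0)
  take <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (pairs$pred_id[i] %in% used_p || pairs$ref_id[i] %in% used_r) next
    take[i] <- TRUE
    used_p <- c(used_p, pairs$pred_id[i])
    used_r <- c(used_r, pairs$ref_id[i])
  }
  matched <- pairs[take, , drop = FALSE]
  list(tp = nrow(matched), fp = length(pred) - nrow(matched),
       fn = length(ref) - nrow(matched), pairs = matched)
}

as_object_list <- function(x) {
  if (inherits(x, "bleb_catalog")) {
    objs <- x$objects
    attr(objs, "stack_dim") <- x$dim
    return(objs)
  }
  x
}

#' Agreement metrics from object-level confusion counts
#'
#' Positive predictive value `TP / (TP + FP)`, sensitivity `TP / (TP + FN)`
#' and their harmonic mean, the F1 score. Zero-denominator cases return 0
#' so reports stay total.
#'
#' @param tp,fp,fn Non-negative confusion counts, or a list with those
#'   fields as the first argument.
#' @return `list(tp, fp, fn, ppv, sensitivity, f1)`.
#' @export
compute_metrics <- function(tp, fp = NULL, fn = NULL) {
  if (is.list(tp)) {
    fp <- tp$fp; fn <- tp$fn; tp <- tp$tp
  }
  assert_that(tp >= 0 && fp >= 0 && fn >= 0, "counts must be non-negative")
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else 0
  list(tp = tp, fp = fp, fn = fn, ppv = ppv, sensitivity = sens, f1 = f1)
}

#' Full object-level evaluation report
#'
#' Matches predicted against reference objects, computes PPV / sensitivity /
#' F1, and adds the pixel-level Jaccard index of the two foreground masks
#' plus both total counts.
#'
#' @param predicted,reference Object lists or `bleb_catalog`s on the same
#'   stack geometry.
#' @param min_overlap Match criterion passed to [match_objects()].
#' @return An `eval_report` list.
#' @export
evaluate_catalogs <- function(predicted, reference, min_overlap = 1L) {
  pred <- as_object_list(predicted)
  ref <- as_object_list(reference)
  counts <- match_objects(pred, ref, min_overlap)
  met <- compute_metrics(counts$tp, counts$fp, counts$fn)
  pj <- jaccard_index(objects_to_mask(pred), objects_to_mask(ref))
  structure(c(met, list(pixel_jaccard = pj, n_predicted = length(pred),
                        n_reference = length(ref))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> TP %d, FP %d, FN %d | PPV %.3f, ",
                     "sensitivity %.3f, F1 %.3f | pixel JI %.3f\n"),
              x$tp, x$fp, x$fn, x$ppv, x$sensitivity, x$f1, x$pixel_jaccard))
  invisible(x)
}

#' Compare per-nerve bleb counts across raters
#'
#' @param counts data.frame with columns `nerve`, `rater`, `count` (one row
#'   per nerve/rater), covering the same nerve set for every rater.
#' @return data.frame with one row per nerve and rater pair: the two counts,
#'   absolute difference, and relative difference as a percentage of the
#'   smaller count.
#' @export
compare_counts <- function(counts) {
  assert_that(all(c("nerve", "rater", "count") %in% names(counts)),
              "counts needs columns nerve, rater, count")
  raters <- sort(unique(counts$rater))
  assert_that(length(raters) >= 2, "need at least 2 raters")
  nerves <- sort(unique(counts$nerve))
  for (r in raters) {
    have <- counts$nerve[counts$rater == r]
    assert_that(setequal(have, nerves), "rater '%s' is missing nerves", r)
  }
  rows <- list()
  for (nv in nerves) {
    sub <- counts[counts$nerve == nv, ]
    for (i in seq_len(length(raters) - 1)) {
      for (j in (i + 1):length(raters)) {
        a <- sub$count[sub$rater == raters[i]]
        b <- sub$count[sub$rater == raters[j]]
        lo <- min(a, b)
        rows[[length(rows) + 1L]] <- data.frame(
          nerve = nv, rater_a = raters[i], rater_b = raters[j],
          count_a = a, count_b = b, abs_diff = abs(a - b),
          rel_diff_pct = if (lo > 0) 100 * abs(a - b) / lo else
            if (a == b) 0 else Inf)
      }
    }
  }
  do.call(rbind, rows)
}
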