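# Threshold-sweep evaluation of tile-level predictions.

metric_from_confusion <- function(tp, fp, fn, tn, metric) {
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      sf_warn(sprintf("%s is undefined (zero denominator); returning 0", what),
              "slideforge_undefined_metric")
      return(0)
    }
    num / den
  }
  switch(metric,
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    precision = safe_ratio(tp, tp + fp, "precision"),
    recall = safe_ratio(tp, tp + fn, "recall"),
    f1 = {
      p <- if (tp + fp == 0) 0 else tp / (tp + fp)
      r <- if (tp + fn == 0) 0 else tp / (tp + fn)
      safe_ratio(2 * p * r, p + r, "f1")
    },
    balanced_accuracy = {
      sens <- safe_ratio(tp, tp + fn, "sensitivity")
      spec <- safe_ratio(tn, tn + fp, "specificity")
      (sens + spec) / 2
    },
    sf_stop(sprintf("Unknown metric '%s'", metric),
            "slideforge_validation_error"))
}

new_metric_series <- function(metric, class_name, thresholds, values) {
  structure(data.frame(threshold = thresholds, value = values),
            metric = metric, class_name = class_name,
            class = c("slideforge_metric_series", "data.frame"))
}

#' Classifier metric sweep over probability thresholds
#'
#' For every threshold `t`, a tile with a stored classifier prediction is
#' predicted positive when its probability for `class_name` is at least
#' `t`, and ground-truth positive when the class's annotations cover at
#' least `overlap_threshold` of its area. The requested metric is computed
#' from the resulting 2x2 confusion counts. Undefined ratios (e.g.
#' precision with no predicted positives) return 0 with a warning so
#' sweeps never abort.
#'
#' @param slide A slide after [infer_classifier()] and
#'   [annotate_tile_dictionary()].
#' @param class_name Class to evaluate.
#' @param thresholds Numeric vector of probability thresholds in `[0, 1]`.
#' @param overlap_threshold Minimum annotation coverage for a tile to be
#'   ground-truth positive (default 0.5).
#' @param metric One of `accuracy`, `balanced_accuracy`, `f1`,
#'   `precision`, `recall`.
#' @return A `slideforge_metric_series` data frame (`threshold`, `value`).
#' @export
classifier_metric_at_threshold <- function(slide, class_name, thresholds,
                                           overlap_threshold = 0.5,
                                           metric = "accuracy") {
  require_tiling(slide)
  for (t in thresholds) check_fraction(t, "threshold")
  check_fraction(overlap_threshold, "overlap_threshold")
  recs <- Filter(function(t) !is.null(t$classifier_probs), slide$tiles)
  if (length(recs) == 0) no_predictions_stop()
  probs <- vapply(recs, function(t) t$classifier_probs[[class_name]],
                  numeric(1))
  gt <- vapply(recs, function(t)
    (if (class_name %in% names(t$overlap)) t$overlap[[class_name]] else 0) >=
      overlap_threshold, logical(1))
  values <- vapply(thresholds, function(t) {
    pred <- probs >= t
    metric_from_confusion(sum(pred & gt), sum(pred & !gt),
                          sum(!pred & gt), sum(!pred & !gt), metric)
  }, numeric(1))
  new_metric_series(metric, class_name, thresholds, values)
}

#' Segmentation Dice sweep over probability thresholds
#'
#' Binarizes every inferred tile's probability map for `class_name` at
#' each threshold and computes the Dice coefficient
#' `2|A n B| / (|A| + |B|)` against the rasterized annotation ground
#' truth. Pixels are pooled over all evaluated tiles (micro average;
#' `pooling = "macro"` averages per-tile Dice instead). Two empty masks
#' have Dice 1.
#'
#' @param slide A slide after [infer_segmenter()].
#' @param annotations The `slideforge_annotations` providing ground truth.
#' @inheritParams classifier_metric_at_threshold
#' @param pooling `"micro"` (default) or `"macro"`.
#' @return A `slideforge_metric_series` with metric `dice_coeff`.
#' @export
segmenter_metric_at_threshold <- function(slide, annotations, class_name,
                                          thresholds,
                                          pooling = c("micro", "macro")) {
  require_tiling(slide)
  pooling <- match.arg(pooling)
  for (t in thresholds) check_fraction(t, "threshold")
  idx <- which(vapply(slide$tiles, function(t)
    !is.null(t$segmenter_probs), logical(1)))
  if (length(idx) == 0) no_predictions_stop()
  maps <- lapply(slide$tiles[idx], function(t)
    t$segmenter_probs[, , class_name])
  truths <- lapply(idx, function(k) {
    rec <- slide$tiles[[k]]
    rasterize_tile_mask(slide, c(rec$col, rec$row), annotations, class_name)
  })
  dice <- function(inter, a, b) if (a + b == 0) 1 else 2 * inter / (a + b)
  values <- vapply(thresholds, function(t) {
    per <- vapply(seq_along(maps), function(i) {
      pred <- maps[[i]] >= t
      tru <- truths[[i]] == 1L
      c(sum(pred & tru), sum(pred), sum(tru))
    }, numeric(3))
    if (pooling == "micro") dice(sum(per[1, ]), sum(per[2, ]), sum(per[3, ]))
    else mean(vapply(seq_len(ncol(per)), function(i)
      dice(per[1, i], per[2, i], per[3, i]), numeric(1)))
  }, numeric(1))
  new_metric_series("dice_coeff", class_name, thresholds, values)
}

#' Count tiles at or above class-probability thresholds
#'
#' @inheritParams classifier_metric_at_threshold
#' @return Integer vector: per threshold, the number of inferred tiles
#'   whose probability for `class_name` is greater than or equal to it
#'   (non-increasing in the threshold).
#' @export
num_tiles_above_threshold <- function(slide, class_name, thresholds) {
  require_tiling(slide)
  for (t in thresholds) check_fraction(t, "threshold")
  recs <- Filter(function(t) !is.null(t$classifier_probs), slide$tiles)
  if (length(recs) == 0) no_predictions_stop()
  probs <- vapply(recs, function(t) t$classifier_probs[[class_name]],
                  numeric(1))
  vapply(thresholds, function(t) sum(probs >= t), integer(1))
}

#' Slide-level AUROC from positive-tile counts
#'
#' Treats each slide's positive-tile count as a score for the slide being
#' positive and computes the area under the ROC curve — equivalently the
#' concordance probability that a random positive slide outscores a
#' random negative one, with ties counting one half (rank/midpoint
#' convention).
#'
#' @param counts Numeric vector of per-slide positive-tile counts.
#' @param labels Logical (or 0/1) vector of slide-level ground truth.
#' @return AUROC in `[0, 1]`.
#' @export
slide_level_auroc <- function(counts, labels) {
  labels <- as.logical(labels)
  stopifnot(length(counts) == length(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    sf_stop("AUROC is undefined: need at least one positive and one negative slide",
            "slideforge_validation_error")
  r <- rank(counts)  # midpoint ranks handle ties
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
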