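# Segmentation-agreement and generalization-gap metrics.

#' Dice similarity coefficient
#'
#' Overlap agreement between two binary masks, `2|A n B| / (|A| + |B|)`. Two
#' empty masks agree perfectly (1); exactly one empty mask scores 0.
#'
#' @param mask_a,mask_b Binary matrices of equal shape.
#' @return Dice score in `[0, 1]`; symmetric in its arguments.
#' @export
dice <- function(mask_a, mask_b) {
  a <- as_binary_mask(mask_a, "mask_a")
  b <- as_binary_mask(mask_b, "mask_b")
  assert_same_shape(a, b, c("mask_a", "mask_b"))
  sa <- sum(a)
  sb <- sum(b)
  if (sa + sb == 0L) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Centerline Dice (clDice)
#'
#' Topology-aware agreement between a predicted and a reference mask. The
#' topology precision is the fraction of the prediction's skeleton lying
#' inside the reference mask; the topology sensitivity is the fraction of the
#' reference's skeleton lying inside the prediction. clDice is their harmonic
#' mean, so it rewards preserved continuity and branching rather than exact
#' border placement. Degenerate cases: both masks empty gives 1; an empty
#' skeleton on exactly one side gives 0; if precision and sensitivity are both
#' zero the score is 0.
#'
#' @param pred Predicted binary mask.
#' @param gt Reference (ground-truth) binary mask, same shape.
#' @return clDice in `[0, 1]`; symmetric under swapping `pred` and `gt`.
#' @export
cl_dice <- function(pred, gt) {
  p <- as_binary_mask(pred, "pred")
  g <- as_binary_mask(gt, "gt")
  assert_same_shape(p, g, c("pred", "gt"))
  if (sum(p) == 0L && sum(g) == 0L) return(1)
  sk_p <- skeletonize_mask(p)
  sk_g <- skeletonize_mask(g)
  if (sum(sk_p) == 0L || sum(sk_g) == 0L) return(0)
  tprec <- sum(sk_p & g) / sum(sk_p)
  tsens <- sum(sk_g & p) / sum(sk_g)
  if (tprec + tsens == 0) return(0)
  2 * tprec * tsens / (tprec + tsens)
}

#' Exponentially weighted moving average
#'
#' Recursive smoother `s[1] = x[1]`, `s[t] = alpha * s[t-1] +
#' (1 - alpha) * x[t]`. Used to stabilize per-epoch loss curves before reading
#' off the train/validation gap. Shift- and scale-equivariant.
#'
#' @param curve Non-empty numeric sequence.
#' @param smoothing_factor Alpha in `(0, 1)`; larger values smooth more.
#' @return Smoothed sequence, same length as the input.
#' @export
ewma <- function(curve, smoothing_factor = 0.9) {
  if (length(curve) == 0L) abort("`curve` must be non-empty.")
  a <- smoothing_factor
  if (!is_number(a) || a <= 0 || a >= 1) {
    abort("`smoothing_factor` must lie strictly inside (0, 1).")
  }
  as.numeric(stats::filter((1 - a) * curve, a, method = "recursive",
                           init = curve[1]))
}

#' Paired train/validation loss curves
#'
#' @param train,val Equal-length numeric per-epoch loss sequences.
#' @param smoothing_factor EWMA alpha used before the gap readout
#'   (default 0.9, a span of roughly 19 epochs).
#' @param eval_epoch Epoch (1-based) at which the gap is read (default 150).
#' @return A `loss_curves` object.
#' @export
loss_curves <- function(train, val, smoothing_factor = 0.9, eval_epoch = 150L) {
  if (length(train) != length(val)) {
    abort("`train` and `val` must have the same length.")
  }
  if (length(train) == 0L) abort("Loss curves must be non-empty.")
  if (!is_count(eval_epoch, min = 1L) || eval_epoch > length(train)) {
    abort("`eval_epoch` must be a positive integer within the curve length.")
  }
  if (smoothing_factor <= 0 || smoothing_factor >= 1) {
    abort("`smoothing_factor` must lie strictly inside (0, 1).")
  }
  structure(
    list(
      train = as.numeric(train),
      val = as.numeric(val),
      smoothing_factor = smoothing_factor,
      eval_epoch = as.integer(eval_epoch)
    ),
    class = "loss_curves"
  )
}

#' Generalization gap delta
#'
#' The difference between the EWMA-smoothed training loss and the smoothed
#' validation loss at the evaluation epoch:
#' `delta = smoothed_train[eval_epoch] - smoothed_val[eval_epoch]`. A negative
#' delta means the validation loss sits above the training loss — the model
#' does not generalize to the validation distribution; a positive delta means
#' the validation samples are easier than the training ones.
#'
#' @param curves A [loss_curves()] object.
#' @return The signed gap (antisymmetric under swapping train and val).
#' @export
delta_gap <- function(curves) {
  stopifnot(inherits(curves, "loss_curves"))
  st <- ewma(curves$train, curves$smoothing_factor)
  sv <- ewma(curves$val, curves$smoothing_factor)
  st[curves$eval_epoch] - sv[curves$eval_epoch]
}

#' Summarize per-sample score distributions
#'
#' For repeated evaluation runs (e.g. many few-shot trainings), summarizes the
#' scores each sample received: quartiles (linear interpolation between order
#' statistics), median, Tukey whiskers at `q1 - 1.5 IQR` and `q3 + 1.5 IQR`,
#' and the per-sample max - min range; plus the dataset-level mean and
#' standard deviation of that range, a headline measure of how strongly
#' performance depends on the training set.
#'
#' @param scores A data frame with one row per (sample, run) score.
#' @param sample Name of the sample-identifier column (default "sample_id").
#' @param score Name of the numeric score column (default "score").
#' @return A `score_summary` object; `tidy()` gives the per-sample table and
#'   `glance()` the dataset-level summary.
#' @export
score_distribution_summary <- function(scores, sample = "sample_id",
                                       score = "score") {
  if (!is.data.frame(scores) || !all(c(sample, score) %in% names(scores))) {
    abort(sprintf("`scores` must be a data frame with `%s` and `%s` columns.",
                  sample, score))
  }
  if (nrow(scores) == 0L) abort("`scores` is empty.")
  if (any(is.na(scores[[score]]))) abort("Scores must not contain NA.")

  groups <- split(scores[[score]],
                  factor(scores[[sample]], levels = unique(scores[[sample]])))
  qtl <- function(p) {
    vapply(groups, quantile, numeric(1), probs = p, names = FALSE, type = 7)
  }
  per_sample <- tibble(
    !!sample := names(groups),
    n_scores = unname(lengths(groups)),
    q1 = unname(qtl(0.25)),
    median = unname(qtl(0.5)),
    q3 = unname(qtl(0.75)),
    range = unname(vapply(groups, function(v) max(v) - min(v), numeric(1)))
  )
  per_sample$whisker_low <- per_sample$q1 - 1.5 * (per_sample$q3 - per_sample$q1)
  per_sample$whisker_high <- per_sample$q3 + 1.5 * (per_sample$q3 - per_sample$q1)

  structure(
    list(
      per_sample = per_sample,
      mean_range = mean(per_sample$range),
      sd_range = sd(per_sample$range)
    ),
    class = "score_summary"
  )
}

#' @describeIn score_distribution_summary Per-sample quartile table.
#' @method tidy score_summary
#' @param x A `score_summary`.
#' @param ... Unused.
#' @export
tidy.score_summary <- function(x, ...) x$per_sample

#' @describeIn score_distribution_summary One-row dataset-level summary.
#' @method glance score_summary
#' @export
glance.score_summary <- function(x, ...) {
  tibble(
    n_samples = nrow(x$per_sample),
    mean_range = x$mean_range,
    sd_range = x$sd_range
  )
}

#' @export
print.score_summary <- function(x, ...) {
  cat(sprintf(
    "<score_summary> %d samples; mean max-min score range %.4f (sd %.4f)\n",
    nrow(x$per_sample), x$mean_range, x$sd_range
  ))
  invisible(x)
}
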