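# Per-slice segmentation evaluation against ground truth: pixel confusion
# counts and the SEN/SPE/PPV/NPV/DSC metric set with stack-level mean +- SD.

#' Pixel confusion counts for one slice
#'
#' "Positive" is the network label (pixel value 1): TP = gt 1 & seg 1,
#' TN = gt 0 & seg 0, FP = gt 0 & seg 1, FN = gt 1 & seg 0.
#'
#' @param gt_slice,seg_slice 2D binary matrices of identical shape.
#' @return Integer vector `c(n_tp, n_tn, n_fp, n_fn)`; the four counts sum
#'   to the pixel count of the slice.
#' @export
confusion_counts <- function(gt_slice, seg_slice) {
  if (!identical(dim(gt_slice), dim(seg_slice)))
    stop_ctx("gt and seg slices differ in shape")
  if (!all(gt_slice == 0 | gt_slice == 1) ||
      !all(seg_slice == 0 | seg_slice == 1))
    stop_ctx("slices must be binary")
  c(n_tp = sum(gt_slice == 1 & seg_slice == 1),
    n_tn = sum(gt_slice == 0 & seg_slice == 0),
    n_fp = sum(gt_slice == 0 & seg_slice == 1),
    n_fn = sum(gt_slice == 1 & seg_slice == 0))
}

#' Evaluation metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)` (completeness of the network label),
#' specificity `TN/(TN+FP)` (completeness of the background label),
#' positive and negative predictive values, and the Dice similarity
#' coefficient `2TP/(2TP+FP+FN)`. A metric whose denominator is zero is
#' `NA` (undefined for that slice) rather than imputed.
#'
#' @param counts output of [confusion_counts()].
#' @return Named numeric vector `c(sen, spe, ppv, npv, dsc)` with values
#'   in `[0, 1]` or `NA`.
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts[["n_tp"]]; tn <- counts[["n_tn"]]
  fp <- counts[["n_fp"]]; fn <- counts[["n_fn"]]
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  c(sen = ratio(tp, tp + fn),
    spe = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    dsc = ratio(2 * tp, 2 * tp + fp + fn))
}

#' Evaluate a segmentation stack against ground truth
#'
#' Computes the metric set slice by slice and aggregates with the
#' arithmetic mean and sample SD over the slices where each metric is
#' defined; undefined slices are excluded from the average (not imputed as
#' 0 or 1), and their count is reported per metric via `n_valid`.
#'
#' @param gt,seg binary [voxel_volume()]s of identical shape (ground truth
#'   and segmentation).
#' @return A `seg_metrics` object: `per_slice` data frame (slice, counts,
#'   metrics) and `summary` data frame (metric, mean, sd, n_valid).
#' @export
evaluate_stack <- function(gt, seg) {
  assert_binary(gt, "gt")
  assert_binary(seg, "seg")
  if (!identical(dim(gt$data), dim(seg$data)))
    stop_ctx("gt and seg volumes differ in shape")
  nz <- dim(gt$data)[1]
  if (nz == 0L) stop_ctx("empty stack")
  rows <- lapply(seq_len(nz), function(z) {
    cc <- confusion_counts(gt$data[z, , ], seg$data[z, , ])
    m <- metrics_from_counts(cc)
    data.frame(slice = z, t(cc), t(m))
  })
  per <- do.call(rbind, rows)
  metrics <- c("sen", "spe", "ppv", "npv", "dsc")
  summary <- do.call(rbind, lapply(metrics, function(q) {
    v <- per[[q]]
    ok <- !is.na(v)
    data.frame(metric = q,
               mean = if (any(ok)) mean(v[ok]) else NA_real_,
               sd = if (sum(ok) > 1L) sd(v[ok]) else 0,
               n_valid = sum(ok))
  }))
  structure(list(per_slice = per, summary = summary),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("<seg_metrics> %d slices\n", nrow(x$per_slice)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s = %.4f (SD %.4f, n = %d)\n",
                toupper(s$metric[i]), s$mean[i], s$sd[i], s$n_valid[i]))
  invisible(x)
}

#' Write per-slice segmentation metrics as CSV
#'
#' One row per slice plus mean/SD/n_valid summary rows.
#'
#' @param metrics a `seg_metrics` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segeval_csv <- function(metrics, path) {
  stopifnot(inherits(metrics, "seg_metrics"))
  per <- metrics$per_slice
  per$row_type <- "slice"
  s <- metrics$summary
  mk <- function(stat) {
    r <- per[1, , drop = FALSE]
    r[] <- NA
    r$row_type <- stat
    for (q in s$metric) r[[q]] <- s[[stat]][s$metric == q]
    r
  }
  utils::write.csv(rbind(per, mk("mean"), mk("sd")), path,
                   row.names = FALSE)
  invisible(path)
}
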