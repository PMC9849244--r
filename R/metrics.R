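# ---------------------------------------------------------------------------
# Evaluation metrics: pixel confusion counts and the DIC/JAC/ACC/SEN/SPE
# report used for ISIC-style binary segmentation.
# ---------------------------------------------------------------------------

#' Pixelwise confusion counts
#'
#' @param pred Binary prediction mask.
#' @param gt Binary ground-truth mask of the same shape.
#' @return List with integer fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) {
    stop("prediction and ground truth shapes differ")
  }
  check_binary(pred)
  check_binary(gt)
  tp <- sum(pred == 1 & gt == 1)
  fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  tn <- sum(pred == 0 & gt == 0)
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

safe_ratio <- function(num, den, agree) {
  if (den == 0) return(if (agree) 1 else 0)
  num / den
}

#' Segmentation metrics from confusion counts
#'
#' Dice `2tp/(2tp+fp+fn)`, Jaccard `tp/(tp+fp+fn)`, accuracy, sensitivity
#' and specificity. When a reference class is empty the metric is 1 if the
#' prediction agrees (no opposing errors) and 0 otherwise.
#'
#' @param c Counts from [confusion()].
#' @return One-row tibble with columns `DIC`, `JAC`, `ACC`, `SEN`, `SPE`.
#' @export
metric_report <- function(c) {
  total <- c$tp + c$fp + c$tn + c$fn
  tibble::tibble(
    DIC = safe_ratio(2 * c$tp, 2 * c$tp + c$fp + c$fn, c$fp == 0 && c$fn == 0),
    JAC = safe_ratio(c$tp, c$tp + c$fp + c$fn, c$fp == 0 && c$fn == 0),
    ACC = safe_ratio(c$tp + c$tn, total, TRUE),
    SEN = safe_ratio(c$tp, c$tp + c$fn, c$fp == 0),
    SPE = safe_ratio(c$tn, c$tn + c$fp, c$fn == 0))
}

#' Metrics for a set of predictions
#'
#' @param preds List of binary masks.
#' @param gts List of matching ground-truth masks.
#' @param ids Character ids, one per pair.
#' @param pooled If `TRUE`, also compute metrics from the pooled confusion
#'   counts; the summary row is otherwise the per-image mean (the ISIC
#'   reporting convention).
#' @return List with `per_image` (tibble, one row per id) and `summary`
#'   (one-row tibble of means, plus pooled rows when requested).
#' @export
metric_table <- function(preds, gts, ids = NULL, pooled = FALSE) {
  n <- length(preds)
  ids <- ids %||% sprintf("img_%03d", seq_len(n))
  rows <- vector("list", n)
  pool <- list(tp = 0, fp = 0, tn = 0, fn = 0)
  for (i in seq_len(n)) {
    cc <- confusion(preds[[i]], gts[[i]])
    rows[[i]] <- cbind(tibble::tibble(id = ids[[i]]), metric_report(cc))
    for (f in names(pool)) pool[[f]] <- pool[[f]] + cc[[f]]
  }
  per_image <- do.call(rbind, rows)
  summary <- cbind(tibble::tibble(id = "mean"),
                   tibble::as_tibble(as.list(colMeans(per_image[, -1]))))
  if (pooled) {
    summary <- rbind(summary, cbind(tibble::tibble(id = "pooled"),
                                    metric_report(pool)))
  }
  list(per_image = per_image, summary = summary)
}
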