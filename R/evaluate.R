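#' Pixel-wise multiclass confusion matrix
#'
#' Cross-tabulates ground-truth against predicted class over every
#' evaluated position: `counts[i, j]` is the number of pixels with truth
#' class `i` predicted as class `j` (ground truth on rows, following the
#' usual heat-matrix convention). Ground-truth positions carrying the
#' unannotated sentinel are excluded — evaluation, like training, only
#' uses annotated pixels.
#'
#' When the masks sit on different grids (full-resolution truth vs 8x
#' prediction), they are aligned first: by default the truth is
#' majority-downsampled to the prediction grid (consistent with how the
#' model was trained); alternatively the prediction can be
#' nearest-neighbour upsampled, which counts each predicted position 64
#' times.
#'
#' @param gt Ground-truth [label_mask()].
#' @param pred Predicted [label_mask()].
#' @param schema A [class_schema()].
#' @param align `"downsample_gt"` (default) or `"upsample_pred"`.
#' @return A `confusion_matrix`: K x K integer matrix with class names on
#'   both dimensions.
#' @export
confusion_matrix <- function(gt, pred, schema = default_class_schema(),
                             align = c("downsample_gt", "upsample_pred")) {
  align <- match.arg(align)
  if (gt$downsample_factor != pred$downsample_factor) {
    if (gt$downsample_factor == 1L && pred$downsample_factor == 8L) {
      if (align == "downsample_gt") {
        gt <- downsample_mask(gt, 8L, schema)
      } else {
        pred <- upsample_mask(pred, 8L)
        d <- dim(gt)
        pred$labels <- pred$labels[seq_len(d[1]), seq_len(d[2]),
                                   drop = FALSE]
      }
    } else {
      stop("cannot align masks with factors ",
           gt$downsample_factor, " and ", pred$downsample_factor)
    }
  }
  if (!identical(dim(gt), dim(pred))) stop("mask grids differ in size")
  K <- n_classes(schema)
  g <- as.vector(gt$labels); p <- as.vector(pred$labels)
  keep <- g != unannotated_id()
  g <- g[keep]; p <- p[keep]
  p[p == unannotated_id()] <- NA_integer_
  keep2 <- !is.na(p)
  cm <- matrix(tabulate(g[keep2] * K + p[keep2] + 1L, nbins = K * K),
               K, K, byrow = TRUE)
  dimnames(cm) <- list(truth = schema$name, predicted = schema$name)
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Row-normalize a confusion matrix to percentages
#'
#' Each row (ground-truth class) is expressed as percentages of its total,
#' the convention of heat-styled confusion matrices ("x% of all pixels
#' labelled as class i were classified as class j"). Rows with no
#' ground-truth pixels are returned as `NA` (undefined), never as zeros.
#'
#' @param cm A [confusion_matrix()] (or plain K x K count matrix).
#' @return K x K numeric matrix; each defined row sums to 100.
#' @export
row_normalize <- function(cm) {
  m <- unclass(cm)
  totals <- rowSums(m)
  out <- m / totals * 100
  out[totals == 0, ] <- NA_real_
  out
}

#' F1 from a precision/recall pair
#'
#' The harmonic mean `2 * P * R / (P + R)`; undefined (NA) when either is
#' undefined or both are zero.
#'
#' @param precision,recall Numeric vectors in `[0, 1]`.
#' @return Numeric vector of F1 values.
#' @examples
#' f1_score(0.94, 0.85)  # 0.89 to 2 d.p. (tubular necrosis)
#' f1_score(0.87, 0.70)  # 0.78 to 2 d.p. (intratubular casts)
#' @export
f1_score <- function(precision, recall) {
  out <- 2 * precision * recall / (precision + recall)
  out[!is.na(precision) & !is.na(recall) & precision + recall == 0] <- NA_real_
  out
}

#' Per-class precision, recall, specificity and F1
#'
#' One-vs-rest TP/FP/FN/TN are read off the confusion matrix for each
#' class and converted with `Precision = TP / (TP + FP)`,
#' `Recall = TP / (TP + FN)`, `Specificity = TN / (TN + FP)` and
#' `F1 = 2PR / (P + R) = 2TP / (2TP + FP + FN)`. Zero denominators yield
#' `NA` (undefined), which summaries must skip rather than propagate.
#'
#' @param cm A [confusion_matrix()].
#' @return A `class_metrics` data frame: one row per class with columns
#'   `class`, `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `specificity`, `f1`.
#' @export
class_metrics <- function(cm) {
  m <- unclass(cm)
  K <- nrow(m)
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(K) - 1L)
  total <- sum(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- total - tp - fp - fn
  div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  specificity <- div(tn, tn + fp)
  f1 <- div(2 * tp, 2 * tp + fp + fn)
  structure(
    data.frame(class = rownames(m), tp = tp, fp = fp, fn = fn, tn = tn,
               precision = precision, recall = recall,
               specificity = specificity, f1 = f1, row.names = NULL),
    class = c("class_metrics", "data.frame")
  )
}

#' Macro and pixel-weighted summary of class metrics
#'
#' Macro averages are unweighted means over the classes where the metric
#' is defined; weighted averages weight each defined class by its
#' ground-truth pixel count. Both are reported because either aggregation
#' convention is found in practice.
#'
#' @param metrics A [class_metrics()] data frame.
#' @param cm The matching [confusion_matrix()] (for ground-truth weights).
#' @return A data frame with rows `macro` and `weighted` and columns
#'   `precision`, `recall`, `f1`.
#' @export
macro_summary <- function(metrics, cm) {
  weights <- rowSums(unclass(cm))
  agg <- function(v) {
    ok <- !is.na(v)
    if (!any(ok)) stop("all classes undefined")
    c(macro = mean(v[ok]),
      weighted = sum(v[ok] * weights[ok]) / sum(weights[ok]))
  }
  out <- data.frame(
    precision = agg(metrics$precision),
    recall = agg(metrics$recall),
    f1 = agg(metrics$f1)
  )
  rownames(out) <- c("macro", "weighted")
  out
}

#' Write confusion matrix / metrics CSVs
#'
#' `write_confusion_csv()` writes both the raw counts and the
#' row-normalized percentage variant (`path` + `_percent.csv`).
#'
#' @param cm A [confusion_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path)
  pct <- row_normalize(cm)
  utils::write.csv(as.data.frame(pct),
                   sub("\\.csv$", "_percent.csv", path))
  invisible(path)
}

#' @rdname write_confusion_csv
#' @param metrics A [class_metrics()] data frame.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
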