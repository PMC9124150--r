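#' Voxel confusion counts
#'
#' Tallies true/false positive/negative voxels between a binary predicted
#' mask and a binary ground-truth mask of identical shape. The four counts
#' always partition the voxel grid.
#'
#' @param pred,truth binary [label_mask()]s (or plain 0/1 arrays) of
#'   identical shape.
#' @return `list(tp, fp, tn, fn)` of class `"confusion_counts"`.
#' @export
confusion_counts <- function(pred, truth) {
  p <- mask_data(pred); t <- mask_data(truth)
  if (!identical(dim(p), dim(t))) {
    stop("prediction and truth shapes differ", call. = FALSE)
  }
  if (!all(p %in% c(0L, 1L)) || !all(t %in% c(0L, 1L))) {
    stop("confusion counts require binary labels {0, 1}", call. = FALSE)
  }
  tp <- sum(p == 1L & t == 1L)
  fp <- sum(p == 1L & t == 0L)
  fn <- sum(p == 0L & t == 1L)
  tn <- length(p) - tp - fp - fn
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' Overlap metrics from confusion counts
#'
#' Dice `2TP/(2TP+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)`, IOU `TP/(TP+FP+FN)` and voxel
#' accuracy `(TP+TN)/total`. Degenerate denominators follow the
#' perfect-agreement convention: when both masks are empty, Dice, IOU and
#' sensitivity are reported as 1; an undefined precision or specificity is
#' likewise 1 when its numerator condition is vacuously satisfied.
#'
#' @param c a [confusion_counts()] result.
#' @return Named list with `dsc`, `sensitivity`, `specificity`,
#'   `precision`, `iou`, `accuracy`.
#' @export
metrics_from_counts <- function(c) {
  stopifnot(all(unlist(c) >= 0))
  sdiv <- function(num, den) if (den == 0) 1 else num / den
  list(dsc = sdiv(2 * c$tp, 2 * c$tp + c$fp + c$fn),
       sensitivity = sdiv(c$tp, c$tp + c$fn),
       specificity = sdiv(c$tn, c$tn + c$fp),
       precision = sdiv(c$tp, c$tp + c$fp),
       iou = sdiv(c$tp, c$tp + c$fp + c$fn),
       accuracy = (c$tp + c$tn) / (c$tp + c$fp + c$tn + c$fn))
}

# Surface voxels: foreground with at least one 6-neighbor background
# (voxels on the array boundary count as surface). Returns an n x 3 matrix
# of physical mm coordinates (voxel centers).
surface_points <- function(mask) {
  m <- mask_data(mask)
  d <- dim(m)
  fg <- m != 0L
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- fg
  interior <-
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  idx <- which(fg & !interior, arr.ind = TRUE)
  sp <- mask_spacing(mask)
  sweep(idx - 1, 2, sp, `*`)
}

#' Hausdorff distance between two masks
#'
#' Maximum of the two directed surface-to-surface distances, in physical
#' mm (surface voxels are foreground voxels with a 6-neighbor background;
#' distances are between voxel centers).
#'
#' @param a,b non-empty binary [label_mask()]s on the same grid.
#' @return Distance in mm; 0 iff the surfaces coincide.
#' @export
hausdorff_distance <- function(a, b) {
  sa <- surface_points(a); sb <- surface_points(b)
  if (nrow(sa) == 0 || nrow(sb) == 0) {
    stop("Hausdorff distance is undefined for an empty mask", call. = FALSE)
  }
  max(max(cpp_min_dists(sa, sb)), max(cpp_min_dists(sb, sa)))
}

#' Normalized surface distance
#'
#' Symmetric fraction of the two segmentation surfaces lying within a
#' tolerance of the other surface:
#' `(|S_pred within tau of S_truth| + |S_truth within tau of S_pred|) /
#'  (|S_pred| + |S_truth|)`.
#'
#' @param pred,truth binary [label_mask()]s on the same grid.
#' @param tolerance_mm non-negative tolerance in mm (default 4).
#' @return Value in \[0, 1\]; 1 when both masks are empty, 0 when exactly
#'   one is.
#' @export
normalized_surface_distance <- function(pred, truth, tolerance_mm = 4) {
  if (tolerance_mm < 0) stop("tolerance must be non-negative", call. = FALSE)
  sp <- surface_points(pred); st <- surface_points(truth)
  if (nrow(sp) == 0 && nrow(st) == 0) return(1)
  if (nrow(sp) == 0 || nrow(st) == 0) return(0)
  hits <- sum(cpp_min_dists(sp, st) <= tolerance_mm) +
          sum(cpp_min_dists(st, sp) <= tolerance_mm)
  hits / (nrow(sp) + nrow(st))
}

#' Evaluate one segmentation case
#'
#' Composes the full metric report: overlap metrics from the confusion
#' counts, Hausdorff distance and normalized surface distance. When either
#' mask is empty the Hausdorff distance is reported as `NA` and Dice/IOU
#' follow the degenerate conventions of [metrics_from_counts()].
#'
#' @inheritParams normalized_surface_distance
#' @return A list of class `"metric_report"` with fields `dsc`,
#'   `sensitivity`, `specificity`, `precision`, `iou`, `accuracy`,
#'   `hausdorff_mm`, `nsd`.
#' @export
evaluate_case <- function(pred, truth, tolerance_mm = 4) {
  cc <- confusion_counts(pred, truth)
  mt <- metrics_from_counts(cc)
  np <- sum(mask_data(pred) != 0L); nt <- sum(mask_data(truth) != 0L)
  if (np > 0 && nt == 0 || np == 0 && nt > 0) {
    mt$dsc <- 0; mt$iou <- 0
  }
  hd <- if (np > 0 && nt > 0) hausdorff_distance(pred, truth) else NA_real_
  structure(c(mt, list(hausdorff_mm = hd,
                       nsd = normalized_surface_distance(pred, truth,
                                                         tolerance_mm))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "dsc %.4f  iou %.4f  sens %.4f  spec %.4f  prec %.4f  acc %.4f\n",
    x$dsc, x$iou, x$sensitivity, x$specificity, x$precision, x$accuracy))
  cat(sprintf("hausdorff %s mm  nsd %.4f\n",
              if (is.na(x$hausdorff_mm)) "NA" else
                sprintf("%.3f", x$hausdorff_mm), x$nsd))
  invisible(x)
}

mask_data <- function(m) {
  if (inherits(m, "label_mask")) m$data
  else {
    x <- m
    storage.mode(x) <- "integer"
    x
  }
}

mask_spacing <- function(m) {
  if (inherits(m, "label_mask")) m$spacing else c(1, 1, 1)
}
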