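# Per-hemisphere quantitative SN measures: analysis-slice selection,
# thresholded QSM/NMS volumes, NMS contrast range, the QSM-NMS composite, the
# group-difference-maximizing threshold search, an SMWI-based nigrosome-1
# volume, and hemisphere aggregation.

slice_counts <- function(mask, grid) {
  apply(mask, grid$slice_axis, sum)
}

slice_values <- function(volume, region, slices, grid) {
  idx <- slice_indexer(dim(volume), grid$slice_axis, slices)
  v <- volume[idx]; r <- region[idx]
  v[r]
}

slice_indexer <- function(dims, axis, slices) {
  sel <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  sel[[axis]] <- slices
  keep <- array(FALSE, dims)
  do.call(`[<-`, c(list(keep), sel, list(TRUE)))
}

#' Select the three analysis slices from the red nucleus mask
#'
#' Scans cranio-caudally (increasing slice index) starting from the slice of
#' maximal red-nucleus cross-section and returns the first slice where the RN
#' is barely or no longer visible -- per-slice RN voxel count below
#' \code{ceiling(fraction * max count)} -- together with the two consecutive
#' inferior slices.
#'
#' @param rn_mask logical red-nucleus mask (either or both sides).
#' @param grid a \code{\link{voxel_grid}}.
#' @param fraction visibility fraction of the per-slice maximum (default 0.1).
#' @return integer vector of 3 slice indices.
#' @export
select_analysis_slices <- function(rn_mask, grid, fraction = 0.1) {
  counts <- slice_counts(rn_mask, grid)
  if (sum(counts) == 0) stop("geometry error: red nucleus mask is empty")
  thr <- ceiling(fraction * max(counts))
  start <- which.max(counts)
  below <- which(counts < thr)
  below <- below[below > start]
  if (length(below) == 0)
    stop("geometry error: red nucleus never disappears caudally")
  first <- below[1]
  if (first + 2 > n_slices(grid))
    stop("geometry error: fewer than 3 slices inferior to the red nucleus")
  as.integer(first + 0:2)
}

#' Thresholded region volume on the analysis slices
#'
#' Counts region voxels on the selected slices whose image value is below
#' (QSM, low susceptibility) or above (NMS, high neuromelanin) the threshold
#' and converts to mm^3.
#'
#' @param image image volume (QSM in ppb or NMS signal).
#' @param region logical region mask (e.g. one hemisphere's SN).
#' @param slices analysis slice indices.
#' @param threshold threshold in image units.
#' @param direction \code{"below"} or \code{"above"}.
#' @param grid a \code{\link{voxel_grid}}.
#' @return volume in mm^3.
#' @export
thresholded_volume <- function(image, region, slices, threshold,
                               direction = c("below", "above"), grid) {
  direction <- match.arg(direction)
  if (any(slices < 1 | slices > n_slices(grid)))
    stop("index error: slices outside grid")
  v <- slice_values(image, region, slices, grid)
  n <- if (direction == "below") sum(v < threshold) else sum(v > threshold)
  n * voxel_volume(grid)
}

#' Group-difference-maximizing threshold search
#'
#' For each candidate threshold, computes every subject's thresholded volume
#' (count of qualifying region voxels) and the PD-vs-HC AUC of those volumes
#' (lower volume treated as PD-positive); returns the threshold with maximal
#' AUC, ties broken toward the smallest threshold.
#'
#' @param values_per_subject named list: per subject, the numeric vector of
#'   region voxel values on the analysis slices.
#' @param labels character vector ("PD"/"HC"), parallel to the list.
#' @param thresholds numeric grid of candidate thresholds.
#' @param direction \code{"below"} or \code{"above"}.
#' @return object of class \code{threshold_search}: list(threshold,
#'   objective, grid = data.frame(threshold, objective)).
#' @export
optimize_threshold <- function(values_per_subject, labels,
                               thresholds, direction = c("below", "above")) {
  direction <- match.arg(direction)
  if (length(thresholds) == 0) stop("threshold grid must be nonempty")
  if (length(unique(labels)) < 2) stop("both groups must be nonempty")
  thresholds <- sort(thresholds)
  obj <- vapply(thresholds, function(t) {
    vols <- vapply(values_per_subject, function(v) {
      if (direction == "below") sum(v < t) else sum(v > t)
    }, 0)
    auc_trapezoid(roc_curve(vols, labels, orientation = "lower_is_positive"))
  }, 0)
  best <- which.max(obj)
  structure(list(threshold = thresholds[best], objective = obj[best],
                 grid = data.frame(threshold = thresholds, objective = obj)),
            class = "threshold_search")
}

#' NMS contrast range within the SN
#'
#' Ratio of the 90th to the 10th percentile of the NMS signal over the region
#' voxels on the analysis slices, using linear-interpolation percentiles.
#'
#' @param nms NMS signal volume.
#' @param region logical SN mask.
#' @param slices analysis slice indices.
#' @param grid a \code{\link{voxel_grid}}.
#' @return dimensionless ratio.
#' @export
nms_contrast_range <- function(nms, region, slices, grid) {
  v <- slice_values(nms, region, slices, grid)
  if (length(v) < 10) stop("need at least 10 region voxels on the slices")
  p10 <- percentile_linear(v, 0.10)
  if (p10 <= 0) stop("undefined-ratio error: 10th percentile is not positive")
  percentile_linear(v, 0.90) / p10
}

#' QSM-NMS composite score
#'
#' Product of the thresholded QSM-based volume, the thresholded NMS-based
#' volume, and the NMS contrast range. Lower values indicate a higher
#' likelihood of PD.
#'
#' @param qsm_vol,nms_vol volumes in mm^3 (nonnegative).
#' @param contrast NMS contrast range (nonnegative).
#' @return composite score.
#' @export
composite_score <- function(qsm_vol, nms_vol, contrast) {
  if (any(c(qsm_vol, nms_vol, contrast) < 0))
    stop("domain error: composite inputs must be nonnegative")
  qsm_vol * nms_vol * contrast
}

#' SMWI-based nigrosome-1 volume
#'
#' Rule-based N1 volumetry: volume of SN voxels on the analysis slices whose
#' SMWI intensity exceeds \code{rel_threshold} times the slice-wise robust
#' (median) background SMWI level -- i.e. residual hyperintensity within the
#' hypointense SN. The background is taken per slice over positive-signal
#' voxels outside the SN (restricted to \code{background_mask} if given).
#'
#' @param smwi an \code{smwi_volume} or plain volume.
#' @param sn_mask logical SN mask for one hemisphere.
#' @param slices analysis slice indices.
#' @param grid a \code{\link{voxel_grid}}.
#' @param rel_threshold fraction of the background level (default 0.15).
#' @param background_mask optional logical mask of valid background tissue.
#' @return volume in mm^3.
#' @export
n1_volume_smwi <- function(smwi, sn_mask, slices, grid, rel_threshold = 0.15,
                           background_mask = NULL) {
  v <- if (inherits(smwi, "smwi_volume")) smwi$values else smwi
  d <- dim(v)
  n_above <- 0L
  for (s in slices) {
    sel <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    sel[[grid$slice_axis]] <- s
    sl <- do.call(`[`, c(list(v), sel, list(drop = FALSE)))
    sn_sl <- do.call(`[`, c(list(sn_mask), sel, list(drop = FALSE)))
    bg_sl <- !sn_sl & sl > 0
    if (!is.null(background_mask)) {
      bm <- do.call(`[`, c(list(background_mask), sel, list(drop = FALSE)))
      bg_sl <- bg_sl & bm
    }
    if (!any(sn_sl)) next
    if (!any(bg_sl)) stop("no background voxels on analysis slice")
    lvl <- stats::median(sl[bg_sl])
    n_above <- n_above + sum(sl[sn_sl] > rel_threshold * lvl)
  }
  if (!any(slice_indexer(d, grid$slice_axis, slices) & sn_mask))
    stop("empty SN on the analysis slices")
  n_above * voxel_volume(grid)
}

#' Aggregate left/right hemisphere values or ratings
#'
#' Continuous measures are averaged; binary ratings follow the rule that a
#' subject is Normal only if both sides are Normal.
#'
#' @param left,right per-side values (numeric) or ratings
#'   ("Normal"/"Abnormal").
#' @param mode \code{"mean"} or \code{"both_normal"}.
#' @return aggregated value or rating.
#' @export
aggregate_hemispheres <- function(left, right, mode = c("mean", "both_normal")) {
  mode <- match.arg(mode)
  if (is.null(left) || length(left) == 0 || any(is.na(left)))
    stop("missing side: left")
  if (is.null(right) || length(right) == 0 || any(is.na(right)))
    stop("missing side: right")
  if (mode == "mean") {
    (as.numeric(left) + as.numeric(right)) / 2
  } else {
    ifelse(left == "Normal" & right == "Normal", "Normal", "Abnormal")
  }
}
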