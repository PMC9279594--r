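# ---- ROI handling ------------------------------------------------------
# An ROI is a list with a `cell_id` and either
#   rect   = c(row0, col0, row1, col1)  half-open, 0-based, row-major, or
#   pixels = integer matrix of (row, col) pairs, 0-based.
# Internally ROIs become linear pixel indices into the image matrix.

roi_indices <- function(roi, dim) {
  nr <- dim[1]; nc <- dim[2]
  if (!is.null(roi$rect)) {
    r <- roi$rect
    if (length(r) != 4L) abort_input("rect ROI must have 4 entries")
    if (r[1] < 0 || r[2] < 0 || r[3] > nr || r[4] > nc ||
        r[3] <= r[1] || r[4] <= r[2]) {
      abort_input("rect ROI out of image bounds or empty")
    }
    rows <- (r[1] + 1L):r[3]
    cols <- (r[2] + 1L):r[4]
    as.vector(outer(rows, (cols - 1L) * nr, `+`))
  } else if (!is.null(roi$pixels)) {
    px <- roi$pixels
    if (is.null(dim(px))) px <- matrix(px, ncol = 2L, byrow = TRUE)
    px <- matrix(as.integer(round(px)), ncol = 2L,
                 dimnames = NULL) + 0L
    if (nrow(px) == 0L) abort_input("pixel ROI is empty")
    if (any(px[, 1] < 0) || any(px[, 1] >= nr) ||
        any(px[, 2] < 0) || any(px[, 2] >= nc)) {
      abort_input("pixel ROI out of image bounds")
    }
    unique(px[, 1] + 1L + px[, 2] * nr)
  } else {
    abort_input("ROI must have a 'rect' or 'pixels' field")
  }
}

#' Subtract a background estimate from a fluorescence image
#'
#' Subtracts either a scalar background level or a scalar estimate derived
#' from a matched reference image (the median of the reference outside the
#' given ROIs, i.e. its non-nuclear region), clipping negative results to 0.
#'
#' @param image Numeric matrix (the signal channel).
#' @param background A scalar level, or a reference image of the same shape.
#' @param exclude_rois When `background` is a reference image, ROIs (nuclei)
#'   excluded from the background-median estimate.
#' @return The background-subtracted image (clipped at 0).
#' @export
subtract_background <- function(image, background, exclude_rois = NULL) {
  if (!is.matrix(image)) abort_input("image must be a matrix")
  if (is.matrix(background)) {
    if (!all(dim(background) == dim(image))) {
      abort_input("signal and reference images must have the same shape")
    }
    keep <- rep(TRUE, length(background))
    for (roi in exclude_rois %||% list()) {
      keep[roi_indices(roi, dim(image))] <- FALSE
    }
    level <- stats::median(background[keep])
  } else {
    assert_scalar_number(background, "background", lower = 0)
    level <- background
  }
  pmax(image - level, 0)
}

# 8-connected component labeling of a logical mask by iterative flood fill
# over foreground pixels only (spot masks are sparse, so this stays cheap).
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0L) return(labels)
  offsets <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  current <- 0L
  for (seed_px in fg) {
    if (labels[seed_px] != 0L) next
    current <- current + 1L
    stack <- seed_px
    labels[seed_px] <- current
    while (length(stack)) {
      px <- stack[length(stack)]
      stack <- stack[-length(stack)]
      row <- (px - 1L) %% nr + 1L
      nb <- px + offsets
      # mask out neighbours that wrap across the top/bottom edge
      valid <- nb >= 1L & nb <= nr * nc
      if (row == 1L) valid <- valid & !(offsets %in% c(-1L, -nr - 1L, nr - 1L))
      if (row == nr) valid <- valid & !(offsets %in% c(1L, -nr + 1L, nr + 1L))
      nb <- nb[valid]
      nb <- nb[mask[nb] & labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- current
        stack <- c(stack, nb)
      }
    }
  }
  labels
}

#' Detect fluorescent spots within a cell ROI
#'
#' Thresholds the image inside the ROI and reports each 8-connected component
#' of supra-threshold pixels with area at least `min_area` as one spot, with
#' its pixel area and mean intensity.
#'
#' @param image Numeric matrix (background-subtracted signal channel).
#' @param roi A cell ROI (see package ROI conventions); must be non-empty.
#' @param threshold Intensity threshold; pixels strictly above it are
#'   foreground. Default: mean + 3 standard deviations of the ROI pixels, a
#'   conventional bright-spot heuristic.
#' @param min_area Minimum component area in pixels (default 2) to suppress
#'   single-pixel noise.
#' @return A data frame of spot measures: `spot_id`, `cell_id`, `area`,
#'   `mean_intensity`, `integrated` (mean x area).
#' @export
detect_spots <- function(image, roi, threshold = NULL, min_area = 2L) {
  if (!is.matrix(image)) abort_input("image must be a matrix")
  idx <- roi_indices(roi, dim(image))
  vals <- image[idx]
  if (is.null(threshold)) threshold <- mean(vals) + 3 * stats::sd(vals)
  assert_scalar_number(threshold, "threshold", lower = 0,
                       strict_lower = TRUE)
  min_area <- assert_count(min_area, "min_area", lower = 1L)
  mask <- matrix(FALSE, nrow(image), ncol(image))
  mask[idx] <- image[idx] > threshold
  labels <- label_components8(mask)
  ids <- setdiff(unique(labels[labels > 0L]), 0L)
  rows <- list()
  spot_no <- 0L
  for (lab in ids) {
    px <- which(labels == lab)
    if (length(px) < min_area) next
    spot_no <- spot_no + 1L
    rows[[spot_no]] <- data.frame(
      spot_id = sprintf("%s_s%03d", roi$cell_id %||% "cell", spot_no),
      cell_id = roi$cell_id %||% "cell",
      area = length(px),
      mean_intensity = mean(image[px]),
      stringsAsFactors = FALSE)
  }
  if (spot_no == 0L) {
    out <- data.frame(spot_id = character(0), cell_id = character(0),
                      area = integer(0), mean_intensity = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
  }
  out$integrated <- out$mean_intensity * out$area
  out
}

#' Per-cell relative telomere length from spot measures
#'
#' The relative telomere length (RTL) of a cell is the sum over its telomeric
#' spots of mean fluorescence intensity times spot area, in arbitrary units.
#'
#' @param spots Spot-measure data frame (from [detect_spots()]).
#' @param cell_id The cell the spots belong to; mixed cell ids are an error.
#' @return A one-row data frame: `cell_id`, `rtl`, `n_spots`.
#' @export
compute_rtl <- function(spots, cell_id) {
  if (nrow(spots) > 0 && any(spots$cell_id != cell_id)) {
    abort_input("spots from multiple cells passed to compute_rtl")
  }
  data.frame(cell_id = cell_id,
             rtl = if (nrow(spots)) sum(spots$mean_intensity * spots$area) else 0,
             n_spots = nrow(spots), stringsAsFactors = FALSE)
}

#' Corrected total cell fluorescence of a cell ROI
#'
#' The standard CTCF: integrated density over the cell ROI minus the cell
#' area times the mean pixel intensity of the background ROIs. May be
#' negative (cell dimmer than background) and is reported as-is.
#'
#' @param image Numeric matrix.
#' @param cell_roi The cell ROI.
#' @param background_rois A list of background ROIs, disjoint from the cell.
#' @return The CTCF value (arbitrary units).
#' @export
compute_ctcf <- function(image, cell_roi, background_rois) {
  if (!is.matrix(image)) abort_input("image must be a matrix")
  if (!is.null(background_rois$rect) || !is.null(background_rois$pixels)) {
    background_rois <- list(background_rois)
  }
  cell_idx <- roi_indices(cell_roi, dim(image))
  bg_idx <- unique(unlist(lapply(background_rois, roi_indices,
                                 dim = dim(image))))
  if (length(bg_idx) == 0L) abort_input("background ROIs are empty")
  if (length(intersect(cell_idx, bg_idx))) {
    abort_input("background ROIs overlap the cell ROI")
  }
  sum(image[cell_idx]) - length(cell_idx) * mean(image[bg_idx])
}

#' Compare per-cell RTL distributions between conditions
#'
#' Bonferroni multiple range test (all pairwise pooled t-tests at
#' `alpha / n_pairs`) on per-cell RTL values grouped by condition.
#'
#' @param rtl_groups Named list of numeric per-cell RTL vectors, one per
#'   condition (>= 2 conditions, >= 2 cells each).
#' @param alpha Familywise significance level.
#' @return A [multiple_range_bonferroni()] result.
#' @export
compare_rtl_groups <- function(rtl_groups, alpha = 0.05) {
  multiple_range_bonferroni(rtl_groups, alpha = alpha)
}

#' Quantify RTL for every cell in an image
#'
#' Convenience wrapper: runs [detect_spots()] and [compute_rtl()] for each
#' cell ROI of an image.
#'
#' @param image Numeric matrix (background-subtracted).
#' @param rois List of cell ROIs.
#' @inheritParams detect_spots
#' @return A list with `cells` (one [compute_rtl()] row per ROI) and `spots`
#'   (all spot measures).
#' @export
quantify_fish_image <- function(image, rois, threshold = NULL,
                                min_area = 2L) {
  spots <- lapply(rois, function(roi) {
    detect_spots(image, roi, threshold = threshold, min_area = min_area)
  })
  cells <- do.call(rbind, lapply(seq_along(rois), function(i) {
    compute_rtl(spots[[i]], rois[[i]]$cell_id)
  }))
  rownames(cells) <- NULL
  list(cells = cells, spots = do.call(rbind, spots))
}
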