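#' Segment neuronal somata from the cell-marker channel
#'
#' Derives per-neuron regions of interest by thresholding the cell-marker
#' channel, filling holes, and labelling connected components; components
#' below the minimum area are discarded. This stands in for interactively
#' drawn ROIs: per-cell intensity and puncta statistics are computed over
#' these soma masks, and puncta falling outside every ROI are excluded from
#' per-cell endpoints.
#'
#' @param marker_image Single-channel numeric matrix (non-negative).
#' @param pixel_size Pixel size in um/pixel.
#' @param min_area Minimum ROI area in um^2 (must be > 0).
#' @param threshold_policy `"otsu"` (default) for a global Otsu threshold on
#'   the marker histogram, or `"fixed"` to threshold at `threshold_value`.
#' @param threshold_value Absolute intensity threshold when
#'   `threshold_policy = "fixed"`.
#' @return A list with `rois`, a data frame (`cell_id`, `area_um2`,
#'   `centroid_x_um`, `centroid_y_um`, `n_px`) ordered by centroid row then
#'   column, and `labels`, an integer label matrix consistent with it
#'   (0 = background). A blank image yields zero ROIs.
#' @export
segment_cells <- function(marker_image, pixel_size, min_area = 20,
                          threshold_policy = c("otsu", "fixed"),
                          threshold_value = NULL) {
  threshold_policy <- match.arg(threshold_policy)
  if (min_area <= 0) stop("min_area must be > 0")
  if (any(marker_image < 0)) stop("marker image must be non-negative")
  empty <- list(
    rois = data.frame(cell_id = integer(), area_um2 = numeric(),
                      centroid_x_um = numeric(), centroid_y_um = numeric(),
                      n_px = integer()),
    labels = matrix(0L, nrow(marker_image), ncol(marker_image)))
  rng <- range(marker_image)
  if (threshold_policy == "otsu") {
    if (diff(rng) <= 0) return(empty)           # degenerate histogram
    norm <- (marker_image - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- norm > thr
  } else {
    if (is.null(threshold_value))
      stop("threshold_value required for the fixed policy")
    mask <- marker_image > threshold_value
  }
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  lab <- EBImage::bwlabel(mask)
  lab <- as.matrix(EBImage::imageData(lab))
  n_lab <- max(lab)
  if (n_lab == 0) return(empty)

  px <- which(lab > 0)
  id <- lab[px]
  rows <- (px - 1) %% nrow(lab) + 1
  cols <- (px - 1) %/% nrow(lab) + 1
  n_px <- tabulate(id, n_lab)
  min_px <- min_area / pixel_size^2
  keep <- which(n_px >= min_px)
  if (length(keep) == 0) return(empty)
  cy <- tapply(rows, id, mean)[as.character(keep)]
  cx <- tapply(cols, id, mean)[as.character(keep)]
  ord <- order(cy, cx)
  keep <- keep[ord]; cy <- cy[ord]; cx <- cx[ord]

  relabel <- integer(n_lab)
  relabel[keep] <- seq_along(keep)
  out_lab <- matrix(0L, nrow(lab), ncol(lab))
  out_lab[px] <- relabel[id]
  rois <- data.frame(
    cell_id = seq_along(keep),
    area_um2 = n_px[keep] * pixel_size^2,
    centroid_x_um = (cx - 0.5) * pixel_size,
    centroid_y_um = (cy - 0.5) * pixel_size,
    n_px = n_px[keep]
  )
  list(rois = rois, labels = out_lab)
}
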