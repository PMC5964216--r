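#' Mean signal intensity over a region of interest
#'
#' Arithmetic mean of pixel values over an ROI, the per-neuron expression
#' readout. Accepts a logical mask or a label matrix plus cell id.
#'
#' @param image Single-channel numeric matrix.
#' @param roi Logical mask of the ROI, or an integer label matrix (use with
#'   `cell_id`).
#' @param cell_id When `roi` is a label matrix, the label to measure.
#' @return Mean intensity (scalar). Errors on an empty ROI.
#' @export
measure_expression <- function(image, roi, cell_id = NULL) {
  mask <- if (!is.null(cell_id)) roi == cell_id else roi
  if (!any(mask)) stop("empty ROI")
  mean(image[mask])
}

# per-label channel means in one pass; rows ordered by label id
roi_channel_means <- function(image_array, labels) {
  px <- which(labels > 0)
  id <- factor(labels[px])
  n_ch <- dim(image_array)[3]
  out <- vapply(seq_len(n_ch), function(ch) {
    as.numeric(tapply(image_array[, , ch][px], id, mean))
  }, numeric(nlevels(id)))
  out <- matrix(out, nrow = nlevels(id), ncol = n_ch,
                dimnames = list(levels(id), paste0("ch", seq_len(n_ch))))
  out
}

#' Measure every cell in one field
#'
#' Runs the per-field measurement chain: soma segmentation on the cell-marker
#' channel, punctum detection on the adaptor and autophagosome channels,
#' assignment of puncta to cells (puncta over background are excluded),
#' per-cell one-to-one colocalization matching, and per-cell expression
#' means. Expression endpoints are also reported background-corrected
#' (ROI mean minus the median intensity outside all ROIs), which removes the
#' ambient offset so that multiplicative expression changes are recovered as
#' such.
#'
#' @param field A `synthetic_field` (or a list with `image` array and
#'   optional `field_id`, `group`, `region`).
#' @param config The [acquisition_config()] describing channel roles and
#'   pixel size.
#' @param detection A [detection_config()].
#' @param matching A [match_config()].
#' @param min_area Minimum ROI area in um^2 for segmentation.
#' @return A list with `cells` (one row per cell: identifiers, raw and
#'   background-corrected channel means, puncta counts, colocalized count and
#'   percentages), `puncta` (all assigned detections with a `channel_role`
#'   column), `rois` and `labels` from segmentation.
#' @export
measure_field <- function(field, config,
                          detection = detection_config(),
                          matching = match_config(),
                          min_area = 20) {
  ps <- config$pixel_size
  img <- field$image
  ch_m <- config$channel_roles[["cell_marker"]]
  ch_a <- config$channel_roles[["adaptor"]]
  ch_l <- config$channel_roles[["autophagosome"]]
  seg <- segment_cells(img[, , ch_m], ps, min_area = min_area)
  det_a <- detect_puncta(img[, , ch_a], ps, detection)
  det_l <- detect_puncta(img[, , ch_l], ps, detection)
  det_a <- assign_to_cells(det_a, seg$labels)
  det_l <- assign_to_cells(det_l, seg$labels)

  n_cells <- nrow(seg$rois)
  bg_mask <- seg$labels == 0
  meas <- NULL
  if (n_cells > 0) {
    means <- roi_channel_means(img, seg$labels)
    bg_med <- vapply(seq_len(dim(img)[3]),
                     function(ch) stats::median(img[, , ch][bg_mask]),
                     numeric(1))
    rows <- vector("list", n_cells)
    for (k in seq_len(n_cells)) {
      a_k <- det_a[!is.na(det_a$cell_id) & det_a$cell_id == k, , drop = FALSE]
      l_k <- det_l[!is.na(det_l$cell_id) & det_l$cell_id == k, , drop = FALSE]
      pairs <- match_puncta(a_k, l_k, matching)
      prof <- coloc_profile(k, a_k, l_k, pairs)
      rows[[k]] <- cbind(
        data.frame(
          field_id = field$field_id %||% NA_integer_,
          region = field$region %||% NA_character_,
          group = field$group %||% NA_character_,
          cell_id = k,
          area_um2 = seg$rois$area_um2[k],
          mean_marker = means[k, ch_m],
          mean_adaptor = means[k, ch_a],
          mean_autophagosome = means[k, ch_l],
          expr_adaptor = means[k, ch_a] - bg_med[ch_a],
          expr_autophagosome = means[k, ch_l] - bg_med[ch_l]
        ),
        prof[, -1])
    }
    meas <- do.call(rbind, rows)
  }
  det_a$channel_role <- if (nrow(det_a)) "adaptor" else character(0)
  det_l$channel_role <- if (nrow(det_l)) "autophagosome" else character(0)
  puncta <- rbind(det_a, det_l)
  if (nrow(puncta))
    puncta <- cbind(field_id = field$field_id %||% NA_integer_, puncta)
  list(cells = meas, puncta = puncta, rois = seg$rois, labels = seg$labels)
}

#' Measure every cell of a simulated or loaded cohort
#'
#' Applies [measure_field()] across a list of fields and binds the per-cell
#' measurement rows into the flat cell-measurement table used by the group
#' statistics.
#'
#' @param cohort A list with `fields` as produced by [generate_cohort()], or
#'   a bare list of fields.
#' @param config,detection,matching,min_area Passed to [measure_field()].
#' @return A data frame, one row per measured cell.
#' @export
measure_cohort <- function(cohort, config,
                           detection = detection_config(),
                           matching = match_config(),
                           min_area = 20) {
  fields <- cohort$fields %||% cohort
  out <- lapply(fields, function(f)
    measure_field(f, config, detection, matching, min_area)$cells)
  do.call(rbind, out)
}

#' Group summary (mean and standard error) for one endpoint
#'
#' @param measurements Cell-measurement data frame.
#' @param endpoint Name of the endpoint column.
#' @param by Grouping columns (default region and group).
#' @return Data frame with `n_cells`, `mean`, `sem` per group; `sem` uses the
#'   sample standard deviation (n - 1). Undefined (NA) entries are excluded
#'   with `n_cells` adjusted. Errors if any group has fewer than 2 defined
#'   values.
#' @export
summarize_group <- function(measurements, endpoint, by = c("region", "group")) {
  v <- measurements[[endpoint]]
  if (is.null(v)) stop("unknown endpoint: ", endpoint)
  keep <- !is.na(v)
  key <- interaction(measurements[by], drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_along(v)[keep], droplevels(key[keep])),
    function(i) {
      if (length(i) < 2)
        stop("fewer than 2 defined values for endpoint ", endpoint)
      data.frame(measurements[i[1], by, drop = FALSE],
                 endpoint = endpoint, n_cells = length(i),
                 mean = mean(v[i]), sem = stats::sd(v[i]) / sqrt(length(i)))
    }))
  rownames(out) <- NULL
  out
}

#' Express group summaries relative to the control group
#'
#' Sets `relative_mean = 100 * group mean / control mean` per region and
#' endpoint (so the control is 100%), the convention for expression
#' endpoints. Also returns per-cell values on the relative scale when the
#' measurement table is supplied, so that group statistics can run on
#' relative values.
#'
#' @param summaries Output of [summarize_group()] (possibly several endpoints
#'   bound together).
#' @param control_label The control group label.
#' @param measurements Optional cell-measurement table; when given, a
#'   `relative` column per cell is returned as attribute `"per_cell"`.
#' @return `summaries` with a `relative_mean` column. Errors if a control
#'   mean is zero or the control group is absent for some region/endpoint.
#' @export
normalize_to_control <- function(summaries, control_label, measurements = NULL) {
  key <- interaction(summaries$region, summaries$endpoint, drop = TRUE)
  out <- lapply(split(summaries, key), function(s) {
    ctrl <- s$mean[s$group == control_label]
    if (length(ctrl) != 1) stop("control group missing for ", s$endpoint[1],
                                " in region ", s$region[1])
    if (ctrl == 0) stop("control mean is zero for ", s$endpoint[1])
    s$relative_mean <- 100 * s$mean / ctrl
    s
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!is.null(measurements)) {
    per_cell <- measurements
    for (ep in unique(summaries$endpoint)) {
      rel_col <- paste0("rel_", ep)
      per_cell[[rel_col]] <- NA_real_
      for (r in unique(summaries$region)) {
        ctrl <- summaries$mean[summaries$region == r & summaries$endpoint == ep &
                                 summaries$group == control_label]
        i <- per_cell$region == r
        per_cell[[rel_col]][i] <- 100 * per_cell[[ep]][i] / ctrl
      }
    }
    attr(out, "per_cell") <- per_cell
  }
  out
}
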