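#' Detection configuration for bright circular puncta
#'
#' Parameters of the multi-scale Laplacian-of-Gaussian punctum detector. The
#' diameter window defaults to the 0.5-2.0 um range used for autophagosome
#' and cargo-adaptor puncta.
#'
#' @param diameter_min,diameter_max Retained punctum diameter bounds in um
#'   (full width at half maximum); `0 < diameter_min < diameter_max`.
#' @param n_scales Number of geometrically spaced detection scales spanning
#'   the diameter window.
#' @param relative_threshold Fraction of the background-subtracted dynamic
#'   range that a candidate's peak must exceed above local background;
#'   in (0, 1).
#' @param circularity_min Minimum circularity of the half-max support of the
#'   blob response, in (0, 1], computed as the minor/major equivalent-ellipse
#'   axis ratio (1 for an ideal disk).
#' @param blobness_min Minimum curvature isotropy of the response surface at
#'   the candidate peak (`sqrt(lambda_min/lambda_max)` of the Hessian), in
#'   `[0, 1)`; rejects ridge and edge structure such as soma rims.
#' @param diameter_tol Relative slack on the diameter gate absorbing
#'   scale-grid discretization of the diameter estimate (default 2%).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(diameter_min = 0.5, diameter_max = 2.0,
                             n_scales = 4L, relative_threshold = 0.2,
                             circularity_min = 0.7, blobness_min = 0.55,
                             diameter_tol = 0.02) {
  if (!(diameter_min > 0 && diameter_min < diameter_max))
    stop("need 0 < diameter_min < diameter_max")
  if (!(relative_threshold > 0 && relative_threshold < 1))
    stop("relative_threshold must be in (0, 1)")
  if (!(circularity_min > 0 && circularity_min <= 1))
    stop("circularity_min must be in (0, 1]")
  if (n_scales < 2) stop("need at least 2 detection scales")
  if (blobness_min < 0 || blobness_min >= 1)
    stop("blobness_min must be in [0, 1)")
  structure(list(diameter_min = diameter_min, diameter_max = diameter_max,
                 n_scales = as.integer(n_scales),
                 relative_threshold = relative_threshold,
                 circularity_min = circularity_min,
                 blobness_min = blobness_min,
                 diameter_tol = diameter_tol),
            class = "detection_config")
}

# FWHM <-> Gaussian sigma
fwhm_to_sigma <- function(d) d / (2 * sqrt(2 * log(2)))
sigma_to_fwhm <- function(s) s * 2 * sqrt(2 * log(2))

# Local background: median filter with window ~ 3 * diameter_max, evaluated
# on a block-mean downsampled copy (the background varies on the soma scale,
# far coarser than the downsampling) and re-expanded by nearest neighbour.
local_background <- function(img, window_px, downsample = 4L) {
  nr <- nrow(img); nc <- ncol(img)
  ds <- max(1L, as.integer(downsample))
  nr2 <- nr %/% ds; nc2 <- nc %/% ds
  if (nr2 < 3 || nc2 < 3) ds <- 1L
  if (ds > 1L) {
    nr2 <- nr %/% ds; nc2 <- nc %/% ds
    cropped <- img[seq_len(nr2 * ds), seq_len(nc2 * ds), drop = FALSE]
    ri <- (seq_len(nr2 * ds) - 1L) %/% ds + 1L
    tmp <- rowsum(cropped, ri) / ds                       # collapse rows
    ci <- (seq_len(nc2 * ds) - 1L) %/% ds + 1L
    small <- t(rowsum(t(tmp), ci) / ds)                   # collapse cols
  } else {
    small <- img
    nr2 <- nr; nc2 <- nc
  }
  radius <- max(1L, as.integer(round(window_px / ds / 2)))
  radius <- min(radius, nr2 %/% 2 - 1L, nc2 %/% 2 - 1L)
  if (radius < 1L) return(matrix(stats::median(img), nr, nc))
  mx <- max(small)
  med <- if (mx > 0) {
    as.matrix(EBImage::imageData(
      EBImage::medianFilter(EBImage::Image(small / mx), radius))) * mx
  } else small
  med[pmin((seq_len(nr) - 1L) %/% ds + 1L, nr2),
      pmin((seq_len(nc) - 1L) %/% ds + 1L, nc2), drop = FALSE]
}

# Curvature isotropy of the response surface at a candidate peak, from a
# finite-difference Hessian at step h: sqrt(lambda_min/lambda_max) of the
# (negative-definite) Hessian, 1 for an isotropic peak, ~0 along a ridge.
# Complements the support-shape test: it is evaluated on the untrimmed
# response surface, so soma-edge ridges score low even where watershed
# trimming makes their supports look compact.
hessian_blobness <- function(R, pr, pc, h) {
  nr <- nrow(R); nc <- ncol(R)
  if (pr - h < 1 || pr + h > nr || pc - h < 1 || pc + h > nc) return(0)
  Hyy <- R[pr - h, pc] - 2 * R[pr, pc] + R[pr + h, pc]
  Hxx <- R[pr, pc - h] - 2 * R[pr, pc] + R[pr, pc + h]
  Hxy <- (R[pr - h, pc - h] + R[pr + h, pc + h] -
            R[pr - h, pc + h] - R[pr + h, pc - h]) / 4
  tr2 <- (Hxx + Hyy) / 2
  disc <- sqrt(((Hxx - Hyy) / 2)^2 + Hxy^2)
  l1 <- tr2 - disc; l2 <- tr2 + disc        # l1 is the most negative
  if (l2 >= 0 || l1 >= 0) return(0)
  sqrt(l2 / l1)
}

# Invert the ideal Gaussian-blob scale response R(x) = c * x0 * x / (x + x0)^2
# (x = sigma^2) from responses at two scales; exact for an ideal spot.
# Returns sigma^2 estimate or NA when degenerate.
invert_blob_scale <- function(R1, x1, R2, x2) {
  if (!is.finite(R1) || !is.finite(R2) || R1 <= 0 || R2 <= 0) return(NA_real_)
  rho <- sqrt((R1 / R2) * (x2 / x1))
  if (abs(rho - 1) < 1e-9) return(NA_real_)
  x0 <- (x2 - rho * x1) / (rho - 1)
  if (!is.finite(x0) || x0 <= 0) NA_real_ else x0
}

# Circularity and centroid of the half-max support around a detection peak,
# computed on the scale-normalized LoG response at the detection scale: the
# response's positive lobe is local-background-free and noise-suppressed, is
# compact and round for circular blobs, and elongates along ridges and soma
# edges. Flood fill from the peak at 65% of the peak response (an inner
# support that stays clear of neighbouring lobes), restricted to the peak's
# Voronoi cell among same-scale candidates so adjacent lobes do not merge.
# Supports reaching the window border are ridge/edge structure, not puncta,
# and are rejected. The circularity is the minor/major equivalent-ellipse
# axis ratio of the response-weighted support (1 for a disk), which is
# stable against boundary raggedness where perimeter estimates are not.
# Compiled kernel; returns NULL for degenerate or border-reaching supports.
support_stats <- function(respmat, pr, pc, win, peers = NULL) {
  if (is.null(peers)) peers <- matrix(0L, 0L, 2L)
  storage.mode(peers) <- "integer"
  out <- .support_moments(respmat, as.integer(pr), as.integer(pc),
                          as.integer(win), peers, 0.65)
  if (out[1] < 0) return(NULL)
  list(area = out[1], circularity = out[2], cy = out[3], cx = out[4])
}

#' Detect bright circular puncta in a single channel
#'
#' Multi-scale Laplacian-of-Gaussian blob detection of bright, circular
#' objects with full-width-at-half-maximum diameters inside a configured
#' window. Candidates are scale-space response maxima; each kept candidate
#' exceeds the relative threshold above a median-filtered local background,
#' has an estimated diameter inside the window, and passes two roundness
#' gates (curvature isotropy of the response surface and axis ratio of the
#' response lobe's support). Overlapping candidates are resolved by keeping
#' the stronger scale-normalized response, with a response-valley test
#' separating genuine close pairs from cross-scale duplicates (ties by
#' smaller row, then column). The detector is invariant to rescaling the
#' image intensities.
#'
#' Scales are geometrically spaced with `sigma = d / (2*sqrt(2*log 2))`
#' (the FWHM convention matching the measured "diameter" of a
#' diffraction-limited punctum); the diameter estimate refines the best
#' scale by inverting the ideal Gaussian-blob response ratio at the two
#' strongest scales, so sizes just outside the window are rejected even
#' though the scale grid only spans the window itself.
#'
#' @param channel_image Single-channel numeric matrix.
#' @param pixel_size Pixel size in um/pixel; the minimum diameter must span
#'   at least 3 pixels.
#' @param config A [detection_config()].
#' @return A data frame of puncta ordered by (row, col): `punctum_id`,
#'   `x_um`, `y_um`, `diameter_um`, `peak_intensity`, `response`,
#'   `circularity`, `row`, `col`, and `cell_id` (NA until
#'   [assign_to_cells()]). Zero rows when nothing qualifies.
#' @export
detect_puncta <- function(channel_image, pixel_size, config = detection_config()) {
  stopifnot(inherits(config, "detection_config"))
  if (pixel_size > config$diameter_min / 3)
    stop("pixel_size ", pixel_size, " um too coarse: minimum resolvable ",
         "diameter is ", 3 * pixel_size,
         " um (diameter_min must span >= 3 pixels)")
  empty <- data.frame(punctum_id = integer(), x_um = numeric(), y_um = numeric(),
                      diameter_um = numeric(), peak_intensity = numeric(),
                      response = numeric(), circularity = numeric(),
                      row = integer(), col = integer(), cell_id = integer())
  img <- channel_image
  nr <- nrow(img); nc <- ncol(img)

  win_px <- 3 * config$diameter_max / pixel_size
  bg <- local_background(img, win_px)
  bgsub <- img - bg
  D <- max(bgsub)
  if (!is.finite(D) || D <= 0) return(empty)
  thr_abs <- config$relative_threshold * D

  sig_um <- exp(seq(log(fwhm_to_sigma(config$diameter_min)),
                    log(fwhm_to_sigma(config$diameter_max)),
                    length.out = config$n_scales))
  sig_px <- sig_um / pixel_size
  w2 <- freq_grid_sq(nr, nc)
  resp <- fft_log_stack(bgsub, sig_px, w2)

  # candidates: spatial 8-neighbourhood response maxima per scale (the
  # cross-scale redundancy is resolved later by overlap suppression, which
  # is robust to noise jitter between adjacent scales)
  c_scale <- integer(0); c_idx <- integer(0); c_resp <- numeric(0)
  for (s in seq_along(sig_px)) {
    mx <- local_maxima_8(resp[[s]])
    mx <- mx & (resp[[s]] > 0) & (bgsub >= thr_abs)
    idx <- which(mx)
    if (length(idx)) {
      c_scale <- c(c_scale, rep.int(s, length(idx)))
      c_idx <- c(c_idx, idx)
      c_resp <- c(c_resp, resp[[s]][idx])
    }
  }
  if (!length(c_idx)) return(empty)
  # collapse duplicates of the same pixel found at several scales
  o <- order(c_idx, -c_resp)
  o <- o[!duplicated(c_idx[o])]
  c_scale <- c_scale[o]; c_idx <- c_idx[o]; c_resp <- c_resp[o]
  c_row <- (c_idx - 1L) %% nr + 1L
  c_col <- (c_idx - 1L) %/% nr + 1L

  x2v <- sig_px^2
  n_cand <- length(c_idx)
  k_ok <- logical(n_cand)
  k_cy <- k_cx <- k_d <- k_circ <- numeric(n_cand)
  n_sc <- length(sig_px)
  for (k in seq_len(n_cand)) {
    s <- c_scale[k]; pr <- c_row[k]; pc <- c_col[k]
    Rs <- vapply(resp, function(m) m[pr, pc], numeric(1))
    nb <- c(s - 1L, s + 1L)
    nb <- nb[nb >= 1L & nb <= n_sc]
    j <- nb[which.max(Rs[nb])]
    x0 <- invert_blob_scale(Rs[s], x2v[s], Rs[j], x2v[j])
    if (is.na(x0)) next      # no coherent blob-scale response: not a punctum
    d_est <- sigma_to_fwhm(sqrt(x0)) * pixel_size
    if (d_est < config$diameter_min * (1 - config$diameter_tol) ||
        d_est > config$diameter_max * (1 + config$diameter_tol)) next
    h <- max(1L, as.integer(round(sig_px[s])))
    if (hessian_blobness(resp[[s]], pr, pc, h) < config$blobness_min) next
    win <- max(3L, as.integer(ceiling(d_est / pixel_size)) + 4L)
    same <- which(c_scale == s & c_idx != c_idx[k] &
                    abs(c_row - pr) <= win & abs(c_col - pc) <= win)
    peers <- cbind(c_row[same], c_col[same])
    ss <- support_stats(resp[[s]], pr, pc, win, peers)
    if (is.null(ss) || ss$circularity < config$circularity_min) next
    k_ok[k] <- TRUE
    k_cy[k] <- ss$cy; k_cx[k] <- ss$cx
    k_d[k] <- d_est; k_circ[k] <- ss$circularity
  }
  if (!any(k_ok)) return(empty)
  ki <- which(k_ok)
  k_row <- c_row[ki]; k_col <- c_col[ki]; k_scale <- c_scale[ki]
  k_resp <- c_resp[ki]
  k_cy <- k_cy[ki]; k_cx <- k_cx[ki]; k_d <- k_d[ki]; k_circ <- k_circ[ki]

  # resolve overlaps: stronger response wins, with the response further
  # normalized by the candidate's scale so that two resolved fine-scale
  # peaks outrank the single merged coarse-scale response of a close pair;
  # ties by (row, col). Candidates very close to an accepted one are
  # duplicates outright; at moderate overlap a valley test on the response
  # surface decides - two real spots show a dip between their peaks,
  # cross-scale duplicates of one spot do not.
  ord <- order(-(k_resp / fwhm_to_sigma(k_d)), k_row, k_col)
  k_row <- k_row[ord]; k_col <- k_col[ord]; k_scale <- k_scale[ord]
  k_resp <- k_resp[ord]; k_cy <- k_cy[ord]; k_cx <- k_cx[ord]
  k_d <- k_d[ord]; k_circ <- k_circ[ord]
  acc <- integer(0)
  for (i in seq_along(k_row)) {
    clash <- FALSE
    if (length(acc)) {
      d2 <- (k_cy[acc] - k_cy[i])^2 + (k_cx[acc] - k_cx[i])^2
      lim_hard <- pmax(0.3 * pmin(k_d[acc], k_d[i]), config$diameter_min / 2) /
        pixel_size
      if (any(d2 < lim_hard^2)) {
        clash <- TRUE
      } else {
        lim_soft <- (0.5 * pmax(k_d[acc], k_d[i])) / pixel_size
        for (j in acc[d2 < lim_soft^2]) {
          R <- resp[[k_scale[j]]]          # scale of the accepted candidate
          pk <- min(R[k_row[i], k_col[i]], R[k_row[j], k_col[j]])
          if (pk <= 0) { clash <- TRUE; break }
          valley <- min(vapply(c(0.3, 0.5, 0.7), function(t) {
            rr <- max(1L, min(nr, as.integer(round(k_cy[i] * (1 - t) + k_cy[j] * t))))
            cc <- max(1L, min(nc, as.integer(round(k_cx[i] * (1 - t) + k_cx[j] * t))))
            R[rr, cc]
          }, numeric(1)))
          if (valley >= 0.85 * pk) { clash <- TRUE; break }  # no dip: one object
        }
      }
    }
    if (!clash) acc <- c(acc, i)
  }
  fin <- acc[order(k_row[acc], k_col[acc])]
  data.frame(punctum_id = seq_along(fin),
             x_um = (k_cx[fin] - 0.5) * pixel_size,
             y_um = (k_cy[fin] - 0.5) * pixel_size,
             diameter_um = k_d[fin],
             peak_intensity = img[cbind(k_row[fin], k_col[fin])],
             response = k_resp[fin],
             circularity = k_circ[fin],
             row = k_row[fin], col = k_col[fin],
             cell_id = NA_integer_)
}

#' Assign detected puncta to segmented cells
#'
#' Sets each punctum's `cell_id` to the segmentation label under its centroid
#' pixel; puncta over background become unassigned (`NA`) and are excluded
#' from per-cell statistics.
#'
#' @param puncta Data frame from [detect_puncta()].
#' @param label_image Integer label matrix from [segment_cells()].
#' @return The puncta data frame with `cell_id` filled in.
#' @export
assign_to_cells <- function(puncta, label_image) {
  if (nrow(puncta) == 0) return(puncta)
  if (any(puncta$row > nrow(label_image)) || any(puncta$col > ncol(label_image)))
    stop("label image geometry does not match the puncta's source field")
  lab <- label_image[cbind(puncta$row, puncta$col)]
  puncta$cell_id <- ifelse(lab > 0, lab, NA_integer_)
  puncta
}
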