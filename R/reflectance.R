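#' Linearize a B-scan and subtract the background
#'
#' Converts a B-scan to the linear intensity scale required by the
#' attenuation estimator and subtracts the noise floor:
#' \code{I(z) = U(z) - N}, clamped at zero.  \code{N} is a scalar per
#' B-scan, estimated as the mean of the particle-free vitreous region
#' (pixels far above the robust particle threshold are excluded), or
#' supplied directly.  Display-compressed inputs are inverted exactly using
#' their recorded compression parameters; a compressed image without
#' recorded parameters is an error, never a guess.
#'
#' @param x a \code{bscan}.
#' @param vitreous_mask optional logical matrix marking vitreous pixels used
#'   to estimate the background (see \code{\link{vitreous_pixel_mask}}).
#' @param background optional scalar noise floor \code{N}; overrides
#'   estimation.  With neither mask nor background, \code{N = 0}.
#' @return a \code{linear_bscan}: list with \code{$pixels} (>= 0),
#'   \code{$axial_pitch_um}, \code{$lateral_pitch_um}, \code{$background}.
#' @export
linearize <- function(x, vitreous_mask = NULL, background = NULL) {
  stopifnot(inherits(x, "bscan"))
  if (x$scale == "log") x <- log_expand(x)  # errors if params missing
  n <- if (!is.null(background)) {
    background
  } else if (!is.null(vitreous_mask)) {
    v <- x$pixels[vitreous_mask]
    if (!length(v)) stop("empty vitreous mask")
    thr <- median(v) + 6 * mad(v)
    mean(v[v <= thr])
  } else 0
  structure(list(pixels = pmax(x$pixels - n, 0),
                 axial_pitch_um = x$axial_pitch_um,
                 lateral_pitch_um = x$lateral_pitch_um,
                 background = n), class = "linear_bscan")
}

#' Estimated attenuation coefficient (eAC) image
#'
#' Depth-resolved attenuation estimated per pixel from a linear-scale,
#' background-subtracted B-scan:
#' \deqn{\hat\mu[i] = I[i] / (2 \Delta \sum_{j>i} I[j])}
#' (complete-attenuation assumption at the image bottom; no signal-decay
#' factor).  Pixels whose remaining tail energy falls below
#' \code{tail_floor_frac} of the A-scan's total energy are masked (NA), as
#' are pixels of all-zero A-scans.  The estimate is invariant to per-A-scan
#' intensity scaling.
#'
#' @param lin a \code{linear_bscan} (from \code{\link{linearize}}).
#' @param tail_floor_frac mask threshold as a fraction of A-scan energy.
#' @return an \code{eac_image}: \code{$eac} matrix in 1/m (NA where masked),
#'   plus geometry.
#' @export
compute_eac <- function(lin, tail_floor_frac = 1e-3) {
  stopifnot(inherits(lin, "linear_bscan"))
  img <- lin$pixels
  nr <- nrow(img)
  delta_m <- lin$axial_pitch_um * 1e-6
  # tail[i] = sum of intensities strictly below pixel i, per column
  tail <- apply(img[nr:1, , drop = FALSE], 2, cumsum)[nr:1, , drop = FALSE] - img
  floor_col <- tail_floor_frac * colSums(img)
  eac <- img / (2 * delta_m * tail)
  masked <- tail <= rep(floor_col, each = nr) | tail <= 0
  eac[masked] <- NA_real_
  structure(list(eac = eac, axial_pitch_um = lin$axial_pitch_um,
                 lateral_pitch_um = lin$lateral_pitch_um,
                 log10_scale = FALSE), class = "eac_image")
}

#' Layer-wise eAC summary within an ROI
#'
#' Mean of log10(eAC) over the unmasked pixels of the named layer inside the
#' ROI, at A-scans valid in the segmentation.  The bottom
#' \code{exclude_bottom_px} image rows are excluded to bound the truncation
#' bias of the complete-attenuation assumption.
#'
#' @param eac an \code{eac_image}.
#' @param seg a \code{segmentation}.
#' @param layer_name layer of the segmentation's schema.
#' @param roi an ROI from \code{\link{select_rois}} (or any list with
#'   \code{$cols}).
#' @param exclude_bottom_px image rows excluded at the bottom.
#' @return list with \code{$mean_log10_eac} (NA if no pixels) and
#'   \code{$n_pixels}.
#' @export
layer_eac <- function(eac, seg, layer_name, roi, exclude_bottom_px = 5) {
  stopifnot(inherits(eac, "eac_image"), inherits(seg, "segmentation"))
  k <- match(layer_name, seg$schema$layer_names)
  if (is.na(k)) stop("unknown layer: ", layer_name)
  cols <- roi$cols[seg$valid[roi$cols]]
  nr <- nrow(eac$eac)
  rmax_img <- nr - exclude_bottom_px
  vals <- numeric(0)
  for (j in cols) {
    lo <- floor(seg$boundaries[k, j]) + 2      # first R row inside the layer
    hi <- min(floor(seg$boundaries[k + 1, j]) + 1, rmax_img)
    if (hi < lo) next
    v <- eac$eac[lo:hi, j]
    vals <- c(vals, v[is.finite(v) & v > 0])
  }
  if (!length(vals)) return(list(mean_log10_eac = NA_real_, n_pixels = 0L))
  list(mean_log10_eac = mean(log10(vals)), n_pixels = length(vals))
}

#' Dip ratio of the IS/OS band
#'
#' Reflectance biomarker computed on the photoreceptor inner/outer segment
#' band: per A-scan in the ROI, the IS peak is the intensity maximum in the
#' upper half of the IS+OS layer and the Dip is the minimum between that
#' peak and the layer's lower boundary; the ratio is
#' mean(IS peak) / mean(Dip) over the ROI.  Only defined for the normal
#' schema (the degenerative schema has a merged OR band).
#'
#' @param lin a \code{linear_bscan}.
#' @param seg a normal-schema \code{segmentation}.
#' @param roi an ROI (list with \code{$cols}).
#' @return the Dip ratio (>= 1 in practice; 1 for a uniform band).
#' @export
dip_ratio <- function(lin, seg, roi) {
  stopifnot(inherits(lin, "linear_bscan"), inherits(seg, "segmentation"))
  if (seg$schema$name != "normal")
    stop("Dip ratio is not applicable to the degenerative schema ",
         "(IS+OS merged into OR)")
  k <- match("IS+OS", seg$schema$layer_names)
  cols <- roi$cols[seg$valid[roi$cols]]
  if (!length(cols)) stop("no valid A-scans in ROI")
  nr <- nrow(lin$pixels)
  peaks <- dips <- numeric(length(cols))
  for (i in seq_along(cols)) {
    j <- cols[i]
    top <- seg$boundaries[k, j]
    bot <- seg$boundaries[k + 1, j]
    lo <- max(floor(top) + 2, 1)
    mid <- min(floor(top + (bot - top) / 2) + 1, nr)
    hi <- min(floor(bot) + 1, nr)
    if (mid < lo || hi < lo) { peaks[i] <- NA; dips[i] <- NA; next }
    seg_up <- lin$pixels[lo:mid, j]
    pk <- which.max(seg_up)
    peaks[i] <- seg_up[pk]
    dips[i] <- min(lin$pixels[(lo + pk - 1):hi, j])
  }
  mean(peaks, na.rm = TRUE) / mean(dips, na.rm = TRUE)
}
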