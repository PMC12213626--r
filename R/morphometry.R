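#' Locate the optic nerve head
#'
#' Returns the lateral column index of the ONH, taken as the center of the
#' invalid (masked) A-scan run nearest the image center; falls back to the
#' image center when no invalid run exists.  With several distant invalid
#' runs the one nearest the center is chosen, with a warning.
#'
#' @param seg a \code{segmentation}.
#' @return integer column index.
#' @export
locate_onh <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  nc <- length(seg$valid)
  ctr <- round((nc + 1) / 2)
  if (all(seg$valid)) return(ctr)
  r <- rle(!seg$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  mids <- round((starts[runs] + ends[runs]) / 2)
  if (length(runs) > 1)
    warning("multiple invalid runs; using the one nearest the image center")
  mids[which.min(abs(mids - ctr))]
}

#' Measurement ROIs relative to the optic nerve head
#'
#' Two regions of interest per B-scan, one on each side of the ONH, spanning
#' 350 to 630 um from the ONH center along the lateral axis (200 A-scans at
#' the default 1.4 um lateral pitch).
#'
#' @param onh_col ONH center column (1-based).
#' @param lateral_pitch_um micrometers per A-scan.
#' @param n_ascans image width (for bounds checking).
#' @param inner_offset_um,outer_offset_um ROI offsets from the ONH center.
#' @return list with \code{$left} and \code{$right}, each an \code{roi}:
#'   \code{$side}, \code{$cols} (1-based column indices), offsets.
#' @export
select_rois <- function(onh_col, lateral_pitch_um, n_ascans,
                        inner_offset_um = 350, outer_offset_um = 630) {
  stopifnot(outer_offset_um > inner_offset_um, lateral_pitch_um > 0)
  oi <- round(inner_offset_um / lateral_pitch_um)
  oo <- round(outer_offset_um / lateral_pitch_um)
  left <- seq.int(onh_col - oo + 1L, onh_col - oi)
  right <- seq.int(onh_col + oi + 1L, onh_col + oo)
  if (left[1] < 1 || right[length(right)] > n_ascans)
    stop("ROI falls outside the image (onh_col = ", onh_col, ")")
  mk <- function(side, cols)
    structure(list(side = side, cols = cols,
                   inner_offset_um = inner_offset_um,
                   outer_offset_um = outer_offset_um), class = "roi")
  list(left = mk("left", left), right = mk("right", right))
}

#' Per-layer mean thickness within an ROI
#'
#' Mean over the ROI's valid A-scans of (lower boundary - upper boundary)
#' times the axial pitch, using sub-pixel boundary positions directly.  For
#' the normal schema an additional \code{OR} entry (IS+OS plus RPE) is
#' emitted so outer-retina thickness is comparable across the schema switch.
#' If more than half the ROI's A-scans are invalid all values are NA.
#'
#' @param seg a \code{segmentation}.
#' @param roi an ROI (list with \code{$cols}).
#' @param axial_pitch_um micrometers per pixel.
#' @return named numeric vector of thicknesses (um) with attribute
#'   \code{n_ascans_used}.
#' @export
layer_thickness <- function(seg, roi, axial_pitch_um) {
  stopifnot(inherits(seg, "segmentation"))
  cols <- roi$cols
  if (any(cols < 1 | cols > ncol(seg$boundaries)))
    stop("ROI columns outside segmentation")
  ok <- seg$valid[cols]
  layers <- seg$schema$layer_names
  out_names <- if (seg$schema$name == "normal") c(layers, "OR") else layers
  if (mean(ok) < 0.5) {
    th <- rep(NA_real_, length(out_names))
    names(th) <- out_names
    attr(th, "n_ascans_used") <- sum(ok)
    return(th)
  }
  use <- cols[ok]
  th <- vapply(seq_along(layers), function(k)
    mean(seg$boundaries[k + 1, use] - seg$boundaries[k, use]) * axial_pitch_um,
    numeric(1))
  names(th) <- layers
  if (seg$schema$name == "normal") th <- c(th, OR = unname(th["IS+OS"] + th["RPE"]))
  attr(th, "n_ascans_used") <- length(use)
  th
}

#' Eye-level aggregation of ROI measurements
#'
#' An eye at one timepoint is represented by the unweighted mean of its ROI
#' values (nominally 8: 4 B-scans x 2 ROIs).  With fewer than
#' \code{min_rois} non-missing values the mean is NA; the count of values
#' used is always reported.
#'
#' @param records data.frame with columns \code{layer} and \code{value}
#'   (one row per ROI measurement).
#' @param min_rois minimum non-missing ROI values required.
#' @return data.frame with \code{layer}, \code{mean}, \code{n_rois},
#'   \code{complete} (n_rois >= 8).
#' @export
aggregate_eye <- function(records, min_rois = 4) {
  stopifnot(all(c("layer", "value") %in% names(records)))
  sp <- split(records$value, records$layer)
  out <- do.call(rbind, lapply(names(sp), function(l) {
    v <- sp[[l]][!is.na(sp[[l]])]
    data.frame(layer = l,
               mean = if (length(v) >= min_rois) mean(v) else NA_real_,
               n_rois = length(v), complete = length(v) >= 8)
  }))
  rownames(out) <- NULL
  out
}

#' Baseline-normalized thickness series
#'
#' Divides each eye's series by its own baseline (day 0) value, then
#' averages the ratios across eyes per day.
#'
#' @param df data.frame with columns \code{eye}, \code{day}, \code{value};
#'   every eye must have a day-0 value.
#' @return data.frame with \code{day}, \code{mean_ratio}, \code{n_eyes}.
#' @export
normalize_baseline <- function(df) {
  stopifnot(all(c("eye", "day", "value") %in% names(df)))
  sp <- split(df, df$eye)
  norm <- lapply(sp, function(d) {
    b <- d$value[d$day == 0]
    if (length(b) != 1 || is.na(b)) stop("missing baseline for an eye")
    if (b == 0) stop("zero baseline value")
    data.frame(eye = d$eye, day = d$day, ratio = d$value / b)
  })
  norm <- do.call(rbind, norm)
  agg <- split(norm$ratio, norm$day)
  out <- data.frame(day = as.numeric(names(agg)),
                    mean_ratio = vapply(agg, mean, numeric(1)),
                    n_eyes = vapply(agg, length, numeric(1)))
  rownames(out) <- NULL
  out[order(out$day), ]
}
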