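#' OCT B-scan container
#'
#' A B-scan is a 2-D intensity image: rows are depth (axial, top = vitreous),
#' columns are A-scans (lateral).  The intensity scale is either
#' \code{"linear"} (pixel value proportional to signal power) or
#' \code{"log"} (display-compressed; the compression parameters must then be
#' recorded so the image can be linearized).
#'
#' @param pixels numeric matrix of intensities (rows = depth).
#' @param axial_pitch_um micrometers per pixel, axial.
#' @param lateral_pitch_um micrometers per A-scan.
#' @param scale "linear" or "log".
#' @param log_params for \code{scale = "log"}: list with \code{a}, \code{b}
#'   such that display = a * log10(1 + b * linear).
#' @return a \code{bscan} object.
#' @export
bscan <- function(pixels, axial_pitch_um = 1.7, lateral_pitch_um = 1.4,
                  scale = c("linear", "log"), log_params = NULL) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(pixels), is.numeric(pixels),
            axial_pitch_um > 0, lateral_pitch_um > 0)
  structure(list(pixels = pixels, axial_pitch_um = axial_pitch_um,
                 lateral_pitch_um = lateral_pitch_um, scale = scale,
                 log_params = log_params), class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan> %d x %d px (%.3g x %.3g um/px), %s scale\n",
              nrow(x$pixels), ncol(x$pixels), x$axial_pitch_um,
              x$lateral_pitch_um, x$scale))
  invisible(x)
}

#' @export
dim.bscan <- function(x) dim(x$pixels)

#' Log display compression and its inverse
#'
#' Display transform \code{D = a * log10(1 + b * I)} used when exporting a
#' linear-scale B-scan for viewing; the parameters are recorded on the
#' object so the transform can be inverted exactly.
#'
#' @param x a linear-scale \code{bscan}.
#' @param a,b compression parameters.
#' @return a log-scale \code{bscan} (for \code{log_compress}) or a
#'   linear-scale one (for \code{log_expand}).
#' @export
log_compress <- function(x, a = 60, b = 1) {
  stopifnot(inherits(x, "bscan"), x$scale == "linear")
  bscan(a * log10(1 + b * x$pixels), x$axial_pitch_um, x$lateral_pitch_um,
        scale = "log", log_params = list(a = a, b = b))
}

#' @rdname log_compress
#' @export
log_expand <- function(x) {
  stopifnot(inherits(x, "bscan"), x$scale == "log")
  if (is.null(x$log_params))
    stop("log-scale image without recorded compression parameters; ",
         "cannot linearize")
  a <- x$log_params$a
  b <- x$log_params$b
  bscan((10^(x$pixels / a) - 1) / b, x$axial_pitch_um, x$lateral_pitch_um,
        scale = "linear")
}
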