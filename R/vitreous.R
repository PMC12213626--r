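#' Vitreous compartment mask and image
#'
#' The vitreous is everything above the first segmentation boundary (inner
#' limiting membrane / vitreous).  \code{vitreous_pixel_mask} returns a
#' logical matrix of vitreous pixels (optionally keeping a safety margin
#' above the boundary); \code{vitreous_mask} returns the image with all
#' pixels at or below the first boundary set to zero.
#'
#' @param x a \code{bscan} (or numeric matrix for \code{vitreous_mask}).
#' @param seg a \code{segmentation}.
#' @param margin_px rows immediately above the boundary to exclude from the
#'   pixel mask (guards against boundary error bleeding retina into the
#'   background estimate).
#' @return \code{vitreous_mask}: numeric matrix; \code{vitreous_pixel_mask}:
#'   logical matrix.
#' @export
vitreous_mask <- function(x, seg) {
  img <- if (inherits(x, "bscan")) x$pixels else x
  stopifnot(inherits(seg, "segmentation"),
            ncol(img) == ncol(seg$boundaries))
  b1 <- floor(seg$boundaries[1, ])       # pixel row r retained iff r <= b1
  rows <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  keep <- rows <= rep(b1, each = nrow(img))
  img * keep
}

#' @rdname vitreous_mask
#' @export
vitreous_pixel_mask <- function(x, seg, margin_px = 4) {
  img <- if (inherits(x, "bscan")) x$pixels else x
  b1 <- floor(seg$boundaries[1, ]) - margin_px
  rows <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  rows <= rep(b1, each = nrow(img))
}

# Otsu threshold on positive pixels (fallback when no background stats)
otsu_threshold <- function(v, n_bins = 256) {
  v <- v[is.finite(v)]
  h <- hist(v, breaks = n_bins, plot = FALSE)
  w <- h$counts / sum(h$counts)
  m <- h$mids
  best <- -Inf
  thr <- m[1]
  for (i in seq_len(length(m) - 1)) {
    w0 <- sum(w[1:i]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(w[1:i] * m[1:i]) / w0
    m1 <- sum(w[(i + 1):length(m)] * m[(i + 1):length(m)]) / w1
    v_b <- w0 * w1 * (m0 - m1)^2
    if (v_b > best) { best <- v_b; thr <- (m[i] + m[i + 1]) / 2 }
  }
  thr
}

#' Count hyper-reflective vitreous particles
#'
#' Binarizes the vitreous image, labels connected components and keeps those
#' whose pixel area lies within \code{size_range} (inclusive), excluding
#' both small artifacts and very large structures such as the optic nerve
#' head.  The default threshold is mean + 4 SD of the particle-free vitreous
#' background; without background statistics an Otsu threshold on the
#' positive pixels is used.
#'
#' @param vimg vitreous image (numeric matrix, zero outside the vitreous;
#'   see \code{\link{vitreous_mask}}).
#' @param intensity_threshold explicit binarization threshold (optional).
#' @param background_stats optional list with \code{mean} and \code{sd} of
#'   the particle-free vitreous background.
#' @param size_range inclusive component-area filter in pixels.
#' @param connectivity 4 or 8 (default 8).
#' @return a \code{particle_set}: list with \code{$particles} (data.frame
#'   centroid_row, centroid_col, area_px), \code{$count},
#'   \code{$threshold}.
#' @export
count_particles <- function(vimg, intensity_threshold = NULL,
                            background_stats = NULL,
                            size_range = c(5, 500), connectivity = 8) {
  stopifnot(is.matrix(vimg), size_range[1] <= size_range[2])
  thr <- if (!is.null(intensity_threshold)) {
    intensity_threshold
  } else if (!is.null(background_stats)) {
    background_stats$mean + 4 * background_stats$sd
  } else {
    pos <- vimg[vimg > 0]
    if (!length(pos))
      return(structure(list(particles = data.frame(centroid_row = numeric(0),
                                                   centroid_col = numeric(0),
                                                   area_px = integer(0)),
                            count = 0L, threshold = NA_real_),
                       class = "particle_set"))
    otsu_threshold(pos)
  }
  mask <- vimg > thr
  lab <- .label_components(mask, as.integer(connectivity))
  n <- max(lab)
  if (n == 0) {
    df <- data.frame(centroid_row = numeric(0), centroid_col = numeric(0),
                     area_px = integer(0))
  } else {
    areas <- tabulate(lab[lab > 0], nbins = n)
    keep <- which(areas >= size_range[1] & areas <= size_range[2])
    rows <- row(lab)[lab > 0]
    cols <- col(lab)[lab > 0]
    ids <- lab[lab > 0]
    df <- data.frame(
      centroid_row = vapply(keep, function(k) mean(rows[ids == k]), numeric(1)),
      centroid_col = vapply(keep, function(k) mean(cols[ids == k]), numeric(1)),
      area_px = areas[keep])
  }
  structure(list(particles = df, count = nrow(df), threshold = thr),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles (threshold %.3g)\n",
              x$count, x$threshold))
  invisible(x)
}
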