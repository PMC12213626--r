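# constructor shared by segment(), ensemble_median() and as_segmentation()
new_segmentation <- function(schema, boundaries, valid, source_model) {
  stopifnot(inherits(schema, "layer_schema"),
            nrow(boundaries) == length(schema$boundary_names),
            length(valid) == ncol(boundaries))
  rownames(boundaries) <- schema$boundary_names
  structure(list(schema = schema, boundaries = boundaries,
                 valid = valid, source_model = source_model),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %s schema, %d boundaries x %d A-scans (%s), %d%% valid\n",
              x$schema$name, nrow(x$boundaries), ncol(x$boundaries),
              x$source_model, round(100 * mean(x$valid))))
  invisible(x)
}

#' Gradient-based boundary cost map
#'
#' Builds a cost map for shortest-path boundary search: cost is low where
#' the signed vertical intensity gradient of the (Gaussian smoothed) image
#' matches the requested polarity, normalized to [0, 1].  A constant image
#' yields a uniform cost map.
#'
#' @param x a \code{bscan} or numeric matrix.
#' @param polarity \code{"dark-to-bright"} (intensity increases with depth)
#'   or \code{"bright-to-dark"}.
#' @param smoothing_sigma Gaussian smoothing sigma in pixels.
#' @param grad_power exponent applied to the normalized matched gradient
#'   before inversion (>1 sharpens the preference for strong edges).
#' @return a \code{cost_map}: list with \code{$cost} (matrix in [0,1]),
#'   \code{$gradient} (signed, polarity-matched) and \code{$polarity}.
#' @export
boundary_cost <- function(x, polarity = c("dark-to-bright", "bright-to-dark"),
                          smoothing_sigma = 1.5, grad_power = 1) {
  polarity <- match.arg(polarity)
  img <- if (inherits(x, "bscan")) x$pixels else x
  stopifnot(is.matrix(img), nrow(img) >= 2, all(is.finite(img)))
  sm <- .gaussian_blur(img, smoothing_sigma, smoothing_sigma)
  nr <- nrow(sm)
  g <- matrix(0, nr, ncol(sm))
  g[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
  s <- if (polarity == "dark-to-bright") g else -g
  smax <- max(s)
  cost <- if (smax <= 0) {
    matrix(1, nr, ncol(sm))
  } else {
    1 - (pmax(s, 0) / smax)^grad_power
  }
  structure(list(cost = cost, gradient = s, polarity = polarity,
                 smoothing_sigma = smoothing_sigma), class = "cost_map")
}

#' Minimum-cost boundary path (exact dynamic programming)
#'
#' Finds the row per A-scan of a minimum-total-cost left-to-right path with
#' \code{|drow| <= max_step} between adjacent A-scans, confined to
#' \code{row_band}.  The optimum is exact; ties are broken toward the
#' smaller row index.
#'
#' @param cost a \code{cost_map} or numeric cost matrix (finite, >= 0).
#' @param row_band integer c(min, max) rows (1-based, inclusive).
#' @param max_step maximum row change between adjacent A-scans.
#' @return integer vector of row indices (1-based), one per column.
#' @export
shortest_path_boundary <- function(cost, row_band = NULL, max_step = 2) {
  cm <- if (inherits(cost, "cost_map")) cost$cost else cost
  stopifnot(is.matrix(cm), all(is.finite(cm)), all(cm >= 0))
  if (is.null(row_band)) row_band <- c(1L, nrow(cm))
  if (row_band[1] > row_band[2]) stop("infeasible row band (min > max)")
  .dp_shortest_path(cm, as.integer(row_band[1]), as.integer(row_band[2]),
                    as.integer(max_step))
}

#' Segmenter variants ("models")
#'
#' The segmentation "models" are parameterized variants of the same
#' gradient/shortest-path segmenter (different smoothing, path stiffness and
#' edge sharpening).  Running several variants and taking the per-A-scan
#' median emulates a model-ensembling workflow.  Inside
#' \code{\link{segment_bscan}} the sigma acts laterally (like averaging
#' neighbouring A-scans); axial smoothing is capped at 1.6 px so that thin
#' layers keep separable edges.
#'
#' @param smoothing_sigma,max_step,grad_power see \code{\link{boundary_cost}}
#'   and \code{\link{shortest_path_boundary}}.
#' @param name model identifier.
#' @return a \code{segmenter_variant} (list).
#' @export
segmenter_variant <- function(smoothing_sigma = 1.8, max_step = 2,
                              grad_power = 1, name = "default") {
  structure(list(smoothing_sigma = smoothing_sigma, max_step = max_step,
                 grad_power = grad_power, name = name),
            class = "segmenter_variant")
}

#' @rdname segmenter_variant
#' @export
default_variants <- function() {
  list(segmenter_variant(1.0, 2, 1.0, "M1"),
       segmenter_variant(1.5, 2, 1.0, "M2"),
       segmenter_variant(2.0, 2, 1.5, "M3"),
       segmenter_variant(2.5, 3, 1.0, "M4"),
       segmenter_variant(3.0, 3, 1.5, "M5"))
}

# per-boundary search priors: polarity and plausible layer thickness range
# (um) of the layer immediately above each boundary; generous enough to
# cover the whole degeneration time course
boundary_priors <- function(schema) {
  gaps <- list(
    NFL = c(7, 27), IPL = c(30, 64), INL = c(14, 42), OPL = c(7, 30),
    ONL = c(3, 78), `IS+OS` = c(20, 56), RPE = c(5.5, 16), OR = c(7, 36),
    choroid = c(40, 112))
  if (schema$name == "normal") {
    pol <- c("dark-to-bright", "bright-to-dark", "bright-to-dark",
             "dark-to-bright", "bright-to-dark", "dark-to-bright",
             "dark-to-bright", "bright-to-dark", "bright-to-dark")
  } else {
    pol <- c("dark-to-bright", "bright-to-dark", "bright-to-dark",
             "dark-to-bright", "bright-to-dark", "dark-to-bright",
             "bright-to-dark", "bright-to-dark")
  }
  list(polarity = pol, gaps_um = gaps[schema$layer_names])
}

# parabolic sub-pixel refinement of an edge position on the matched
# gradient; returns 0-based boundary values (see layer_schema for the
# coordinate convention: 0-based estimate = peak row (1-based) - 0.5)
refine_subpixel <- function(grad, rows, cols) {
  nr <- nrow(grad)
  r <- pmin(pmax(rows, 2L), nr - 1L)
  y0 <- grad[cbind(r, cols)]
  ym <- grad[cbind(r - 1L, cols)]
  yp <- grad[cbind(r + 1L, cols)]
  den <- ym - 2 * y0 + yp
  off <- ifelse(is.finite(den) & den < 0, 0.5 * (ym - yp) / den, 0)
  off <- pmin(pmax(off, -0.5), 0.5)
  rows + off - 0.5
}

# robust retina-surface estimate: heavy lateral smoothing suppresses small
# hyper-reflective blobs (vitreous particles) while the laterally continuous
# surface edge survives; the DP path over the result anchors the per-variant
# boundary-1 search.  Errors if no plausible surface exists.
find_surface <- function(img, r1_max, max_step = 2) {
  nr <- nrow(img)
  nc <- ncol(img)
  sm <- .gaussian_blur(img, 1.2, 8)
  g <- matrix(0, nr, nc)
  g[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
  smax <- max(g)
  if (smax <= 1e-9 * (diff(range(img)) + 1e-12) || smax <= 0)
    stop("segmentation failure: no plausible retina structure in image")
  cost <- 1 - pmax(g[seq_len(r1_max), , drop = FALSE], 0) / smax
  rows <- .dp_shortest_path(cost, 3L, as.integer(r1_max),
                            as.integer(max_step))
  med_g <- median(abs(g)[seq(1, nr * nc, by = 13)])
  if (mean(g[cbind(rows, seq_len(nc))]) < 3 * med_g)
    stop("segmentation failure: no plausible retina surface found")
  rows
}

# detect the ONH gap: contiguous run of low gradient-energy columns nearest
# the image center, grown by `grow` columns on each side
detect_onh_gap <- function(grad_abs_colsums, frac = 0.3, grow = 5L) {
  nc <- length(grad_abs_colsums)
  low <- grad_abs_colsums < frac * median(grad_abs_colsums)
  if (!any(low)) return(NULL)
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  ctr <- (nc + 1) / 2
  mids <- (starts[runs] + ends[runs]) / 2
  best <- runs[which.min(abs(mids - ctr))]
  c(max(1L, starts[best] - grow), min(nc, ends[best] + grow))
}

#' Segment a B-scan into ordered retinal/choroid boundaries
#'
#' Boundaries are found top to bottom by sequential shortest-path search:
#' each boundary is searched in a band placed below the previous boundary at
#' the plausible thickness range of the intervening layer, which enforces
#' monotone ordering by construction.  The optic-nerve-head gap (columns
#' whose gradient energy falls below 30% of the B-scan median, grown by 5
#' columns) is masked out of \code{valid}, and the two sides of the gap are
#' segmented independently.  Boundary positions are sub-pixel (parabolic
#' refinement of the matched gradient around the DP path) and 0-based.
#'
#' @param x a \code{bscan} (linear or display scale).
#' @param schema a \code{\link{layer_schema}} or schema name.
#' @param variant a \code{\link{segmenter_variant}}.
#' @param surface_hint optional integer row per A-scan near the
#'   vitreoretinal boundary (shared across variants by
#'   \code{\link{analyze_bscan}}); computed internally when NULL.
#' @return a \code{segmentation}.
#' @export
segment_bscan <- function(x, schema = layer_schema("normal"),
                          variant = segmenter_variant(),
                          surface_hint = NULL) {
  if (is.character(schema)) schema <- layer_schema(schema)
  stopifnot(inherits(x, "bscan"), inherits(schema, "layer_schema"))
  img <- x$pixels
  nr <- nrow(img)
  nc <- ncol(img)
  pitch <- x$axial_pitch_um
  # one blur per variant; both polarities share the gradient; costs for
  # boundaries >= 2 are evaluated lazily on their search bands only.
  # The variant's sigma smooths laterally (emulating A-scan averaging);
  # axial smoothing is capped so thin layers (RPE ~6 px) keep distinct edges
  sm <- .gaussian_blur(img, min(variant$smoothing_sigma, 1.6),
                       variant$smoothing_sigma)
  g <- matrix(0, nr, nc)
  g[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
  gabs <- abs(g)
  smax <- c(`dark-to-bright` = max(g), `bright-to-dark` = max(-g))
  cost_at <- function(polarity, vals) {
    sm_ <- smax[polarity]
    if (sm_ <= 0) return(array(1, dim(vals)))
    s <- if (polarity == "dark-to-bright") vals else -vals
    1 - (pmax(s, 0) / sm_)^variant$grad_power
  }
  if (max(gabs) <= 1e-9 * (diff(range(img)) + 1e-12) || max(gabs) == 0)
    stop("segmentation failure: no plausible retina structure in image")
  pri <- boundary_priors(schema)
  nb <- length(schema$boundary_names)
  gap <- detect_onh_gap(colSums(gabs))
  sides <- if (is.null(gap)) list(seq_len(nc)) else {
    s <- list()
    if (gap[1] > 1) s <- c(s, list(seq_len(gap[1] - 1L)))
    if (gap[2] < nc) s <- c(s, list(seq.int(gap[2] + 1L, nc)))
    if (!length(s)) s <- list(seq_len(nc))  # pathological: gap covers image
    s
  }
  B <- matrix(NA_real_, nb, nc)
  grads <- list(`dark-to-bright` = g, `bright-to-dark` = -g)
  # the surface must leave room below it for the thinnest plausible retina
  min_below <- sum(vapply(pri$gaps_um, function(gg) floor(gg[1] / pitch), 0))
  r1_max <- max(4L, as.integer(nr - min_below))
  if (is.null(surface_hint)) surface_hint <- find_surface(img, r1_max)
  for (cols in sides) {
    # boundary 1: narrow search around the particle-robust surface estimate
    offs1 <- -8:8
    idx1 <- outer(offs1, surface_hint[cols], "+")
    oob1 <- idx1 < 2 | idx1 > r1_max
    idx1[oob1] <- 2L
    c1 <- matrix(cost_at(pri$polarity[1],
                         g[cbind(as.vector(idx1),
                                 rep(cols, each = length(offs1)))]),
                 length(offs1), length(cols))
    c1[oob1] <- 1.5
    rel1 <- .dp_shortest_path(c1, 1L, as.integer(length(offs1)),
                              as.integer(variant$max_step))
    rows1 <- pmin(pmax(surface_hint[cols] + offs1[rel1], 2L), r1_max)
    B[1, cols] <- refine_subpixel(grads[[pri$polarity[1]]],
                                  as.integer(rows1), cols)
    # anchor: the lower ONL boundary (ONL/IS+OS or ONL/OR) is the most
    # prominent dark-to-bright rise below the surface.  Placing it before
    # the inner boundaries caps their search bands from below, so a thin
    # outer retina cannot capture an inner-boundary path
    ka <- 6L
    lay <- schema$layer_names
    min_px <- vapply(lay, function(l)
      max(1L, as.integer(floor(pri$gaps_um[[l]][1] / pitch))), integer(1))
    max_px <- vapply(lay, function(l)
      as.integer(ceiling(pri$gaps_um[[l]][2] / pitch)), integer(1))
    run_band <- function(prev, offs, polarity, cap = NULL) {
      idx_r <- outer(offs, prev, "+")
      oob <- idx_r > nr
      idx_r[oob] <- nr
      gvals <- matrix(g[cbind(as.vector(idx_r),
                              rep(cols, each = length(offs)))],
                      length(offs), length(cols))
      crel <- cost_at(polarity, gvals)
      crel[oob] <- 1.5  # discourage paths pushed off the image
      if (!is.null(cap)) {
        # forbid rows below the cap, but always keep the minimal offset
        # feasible (pinched ONH columns are masked invalid anyway)
        over <- sweep(idx_r, 2, pmax(cap, prev + offs[1]), `>`)
        crel[over] <- 1.5
      }
      rel <- .dp_shortest_path(crel, 1L, as.integer(length(offs)),
                               as.integer(variant$max_step))
      pmin(prev + offs[rel], nr)
    }
    anchor <- run_band(as.integer(rows1),
                       sum(min_px[1:(ka - 1)]):sum(max_px[1:(ka - 1)]),
                       pri$polarity[ka])
    prev <- as.integer(rows1)
    for (k in 2:nb) {
      if (k == ka) {
        rows_k <- anchor
      } else if (k < ka) {
        cap <- as.integer(anchor) - sum(min_px[k:(ka - 1)])
        rows_k <- run_band(prev, min_px[k - 1]:max_px[k - 1],
                           pri$polarity[k], cap = cap)
      } else {
        rows_k <- run_band(prev, min_px[k - 1]:max_px[k - 1],
                           pri$polarity[k])
      }
      B[k, cols] <- refine_subpixel(grads[[pri$polarity[k]]],
                                    as.integer(rows_k), cols)
      prev <- as.integer(rows_k)
    }
  }
  valid <- !is.na(B[1, ])
  if (!is.null(gap)) valid[gap[1]:gap[2]] <- FALSE
  # columns never segmented (inside gap): carry nearest segmented values so
  # downstream geometry stays defined; they are flagged invalid
  if (anyNA(B)) {
    for (k in seq_len(nb)) {
      v <- B[k, ]
      B[k, ] <- stats::approx(which(!is.na(v)), v[!is.na(v)],
                              xout = seq_len(nc), rule = 2)$y
    }
  }
  # enforce monotone ordering at the sub-pixel level (refinement can nudge
  # adjacent boundaries of very thin layers by < 1 px)
  for (k in 2:nb) B[k, ] <- pmax(B[k, ], B[k - 1, ] + 0.1)
  new_segmentation(schema, B, valid, variant$name)
}

#' Median ensemble of segmentations
#'
#' Per boundary and per A-scan, the ensemble position is the median of the
#' input segmentations' positions (for an even count, the mean of the two
#' central values).  The valid mask is the AND of the inputs' masks.
#'
#' @param segs list of \code{segmentation} objects with identical schema and
#'   width.
#' @param name source_model identifier of the result.
#' @return a \code{segmentation}.
#' @export
ensemble_median <- function(segs, name = "Model_median") {
  stopifnot(length(segs) >= 1)
  sch <- segs[[1]]$schema
  nc <- ncol(segs[[1]]$boundaries)
  for (s in segs) {
    if (!identical(s$schema$name, sch$name))
      stop("mixed schemas in ensemble")
    if (ncol(s$boundaries) != nc) stop("mixed widths in ensemble")
  }
  stack <- vapply(segs, function(s) as.vector(s$boundaries),
                  numeric(nrow(segs[[1]]$boundaries) * nc))
  med <- .row_medians(matrix(stack, ncol = length(segs)))
  valid <- Reduce(`&`, lapply(segs, `[[`, "valid"))
  new_segmentation(sch, matrix(med, nrow = nrow(segs[[1]]$boundaries)),
                   valid, name)
}

# integer pixel rows occupied by a layer: 0-based rows floor(b_up)+1 ..
# floor(b_low), i.e. R rows floor(b_up)+2 .. floor(b_low)+1
layer_pixel_counts <- function(b_up, b_low, image_height) {
  lo <- pmin(pmax(floor(b_up), 0), image_height - 1)
  hi <- pmin(pmax(floor(b_low), 0), image_height - 1)
  list(lo = lo, hi = hi, n = pmax(hi - lo, 0))
}

#' Dice overlap of one layer between two segmentations
#'
#' 2|A intersect B| / (|A| + |B|) over the pixel masks of the named layer,
#' restricted to A-scans valid in both segmentations.  If both masks are
#' empty the score is defined as 1.
#'
#' @param seg_a,seg_b \code{segmentation}s with the same schema and width.
#' @param layer_name a layer of the shared schema.
#' @param image_height image height in pixels.
#' @return Dice score in [0, 1].
#' @export
dice_score <- function(seg_a, seg_b, layer_name, image_height) {
  stopifnot(identical(seg_a$schema$name, seg_b$schema$name),
            ncol(seg_a$boundaries) == ncol(seg_b$boundaries))
  k <- match(layer_name, seg_a$schema$layer_names)
  if (is.na(k)) stop("unknown layer: ", layer_name)
  ok <- seg_a$valid & seg_b$valid
  a <- layer_pixel_counts(seg_a$boundaries[k, ok], seg_a$boundaries[k + 1, ok],
                          image_height)
  b <- layer_pixel_counts(seg_b$boundaries[k, ok], seg_b$boundaries[k + 1, ok],
                          image_height)
  inter <- pmax(pmin(a$hi, b$hi) - pmax(a$lo, b$lo), 0)
  tot <- sum(a$n) + sum(b$n)
  if (tot == 0) return(1.0)
  2 * sum(inter) / tot
}

#' Model usage rates
#'
#' Fraction of images for which each model/variant was selected as the best
#' fit.  Rates sum to 1 over \code{model_ids}.
#'
#' @param selections character vector of chosen model identifiers (one per
#'   image).
#' @param model_ids all candidate model identifiers.
#' @return named numeric vector of rates.
#' @export
usage_rate <- function(selections, model_ids) {
  if (length(selections) == 0) stop("empty selection list")
  if (!all(selections %in% model_ids))
    stop("selections contain unknown model ids")
  counts <- table(factor(selections, levels = model_ids))
  rates <- as.numeric(counts) / length(selections)
  names(rates) <- model_ids
  rates
}
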