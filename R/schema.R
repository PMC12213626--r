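#' Retinal layer schemas
#'
#' Two segmentation schemas are supported.  The \code{"normal"} schema uses
#' nine boundary lines to delineate seven retinal layers plus the choroid
#' (NFL, IPL, INL, OPL, ONL, IS+OS, RPE, choroid).  The
#' \code{"degenerative"} schema, used once the photoreceptor inner/outer
#' segments and the RPE have merged into a single outer-retina (OR) band,
#' uses eight boundary lines for six retinal layers plus the choroid.
#'
#' Boundary positions are stored 0-based: a boundary value \code{b} places
#' the transition between pixel rows \code{floor(b)} and \code{floor(b)+1}
#' (row 0 is the top of the image, i.e. the vitreous side).
#'
#' @param name "normal" or "degenerative".
#' @return A \code{layer_schema} object with \code{$name},
#'   \code{$boundary_names} (ordered, outer/vitreous side first) and
#'   \code{$layer_names}.
#' @examples
#' layer_schema("normal")$layer_names
#' @export
layer_schema <- function(name = c("normal", "degenerative")) {
  name <- match.arg(name)
  if (name == "normal") {
    boundaries <- c("vitreous/NFL", "NFL/IPL", "IPL/INL", "INL/OPL",
                    "OPL/ONL", "ONL/IS+OS", "IS+OS/RPE", "RPE/choroid",
                    "choroid/sclera")
    layers <- c("NFL", "IPL", "INL", "OPL", "ONL", "IS+OS", "RPE", "choroid")
  } else {
    boundaries <- c("vitreous/NFL", "NFL/IPL", "IPL/INL", "INL/OPL",
                    "OPL/ONL", "ONL/OR", "OR/choroid", "choroid/sclera")
    layers <- c("NFL", "IPL", "INL", "OPL", "ONL", "OR", "choroid")
  }
  structure(list(name = name, boundary_names = boundaries,
                 layer_names = layers),
            class = "layer_schema")
}

#' @export
print.layer_schema <- function(x, ...) {
  cat("<layer_schema>", x$name, ":", length(x$boundary_names),
      "boundaries /", length(x$layer_names), "layers\n")
  invisible(x)
}

# schema appropriate for a post-injection day, given the merge day
schema_for_day <- function(day, merge_day = 6) {
  layer_schema(if (day >= merge_day) "degenerative" else "normal")
}
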