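#' Read and write B-scans as portable graymap + JSON sidecar
#'
#' B-scans are stored as plain-text 16-bit PGM (P2) images with a JSON
#' metadata sidecar (\code{<path>.json}) recording the pixel pitches, the
#' intensity scale type, the quantization factor, and any display
#' compression parameters.  Reading without the sidecar is an error: pixel
#' geometry is never silently defaulted.  Pixel values are quantized to 16
#' bits on write; a write-read round trip of an already-quantized image is
#' exact.
#'
#' @param x a \code{bscan}.
#' @param path file path (the sidecar goes to \code{paste0(path, ".json")}).
#' @return \code{read_bscan} returns a \code{bscan}.
#' @export
write_bscan <- function(x, path) {
  stopifnot(inherits(x, "bscan"))
  img <- x$pixels
  qscale <- if (max(img) > 0) 65535 / max(img) else 1
  q <- matrix(as.integer(round(img * qscale)), nrow(img), ncol(img))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), "65535"), con)
  # one image row per line
  writeLines(apply(q, 1, paste, collapse = " "), con)
  meta <- list(axial_pitch_um = x$axial_pitch_um,
               lateral_pitch_um = x$lateral_pitch_um,
               scale = x$scale, quant_scale = qscale,
               log_params = x$log_params)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_bscan
#' @export
read_bscan <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("metadata sidecar missing: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("axial_pitch_um", "lateral_pitch_um", "scale", "quant_scale"))
    if (is.null(meta[[f]])) stop("metadata sidecar missing field: ", f)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
  if (length(vals) != dims[1] * dims[2])
    stop("PGM pixel count mismatch in ", path)
  img <- matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  lp <- meta$log_params
  if (!is.null(lp) && !length(lp)) lp <- NULL
  bscan(img / meta$quant_scale, meta$axial_pitch_um, meta$lateral_pitch_um,
        scale = meta$scale, log_params = lp)
}

#' Read and write boundary files
#'
#' CSV format: columns \code{ascan_index} (1-based), \code{boundary_name},
#' \code{row_position} (0-based, sub-pixel), \code{valid}.  JSON format:
#' schema name plus per-boundary arrays.
#'
#' @param seg a \code{segmentation}.
#' @param path output file; format chosen by extension (.csv or .json).
#' @return \code{read_segmentation} returns a \code{segmentation}.
#' @export
write_segmentation <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation"))
  if (grepl("\\.json$", path)) {
    obj <- list(schema = seg$schema$name, source_model = seg$source_model,
                valid = seg$valid,
                boundaries = stats::setNames(
                  lapply(seq_len(nrow(seg$boundaries)),
                         function(k) unname(seg$boundaries[k, ])),
                  seg$schema$boundary_names))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    nb <- nrow(seg$boundaries)
    nc <- ncol(seg$boundaries)
    df <- data.frame(
      ascan_index = rep(seq_len(nc), times = nb),
      boundary_name = rep(seg$schema$boundary_names, each = nc),
      row_position = as.vector(t(seg$boundaries)),
      valid = rep(seg$valid, times = nb))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_segmentation
#' @param schema_name used when the file does not carry a schema (CSV);
#'   inferred from the boundary count if NULL.
#' @export
read_segmentation <- function(path, schema_name = NULL) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    sch <- layer_schema(obj$schema)
    B <- do.call(rbind, obj$boundaries[sch$boundary_names])
    return(new_segmentation(sch, B, obj$valid, obj$source_model))
  }
  df <- utils::read.csv(path)
  need <- c("ascan_index", "boundary_name", "row_position", "valid")
  if (!all(need %in% names(df)))
    stop("malformed boundary CSV ", path, ": missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(!is.finite(df$row_position))
  if (length(bad))
    stop("malformed boundary CSV ", path, ": non-numeric row_position at ",
         "line ", bad[1] + 1)
  if (is.null(schema_name)) {
    nb <- length(unique(df$boundary_name))
    schema_name <- if (nb == 9) "normal" else if (nb == 8) "degenerative" else
      stop("cannot infer schema from ", nb, " boundaries")
  }
  sch <- layer_schema(schema_name)
  nc <- max(df$ascan_index)
  B <- matrix(NA_real_, length(sch$boundary_names), nc)
  for (k in seq_along(sch$boundary_names)) {
    rows <- df[df$boundary_name == sch$boundary_names[k], ]
    if (nrow(rows) != nc)
      stop("malformed boundary CSV ", path, ": boundary ",
           sch$boundary_names[k], " has ", nrow(rows), " of ", nc, " A-scans")
    B[k, rows$ascan_index] <- rows$row_position
  }
  valid <- df$valid[df$boundary_name == sch$boundary_names[1]][
    order(df$ascan_index[df$boundary_name == sch$boundary_names[1]])]
  new_segmentation(sch, B, as.logical(valid), "file")
}

#' Write a study table with a fixed column order
#'
#' @param df long-format study table (mouse, eye, day, layer, metric, value,
#'   n).
#' @param path CSV output path.
#' @export
write_study_table <- function(df, path) {
  cols <- c("mouse", "eye", "day", "layer", "metric", "value", "n")
  stopifnot(all(cols %in% names(df)))
  utils::write.csv(df[, cols], path, row.names = FALSE)
  invisible(path)
}
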