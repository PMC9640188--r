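#' Write an image stack as multi-page TIFF files with a YAML sidecar
#'
#' Each channel is written as one multi-page 32-bit float TIFF (pages = z
#' planes), intensities scaled into [0, 1] by a per-channel factor recorded,
#' together with the spatial calibration, in a \code{<prefix>.yaml} sidecar.
#' \code{read_stack} restores the stack losslessly up to float precision.
#'
#' @param stack an \code{image_stack}.
#' @param prefix path prefix; files become \code{<prefix>_<channel>.tif} and
#'   \code{<prefix>.yaml}.
#' @return invisibly, the sidecar path.
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "image_stack"))
  meta <- list(pixel_size_xy = stack$pixel_size_xy,
               z_step = stack$z_step,
               axial_scale = stack$axial_scale,
               origin = as.numeric(stack$origin),
               channels = list())
  for (ch in names(stack$channels)) {
    vol <- stack$channels[[ch]]
    lo <- min(vol); hi <- max(vol)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(dim(vol)[3]),
                    function(k) (vol[, , k] - lo) / scale)
    path <- paste0(prefix, "_", ch, ".tif")
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    meta$channels[[ch]] <- list(file = basename(path), offset = lo,
                                scale = scale, n_planes = dim(vol)[3])
  }
  sidecar <- paste0(prefix, ".yaml")
  yaml::write_yaml(meta, sidecar)
  invisible(sidecar)
}

#' @rdname write_stack
#' @export
read_stack <- function(prefix) {
  sidecar <- paste0(prefix, ".yaml")
  if (!file.exists(sidecar)) stop("missing calibration sidecar: ", sidecar)
  meta <- yaml::read_yaml(sidecar)
  channels <- list()
  for (ch in names(meta$channels)) {
    info <- meta$channels[[ch]]
    pages <- tiff::readTIFF(file.path(dirname(prefix), info$file), all = TRUE)
    vol <- array(0, c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages))
      vol[, , k] <- pages[[k]] * info$scale + info$offset
    channels[[ch]] <- vol
  }
  image_stack(channels, meta$pixel_size_xy, meta$z_step, meta$axial_scale,
              origin = unlist(meta$origin))
}

annotation_schemas <- list(
  roi = c("cell_id", "structure", "x_px", "y_px", "z_plane", "roi_size_px"),
  points = c("cell_id", "object", "pair_id", "x_px", "y_px", "z_plane",
             "frame"),
  trace = c("cell_id", "bundle_id", "bundle_class", "point_index",
            "x_um", "y_um"),
  trajectory = c("cell_id", "pair_id", "frame", "sister", "x", "y", "z",
                 "elongation")
)

#' Read and validate an annotation table
#'
#' Reads a CSV of manual annotations and validates it against the schema for
#' its kind, reporting the offending column on mismatch. Kinds: \code{"roi"}
#' (square-ROI placements), \code{"points"} (kinetochore/pole/plate-edge
#' points), \code{"trace"} (bundle traces), \code{"trajectory"} (tracked
#' positions over time).
#'
#' @param path CSV file path.
#' @param kind schema to validate against.
#' @return the validated data.frame.
#' @export
read_annotations <- function(path, kind = c("roi", "points", "trace",
                                            "trajectory")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- annotation_schemas[[kind]]
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop(sprintf("annotation validation error: missing column(s) %s in %s",
                 paste(missing, collapse = ", "), basename(path)))
  df
}

#' Write measurement records and a human-readable summary
#'
#' @param records data.frame of per-object measurements.
#' @param path output CSV path; a \code{<path>.summary.txt} sibling receives a
#'   short column summary.
#' @return invisibly, the CSV path.
#' @export
write_reports <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  txt <- paste0(path, ".summary.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines(sprintf("%d records, %d columns", nrow(records), ncol(records)),
             con)
  num <- names(records)[vapply(records, is.numeric, TRUE)]
  for (cl in num)
    writeLines(sprintf("  %s: mean %.4g, sd %.4g", cl,
                       mean(records[[cl]], na.rm = TRUE),
                       stats::sd(records[[cl]], na.rm = TRUE)), con)
  invisible(path)
}
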