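#' Construct a CEUS cine loop
#'
#' A loop is an ordered stack of grayscale frames with per-frame timestamps.
#' Dual-display recordings hold the contrast (CEUS) panel in one horizontal
#' half of each frame and the B-mode panel in the other; `layout` says which.
#' Pixel coordinates throughout the package are 0-based `(x = column,
#' y = row)` and boxes are half-open `[x0, x1) x [y0, y1)`.
#'
#' @param pixels numeric array `rows x cols x n_frames`, values in `[0, 255]`.
#' @param times_s strictly increasing frame times in seconds from loop start.
#' @param layout `"ceus_left"` or `"ceus_right"`: which half of a dual frame
#'   is the contrast panel.
#' @param source_id opaque identifier carried through the pipeline.
#' @param injection_time_s contrast injection time on the loop clock
#'   (default 0 = loop start).
#' @param panel `"dual"` (side-by-side CEUS + B-mode) or `"ceus_only"`.
#' @return An object of class `ceus_loop`.
#' @export
ceus_loop <- function(pixels, times_s, layout = c("ceus_left", "ceus_right"),
                      source_id = "loop", injection_time_s = 0,
                      panel = c("dual", "ceus_only")) {
  layout <- match.arg(layout)
  panel <- match.arg(panel)
  if (length(dim(pixels)) != 3L)
    stop("pixels must be a rows x cols x frames array")
  nf <- dim(pixels)[3L]
  if (nf < 2L) stop("a loop needs at least 2 frames")
  if (length(times_s) != nf) stop("times_s length must match frame count")
  if (any(times_s < 0)) stop("frame times must be non-negative")
  if (any(diff(times_s) <= 0)) stop("frame times must be strictly increasing")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) stop("pixel values must lie in [0, 255]")
  structure(list(pixels = pixels, times_s = as.numeric(times_s),
                 layout = layout, panel = panel,
                 source_id = source_id,
                 injection_time_s = injection_time_s),
            class = "ceus_loop")
}

#' @export
print.ceus_loop <- function(x, ...) {
  dm <- dim(x$pixels)
  cat(sprintf("<ceus_loop '%s'> %d frames, %dx%d px (%s, %s), %.1f s\n",
              x$source_id, dm[3], dm[1], dm[2], x$panel, x$layout,
              loop_duration(x)))
  invisible(x)
}

#' Loop duration in seconds
#' @param loop a [ceus_loop()].
#' @return Last frame time minus first frame time (seconds).
#' @export
loop_duration <- function(loop) {
  diff(range(loop$times_s))
}

#' Read a multiframe DICOM cine loop
#'
#' Frame times are reconstructed from the frame-time vector when present
#' (cumulative sum of inter-frame increments), otherwise from the cine rate
#' or per-frame time tag. A file carrying none of these is rejected, mirroring
#' the usual "no frame timing" exclusion applied to clinical exports.
#' RGB frames are collapsed to grayscale by channel mean; only the grayscale
#' mean of the contrast panel is ever used downstream.
#'
#' @param path path to a multiframe DICOM file (explicit VR little endian).
#' @param layout which half of each dual frame is the CEUS panel.
#' @param panel `"dual"` or `"ceus_only"`.
#' @return A [ceus_loop()].
#' @export
read_ceus_loop <- function(path, layout = c("ceus_left", "ceus_right"),
                           panel = "dual") {
  layout <- match.arg(layout)
  tags <- .dicom_parse(path)
  rows <- .dicom_us(tags, "0028,0010")
  cols <- .dicom_us(tags, "0028,0011")
  nf <- .dicom_numeric(tags, "0028,0008")
  spp <- .dicom_us(tags, "0028,0002")
  if (is.null(spp)) spp <- 1L
  if (is.null(rows) || is.null(cols) || is.null(nf))
    stop("missing image geometry tags in ", path)
  nf <- as.integer(nf)

  ftv <- .dicom_numeric(tags, "0018,1065") # FrameTimeVector, ms increments
  if (!is.null(ftv) && length(ftv) == nf) {
    times <- cumsum(ftv) / 1000
    times <- times - times[1L]
  } else {
    ft <- .dicom_numeric(tags, "0018,1063") # FrameTime, ms
    cr <- .dicom_numeric(tags, "0018,0040") # CineRate, fps
    if (!is.null(ft) && is.finite(ft[1L]) && ft[1L] > 0) {
      times <- (seq_len(nf) - 1L) * ft[1L] / 1000
    } else if (!is.null(cr) && is.finite(cr[1L]) && cr[1L] > 0) {
      times <- (seq_len(nf) - 1L) / cr[1L]
    } else {
      stop("no frame timing in ", path,
           " (need FrameTimeVector, FrameTime or CineRate)")
    }
  }

  el <- tags[["7FE0,0010"]]
  if (is.null(el)) stop("no PixelData in ", path)
  vals <- as.numeric(el$bytes)
  need <- rows * cols * nf * spp
  if (length(vals) < need) stop("truncated PixelData in ", path)
  vals <- vals[seq_len(need)]
  if (spp == 3L) { # interleaved RGB -> grayscale channel mean
    vals <- (vals[seq(1, need, 3)] + vals[seq(2, need, 3)] +
               vals[seq(3, need, 3)]) / 3
  } else if (spp != 1L) {
    stop("unsupported SamplesPerPixel: ", spp)
  }
  # stored row-major per frame; R arrays are column-major
  px <- aperm(array(vals, dim = c(cols, rows, nf)), c(2L, 1L, 3L))
  ceus_loop(px, times, layout = layout,
            source_id = basename(path), panel = panel)
}

#' Write a loop as a multiframe DICOM file
#'
#' Inverse of [read_ceus_loop()]: pixels are stored as 8-bit grayscale and
#' frame times as a frame-time vector, so a write/read round trip reproduces
#' integer-valued pixel arrays and frame times exactly.
#'
#' @param loop a [ceus_loop()].
#' @param path output path.
#' @param instance_uid optional SOP instance UID (deterministic default).
#' @return `path`, invisibly.
#' @export
write_ceus_loop <- function(loop, path, instance_uid = NULL) {
  stopifnot(inherits(loop, "ceus_loop"))
  .dicom_write_multiframe(path, loop$pixels, loop$times_s,
                          instance_uid = instance_uid)
}

#' Split a dual-display frame into CEUS and B-mode panels
#'
#' @param frame numeric matrix (one grayscale frame).
#' @param layout which half is the contrast panel.
#' @param panel `"dual"` or `"ceus_only"`; a `ceus_only` frame is returned
#'   unchanged with an empty B-mode element.
#' @return `list(ceus = <matrix>, bmode = <matrix or NULL>)`.
#' @export
split_dual_panel <- function(frame, layout = c("ceus_left", "ceus_right"),
                             panel = "dual") {
  layout <- match.arg(layout)
  if (panel == "ceus_only") return(list(ceus = frame, bmode = NULL))
  w <- ncol(frame)
  if (w %% 2L != 0L) stop("dual frame width must be even, got ", w)
  half <- w %/% 2L
  left <- frame[, seq_len(half), drop = FALSE]
  right <- frame[, (half + 1L):w, drop = FALSE]
  if (layout == "ceus_left") list(ceus = left, bmode = right)
  else list(ceus = right, bmode = left)
}

# CEUS-panel pixel stack of a loop (rows x cols/2 x frames for dual layouts)
.ceus_panel_stack <- function(loop) {
  if (loop$panel == "ceus_only") return(loop$pixels)
  w <- dim(loop$pixels)[2L]
  if (w %% 2L != 0L) stop("dual frame width must be even, got ", w)
  half <- w %/% 2L
  if (loop$layout == "ceus_left") loop$pixels[, seq_len(half), , drop = FALSE]
  else loop$pixels[, (half + 1L):w, , drop = FALSE]
}

#' Construct a lesion annotation
#'
#' Clinicians mark the lesion's long and short axis with four caliper points
#' on one frame; those markers bound the lesion and seed the ROI crop.
#' Coordinates are 0-based pixels of the CEUS panel.
#'
#' @param frame_index 0-based index of the annotated frame.
#' @param markers 4x2 numeric matrix of `(x, y)` marker positions.
#' @param long_axis_mm,short_axis_mm lesion axes in millimetres.
#' @param panel_shape optional `c(rows, cols)` of the CEUS panel; when given,
#'   markers outside the panel are rejected.
#' @return An object of class `lesion_annotation`.
#' @export
lesion_annotation <- function(frame_index, markers, long_axis_mm,
                              short_axis_mm, panel_shape = NULL) {
  markers <- as.matrix(markers)
  if (nrow(markers) != 4L || ncol(markers) != 2L)
    stop("markers: expected 4 (x, y) points, got ", nrow(markers))
  if (!all(is.finite(markers))) stop("markers: non-finite coordinate")
  if (!is.finite(long_axis_mm) || long_axis_mm <= 0)
    stop("long_axis_mm: must be a positive number")
  if (!is.finite(short_axis_mm) || short_axis_mm <= 0)
    stop("short_axis_mm: must be a positive number")
  if (short_axis_mm > long_axis_mm)
    stop("short_axis_mm: must not exceed long_axis_mm")
  if (!is.null(panel_shape)) {
    if (any(markers[, 1] < 0) || any(markers[, 1] >= panel_shape[2]) ||
        any(markers[, 2] < 0) || any(markers[, 2] >= panel_shape[1]))
      stop("markers: outside the CEUS panel")
  }
  structure(list(frame_index = as.integer(frame_index),
                 markers = unname(markers),
                 long_axis_mm = long_axis_mm,
                 short_axis_mm = short_axis_mm),
            class = "lesion_annotation")
}

#' Read a sidecar lesion annotation (JSON)
#'
#' Sidecar schema: `{"frame_index": int, "markers": [[x,y] x 4],
#' "long_axis_mm": float, "short_axis_mm": float}`.
#'
#' @param path JSON file path.
#' @param panel_shape optional `c(rows, cols)` for an in-panel check.
#' @return A [lesion_annotation()].
#' @export
read_annotation <- function(path, panel_shape = NULL) {
  obj <- jsonlite::fromJSON(path)
  for (f in c("frame_index", "markers", "long_axis_mm", "short_axis_mm"))
    if (is.null(obj[[f]])) stop(f, ": missing from annotation ", path)
  lesion_annotation(obj$frame_index, obj$markers, obj$long_axis_mm,
                    obj$short_axis_mm, panel_shape = panel_shape)
}

#' Write a sidecar lesion annotation (JSON)
#' @param ann a [lesion_annotation()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "lesion_annotation"))
  obj <- list(frame_index = ann$frame_index,
              markers = ann$markers,
              long_axis_mm = ann$long_axis_mm,
              short_axis_mm = ann$short_axis_mm)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
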