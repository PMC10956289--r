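#' ROI box in CEUS-panel pixel coordinates
#'
#' Boxes are half-open `[x0, x1) x [y0, y1)` with 0-based `(x = column,
#' y = row)` coordinates.
#'
#' @param x0,y0,x1,y1 integer corners.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(x0, y0, x1, y1) {
  if (x1 <= x0 || y1 <= y0) stop("degenerate (zero-area) box")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "roi_box")
}

#' Axis-aligned bounding box of the four axis markers
#'
#' The markers are the caliper endpoints of the lesion's long and short axis;
#' their min/max coordinates bound the lesion. Four coincident markers get a
#' minimal 1x1 box; collinear markers (zero area in one dimension only) are
#' rejected.
#'
#' @param ann a [lesion_annotation()].
#' @return A [roi_box()].
#' @export
marker_bounding_box <- function(ann) {
  stopifnot(inherits(ann, "lesion_annotation"))
  m <- ann$markers
  x0 <- floor(min(m[, 1])); x1 <- ceiling(max(m[, 1]))
  y0 <- floor(min(m[, 2])); y1 <- ceiling(max(m[, 2]))
  if (x1 == x0 && y1 == y0) { x1 <- x0 + 1L; y1 <- y0 + 1L } # point markers
  if (x1 <= x0 || y1 <= y0) stop("degenerate (zero-area) box from markers")
  roi_box(x0, y0, x1, y1)
}

#' Expand an ROI box about its centre
#'
#' Width and height are each multiplied by `1 + factor` (default 0.5, i.e.
#' the 50% expansion that absorbs respiratory excursion of the lesion),
#' rounded outward and clipped to the panel.
#'
#' @param box a [roi_box()].
#' @param factor fractional growth per dimension (>= 0).
#' @param panel_shape `c(rows, cols)` of the CEUS panel for clipping.
#' @return A [roi_box()].
#' @export
expand_box <- function(box, factor = 0.5, panel_shape = NULL) {
  stopifnot(inherits(box, "roi_box"), factor >= 0)
  cx <- (box$x0 + box$x1) / 2; cy <- (box$y0 + box$y1) / 2
  hw <- (box$x1 - box$x0) * (1 + factor) / 2
  hh <- (box$y1 - box$y0) * (1 + factor) / 2
  x0 <- floor(cx - hw); x1 <- ceiling(cx + hw)
  y0 <- floor(cy - hh); y1 <- ceiling(cy + hh)
  if (!is.null(panel_shape)) {
    x0 <- max(x0, 0L); y0 <- max(y0, 0L)
    x1 <- min(x1, panel_shape[2]); y1 <- min(y1, panel_shape[1])
  }
  if (x1 <= x0 || y1 <= y0) stop("box empty after clipping to panel")
  roi_box(x0, y0, x1, y1)
}

#' Extract the lesion time-intensity curve
#'
#' Per-frame mean grayscale intensity of the CEUS panel over the box, paired
#' with the frame times.
#'
#' @param loop a [ceus_loop()].
#' @param box a [roi_box()] in CEUS-panel coordinates.
#' @return A [tic()].
#' @export
extract_tic <- function(loop, box) {
  stopifnot(inherits(loop, "ceus_loop"), inherits(box, "roi_box"))
  panel <- .ceus_panel_stack(loop)
  dm <- dim(panel)
  x0 <- max(box$x0, 0L); y0 <- max(box$y0, 0L)
  x1 <- min(box$x1, dm[2L]); y1 <- min(box$y1, dm[1L])
  if (x1 <= x0 || y1 <= y0) stop("empty box after clipping to panel")
  sub <- panel[(y0 + 1L):y1, (x0 + 1L):x1, , drop = FALSE]
  tic(loop$times_s, apply(sub, 3L, mean))
}

#' Reject out-of-plane frames by the 2-sigma residual rule
#'
#' A frame is kept iff the absolute difference between its mean intensity and
#' the fitted TIC is at most twice the standard deviation of the mean
#' intensities of all frames of the loop (the threshold is inclusive). Frames
#' pushed off-plane by respiration lose enhancement abruptly and show up as
#' large negative residuals against the smooth bolus fit.
#'
#' @param x a [tic()] (one sample per frame, loop order).
#' @param fit a `perfusion_fit` of that TIC.
#' @return Integer indices of kept frames, in original order.
#' @export
reject_outlier_frames <- function(x, fit) {
  stopifnot(inherits(x, "tic"), inherits(fit, "perfusion_fit"))
  sd_all <- stats::sd(x$intensities)
  resid <- abs(x$intensities - fit$fitted(x$times_s))
  kept <- which(resid <= 2 * sd_all)
  if (!length(kept)) stop("loop unusable: all frames rejected")
  kept
}

#' Segment a loop into the three liver contrast phases
#'
#' Phases follow the standard liver CEUS convention, anchored at bolus
#' arrival: arterial phase `[onset, onset + ap_end)`, portal-venous phase
#' `[onset + ap_end, onset + pvp_end)`, late phase `[onset + pvp_end,
#' loop end]`. Loops shorter than `min_duration_s` are excluded outright.
#'
#' @param onset_s bolus arrival time (seconds), or a `perfusion_fit` whose
#'   onset is used.
#' @param loop_end_s last frame time of the loop.
#' @param ap_end,pvp_end phase boundaries in seconds after onset
#'   (defaults 30 and 120).
#' @param min_duration_s minimum usable loop length (default 45 s).
#' @return An object of class `phase_segmentation` with elements `onset_s`,
#'   `ap`, `pvp`, `lp` (each `c(start, end)`).
#' @export
segment_phases <- function(onset_s, loop_end_s, ap_end = 30, pvp_end = 120,
                           min_duration_s = 45) {
  if (inherits(onset_s, "perfusion_fit")) onset_s <- onset_s$params$t0
  if (loop_end_s < min_duration_s)
    stop(sprintf("loop shorter than %g s (%.1f s): excluded",
                 min_duration_s, loop_end_s))
  if (loop_end_s <= onset_s + ap_end)
    stop("loop ends before the arterial phase completes")
  structure(list(onset_s = onset_s,
                 ap = c(onset_s, onset_s + ap_end),
                 pvp = c(onset_s + ap_end, min(onset_s + pvp_end, loop_end_s)),
                 lp = c(onset_s + pvp_end, loop_end_s)),
            class = "phase_segmentation")
}

# Anchor times for one phase. AP anchors run forward from the phase start;
# PVP/LP anchors run backward from the phase end (the last seconds of those
# phases carry the washout evidence). `shift` moves anchors into the phase.
.phase_anchors <- function(bounds, F, shift, back) {
  len <- bounds[2L] - bounds[1L]
  interval <- len / F
  if (back) bounds[2L] - (0:(F - 1L)) * interval - shift
  else bounds[1L] + (0:(F - 1L)) * interval + shift
}

#' Split a loop into phase-labelled mini-loops
#'
#' For each phase, `F` anchor times are laid out at equal intervals (forward
#' from the start of AP; backward from the end of PVP and LP). Mini-loop `j`
#' (`j = 0..M-1`) shifts every anchor by `j * interval / M` into its phase
#' and takes the kept frame nearest each shifted anchor, substituting the
#' next-nearest frame when a frame would be picked twice within a phase.
#' Selected frames are cropped with the (already expanded) ROI box and
#' resized to `input_size`.
#'
#' @param loop a [ceus_loop()].
#' @param kept_indices frame indices surviving [reject_outlier_frames()].
#' @param phases a [segment_phases()] result.
#' @param box expanded [roi_box()] used for cropping.
#' @param F frames per phase (default 4).
#' @param M number of mini-loops per loop (default 3).
#' @param input_size `c(rows, cols)` of the resized crop (default 224x224).
#' @param label optional case label (0 benign, 1 malignant).
#' @param case_id case identifier (default the loop's source id).
#' @return List of `M` `mini_loop` objects, each with `crops`
#'   (`input_size[1] x input_size[2] x 3F` array, AP then PVP then LP),
#'   `times_s`, `phase_labels`, `case_id`, `label`.
#' @export
build_mini_loops <- function(loop, kept_indices, phases, box, F = 4L, M = 3L,
                             input_size = c(224L, 224L), label = NULL,
                             case_id = loop$source_id) {
  stopifnot(inherits(loop, "ceus_loop"), inherits(phases, "phase_segmentation"),
            inherits(box, "roi_box"), F >= 1L, M >= 1L)
  panel <- .ceus_panel_stack(loop)
  dm <- dim(panel)
  x0 <- max(box$x0, 0L); y0 <- max(box$y0, 0L)
  x1 <- min(box$x1, dm[2L]); y1 <- min(box$y1, dm[1L])
  if (x1 <= x0 || y1 <= y0) stop("empty ROI box after clipping")
  times <- loop$times_s
  phase_list <- list(ap = list(b = phases$ap, back = FALSE),
                     pvp = list(b = phases$pvp, back = TRUE),
                     lp = list(b = phases$lp, back = TRUE))

  # candidate kept frames per phase (LP end inclusive)
  cand <- lapply(names(phase_list), function(ph) {
    b <- phase_list[[ph]]$b
    inside <- if (ph == "lp") times >= b[1L] & times <= b[2L] + 1e-9
    else times >= b[1L] & times < b[2L]
    idx <- kept_indices[inside[kept_indices]]
    if (length(idx) < F)
      stop(sprintf("phase %s has < F frames (%d < %d)", ph, length(idx), F))
    idx
  })
  names(cand) <- names(phase_list)

  crop_resize <- function(i) {
    img <- panel[(y0 + 1L):y1, (x0 + 1L):x1, i]
    if (!identical(dim(img), as.integer(input_size))) {
      img <- EBImage::resize(EBImage::Image(img / 255),
                             w = input_size[1L], h = input_size[2L])
      img <- pmin(pmax(EBImage::imageData(img), 0), 1) * 255
    }
    img
  }

  out <- vector("list", M)
  for (j in seq_len(M) - 1L) {
    sel_all <- integer(0)
    for (ph in names(phase_list)) {
      b <- phase_list[[ph]]$b
      interval <- (b[2L] - b[1L]) / F
      anchors <- .phase_anchors(b, F, j * interval / M, phase_list[[ph]]$back)
      idx <- cand[[ph]]
      chosen <- integer(0)
      for (a in anchors) {
        d <- abs(times[idx] - a)
        d[idx %in% chosen] <- Inf # next-nearest substitution
        pick <- idx[which.min(d)]
        chosen <- c(chosen, pick)
      }
      sel_all <- c(sel_all, sort(chosen))
    }
    crops <- array(0, dim = c(input_size[1L], input_size[2L], 3L * F))
    for (k in seq_along(sel_all)) crops[, , k] <- crop_resize(sel_all[k])
    out[[j + 1L]] <- structure(
      list(crops = crops, times_s = times[sel_all],
           frame_indices = sel_all,
           phase_labels = rep(c("ap", "pvp", "lp"), each = F),
           case_id = case_id, label = label),
      class = "mini_loop")
  }
  out
}

#' @export
print.mini_loop <- function(x, ...) {
  dm <- dim(x$crops)
  cat(sprintf("<mini_loop %s> %d crops %dx%d, label %s\n", x$case_id, dm[3],
              dm[1], dm[2], ifelse(is.null(x$label), "NA", x$label)))
  invisible(x)
}

#' One-call preprocessing of an annotated loop
#'
#' ROI crop from the markers (with 50% expansion), lesion TIC extraction,
#' best-model bolus fit, 2-sigma frame rejection, phase segmentation and
#' mini-loop construction.
#'
#' @inheritParams build_mini_loops
#' @param ann a [lesion_annotation()].
#' @param expand_factor ROI expansion (default 0.5).
#' @param ap_end,pvp_end phase bounds after onset (seconds).
#' @return List with `mini_loops`, `tic`, `fit`, `params`
#'   (a `perfusion_parameters`), `kept_indices`, `phases`, `box`.
#' @export
preprocess_loop <- function(loop, ann, F = 4L, M = 3L,
                            input_size = c(224L, 224L), expand_factor = 0.5,
                            ap_end = 30, pvp_end = 120, label = NULL) {
  panel_shape <- dim(.ceus_panel_stack(loop))[1:2]
  box <- expand_box(marker_bounding_box(ann), expand_factor, panel_shape)
  x <- extract_tic(loop, box)
  fit <- fit_best_model(x)
  kept <- reject_outlier_frames(x, fit)
  phases <- segment_phases(fit$params$t0, max(loop$times_s),
                           ap_end = ap_end, pvp_end = pvp_end)
  ml <- build_mini_loops(loop, kept, phases, box, F = F, M = M,
                         input_size = input_size, label = label)
  params <- derive_parameters(fit, ann$long_axis_mm)
  list(mini_loops = ml, tic = x, fit = fit, params = params,
       kept_indices = kept, phases = phases, box = box)
}
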