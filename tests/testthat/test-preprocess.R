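test_that("marker bounding boxes take the min/max of the four points", {
  box <- marker_bounding_box(make_square_annotation())
  expect_equal(unclass(box)[c("x0", "x1", "y0", "y1")],
               list(x0 = 100L, x1 = 200L, y0 = 100L, y1 = 200L))
  collinear <- lesion_annotation(0, rbind(c(10, 50), c(20, 50),
                                          c(14, 50), c(16, 50)), 5, 5)
  expect_error(marker_bounding_box(collinear), "degenerate")
  point <- lesion_annotation(0, matrix(rep(c(40, 60), each = 4), 4), 5, 5)
  tiny <- marker_bounding_box(point)
  expect_equal(c(tiny$x1 - tiny$x0, tiny$y1 - tiny$y0), c(1L, 1L))
})

test_that("box expansion is centred, outward-rounded and clipped", {
  box <- roi_box(100, 100, 200, 200)
  big <- expand_box(box, 0.5)
  expect_equal(c(big$x0, big$x1, big$y0, big$y1), c(75, 225, 75, 225))
  expect_equal(expand_box(box, 0), box)
  corner <- expand_box(roi_box(0, 0, 40, 40), 0.5, panel_shape = c(100, 100))
  expect_equal(c(corner$x0, corner$y0), c(0, 0))
  expect_lte((corner$x1 - corner$x0) * (corner$y1 - corner$y0), 60 * 60)
})

test_that("extract_tic averages the CEUS panel over the box", {
  loop <- make_toy_loop(c(50, 50, 50, 50, 50, 50, 50, 50))
  x <- extract_tic(loop, roi_box(1, 1, 5, 6))
  expect_equal(x$intensities, rep(50, 8))
  expect_equal(x$times_s, loop$times_s)
  expect_error(extract_tic(loop, roi_box(50, 1, 60, 6)), "empty box")
})

test_that("extracted TICs match the simulator ground truth", {
  # noiseless, motionless: inner lesion box reproduces the analytic TIC
  spec <- sample_case_spec("malignant", seed = 21, panel_shape = c(96L, 128L),
                           frame_rate_hz = 0.5, speckle_cv = 0,
                           tex_cv = 0, motion = list(amplitude_px = 0,
                                                     period_s = 4),
                           dropout = list(count = 0L, intensity_factor = 1))
  r <- render_loop(spec)
  x <- extract_tic(r$loop, r$truth$inner_box)
  expect_lt(max(abs(x$intensities - r$truth$lesion_tic)), 1)

  # default noise: mean abs error below 2% of peak
  spec2 <- sample_case_spec("malignant", seed = 21,
                            panel_shape = c(96L, 128L), frame_rate_hz = 0.5,
                            dropout = list(count = 0L, intensity_factor = 1))
  r2 <- render_loop(spec2)
  x2 <- extract_tic(r2$loop, r2$truth$inner_box)
  expect_lt(mean(abs(x2$intensities - r2$truth$lesion_tic)),
            0.02 * max(r2$truth$lesion_tic))

  # hyperenhancement: lesion box peaks above a pure-background box
  bg_box <- roi_box(2, 2, 20, 20)
  xbg <- extract_tic(r2$loop, bg_box)
  expect_gt(max(x2$intensities), max(xbg$intensities))
})

test_that("the 2-sigma rejection rule keeps the boundary inclusive", {
  t <- seq(0, 119, by = 1)
  p <- lognormal_params(t0 = 10, baseline = 5, auc = 2000, mu = 2.5,
                        sigma = 0.5)
  y <- model_curve("lognormal", p, t)
  fit <- new_perfusion_fit("lognormal", p, 0, range(t))
  expect_equal(reject_outlier_frames(tic(t, y), fit), seq_along(t))

  # exact boundary: a frame whose residual is bit-identical to 2*sd is kept
  yb <- y; yb[30] <- 0
  thr <- 2 * sd(yb)
  fit_b <- fit
  fit_b$fitted <- function(tt) {
    out <- model_curve("lognormal", p, tt)
    out[tt == t[30]] <- -thr # residual |0 - (-thr)| == thr exactly
    out
  }
  kept <- reject_outlier_frames(tic(t, yb), fit_b)
  expect_true(30 %in% kept) # <= is inclusive
  fit_b$fitted <- function(tt) {
    out <- model_curve("lognormal", p, tt)
    out[tt == t[30]] <- -thr * (1 + 1e-9)
    out
  }
  expect_false(30 %in% reject_outlier_frames(tic(t, yb), fit_b))

  # order preserved; a second pass over the surviving frames keeps them all
  expect_true(all(diff(kept) > 0))
  keep1 <- reject_outlier_frames(tic(t, y), fit)
  expect_identical(reject_outlier_frames(tic(t[keep1], y[keep1]), fit),
                   seq_along(keep1))
})

test_that("injected out-of-plane dropouts are rejected, clean frames kept", {
  res <- run_rejection_study(n_loops = 8, seed = 42)
  expect_gte(res$dropout_rejected_rate, 0.99)
  expect_gte(res$clean_kept_rate, 0.95)
})

test_that("phase segmentation follows the liver convention", {
  ph <- segment_phases(10, 360)
  expect_equal(ph$ap, c(10, 40))
  expect_equal(ph$pvp, c(40, 130))
  expect_equal(ph$lp, c(130, 360))
  expect_error(segment_phases(10, 44), "shorter than 45")
  ph2 <- segment_phases(10, 100)
  expect_true(ph2$lp[1] >= ph2$lp[2]) # empty LP under defaults
})

test_that("mini-loop anchors follow the forward/backward rules", {
  # dense loop: frame every 1 s over 0..360, lesion trivially constant
  nf <- 361
  px <- array(50, c(8, 12, nf))
  loop <- ceus_loop(px, 0:360)
  phases <- segment_phases(10, 360)
  box <- roi_box(0, 0, 6, 8)
  ml <- build_mini_loops(loop, seq_len(nf), phases, box, F = 4L, M = 1L,
                         input_size = c(8L, 8L))
  expect_length(ml, 1)
  # raw anchors: forward from AP start, backward from PVP/LP end
  expect_equal(ceusdx:::.phase_anchors(c(10, 40), 4L, 0, FALSE),
               c(10, 17.5, 25, 32.5))
  expect_equal(ceusdx:::.phase_anchors(c(130, 360), 4L, 0, TRUE),
               c(360, 302.5, 245, 187.5))
  times <- ml[[1]]$times_s
  # nearest-frame snapping (ties to the earlier frame) lands on 1 s frames
  expect_equal(times[1:4], c(10, 17, 25, 32))
  expect_equal(times[9:12], c(187, 245, 302, 360))
  expect_equal(ml[[1]]$phase_labels, rep(c("ap", "pvp", "lp"), each = 4))
})

test_that("M mini-loops are deterministic with disjoint AP picks", {
  nf <- 361
  px <- array(0, c(8, 12, nf))
  for (i in seq_len(nf)) px[, , i] <- (i %% 7) * 10
  loop <- ceus_loop(px, 0:360)
  phases <- segment_phases(10, 360)
  box <- roi_box(0, 0, 6, 8)
  ml1 <- build_mini_loops(loop, seq_len(nf), phases, box, F = 4L, M = 3L,
                          input_size = c(8L, 8L))
  ml2 <- build_mini_loops(loop, seq_len(nf), phases, box, F = 4L, M = 3L,
                          input_size = c(8L, 8L))
  expect_identical(ml1, ml2)
  ap_sets <- lapply(ml1, function(m) m$frame_indices[1:4])
  expect_equal(length(unique(unlist(ap_sets))), 12)
  for (m in ml1) {
    expect_equal(dim(m$crops)[3], 12)
    expect_true(all(diff(m$times_s[1:4]) > 0))
    expect_true(all(diff(m$times_s[5:8]) > 0))
    expect_true(all(diff(m$times_s[9:12]) > 0))
  }
})

test_that("a phase with too few kept frames errors", {
  px <- array(50, c(8, 12, 60))
  loop <- ceus_loop(px, seq(0, 295, by = 5))
  phases <- segment_phases(10, 295)
  box <- roi_box(0, 0, 6, 8)
  kept <- which(loop$times_s < 130 | loop$times_s > 280) # LP nearly emptied
  expect_error(build_mini_loops(loop, kept, phases, box, F = 4L, M = 1L,
                                input_size = c(8L, 8L)),
               "phase lp has < F frames")
})
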