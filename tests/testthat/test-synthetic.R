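test_that("case specs are seeded, deterministic and class-conditional", {
  s1 <- sample_case_spec("malignant", seed = 1)
  s2 <- sample_case_spec("malignant", seed = 1)
  expect_identical(s1, s2)
  expect_false(identical(s1, sample_case_spec("malignant", seed = 2)))

  small <- list(panel_shape = c(64L, 96L), frame_rate_hz = 0.5)
  for (s in c(1, 7, 19)) {
    rm_ <- render_loop(sample_case_spec("malignant", seed = s,
                                        panel_shape = small$panel_shape,
                                        frame_rate_hz = small$frame_rate_hz))
    rb <- render_loop(sample_case_spec("benign", seed = s,
                                       panel_shape = small$panel_shape,
                                       frame_rate_hz = small$frame_rate_hz))
    # malignant: true TIC washes out steeply after its peak
    y <- rm_$truth$lesion_tic; t <- rm_$truth$times_s
    post <- which.max(y):length(y)
    slope <- coef(lm(y[post] ~ t[post]))[[2]]
    expect_lt(slope, -0.05)
    # benign: sustained, essentially flat late slope
    expect_lt(abs(ceusdx:::.true_late_slope(rb$truth)), 0.02)
    # washout below parenchyma (malignant), sustained above it (benign)
    lp <- t >= rm_$truth$onset_s + 120
    expect_true(all(rm_$truth$lesion_tic[lp] < rm_$truth$background_tic[lp]))
    expect_true(all(rb$truth$lesion_tic[lp] >= rb$truth$background_tic[lp]))
  }
})

test_that("rendered loops honour the dropout and motion ground truth", {
  spec <- sample_case_spec("benign", seed = 9, panel_shape = c(64L, 96L),
                           frame_rate_hz = 0.5,
                           dropout = list(count = 5L, intensity_factor = 0.6))
  r <- render_loop(spec)
  expect_length(r$truth$dropout_indices, 5)
  panel <- ceusdx:::.ceus_panel_stack(r$loop)
  means <- apply(panel, 3, mean)
  for (i in r$truth$dropout_indices) {
    neighbours <- mean(means[setdiff(max(1, i - 2):min(length(means), i + 2),
                                     r$truth$dropout_indices)])
    expect_lt(means[i], 0.75 * neighbours)
  }

  # TIC variance over the lesion box grows with motion amplitude
  v <- vapply(c(0, 10), function(amp) {
    sp <- sample_case_spec("benign", seed = 9, panel_shape = c(64L, 96L),
                           frame_rate_hz = 0.5,
                           motion = list(amplitude_px = amp, period_s = 3.7),
                           dropout = list(count = 0L, intensity_factor = 1))
    rr <- render_loop(sp)
    box <- expand_box(marker_bounding_box(rr$annotation), 0.5, c(64, 96))
    x <- extract_tic(rr$loop, box)
    late <- x$times_s > rr$truth$onset_s + 20
    var(x$intensities[late] - rr$truth$lesion_tic[late])
  }, numeric(1))
  expect_gt(v[2], v[1])
})

test_that("lesions outside the panel are refused", {
  spec <- sample_case_spec("benign", seed = 1, panel_shape = c(64L, 96L))
  spec$lesion_center <- c(x = 2, y = 2)
  expect_error(render_loop(spec), "outside")
})

test_that("generated datasets are reproducible and complete", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  args <- list(n_benign = 2L, n_malignant = 2L, seed = 7,
               panel_shape = c(32L, 48L), duration_s = 50,
               frame_rate_hz = 0.2)
  m1 <- do.call(generate_dataset, c(list(out_dir = d1), args))
  m2 <- do.call(generate_dataset, c(list(out_dir = d2), args))
  expect_equal(nrow(m1), 4)
  expect_equal(sum(m1$label), 2)
  expect_identical(readBin(file.path(d1, "manifest.csv"), "raw", 1e6),
                   readBin(file.path(d2, "manifest.csv"), "raw", 1e6))
  # loop files byte-identical too
  expect_identical(readBin(file.path(d1, m1$dicom[1]), "raw", 1e7),
                   readBin(file.path(d2, m2$dicom[1]), "raw", 1e7))
  loop <- read_ceus_loop(file.path(d1, m1$dicom[1]), "ceus_left")
  expect_s3_class(loop, "ceus_loop")
  ann <- read_annotation(file.path(d1, m1$annotation[1]))
  expect_s3_class(ann, "lesion_annotation")
})

test_that("generator -> io -> preprocess -> perfusion recovers truth", {
  # the central oracle chain, at default noise
  spec <- sample_case_spec("malignant", seed = 31, panel_shape = c(96L, 128L),
                           frame_rate_hz = 0.5)
  r <- render_loop(spec)
  dcm <- withr::local_tempfile(fileext = ".dcm")
  write_ceus_loop(r$loop, dcm)
  loop <- read_ceus_loop(dcm, "ceus_left")
  x <- extract_tic(loop, r$truth$inner_box)
  fit <- fit_best_model(x)
  tp <- r$truth$true_parameters
  dp <- derive_parameters(fit, tp$lesion_size_mm)
  expect_lt(abs(dp$onset_time_s - tp$onset_time_s), 2)
  expect_lt(abs(dp$peak_time_s - tp$peak_time_s) / tp$peak_time_s, 0.1)
  # fitted curve tracks the true lesion kinetics well inside the window
  tt <- seq(tp$onset_time_s + 1, 170, by = 1)
  true_y <- model_curve(spec$lesion_kinetics$model_id,
                        spec$lesion_kinetics$params, tt)
  expect_lt(mean(abs(fit$fitted(tt) - true_y)), 0.05 * tp$peak_intensity)
})
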