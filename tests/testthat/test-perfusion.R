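test_that("model curves return baseline before onset and a bolus after", {
  t <- seq(0, 60, by = 0.5)
  for (m in perfusion_models) {
    p <- ceusdx:::.random_model_params(m)
    p$t0 <- 10; p$baseline <- 4
    y <- model_curve(m, p, t)
    expect_equal(y[t <= 10], rep(4, sum(t <= 10)), info = m)
    expect_true(all(y >= 4 - 1e-9), info = m)
    expect_gt(max(y), 4)
    # unimodal past onset: rises then falls around a single maximum
    post <- y[t > 10]
    i <- which.max(post)
    expect_true(all(diff(post[seq_len(i)]) >= -1e-9), info = m)
    expect_true(all(diff(post[i:length(post)]) <= 1e-9), info = m)
  }
  expect_error(model_curve("lognormal", lognormal_params(sigma = -1), t),
               "non-positive")
  expect_error(model_curve("lognormal", list(t0 = 1), t), "missing")
})

test_that("lognormal and gamma-variate peak times and means match their closed forms", {
  grid <- seq(0.001, 120, length.out = 400001)
  ln <- lognormal_params()
  y <- model_curve("lognormal", ln, grid)
  expect_equal(grid[which.max(y)], 5 + exp(2 - 0.25), tolerance = 1e-3)
  gv <- list(t0 = 5, baseline = 0, auc = 100, alpha = 2, beta = 3)
  y2 <- model_curve("gamma_variate", gv, grid)
  expect_equal(grid[which.max(y2)], 5 + 2 * 3, tolerance = 1e-3)

  # first moments against quadrature, all families (the lagged normal
  # reports MTT from its effective onset rather than the raw delay t0)
  for (m in perfusion_models) {
    p <- ceusdx:::.random_model_params(m)
    fit <- new_perfusion_fit(m, p, 0, c(0, 120))
    dp <- derive_parameters(fit, 20)
    shift <- dp$onset_time_s - p$t0
    expect_equal(dp$mtt_s + shift, ceusdx:::.numeric_mtt(fit),
                 tolerance = 1e-3, info = m)
  }
})

test_that("noiseless self-generated TICs are recovered within 1%", {
  t <- seq(0, 120, by = 2)
  set.seed(99)
  for (m in perfusion_models) {
    p <- ceusdx:::.random_model_params(m)
    x <- tic(t, model_curve(m, p, t))
    f <- fit_model(x, m)
    expect_lt(f$rss, 1e-6 * sum(x$intensities^2))
    dp <- derive_parameters(f, 20)
    tdp <- derive_parameters(new_perfusion_fit(m, p, 0, range(t)), 20)
    expect_lt(abs(dp$auc - tdp$auc) / tdp$auc, 0.01)
    expect_lt(abs(dp$peak_time_s - tdp$peak_time_s) / tdp$peak_time_s, 0.01)
    expect_lt(abs(dp$mtt_s - tdp$mtt_s) / tdp$mtt_s, 0.01)
  }
})

test_that("noisy lognormal TICs recover auc and peak time within 5% (median)", {
  t <- seq(0, 120, by = 2)
  p <- lognormal_params(t0 = 8, baseline = 3, auc = 900, mu = 2.3,
                        sigma = 0.55)
  clean <- model_curve("lognormal", p, t)
  tdp <- derive_parameters(new_perfusion_fit("lognormal", p, 0, range(t)), 20)
  set.seed(4)
  errs <- t(replicate(40, {
    y <- pmax(clean + rnorm(length(t), 0, 0.02 * max(clean)), 0)
    dp <- derive_parameters(fit_model(tic(t, y), "lognormal"), 20)
    c(auc = abs(dp$auc - tdp$auc) / tdp$auc,
      pk = abs(dp$peak_time_s - tdp$peak_time_s) / tdp$peak_time_s)
  }))
  expect_lt(median(errs[, "auc"]), 0.05)
  expect_lt(median(errs[, "pk"]), 0.05)
})

test_that("degenerate TICs are refused", {
  t <- seq(0, 30, by = 1)
  expect_error(fit_model(tic(t, rep(50, length(t))), "lognormal"),
               "degenerate")
  expect_error(fit_model(tic(1:7, c(1, 2, 5, 9, 5, 2, 1)), "lognormal"),
               "at least 8")
})

test_that("best-model selection is the RSS argmin with enum-order ties", {
  t <- seq(0, 120, by = 2)
  set.seed(7)
  for (rep in 1:5) {
    m <- sample(perfusion_models, 1)
    p <- ceusdx:::.random_model_params(m)
    y <- pmax(model_curve(m, p, t) + rnorm(length(t), 0, 0.5), 0)
    best <- fit_best_model(tic(t, y))
    expect_true(all(best$rss <= best$all_rss + 1e-12))
  }
  # noiseless lognormal: winning curve reproduces the generator pointwise
  p <- lognormal_params(t0 = 8, baseline = 2, auc = 800, mu = 2.4,
                        sigma = 0.5)
  y <- model_curve("lognormal", p, t)
  best <- fit_best_model(tic(t, y))
  expect_lt(max(abs(best$fitted(t) - y)), 0.01 * max(y))
})

test_that("ties break by model enum order", {
  # force identical RSS by handing fit_best_model a flat-noise-free curve
  # both families can fit exactly is impractical; instead check the rule
  # directly on the ordering used by fit_best_model
  expect_equal(perfusion_models[1], "lognormal")
  t <- seq(0, 120, by = 2)
  p <- lognormal_params(t0 = 8, baseline = 2, auc = 800, mu = 2.4, sigma = 0.5)
  best <- fit_best_model(tic(t, model_curve("lognormal", p, t)))
  # ldrw/fpt/lagged-normal can match the curve to near machine precision,
  # but an exact tie must resolve to the earliest family in enum order
  rss <- best$all_rss
  tied <- names(rss)[rss <= min(rss) + 1e-15]
  expect_equal(best$model_id, intersect(perfusion_models, tied)[1])
})

test_that("derived gradients follow their definitions", {
  # near-flat post-peak plateau: wash-out gradient is essentially zero,
  # orders of magnitude below the wash-in gradient
  flat <- new_perfusion_fit(
    "gamma_variate",
    ceusdx:::.gamma_from_plateau(0, 0, 0.5, 300, 60, at = 150),
    0, c(0, 180))
  dpf <- derive_parameters(flat, 20)
  expect_lt(abs(dpf$wash_out_gradient), 0.05)
  expect_lt(abs(dpf$wash_out_gradient), 0.1 * dpf$wash_in_gradient)

  # lognormal closed forms flow into derive_parameters
  fit <- new_perfusion_fit("lognormal", lognormal_params(), 0, c(0, 60))
  out <- derive_parameters(fit, 25)
  expect_equal(out$onset_time_s, 5)
  expect_equal(out$peak_time_s, 5 + exp(2 - 0.25))
  expect_equal(out$mtt_s, exp(2 + 0.125))
  expect_equal(out$lesion_size_mm, 25)
  expect_gt(out$wash_in_gradient, 0)
  expect_lt(out$wash_out_gradient, 0)

  # peak at/after the window end: wash-out unavailable
  late <- new_perfusion_fit("lognormal", lognormal_params(), 0, c(0, 10.75))
  expect_true(is.na(derive_parameters(late, 25)$wash_out_gradient))
})

test_that("parameter error degrades monotonically with noise", {
  t <- seq(0, 120, by = 2)
  p <- lognormal_params(t0 = 8, baseline = 3, auc = 900, mu = 2.3,
                        sigma = 0.55)
  clean <- model_curve("lognormal", p, t)
  tdp <- derive_parameters(new_perfusion_fit("lognormal", p, 0, range(t)), 20)
  med_err <- vapply(c(0, 0.01, 0.02, 0.05), function(cv) {
    set.seed(11)
    median(replicate(15, {
      y <- pmax(clean + rnorm(length(t), 0, cv * max(clean)), 0)
      dp <- derive_parameters(fit_model(tic(t, y), "lognormal"), 20)
      abs(dp$auc - tdp$auc) / tdp$auc
    }))
  }, numeric(1))
  expect_true(all(diff(med_err) >= -1e-6))
})

test_that("TIC CSV round-trips", {
  x <- tic(c(0, 1, 2.5), c(5, 9, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tic(x, path)
  back <- read_tic(path)
  expect_equal(back$times_s, x$times_s)
  expect_equal(back$intensities, x$intensities)
})
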