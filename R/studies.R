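# Self-contained simulation studies: cohort builders and end-to-end runs
# shared by the test-suite and the acceptance script. Problem sizes default
# to desk-scale settings (small panels, 0.5 Hz loops, 32x32 crops).

#' Build a preprocessed synthetic cohort for the end-to-end classifier
#'
#' Renders `n_per_class` loops per class, runs the full preprocessing chain
#' (ROI from markers, best-model TIC fit, 2-sigma rejection, phase
#' segmentation, mini-loop sampling) and returns per-case mini-loops plus
#' the 8 TIC features, ready for [compare_methods()] or [run_e2e_study()].
#'
#' @param n_per_class cases per class.
#' @param seed master seed.
#' @param panel_shape,frame_rate_hz rendering geometry (scaled-down
#'   defaults for CPU runs).
#' @param F,M,input_size mini-loop sampling parameters.
#' @return List of cases: `list(case_id, label, mini_loops, features)`.
#' @export
build_e2e_cohort <- function(n_per_class = 30L, seed = 1L,
                             panel_shape = c(96L, 128L), frame_rate_hz = 0.5,
                             F = 4L, M = 3L, input_size = c(32L, 32L)) {
  labels <- rep(c("benign", "malignant"), each = n_per_class)
  case_seeds <- .with_seed(seed, sample.int(2^30, length(labels)))
  lapply(seq_along(labels), function(i) {
    r <- render_loop(sample_case_spec(labels[i], seed = case_seeds[i],
                                      panel_shape = panel_shape,
                                      frame_rate_hz = frame_rate_hz))
    y <- as.integer(labels[i] == "malignant")
    pp <- preprocess_loop(r$loop, r$annotation, F = F, M = M,
                          input_size = input_size, label = y)
    list(case_id = sprintf("case_%03d", i), label = y,
         mini_loops = pp$mini_loops, features = build_features(pp$params))
  })
}

#' Train/held-out evaluation of the CNN-LSTM on a preprocessed cohort
#'
#' One stratified fold (of `k`) is held out; the CNN-LSTM trains on the
#' rest under the standard 6-epoch schedule and is scored by case-level
#' mean-probability AUC on the held-out cases.
#'
#' @param cases cohort from [build_e2e_cohort()].
#' @param seed seed for folds, init and shuffling.
#' @param mcfg,tcfg optional configs (defaults: `small_cnn` at the cohort's
#'   crop size; [train_config()] with this seed).
#' @param k folds used for the split (default 4; fold 1 is held out).
#' @return List with `auc`, `case_probs`, `labels`, `history`.
#' @export
run_e2e_study <- function(cases, seed = 1L, mcfg = NULL, tcfg = NULL,
                          k = 4L) {
  labels <- vapply(cases, function(cs) as.integer(cs$label), integer(1L))
  if (is.null(mcfg)) {
    dmc <- dim(cases[[1L]]$mini_loops[[1L]]$crops)
    mcfg <- model_config("small_cnn", input_size = dmc[1:2])
  }
  if (is.null(tcfg)) tcfg <- train_config(seed = seed)
  folds <- stratified_kfold(labels, k = k, seed = seed)
  tr <- which(folds != 1L); te <- which(folds == 1L)
  tr_ml <- unlist(lapply(cases[tr], function(cs) cs$mini_loops),
                  recursive = FALSE)
  fit <- train_cnn_lstm(tr_ml, mcfg, tcfg)
  probs <- vapply(te, function(i) {
    p <- vapply(cases[[i]]$mini_loops, predict_miniloop, numeric(1L),
                weights = fit$weights, config = mcfg)
    aggregate_case(p)$case_prob
  }, numeric(1L))
  list(auc = roc_auc(probs, labels[te])$auc, case_probs = probs,
       labels = labels[te], history = fit$history)
}

#' TIC-feature cohort for the gradient-boosted baseline
#'
#' Synthesises one lesion TIC per case from the class-conditional kinetics
#' (1 Hz sampling over 180 s, additive Gaussian noise of 2% of the curve
#' peak), fits the best bolus model and derives the 8 features. A fraction
#' of labels is flipped to emulate adjudication noise.
#'
#' @param n_per_class cases per class (default 100).
#' @param seed master seed.
#' @param label_noise fraction of flipped labels (default 0.05).
#' @return `list(features (n x 8 matrix), labels, true_labels)`.
#' @export
build_baseline_cohort <- function(n_per_class = 100L, seed = 1L,
                                  label_noise = 0.05) {
  labels <- rep(c(0L, 1L), each = n_per_class)
  n <- length(labels)
  case_seeds <- .with_seed(seed, sample.int(2^30, n))
  times <- seq(0, 180, by = 1)
  feats <- matrix(NA_real_, n, 8L)
  for (i in seq_len(n)) {
    spec <- sample_case_spec(ifelse(labels[i] == 1L, "malignant", "benign"),
                             seed = case_seeds[i])
    y <- .kinetics_at(spec$lesion_kinetics, times)
    y <- .with_seed(case_seeds[i] + 1L,
                    pmax(y + stats::rnorm(length(y), 0, 0.02 * max(y)), 0))
    fit <- fit_best_model(tic(times, y))
    feats[i, ] <- build_features(
      derive_parameters(fit, 2 * spec$lesion_axes_px[["a"]] * spec$mm_per_px))
  }
  colnames(feats) <- c("onset_time_s", "peak_time_s", "peak_intensity",
                       "auc", "mtt_s", "wash_in_gradient",
                       "wash_out_gradient", "lesion_size_mm")
  noisy <- .with_seed(seed + 1L, {
    flip <- sample.int(n, round(label_noise * n))
    out <- labels
    out[flip] <- 1L - out[flip]
    out
  })
  list(features = feats, labels = noisy, true_labels = labels)
}

#' Held-out AUC of the boosted-tree baseline on a TIC-feature cohort
#'
#' Stratified half/half split: train on one half, score the other.
#'
#' @param cohort from [build_baseline_cohort()].
#' @param seed split/booster seed.
#' @param shuffle_labels permute training labels first (null control).
#' @return Held-out AUC.
#' @export
run_baseline_study <- function(cohort, seed = 1L, shuffle_labels = FALSE) {
  labels <- cohort$labels
  folds <- stratified_kfold(labels, k = 2L, seed = seed)
  tr <- which(folds == 1L); te <- which(folds == 2L)
  ytr <- labels[tr]
  if (shuffle_labels) ytr <- .with_seed(seed + 2L, sample(ytr))
  model <- train_baseline(cohort$features[tr, ], ytr, seed = seed)
  roc_auc(predict_baseline(model, cohort$features[te, ]), labels[te])$auc
}

#' Out-of-plane frame-rejection study
#'
#' Renders seeded sustained-enhancement loops (the dropout phantom: early
#' onset 3-5 s, plateau 55-75, 240 s at 0.75 Hz) with `n_dropout` injected
#' out-of-plane frames retaining 60% intensity, runs the ROI + fit + 2-sigma
#' rejection chain, and tallies how many injected dropouts were rejected and
#' how many clean frames survived.
#'
#' @param n_loops number of loops (default 100).
#' @param seed master seed.
#' @param n_dropout injected dropout frames per loop (default 5).
#' @param panel_shape rendering size.
#' @return `list(dropout_rejected_rate, clean_kept_rate, n_loops)`.
#' @export
run_rejection_study <- function(n_loops = 100L, seed = 1L, n_dropout = 5L,
                                panel_shape = c(96L, 128L)) {
  seeds <- .with_seed(seed, sample.int(2^30, n_loops))
  rej <- tot <- kept_clean <- tot_clean <- 0L
  for (s in seeds) {
    spec <- sample_case_spec("benign", seed = s, onset_range = c(3, 5),
                             duration_s = 240, frame_rate_hz = 0.75,
                             panel_shape = panel_shape,
                             dropout = list(count = as.integer(n_dropout),
                                            intensity_factor = 0.6))
    r <- render_loop(spec)
    panel_dim <- dim(.ceus_panel_stack(r$loop))[1:2]
    box <- expand_box(marker_bounding_box(r$annotation), 0.5, panel_dim)
    x <- extract_tic(r$loop, box)
    kept <- reject_outlier_frames(x, fit_best_model(x))
    di <- r$truth$dropout_indices
    clean <- setdiff(seq_along(x$times_s), di)
    rej <- rej + sum(!di %in% kept); tot <- tot + length(di)
    kept_clean <- kept_clean + sum(clean %in% kept)
    tot_clean <- tot_clean + length(clean)
  }
  list(dropout_rejected_rate = rej / tot,
       clean_kept_rate = kept_clean / tot_clean, n_loops = n_loops)
}

#' Parameter-recovery study for the five bolus models
#'
#' For each model family, draws random parameter sets, generates noiseless
#' TICs (0-120 s at 2 s spacing) and refits the same family; reports the
#' worst relative recovery error of AUC, peak time and mean transit time,
#' and the slowest single fit.
#'
#' @param n_draws draws per family (default 20).
#' @param seed master seed.
#' @return `list(max_rel_error, max_fit_seconds, per_model)`.
#' @export
run_recovery_study <- function(n_draws = 20L, seed = 1L) {
  t <- seq(0, 120, by = 2)
  per <- list()
  worst <- 0; slowest <- 0
  .with_seed(seed, {
    for (m in perfusion_models) {
      errs <- numeric(n_draws)
      for (i in seq_len(n_draws)) {
        p <- .random_model_params(m)
        x <- tic(t, model_curve(m, p, t))
        el <- system.time(f <- fit_model(x, m))[["elapsed"]]
        slowest <- max(slowest, el)
        dp <- derive_parameters(f, 20)
        tdp <- derive_parameters(new_perfusion_fit(m, p, 0, range(t)), 20)
        errs[i] <- max(abs(dp$auc - tdp$auc) / tdp$auc,
                       abs(dp$peak_time_s - tdp$peak_time_s) / tdp$peak_time_s,
                       abs(dp$mtt_s - tdp$mtt_s) / tdp$mtt_s)
      }
      per[[m]] <- max(errs)
      worst <- max(worst, max(errs))
    }
  })
  list(max_rel_error = worst, max_fit_seconds = slowest, per_model = per)
}

# random but fit-range-compatible parameter draws, one family
.random_model_params <- function(model_id) {
  base <- list(t0 = stats::runif(1, 3, 15),
               baseline = stats::runif(1, 0, 8),
               auc = stats::runif(1, 300, 1500))
  c(base, switch(model_id,
    lognormal = list(mu = stats::runif(1, 1.5, 2.8),
                     sigma = stats::runif(1, 0.3, 0.8)),
    gamma_variate = list(alpha = stats::runif(1, 1.2, 4),
                         beta = stats::runif(1, 2, 6)),
    ldrw = list(mu = stats::runif(1, 8, 20),
                lambda = stats::runif(1, 1.5, 5)),
    fpt = list(mu = stats::runif(1, 8, 20),
               lambda = stats::runif(1, 1.5, 5)),
    # mu_g >= ~3.2 sigma_g keeps the Gaussian edge clear of zero, the
    # regime where the lagged normal's delay is identifiable
    lagged_normal = list(mu_g = stats::runif(1, 8, 12),
                         sigma_g = stats::runif(1, 1.5, 2.5),
                         tau = stats::runif(1, 3, 8))))
}
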