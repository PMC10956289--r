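#' Assemble the TIC-feature vector for the gradient-boosted baseline
#'
#' Fixed order: onset time, peak time, peak intensity, AUC, mean transit
#' time, wash-in gradient, wash-out gradient, lesion size. A missing
#' wash-out gradient (peak beyond the observation window) is imputed as 0;
#' any other non-finite entry is an error naming the offending field.
#'
#' @param params a `perfusion_parameters` from [derive_parameters()].
#' @return Named numeric vector of length 8.
#' @export
build_features <- function(params) {
  stopifnot(inherits(params, "perfusion_parameters"))
  v <- c(onset_time_s = params$onset_time_s,
         peak_time_s = params$peak_time_s,
         peak_intensity = params$peak_intensity,
         auc = params$auc,
         mtt_s = params$mtt_s,
         wash_in_gradient = params$wash_in_gradient,
         wash_out_gradient = params$wash_out_gradient,
         lesion_size_mm = params$lesion_size_mm)
  if (is.na(v[["wash_out_gradient"]])) v[["wash_out_gradient"]] <- 0
  bad <- names(v)[!is.finite(v)]
  if (length(bad)) stop("non-finite feature: ", paste(bad, collapse = ", "))
  v
}

#' Train the gradient-boosted-tree TIC baseline
#'
#' Boosted decision trees (200 rounds, depth 3, learning rate 0.1 unless
#' overridden) on the 8 TIC features, predicting malignancy probability.
#'
#' @param features numeric matrix (cases x 8) from [build_features()].
#' @param labels 0/1 vector.
#' @param seed RNG seed for the booster.
#' @param nrounds,max_depth,eta booster hyperparameters.
#' @return A `baseline_model` wrapping the fitted booster.
#' @export
train_baseline <- function(features, labels, seed = 1L, nrounds = 200L,
                           max_depth = 3L, eta = 0.1) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L)
    stop("training labels must contain both classes")
  .with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(features, label = labels, nthread = 1L)
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1L, seed = seed),
      data = dtrain, nrounds = nrounds, verbose = 0)
    structure(list(booster = booster, n_features = ncol(features)),
              class = "baseline_model")
  })
}

#' Predict malignancy probability with the TIC baseline
#' @param model a `baseline_model`.
#' @param features matrix or vector of 8 TIC features.
#' @return Probabilities in `[0, 1]`.
#' @export
predict_baseline <- function(model, features) {
  stopifnot(inherits(model, "baseline_model"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  if (ncol(features) != model$n_features)
    stop("expected ", model$n_features, " features, got ", ncol(features))
  as.numeric(predict(model$booster,
                     xgboost::xgb.DMatrix(features, nthread = 1L)))
}
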