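#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`.
#'
#' @param tp,fn,tn,fp non-negative counts.
#' @return `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(tp, fn, tn, fp) {
  if (tp + fn == 0) stop("no positive cases: sensitivity undefined")
  if (tn + fp == 0) stop("no negative cases: specificity undefined")
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps thresholds over the unique scores (ties grouped), accumulating
#' true/false positive rates; the AUC is the trapezoidal area, which equals
#' the Mann-Whitney statistic `P(score_pos > score_neg) + P(tie)/2`.
#'
#' @param scores numeric scores (higher = more malignant).
#' @param labels 0/1 vector.
#' @return A `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("ROC needs both classes present")
  if (length(scores) != length(labels)) stop("length mismatch")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  # group tied scores
  grp <- cumsum(!duplicated(s))
  tp <- tapply(y == 1L, grp, sum)
  fp <- tapply(y == 0L, grp, sum)
  tpr <- c(0, cumsum(tp) / npos)
  fpr <- c(0, cumsum(fp) / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[!duplicated(s)]),
                 tpr = as.numeric(tpr), fpr = as.numeric(fpr),
                 auc = auc),
            class = "roc_result")
}

#' Stratified patient-level k-fold assignment
#'
#' Cases are split per class by seeded shuffling and round-robin dealing, so
#' per-fold class proportions differ from the global ones by at most one
#' case. Splitting is per case: every mini-loop of a case inherits the
#' case's fold, which rules out case-level leakage between folds.
#'
#' @param labels per-case 0/1 labels.
#' @param k number of folds (default 4).
#' @param seed RNG seed.
#' @return Integer fold assignment (1..k) per case.
#' @export
stratified_kfold <- function(labels, k = 4L, seed = 1L) {
  labels <- as.integer(labels)
  folds <- integer(length(labels))
  .with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop("class ", cl, " has fewer cases (", length(idx),
             ") than folds (", k, ")")
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated comparison of the CNN-LSTM and the TIC baseline
#'
#' Both methods consume the same preprocessing output (shared TIC fits,
#' shared stratified case-level folds), so the comparison is like for like.
#' For each fold the CNN-LSTM trains on the remaining folds and predicts the
#' held-out cases by majority vote / mean probability; the boosted-tree
#' baseline does the same from the 8 TIC features.
#'
#' @param cases list of preprocessed cases, each
#'   `list(case_id, label, mini_loops, features)` (as produced by
#'   [preprocess_loop()] + [build_features()]).
#' @param mcfg a [model_config()].
#' @param tcfg a [train_config()].
#' @param k folds (default 4).
#' @param seed fold/shuffle seed.
#' @param thresholds operating thresholds for sensitivity/specificity.
#' @return A list: per-fold and mean/sd AUC per method, and per-threshold
#'   `(sensitivity, specificity)` pairs per method from pooled
#'   out-of-fold case probabilities.
#' @export
compare_methods <- function(cases, mcfg, tcfg, k = 4L, seed = 1L,
                            thresholds = c(0.3, 0.5, 0.7)) {
  labels <- vapply(cases, function(cs) as.integer(cs$label), integer(1L))
  ids <- vapply(cases, function(cs) as.character(cs$case_id), character(1L))
  if (anyDuplicated(ids)) stop("duplicate case ids")
  folds <- stratified_kfold(labels, k = k, seed = seed)
  res <- list(cnn_lstm = list(fold_auc = numeric(k)),
              tic_baseline = list(fold_auc = numeric(k)))
  pooled <- data.frame(case_id = ids, label = labels, fold = folds,
                       cnn_prob = NA_real_, tic_prob = NA_real_)
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    if (length(intersect(ids[tr], ids[te])))
      stop("fold leakage: case present in both train and test")
    tr_ml <- unlist(lapply(cases[tr], function(cs) cs$mini_loops),
                    recursive = FALSE)
    fit <- train_cnn_lstm(tr_ml, mcfg, tcfg)
    cnn_probs <- vapply(te, function(i) {
      probs <- vapply(cases[[i]]$mini_loops, predict_miniloop,
                      numeric(1L), weights = fit$weights, config = mcfg)
      aggregate_case(probs)$case_prob
    }, numeric(1L))
    X <- t(vapply(cases[tr], function(cs) cs$features, numeric(8L)))
    bl <- train_baseline(X, labels[tr], seed = seed)
    tic_probs <- predict_baseline(
      bl, t(vapply(cases[te], function(cs) cs$features, numeric(8L))))
    pooled$cnn_prob[te] <- cnn_probs
    pooled$tic_prob[te] <- tic_probs
    res$cnn_lstm$fold_auc[f] <- roc_auc(cnn_probs, labels[te])$auc
    res$tic_baseline$fold_auc[f] <- roc_auc(tic_probs, labels[te])$auc
  }
  for (m in names(res)) {
    res[[m]]$mean_auc <- mean(res[[m]]$fold_auc)
    res[[m]]$sd_auc <- stats::sd(res[[m]]$fold_auc)
    prob <- if (m == "cnn_lstm") pooled$cnn_prob else pooled$tic_prob
    res[[m]]$operating_points <- t(vapply(thresholds, function(th) {
      pred <- as.integer(prob >= th)
      sens_spec(tp = sum(pred == 1L & labels == 1L),
                fn = sum(pred == 0L & labels == 1L),
                tn = sum(pred == 0L & labels == 0L),
                fp = sum(pred == 1L & labels == 0L))
    }, numeric(2L)))
    rownames(res[[m]]$operating_points) <- thresholds
  }
  res$folds <- folds
  res$pooled <- pooled
  res
}
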