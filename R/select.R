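## Classifier-based physiological-source selection: annotate sources against
## a reference, train a gradient-boosted tree classifier on scattering
## features under leave-one-subject-out cross-validation, and select SOBI
## components at a probability threshold with a power-ratio fallback.

#' Annotate a source against the reference pulse
#'
#' A source is labelled physiological (1) when its absolute Pearson
#' correlation with the reference reaches `r_thresh` and the FFT magnitude
#' peaks of source and reference (within the cardiac band) fall within
#' `bin_tol` FFT bins of each other; otherwise 0. Used to build training
#' corpora automatically.
#'
#' @param source,reference numeric vectors at the same rate and length.
#' @param fs sampling rate (Hz).
#' @param r_thresh correlation threshold (default 0.7).
#' @param bin_tol FFT-peak tolerance in bins (default 1).
#' @param band cardiac band (Hz).
#' @return Integer label, 0 or 1.
#' @export
auto_annotate <- function(source, reference, fs, r_thresh = 0.7,
                          bin_tol = 1L, band = c(0.8, 3.0)) {
  stopifnot(length(source) == length(reference))
  r <- suppressWarnings(abs(stats::cor(source, reference)))
  if (!is.finite(r)) r <- 0
  b1 <- detect_peak_bin(source, fs, band)
  b2 <- detect_peak_bin(reference, fs, band)
  as.integer(r >= r_thresh && abs(b1 - b2) <= bin_tol)
}

## in-band FFT magnitude argmax bin (1-based)
detect_peak_bin <- function(x, fs, band = c(0.8, 3.0)) {
  n <- length(x)
  f <- (seq_len(n) - 1L) / n * fs
  sel <- which(f >= band[1L] & f <= band[2L] & f <= fs / 2)
  sel[which.max(Mod(stats::fft(x - mean(x)))[sel])]
}

.binary_metrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1); fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0); tn <- sum(truth == 0 & pred == 0)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  c(accuracy = (tp + tn) / length(truth), precision = precision,
    recall = recall, f1 = f1)
}

.fit_gbt <- function(X, y, nrounds, max_depth, eta, seed) {
  spw <- sum(y == 0) / max(sum(y == 1), 1)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  with_preserved_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, scale_pos_weight = spw, nthread = 1,
                  seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0))
}

#' Train the physiological-source classifier
#'
#' Fits a gradient-boosted decision-tree classifier (binary logistic
#' objective, class-weighted for the physiological/noise imbalance) on
#' source feature vectors, and reports leave-one-subject-out
#' cross-validation (LOSOCV) accuracy, precision, recall and F1 at the
#' deployment decision threshold. The returned model is refit on all data;
#' LOSOCV is a validation harness only.
#'
#' @param features numeric matrix, one row per source ([featurize]).
#' @param labels 0/1 integer vector.
#' @param subject_groups subject id per source (grouped CV folds).
#' @param threshold decision threshold used in the CV report (default 0.35,
#'   the deployment threshold).
#' @param nrounds,max_depth,eta boosting hyperparameters.
#' @param seed RNG seed for model fitting (restored afterwards).
#' @return A `source_selector`: list with `model`, `cv` (pooled LOSOCV
#'   metrics), `cv_predictions`, `threshold`, `feature_names`.
#' @export
train_selector <- function(features, labels, subject_groups,
                           threshold = 0.35, nrounds = 200L, max_depth = 6L,
                           eta = 0.05, seed = 1L) {
  X <- as.matrix(features)
  y <- as.integer(labels)
  stopifnot(nrow(X) == length(y), length(subject_groups) == length(y))
  if (length(unique(y)) < 2L)
    stop("training error: both classes must be present", call. = FALSE)
  subjects <- unique(subject_groups)
  if (length(subjects) < 2L)
    stop("training error: need at least 2 subjects for LOSOCV", call. = FALSE)
  prob <- rep(NA_real_, length(y))
  for (s in subjects) {
    test <- subject_groups == s
    if (length(unique(y[!test])) < 2L) next
    fit <- .fit_gbt(X[!test, , drop = FALSE], y[!test], nrounds, max_depth,
                    eta, seed)
    prob[test] <- stats::predict(fit,
                                 xgboost::xgb.DMatrix(X[test, , drop = FALSE],
                                                      nthread = 1))
  }
  ok <- !is.na(prob)
  cv <- .binary_metrics(y[ok], as.integer(prob[ok] > threshold))
  model <- .fit_gbt(X, y, nrounds, max_depth, eta, seed)
  structure(list(model = model, cv = cv,
                 cv_predictions = data.frame(subject = subject_groups,
                                             label = y, prob = prob),
                 threshold = threshold,
                 feature_names = colnames(X)),
            class = "source_selector")
}

#' @export
print.source_selector <- function(x, ...) {
  cat("source_selector (gradient-boosted trees)\n")
  cat(sprintf("  LOSOCV @ %.2f: acc %.3f, precision %.3f, recall %.3f, F1 %.3f\n",
              x$threshold, x$cv["accuracy"], x$cv["precision"],
              x$cv["recall"], x$cv["f1"]))
  invisible(x)
}

#' Predict physiological-source probabilities
#'
#' @param selector a `source_selector`.
#' @param features matrix of feature rows.
#' @return Numeric probabilities in `[0, 1]`.
#' @export
predict_selector <- function(selector, features) {
  stats::predict(selector$model,
                 xgboost::xgb.DMatrix(as.matrix(features), nthread = 1))
}

#' Save/load a trained selector
#'
#' Serialized as xgboost's portable JSON plus metadata, so the model file is
#' plain text.
#'
#' @param selector a `source_selector`.
#' @param path file path (JSON).
#' @return `path` (save) or the restored `source_selector` (load).
#' @export
save_selector <- function(selector, path) {
  raw <- xgboost::xgb.save.raw(selector$model, raw_format = "json")
  obj <- list(model_json = rawToChar(raw),
              cv = as.list(selector$cv),
              threshold = selector$threshold,
              feature_names = selector$feature_names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_selector
#' @export
load_selector <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- xgboost::xgb.load.raw(charToRaw(obj$model_json))
  structure(list(model = model, cv = unlist(obj$cv),
                 threshold = obj$threshold,
                 feature_names = obj$feature_names),
            class = "source_selector")
}

#' Per-component power ratio of a SOBI decomposition
#'
#' Fraction of the total back-projected signal power contributed by each
#' (unit-variance) SOBI component: `||a_i||^2 / sum_j ||a_j||^2` with `a_i`
#' the i-th mixing column. Ratios are non-negative and sum to 1.
#'
#' @param sobi_set a `sobi` component set.
#' @return Numeric vector of power fractions.
#' @export
component_power_ratio <- function(sobi_set) {
  stopifnot(identical(sobi_set$stage, "sobi"))
  p <- colSums(sobi_set$mixing^2)
  p / sum(p)
}

#' Select physiological SOBI components
#'
#' Components with classifier probability strictly above `p_threshold` are
#' selected (`mode = "classifier"`). If none pass (or no classifier is
#' given), the fallback inspects the first SOBI component's power ratio: if
#' it exceeds `power_ratio_threshold` it is selected alone
#' (`mode = "fallback"`); otherwise no component is selected
#' (`mode = "null"`), which deliberately yields a null heart-rate estimate
#' downstream rather than a spurious one.
#'
#' @param selector a `source_selector`, or `NULL` to use only the fallback.
#' @param sobi_set a (cleaned) `sobi` component set.
#' @param fs sampling rate (Hz) for featurization.
#' @param p_threshold classifier decision threshold (default 0.35).
#' @param power_ratio_threshold fallback threshold (default 0.75).
#' @param probabilities optional precomputed per-component probabilities
#'   (bypasses the classifier; useful for testing the decision rule).
#' @return A `selection_result`: `indices`, `mode`
#'   (classifier/fallback/null), `probabilities`, `power_ratio`.
#' @export
select_components <- function(selector, sobi_set, fs, p_threshold = 0.35,
                              power_ratio_threshold = 0.75,
                              probabilities = NULL) {
  S <- sobi_set$components
  probs <- probabilities
  idx <- integer(0)
  if (is.null(probs) && !is.null(selector)) {
    feats <- t(apply(S, 1L, featurize, fs = fs))
    probs <- predict_selector(selector, feats)
  }
  if (!is.null(probs)) idx <- which(probs > p_threshold)
  pr <- component_power_ratio(sobi_set)
  if (length(idx) > 0L) {
    mode <- "classifier"
  } else if (pr[1L] > power_ratio_threshold) {
    idx <- 1L
    mode <- "fallback"
  } else {
    mode <- "null"
  }
  structure(list(indices = idx, mode = mode, probabilities = probs,
                 power_ratio = pr),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: mode=%s, %d component(s) selected\n",
              x$mode, length(x$indices)))
  invisible(x)
}
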