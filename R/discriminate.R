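# Frequency-split noise features and support-vector event classification.

#' Split a trace into low-pass and high-pass portions
#'
#' Butterworth low-pass at `cutoff` (zero-phase by default, so event shapes
#' are not skewed); the high-pass portion is defined as the residual
#' `trace - low_pass`, which makes the decomposition exactly additive. A
#' causal (single-pass) variant is available via `zero_phase = FALSE`.
#'
#' @param trace A `sense_trace`, or a numeric vector (then `fs` is needed).
#' @param cutoff Cut-off frequency, Hz (default 100).
#' @param order Butterworth order (default 4).
#' @param zero_phase Forward-backward filtering (default `TRUE`).
#' @param fs Sampling rate when `trace` is a bare numeric vector.
#' @return A `split_trace`: list with `low_pass`, `high_pass`, `cutoff`,
#'   `order`, `zero_phase`, `fs`.
#' @export
frequency_split <- function(trace, cutoff = 100, order = 4,
                            zero_phase = TRUE, fs = NULL) {
  if (inherits(trace, "sense_trace")) {
    x <- trace$current
    fs <- trace$acq$sampling_rate
  } else {
    x <- as.numeric(trace)
    if (is.null(fs)) stop_config("fs required for a bare numeric trace")
  }
  if (cutoff >= fs / 2) stop_config("cutoff must be below Nyquist (fs/2)")
  flt <- design_lowpass(order, cutoff, fs, type = "butterworth")
  lp <- if (zero_phase) zero_phase_filter(flt, x) else iir_filter(flt, x)
  structure(list(low_pass = lp, high_pass = x - lp, cutoff = cutoff,
                 order = order, zero_phase = zero_phase, fs = fs),
            class = "split_trace")
}

#' Per-event frequency-split noise features
#'
#' For each event window (edge guard bands excluded), the SD of the low-pass
#' and of the high-pass portion of the trace — the two-dimensional noise
#' signature used to discriminate analyte classes.
#'
#' @param split A `split_trace` from [frequency_split()].
#' @param events An `event_table` referring to the same trace.
#' @param guard_samples Samples trimmed from each event edge (default: two
#'   cut-off periods, so the split filter's edge smearing stays outside the
#'   window); events too short for the guards are computed on the full
#'   window and flagged.
#' @return data.frame with `event_id`, `lp_sd`, `hp_sd`, `guard_flag`
#'   (class `event_features`).
#' @export
extract_features <- function(split, events, guard_samples = NULL) {
  stopifnot(inherits(split, "split_trace"))
  guard_samples <- guard_samples %||% as.integer(ceiling(2 * split$fs / split$cutoff))
  n_ev <- nrow(events)
  lp_sd <- hp_sd <- numeric(n_ev); flag <- logical(n_ev)
  for (i in seq_len(n_ev)) {
    a <- events$start_sample[i] + 1L
    b <- events$end_sample[i]
    g <- guard_samples
    if (b - a + 1L > 2L * g + 1L) {
      idx <- (a + g):(b - g)
    } else {
      idx <- a:b
      flag[i] <- TRUE
    }
    lp_sd[i] <- if (length(idx) > 1L) sd(split$low_pass[idx]) else 0
    hp_sd[i] <- if (length(idx) > 1L) sd(split$high_pass[idx]) else 0
  }
  structure(data.frame(event_id = events$event_id, lp_sd = lp_sd,
                       hp_sd = hp_sd, guard_flag = flag),
            class = c("event_features", "data.frame"))
}

feature_matrix <- function(features, feature_names) {
  m <- as.matrix(as.data.frame(features)[, feature_names, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Train a support-vector event classifier
#'
#' Standardizes the features (z-score, parameters stored with the model) and
#' trains a support-vector classifier. Defaults: RBF kernel, `cost = 1`,
#' `gamma = 1/(n_features * var)` of the standardized training matrix.
#' Retraining on identical data yields an identical model.
#'
#' @param features data.frame of per-event features (default feature set:
#'   `lp_sd`, `hp_sd`).
#' @param labels Class labels, one per event.
#' @param feature_names Columns of `features` used for training.
#' @param kernel,cost,gamma Passed to the SVC (`gamma = "scale"` uses
#'   `1/(d * var)`).
#' @param seed Stored with the model (training itself is deterministic).
#' @return An `event_classifier` with a `predict` method.
#' @export
train_classifier <- function(features, labels,
                             feature_names = c("lp_sd", "hp_sd"),
                             kernel = "radial", cost = 1, gamma = "scale",
                             seed = NULL) {
  labels <- factor(labels)
  X <- feature_matrix(features, feature_names)
  if (nrow(X) != length(labels)) stop_config("one label per event required")
  single_class <- nlevels(labels) < 2L
  if (single_class)
    warning("single-class training set: trivial model predicting that class")
  if (!single_class && min(table(labels)) < 10L)
    stop_insufficient("need >= 10 events per class (smallest class has %d)",
                      min(table(labels)))
  center <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  scale_[scale_ == 0] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale_, "/")
  if (identical(gamma, "scale")) {
    v <- mean(apply(Z, 2, var))
    gamma <- 1 / (ncol(Z) * max(v, 1e-12))
  }
  svm_fit <- if (single_class) NULL else
    e1071::svm(Z, labels, kernel = kernel, cost = cost, gamma = gamma,
               scale = FALSE, probability = FALSE)
  structure(list(svm = svm_fit, center = center, scale = scale_,
                 levels = levels(labels), feature_names = feature_names,
                 kernel = kernel, cost = cost, gamma = gamma, seed = seed,
                 n_train = nrow(Z), training_hash = hash_object(list(Z, labels))),
            class = "event_classifier")
}

#' @export
print.event_classifier <- function(x, ...) {
  cat(sprintf("Support-vector event classifier: %d classes (%s)\n",
              length(x$levels), paste(x$levels, collapse = ", ")))
  cat(sprintf("  features: %s; kernel %s, cost %g, gamma %.4g\n",
              paste(x$feature_names, collapse = ", "), x$kernel, x$cost,
              x$gamma))
  cat(sprintf("  trained on %d events (hash %s)\n", x$n_train,
              substr(x$training_hash, 1, 12)))
  invisible(x)
}

#' Classify events with a trained model
#'
#' @param object An `event_classifier`.
#' @param newdata data.frame of features (same feature set as training).
#' @param ... Unused.
#' @return Factor of predicted labels (levels = training classes).
#' @export
predict.event_classifier <- function(object, newdata, ...) {
  if (nrow(as.data.frame(newdata)) == 0L)
    return(factor(character(0), levels = object$levels))
  missing <- setdiff(object$feature_names, names(as.data.frame(newdata)))
  if (length(missing))
    stop_config("feature(s) missing from newdata: %s",
                paste(missing, collapse = ", "))
  X <- feature_matrix(newdata, object$feature_names)
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  if (is.null(object$svm))
    return(factor(rep(object$levels[1], nrow(Z)), levels = object$levels))
  factor(as.character(predict(object$svm, Z)), levels = object$levels)
}

#' Confusion matrix and accuracies
#'
#' Square count matrix (true x predicted) over the lexicographically ordered
#' union of labels; labels absent from truth or prediction appear as zero
#' rows/columns.
#'
#' @param truth,predicted Equal-length label vectors.
#' @return A `confusion_matrix`: list with `table`, `per_class_accuracy`,
#'   `overall_accuracy`, `n`.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop_config("truth and predicted must have equal length")
  lev <- sort(unique(c(as.character(truth), as.character(predicted))))
  t_f <- factor(as.character(truth), levels = lev)
  p_f <- factor(as.character(predicted), levels = lev)
  tab <- table(true = t_f, predicted = p_f)
  per_class <- diag(tab) / pmax(1, rowSums(tab))
  per_class[rowSums(tab) == 0] <- NA_real_
  structure(list(table = unclass(tab),
                 per_class_accuracy = per_class,
                 overall_accuracy = sum(diag(tab)) / max(1, length(truth)),
                 n = length(truth)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = truth):\n")
  print(x$table)
  cat("per-class accuracy:",
      paste(sprintf("%s %.1f%%", names(x$per_class_accuracy),
                    100 * x$per_class_accuracy), collapse = ", "), "\n")
  cat(sprintf("overall accuracy: %.1f%% (n = %d)\n",
              100 * x$overall_accuracy, x$n))
  invisible(x)
}

#' Decision-boundary grid for a 2-feature classifier
#'
#' Classifies a dense grid over the feature plane, for decision-region
#' plots over the event scatter.
#'
#' @param model A trained `event_classifier` with exactly 2 features.
#' @param lp_range,hp_range Ranges `c(min, max)` of the two features.
#' @param resolution Grid points per axis.
#' @return A `decision_grid`: list with `lp`, `hp` (axis vectors) and
#'   `labels` (resolution x resolution factor matrix, rows = lp axis).
#' @export
decision_boundary_grid <- function(model, lp_range, hp_range,
                                   resolution = 100L) {
  stopifnot(inherits(model, "event_classifier"))
  if (length(model$feature_names) != 2L)
    stop_config("decision grid requires a 2-feature model")
  if (lp_range[1] >= lp_range[2] || hp_range[1] >= hp_range[2])
    stop_config("degenerate feature range (min >= max)")
  lp <- seq(lp_range[1], lp_range[2], length.out = resolution)
  hp <- seq(hp_range[1], hp_range[2], length.out = resolution)
  g <- expand.grid(lp, hp)
  names(g) <- model$feature_names
  lab <- predict(model, g)
  structure(list(lp = lp, hp = hp,
                 labels = matrix(as.character(lab), nrow = resolution),
                 levels = levels(lab)),
            class = "decision_grid")
}

#' @export
plot.decision_grid <- function(x, ...) {
  z <- matrix(match(x$labels, x$levels), nrow = length(x$lp))
  image(x$lp, x$hp, z, xlab = "low-pass SD (pA)", ylab = "high-pass SD (pA)",
        col = grDevices::hcl.colors(max(2L, length(x$levels)), "Set 2"), ...)
  invisible(x)
}

#' Stratified train/test split, train and evaluate an event classifier
#'
#' Convenience wrapper: stratified split (default 70/30) with a fixed seed,
#' training on the first part and a held-out confusion matrix on the rest.
#'
#' @inheritParams train_classifier
#' @param train_frac Fraction per class used for training.
#' @return List with `model`, `confusion` (held-out), `train_idx`.
#' @export
evaluate_classifier <- function(features, labels, train_frac = 0.7,
                                feature_names = c("lp_sd", "hp_sd"),
                                kernel = "radial", cost = 1, gamma = "scale",
                                seed = 1L) {
  labels <- factor(labels)
  set.seed(seed)
  idx <- unlist(lapply(split(seq_along(labels), labels), function(ii)
    sample(ii, max(1L, round(train_frac * length(ii))))))
  model <- train_classifier(as.data.frame(features)[idx, , drop = FALSE],
                            labels[idx], feature_names = feature_names,
                            kernel = kernel, cost = cost, gamma = gamma,
                            seed = seed)
  test <- setdiff(seq_along(labels), idx)
  pred <- predict(model, as.data.frame(features)[test, , drop = FALSE])
  list(model = model,
       confusion = confusion_matrix(labels[test], pred),
       train_idx = sort(idx))
}
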