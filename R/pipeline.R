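#' Augment traditional-grip sequences by scaling and translation
#'
#' Class balancing for training: every traditional (four-finger) sequence
#' receives one geometrically transformed copy — a uniform scale about the
#' frame's wrist landmark and a global translation, both drawn once per
#' copy — so the traditional count exactly doubles. Nontraditional
#' sequences are passed through untouched. Augmentation operates on raw
#' landmark + chopstick sequences, before feature extraction, so the
#' copies' distance features are exact scalar multiples of the originals.
#'
#' @param dataset a `grip_dataset` (or list of `grip_sequence`).
#' @param labels per-sequence labels; defaults to the dataset's own.
#' @param factor_range range of the uniform scale factor (default
#'   `c(0.9, 1.1)`).
#' @param shift_range range of each translation component in px (default
#'   `c(-20, 20)`).
#' @param seed RNG seed for the transform draws.
#' @return an augmented `grip_dataset` with updated `labels`,
#'   `archetypes` and `augmented` attributes (copies appended at the end).
#' @export
augment_samples <- function(dataset, labels = attr(dataset, "labels"),
                            factor_range = c(0.9, 1.1),
                            shift_range = c(-20, 20), seed = 1) {
  if (is.null(labels))
    labels <- vapply(dataset, function(s) s$label, "")
  stopifnot(length(labels) == length(dataset))
  trad <- which(labels == "traditional")
  if (!length(trad)) {
    warning("no traditional sequences to augment; returning input unchanged")
    return(dataset)
  }
  copies <- with_seed(seed, lapply(trad, function(i) {
    s <- dataset[[i]]
    sc <- stats::runif(1, factor_range[1], factor_range[2])
    sh <- stats::runif(2, shift_range[1], shift_range[2])
    wx <- s$landmarks[, 1]; wy <- s$landmarks[, 2]  # per-frame wrist
    for (k in 1:21) {
      s$landmarks[, 2 * k - 1] <- wx + sc * (s$landmarks[, 2 * k - 1] - wx) + sh[1]
      s$landmarks[, 2 * k] <- wy + sc * (s$landmarks[, 2 * k] - wy) + sh[2]
    }
    for (k in c(1, 3, 5, 7)) {
      s$chopsticks[, k] <- wx + sc * (s$chopsticks[, k] - wx) + sh[1]
      s$chopsticks[, k + 1] <- wy + sc * (s$chopsticks[, k + 1] - wy) + sh[2]
    }
    s$truth <- s$truth * sc
    s$augmented <- TRUE
    s
  }))
  out <- c(dataset, copies)
  structure(out,
            labels = c(labels, rep("traditional", length(copies))),
            archetypes = c(attr(dataset, "archetypes") %||%
                             vapply(dataset, function(s) s$archetype, ""),
                           rep("four_finger", length(copies))),
            augmented = c(rep(FALSE, length(dataset)), rep(TRUE, length(copies))),
            seed = attr(dataset, "seed"), class = "grip_dataset")
}

#' Fit the grip decision-tree classifier
#'
#' Two-stage decision-tree fit for the binary traditional/nontraditional
#' verdict. Stage 1 grows a tree on all sequence-summary features and
#' records impurity-based variable importances; stage 2 weights features
#' by that importance, dropping those below the chosen importance quantile
#' (default the median), and refits on the retained set. Trees use Gini
#' impurity, shallow depth and a minimum leaf size to resist overfitting
#' at the ~160-sample scale, and no surrogate splits, so fits are fully
#' deterministic.
#'
#' @param summaries numeric matrix of sequence summaries (rows =
#'   sequences), e.g. from [summarize_dataset()].
#' @param labels character vector, `"traditional"` / `"nontraditional"`.
#' @param config list overriding any of `max_depth` (5), `min_leaf` (5),
#'   `cp` (0.001), `importance_quantile` (0.5), `seed` (1234).
#' @return an object of class `grip_classifier` with elements `tree`
#'   (the stage-2 [rpart::rpart] fit), `retained`, `importance`,
#'   `config`, `feature_names`, `levels`.
#' @export
grip_classifier <- function(summaries, labels, config = list()) {
  summaries <- as.matrix(summaries)
  labels <- as.character(labels)
  stopifnot(nrow(summaries) == length(labels))
  lv <- c("traditional", "nontraditional")
  if (!all(labels %in% lv)) stopf("labels must be traditional/nontraditional")
  if (length(unique(labels)) < 2)
    stopf("training requires both classes; got only '%s'", unique(labels))
  if (min(table(labels)) < 2)
    stopf("training requires >= 2 samples per class")
  cfg <- utils::modifyList(list(max_depth = 5, min_leaf = 5, cp = 0.001,
                                importance_quantile = 0.5, seed = 1234),
                           config)
  ctrl <- rpart::rpart.control(maxdepth = cfg$max_depth,
                               minbucket = cfg$min_leaf,
                               minsplit = 2 * cfg$min_leaf,
                               cp = cfg$cp, xval = 0,
                               maxsurrogate = 0, usesurrogate = 0,
                               maxcompete = 0)
  df <- as.data.frame(summaries)
  df$.label <- factor(labels, levels = lv)
  fit1 <- with_seed(cfg$seed,
    rpart::rpart(.label ~ ., data = df, method = "class",
                 parms = list(split = "gini"), control = ctrl))
  imp <- stats::setNames(numeric(ncol(summaries)), colnames(summaries))
  vi <- fit1$variable.importance
  if (!is.null(vi)) imp[names(vi)] <- vi
  q <- stats::quantile(imp, cfg$importance_quantile, names = FALSE)
  retained <- names(imp)[imp >= q & imp > 0]
  if (!length(retained)) retained <- names(imp)  # stumpless fallback
  df2 <- df[, c(retained, ".label"), drop = FALSE]
  fit2 <- with_seed(cfg$seed,
    rpart::rpart(.label ~ ., data = df2, method = "class",
                 parms = list(split = "gini"), control = ctrl))
  structure(list(tree = fit2, retained = retained, importance = imp,
                 config = cfg, feature_names = colnames(summaries),
                 levels = lv),
            class = "grip_classifier")
}

#' @export
print.grip_classifier <- function(x, ...) {
  cat(sprintf("Grip classifier: decision tree on %d/%d retained summary features\n",
              length(x$retained), length(x$feature_names)))
  cat("  top features:",
      paste(utils::head(names(sort(x$importance, decreasing = TRUE)), 5),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.grip_classifier <- function(object, ...) {
  cat("Grip decision-tree classifier\n")
  cat(sprintf("  depth limit %d, min leaf %d, importance quantile %.2f\n",
              object$config$max_depth, object$config$min_leaf,
              object$config$importance_quantile))
  cat(sprintf("  retained %d of %d features\n", length(object$retained),
              length(object$feature_names)))
  imp <- sort(object$importance[object$importance > 0], decreasing = TRUE)
  if (length(imp)) {
    cat("  importances:\n")
    print(round(imp, 3))
  }
  invisible(object)
}

#' @export
plot.grip_classifier <- function(x, ...) {
  plot(x$tree, margin = 0.1, ...)
  graphics::text(x$tree, use.n = TRUE, cex = 0.8)
  invisible(x)
}

#' Predict grip labels from sequence summaries
#'
#' @param object a [grip_classifier()] fit.
#' @param newdata a named summary vector, a matrix of summaries, or the
#'   list returned by [summarize_dataset()]. Must contain every retained
#'   feature.
#' @param type `"label"` for class labels, `"prob"` for the leaf's
#'   traditional-class fraction.
#' @param ... unused.
#' @return character labels or numeric probabilities.
#' @export
predict.grip_classifier <- function(object, newdata,
                                    type = c("label", "prob"), ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.null(newdata$summaries))
    newdata <- newdata$summaries
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1,
                                             dimnames = list(NULL, names(newdata)))
  miss <- setdiff(object$retained, colnames(newdata))
  if (length(miss))
    stopf("summary lacks retained feature(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(newdata[, object$retained, drop = FALSE])
  if (inherits(object$tree, "grip_tree_nodes")) {
    leaves <- lapply(seq_len(nrow(df)), function(i)
      predict_tree_list(object$tree, df[i, , drop = FALSE]))
    if (type == "label")
      return(vapply(leaves, function(l) l$class, ""))
    return(vapply(leaves, function(l) unname(l$prob["traditional"]), 0))
  }
  if (type == "label")
    as.character(predict(object$tree, df, type = "class"))
  else
    unname(predict(object$tree, df, type = "prob")[, "traditional"])
}

#' Confusion-matrix metrics for the binary grip verdict
#'
#' Accuracy, precision, recall and F1 with the traditional grip as the
#' positive class. When no positive is predicted while positives exist,
#' precision is reported as 0 with a warning (the 0/0 convention used
#' throughout the package's evaluation).
#'
#' @param predicted,truth equal-length character vectors of
#'   `"traditional"` / `"nontraditional"` labels.
#' @param positive the positive class (default `"traditional"`).
#' @return named list: `accuracy`, `precision`, `recall`, `f1`, and the
#'   `confusion` table (tp, fp, fn, tn).
#' @export
evaluate_metrics <- function(predicted, truth, positive = "traditional") {
  if (length(predicted) == 0) stopf("empty prediction vector")
  if (length(predicted) != length(truth))
    stopf("predicted and truth differ in length (%d vs %d)",
          length(predicted), length(truth))
  tp <- sum(predicted == positive & truth == positive)
  fp <- sum(predicted == positive & truth != positive)
  fn <- sum(predicted != positive & truth == positive)
  tn <- sum(predicted != positive & truth != positive)
  if (tp + fp == 0) {
    if (tp + fn > 0)
      warning("no positives predicted although positives are present; precision set to 0")
    precision <- 0
  } else precision <- tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / length(predicted), precision = precision,
       recall = recall, f1 = f1,
       confusion = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

# deterministic stratified fold assignment
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validated grip classification
#'
#' Stratified k-fold cross-validation of the decision-tree classifier on
#' sequence summaries, reporting per-fold and mean confusion-matrix
#' metrics.
#'
#' @param summaries summary matrix (rows = sequences).
#' @param labels per-sequence labels.
#' @param k number of folds (default 5).
#' @param config classifier configuration, see [grip_classifier()].
#' @param seed fold-assignment seed.
#' @return list with `mean` (named metric means), `folds` (k x 4 matrix)
#'   and `predictions` (out-of-fold labels).
#' @export
cv_grip_classifier <- function(summaries, labels, k = 5, config = list(),
                               seed = 1234) {
  summaries <- as.matrix(summaries)
  fold <- stratified_folds(labels, k, seed)
  pred <- character(length(labels))
  metrics <- matrix(NA_real_, k, 4,
                    dimnames = list(NULL, c("accuracy", "precision",
                                            "recall", "f1")))
  for (f in seq_len(k)) {
    te <- fold == f
    fit <- grip_classifier(summaries[!te, , drop = FALSE], labels[!te], config)
    pred[te] <- predict(fit, summaries[te, , drop = FALSE])
    m <- evaluate_metrics(pred[te], labels[te])
    metrics[f, ] <- c(m$accuracy, m$precision, m$recall, m$f1)
  }
  list(mean = colMeans(metrics), folds = metrics, predictions = pred)
}

#' End-to-end assessment of a grip dataset
#'
#' Runs the full classification pipeline on a labelled dataset in the
#' fixed order: augment the traditional class on the raw sequences,
#' extract per-frame features, summarize each sequence, then
#' cross-validate the decision tree at the sequence level. A per-frame
#' voting variant (`unit = "frame"`: the tree consumes per-frame distance
#' rows and each sequence takes the majority vote of its frames) is
#' available for comparison.
#'
#' @param dataset a labelled `grip_dataset`.
#' @param augment double the traditional class first (default `TRUE`).
#' @param k CV folds.
#' @param config classifier configuration.
#' @param mode,normalize feature options, see [summarize_dataset()].
#' @param unit `"sequence"` (default) or `"frame"`.
#' @param seed seed for augmentation and fold assignment.
#' @return list with `metrics` (CV mean), `folds`, `n_traditional`,
#'   `n_nontraditional`.
#' @export
assess_grip_dataset <- function(dataset, augment = TRUE, k = 5,
                                config = list(), mode = "perpendicular",
                                normalize = "none",
                                unit = c("sequence", "frame"), seed = 1234) {
  unit <- match.arg(unit)
  if (augment) dataset <- augment_samples(dataset, seed = seed)
  labels <- attr(dataset, "labels")
  if (unit == "sequence") {
    sd_ <- summarize_dataset(dataset, mode = mode, normalize = normalize)
    cv <- cv_grip_classifier(sd_$summaries, sd_$labels, k = k,
                             config = config, seed = seed)
  } else {
    cv <- cv_frame_voting(dataset, labels, k = k, config = config,
                          mode = mode, seed = seed)
  }
  list(metrics = cv$mean, folds = cv$folds,
       n_traditional = sum(labels == "traditional"),
       n_nontraditional = sum(labels == "nontraditional"))
}

# per-frame voting variant: tree on raw per-frame distance rows, majority
# vote per sequence
cv_frame_voting <- function(dataset, labels, k, config, mode, seed) {
  feats <- lapply(dataset, function(s) compute_features(s, mode = mode))
  fold <- stratified_folds(labels, k, seed)
  pred <- character(length(labels))
  metrics <- matrix(NA_real_, k, 4,
                    dimnames = list(NULL, c("accuracy", "precision",
                                            "recall", "f1")))
  frame_rows <- function(idx) {
    do.call(rbind, lapply(idx, function(i) {
      x <- feats[[i]]$feats[!feats[[i]]$missing, , drop = FALSE]
      cbind(x, .seq = i)
    }))
  }
  cfg <- utils::modifyList(list(max_depth = 5, min_leaf = 5, cp = 0.001,
                                seed = 1234), config)
  ctrl <- rpart::rpart.control(maxdepth = cfg$max_depth,
                               minbucket = cfg$min_leaf, cp = cfg$cp,
                               xval = 0, maxsurrogate = 0,
                               usesurrogate = 0, maxcompete = 0)
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- which(fold != f)
    trn <- frame_rows(tr)
    df <- as.data.frame(trn[, c("a", "b", "c", "d"), drop = FALSE])
    df$.label <- factor(labels[trn[, ".seq"]],
                        levels = c("traditional", "nontraditional"))
    fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                        parms = list(split = "gini"), control = ctrl)
    for (i in te) {
      x <- as.data.frame(feats[[i]]$feats[!feats[[i]]$missing, , drop = FALSE])
      votes <- predict(fit, x, type = "class")
      pred[i] <- names(which.max(table(votes)))
    }
    m <- evaluate_metrics(pred[te], labels[te])
    metrics[f, ] <- c(m$accuracy, m$precision, m$recall, m$f1)
  }
  list(mean = colMeans(metrics), folds = metrics, predictions = pred)
}
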