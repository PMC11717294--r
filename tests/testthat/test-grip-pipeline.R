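test_that("augmentation doubles the traditional class and nothing else", {
  ds <- make_grip_dataset(5, 7, protocol = clean_protocol(duration_s = 0.5),
                          seed = 31)
  aug <- augment_samples(ds, seed = 1)
  lab <- attr(aug, "labels")
  expect_equal(sum(lab == "traditional"), 10)
  expect_equal(sum(lab == "nontraditional"), 7)
  # nontraditional sequences are bit-identical to the originals
  for (i in which(attr(ds, "labels") == "nontraditional"))
    expect_identical(aug[[i]], ds[[i]])

  # identity transform produces exact copies
  aug_id <- augment_samples(ds, factor_range = c(1, 1),
                            shift_range = c(0, 0), seed = 1)
  orig <- which(attr(ds, "labels") == "traditional")
  for (k in seq_along(orig)) {
    expect_equal(aug_id[[length(ds) + k]]$landmarks,
                 ds[[orig[k]]]$landmarks)
    expect_equal(aug_id[[length(ds) + k]]$chopsticks,
                 ds[[orig[k]]]$chopsticks)
  }

  # pure scaling multiplies the distance features exactly
  aug_s <- augment_samples(ds, factor_range = c(1.3, 1.3),
                           shift_range = c(0, 0), seed = 1)
  f_orig <- compute_features(ds[[orig[1]]])$feats
  f_copy <- compute_features(aug_s[[length(ds) + 1]])$feats
  expect_equal(f_copy, 1.3 * f_orig, tolerance = 1e-9)

  nontrad_only <- make_grip_dataset(1, 3,
                                    protocol = clean_protocol(duration_s = 0.2))
  attr(nontrad_only, "labels")[1] <- "nontraditional"
  expect_warning(augment_samples(nontrad_only), "no traditional")
})

test_that("the decision tree separates separable summaries and is deterministic", {
  toy <- toy_summaries()
  fit <- grip_classifier(toy$summaries, toy$labels)
  expect_equal(predict(fit, toy$summaries), toy$labels)  # training accuracy 1
  expect_true("sig" %in% fit$retained)

  fit2 <- grip_classifier(toy$summaries, toy$labels)
  expect_identical(fit$tree$frame, fit2$tree$frame)      # same seed, same tree

  expect_error(grip_classifier(toy$summaries,
                               rep("traditional", nrow(toy$summaries))),
               "both classes")
  expect_error(grip_classifier(toy$summaries[1:3, ],
                               c("traditional", "traditional",
                                 "nontraditional")), ">= 2 samples")
})

test_that("importance weighting drops redundant duplicate features", {
  toy <- toy_summaries(n_per = 20)
  dup <- cbind(toy$summaries, sig_copy = toy$summaries[, "sig"])
  fit <- grip_classifier(dup, toy$labels)
  expect_false(all(c("sig", "sig_copy") %in% fit$retained))
  expect_true(any(c("sig", "sig_copy") %in% fit$retained))
})

test_that("prediction is total and validates its input schema", {
  toy <- toy_summaries()
  fit <- grip_classifier(toy$summaries, toy$labels)
  # all-sentinel summary still yields a defined label
  sent <- stats::setNames(rep(299, ncol(toy$summaries)),
                          colnames(toy$summaries))
  expect_true(predict(fit, sent) %in% c("traditional", "nontraditional"))
  probs <- predict(fit, toy$summaries, type = "prob")
  expect_true(all(probs >= 0 & probs <= 1))
  bad <- toy$summaries[, setdiff(colnames(toy$summaries), fit$retained),
                       drop = FALSE]
  expect_error(predict(fit, bad), "retained")
})

test_that("confusion-matrix metrics match direct arithmetic", {
  all_good <- rep(c("traditional", "nontraditional"), 5)
  m <- evaluate_metrics(all_good, all_good)
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  # TP=30 FP=6 FN=4 TN=20
  truth <- c(rep("traditional", 34), rep("nontraditional", 26))
  pred <- c(rep("traditional", 30), rep("nontraditional", 4),
            rep("traditional", 6), rep("nontraditional", 20))
  m <- evaluate_metrics(pred, truth)
  expect_equal(m$precision, 30 / 36, tolerance = 1e-12)
  expect_equal(m$recall, 30 / 34, tolerance = 1e-12)
  expect_equal(m$accuracy, 50 / 60, tolerance = 1e-12)
  expect_equal(m$f1, 2 * (30 / 36) * (30 / 34) / (30 / 36 + 30 / 34),
               tolerance = 1e-12)
  expect_equal(unname(m$confusion), c(30, 6, 4, 20))

  expect_warning(
    m0 <- evaluate_metrics(rep("nontraditional", 4),
                           c("traditional", "traditional",
                             "nontraditional", "nontraditional")),
    "precision")
  expect_equal(m0$precision, 0)
  expect_error(evaluate_metrics(character(0), character(0)), "empty")
  expect_error(evaluate_metrics("traditional",
                                c("traditional", "traditional")), "length")
})

test_that("the end-to-end pipeline is deterministic for fixed seeds", {
  ds <- make_grip_dataset(6, 8, protocol = trial_protocol(duration_s = 2,
                                                          seed = 1),
                          seed = 55)
  r1 <- assess_grip_dataset(ds, k = 3, seed = 9)
  r2 <- assess_grip_dataset(make_grip_dataset(6, 8,
                                              protocol = trial_protocol(duration_s = 2, seed = 1),
                                              seed = 55),
                            k = 3, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(r1$metrics >= 0 & r1$metrics <= 1))
  expect_equal(r1$n_traditional, 12)     # augmentation doubled 6 -> 12

  # per-frame voting variant runs and reports the same metric names
  rf <- assess_grip_dataset(ds, k = 3, seed = 9, unit = "frame",
                            augment = FALSE)
  expect_named(rf$metrics, c("accuracy", "precision", "recall", "f1"))
})

test_that("model JSON round-trip preserves predictions", {
  toy <- toy_summaries(n_per = 15)
  fit <- grip_classifier(toy$summaries, toy$labels)
  path <- tempfile(fileext = ".json")
  write_grip_model(fit, path)
  loaded <- read_grip_model(path)
  expect_identical(predict(loaded, toy$summaries), predict(fit, toy$summaries))
  expect_equal(loaded$retained, fit$retained)
  sent <- stats::setNames(rep(1e6, ncol(toy$summaries)),
                          colnames(toy$summaries))
  expect_identical(predict(loaded, sent), predict(fit, sent))
})
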