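test_that("DCDQ scoring follows the 6/4/5 subscale mapping", {
  hi <- score_dcdq(rep(5, 15))
  expect_equal(hi$control_during_movement, 30)
  expect_equal(hi$fine_motor_handwriting, 20)
  expect_equal(hi$general_coordination, 25)
  expect_equal(hi$total, 75)
  expect_equal(score_dcdq(rep(1, 15))$total, 15)

  items <- rep(3, 15); items[8] <- NA
  sc <- score_dcdq(items)
  expect_true(is.na(sc$fine_motor_handwriting))
  expect_true(is.na(sc$total))
  expect_equal(sc$control_during_movement, 18)  # unaffected subscale intact

  expect_error(score_dcdq(c(rep(3, 14), 6)), "1..5")
  expect_error(score_dcdq(rep(3, 14)), "15 items")

  # generator calibration: totals track the cohort mean and SD
  big <- make_survey_table(5000, seed = 77)
  sc_big <- score_dcdq(big[, paste0("dcdq_", 1:15)])
  expect_equal(sc_big$total, big$dcdq_total)
  expect_equal(mean(sc_big$total), 51.25, tolerance = 0.5)
  expect_equal(sd(sc_big$total), 9.93, tolerance = 0.5)
  expect_true(all(sc_big$total >= 15 & sc_big$total <= 75))
})

test_that("grip tallies count the four classes plus the merged group", {
  g <- c(rep("four_finger", 64), rep("three_finger", 49),
         rep("palm", 20), rep("other", 32))
  tal <- tally_grip_classes(g)
  expect_equal(tal$n, c(64L, 49L, 20L, 32L, 52L))
  expect_equal(tal$pct[1:4], c(38.79, 29.70, 12.12, 19.39), tolerance = 0.01)
  expect_equal(sum(tal$pct[1:4]), 100, tolerance = 0.1)

  empty <- tally_grip_classes(character(0))
  expect_equal(empty$n, rep(0L, 5))

  df <- make_survey_table(200, seed = 3)
  tal2 <- tally_grip_classes(df)
  expect_equal(sum(tal2$n[1:4]), 200)
})

test_that("Fleiss kappa matches its defining formula", {
  perfect <- cbind(rep(c("a", "b", "c"), 4), rep(c("a", "b", "c"), 4))
  expect_equal(fleiss_kappa(perfect), 1.0)

  # independent uniform raters agree only by chance
  set.seed(5)
  indep <- cbind(sample(letters[1:4], 10000, TRUE),
                 sample(letters[1:4], 10000, TRUE))
  expect_lt(abs(fleiss_kappa(indep)), 0.03)

  expect_error(fleiss_kappa(matrix("a", 3, 1)), "2 raters")
  expect_error(fleiss_kappa(cbind(c("a", NA), c("a", "b"))), "every subject")

  # exhaustive equivalence with the brute-force oracle on small tables
  cats <- c("x", "y", "z")
  for (n in 1:3) {
    grid <- expand.grid(rep(list(seq_len(9)), n))
    pair <- expand.grid(r1 = cats, r2 = cats, stringsAsFactors = FALSE)
    for (g in seq_len(nrow(grid))) {
      tab <- cbind(pair$r1[unlist(grid[g, ])], pair$r2[unlist(grid[g, ])])
      expected <- fleiss_oracle(tab)
      if (is.na(expected)) next  # degenerate single-category table
      expect_equal(fleiss_kappa(tab), expected, tolerance = 1e-12)
    }
  }
  # randomized coverage of larger tables
  set.seed(11)
  for (rep_i in 1:500) {
    n <- sample(4:6, 1)
    tab <- cbind(sample(cats, n, TRUE), sample(cats, n, TRUE))
    expected <- fleiss_oracle(tab)
    if (is.na(expected)) next
    expect_equal(fleiss_kappa(tab), expected, tolerance = 1e-12)
  }
})

test_that("normality screen accepts normal data and transforms skewed data", {
  set.seed(21)
  norm_sample <- rnorm(200)
  r <- ks_normality(norm_sample)
  expect_true(r$normal)
  expect_null(r$transformed)

  skew <- rexp(500)
  r2 <- ks_normality(skew)
  expect_false(r2$normal)
  expect_equal(r2$transformed, log(skew))

  expect_error(ks_normality(c(1, 2, 3)), "n >= 5")
  set.seed(22)
  with_zero <- c(0, rexp(499))
  expect_error(ks_normality(with_zero), "positive")
})

test_that("multinomial logit matches an independent optimizer", {
  skip_if_not_installed("nnet")
  df <- make_survey_table(1200, seed = 31)
  fit <- fit_multinomial_logit(df)
  y <- factor(ifelse(df$grip_class %in% c("palm", "other"), "palm_other",
                     df$grip_class),
              levels = c("four_finger", "three_finger", "palm_other"))
  ref <- nnet::multinom(y ~ I(age == 7) + I(sex == "boy") + cohabitation +
                          training + dcdq_total,
                        data = df, trace = FALSE, maxit = 500, reltol = 1e-12)
  expect_lt(max(abs(t(coef(ref)) - coef(fit))), 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})

test_that("null data recover odds ratios near one", {
  co0 <- lapply(survey_default_coefficients(), function(v) { v[-1] <- 0; v })
  est <- sapply(1:6, function(r) {
    f <- fit_multinomial_logit(make_survey_table(5000, coefficients = co0,
                                                 seed = 300 + r))
    o <- or_table(f)
    o$or[o$predictor != "(Intercept)"]
  })
  expect_true(all(rowMeans(est) > 0.9 & rowMeans(est) < 1.1))
})

test_that("sandwich covariance changes SEs but never point estimates", {
  df <- make_survey_table(800, seed = 41)
  fit <- fit_multinomial_logit(df, robust = TRUE)
  tab_m <- or_table(fit, robust = FALSE)
  tab_r <- or_table(fit, robust = TRUE)
  expect_identical(tab_m$or, tab_r$or)
  expect_identical(tab_m$estimate, tab_r$estimate)
  expect_false(isTRUE(all.equal(tab_m$se, tab_r$se)))
  expect_equal(dim(vcov(fit, "robust")), dim(vcov(fit)))
})

test_that("generating log-odds are recovered within Wald CIs at n = 2000", {
  hits <- 0
  reps <- 100
  true_lo <- log(0.15)
  for (r in seq_len(reps)) {
    df <- make_survey_table(2000, seed = 1000 + r)
    tab <- or_table(fit_multinomial_logit(df))
    row <- tab[tab$contrast == "three_finger" &
                 tab$predictor == "cohabitation", ]
    lo <- row$estimate - 1.96 * row$se
    hi <- row$estimate + 1.96 * row$se
    if (lo <= true_lo && true_lo <= hi) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.90)
})

test_that("Nagelkerke R2 is 0 for the null fit and near 1 when separated", {
  df <- make_survey_table(600, seed = 51)
  null_fit <- fit_multinomial_logit(df, predictors = character(0))
  expect_equal(nagelkerke_r2(null_fit, null_fit), 0, tolerance = 1e-10)
  full_fit <- fit_multinomial_logit(df)
  expect_equal(nagelkerke_r2(full_fit),
               nagelkerke_r2(full_fit, null_fit), tolerance = 1e-6)
  expect_error(nagelkerke_r2(null_fit, full_fit), "lower likelihood")

  # near-perfectly separated classes (DCDQ thresholds, 3 contrary records)
  set.seed(1)
  n <- 900
  d <- data.frame(age = sample(6:7, n, TRUE),
                  sex = sample(c("boy", "girl"), n, TRUE),
                  cohabitation = rbinom(n, 1, 0.3),
                  training = rbinom(n, 1, 0.8),
                  dcdq_total = round(runif(n, 20, 80)))
  cls <- ifelse(d$dcdq_total <= 45, "four_finger",
                ifelse(d$dcdq_total <= 57, "three_finger", "palm"))
  flip <- sample(n, 3)
  cls[flip] <- vapply(cls[flip], function(cl)
    setdiff(c("four_finger", "three_finger", "palm"), cl)[1], "")
  d$grip_class <- cls
  f <- fit_multinomial_logit(d, predictors = "dcdq_total")
  expect_gt(nagelkerke_r2(f), 0.95)
})

test_that("cohort description reproduces the generator's marginals", {
  df <- make_survey_table(2000, seed = 61)
  desc <- describe_cohort(df)
  tot <- desc$dcdq[desc$dcdq$scale == "total", ]
  expect_equal(tot$total_mean, 51.25, tolerance = 0.8)
  expect_equal(desc$maternal$age[["mean"]], 37.88, tolerance = 0.5)
  expect_equal(desc$maternal$taught[["pct_yes"]], 100 * 136 / 165,
               tolerance = 3)
  expect_equal(sum(desc$n[c("age6", "age7")]), 2000)

  one <- describe_cohort(make_survey_table(10, seed = 1)[1, ])
  expect_true(is.na(one$dcdq$total_sd[1]))
})

test_that("survey generator controls missingness and validates inputs", {
  df0 <- make_survey_table(100, missing_rate = 0, seed = 1)
  expect_false(anyNA(df0))
  dfm <- make_survey_table(400, missing_rate = 0.05, seed = 2)
  expect_gt(sum(is.na(dfm)), 0)
  expect_true(anyNA(dfm$dcdq_total))   # missing items propagate, no imputation
  expect_error(make_survey_table(5), "n >= 10")
  bad <- survey_default_coefficients()
  names(bad$three_finger)[2] <- "shoe_size"
  expect_error(make_survey_table(100, coefficients = bad), "unknown predictor")
  expect_identical(make_survey_table(100, seed = 9),
                   make_survey_table(100, seed = 9))
})
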