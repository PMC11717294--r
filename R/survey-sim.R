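#' Default generating coefficients for the synthetic survey
#'
#' Log-odds of the multinomial generative model behind
#' [make_survey_table()], one named vector per outcome contrast
#' (vs the four-finger reference). The slope defaults are the cohort's
#' reported determinants of traditional chopstick holding (e.g.
#' grandparent cohabitation OR 0.15 for the three-finger contrast and
#' 0.12 for the palm contrast, age OR 0.33 for the palm contrast); the
#' intercepts are calibrated once so that, at the default covariate
#' distribution, the expected class mix matches the observed
#' 64 : 49 : 52 composition.
#'
#' @return named list with elements `three_finger` and `palm_other`.
#' @export
survey_default_coefficients <- function() {
  list(
    three_finger = c("(Intercept)" = 0.3693, age = log(0.49),
                     sex = log(1.35), cohabitation = log(0.15),
                     training = log(0.59), dcdq_total = log(1.01)),
    palm_other = c("(Intercept)" = 0.8942, age = log(0.33),
                   sex = log(0.96), cohabitation = log(0.12),
                   training = log(1.66), dcdq_total = log(0.99)))
}

#' Generate a synthetic survey table
#'
#' Synthetic twin of the study's questionnaire data with a fully known
#' generative model, so the survey statistics can be validated by
#' parameter recovery. Covariates are drawn from the cohort marginals
#' (age 7 with probability 51/165, boys 75/165, grandparent cohabitation
#' 0.30, prior chopstick training 0.82; DCDQ items from a latent
#' per-child mean calibrated to a total of 51.25 +/- 9.93 truncated to
#' [15, 75]); the grip class is then drawn from a multinomial logit with
#' the supplied log-odds; two synthetic raters relabel the true class
#' with a small error rate; maternal variables follow the reported
#' marginals (age 37.88 +/- 6.11 within 26-49, teaching experience
#' 82.4%, knowledge 92.1%, ability 70.9%).
#'
#' @param n number of children (>= 10; default 165, the cohort size).
#' @param coefficients generating log-odds, see
#'   [survey_default_coefficients()]; all-zero slopes give a null model.
#' @param missing_rate probability that each optional cell (cohabitation,
#'   training, DCDQ items, maternal fields) is blanked to `NA`.
#' @param seed RNG seed.
#' @param rater_error probability that a rater mislabels a child's grip
#'   class (uniformly to another class).
#' @return data frame with columns `id`, `age` (6/7), `sex`
#'   (`"boy"`/`"girl"`), `cohabitation` (0/1), `training` (0/1),
#'   `dcdq_1..dcdq_15`, `dcdq_total`, `grip_class`
#'   (`four_finger`/`three_finger`/`palm`/`other`), `rater1`, `rater2`,
#'   `mother_age`, `mother_taught`, `mother_knows`, `mother_can_use`;
#'   attribute `coefficients` records the generating model.
#' @export
make_survey_table <- function(n = 165,
                              coefficients = survey_default_coefficients(),
                              missing_rate = 0, seed = 1,
                              rater_error = 0.012) {
  if (n < 10) stopf("survey generator requires n >= 10")
  if (!all(c("three_finger", "palm_other") %in% names(coefficients)))
    stopf("coefficients must be keyed by contrast: three_finger, palm_other")
  known <- c("(Intercept)", "age", "sex", "cohabitation", "training",
             "dcdq_total")
  for (ct in c("three_finger", "palm_other")) {
    bad <- setdiff(names(coefficients[[ct]]), known)
    if (length(bad))
      stopf("coefficients for unknown predictor '%s' in contrast %s",
            bad[1], ct)
  }
  if (missing_rate < 0 || missing_rate >= 1)
    stopf("missing_rate must lie in [0, 1)")

  with_seed(seed, {
    age <- 6 + stats::rbinom(n, 1, 51 / 165)
    sex <- ifelse(stats::rbinom(n, 1, 75 / 165) == 1, "boy", "girl")
    cohabitation <- stats::rbinom(n, 1, 0.30)
    training <- stats::rbinom(n, 1, 0.82)
    # latent-mean item model calibrated to total 51.25 +/- 9.93 in [15, 75]
    mu <- stats::rnorm(n, 3.4235, 0.662)
    items <- matrix(pmin(pmax(round(mu + stats::rnorm(n * 15, 0, 0.55)), 1), 5),
                    n, 15)
    colnames(items) <- paste0("dcdq_", 1:15)
    dcdq_total <- rowSums(items)

    xvec <- function(b) {
      v <- stats::setNames(numeric(6), known)
      v[names(b)] <- b
      v["(Intercept)"] +
        v["age"] * (age == 7) + v["sex"] * (sex == "boy") +
        v["cohabitation"] * cohabitation + v["training"] * training +
        v["dcdq_total"] * dcdq_total
    }
    eta3 <- xvec(coefficients$three_finger)
    etap <- xvec(coefficients$palm_other)
    den <- 1 + exp(eta3) + exp(etap)
    u <- stats::runif(n)
    p4 <- 1 / den; p3 <- exp(eta3) / den
    cls <- ifelse(u < p4, "four_finger",
                  ifelse(u < p4 + p3, "three_finger", "palm_other"))
    # split the merged palm group into palm / other at the cohort 20:32 ratio
    po <- cls == "palm_other"
    cls[po] <- ifelse(stats::runif(sum(po)) < 20 / 52, "palm", "other")

    relabel <- function(truth) {
      lv <- c("four_finger", "three_finger", "palm", "other")
      err <- stats::runif(n) < rater_error
      out <- truth
      out[err] <- vapply(truth[err], function(cl)
        sample(setdiff(lv, cl), 1), "")
      out
    }
    rater1 <- relabel(cls); rater2 <- relabel(cls)

    mother_age <- pmin(pmax(round(stats::rnorm(n, 37.88, 6.11)), 26), 49)
    mother_taught <- stats::rbinom(n, 1, 136 / 165)
    mother_knows <- stats::rbinom(n, 1, 152 / 165)
    mother_can_use <- stats::rbinom(n, 1, 117 / 165)

    df <- data.frame(id = seq_len(n), age = age, sex = sex,
                     cohabitation = cohabitation, training = training,
                     items, dcdq_total = dcdq_total, grip_class = cls,
                     rater1 = rater1, rater2 = rater2,
                     mother_age = mother_age, mother_taught = mother_taught,
                     mother_knows = mother_knows,
                     mother_can_use = mother_can_use,
                     stringsAsFactors = FALSE)
    if (missing_rate > 0) {
      blank <- c("cohabitation", "training", paste0("dcdq_", 1:15),
                 "mother_age", "mother_taught", "mother_knows",
                 "mother_can_use")
      for (col in blank) {
        hit <- stats::runif(n) < missing_rate
        df[[col]][hit] <- NA
      }
      df$dcdq_total <- score_dcdq(df[, paste0("dcdq_", 1:15)])$total
    }
    attr(df, "coefficients") <- coefficients
    df
  })
}
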