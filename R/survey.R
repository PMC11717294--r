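#' Score the Developmental Coordination Disorder Questionnaire
#'
#' Sums the 15 parent-rated items (each 1-5) into the three standard
#' subscales — control during movement (items 1-6), fine motor /
#' handwriting (items 7-10), general coordination (items 11-15) — and the
#' total. Any missing item leaves its subscale and the total missing: no
#' imputation is performed. The item-to-subscale mapping is configurable
#' for translated versions of the questionnaire.
#'
#' @param items length-15 numeric vector, or an n x 15 matrix/data frame
#'   (one child per row). Values must be in 1..5 or `NA`.
#' @param mapping list of item index vectors for the three subscales
#'   (default the standard 6/4/5 split).
#' @return a data frame (one row per child) with columns
#'   `control_during_movement`, `fine_motor_handwriting`,
#'   `general_coordination`, `total`.
#' @export
score_dcdq <- function(items,
                       mapping = list(control_during_movement = 1:6,
                                      fine_motor_handwriting = 7:10,
                                      general_coordination = 11:15)) {
  if (is.null(dim(items))) {
    if (length(items) != 15)
      stopf("DCDQ requires 15 items, got %d", length(items))
    m <- matrix(as.numeric(items), nrow = 1)
  } else {
    m <- as.matrix(items)
    storage.mode(m) <- "numeric"
  }
  if (ncol(m) != 15) stopf("DCDQ requires 15 items, got %d columns", ncol(m))
  bad <- !is.na(m) & (m < 1 | m > 5 | m != round(m))
  if (any(bad))
    stopf("DCDQ items must be integers in 1..5; offending value %s",
          format(m[bad][1]))
  sub <- vapply(mapping, function(ix) rowSums(m[, ix, drop = FALSE]),
                numeric(nrow(m)))
  sub <- matrix(sub, nrow = nrow(m),
                dimnames = list(NULL, names(mapping)))
  out <- as.data.frame(sub)
  out$total <- rowSums(sub)
  out
}

#' Tally grip classes
#'
#' Counts and percentages over the four-level grip taxonomy (four-finger,
#' three-finger, palm, others), plus the merged palm + others group used
#' as a single category in the regression analysis.
#'
#' @param records survey data frame with a `grip_class` column, or a
#'   vector of grip classes.
#' @return data frame with `class`, `n`, `pct` rows for the four classes
#'   and a final `palm_other` row.
#' @export
tally_grip_classes <- function(records) {
  g <- if (is.data.frame(records)) as.character(records$grip_class)
       else as.character(records)
  lv <- c("four_finger", "three_finger", "palm", "other")
  g <- g[!is.na(g)]
  n <- vapply(lv, function(cl) sum(g == cl), 0L)
  total <- length(g)
  pct <- if (total) 100 * n / total else rep(0, 4)
  rbind(data.frame(class = lv, n = as.integer(n), pct = pct),
        data.frame(class = "palm_other", n = as.integer(n[3] + n[4]),
                   pct = pct[3] + pct[4]))
}

#' Fleiss' kappa for inter-rater agreement
#'
#' Chance-corrected agreement for categorical ratings of n subjects by r
#' raters, per the standard category-proportion formula: per-subject
#' agreement averaged over subjects, corrected by the agreement expected
#' from the marginal category proportions.
#'
#' @param ratings an n x r matrix or data frame of categorical labels
#'   (characters or factors), one row per subject, one column per rater.
#' @return Fleiss' kappa (1 = perfect agreement, ~0 = chance).
#' @export
fleiss_kappa <- function(ratings) {
  m <- as.matrix(ratings)
  if (ncol(m) < 2) stopf("Fleiss' kappa needs at least 2 raters")
  if (anyNA(m)) stopf("every subject must be rated by every rater")
  r <- ncol(m); n <- nrow(m)
  cats <- sort(unique(as.vector(m)))
  counts <- vapply(cats, function(cl) rowSums(m == cl),
                   numeric(n))
  counts <- matrix(counts, nrow = n)
  P_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  p_j <- colSums(counts) / (n * r)
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  if (1 - P_e < .Machine$double.eps) return(1)
  (P_bar - P_e) / (1 - P_e)
}

#' Normality screen with the Lilliefors-corrected KS test
#'
#' Kolmogorov-Smirnov test against a normal distribution with estimated
#' mean and SD (Lilliefors correction). When normality is rejected at
#' `alpha` and `transform = TRUE`, the log-transformed values are
#' returned alongside for use in downstream models.
#'
#' @param values numeric vector, n >= 5.
#' @param alpha rejection level (default 0.05).
#' @param transform attempt a logarithmic transformation on rejection;
#'   requires strictly positive values.
#' @return list with `statistic`, `p`, `normal` (logical),
#'   `transformed` (log values or `NULL`).
#' @export
ks_normality <- function(values, alpha = 0.05, transform = TRUE) {
  values <- values[!is.na(values)]
  if (length(values) < 5)
    stopf("normality screen needs n >= 5, got %d", length(values))
  kt <- nortest::lillie.test(values)
  normal <- kt$p.value >= alpha
  transformed <- NULL
  if (!normal && transform) {
    if (any(values <= 0))
      stopf("log transform requested but values are not strictly positive")
    transformed <- log(values)
  }
  list(statistic = unname(kt$statistic), p = kt$p.value, normal = normal,
       transformed = transformed)
}

#' Cohort description tables
#'
#' Reproduces the questionnaire descriptives: DCDQ subscale and total
#' means +/- SD overall and split by age group and sex, and the maternal
#' summary (mean age, counts and percentages of chopstick teaching
#' experience, knowledge and self-reported ability).
#'
#' @param records survey data frame (schema of [make_survey_table()]).
#' @return list with `dcdq` (data frame, one row per subscale, columns
#'   for each stratum as `mean (sd)` pairs), `maternal` (named list), and
#'   `n` per stratum.
#' @export
describe_cohort <- function(records) {
  if (nrow(records) == 0) stopf("empty records")
  sc <- score_dcdq(records[, paste0("dcdq_", 1:15)])
  strata <- list(total = rep(TRUE, nrow(records)),
                 age6 = records$age == 6,
                 age7 = records$age == 7,
                 boy = records$sex == "boy",
                 girl = records$sex == "girl")
  msd <- function(x) c(mean = mean(x, na.rm = TRUE),
                       sd = if (sum(!is.na(x)) > 1) stats::sd(x, na.rm = TRUE)
                            else NA_real_)
  dcdq <- do.call(rbind, lapply(names(sc), function(scale) {
    row <- lapply(strata, function(sel) msd(sc[[scale]][sel]))
    data.frame(scale = scale,
               t(stats::setNames(unlist(row),
                                 paste(rep(names(strata), each = 2),
                                       c("mean", "sd"), sep = "_"))))
  }))
  count_pct <- function(x) {
    yes <- sum(x == 1, na.rm = TRUE); no <- sum(x == 0, na.rm = TRUE)
    miss <- sum(is.na(x))
    c(yes = yes, no = no, missing = miss,
      pct_yes = 100 * yes / length(x))
  }
  maternal <- list(
    age = msd(records$mother_age),
    taught = count_pct(records$mother_taught),
    knows = count_pct(records$mother_knows),
    can_use = count_pct(records$mother_can_use))
  list(dcdq = dcdq, maternal = maternal,
       n = vapply(strata, sum, 0L))
}
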