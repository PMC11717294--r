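#' Multinomial logistic regression for grip-class determinants
#'
#' Maximum-likelihood multinomial logit relating the three-level grip
#' outcome (four-finger prehension as the reference category; three-finger;
#' palm prehension merged with the "others" group) to child covariates.
#' The fit uses full Newton-Raphson iterations on the stacked coefficient
#' vector (analytic gradient and Hessian, convergence tolerance 1e-8 with
#' step halving), reports odds ratios with Wald 95% confidence intervals
#' on the log-odds scale, and optionally a heteroscedasticity-robust
#' sandwich covariance. Dummy coding follows the study's convention:
#' age 7 = 1, boy = 1, cohabitation yes = 1, training yes = 1; the DCDQ
#' total score enters as a raw sum. Rows with missing values in any used
#' variable are dropped (listwise deletion).
#'
#' @param records survey data frame (see [make_survey_table()] for the
#'   schema): needs `grip_class` plus the predictor columns.
#' @param reference reference outcome level (default `"four_finger"`).
#' @param predictors character subset of
#'   `c("age", "sex", "cohabitation", "training", "dcdq_total")`;
#'   `character(0)` fits the intercept-only (null) model.
#' @param merge_others merge `"other"` records into the palm group
#'   (default `TRUE`); `FALSE` excludes them.
#' @param robust also compute the sandwich covariance (default `TRUE`).
#' @param tol Newton convergence tolerance on the score/step (default 1e-8).
#' @param max_iter iteration cap.
#' @return an object of class `mnl_fit`: `coefficients` (p x 2 matrix,
#'   columns = contrasts vs the reference), `vcov`, `vcov_robust`,
#'   `loglik`, `n`, `converged`, `iterations`, plus the model frame
#'   pieces needed to refit the null model.
#' @export
fit_multinomial_logit <- function(records, reference = "four_finger",
                                  predictors = c("age", "sex", "cohabitation",
                                                 "training", "dcdq_total"),
                                  merge_others = TRUE, robust = TRUE,
                                  tol = 1e-8, max_iter = 100) {
  known <- c("age", "sex", "cohabitation", "training", "dcdq_total")
  bad <- setdiff(predictors, known)
  if (length(bad)) stopf("unknown predictor(s): %s", paste(bad, collapse = ", "))
  if (!reference %in% c("four_finger"))
    stopf("reference must be 'four_finger'")

  y_raw <- as.character(records$grip_class)
  if (merge_others) y_raw[y_raw %in% c("palm", "other")] <- "palm_other"
  else {
    keep0 <- y_raw != "other"
    records <- records[keep0, , drop = FALSE]
    y_raw <- y_raw[keep0]
    y_raw[y_raw == "palm"] <- "palm_other"
  }
  lv <- c(reference, "three_finger", "palm_other")

  X <- cbind("(Intercept)" = rep(1, nrow(records)))
  if ("age" %in% predictors)
    X <- cbind(X, age = as.numeric(records$age == 7))
  if ("sex" %in% predictors)
    X <- cbind(X, sex = as.numeric(records$sex %in% c("boy", "1", 1)))
  if ("cohabitation" %in% predictors)
    X <- cbind(X, cohabitation = as.numeric(records$cohabitation))
  if ("training" %in% predictors)
    X <- cbind(X, training = as.numeric(records$training))
  if ("dcdq_total" %in% predictors) {
    tot <- if ("dcdq_total" %in% names(records)) records$dcdq_total
           else score_dcdq(records[, paste0("dcdq_", 1:15)])$total
    X <- cbind(X, dcdq_total = as.numeric(tot))
  }
  keep <- stats::complete.cases(X) & !is.na(y_raw) & y_raw %in% lv
  X <- X[keep, , drop = FALSE]
  y <- factor(y_raw[keep], levels = lv)
  n <- nrow(X); p <- ncol(X); K <- 3L
  if (n == 0) stopf("no complete cases to fit")
  if (any(table(y)[-1] == 0)) stopf("an outcome contrast has no observations")

  Y <- cbind(as.numeric(y == lv[2]), as.numeric(y == lv[3]))
  B <- matrix(0, p, 2, dimnames = list(colnames(X), lv[2:3]))
  loglik <- function(B) {
    eta <- X %*% B
    m <- pmax(eta[, 1], eta[, 2], 0)
    sum(rowSums(Y * eta) - (m + log(exp(-m) + exp(eta[, 1] - m) + exp(eta[, 2] - m))))
  }
  probs <- function(B) {
    eta <- X %*% B
    m <- pmax(eta[, 1], eta[, 2], 0)
    den <- exp(-m) + exp(eta[, 1] - m) + exp(eta[, 2] - m)
    cbind(exp(eta[, 1] - m) / den, exp(eta[, 2] - m) / den)
  }
  ll <- loglik(B)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    P <- probs(B)
    R <- Y - P
    grad <- c(crossprod(X, R[, 1]), crossprod(X, R[, 2]))
    W11 <- P[, 1] * (1 - P[, 1]); W22 <- P[, 2] * (1 - P[, 2])
    W12 <- -P[, 1] * P[, 2]
    info <- rbind(cbind(crossprod(X, X * W11), crossprod(X, X * W12)),
                  cbind(crossprod(X, X * W12), crossprod(X, X * W22)))
    step <- tryCatch(solve(info, grad), error = function(e)
      stopf("singular information matrix (perfect separation or collinear predictors)"))
    sc <- 1
    repeat {
      Bnew <- B + matrix(sc * step, p, 2)
      llnew <- loglik(Bnew)
      if (is.finite(llnew) && llnew >= ll - 1e-12) break
      sc <- sc / 2
      if (sc < 1e-8) stopf("step halving failed; likelihood not improving")
    }
    B <- Bnew
    moved <- max(abs(sc * step))
    ll <- llnew
    if (max(abs(grad)) < tol || moved < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("Newton iterations did not converge in ", max_iter,
                          " steps")
  Bs <- B[-1, , drop = FALSE]
  if (nrow(Bs) && any(abs(Bs) > 30)) {
    off <- rownames(Bs)[which(abs(Bs) > 30, arr.ind = TRUE)[, 1]]
    stopf("apparent separation: coefficient diverged for predictor '%s'", off[1])
  }

  P <- probs(B)
  W11 <- P[, 1] * (1 - P[, 1]); W22 <- P[, 2] * (1 - P[, 2])
  W12 <- -P[, 1] * P[, 2]
  info <- rbind(cbind(crossprod(X, X * W11), crossprod(X, X * W12)),
                cbind(crossprod(X, X * W12), crossprod(X, X * W22)))
  V <- solve(info)
  nm <- c(paste0(lv[2], ":", colnames(X)), paste0(lv[3], ":", colnames(X)))
  dimnames(V) <- list(nm, nm)
  Vr <- NULL
  if (robust) {
    S <- cbind(X * (Y[, 1] - P[, 1]), X * (Y[, 2] - P[, 2]))
    meat <- crossprod(S)
    Vr <- V %*% meat %*% V
    dimnames(Vr) <- dimnames(V)
  }
  structure(list(coefficients = B, vcov = V, vcov_robust = Vr,
                 loglik = ll, n = n, levels = lv, predictors = predictors,
                 X = X, y = y, converged = converged, iterations = iter,
                 call = match.call()),
            class = "mnl_fit")
}

#' @export
coef.mnl_fit <- function(object, ...) object$coefficients

#' @export
logLik.mnl_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
vcov.mnl_fit <- function(object, type = c("model", "robust"), ...) {
  type <- match.arg(type)
  if (type == "robust") {
    if (is.null(object$vcov_robust)) stopf("fit was made with robust = FALSE")
    object$vcov_robust
  } else object$vcov
}

#' Odds-ratio table of a multinomial logit fit
#'
#' @param fit an `mnl_fit`.
#' @param robust use the sandwich covariance for SEs/CIs/p-values.
#' @param level confidence level (default 0.95).
#' @return data frame with one row per contrast x predictor: log-odds
#'   `estimate`, `se`, `z`, `p`, `or` and Wald CI bounds `or_lo`, `or_hi`.
#' @export
or_table <- function(fit, robust = FALSE, level = 0.95) {
  stopifnot(inherits(fit, "mnl_fit"))
  V <- vcov(fit, if (robust) "robust" else "model")
  se <- matrix(sqrt(diag(V)), ncol = 2,
               dimnames = dimnames(fit$coefficients))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- do.call(rbind, lapply(colnames(fit$coefficients), function(ct) {
    b <- fit$coefficients[, ct]; s <- se[, ct]
    data.frame(contrast = ct, predictor = names(b), estimate = b, se = s,
               z = b / s, p = 2 * stats::pnorm(-abs(b / s)),
               or = exp(b), or_lo = exp(b - zq * s), or_hi = exp(b + zq * s),
               row.names = NULL)
  }))
  out
}

#' @export
print.mnl_fit <- function(x, ...) {
  cat(sprintf("Multinomial logit (reference: %s), n = %d, logLik = %.3f\n",
              x$levels[1], x$n, x$loglik))
  tab <- or_table(x)
  tab[c("estimate", "se", "or", "or_lo", "or_hi", "p")] <-
    lapply(tab[c("estimate", "se", "or", "or_lo", "or_hi", "p")],
           function(v) round(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mnl_fit <- function(object, robust = FALSE, ...) {
  cat(sprintf("Multinomial logistic regression (Newton ML, %d iterations%s)\n",
              object$iterations,
              if (object$converged) "" else ", NOT converged"))
  cat(sprintf("  n = %d complete cases; reference category: %s\n",
              object$n, object$levels[1]))
  if (robust) cat("  sandwich (robust) standard errors\n")
  print(or_table(object, robust = robust), row.names = FALSE)
  invisible(object)
}

#' @export
predict.mnl_fit <- function(object, newdata = NULL,
                            type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else as.matrix(newdata)
  eta <- X %*% object$coefficients
  m <- pmax(eta[, 1], eta[, 2], 0)
  den <- exp(-m) + exp(eta[, 1] - m) + exp(eta[, 2] - m)
  P <- cbind(exp(-m) / den, exp(eta[, 1] - m) / den, exp(eta[, 2] - m) / den)
  colnames(P) <- object$levels
  if (type == "prob") P else object$levels[max.col(P)]
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell R2 = 1 - (L0/L1)^(2/n), rescaled by its maximum
#' 1 - L0^(2/n) to the Nagelkerke 0-1 range.
#'
#' @param fitted an `mnl_fit` (the full model).
#' @param null_fitted the intercept-only fit on the same rows; refitted
#'   automatically when `NULL`.
#' @param n number of observations (defaults to the fit's).
#' @return the Nagelkerke pseudo-R2.
#' @export
nagelkerke_r2 <- function(fitted, null_fitted = NULL, n = fitted$n) {
  stopifnot(inherits(fitted, "mnl_fit"))
  if (is.null(null_fitted)) {
    counts <- table(fitted$y)
    pr <- as.numeric(counts) / sum(counts)
    ll0 <- sum(counts * log(pr))
  } else {
    if (null_fitted$n != fitted$n)
      stopf("null and full fits use different rows (n = %d vs %d)",
            null_fitted$n, fitted$n)
    ll0 <- null_fitted$loglik
  }
  ll1 <- fitted$loglik
  if (ll1 < ll0 - 1e-8)
    stopf("full model has lower likelihood than the null; fits swapped?")
  cox_snell <- 1 - exp((2 / n) * (ll0 - ll1))
  cox_snell / (1 - exp((2 / n) * ll0))
}
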