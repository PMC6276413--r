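## Least-squares fitting with the information criteria and squared
## partial correlations used throughout the model-selection strategies.
## A light internal path (.fast_ols) serves the hot loops (exhaustive
## subset scoring, stepwise over bootstrap resamples); the user-facing
## ols_fit() wraps stats::lm and reports the full coefficient table.

## criteria constants follow the Gaussian log-likelihood convention of
## stats::AIC / stats::BIC: k counts the intercept, slopes and the error
## variance; AICC = AIC + 2k(k+1)/(n-k-1)
.criteria <- function(rss, n, p_slopes) {
  k <- p_slopes + 2                       # intercept + slopes + sigma^2
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  aic <- -2 * ll + 2 * k
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  bic <- -2 * ll + log(n) * k
  c(aic = aic, aicc = aicc, bic = bic)
}

## X: numeric matrix WITHOUT intercept column; returns what the subset /
## stepwise searches need. Set `se = TRUE` for coefficient inference.
.fast_ols <- function(y, X, se = FALSE) {
  n <- length(y)
  Xm <- cbind(`(Intercept)` = 1, X)
  fit <- .lm.fit(Xm, y)
  if (fit$rank < ncol(Xm)) return(NULL)    # rank-deficient
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  p <- ncol(Xm) - 1L
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj <- if (n - p - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  out <- list(n = n, p = p, rss = rss, tss = tss, r2 = r2, adj_r2 = adj,
              crit = .criteria(rss, n, p))
  cf <- numeric(ncol(Xm))
  cf[fit$pivot] <- fit$coefficients
  names(cf) <- colnames(Xm)
  out$coef <- cf
  if (se) {
    df <- n - p - 1L
    sigma2 <- rss / df
    xtxi <- chol2inv(chol(crossprod(Xm)))
    out$se <- sqrt(diag(xtxi) * sigma2)
    names(out$se) <- colnames(Xm)
    out$t <- cf / out$se
    out$p_value <- 2 * stats::pt(abs(out$t), df, lower.tail = FALSE)
    out$df_resid <- df
  }
  out
}

#' Fit a multiple linear regression with reporting for lipid models
#'
#' Ordinary least squares with the coefficient table, fit criteria (R2,
#' adjusted R2, AIC, AICC, BIC) and per-predictor squared partial
#' correlations used by the model-selection strategies. Errors on
#' rank-deficient designs, naming the collinear columns.
#'
#' @param formula model formula (e.g. `tc ~ age + energy100 + grs_tc`).
#' @param data data.frame holding the response and predictors.
#' @return object of class `"lipid_fit"`.
#' @export
ols_fit <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X)
  if (n <= ncol(X)) .fail("need n > p + 1 observations (n = %d, p = %d)",
                          n, ncol(X) - 1L)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    .fail("design is rank-deficient; collinear column(s): %s",
          paste(aliased, collapse = ", "))
  }
  fit <- stats::lm(formula, data = data, na.action = stats::na.omit)
  s <- summary(fit)
  coefs <- s$coefficients
  df_resid <- fit$df.residual
  preds <- setdiff(rownames(coefs), "(Intercept)")
  tvals <- stats::setNames(coefs[preds, "t value"], preds)
  pc2 <- tvals^2 / (tvals^2 + df_resid)
  crit <- .criteria(sum(stats::residuals(fit)^2), n, length(preds))
  structure(list(
    formula = formula, lm = fit, n = n,
    predictors = preds,
    coef_table = coefs,
    r2 = s$r.squared, adj_r2 = s$adj.r.squared,
    aic = crit[["aic"]], aicc = crit[["aicc"]], bic = crit[["bic"]],
    pc2 = pc2, df_resid = df_resid, sigma = s$sigma
  ), class = "lipid_fit")
}

#' Squared partial correlations of a fitted model
#'
#' PC2_j = t_j^2 / (t_j^2 + df_residual): the proportion of the response
#' variance unexplained by the other predictors that predictor j
#' uniquely accounts for. Equals the squared correlation between the
#' response and the predictor after both are residualized on the
#' remaining predictors.
#'
#' @param fit a [ols_fit()] result (or an `lm`).
#' @return named numeric vector of PC2 values, one per predictor.
#' @export
squared_partial_correlation <- function(fit) {
  if (inherits(fit, "lipid_fit")) return(fit$pc2)
  if (inherits(fit, "lm")) {
    s <- summary(fit)
    df <- fit$df.residual
    if (df <= 0) .fail("residual degrees of freedom must be positive")
    tv <- s$coefficients[setdiff(rownames(s$coefficients), "(Intercept)"), "t value"]
    return(tv^2 / (tv^2 + df))
  }
  .fail("'fit' must be a lipid_fit or lm object")
}

#' @export
print.lipid_fit <- function(x, digits = 4, ...) {
  cat("Linear lipid model:", deparse(x$formula), "\n")
  cat(sprintf("n = %d, R2 = %.4f, adj R2 = %.4f, AIC = %.1f, AICC = %.1f, BIC = %.1f\n",
              x$n, x$r2, x$adj_r2, x$aic, x$aicc, x$bic))
  tab <- cbind(x$coef_table[, c("Estimate", "Std. Error"), drop = FALSE],
               `PC2` = c(NA, x$pc2)[match(rownames(x$coef_table),
                                          c("(Intercept)", names(x$pc2)))])
  print(round(tab, digits))
  invisible(x)
}

#' @export
summary.lipid_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.lipid_fit <- function(object, ...) stats::coef(object$lm)

#' @export
predict.lipid_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$lm)
  else stats::predict(object$lm, newdata = newdata)
}

#' @export
residuals.lipid_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
plot.lipid_fit <- function(x, ...) {
  graphics::plot(stats::fitted(x$lm), stats::residuals(x$lm),
                 xlab = "Fitted (mg/dl)", ylab = "Residual (mg/dl)",
                 main = deparse(x$formula), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' @export
simulate.lipid_fit <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$lm, nsim = nsim, seed = seed, ...)
}
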