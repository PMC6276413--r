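#' Harrell bootstrap optimism correction of a model-building procedure
#'
#' Quantifies the overfitting of an entire model-building process
#' (selection included): for each bootstrap resample the whole procedure
#' is rerun, its apparent performance on the resample is compared with
#' the performance of the same frozen model applied to the original
#' data, and the average difference (the optimism) is subtracted from
#' the apparent metrics of the model built on the original data.
#'
#' @param procedure a function `data -> lipid_fit` that reruns the full
#'   selection (must be deterministic given the data).
#' @param data the original data.frame.
#' @param B number of bootstrap resamples (default 500; >= 100 for
#'   reported results).
#' @param seed integer seed.
#' @return object of class `"optimism_report"`: `apparent`, `optimism`
#'   and `corrected` (each with `r2` and `adj_r2`; corrected = apparent
#'   - optimism exactly), `B`, `seed`, `n_redrawn` (degenerate
#'   resamples redrawn).
#' @export
optimism_correct <- function(procedure, data, B = 500, seed = 1L) {
  if (B < 1) .fail("B must be >= 1")
  apparent_fit <- procedure(data)
  if (!inherits(apparent_fit, "lipid_fit"))
    .fail("'procedure' must return a lipid_fit")
  response <- all.vars(apparent_fit$formula)[1]
  y_orig <- data[[response]]
  ok <- !is.na(y_orig)
  tss_orig <- sum((y_orig[ok] - mean(y_orig[ok]))^2)
  n_orig <- sum(ok)

  set.seed(seed)
  opt_r2 <- numeric(B)
  opt_adj <- numeric(B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    fit_b <- NULL
    for (try in 1:20) {
      idx <- sample.int(nrow(data), replace = TRUE)
      fit_b <- tryCatch(procedure(data[idx, , drop = FALSE]),
                        error = function(e) NULL)
      if (!is.null(fit_b)) break
      n_redrawn <- n_redrawn + 1L
    }
    if (is.null(fit_b))
      .fail("could not fit the procedure on 20 consecutive resamples")
    ## frozen model_b evaluated on the original data
    pred <- stats::predict(fit_b$lm, newdata = data)
    rss <- sum((y_orig[ok] - pred[ok])^2)
    r2_orig <- 1 - rss / tss_orig
    p_b <- length(fit_b$predictors)
    adj_orig <- 1 - (1 - r2_orig) * (n_orig - 1) / (n_orig - p_b - 1)
    opt_r2[b] <- fit_b$r2 - r2_orig
    opt_adj[b] <- fit_b$adj_r2 - adj_orig
  }
  optimism <- c(r2 = mean(opt_r2), adj_r2 = mean(opt_adj))
  apparent <- c(r2 = apparent_fit$r2, adj_r2 = apparent_fit$adj_r2)
  structure(list(
    apparent = apparent, optimism = optimism,
    corrected = apparent - optimism,
    B = B, seed = seed, n_redrawn = n_redrawn,
    fit = apparent_fit
  ), class = "optimism_report")
}

#' @export
print.optimism_report <- function(x, ...) {
  tab <- rbind(apparent = x$apparent, optimism = x$optimism,
               corrected = x$corrected)
  colnames(tab) <- c("R2", "adj R2")
  cat(sprintf("Bootstrap optimism correction (B = %d, %d resample(s) redrawn)\n",
              x$B, x$n_redrawn))
  print(round(tab, 4))
  invisible(x)
}

#' Scan GRS-by-lifestyle interactions
#'
#' For each lifestyle variable L fits `response ~ GRS + L + GRS:L` and
#' reports the product-term coefficient and p-value. Constant variables
#' are skipped with a warning.
#'
#' @param grs numeric GRS vector.
#' @param lifestyle data.frame of lifestyle variables.
#' @param response numeric response vector.
#' @return data.frame: `variable`, `beta_interaction`, `se`, `p`,
#'   `skipped`.
#' @export
interaction_scan <- function(grs, lifestyle, response) {
  if (length(grs) != length(response) || nrow(lifestyle) != length(response))
    .fail("grs, lifestyle and response must be aligned")
  rows <- lapply(names(lifestyle), function(v) {
    L <- lifestyle[[v]]
    if (length(unique(L[!is.na(L)])) < 2L) {
      warning(sprintf("'%s' is constant; skipped", v), call. = FALSE)
      return(data.frame(variable = v, beta_interaction = NA_real_,
                        se = NA_real_, p = NA_real_, skipped = TRUE))
    }
    d <- data.frame(y = response, grs = grs, L = as.numeric(L))
    fit <- stats::lm(y ~ grs * L, data = d)
    cf <- summary(fit)$coefficients
    if (!"grs:L" %in% rownames(cf))
      return(data.frame(variable = v, beta_interaction = NA_real_,
                        se = NA_real_, p = NA_real_, skipped = TRUE))
    data.frame(variable = v, beta_interaction = cf["grs:L", "Estimate"],
               se = cf["grs:L", "Std. Error"], p = cf["grs:L", "Pr(>|t|)"],
               skipped = FALSE)
  })
  do.call(rbind, rows)
}
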