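## The three model-selection strategies compared per lipid: exhaustive
## best subsets (BSRP), least-angle regression (LARS) and the
## bootstrapped stepwise method (BSM). Each returns the OLS refit of the
## selected support as a "lipid_fit" with the strategy recorded.

.refit <- function(response, support, data, strategy, extra = list()) {
  rhs <- if (length(support)) paste(support, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- ols_fit(fml, data)
  fit$strategy <- strategy
  fit[names(extra)] <- extra
  fit
}

#' Exhaustive best-subset regression (BSRP)
#'
#' Scores every subset of the candidate predictors up to `max_size` by
#' the requested information criterion and returns the minimizer, refit
#' by OLS. Ties break toward fewer predictors, then lexicographically.
#'
#' @param response name of the response column in `data`.
#' @param candidates character vector of candidate predictor columns
#'   (at most 20; the search is exhaustive).
#' @param data data.frame.
#' @param criterion `"aic"`, `"aicc"` or `"bic"`.
#' @param max_size largest subset size considered (default: all).
#' @return a `lipid_fit` with `strategy = "BSRP"`, plus `criterion` and
#'   the scored-subset `search` table.
#' @export
best_subset <- function(response, candidates, data,
                        criterion = c("aic", "aicc", "bic"),
                        max_size = length(candidates)) {
  criterion <- match.arg(criterion)
  if (length(candidates) > 20L)
    .fail("exhaustive search is limited to <= 20 candidates (got %d)",
          length(candidates))
  keep <- stats::complete.cases(data[c(response, candidates)])
  d <- data[keep, , drop = FALSE]
  y <- d[[response]]
  X <- as.matrix(d[candidates])
  best <- NULL
  search <- list()
  for (size in 0:min(max_size, length(candidates))) {
    sets <- if (size == 0) list(integer(0))
    else utils::combn(length(candidates), size, simplify = FALSE)
    for (idx in sets) {
      f <- .fast_ols(y, X[, idx, drop = FALSE])
      if (is.null(f)) next
      score <- f$crit[[criterion]]
      search[[length(search) + 1L]] <- data.frame(
        size = size, subset = paste(candidates[idx], collapse = "+"),
        score = score)
      if (is.null(best) || score < best$score - 1e-10) {
        best <- list(score = score, idx = idx)
      }
      ## ties: fewer predictors first (sizes are visited in increasing
      ## order, so an equal later score never replaces the incumbent);
      ## lexicographic order is the combn enumeration order
    }
  }
  .refit(response, candidates[best$idx], d, "BSRP",
         list(criterion = criterion, search = do.call(rbind, search)))
}

#' Least-angle regression selection (LARS)
#'
#' Computes the full LARS path on internally standardized predictors
#' (Efron's equiangular algorithm), picks the path model minimizing
#' Mallows' Cp (error variance from the full OLS model), and returns the
#' OLS refit of the selected support. The final path solution equals the
#' full OLS fit.
#'
#' @inheritParams best_subset
#' @return a `lipid_fit` with `strategy = "LARS"`, plus the `path`
#'   (entry order, per-step standardized coefficients) and `cp` values.
#' @export
lars_select <- function(response, candidates, data) {
  keep <- stats::complete.cases(data[c(response, candidates)])
  d <- data[keep, , drop = FALSE]
  y0 <- d[[response]]
  X0 <- as.matrix(d[candidates])
  sds <- apply(X0, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("constant predictor(s) excluded: %s",
                    paste(candidates[sds == 0], collapse = ", ")),
            call. = FALSE)
    candidates <- candidates[sds > 0]
    X0 <- X0[, sds > 0, drop = FALSE]
  }
  if (!length(candidates)) .fail("no usable candidate predictors")
  path <- .lars_path(y0, X0)
  ## Mallows' Cp per path step over the OLS refits of each active set
  n <- length(y0)
  y <- y0 - mean(y0)
  Xs <- scale(X0)
  rss_of <- function(idx) {           # pivoted, tolerant of collinearity
    sum(.lm.fit(cbind(1, Xs[, idx, drop = FALSE]), y)$residuals^2)
  }
  sigma2 <- rss_of(seq_len(ncol(Xs))) / (n - ncol(Xs) - 1L)
  steps <- seq_along(path$active_sets)
  cp <- vapply(steps, function(k) {
    idx <- path$active_sets[[k]]
    rss_of(idx) / sigma2 - n + 2 * (length(idx) + 1)
  }, numeric(1))
  pick <- which.min(cp)
  support <- candidates[path$active_sets[[pick]]]
  .refit(response, support, d, "LARS",
         list(path = path, cp = cp, cp_step = pick))
}

## Efron's LARS path on centered y / standardized X. Returns the entry
## order, the per-step gamma advances and the standardized coefficient
## matrix after each step.
.lars_path <- function(y, X) {
  n <- nrow(X); m <- ncol(X)
  Xs <- scale(X)                           # mean 0, sd 1 per column
  ys <- y - mean(y)
  beta <- numeric(m)
  mu <- numeric(n)
  active <- integer(0)
  entry_order <- integer(0)
  gammas <- numeric(0)
  betas <- list()
  active_sets <- list()
  excluded <- integer(0)                   # collinear with the active set
  eps <- 1e-10
  while (length(active) + length(excluded) < m) {
    cvec <- drop(crossprod(Xs, ys - mu))
    pool <- setdiff(seq_len(m), c(active, excluded))
    new <- pool[which.max(abs(cvec[pool]))]  # one entry per step; exact
    cmax <- abs(cvec[new])                   # ties resolve by index order
    trial <- c(active, new)
    s <- sign(cvec[trial])
    Xa <- Xs[, trial, drop = FALSE] * rep(s, each = n)
    G <- crossprod(Xa)
    Ginv1 <- tryCatch(solve(G, rep(1, length(trial))), error = function(e) NULL)
    if (is.null(Ginv1) || any(!is.finite(Ginv1))) {
      excluded <- c(excluded, new)           # linearly dependent entrant
      next
    }
    entry_order <- c(entry_order, new)
    active <- trial
    Anorm <- 1 / sqrt(sum(Ginv1))
    w <- Anorm * Ginv1
    u <- drop(Xa %*% w)
    inactive <- setdiff(seq_len(m), c(active, excluded))
    if (!length(inactive)) {
      gamma <- cmax / Anorm
    } else {
      a <- drop(crossprod(Xs, u))
      cand <- c((cmax - cvec[inactive]) / (Anorm - a[inactive]),
                (cmax + cvec[inactive]) / (Anorm + a[inactive]))
      cand <- cand[is.finite(cand) & cand > eps]
      gamma <- if (length(cand)) min(cand, cmax / Anorm) else cmax / Anorm
    }
    beta[active] <- beta[active] + gamma * w * s
    mu <- mu + gamma * u
    gammas <- c(gammas, gamma)
    betas[[length(betas) + 1L]] <- beta
    active_sets[[length(active_sets) + 1L]] <- active
  }
  list(entry_order = entry_order, gammas = gammas,
       betas = do.call(rbind, betas), active_sets = active_sets)
}

#' Bootstrapped stepwise selection (BSM)
#'
#' Runs bidirectional p-value stepwise (entry p < `p_enter`, stay p <
#' `p_stay`) on each of `B` bootstrap resamples; predictors whose
#' inclusion frequency reaches `threshold` form the final support,
#' refit by OLS on the full data. An empty support yields the
#' intercept-only model with a warning.
#'
#' @inheritParams best_subset
#' @param B number of bootstrap resamples (>= 50).
#' @param threshold inclusion-frequency cutoff (default 0.60).
#' @param p_enter,p_stay stepwise entry / stay p-values (0.05 / 0.10).
#' @param seed integer seed.
#' @return a `lipid_fit` with `strategy = "BSM"` and the
#'   `inclusion_freq` table.
#' @export
bootstrap_stepwise <- function(response, candidates, data, B = 200,
                               threshold = 0.60, p_enter = 0.05,
                               p_stay = 0.10, seed = 1L) {
  if (B < 50) .fail("B must be >= 50")
  keep <- stats::complete.cases(data[c(response, candidates)])
  d <- data[keep, , drop = FALSE]
  y <- d[[response]]
  X <- as.matrix(d[candidates])
  set.seed(seed)
  count <- stats::setNames(numeric(length(candidates)), candidates)
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(X), replace = TRUE)
    sel <- .stepwise_p(y[idx], X[idx, , drop = FALSE], p_enter, p_stay)
    count[sel] <- count[sel] + 1
  }
  freq <- count / B
  support <- candidates[freq >= threshold]
  if (!length(support))
    warning("no predictor reached the inclusion threshold; returning the intercept-only model",
            call. = FALSE)
  .refit(response, support, d, "BSM",
         list(inclusion_freq = freq, B = B, threshold = threshold,
              seed = seed))
}

## bidirectional p-based stepwise on a numeric matrix; returns the
## selected column names
.stepwise_p <- function(y, X, p_enter = 0.05, p_stay = 0.10) {
  cand <- colnames(X)
  active <- character(0)
  repeat {
    changed <- FALSE
    ## forward: best entering p
    avail <- setdiff(cand, active)
    if (length(avail)) {
      ps <- vapply(avail, function(v) {
        f <- .fast_ols(y, X[, c(active, v), drop = FALSE], se = TRUE)
        if (is.null(f)) return(NA_real_)
        f$p_value[[v]]
      }, numeric(1))
      if (any(!is.na(ps)) && min(ps, na.rm = TRUE) < p_enter) {
        active <- c(active, avail[which.min(ps)])
        changed <- TRUE
      }
    }
    ## backward: drop the worst active predictor if p >= p_stay
    if (length(active)) {
      f <- .fast_ols(y, X[, active, drop = FALSE], se = TRUE)
      if (!is.null(f)) {
        ps <- f$p_value[active]
        if (max(ps) >= p_stay) {
          active <- setdiff(active, active[which.max(ps)])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  active
}

#' Pick the winning model across strategies
#'
#' The winner maximizes the optimism-corrected adjusted R-squared; ties
#' break toward fewer predictors.
#'
#' @param reports list of `lipid_fit` objects, each carrying an
#'   `optimism` element (see [optimism_correct()]).
#' @return the winning `lipid_fit`.
#' @export
select_best_model <- function(reports) {
  if (length(reports) < 1L) .fail("no candidate reports")
  score <- vapply(reports, function(r) {
    if (is.null(r$optimism)) .fail("every report needs an attached optimism correction")
    r$optimism$corrected[["adj_r2"]]
  }, numeric(1))
  sizes <- vapply(reports, function(r) length(r$predictors), numeric(1))
  best <- which(score > max(score) - 1e-12)
  winner <- best[which.min(sizes[best])]
  reports[[winner]]
}
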