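#' Right-censored survival data
#'
#' @param time nonnegative follow-up times (days).
#' @param event binary event indicators (1 = event observed, 0 = right-censored).
#' @return list of class `SurvivalData`.
#' @export
survival_data <- function(time, event) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(time) != length(event)) stop("survival_data: length mismatch")
  if (any(time < 0)) stop("survival_data: negative time")
  if (!all(event %in% c(0L, 1L))) stop("survival_data: event must be 0/1")
  structure(list(time = time, event = event), class = "SurvivalData")
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-continuous decreasing step function starting at 1. Without censoring
#' it equals the empirical survival function.
#'
#' @param surv a [survival_data()].
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(surv) {
  stopifnot(inherits(surv, "SurvivalData"))
  if (length(surv$time) == 0) stop("km_estimate: empty data")
  if (all(surv$time == 0) && sum(surv$event) == 0) {
    stop("km_estimate: degenerate input (all times zero, no events)")
  }
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

#' Log-rank test across groups
#'
#' @param surv a [survival_data()].
#' @param groups group labels, at least two nonempty groups.
#' @return list: `chisq`, `df` (groups - 1), `p`.
#' @export
logrank_test <- function(surv, groups) {
  stopifnot(inherits(surv, "SurvivalData"))
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("logrank_test: need at least two groups")
  if (sum(surv$event) < 1) stop("logrank_test: no events")
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ groups)
  df <- nlevels(droplevels(groups)) - 1L
  list(chisq = sd$chisq, df = df, p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

# --- Firth-penalized Cox proportional hazards ------------------------------

# Breslow-ties partial likelihood machinery. Returns the unpenalized loglik,
# score U, information I, and (optionally) dI/dbeta (m x m x m) at beta.
cox_breslow_quantities <- function(X, time, event, beta, third = TRUE) {
  n <- nrow(X)
  m <- ncol(X)
  eta <- as.numeric(X %*% beta)
  # cap the linear predictor to keep exp() finite during line searches
  eta <- pmin(pmax(eta, -200), 200)
  w <- exp(eta)
  ord <- order(time, decreasing = TRUE)
  s0 <- 0
  s1 <- numeric(m)
  s2 <- matrix(0, m, m)
  s3 <- if (third) array(0, c(m, m, m)) else NULL
  loglik <- 0
  U <- numeric(m)
  I <- matrix(0, m, m)
  dI <- if (third) array(0, c(m, m, m)) else NULL
  i <- 1L
  while (i <= n) {
    t_i <- time[ord[i]]
    # add all subjects entering the risk set at this time
    j <- i
    while (j <= n && time[ord[j]] == t_i) {
      idx <- ord[j]
      xi <- X[idx, ]
      s0 <- s0 + w[idx]
      s1 <- s1 + w[idx] * xi
      s2 <- s2 + w[idx] * tcrossprod(xi)
      if (third) s3 <- s3 + w[idx] * outer(tcrossprod(xi), xi)
      j <- j + 1L
    }
    # Breslow: each event at this time contributes with the full risk set
    for (jj in i:(j - 1L)) {
      idx <- ord[jj]
      if (event[idx] == 1L) {
        xi <- X[idx, ]
        mbar <- s1 / s0
        A <- s2 / s0
        Ict <- A - tcrossprod(mbar)
        loglik <- loglik + eta[idx] - log(s0)
        U <- U + xi - mbar
        I <- I + Ict
        if (third) {
          Tt <- s3 / s0
          for (u in seq_len(m)) {
            dI[, , u] <- dI[, , u] + Tt[, , u] - A * mbar[u] -
              outer(Ict[, u], mbar) - outer(mbar, Ict[, u])
          }
        }
      }
    }
    i <- j
  }
  list(loglik = loglik, U = U, I = I, dI = dI)
}

#' Firth-penalized Cox partial log-likelihood at a given coefficient vector
#'
#' `l(b) + 0.5 log det I(b)` with Breslow ties; useful for profiling the
#' penalized surface or validating the optimizer against direct search.
#'
#' @param X covariate matrix.
#' @param surv a [survival_data()].
#' @param beta coefficient vector.
#' @return scalar (`-Inf` where the information matrix is singular).
#' @export
cox_firth_loglik <- function(X, surv, beta) {
  q <- cox_breslow_quantities(as.matrix(X), surv$time, surv$event, beta, third = FALSE)
  det_I <- det(q$I)
  if (det_I <= 0) return(-Inf)
  q$loglik + 0.5 * log(det_I)
}

#' Cox proportional hazards with Firth's penalization
#'
#' Maximizes the penalized partial likelihood `l*(b) = l(b) + 0.5 log det I(b)`
#' (Jeffreys-prior penalty) with Breslow handling of tied event times, by
#' Newton-Raphson on the modified score with step-halving. The penalty keeps
#' the estimates finite under monotone likelihood / complete separation, where
#' the unpenalized fit diverges — essential with heavily censored cohorts.
#' Standard errors come from the inverse information at the optimum; Wald
#' p-values and 95% Wald confidence intervals on the hazard ratio follow.
#'
#' @param X numeric covariate matrix (samples x covariates); no constant
#'   columns, `n > m`.
#' @param surv a [survival_data()] with at least one event.
#' @param max_iter,tol Newton-Raphson controls.
#' @return An object of class `CoxFirthFit`: `beta`, `se`, `hr`, `ci_low`,
#'   `ci_high`, `wald_p`, `loglik` (penalized, at the optimum), `m`, `n`,
#'   `iterations`, `converged`.
#' @export
cox_firth_fit <- function(X, surv, max_iter = 50, tol = 1e-8) {
  stopifnot(inherits(surv, "SurvivalData"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (sum(surv$event) < 1) stop("cox_firth_fit: no events")
  if (!all(is.finite(X))) stop("cox_firth_fit: non-finite covariates")
  if (nrow(X) <= ncol(X)) stop("cox_firth_fit: need n > number of covariates")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("cox_firth_fit: constant covariate column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }

  m <- ncol(X)
  beta <- numeric(m)
  pl <- cox_firth_loglik(X, surv, beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    q <- cox_breslow_quantities(X, surv$time, surv$event, beta, third = TRUE)
    Iinv <- solve(q$I)
    # modified score: U*_u = U_u + 0.5 tr(I^{-1} dI/dbeta_u)
    Ustar <- q$U + 0.5 * vapply(seq_len(m),
                                function(u) sum(Iinv * q$dI[, , u]),
                                numeric(1))
    step <- as.numeric(Iinv %*% Ustar)
    # step-halving on the penalized likelihood
    h <- 1
    repeat {
      cand <- beta + h * step
      pl_new <- cox_firth_loglik(X, surv, cand)
      if (pl_new >= pl - 1e-12 || h < 1e-8) break
      h <- h / 2
    }
    beta <- beta + h * step
    improved <- pl_new - pl
    pl <- pl_new
    if (max(abs(Ustar)) < tol || (h == 1 && abs(improved) < tol)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("cox_firth_fit: Newton-Raphson did not converge; returning last iterate")
  }
  q <- cox_breslow_quantities(X, surv$time, surv$event, beta, third = FALSE)
  se <- sqrt(diag(solve(q$I)))
  hr <- exp(beta)
  z <- beta / se
  structure(list(beta = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 hr = hr, ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 wald_p = 2 * stats::pnorm(-abs(z)),
                 loglik = pl, m = m, n = nrow(X),
                 iterations = iter, converged = converged),
            class = "CoxFirthFit")
}

#' @export
print.CoxFirthFit <- function(x, ...) {
  cat(sprintf("Firth-penalized Cox fit: n = %d, penalized loglik = %.4f\n",
              x$n, x$loglik))
  print(data.frame(beta = round(x$beta, 4), hr = round(x$hr, 4),
                   ci_low = round(x$ci_low, 4), ci_high = round(x$ci_high, 4),
                   wald_p = signif(x$wald_p, 3)))
  invisible(x)
}

#' Bayesian information criterion
#'
#' `BIC = -2 loglik + m log(n)`; lower favors the model.
#'
#' @param loglik log-likelihood at the optimum.
#' @param m number of parameters.
#' @param n number of samples.
#' @export
bic_of_fit <- function(loglik, m, n) {
  stopifnot(n >= 1, m >= 0)
  -2 * loglik + m * log(n)
}

# --- AFT with iterative censoring imputation --------------------------------

#' Accelerated failure time fit with iterative imputation of censored times
#'
#' Log-times are regressed on the covariates by least squares; censored rows
#' are initialized at their log censoring times and then repeatedly replaced
#' by the conditional mean of a normal at the fitted value truncated below at
#' the censoring time, `mu_i + sigma * phi(z_i) / (1 - Phi(z_i))` with
#' `z_i = (log c_i - mu_i) / sigma`, until the imputed values stabilize.
#' Every imputed time is at least its censoring time by construction.
#'
#' @param X covariate matrix (samples x covariates).
#' @param surv a [survival_data()] with strictly positive times and at least
#'   two events.
#' @param max_iter,tol imputation loop controls (max absolute change in
#'   imputed log-times).
#' @return An object of class `AFTFit`: `intercept`, `coef`, `sigma`,
#'   `imputed_log_times` (full vector on the log scale), `iterations`.
#' @export
aft_fit_imputed <- function(X, surv, max_iter = 50, tol = 1e-6) {
  stopifnot(inherits(surv, "SurvivalData"))
  X <- as.matrix(X)
  if (any(surv$time <= 0)) stop("aft_fit_imputed: times must be positive")
  if (sum(surv$event) < 2) stop("aft_fit_imputed: need at least two events")
  n <- nrow(X)
  cens <- surv$event == 0L
  y <- log(surv$time)
  Xd <- cbind(`(Intercept)` = 1, X)
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    fit <- stats::lm.fit(Xd, y)
    mu <- as.numeric(Xd %*% fit$coefficients)
    dfres <- n - fit$rank
    sigma <- sqrt(sum(fit$residuals^2) / max(dfres, 1))
    if (!is.finite(sigma) || sigma < 1e-10) {
      stop("aft_fit_imputed: residual scale collapsed to zero")
    }
    if (!any(cens)) break
    z <- (log(surv$time[cens]) - mu[cens]) / sigma
    y_new <- mu[cens] + sigma * truncnorm_mills(z)
    delta <- max(abs(y_new - y[cens]))
    y[cens] <- y_new
    if (delta < tol) break
  }
  cf <- fit$coefficients
  structure(list(intercept = cf[1L], coef = cf[-1L], sigma = sigma,
                 imputed_log_times = y, iterations = iter),
            class = "AFTFit")
}

# E[Z | Z > z] for standard normal Z: the inverse Mills ratio, numerically
# stable in the deep upper tail via the asymptotic expansion.
truncnorm_mills <- function(z) {
  out <- numeric(length(z))
  hi <- z > 8
  out[hi] <- z[hi] + 1 / z[hi]  # phi/Phi_bar ~ z + 1/z for large z
  lo <- !hi
  out[lo] <- exp(stats::dnorm(z[lo], log = TRUE) -
                 stats::pnorm(z[lo], lower.tail = FALSE, log.p = TRUE))
  out
}

#' Predict log survival times from an AFT fit
#' @param object an [aft_fit_imputed()] result.
#' @param newdata covariate matrix.
#' @param ... unused.
#' @export
predict.AFTFit <- function(object, newdata, ...) {
  as.numeric(cbind(1, as.matrix(newdata)) %*% c(object$intercept, object$coef))
}

#' Censoring-adjusted root mean squared error
#'
#' On the log scale: event rows contribute `(log T - log That)^2`; censored
#' rows contribute `max(0, log c - log That)^2`, penalizing only predictions
#' below the known survival lower bound.
#'
#' @param predicted_time positive predicted survival times.
#' @param surv a [survival_data()].
#' @return nonnegative scalar.
#' @export
censored_rmse <- function(predicted_time, surv) {
  stopifnot(inherits(surv, "SurvivalData"))
  if (any(predicted_time <= 0)) stop("censored_rmse: nonpositive prediction")
  lp <- log(predicted_time)
  lt <- log(surv$time)
  contrib <- ifelse(surv$event == 1L, (lt - lp)^2, pmax(0, lt - lp)^2)
  sqrt(mean(contrib))
}

#' Harrell's concordance index
#'
#' A pair is comparable when the shorter observed time belongs to an event
#' (pairs with exactly tied times are not orderable and are skipped); it is
#' concordant when the shorter-lived member has the higher risk score, and
#' tied risk scores count 0.5.
#'
#' @param risk per-sample risk scores (higher = worse prognosis).
#' @param surv a [survival_data()].
#' @return scalar in `[0, 1]`.
#' @export
harrell_c <- function(risk, surv) {
  stopifnot(inherits(surv, "SurvivalData"))
  t <- surv$time; e <- surv$event
  n <- length(t)
  conc <- 0; comp <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (t[i] == t[j]) next
      shorter <- if (t[i] < t[j]) i else j
      longer <- if (t[i] < t[j]) j else i
      if (e[shorter] != 1L) next
      comp <- comp + 1
      if (risk[shorter] > risk[longer]) conc <- conc + 1
      else if (risk[shorter] == risk[longer]) conc <- conc + 0.5
    }
  }
  if (comp == 0) stop("harrell_c: no comparable pairs")
  conc / comp
}

#' Cross-validated AFT evaluation
#'
#' 10-fold cross-validation repeated 10 times (the defaults): folds are
#' stratified by the event indicator so that no training fold is event-free
#' under heavy censoring. Per fold, an AFT model with iterative censoring
#' imputation is fitted on the training part, test-set survival times are
#' predicted, and censoring-adjusted rmse plus Harrell's c (risk = negative
#' predicted log-time) are accumulated; means over folds x repeats are
#' returned.
#'
#' @param X covariate matrix.
#' @param surv a [survival_data()].
#' @param folds,repeats cross-validation layout.
#' @param seed integer seed for the fold shuffles.
#' @return list: `rmse`, `c_index` (means), `per_fold` data.frame.
#' @export
cv_evaluate <- function(X, surv, folds = 10, repeats = 10, seed = 1L) {
  stopifnot(inherits(surv, "SurvivalData"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < folds) stop("cv_evaluate: fewer samples than folds")
  rng <- make_rng(seed)
  rmse_all <- c_all <- numeric(0)
  for (rep in seq_len(repeats)) {
    assignment <- stratified_folds(surv$event, folds, rng)
    for (f in seq_len(folds)) {
      test <- which(assignment == f)
      train <- setdiff(seq_len(n), test)
      if (sum(surv$event[train]) < 2) next  # stratification makes this rare
      fit <- aft_fit_imputed(X[train, , drop = FALSE],
                             survival_data(surv$time[train], surv$event[train]))
      pred_log <- predict(fit, X[test, , drop = FALSE])
      test_surv <- survival_data(surv$time[test], surv$event[test])
      rmse_all <- c(rmse_all, censored_rmse(exp(pred_log), test_surv))
      cval <- tryCatch(harrell_c(-pred_log, test_surv), error = function(e) NA_real_)
      c_all <- c(c_all, cval)
    }
  }
  list(rmse = mean(rmse_all), c_index = mean(c_all, na.rm = TRUE),
       per_fold = data.frame(rmse = rmse_all, c_index = c_all))
}

# event-stratified fold assignment; resamples (up to 10 tries) if a fold
# catches no events at all
stratified_folds <- function(event, folds, rng) {
  n <- length(event)
  for (attempt in 1:10) {
    assignment <- integer(n)
    for (g in unique(event)) {
      ix <- which(event == g)
      perm <- with_rng(rng, sample(ix))
      assignment[perm] <- rep_len(seq_len(folds), length(ix))
    }
    ev_per_fold <- tapply(event, assignment, sum)
    if (sum(event) < folds || all(ev_per_fold > 0)) return(assignment)
    message("cv_evaluate: resampling a fold layout with an event-free fold")
  }
  stop("cv_evaluate: could not build folds with events in every fold")
}

#' Compare candidate stratifications by survival model fit
#'
#' For each candidate cluster assignment, fits a Firth-penalized Cox model with
#' covariates {cluster indicators (reference coding), age, stage}, reports the
#' hazard ratio / CI / Wald p of the cluster covariate (for k > 2, the
#' indicator with the smallest Wald p), the BIC from the penalized
#' log-likelihood, and cross-validated AFT metrics. A baseline row using the
#' literature high-risk / low-risk labels is appended. Samples with missing
#' age or stage are dropped with a message; constant assignments are skipped
#' with a warning.
#'
#' @param candidates named list of cluster assignments (vectors over samples).
#' @param clinical a [clinical_table()] supplying `age`, `stage`, `high_risk`.
#' @param surv a [survival_data()] aligned with `clinical`.
#' @param folds,repeats,seed passed to [cv_evaluate()].
#' @return data.frame of class `StratificationEval` with one row per model:
#'   `model`, `k`, `hr`, `ci_low`, `ci_high`, `wald_p`, `bic`, `rmse`,
#'   `c_index`.
#' @export
compare_stratifications <- function(candidates, clinical, surv,
                                    folds = 10, repeats = 10, seed = 1L) {
  stopifnot(inherits(clinical, "ClinicalTable"), inherits(surv, "SurvivalData"))
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("model", seq_along(candidates))
  }
  keep <- !is.na(clinical$age) & !is.na(clinical$stage)
  if (any(!keep)) {
    message(sprintf("compare_stratifications: dropping %d sample(s) with missing age/stage",
                    sum(!keep)))
  }
  age <- clinical$age[keep]
  stage <- as.numeric(clinical$stage[keep])
  surv_k <- survival_data(surv$time[keep], surv$event[keep])
  candidates <- c(candidates,
                  list(`High Risk / Low Risk` = clinical$high_risk))
  rows <- list()
  for (nm in names(candidates)) {
    assignment <- candidates[[nm]][keep]
    if (length(unique(assignment)) < 2) {
      warning(sprintf("compare_stratifications: '%s' is constant; skipped", nm))
      next
    }
    f <- factor(assignment)
    ind <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
    colnames(ind) <- paste0("cluster", levels(f)[-1L])
    Xc <- cbind(ind, age = age, stage = stage)
    fit <- cox_firth_fit(Xc, surv_k)
    ci <- seq_len(ncol(ind))
    best <- ci[which.min(fit$wald_p[ci])]
    cv <- cv_evaluate(Xc, surv_k, folds = folds, repeats = repeats, seed = seed)
    rows[[nm]] <- data.frame(
      model = nm, k = nlevels(f),
      hr = fit$hr[best], ci_low = fit$ci_low[best], ci_high = fit$ci_high[best],
      wald_p = fit$wald_p[best],
      bic = bic_of_fit(fit$loglik, fit$m, fit$n),
      rmse = cv$rmse, c_index = cv$c_index,
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("StratificationEval", "data.frame")
  out
}

#' Write a stratification comparison table to CSV
#' @param eval a [compare_stratifications()] result.
#' @param path output CSV path.
#' @export
write_stratification_eval <- function(eval, path) {
  utils::write.csv(as.data.frame(eval), path, row.names = FALSE)
  invisible(path)
}
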