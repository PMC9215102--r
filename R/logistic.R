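# Logistic-regression machinery: a full glm-backed fit for reporting and a
# fast closed-form / glm.fit path used inside the cutoff search.

# Closed-form logistic fit of y on a binary predictor S: the MLE of the
# slope is the log odds ratio of the 2x2 table and the Wald s.e. is
# sqrt(sum of reciprocal cell counts). With an empty cell the MLE diverges
# (separation); the likelihood-ratio (G-test) p-value is returned instead.
fast_logit_binary <- function(S, y) {
  a <- sum(S == 1 & y == 1); b <- sum(S == 1 & y == 0)
  c_ <- sum(S == 0 & y == 1); d <- sum(S == 0 & y == 0)
  if ((a + b) == 0 || (c_ + d) == 0)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                method = "degenerate"))
  if (a == 0 || b == 0 || c_ == 0 || d == 0) {
    obs <- c(a, b, c_, d)
    n <- sum(obs)
    exp_ <- c((a + b) * (a + c_), (a + b) * (b + d),
              (c_ + d) * (a + c_), (c_ + d) * (b + d)) / n
    g <- 2 * sum(ifelse(obs > 0, obs * log(obs / exp_), 0))
    return(list(beta = log((a * d) / (b * c_)),  # +/- Inf
                se = Inf, p = pchisq(g, 1, lower.tail = FALSE),
                method = "lrt"))
  }
  beta <- log((a * d) / (b * c_))
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)), method = "wald")
}

# glm.fit-based logistic fit of y on S (+ optional covariates); Wald p for
# the S coefficient, with a likelihood-ratio fallback when the fit separates.
fast_logit <- function(S, y, covariates = NULL) {
  X <- if (is.null(covariates)) cbind(1, S) else cbind(1, S, covariates)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = binomial()))
  beta <- fit$coefficients[2]
  R <- fit$qr$qr[seq_len(ncol(X)), , drop = FALSE]
  cov_unscaled <- tryCatch(chol2inv(R), error = function(e) NULL)
  se <- if (is.null(cov_unscaled)) NA_real_ else sqrt(cov_unscaled[2, 2])
  separated <- !fit$converged || is.na(se) || !is.finite(se) ||
    (is.finite(beta) && abs(beta) > 15) || (is.finite(se) && se > 100)
  if (separated) {
    X0 <- X[, -2, drop = FALSE]
    fit0 <- suppressWarnings(stats::glm.fit(X0, y, family = binomial()))
    g <- fit0$deviance - fit$deviance
    return(list(beta = beta, se = se,
                p = pchisq(max(g, 0), 1, lower.tail = FALSE), method = "lrt"))
  }
  list(beta = unname(beta), se = unname(se),
       p = 2 * pnorm(-abs(beta / se)), method = "wald")
}

#' Logistic association fit of a super-taxon feature
#'
#' Maximum-likelihood logistic regression of disease status on an intercept
#' and a super-taxon feature (plus optional covariates), reporting the Wald
#' p-value, the odds ratio with its 95% Wald interval, and the AIC. When the
#' fit separates (diverging coefficient), the likelihood-ratio p-value is
#' reported and the result is flagged.
#'
#' @param S Numeric per-sample feature (binary for STB, non-negative for
#'   STC).
#' @param labels 0/1 disease status.
#' @param covariates Optional numeric matrix of per-sample covariates.
#' @return An object of class `st_fit` with fields `beta`, `se`,
#'   `odds_ratio`, `ci95`, `pvalue`, `aic`, `n`, `method`
#'   (`"wald"`/`"lrt"`), `converged`. Use [tidy()]/[glance()] for tibbles.
#' @export
fit_logistic <- function(S, labels, covariates = NULL) {
  labels <- check_binary_labels(labels)
  if (length(S) != length(labels))
    stop("feature and labels differ in length", call. = FALSE)
  if (length(unique(S)) < 2L)
    stop("constant super-taxon feature cannot be tested", call. = FALSE)
  df <- data.frame(y = labels, S = S)
  form <- y ~ S
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    df <- cbind(df, as.data.frame(covariates))
    form <- stats::as.formula(paste("y ~ S +",
                                    paste(colnames(as.data.frame(covariates)),
                                          collapse = " + ")))
  }
  fit <- suppressWarnings(glm(form, data = df, family = binomial()))
  beta <- unname(coef(fit)["S"])
  se <- unname(sqrt(diag(stats::vcov(fit))["S"]))
  separated <- !fit$converged || !is.finite(se) || abs(beta) > 15 || se > 100
  if (separated) {
    fit0 <- suppressWarnings(glm(stats::update(form, . ~ . - S), data = df,
                                 family = binomial()))
    p <- pchisq(max(fit0$deviance - fit$deviance, 0), 1, lower.tail = FALSE)
    method <- "lrt"
  } else {
    p <- 2 * pnorm(-abs(beta / se))
    method <- "wald"
  }
  structure(list(beta = beta, se = se, odds_ratio = exp(beta),
                 ci95 = c(low = exp(beta - 1.96 * se),
                          high = exp(beta + 1.96 * se)),
                 pvalue = p, aic = stats::AIC(fit), n = length(labels),
                 method = method, converged = !separated, fit = fit),
            class = "st_fit")
}

#' @export
print.st_fit <- function(x, ...) {
  cat(sprintf("Logistic super-taxon fit (n = %d)\n", x$n))
  cat(sprintf("  OR %.4f (95%% CI %.4f, %.4f), p = %.3g [%s], AIC = %.2f\n",
              x$odds_ratio, x$ci95[["low"]], x$ci95[["high"]], x$pvalue,
              x$method, x$aic))
  invisible(x)
}

#' @rdname fit_logistic
#' @param x An `st_fit` object.
#' @param ... Unused.
#' @export
tidy.st_fit <- function(x, ...) {
  tibble::tibble(term = "S", estimate = x$beta, std.error = x$se,
                 statistic = x$beta / x$se, p.value = x$pvalue,
                 odds.ratio = x$odds_ratio, conf.low = x$ci95[["low"]],
                 conf.high = x$ci95[["high"]])
}

#' @rdname fit_logistic
#' @export
glance.st_fit <- function(x, ...) {
  tibble::tibble(aic = x$aic, n = x$n, method = x$method,
                 converged = x$converged)
}
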