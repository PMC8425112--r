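## GLM machinery for pattern fits. Fits go through stats::glm.fit / lm.fit
## on prebuilt design matrices (much faster than the formula interface when
## scanning 27 patterns per pair); BIC, the joint interaction test and Wald
## CIs are computed from the returned log-likelihoods and covariances.

#' Fit a logistic or linear regression on an explicit design matrix
#'
#' Maximum-likelihood fit with the intercept already inside \code{design}.
#' For the linear family the Gaussian log-likelihood at the variance MLE is
#' returned so BIC is well defined. Non-convergence and quasi-separation
#' (|coefficient| > 15 or SE > 100 on the logit scale) are reported through
#' \code{converged = FALSE}, never as an exception; rank-deficient designs
#' are flagged non-estimable.
#'
#' @param design numeric matrix including an intercept column.
#' @param outcome response vector: 0/1 for \code{"logistic"}, real for
#'   \code{"linear"}. No missing values (apply complete cases upstream).
#' @param family \code{"logistic"} or \code{"linear"}.
#' @return An object of class \code{"snpxe_fit"}: coefficients, standard
#'   errors, covariance matrix, log-likelihood, \code{n_used},
#'   \code{n_params}, \code{converged}, \code{estimable}, fitted values and,
#'   for the linear family, the residual sum of squares.
#' @export
fit_glm <- function(design, outcome, family = c("logistic", "linear")) {
  family <- match.arg(family)
  X <- as.matrix(design)
  y <- as.numeric(outcome)
  if (anyNA(X) || anyNA(y))
    stop("missing values in design or outcome; apply complete cases first",
         call. = FALSE)
  if (family == "logistic" && !all(y %in% c(0, 1)))
    stop("logistic family requires a 0/1 outcome", call. = FALSE)
  n <- length(y)
  p <- ncol(X)
  res <- list(coefficients = stats::setNames(rep(NA_real_, p), colnames(X)),
              se = stats::setNames(rep(NA_real_, p), colnames(X)),
              vcov = matrix(NA_real_, p, p, dimnames = list(colnames(X),
                                                            colnames(X))),
              log_likelihood = NA_real_, n_used = n, n_params = p,
              converged = FALSE, estimable = FALSE, family = family,
              fitted = rep(NA_real_, n), rss = NA_real_)
  class(res) <- "snpxe_fit"
  if (n <= p) return(res)

  if (family == "logistic") {
    z <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                      control = list(epsilon = 1e-8,
                                                     maxit = 100L))),
      error = function(e) NULL)
    if (is.null(z)) return(res)
    full_rank <- z$rank == p
    res$coefficients[] <- z$coefficients
    if (full_rank) {
      R <- z$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
      R[lower.tri(R)] <- 0
      V <- tryCatch(chol2inv(R), error = function(e) NULL)
      if (!is.null(V)) {
        piv <- z$qr$pivot
        V <- V[order(piv), order(piv), drop = FALSE]
        dimnames(V) <- dimnames(res$vcov)
        res$vcov <- V
        res$se[] <- sqrt(diag(V))
      }
    }
    res$log_likelihood <- (2 * z$rank - z$aic) / 2
    res$fitted <- z$fitted.values
    separated <- any(abs(z$coefficients) > 15, na.rm = TRUE) ||
      any(res$se > 100, na.rm = TRUE)
    res$converged <- isTRUE(z$converged) && !separated
    res$estimable <- res$converged && full_rank && !anyNA(res$se)
  } else {
    z <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
    if (is.null(z)) return(res)
    full_rank <- z$rank == p
    res$coefficients[] <- z$coefficients
    rss <- sum(z$residuals^2)
    res$rss <- rss
    res$fitted <- z$fitted.values
    ## Gaussian log-likelihood at the variance MLE sigma2 = RSS/n
    res$log_likelihood <- -n / 2 * (log(2 * pi * rss / n) + 1)
    if (full_rank && n > p) {
      R <- z$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
      R[lower.tri(R)] <- 0
      V <- tryCatch(chol2inv(R) * rss / (n - p), error = function(e) NULL)
      if (!is.null(V)) {
        piv <- z$qr$pivot
        V <- V[order(piv), order(piv), drop = FALSE]
        dimnames(V) <- dimnames(res$vcov)
        res$vcov <- V
        res$se[] <- sqrt(diag(V))
      }
    }
    res$converged <- TRUE
    res$estimable <- full_rank && !anyNA(res$se)
  }
  res
}

#' @export
print.snpxe_fit <- function(x, ...) {
  cat(sprintf("%s regression fit: n = %d, %d parameters, logLik = %.4f\n",
              x$family, x$n_used, x$n_params, x$log_likelihood))
  print(cbind(Estimate = x$coefficients, `Std. Error` = x$se))
  if (!x$converged) cat("  [did not converge / separation detected]\n")
  invisible(x)
}

#' Bayesian information criterion of a fit
#'
#' \code{-2 logLik + k log(n)} where \code{k} counts every regression
#' coefficient plus, for the linear family, the error-variance parameter.
#' Missing for non-converged fits.
#'
#' @param fit an \code{snpxe_fit}.
#' @return BIC value (smaller is preferred), or \code{NA}.
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "snpxe_fit"))
  if (!isTRUE(fit$converged) || is.na(fit$log_likelihood)) return(NA_real_)
  k <- fit$n_params + (fit$family == "linear")
  -2 * fit$log_likelihood + k * log(fit$n_used)
}

#' Joint test of the interaction coefficients
#'
#' Compares the full pattern model against the nested reduction with all
#' interaction columns removed (the structure's main effects and covariates
#' are retained). Default is the likelihood-ratio test with a chi-square
#' reference on df = number of interaction columns; the linear family uses
#' the exact partial F-test. \code{method = "wald"} instead forms the joint
#' Wald chi-square on the interaction coefficients of the full fit.
#'
#' @param fit_full,fit_reduced nested \code{snpxe_fit} objects (the reduced
#'   one with the interaction columns removed).
#' @param method \code{"lrt"} or \code{"wald"}.
#' @param wald_terms for \code{method = "wald"}: names or indices of the
#'   interaction columns in the full design.
#' @return A list with \code{statistic}, \code{df} and \code{p}.
#' @export
interaction_test <- function(fit_full, fit_reduced,
                             method = c("lrt", "wald"), wald_terms = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(fit_full, "snpxe_fit"), inherits(fit_reduced, "snpxe_fit"))
  df <- fit_full$n_params - fit_reduced$n_params
  if (df < 0)
    stop("models are not nested: reduced model has more parameters",
         call. = FALSE)
  if (df == 0L)
    return(list(statistic = 0, df = 0L, p = 1))
  if (!isTRUE(fit_full$converged) || !isTRUE(fit_reduced$converged))
    return(list(statistic = NA_real_, df = df, p = NA_real_))
  if (method == "wald") {
    if (is.null(wald_terms))
      stop("wald_terms must identify the interaction columns", call. = FALSE)
    b <- fit_full$coefficients[wald_terms]
    V <- fit_full$vcov[wald_terms, wald_terms, drop = FALSE]
    stat <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
    return(list(statistic = stat, df = df,
                p = stats::pchisq(stat, df, lower.tail = FALSE)))
  }
  if (fit_full$family == "linear") {
    ## exact partial F-test on residual sums of squares
    n <- fit_full$n_used
    df2 <- n - fit_full$n_params
    Fstat <- max(0, (fit_reduced$rss - fit_full$rss) / df) / (fit_full$rss / df2)
    return(list(statistic = Fstat, df = df,
                p = stats::pf(Fstat, df, df2, lower.tail = FALSE)))
  }
  stat <- max(0, 2 * (fit_full$log_likelihood - fit_reduced$log_likelihood))
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

## internal: complete-case row filter across the analysis columns
.complete_rows <- function(data, cols, covariates = NULL) {
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  keep
}

#' Fit one interaction pattern on subject-level data
#'
#' Builds the coded design for \code{spec}, fits it, tests the interaction
#' columns jointly against the matching reduced model, and computes BIC and
#' per-term Wald confidence intervals (exponentiated to odds ratios under
#' the logistic family).
#'
#' @param data data frame with the genotype (minor-allele counts 0/1/2),
#'   environment and outcome columns.
#' @param spec a \code{pattern_spec} (or canonical label string).
#' @param snp,env,outcome column names in \code{data}.
#' @param env_type \code{"ordinal"} or \code{"categorical"}.
#' @param family \code{"logistic"} or \code{"linear"}.
#' @param covariates optional character vector of covariate column names.
#' @param ci_level confidence level for the per-term Wald intervals.
#' @param test \code{"lrt"} (default) or \code{"wald"} for the overall
#'   interaction p-value.
#' @param env_reference reference level for a categorical environment.
#' @return An object of class \code{"pattern_fit"}: the \code{spec}, the
#'   full \code{fit}, \code{p_interaction}, \code{bic}, an \code{estimable}
#'   flag and a per-term effect table.
#' @export
fit_pattern <- function(data, spec, snp, env, outcome,
                        env_type = c("ordinal", "categorical"),
                        family = c("logistic", "linear"),
                        covariates = NULL, ci_level = 0.95,
                        test = c("lrt", "wald"), env_reference = NULL) {
  env_type <- match.arg(env_type)
  family <- match.arg(family)
  test <- match.arg(test)
  if (is.character(spec)) spec <- parse_label(spec)
  stopifnot(inherits(spec, "pattern_spec"))
  cols <- c(outcome, snp, env, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  keep <- .complete_rows(data, cols)
  d <- data[keep, , drop = FALSE]
  n_used <- nrow(d)

  out <- structure(
    list(spec = spec, fit = NULL, fit_reduced = NULL,
         p_interaction = NA_real_, bic = NA_real_, per_term = NULL,
         estimable = FALSE, n_used = n_used, family = family,
         test = test, env_coding = NULL),
    class = "pattern_fit")

  cv <- if (is.null(covariates)) NULL else
    as.matrix(d[, covariates, drop = FALSE])
  ## a monomorphic SNP has no interaction to estimate under any coding
  ## (reversed binary codings would degenerate to the env dummies)
  if (length(unique(d[[snp]])) <= 1L) return(out)
  s <- code_snp(d[[snp]], spec$mode, spec$snp_dir)
  ec <- tryCatch(code_env(d[[env]], spec$env_dir, env_type, env_reference),
                 error = function(e) NULL)
  if (is.null(ec) || n_used == 0L) return(out)
  out$env_coding <- list(reference = ec$reference, levels = ec$levels)
  des <- build_design(s, ec$dummies, spec$structure, cv)
  if (!des$estimable) return(out)

  y <- d[[outcome]]
  full <- fit_glm(des$design, y, family)
  out$fit <- full
  if (!full$estimable) return(out)

  red_cols <- setdiff(colnames(des$design), des$interaction_cols)
  reduced <- fit_glm(des$design[, red_cols, drop = FALSE], y, family)
  out$fit_reduced <- reduced
  if (!reduced$estimable) return(out)

  it <- interaction_test(full, reduced, method = test,
                         wald_terms = des$interaction_cols)
  out$p_interaction <- it$p
  out$interaction_statistic <- it$statistic
  out$interaction_df <- it$df
  out$bic <- bic(full)
  out$estimable <- TRUE
  out$residuals_response <- y - full$fitted

  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  terms <- setdiff(colnames(des$design), "(Intercept)")
  est <- full$coefficients[terms]
  se <- full$se[terms]
  tab <- data.frame(term = terms, estimate = est, se = se,
                    ci_low = est - zq * se, ci_high = est + zq * se,
                    p_wald = 2 * stats::pnorm(-abs(est / se)),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (family == "logistic") {
    tab$OR <- exp(tab$estimate)
    tab$OR_low <- exp(tab$ci_low)
    tab$OR_high <- exp(tab$ci_high)
  }
  tab$interaction <- terms %in% des$interaction_cols
  out$per_term <- tab
  out
}

#' @export
print.pattern_fit <- function(x, digits = 4, ...) {
  cat("Pattern", x$spec$label,
      sprintf("(%s family, n = %d)\n", x$family, x$n_used))
  if (!x$estimable) {
    cat("  not estimable (degenerate design, separation or non-convergence)\n")
    return(invisible(x))
  }
  cat(sprintf("  interaction p-value (%s) = %s   BIC = %.*f\n",
              toupper(x$test), format_pvalue(x$p_interaction),
              digits, x$bic))
  tab <- x$per_term
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
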