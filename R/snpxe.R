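#' Pattern search for one SNP-environment pair
#'
#' The workhorse of the package: enumerates the designed interaction
#' pattern family (27 patterns for an ordinal environmental factor, 18 for
#' a categorical one), fits every pattern by logistic or linear regression,
#' and selects the best pattern by the smallest BIC (default) or the
#' smallest overall interaction p-value. BIC is the default because a
#' parsimonious pattern generalises better.
#'
#' The selected pattern's interaction p-value is reported unadjusted for
#' the within-pair search over patterns; multiplicity correction applies
#' across pairs (see \code{\link{snpxe_batch}}). Under the null the minimum
#' p-value over the family is stochastically smaller than uniform.
#'
#' Ties in the selection statistic (within 1e-9) are broken by the other
#' statistic, then by enumeration order, so reruns are bit-identical.
#'
#' @param data data frame of subjects.
#' @param snp name of the genotype column (minor-allele counts 0/1/2; use
#'   \code{\link{maf_info}} + \code{\link{recode_minor_count}} for
#'   allele-pair strings).
#' @param env name of the environmental factor column.
#' @param outcome name of the phenotype column (0/1 for logistic).
#' @param env_type \code{"ordinal"} or \code{"categorical"}.
#' @param family \code{"logistic"} or \code{"linear"}.
#' @param covariates optional character vector of covariate columns,
#'   adjusted for in every pattern and its reduced model.
#' @param selection \code{"bic"} or \code{"pvalue"}.
#' @param test overall interaction test: \code{"lrt"} or \code{"wald"}.
#' @param ci_level confidence level for per-term intervals.
#' @param env_reference reference level for a categorical environment.
#' @return An object of class \code{"snpxe_pair"}: \code{all_fits} (one
#'   \code{pattern_fit} per enumerated pattern, non-estimable ones kept
#'   with missing statistics), \code{best}, \code{selection_rule},
#'   \code{n_used}, and \code{failed}/\code{failure_reason} when fewer than
#'   two patterns are estimable.
#' @examples
#' set.seed(1)
#' d <- data.frame(outcome = rbinom(300, 1, 0.3),
#'                 snp = simulate_genotypes(300, 0.3),
#'                 env = sample(1:3, 300, replace = TRUE))
#' fit <- snpxe_pair(d, "snp", "env", "outcome")
#' fit$best$spec$label
#' @export
snpxe_pair <- function(data, snp, env, outcome,
                       env_type = c("ordinal", "categorical"),
                       family = c("logistic", "linear"),
                       covariates = NULL,
                       selection = c("bic", "pvalue"),
                       test = c("lrt", "wald"),
                       ci_level = 0.95, env_reference = NULL) {
  env_type <- match.arg(env_type)
  family <- match.arg(family)
  selection <- match.arg(selection)
  test <- match.arg(test)
  fam <- enumerate_patterns(env_type)
  fits <- lapply(fam, function(sp)
    fit_pattern(data, sp, snp, env, outcome, env_type, family,
                covariates, ci_level, test, env_reference))
  obj <- structure(
    list(snp_name = snp, env_name = env, outcome_name = outcome,
         env_type = env_type, family = family, covariates = covariates,
         all_fits = fits, best = NULL, selection_rule = selection,
         test = test, n_used = max(vapply(fits, `[[`, 0L, "n_used")),
         failed = FALSE, failure_reason = NA_character_),
    class = "snpxe_pair")

  est <- which(vapply(fits, `[[`, FALSE, "estimable"))
  if (length(est) < 2L) {
    obj$failed <- TRUE
    obj$failure_reason <- sprintf(
      "only %d of %d patterns estimable (monomorphic SNP, degenerate environment or separation)",
      length(est), length(fits))
    return(obj)
  }
  bics <- vapply(fits[est], `[[`, 0, "bic")
  ps <- vapply(fits[est], `[[`, 0, "p_interaction")
  if (selection == "bic") {
    key1 <- bics; key2 <- ps
  } else {
    key1 <- ps; key2 <- bics
  }
  cand <- which(key1 <= min(key1) + 1e-9)
  if (length(cand) > 1L) {
    k2 <- key2[cand]
    cand <- cand[k2 <= min(k2) + 1e-9]
  }
  obj$best <- fits[[est[cand[1L]]]]
  ## keep fitted values only on the selected pattern to stay light
  obj$all_fits <- lapply(fits, function(f) {
    if (!is.null(f$fit)) f$fit$fitted <- NULL
    f$fit_reduced <- NULL
    f$residuals_response <- NULL
    f
  })
  obj$all_fits[[obj$best$spec$label]] <- obj$best
  obj
}

## summary table used by summary() and the long-format writer
.pair_table <- function(object) {
  fits <- object$all_fits
  data.frame(
    pattern = vapply(fits, function(f) f$spec$label, ""),
    structure = vapply(fits, function(f) f$spec$structure, ""),
    mode = vapply(fits, function(f) f$spec$mode, ""),
    estimable = vapply(fits, `[[`, FALSE, "estimable"),
    bic = vapply(fits, `[[`, 0, "bic"),
    p_interaction = vapply(fits, `[[`, 0, "p_interaction"),
    n_used = vapply(fits, `[[`, 0L, "n_used"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.snpxe_pair <- function(x, ...) {
  cat(sprintf("SNPxE pattern search: %s x %s -> %s (%s family, %s env, n = %d)\n",
              x$snp_name, x$env_name, x$outcome_name, x$family,
              x$env_type, x$n_used))
  if (x$failed) {
    cat("  FAILED:", x$failure_reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  %d patterns evaluated; best by %s: %s\n",
              length(x$all_fits),
              if (x$selection_rule == "bic") "smallest BIC" else
                "smallest interaction p-value",
              x$best$spec$label))
  cat(sprintf("  best-pattern interaction p = %s, BIC = %.2f\n",
              format_pvalue(x$best$p_interaction), x$best$bic))
  invisible(x)
}

#' @export
summary.snpxe_pair <- function(object, ...) {
  out <- list(pair = object, table = .pair_table(object))
  class(out) <- "summary.snpxe_pair"
  out
}

#' @export
print.summary.snpxe_pair <- function(x, digits = 4, ...) {
  print(x$pair)
  tab <- x$table
  tab$bic <- round(tab$bic, 2)
  tab$p_interaction <- format_pvalue(tab$p_interaction)
  print(tab, row.names = FALSE)
  if (!x$pair$failed) {
    cat("\nSelected pattern detail:\n")
    print(x$pair$best, digits = digits)
  }
  invisible(x)
}

#' @export
coef.snpxe_pair <- function(object, ...) {
  if (object$failed) return(NULL)
  object$best$fit$coefficients
}

#' @export
logLik.snpxe_pair <- function(object, ...) {
  if (object$failed) return(NA_real_)
  f <- object$best$fit
  structure(f$log_likelihood, df = f$n_params, nobs = f$n_used,
            class = "logLik")
}

#' Predict from the selected pattern
#'
#' Rebuilds the selected pattern's coded design on \code{newdata} and
#' returns the linear predictor or, for the logistic family, fitted
#' outcome probabilities.
#'
#' @param object an \code{snpxe_pair}.
#' @param newdata data frame with the pair's columns; defaults to refitting
#'   rows used in the search.
#' @param type \code{"response"} (default) or \code{"link"}.
#' @param ... unused.
#' @export
predict.snpxe_pair <- function(object, newdata = NULL,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (object$failed) stop("no estimable pattern to predict from", call. = FALSE)
  best <- object$best
  if (is.null(newdata)) {
    eta <- stats::qlogis(best$fit$fitted)
    if (object$family == "linear") eta <- best$fit$fitted
  } else {
    sp <- best$spec
    s <- code_snp(newdata[[object$snp_name]], sp$mode, sp$snp_dir)
    ec <- code_env(newdata[[object$env_name]], sp$env_dir, object$env_type,
                   best$env_coding$reference)
    cv <- if (is.null(object$covariates)) NULL else
      as.matrix(newdata[, object$covariates, drop = FALSE])
    des <- build_design(s, ec$dummies, sp$structure, cv)
    eta <- drop(des$design %*% best$fit$coefficients)
  }
  if (object$family == "logistic" && type == "response")
    stats::plogis(eta)
  else if (object$family == "linear") eta
  else eta
}

#' @export
residuals.snpxe_pair <- function(object, ...) {
  if (object$failed) return(NULL)
  ## response residuals on the complete-case rows used by the selected fit
  object$best$residuals_response
}

#' Batch pattern search across SNPs with Bonferroni correction
#'
#' Runs \code{\link{snpxe_pair}} for each SNP against one environmental
#' factor and combines, per SNP, the allele/MAF summary
#' (\code{\link{maf_info}}), the SNP main-effect test across inheritance
#' modes (\code{\link{snp_main}}), and the selected interaction pattern.
#' Genotype columns holding allele-pair strings are recoded to minor-allele
#' counts first, so "original" coding always refers to the minor allele.
#' Individual SNP failures are recorded per row; the batch continues.
#'
#' @inheritParams snpxe_pair
#' @param snps character vector of genotype column names.
#' @param alpha family-wise significance level; the corrected per-pair
#'   threshold is \code{alpha / length(snps)} (Bonferroni).
#' @return An object of class \code{"snpxe_batch"}: a results data frame
#'   (\code{SNP}, \code{Environment}, \code{maj_min}, \code{MAF},
#'   \code{SNP_Mode}, \code{p_SNPiv}, \code{Interaction_Pattern},
#'   \code{p_int}, \code{significant}), \code{alpha_corrected},
#'   \code{m_tests}, and the underlying \code{pairs} and \code{snp_info}.
#' @export
snpxe_batch <- function(data, snps, env, outcome,
                        env_type = c("ordinal", "categorical"),
                        family = c("logistic", "linear"),
                        covariates = NULL,
                        selection = c("bic", "pvalue"),
                        test = c("lrt", "wald"),
                        alpha = 0.05, env_reference = NULL) {
  env_type <- match.arg(env_type)
  family <- match.arg(family)
  selection <- match.arg(selection)
  test <- match.arg(test)
  stopifnot(length(snps) >= 1L)
  missing_cols <- setdiff(c(snps, env, outcome, covariates), names(data))
  if (length(missing_cols))
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  thr <- bonferroni_threshold(alpha, length(snps))

  rows <- vector("list", length(snps))
  pairs <- vector("list", length(snps))
  infos <- vector("list", length(snps))
  names(pairs) <- names(infos) <- snps
  for (i in seq_along(snps)) {
    sn <- snps[i]
    row <- data.frame(SNP = sn, Environment = env,
                      maj_min = NA_character_, MAF = NA_real_,
                      SNP_Mode = NA_character_, p_SNPiv = NA_real_,
                      Interaction_Pattern = NA_character_, p_int = NA_real_,
                      significant = NA, note = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      info <- maf_info(data[[sn]], snp_name = sn)
      d <- data
      if (is.character(data[[sn]]) || is.factor(data[[sn]]))
        d[[sn]] <- recode_minor_count(data[[sn]], info)
      row$maj_min <- if (!is.na(info$major_allele))
        paste0(info$major_allele, "/", info$minor_allele) else NA_character_
      row$MAF <- info$maf
      if (info$monomorphic) {
        row$note <- "monomorphic SNP"
        list(row = row, pair = NULL, info = info)
      } else {
        sm <- snp_main(d, sn, outcome, family, covariates)
        row$SNP_Mode <- .mode_display(sm$best_mode)
        row$p_SNPiv <- sm$p_SNPiv
        pr <- snpxe_pair(d, sn, env, outcome, env_type, family, covariates,
                         selection, test, env_reference = env_reference)
        if (pr$failed) {
          row$note <- pr$failure_reason
        } else {
          row$Interaction_Pattern <- pr$best$spec$label
          row$p_int <- pr$best$p_interaction
          row$significant <- row$p_int < thr
        }
        list(row = row, pair = pr, info = info)
      }
    }, error = function(e) {
      row$note <- conditionMessage(e)
      list(row = row, pair = NULL, info = NULL)
    })
    rows[[i]] <- res$row
    pairs[[i]] <- res$pair
    infos[[i]] <- res$info
  }
  structure(list(results = do.call(rbind, rows),
                 alpha = alpha, alpha_corrected = thr,
                 m_tests = length(snps), selection_rule = selection,
                 family = family, env_type = env_type,
                 pairs = pairs, snp_info = infos),
            class = "snpxe_batch")
}

.mode_display <- function(mode) {
  c(additive = "Add", dominant = "Dom", recessive = "Rec")[[mode]]
}

#' @export
print.snpxe_batch <- function(x, ...) {
  cat(sprintf("SNPxE batch: %d SNP-environment pairs (%s family, %s selection)\n",
              x$m_tests, x$family, x$selection_rule))
  cat(sprintf("Bonferroni-corrected threshold: %g (= %g / %d pairs)\n",
              x$alpha_corrected, x$alpha, x$m_tests))
  tab <- x$results
  tab$MAF <- round(tab$MAF, 3)
  tab$p_SNPiv <- format_pvalue(tab$p_SNPiv)
  tab$p_int <- format_pvalue(tab$p_int)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.snpxe_batch <- function(x, ...) x$results

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param m number of tests, at least 1.
#' @return \code{alpha / m}.
#' @examples
#' bonferroni_threshold(0.05, 5)  # 0.01
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value in (0, 1)", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("m must be a positive integer count of tests", call. = FALSE)
  alpha / m
}

#' Heat-table plot of the selected pattern
#'
#' Displays the outcome-proportion grid for the pair with the reference
#' sub-groups implied by the selected pattern framed (logistic family).
#'
#' @param x an \code{snpxe_pair} fitted on a binary outcome.
#' @param data the data frame the pair was fitted on.
#' @param ... passed to \code{\link{render_heattable}}.
#' @export
plot.snpxe_pair <- function(x, data, ...) {
  if (x$family != "logistic")
    stop("heat-tables are defined for binary outcomes", call. = FALSE)
  g <- grid_proportions(data, x$snp_name, x$env_name, x$outcome_name)
  render_heattable(g, highlight = if (!x$failed) x$best$spec else NULL, ...)
}
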