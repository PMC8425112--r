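test_that("saturated 2x2 logistic fit reproduces the cross-product odds ratio", {
  # exposure x=1: 10 cases / 40 controls; x=0: 5 cases / 45 controls
  x <- rep(c(1, 0), c(50, 50))
  y <- c(rep(1, 10), rep(0, 40), rep(1, 5), rep(0, 45))
  fit <- fit_glm(cbind(1, x = x), y, "logistic")
  or_closed <- (10 * 45) / (40 * 5)  # 2.25
  expect_close(exp(fit$coefficients[["x"]]), or_closed, 1e-6)
})

test_that("intercept-only logistic log-likelihood and BIC match closed forms", {
  y <- rep(c(1, 0), c(30, 70))
  fit <- fit_glm(matrix(1, 100, 1), y, "logistic")
  ll_closed <- 30 * log(0.3) + 70 * log(0.7)
  expect_close(fit$log_likelihood, ll_closed, 1e-6)
  expect_close(bic(fit), -2 * ll_closed + log(100), 1e-6)
})

test_that("both families agree with the reference GLM implementation", {
  set.seed(11)
  for (n in c(20, 200)) {
    X <- cbind(1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.5),
               x3 = sample(0:2, n, TRUE))
    eta <- -0.3 + 0.5 * X[, "x1"] - 0.4 * X[, "x3"]
    yb <- rbinom(n, 1, plogis(eta))
    yc <- eta + rnorm(n)
    fb <- fit_glm(X, yb, "logistic")
    rb <- ref_glm(X, yb, "logistic")
    expect_close(unname(fb$coefficients), unname(coef(rb)), 1e-6)
    expect_close(unname(fb$se), unname(sqrt(diag(vcov(rb)))), 1e-6)
    expect_close(fb$log_likelihood, as.numeric(logLik(rb)), 1e-6)
    expect_close(bic(fb), BIC(rb), 1e-6)
    fc <- fit_glm(X, yc, "linear")
    rc <- ref_glm(X, yc, "linear")
    expect_close(unname(fc$coefficients), unname(coef(rc)), 1e-6)
    expect_close(unname(fc$se), unname(sqrt(diag(vcov(rc)))), 1e-6)
    expect_close(fc$log_likelihood, as.numeric(logLik(rc)), 1e-6)
    # linear BIC counts the variance parameter, matching stats::BIC on lm
    expect_close(bic(fc), BIC(rc), 1e-6)
  }
})

test_that("separation and degenerate designs yield flags, not exceptions", {
  x <- c(rep(0, 10), rep(1, 10))
  y <- x  # perfect separation
  fit <- fit_glm(cbind(1, x = x), y, "logistic")
  expect_false(fit$converged)
  expect_false(fit$estimable)
  expect_true(is.na(bic(fit)))
  # more parameters than rows
  fit2 <- fit_glm(matrix(rnorm(12), 3, 4), rnorm(3), "linear")
  expect_false(fit2$estimable)
  expect_error(fit_glm(cbind(1, x), c(y[-1], 2), "logistic"), "0/1")
  expect_error(fit_glm(cbind(1, c(x[-1], NA)), y, "logistic"), "missing")
})

test_that("interaction LRT behaves on nested, identical and reversed models", {
  set.seed(5)
  d <- make_cohort(300, pattern = "Full_AE_oo", beta_int = log(c(1.8, 2.5)),
                   beta_snp = 0.3, beta_env = c(0.2, 0.4))
  s <- code_snp(d$snp, "additive", "original")
  ec <- code_env(d$env, "original", "ordinal")
  des <- build_design(s, ec$dummies, "Full")
  full <- fit_glm(des$design, d$outcome, "logistic")
  red <- fit_glm(des$design[, setdiff(colnames(des$design),
                                      des$interaction_cols)],
                 d$outcome, "logistic")
  lrt <- interaction_test(full, red)
  expect_equal(lrt$df, 2)
  expect_gte(lrt$statistic, 0)
  expect_close(lrt$p, pchisq(lrt$statistic, 2, lower.tail = FALSE), 1e-12)
  # identical models: statistic 0, p 1
  same <- interaction_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # reduced larger than full is a nesting error
  expect_error(interaction_test(red, full), "nested")
  # Wald joint test agrees with LRT to leading order on well-behaved data
  wd <- interaction_test(full, red, method = "wald",
                         wald_terms = des$interaction_cols)
  expect_equal(wd$df, 2)
  expect_lt(abs(wd$statistic - lrt$statistic) / lrt$statistic, 0.25)
})

test_that("linear-family interaction test is the exact partial F-test", {
  set.seed(6)
  d <- make_cohort(120, family = "linear", pattern = "Full_AE_oo",
                   beta_int = c(0.4, 0.7), noise_sd = 1)
  s <- code_snp(d$snp, "additive", "original")
  ec <- code_env(d$env, "original", "ordinal")
  des <- build_design(s, ec$dummies, "Full")
  full <- fit_glm(des$design, d$outcome, "linear")
  red <- fit_glm(des$design[, setdiff(colnames(des$design),
                                      des$interaction_cols)],
                 d$outcome, "linear")
  ours <- interaction_test(full, red)
  # oracle: anova() on the formula-interface fits
  lm_f <- ref_glm(des$design, d$outcome, "linear")
  lm_r <- ref_glm(des$design[, setdiff(colnames(des$design),
                                       des$interaction_cols)],
                  d$outcome, "linear")
  a <- anova(lm_r, lm_f)
  expect_close(ours$statistic, a$F[2], 1e-8)
  expect_close(ours$p, a$`Pr(>F)`[2], 1e-10)
})

test_that("LRT is invariant under affine recoding of main-effect columns", {
  set.seed(7)
  d <- make_cohort(250, pattern = "Full_AE_oo", beta_int = log(c(1.5, 2)))
  s <- code_snp(d$snp, "additive", "original")
  ec <- code_env(d$env, "original", "ordinal")
  get_p <- function(smain) {
    des <- build_design(s, ec$dummies, "Full")
    des$design[, "SNP"] <- smain
    full <- fit_glm(des$design, d$outcome, "logistic")
    red <- fit_glm(des$design[, setdiff(colnames(des$design),
                                        des$interaction_cols)],
                   d$outcome, "logistic")
    interaction_test(full, red)$p
  }
  expect_close(get_p(s), get_p(3 * s - 1), 1e-6)
})

test_that("direction reversal never changes fits within a redundant structure", {
  # span equivalence behind the 27-pattern reduction: Full is invariant to
  # both directions, Mint_SNP to the env direction, Mint_Env to the SNP one
  set.seed(8)
  d <- make_cohort(400, pattern = "Full_AE_oo", beta_int = log(c(1.4, 2.1)),
                   beta_snp = 0.2, beta_env = c(0.1, 0.3))
  ll <- function(structure, mode, sdir, edir) {
    s <- code_snp(d$snp, mode, sdir)
    ec <- code_env(d$env, edir, "ordinal")
    des <- build_design(s, ec$dummies, structure)
    fit_glm(des$design, d$outcome, "logistic")$log_likelihood
  }
  for (mode in c("additive", "dominant", "recessive")) {
    base <- ll("Full", mode, "original", "original")
    for (sd_ in c("original", "reverse")) for (ed in c("original", "reverse"))
      expect_close(ll("Full", mode, sd_, ed), base, 1e-6)
    expect_close(ll("Mint_SNP", mode, "original", "reverse"),
                 ll("Mint_SNP", mode, "original", "original"), 1e-6)
    expect_close(ll("Mint_SNP", mode, "reverse", "reverse"),
                 ll("Mint_SNP", mode, "reverse", "original"), 1e-6)
    expect_close(ll("Mint_Env", mode, "reverse", "original"),
                 ll("Mint_Env", mode, "original", "original"), 1e-6)
    expect_close(ll("Mint_Env", mode, "reverse", "reverse"),
                 ll("Mint_Env", mode, "original", "reverse"), 1e-6)
  }
})

test_that("fit_pattern matches a hand-built reference fit and reports effects", {
  set.seed(9)
  d <- make_cohort(500, pattern = "Int_AE_oo", beta_int = log(c(1.5, 2.2)))
  pf <- fit_pattern(d, "Full_AE_oo", "snp", "env", "outcome")
  expect_true(pf$estimable)
  # oracle: formula-interface glm with the same coding
  ref <- glm(outcome ~ snp * factor(env), data = d, family = binomial())
  expect_close(sort(unname(pf$fit$coefficients)), sort(unname(coef(ref))),
               1e-6)
  # per-term table: OR = exp(estimate), CI brackets the estimate
  tab <- pf$per_term
  expect_close(tab$OR, exp(tab$estimate), 1e-12)
  expect_true(all(tab$ci_low <= tab$estimate & tab$estimate <= tab$ci_high))
  expect_equal(sum(tab$interaction), 2)
  expect_true(pf$p_interaction >= 0 && pf$p_interaction <= 1)
  # monomorphic SNP: every pattern non-estimable, no exception
  d$snp <- 0
  pf0 <- fit_pattern(d, "Full_AE_oo", "snp", "env", "outcome")
  expect_false(pf0$estimable)
  expect_true(is.na(pf0$p_interaction) && is.na(pf0$bic))
})

test_that("missing data are handled listwise and n_used is reported", {
  set.seed(10)
  d <- make_cohort(200)
  d$snp[1:5] <- NA
  d$env[6:8] <- NA
  pf <- fit_pattern(d, "Full_AE_oo", "snp", "env", "outcome")
  expect_equal(pf$n_used, 192)
  expect_equal(pf$fit$n_used, 192)
})
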