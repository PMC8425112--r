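# shared fixture builders; all stochastic helpers take an explicit seed

# cohort with one SNP, a 3-level ordinal exposure and a binary outcome,
# optionally planted with an interaction pattern
make_cohort <- function(n = 500, maf = 0.3, seed = 1, pattern = NULL,
                        beta_int = NULL, prevalence = 0.3, ...) {
  set.seed(seed)
  snp <- simulate_genotypes(n, maf)
  env <- simulate_env(n)
  outcome <- simulate_outcome(snp, env, pattern = pattern,
                              beta_int = beta_int, prevalence = prevalence,
                              ...)
  data.frame(outcome = outcome, snp = snp, env = env)
}

# fit a design with the reference implementation (formula-interface glm/lm)
ref_glm <- function(design, y, family) {
  df <- as.data.frame(design[, -1, drop = FALSE])
  names(df) <- paste0("x", seq_len(ncol(df)))
  df$y <- y
  if (family == "logistic")
    stats::glm(y ~ ., data = df, family = binomial())
  else
    stats::lm(y ~ ., data = df)
}

expect_close <- function(actual, expected, tol = 1e-6) {
  expect_lt(max(abs(actual - expected)), tol)
}
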