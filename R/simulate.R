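## Synthetic case-control generator: genotypes under Hardy-Weinberg
## equilibrium, an ordinal/categorical exposure, and outcomes planted under
## any interaction pattern of the family. Used for tests, demos and power
## studies; it deliberately omits linkage disequilibrium, population
## stratification and genotyping error.

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Independent draws with P(2) = maf^2, P(1) = 2 maf (1-maf),
#' P(0) = (1-maf)^2.
#'
#' @param n number of subjects.
#' @param maf minor allele frequency in (0, 0.5].
#' @param seed optional seed for reproducibility.
#' @return Integer vector of minor-allele counts.
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf > 0.5)
    stop("maf must be in (0, 0.5]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sample(0:2, n, replace = TRUE,
         prob = c((1 - maf)^2, 2 * maf * (1 - maf), maf^2))
}

#' Simulate an environmental factor
#'
#' @param n number of subjects.
#' @param probs level probabilities (normalised to sum 1); default uniform
#'   over 3 levels.
#' @param levels level codes, default \code{1:length(probs)}.
#' @param seed optional seed.
#' @export
simulate_env <- function(n, probs = rep(1 / 3, 3), levels = seq_along(probs),
                         seed = NULL) {
  stopifnot(length(probs) == length(levels), all(probs > 0))
  if (!is.null(seed)) set.seed(seed)
  sample(levels, n, replace = TRUE, prob = probs / sum(probs))
}

#' Simulate outcomes under a planted interaction pattern
#'
#' Builds the coded design of the truth pattern from the supplied genotypes
#' and environment and draws the outcome from the implied model: logistic
#' family, \code{Y ~ Bernoulli(expit(eta))} with coefficients on the
#' log-odds scale (so OR = exp(coefficient)); linear family,
#' \code{Y = eta + Normal(0, noise_sd)}. With no pattern the null
#' (intercept-only) model is used.
#'
#' @param genotypes 0/1/2 minor-allele counts.
#' @param env environment vector.
#' @param pattern optional \code{pattern_spec} or canonical label; NULL for
#'   the null model.
#' @param beta0 intercept on the link scale (log-odds for logistic);
#'   alternatively give \code{prevalence} for the logistic family.
#' @param prevalence baseline outcome probability; sets
#'   \code{beta0 = qlogis(prevalence)}.
#' @param beta_int interaction coefficients, one per non-reference
#'   environment level (ordered by level).
#' @param beta_snp SNP main-effect coefficient (used when the structure
#'   includes it).
#' @param beta_env environment main-effect coefficients, one per dummy
#'   (used when the structure includes them).
#' @param family \code{"logistic"} or \code{"linear"}.
#' @param noise_sd residual standard deviation (linear family).
#' @param env_type environment type for the coding.
#' @param seed optional seed.
#' @return Numeric outcome vector of length \code{length(genotypes)}.
#' @export
simulate_outcome <- function(genotypes, env, pattern = NULL,
                             beta0 = NULL, prevalence = 0.25,
                             beta_int = NULL, beta_snp = 0, beta_env = NULL,
                             family = c("logistic", "linear"),
                             noise_sd = 1,
                             env_type = c("ordinal", "categorical"),
                             seed = NULL) {
  family <- match.arg(family)
  env_type <- match.arg(env_type)
  if (!is.null(seed)) set.seed(seed)
  n <- length(genotypes)
  stopifnot(length(env) == n)
  if (is.null(beta0))
    beta0 <- if (family == "logistic") stats::qlogis(prevalence) else 0
  eta <- rep(beta0, n)
  if (!is.null(pattern)) {
    if (is.character(pattern)) pattern <- parse_label(pattern)
    s <- code_snp(genotypes, pattern$mode, pattern$snp_dir)
    ec <- code_env(env, pattern$env_dir, env_type)
    k1 <- ncol(ec$dummies)
    if (is.null(beta_int)) stop("beta_int required with a pattern",
                                call. = FALSE)
    stopifnot(length(beta_int) == k1)
    eta <- eta + drop((s * ec$dummies) %*% beta_int)
    if (pattern$structure %in% c("Full", "Mint_SNP"))
      eta <- eta + beta_snp * s
    if (pattern$structure %in% c("Full", "Mint_Env")) {
      if (is.null(beta_env)) beta_env <- rep(0, k1)
      stopifnot(length(beta_env) == k1)
      eta <- eta + drop(ec$dummies %*% beta_env)
    }
  }
  if (family == "logistic")
    stats::rbinom(n, 1L, stats::plogis(eta))
  else
    eta + stats::rnorm(n, 0, noise_sd)
}

#' Generate an example cohort with planted SNP-environment interactions
#'
#' Emulates a candidate-SNP case-control study: n subjects, five SNPs
#' (\code{snp1}..\code{snp5}) with MAFs 0.210, 0.071, 0.343, 0.342 and
#' 0.445, a three-level ordinal exposure \code{env_g3} (uniform levels
#' 1/2/3), and a binary outcome. Two interactions are planted on the
#' log-odds scale: an additive-SNP, original-coding interaction-only effect
#' (\code{Int_AE_oo}) on \code{snp2} with per-allele ORs 1.5 (level 2 vs 1)
#' and 2.2 (level 3 vs 1), and a recessive-SNP, reverse-environment
#' interaction-only effect (\code{Int_RE_or}) on \code{snp3} with ORs 4.3
#' (level 1 vs 3) and 1.8 (level 2 vs 3). The remaining SNPs are null.
#' Baseline prevalence is 0.25.
#'
#' @param seed integer seed; one global seed drives every draw.
#' @param n number of subjects.
#' @return A data frame with columns \code{id}, \code{outcome},
#'   \code{env_g3}, \code{snp1}..\code{snp5} and a \code{"truth"}
#'   attribute describing the planted effects.
#' @export
make_simdata2_like <- function(seed = NULL, n = 2000L) {
  if (!is.null(seed)) set.seed(seed)
  mafs <- c(snp1 = 0.210, snp2 = 0.071, snp3 = 0.343,
            snp4 = 0.342, snp5 = 0.445)
  snps <- lapply(mafs, function(q) simulate_genotypes(n, q))
  env <- simulate_env(n)
  truth <- list(
    baseline_prevalence = 0.25,
    planted = list(
      snp2 = list(pattern = "Int_AE_oo", beta_int = log(c(1.5, 2.2))),
      snp3 = list(pattern = "Int_RE_or", beta_int = log(c(4.3, 1.8)))))
  ## combined linear predictor: baseline + both planted interaction terms
  eta <- rep(stats::qlogis(truth$baseline_prevalence), n)
  for (sn in names(truth$planted)) {
    tr <- truth$planted[[sn]]
    sp <- parse_label(tr$pattern)
    s <- code_snp(snps[[sn]], sp$mode, sp$snp_dir)
    ec <- code_env(env, sp$env_dir, "ordinal")
    eta <- eta + drop((s * ec$dummies) %*% tr$beta_int)
  }
  outcome <- stats::rbinom(n, 1L, stats::plogis(eta))
  out <- data.frame(id = seq_len(n), outcome = outcome, env_g3 = env)
  for (sn in names(snps)) out[[sn]] <- snps[[sn]]
  attr(out, "truth") <- truth
  out
}
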