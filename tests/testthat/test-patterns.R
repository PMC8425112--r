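# the canonical ordinal family in its reading order: structures Full,
# Mint_SNP, Mint_Env, Int; modes A, D, R within structure; direction pairs
# oo, or, ro, rr within mode as admitted
canonical_labels <- c(
  "Full_AE_oo", "Full_DE_oo", "Full_RE_oo",
  "Mint_SNP_AE_oo", "Mint_SNP_AE_ro", "Mint_SNP_DE_oo", "Mint_SNP_DE_ro",
  "Mint_SNP_RE_oo", "Mint_SNP_RE_ro",
  "Mint_Env_AE_oo", "Mint_Env_AE_or", "Mint_Env_DE_oo", "Mint_Env_DE_or",
  "Mint_Env_RE_oo", "Mint_Env_RE_or",
  "Int_AE_oo", "Int_AE_or", "Int_AE_ro", "Int_AE_rr",
  "Int_DE_oo", "Int_DE_or", "Int_DE_ro", "Int_DE_rr",
  "Int_RE_oo", "Int_RE_or", "Int_RE_ro", "Int_RE_rr")

test_that("pattern family has the designed size, composition and order", {
  ord <- enumerate_patterns("ordinal")
  cat_ <- enumerate_patterns("categorical")
  expect_length(ord, 27)
  expect_length(cat_, 18)
  expect_identical(names(ord), canonical_labels)
  expect_false(anyDuplicated(names(ord)) > 0)
  # categorical = ordinal minus every env-reversed pattern
  dropped <- grepl("_(or|rr)$", names(ord))
  expect_equal(sum(dropped), 9)
  expect_identical(names(cat_), names(ord)[!dropped])
  # per-structure counts 3 + 6 + 6 + 12
  structs <- vapply(ord, function(s) s$structure, "")
  expect_equal(unname(table(structs)[c("Full", "Mint_SNP", "Mint_Env", "Int")]),
               c(3L, 6L, 6L, 12L), ignore_attr = TRUE)
  expect_identical(names(ord)[structs == "Full"],
                   c("Full_AE_oo", "Full_DE_oo", "Full_RE_oo"))
  expect_error(enumerate_patterns("nominal"))
})

test_that("labels round-trip through the parser for the whole family", {
  for (sp in enumerate_patterns("ordinal")) {
    back <- parse_label(pattern_label(sp))
    expect_identical(back, sp)
  }
  sp <- pattern_spec("Int", "recessive", "reverse", "original")
  expect_identical(sp$label, "Int_RE_ro")
  sp <- pattern_spec("Mint_Env", "dominant", "original", "reverse")
  expect_identical(sp$label, "Mint_Env_DE_or")
  p <- parse_label("Full_AE_oo")
  expect_identical(p$structure, "Full")
  expect_identical(p$mode, "additive")
  expect_identical(p$snp_dir, "original")
  expect_identical(p$env_dir, "original")
  expect_error(parse_label("Full_AE_or"), "canonical")
  expect_error(parse_label("Int_XE_oo"), "canonical")
})

test_that("structure constraints forbid redundant direction variants", {
  expect_error(pattern_spec("Full", "additive", "reverse", "original"))
  expect_error(pattern_spec("Full", "additive", "original", "reverse"))
  expect_error(pattern_spec("Mint_SNP", "dominant", "original", "reverse"))
  expect_error(pattern_spec("Mint_Env", "recessive", "reverse", "original"))
})

test_that("SNP codings match the mode/direction table and complement identity", {
  g <- c(0, 1, 2)
  expect_equal(code_snp(g, "additive", "original"), c(0, 1, 2))
  expect_equal(code_snp(g, "additive", "reverse"), c(2, 1, 0))
  expect_equal(code_snp(g, "dominant", "original"), c(0, 1, 1))
  expect_equal(code_snp(g, "dominant", "reverse"), c(1, 0, 0))
  expect_equal(code_snp(g, "recessive", "original"), c(0, 0, 1))
  expect_equal(code_snp(g, "recessive", "reverse"), c(1, 1, 0))
  # original + reverse = 2 (additive) or 1 (binary modes), elementwise
  set.seed(42)
  gg <- sample(c(0:2, NA), 50, replace = TRUE)
  for (mode in c("additive", "dominant", "recessive")) {
    tot <- code_snp(gg, mode, "original") + code_snp(gg, mode, "reverse")
    expect_equal(tot[!is.na(gg)],
                 rep(if (mode == "additive") 2 else 1, sum(!is.na(gg))))
    expect_true(all(is.na(tot[is.na(gg)])))
  }
  expect_error(code_snp(c(0, 3, 1), "additive"), "row\\(s\\) 2")
})

test_that("environment coding picks the right reference and dummies", {
  e <- c(1, 2, 3, 2, 1, 3)
  orig <- code_env(e, "original", "ordinal")
  expect_identical(orig$reference, 1)
  expect_identical(colnames(orig$dummies), c("ENV_2vs1", "ENV_3vs1"))
  expect_equal(orig$dummies[, 1], as.numeric(e == 2))
  rev <- code_env(e, "reverse", "ordinal")
  expect_identical(rev$reference, 3)
  expect_identical(colnames(rev$dummies), c("ENV_1vs3", "ENV_2vs3"))
  # two-level factor: a single indicator
  two <- code_env(c(1, 2, 1, 2), "original", "ordinal")
  expect_equal(ncol(two$dummies), 1)
  # categorical: user reference, reverse undefined
  cc <- code_env(c("A", "B", "C"), "original", "categorical", reference = "B")
  expect_identical(cc$reference, "B")
  expect_identical(colnames(cc$dummies), c("ENV_AvsB", "ENV_CvsB"))
  expect_error(code_env(c("A", "B"), "reverse", "categorical"), "categorical")
  expect_error(code_env(rep(1, 5), "original", "ordinal"), "fewer than 2")
})

test_that("design matrices contain the structure-dependent columns", {
  set.seed(3)
  g <- simulate_genotypes(40, 0.4)
  e <- simulate_env(40)
  s <- code_snp(g, "additive", "original")
  ec <- code_env(e, "original", "ordinal")
  want <- list(
    Full     = c("(Intercept)", "SNP", "ENV_2vs1", "ENV_3vs1",
                 "SNP:ENV_2vs1", "SNP:ENV_3vs1"),
    Mint_SNP = c("(Intercept)", "SNP", "SNP:ENV_2vs1", "SNP:ENV_3vs1"),
    Mint_Env = c("(Intercept)", "ENV_2vs1", "ENV_3vs1",
                 "SNP:ENV_2vs1", "SNP:ENV_3vs1"),
    Int      = c("(Intercept)", "SNP:ENV_2vs1", "SNP:ENV_3vs1"))
  for (st in names(want)) {
    des <- build_design(s, ec$dummies, st)
    expect_identical(colnames(des$design), want[[st]])
    # interaction columns are the elementwise product
    expect_equal(des$design[, "SNP:ENV_2vs1"], s * ec$dummies[, 1],
                 ignore_attr = TRUE)
    expect_equal(des$design[, "SNP:ENV_3vs1"], s * ec$dummies[, 2],
                 ignore_attr = TRUE)
    expect_true(des$estimable)
  }
  # constant column flags non-estimability instead of crashing
  des <- build_design(rep(0, 40), ec$dummies, "Full")
  expect_false(des$estimable)
  # covariates are appended
  des <- build_design(s, ec$dummies, "Int", covariates = cbind(age = rnorm(40)))
  expect_true("age" %in% colnames(des$design))
})
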