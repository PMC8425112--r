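# snpxe

Pattern-search testing of SNP-environment interactions for genetic
association studies.

## The problem

The conventional test for a SNP-environment (GxE) interaction is a single
full interaction model with an additively coded SNP — `logit P(Y=1) =
β0 + β1 S + β2 I(E=2) + β3 I(E=3) + β4 S·I(E=2) + β5 S·I(E=3)`. When the
true interaction does not follow that one pattern (e.g. the risk genotype
acts recessively, or the main effects are negligible), the full model
wastes degrees of freedom and loses power. `snpxe` instead evaluates a
designed family of interaction regression patterns per SNP-environment
pair, built from three components:

1. **model structure** — which main effects accompany the interaction
   terms: `Full`, `Mint_SNP` (SNP main + interaction), `Mint_Env`
   (environment main + interaction), `Int` (interaction only);
2. **SNP inheritance mode** — additive (0/1/2 minor-allele count),
   dominant (carrier vs non-carrier), recessive (homozygous minor vs
   other);
3. **risk direction** of each factor — original or reverse coding
   (which pole is the reference).

Direction reversal is redundant whenever the structure contains that
factor's main effect (the design spans the same column space), which
prunes the family to **27 patterns for an ordinal environmental factor**
and **18 for a categorical one** (the 9 labels ending `_or`/`_rr` drop
out because a categorical reference is user-chosen). Each pattern is
fitted by logistic (binary phenotype) or linear (continuous phenotype)
regression; the interaction is tested jointly over the interaction
columns by a likelihood-ratio test (partial F-test for the linear
family); the best pattern per pair is the one with the smallest BIC
(default — parsimony generalises better) or the smallest interaction
p-value. Batch scans over candidate SNPs apply a Bonferroni-corrected
threshold `α / m` across pairs.

Pattern labels read as `<structure>_<A|D|R>E_<snp dir><env dir>`, e.g.
`Int_RE_or` = interaction-only, recessive SNP with original coding,
environment reverse-coded (highest level as reference).

## Worked example

```r
library(snpxe)

d <- make_simdata2_like(seed = 7)   # 2000 subjects, 5 SNPs, 3-level exposure
b <- snpxe_batch(d, paste0("snp", 1:5), "env_g3", "outcome", alpha = 0.05)
print(b)
```

```
SNPxE batch: 5 SNP-environment pairs (logistic family, bic selection)
Bonferroni-corrected threshold: 0.01 (= 0.05 / 5 pairs)
  SNP Environment maj_min   MAF SNP_Mode  p_SNPiv Interaction_Pattern    p_int
 snp1      env_g3    <NA> 0.210      Dom 6.37e-01           Int_DE_rr 7.62e-02
 snp2      env_g3    <NA> 0.072      Dom 6.40e-04           Int_DE_oo 2.55e-05
 snp3      env_g3    <NA> 0.332      Rec 6.00e-04           Int_RE_or 2.60e-08
 snp4      env_g3    <NA> 0.340      Dom 1.41e-01           Int_DE_ro 7.79e-02
 snp5      env_g3    <NA> 0.438      Add 5.16e-01           Int_AE_or 2.16e-01
 significant note
       FALSE     
        TRUE     
        TRUE     
       FALSE     
       FALSE     
```

The generator plants an `Int_AE_oo` interaction on `snp2` and an
`Int_RE_or` interaction on `snp3`; both are flagged at the corrected
0.01 threshold and `snp3`'s selected pattern is exactly the planted one.
Per SNP the row shows the allele summary (`maj_min` is `NA` here because
genotypes are numeric counts, not allele strings), the best-fitting
inheritance mode for the SNP's individual effect with its p-value
(`p_SNPiv`), and the selected interaction pattern with its joint LRT
p-value (`p_int`).

Drill into one pair, inspect all 27 fits, and visualise the risk
sub-groups:

```r
pr <- snpxe_pair(d, "snp3", "env_g3", "outcome")
summary(pr)                      # per-pattern BIC and p-value table
coef(pr)                         # coefficients of the selected pattern
plot(pr, d)                      # heat-table, reference sub-groups framed
print(grid_proportions(d, "snp3", "env_g3", "outcome"))
```

A command-line wrapper is installed under `inst/cli/snpxe.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/snpxe.R", package="snpxe"))')" \
  batch --data cohort.csv --outcome outcome --env env_g3 \
  --snps snp1,snp2,snp3,snp4,snp5 --alpha 0.05 --out results.tsv
```

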