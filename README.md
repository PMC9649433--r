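# snowmatch

HLA Class I epitope matching built on **allele-specific solvent
accessibility**, for transplant immunologists and histocompatibility
researchers who want epitope-level mismatch scores and the statistical
machinery to validate them against antibody outcomes.

Donor-specific HLA antibodies (DSA) — and their pregnancy counterpart,
child-specific antibodies (CSA) — bind patches on the *surface* of the
immunizing HLA protein. Because solvent accessibility differs between HLA
proteins, this package defines each allele's own surface and scores a
donor–recipient pair by the **Snowflake score**:

> for each donor allele *d* at a locus, take the positions *p* with
> relative solvent accessibility RSA\_d(p) ≥ t (default t = 0.3717);
> a pair (p, residue) is mismatched when no allele in the recipient's
> HLA-A/B/C repertoire carries that residue at *p*; the locus score is
> |⋃\_d mismatched pairs|.

RSA comes from Shrake–Rupley SASA on 3D structures (golden-spiral
quadrature, probe 1.4 Å), normalized by per-residue maximal areas, and is
extrapolated to alleles without structures through a pluggable
sequence→surface predictor (reference implementation: k-nearest-allele
position-wise averaging). Alongside Snowflake the package computes reference
eplet mismatch counts (AllEPS / antibody-verified AbvEPS) and a surrogate
count of mismatched donor-derived 9-mer peptides per presenter locus;
resolves intermediate-resolution typings to frequency-weighted genotypes via
haplotype tables and multiple-allele codes; pools per-locus records the way
the two validation cohort designs do; and runs the statistical battery (rank
tests, Spearman, univariable + stepwise-AIC logistic regression, Cox
regression). A synthetic-cohort generator makes the whole pipeline testable
without clinical data.

## Worked example

```r
library(snowmatch)

cfg  <- simulationConfig(seed = 42, nCases = 300)
pool <- makeAllelePool(cfg)         # alleles, profiles, registry, haplotypes
pool
#> AllelePool: 18 alleles, 50-position grid, 48 eplets, 12 haplotypes, 2 structures

donor     <- genotype(A = c("A*01:01", "A*02:01"), B = c("B*01:02", "B*03:01"),
                      C = "C*02:01", DRB1 = "DRB1*01:01", DQB1 = "DQB1*01:01")
recipient <- genotype(A = c("A*01:01", "A*03:02"), B = c("B*02:01", "B*02:02"),
                      C = c("C*01:01", "C*03:01"), DRB1 = "DRB1*02:01",
                      DQB1 = "DQB1*02:01")
locusScores(donor, recipient, pool$db, registry = pool$registry)
#>  locus snowflake all_eps abv_eps pirche_DRB1 pirche_DQB1 matched homozygous
#>      A         3       4       2          24          24   FALSE      FALSE
#>      B         3       3       3          22          22   FALSE      FALSE
#>      C         0       1       1           9           9   FALSE       TRUE
```

The shared allele A\*01:01 contributes nothing; at HLA-A the other donor
allele carries 3 surface residues the recipient lacks, 2 of them covered by
antibody-verified eplets; the homozygous donor HLA-C is fully
surface-matched (Snowflake 0) although one unverified eplet and 9 mismatched
peptide windows remain.

End-to-end, with outcomes simulated at true OR 1.63 per SD of Snowflake:

```r
pc  <- simulatePregnancy(pool, cfg)
rec <- normalizeRecords(poolPregnancy(pc$scores))
nrow(rec); sum(rec$outcome)
#> [1] 577      # pooled mismatched, non-homozygous locus records
#> [1] 136      # CSA-positive records
logisticUnivariable(rec, "z_snowflake")$table
#>         term estimate ci_low ci_high       p
#>  z_snowflake     1.68   1.39    2.03 8.9e-08
```

The fitted odds ratio per SD (1.68, CI 1.39–2.03) recovers the simulated
effect.

A thin CLI over the same functions is installed at
`inst/scripts/snowmatch.R` (subcommands `surface`, `build-db`, `score`,
`impute`, `simulate`, `analyze`).

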