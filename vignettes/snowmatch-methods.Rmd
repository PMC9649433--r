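---
title: "Allele-specific solvent-accessibility epitope matching: models and design choices"
author: "snowmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific solvent-accessibility epitope matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snowmatch)
```

## The problem

Antibodies raised against mismatched HLA — after transplantation (donor-specific
antibodies, DSA) or pregnancy (child-specific antibodies, CSA) — target patches
on the *surface* of the immunizing HLA protein. Classical antigen-level
matching treats any allele difference as equivalent; epitope-level models try
to count only differences an antibody could actually see. Because solvent
accessibility varies between HLA proteins, a locus-wide accessibility map
over- or under-calls surface residues for individual alleles. The score at the
centre of this package — the Snowflake score — therefore counts, for each
donor (or child) allele, the amino acids at *that allele's own*
solvent-accessible positions that are absent from the recipient's (or
mother's) entire HLA Class I repertoire.

## From structure to accessibility profile

Per-atom solvent-accessible surface area (SASA) is computed with the
Shrake-Rupley method: each atom is inflated by the probe radius (default
1.4 Å, a water molecule) and covered with a deterministic golden-spiral point
set (default 960 points); the exposed fraction times the inflated-sphere area
is the atom's SASA. Residue SASA is the sum over its atoms, and relative
accessibility (RSA) divides by the residue type's theoretical maximum
accessible area (the packaged Tien et al. table), giving a dimensionless
value mostly in [0, 1] (values slightly above 1 occur for exposed termini and
are clipped at 1.5). Van der Waals radii come from a packaged NACCESS-style
element table (C 1.70, N 1.55, O 1.52, S 1.80 Å).

Numerical behaviour worth knowing:

* The golden-spiral point set involves no randomness, so identical inputs are
  bit-identical across runs, and adding atoms can only turn exposed test
  points into buried ones — SASA is exactly monotone under occlusion.
* At 960 points the isolated-sphere error is well below 0.5 %; refining to
  3840 points moves per-atom values of a small helix by under 2 % in total.
* All chains of a structure occlude (a docked peptide in the binding groove
  shadows groove residues) but only the heavy chain contributes profile
  positions. Missing density and alignment gaps become `NA` — *absent*, which
  is deliberately distinct from 0 (= genuinely buried).
* HETATM records, waters, ions, and alternate locations beyond the first are
  ignored; no protonation or minimization is attempted.

Chain residues are mapped to mature-protein positions by global alignment
(BLOSUM62, Needleman-Wunsch) against a reference sequence, requiring ≥ 95 %
identity over aligned columns; automatic chain selection takes the longest
chain and refuses structures whose longest chain is under 80 residues (toy
structures must name their chain explicitly).

## The allele database and the sequence-to-surface contract

All profiles live on one alignment grid (a consensus coordinate system), so
positions are comparable across alleles and loci. Multiple structures of one
allele are averaged position-wise. Alleles without structures get *predicted*
profiles via a pluggable predictor contract: fitted state in, deterministic
per-position RSA out. The reference implementation is deliberately simple —
the k nearest training alleles by position-wise sequence identity (k = 3 by
default, ties broken lexicographically by allele name) contribute a
position-wise mean RSA, and a query identical to a training sequence returns
that profile. A neural-network predictor honouring the same contract can be
swapped in; nothing downstream changes.

A position counts as surface when RSA ≥ 0.3717. That default is the median
accessibility score over a reference allele panel, stored in configuration
rather than hard-coded; the normalization behind it (relative rather than
absolute area) is this package's choice, made because a dimensionless
median of that magnitude is only consistent with a fraction.

## Mismatch scores

**Snowflake.** For each donor allele at a locus, scan its surface positions;
a (position, residue) pair is mismatched when no recipient Class I allele
carries that residue there (interlocus comparison — the recipient's full A/B/C
repertoire is the "self" set; an intralocus variant restricts to the same
locus). The locus score is the size of the union of mismatched pairs over the
locus's two donor alleles: summing per allele would double-count a mismatch
shared by both, and the union matches the locus-specific (rather than
mismatch-specific) framing of the validation design. When both donor alleles
mismatch *differently* at one position, both pairs count — counting pairs
rather than positions is a documented choice. Surface positions are always
taken from the donor allele's own profile: the immunogen's surface is what an
antibody sees. An allele the recipient also carries contributes zero at any
threshold.

**Eplet counts.** An eplet — a named configuration of (position, residue)
pairs with an antibody-verified flag — is present on an allele only when
*every* pair matches (no partial credit). The count (AllEPS, or AbvEPS when
restricted to verified eplets) is the number of distinct eplets present on at
least one donor allele of the locus and on none of the recipient's six
Class I alleles, so AbvEPS ≤ AllEPS always.

**Surrogate peptide count.** Indirect T-cell epitope models count
donor-derived peptides presentable by recipient Class II. True peptide-MHC
binding prediction is out of scope here; the surrogate enumerates all 9-mer
windows (length configurable) of the donor sequence containing at least one
mismatched residue and passes them to a pluggable
`predicate(peptide, presenterAllele)` — accept-all by default, per presenter
locus. It is a clearly labelled surrogate: its value is that it responds to
the same mismatch structure, not that it models binding.

## Imputation of intermediate-resolution typing

Typings given as serologic antigens or multiple-allele codes are expanded to
candidate lists, and haplotype pairs from a frequency table are retained when
compatible locus-by-locus. Pair weights follow Hardy-Weinberg
(f₁·f₂, doubled for heterozygous pairs), are normalized over matching pairs,
pairs at or below 1 % normalized frequency are discarded ("exceeds 1 %" read
strictly), and the survivors are renormalized to sum to one — so the weighted
score is a proper expectation; leaving weights sub-unity after the cut was
the alternative, and renormalization is the documented choice. Donor and
recipient are imputed independently, and any score family is averaged over
the candidate product with product weights. Consequences: imputed scores are
convex combinations (never outside the candidate min/max), and an
unambiguous typing reproduces direct scoring exactly.

## Cohort pooling and statistics

Pregnancy cases contribute up to three records (one per mismatched,
non-homozygous Class I locus; matched and homozygous loci carry no
immunizing mismatch). Transplant cases contribute one record per locus,
dropping records whose four score families are all zero — with
intermediate-resolution typing that is the only reliable mark of a matched
locus. Scores are standardized within locus on the post-exclusion analysis
set (centre, divide by the *sample* standard deviation — the n−1 convention,
documented because both conventions are defensible), so effects read "per
1 SD"; surrogate peptide counts are log(1+x)-transformed instead, following
their reported logarithmic hazard shape.

The battery: a two-sample rank test (Mann-Whitney form — the validation
design names the signed-rank test but compares two independent groups, so
the rank-sum form is the defensible reading; exact for combined n ≤ 20, by
the exact Wilcoxon distribution without ties or full enumeration on
mid-ranks with ties, normal approximation with tie correction above);
Spearman correlation on mid-ranks; univariable binomial logistic regression
(Wald 95 % CIs on the log-odds scale, complete separation flagged rather
than reported); bidirectional stepwise selection by AIC starting from the
full model (the "minimal model" framing suggests a full-model start; the
null-model start was the open alternative); and Cox regression with Breslow
tie handling, whose score test coincides with the log-rank test in the
two-group untied case. No multiplicity correction is applied, matching the
validation design. For cross-locus questions, cases mismatched at all three
loci are pivoted wide (per-locus Snowflake z-scores and log peptide counts
as case-level predictors) and each target locus gets the univariable +
stepwise treatment.

## What the synthetic cohorts emulate — and what they do not

The generator exists so every module is testable without clinical data.
One `simulationConfig` + seed determines everything bit-identically.

* **Alleles.** A 50-position grid (a desk-scale stand-in for the ~275
  mature positions of a Class I heavy chain) with 6 alleles per locus in 3
  serologic groups. Surface candidates are 40 % of positions (so designed
  alleles carry exactly 20 surface positions, RSA in [0.45, 1] vs [0, 0.25]
  for buried); a further ~20 % of positions are buried but polymorphic —
  the analogue of peptide-groove polymorphism, which feeds peptide counts
  but not surface mismatches and keeps the two score families from being
  collinear. Two locus-A alleles carry toy α-helix structures (idealized
  backbone, dummy side-chain spheres coarsely sized by residue bulk); their
  truth profile *is* the structure-computed one, making the
  structure-module round-trip exact by construction.
* **Eplet registry.** One single-residue eplet per non-consensus
  configuration at a surface candidate position (capped at 60, ~60 %
  verified): a densely surface-derived registry, which is what ties eplet
  counts to the surface mismatch count by construction and reproduces the
  qualitative correlation ordering (Snowflake closer to verified eplets
  than to peptide counts).
* **Cohorts.** Mothers draw two haplotypes from a 12-row frequency table;
  children inherit one maternal haplotype plus an independent draw.
  Per-locus CSA is Bernoulli with logit p = β₀ + β·z(true Snowflake),
  β₀ = logit(0.21) (the pooled positive fraction of the emulated pregnancy
  validation) and β = log(1.63) per SD (its reported Snowflake odds
  ratio — used as generator *input*, not as a reproduction claim).
  Transplant cohorts draw donor and recipient independently; DSA times are
  exponential with log-hazard log(1.32)·z, baseline hazard 0.025/yr,
  censoring uniform on (0, 10] years — roughly a 10 % per-record event
  rate. A degraded typing view (serologic antigens, 30 % multiple-allele
  codes) exercises imputation against known truth. Bead panels get
  log-normal MFI (baseline median 30, noise SD 0.3 on the log scale,
  targets at 3000) and the sample-specific calling rule MFI > 100 and
  > mean(self) + 3 SD(self).
* **Presentation predicate.** The generators pass a deterministic
  hash-based predicate accepting ~30 % of (peptide, presenter) pairs — the
  pluggable-contract path, presenter-dependent so presenter-locus scores
  are not collinear; the package default remains accept-all.

Not emulated: real HLA allele frequencies or linkage, real registry
content, real folds, Class II structures, antibody strength. Passing tests
therefore demonstrate *internal* correctness (score definitions, pooling
rules, estimator calibration), not clinical reproduction: the validation
cohorts' printed effect sizes derive from restricted clinical data and are
deliberately only echoed as generator inputs.

## Problem sizes used in the checks

The bundled checks run at desk scale, chosen as the smallest sizes at which
the statistical properties are stable: parameter recovery uses 50 replicate
cohorts of 600 pooled records (≈ the pooled pregnancy analysis size) from
one allele pool; the correlation-ordering check uses 20 replicate cohorts at
the default 231 cases; oracle comparisons use 200 random genotype pairs and
100 imputation fixtures.

## Known limitations

* The k-nearest predictor is a contract reference, not a serious
  structure-from-sequence model; predictions for sequences far from the
  training set revert toward training means.
* The surrogate peptide count is not a binding predictor; absolute values
  are meaningless, only their mismatch-driven variation is used.
* Alignment-based position mapping assumes the locus group shares one grid;
  sequences under 70 % identity to the consensus are rejected rather than
  force-fitted.
* The Shrake-Rupley implementation is quadratic in atom count per structure
  and intended for single-protein structures, not large complexes.
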