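---
title: "Methods: brain-eQTL Mendelian randomization for target discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-eQTL Mendelian randomization for target discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetMR)
```

## The design

`targetMR` estimates the causal effect of a gene's brain expression on
disease risk by two-sample Mendelian randomization, using a single clumped
cis-eQTL per gene as the instrument, and then asks whether the eQTL and
GWAS association signals in the surrounding region are driven by the same
causal variant. The two steps answer different failure modes: the MR
estimate can be non-zero merely because the instrument is in LD with an
independent disease variant, and colocalization is what rules that out.
Downstream modules probe the two remaining threats to validity —
directionality (does disease drive expression rather than the reverse?) and
horizontal pleiotropy (does the instrument act on disease through a pathway
other than this gene?).

The MR step assumes the instrument (i) associates with expression (checked
via PVE and the Cragg–Donald F), (ii) shares no confounder with the outcome
(plausible for germline genotype), and (iii) affects the outcome only
through expression (probed, not guaranteed, by the PheWAS and molecular
pleiotropy scans). A single-instrument design cannot use Egger-type checks
in the forward direction; those estimators are reserved for reverse MR,
where the disease contributes many instruments.

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| instrument p-threshold | 5e-8 | strict (<); genome-wide significance |
| clump r² | 0.001 | pairwise r² above which a weaker record is removed |
| clump window | 10 Mb | total width centred on the index SNP (± 5 Mb) |
| MHC mask | chr6:24–36 Mb | inclusive, hg19; removed before selection |
| palindrome band | 0.08 | drop A/T, C/G variants with eaf within 0.08 of 0.5 |
| MR alpha | 0.05 | Bonferroni-corrected over all tests actually run |
| coloc window | ± 500 kb | around the instrument, boundaries inclusive |
| coloc priors | 5e-4 / 5e-4 / 5e-5 | p1, p2, p12 per SNP |
| ABF prior SD | 0.15 / 0.2 | quantitative traits / case-control log-odds |
| PP4 pass | > 0.70 | strict |
| heterogeneity flag | q_p < 0.001 | Cochran's Q across tissues, strict |
| proxy-GWAS rescale | ×2 | log-odds and SE of family-history GWAS |

Two points deserve comment. First, the coloc p-priors above are the values
this analysis design uses; the reference implementation of the ABF method
ships 1e-4/1e-4/1e-5 as its own defaults, so users comparing against other
coloc runs should set priors explicitly. Second, the Cragg–Donald
denominator is `(1 − PVE)·k`; at `k = 1` — the only case the single-SNP
design uses — every parenthesization of the formula agrees, and `F ≈ z²`
for large n (tested to 2%).

## The Wald ratio standard error

The default SE is the first-order delta approximation
`se_out / |β_std|`, the convention of standard two-sample MR tooling, and
the one under which the Wald p-value is exactly the outcome z-test —
which is why the null calibration checks (p < 0.05 rate of 5% under a true
zero effect) use it. For *interval coverage*, however, the neglected
exposure-noise term is not negligible at realistic strengths: with exposure
z ≈ 5–8 and outcome z ≈ 6–10, the ratio γ·σ_x/σ_o ≈ γ√(n_g/n_x) is close
to 1, and first-order intervals cover at roughly 80%. `waldRatio()`
therefore accepts the exposure SE (`seExposure`) and then uses the full
delta variance `se_o²/β_x² + β_o² se_x²/β_x⁴`; the parameter-recovery
checks build their 95% intervals this way, restoring coverage to the
nominal band. Point estimates and p-values are unaffected.

## What the generator emulates — and what it does not

`simulateRegion()` draws marginal z-scores directly at the summary level,
`z ~ MVN(R λ √n, R)`, where `R` is an exact AR(1) LD matrix
(`r_ij = ρ^|i−j|`, positive definite for any ρ ∈ [0,1)) and `λ` holds the
per-SNP joint standardized effects implied by the scenario: `λ_c = √PVE`
for the causal eQTL, `γ·λ` for a disease effect mediated by expression,
an independent direct effect `√gwasPve` for distinct-variant, reverse and
pleiotropic configurations. Betas and SEs are back-filled per allele via
`se = 1/√(2·maf(1−maf)·n)`. Defaults are the study's conditions:
n_eQTL = 1,286 (prefrontal-cortex scale), n_GWAS = 50,000 effective,
eQTL PVE 5% (2–5% in the recovery checks), γ = 0.2, 100 SNPs at ρ = 0.9.
`gwasPve = 0.01` for direct disease loci — a strong hit (z ≈ 22 at
n = 50,000), chosen so that the reverse-causation scenario has a
disease→expression path that is detectable in principle at n = 1,286 rather
than vacuously invisible.

This construction gives exact LD, known truth, and determinism from one
seed (sub-draws continue a single RNG stream). It does **not** emulate:
real haplotype block structure or allele-frequency/LD coupling; sample
overlap between exposure and outcome studies; population stratification;
case-control ascertainment beyond the effective-n log-odds approximation;
or multiple causal variants per trait per region. Passing the simulation
checks therefore demonstrates the statistical machinery is correct under
the stated model, not that the pipeline is robust to those real-data
complications.

## Numerical and procedural choices

- **Colocalization in log space.** Strong eQTLs reach |z| ≈ 40, where
  `exp(labf)` overflows; all hypothesis sums use log-sum-exp, and the H3
  cross term `L1·L2 − L12` uses a guarded log-difference that returns
  exactly zero probability for a single-SNP region. Agreement with a naive
  enumeration oracle is tested at 1e-8 where the oracle is finite.
- **Clump determinism.** Ties on p are broken by (chrom, pos, variant id),
  so clumping is invariant to input order. Variants absent from the LD
  panel are dropped (with a warning) before clumping rather than treated as
  independent. The clump window is the *total* width: records within half
  the window of the index SNP are eligible for removal.
- **Palindromic variants.** Allele letters carry no strand information for
  A/T and C/G variants, so orientation is inferred from allele frequency
  alone, and dropped entirely when either study's eaf is within 0.08 of
  0.5. Harmonization is idempotent, and a double sign-flip restores the
  original record.
- **Strictness.** The significance filter, the PP4 pass and the
  heterogeneity flag are all strict inequalities.
- **Permutation p.** The empirical p uses the add-one estimator
  `(1 + #{null ≥ obs})/(n + 1)`, which cannot report zero; with 10,000
  iterations and no exceedances this reads 1e-4, consistent with reporting
  conventions for permutation tests.
- **Binary-trait correlations.** For Steiger filtering the instrument-
  outcome correlation on a case-control trait is proxied by `z/√n` on the
  observed scale. This is not a latent-scale conversion; it preserves the
  ordering of correlation magnitudes, which is the only property the
  direction call uses.
- **Degenerate inputs.** eaf ∈ {0,1} raises a degenerate-frequency error in
  standardization; a zero exposure effect raises an undefined-ratio error;
  PVE ≥ 1 is clipped with a warning; 2-instrument Egger and 1-instrument
  IVW are errors, with reverse MR falling back to a flagged Wald ratio for
  a single surviving instrument.
- **Annotation lookups are offline.** Allelic-series and druggability
  evidence enter as a plain TSV (`gene_id`, `allelic_series`, `druggable`,
  `adverse_traits`) rather than live database queries; the safety criterion
  reports flags instead of hard-excluding, since "satisfying safety
  profile" is a judgement call on the flagged traits.

## Calibration check design

The parameter-recovery and calibration checks instrument each simulated
region at its *true* causal variant (the generator's truth record exists
for this purpose). Gating recovery runs on p < 5e-8 would discard roughly
half the replicates at PVE = 2% (mean z ≈ 5.1) and condition the survivors
on inflated exposure effects — a winner's-curse selection the recovery
question is not about. The pipeline tests exercise the full
selection-then-estimation path separately on stronger planted signals.
Problem sizes: 500 regions of 25 SNPs for recovery, 200 regions of 100 SNPs
per colocalization scenario, 200 of 15 SNPs per Steiger scenario, 2,000 of
5 SNPs for null calibration, 100 pooled 10-locus replicates for reverse-MR
calibration.

## Known limitations

- Single-variant colocalization: multiple causal variants in a region can
  obscure or mimic sharing; SuSiE-style conditional colocalization is out
  of scope.
- The weighted-median SE is a parametric bootstrap (1,000 draws, explicit
  seed required), not the analytic approximation; the two differ slightly
  in small instrument sets.
- Effective-n handling of case-control outcomes means odds-ratio
  interpretation is approximate for very unbalanced designs.
- No genome-build liftover: coordinates are taken as given, with the build
  carried as a tag.
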