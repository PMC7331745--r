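---
title: "Methods: ceRNA network inference and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A competing endogenous RNA (ceRNA) circuit consists of a circRNA and an
mRNA that share miRNA response elements (MREs) for the same miRNA. Under
the sponge hypothesis, an induced circRNA titrates the shared miRNA away
from the mRNA. In a case/control expression study this predicts a joint
signature that `cernet` uses as its inference target:

* circRNA and mRNA are differentially expressed in the **same** direction,
  the miRNA in the **opposite** direction;
* both the circRNA and the mRNA carry sequence-predicted MREs for the
  miRNA;
* across samples, miRNA–circRNA and miRNA–mRNA correlations are negative
  and the circRNA–mRNA correlation is positive.

The pipeline operationalizes each clause as a filter and finally scores
circRNA–mRNA pairs by how surprising their *sharing* of validated miRNA
partners is: with `M` differentially expressed miRNAs, `K` validated
partners of the circRNA, `n` of the mRNA and `k` shared, the ceRNA score
is the hypergeometric tail `P(X >= k)`, `X ~ Hypergeometric(M, K, n)`.
This is the standard shared-miRNA enrichment statistic for ceRNA pairs;
we state it explicitly because "ceRNA score" is often left undefined in
applied work. With study-scale universes (`M` near 22) a single shared
partner (`k = K = n = 1`) has `p = 1/M < 0.05`, which is why final
networks may legitimately contain single-miRNA links; `k_min` and the
candidate threshold are exposed.

Assumptions worth stating: the three filters are treated as independent
evidence (no joint model); correlations are computed across the pooled
groups, so the differential-expression signal itself contributes to the
correlation — this is intentional and matches how "prominently coexpressed
pairs" behave at n = 6; and direction consistency is a hard constraint,
not a prior.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fc_threshold`, `alpha` | 1.5, 0.05 | DE filter: fold change >= 1.5 (applied as `2^|log2fc| >= 1.5`, boundary inclusive) and raw p < 0.05; `use_q` filters on BH q instead |
| `r_min`, `coexpr_alpha` | 0.9, 0.05 | edge filter; at n = 6 the |r| needed for p < 0.05 is 0.811, so `r_min` is the binding constraint |
| `score_min` | 140 | duplex alignment threshold; a full 21-nt complement of miRNA positions 2–22 scores exactly 140 (7 seed pairs doubled + 14 plain matches) |
| `energy_max` | −20 kcal/mol | additive pair-energy threshold |
| `k_min`, `cerna_alpha` | 1, 0.05 | candidate filter on the hypergeometric score |

Alignment scoring constants (`align_params()`): Watson–Crick +5, G:U +2,
mismatch −3, gap open −8, gap extend −2 (a run of g gaps costs
`open + (g−1)·extend`), and pair scores over miRNA positions 1–8 are
doubled. The doubled region is stated by its worked consequence: an 8-nt
perfect WC duplex lying entirely in that region scores 8 × 5 × 2 = 80.
Seed-*type* calls (6mer/7mer-m8/7mer-A1/8mer) use the conventional
positions 2–7/2–8 plus the A1 anchor; the A1 anchor is an A on the target
regardless of complementarity. These constants are package defaults in the
spirit of common miRanda usage, not claims about the miRanda binary.

The energy model is deliberately a crude additive per-pair approximation
(G:C −3, A:U −2, G:U −1, mismatch/gap +0.5), not nearest-neighbor
thermodynamics: it keeps the stage dependency-free, monotone and exactly
testable. Users wanting physical energies should rescan final candidates
with a thermodynamic tool.

## Coordinates and other conventions

All site coordinates are 0-based half-open on the target, 5'→3' as
supplied. circRNA targets are scanned as circular sequences: the sequence
is extended by its first (miRNA length − 1) nt, start coordinates are
reported modulo the original length, and `end` may exceed the length for a
junction-spanning site. Size factors are median-of-ratios rescaled to
geometric mean 1, so renormalizing an already-normalized matrix returns
unit factors (log2 fold changes are invariant to this rescale). Degenerate
DE features (zero within-group variance in both groups) get p = 1 when the
means agree and p = 0 otherwise, with a logged count. Constant features in
the correlation stage get (r = 0, p = 1) with a warning. All outputs are
sorted lexicographically so repeated runs are byte-identical; the GMT
reader takes the union of members as the universe unless one is supplied
(writing a collection does not persist an explicit universe).

## The synthetic study

`simulate_dataset()` emulates the profiled study: 3 case (OVX) vs 3
control samples; 60 circRNAs and 600 mRNAs as negative-binomial counts
(`Var = mu + alpha mu^2`, dispersion 0.1, log-normal baselines around
exp(6) counts, library size factors drawn log-uniform in [0.7, 1.4]); 40
miRNAs as Gaussian log2 intensities (residual SD 0.25). Four planted
circuits occupy the first features of each class with alternating
directions; planted |log2FC| defaults to 1.5 and the validation studies
in this package use 2, the mid-range of qPCR-validated effect sizes in
this setting. Additional DE features without binding sites (16/18/76)
bring the DE tables to 20 circRNAs, 22 miRNAs and 80 mRNAs — the 22 DE
miRNAs matter because they are the hypergeometric universe `M`.

Two generator choices deserve explanation:

* **Planted sites are 21-nt full complements** (miRNA positions 2–22),
  with the target base opposite miRNA position 1 pinned to a base that
  neither pairs with position 1 nor is an A. A 7-nt seed-only site cannot
  clear `score_min = 140`/`energy_max = −20`, so full complements are the
  minimal site that guarantees threshold clearance, and the pinned base
  makes recovery coordinate-exact and the type call deterministic
  (7mer-m8).
* **The sponge factor is a shared fraction of the biological variance,
  not an added one.** Each circuit has a per-sample latent factor
  `z_s ~ N(0,1)`; a fraction `sponge_rho = 0.95` of each member's
  biological variance is carried by `z` (positive loading for circRNA and
  mRNA, negative for miRNA) and the member's residual NB dispersion is
  reduced so its *marginal* dispersion stays at 0.1. A purely additive
  factor strong enough to push |r| above 0.9 at n = 6 would inflate
  within-group variance and destroy the very DE power the circuit needs;
  the decomposition delivers both properties at once and is the
  biologically sensible reading (sponge coupling is part of, not added
  to, biological covariation).

What the generator does **not** emulate: batch effects, isoform structure,
microarray probe effects, non-uniform nucleotide composition, dispersion
trends over expression, and outlier samples. Passing tests therefore show
the inference machinery is correct and calibrated under its own model;
they do not show robustness to the artefacts of real sequencing data.

## Measured operating characteristics

Numbers below are computed by the test suite and `scripts/acceptance.R`;
they are properties of the method at the study's size, not tuning targets.

* **Type-I error.** The Welch t on log2(x+1)-transformed NB counts at
  3 vs 3 is *conservative*: the null rejection rate at nominal 0.05 is
  about 0.033 (3 × 1000 null features). This is the familiar small-sample
  heavy-tail effect; it means the DE stage under-calls rather than
  over-calls.
* **Planted-circuit recovery** at |log2FC| = 2 is about 0.88 over 50
  seeds. The loss is almost entirely DE power: per count feature the
  Welch test has ~0.95 power at these settings and a circuit needs both
  its circRNA and mRNA to pass, capping recovery near 0.9; coexpression,
  MRE recovery and scoring lose ~1% combined. With three animals per
  group this is an honest ceiling of the design, not an implementation
  artefact.
* **Specificity.** On null simulations (no circuits planted, background
  DE present) the pipeline emitted zero triplets in 100/100 seeds, and
  recovered circuits never mix members across circuits.
* **Enrichment calibration.** The hypergeometric ORA is exactly as
  conservative as its discreteness forces: for the null fixture used
  (universe 1000, sets and queries of 200) the attainable level below
  0.05 is 0.0484 and the empirical rate matches it within Monte-Carlo
  error.

## Problem sizes used by the automated checks

Unit tests run the generator at desk scale (12–60 circRNAs, 24–40 miRNAs,
60–600 mRNAs); the end-to-end checks use 50 recovery seeds and 100 null
seeds at the full default scale; alignment DP/enumeration equivalence uses
106 instances of length ≤ 12 (the enumeration oracle is exponential);
hypergeometric enumeration is exhaustive for universes ≤ 12. The whole
suite and the acceptance script each run in a few minutes on one CPU.

## Known limitations

* No NB GLM or dispersion shrinkage: with three replicates per group,
  Welch-on-log is transparent but underpowered relative to
  information-sharing methods; this is the dominant loss mechanism above.
* Correlation thresholds at n = 6 are coarse; |r| ≥ 0.9 admits ~1.5% of
  null pairs two-sided and the estimate is highly variable.
* The energy model ignores stacking, loops and accessibility;
  conservation and CLIP evidence are out of scope.
* The hypergeometric ceRNA score treats partners as exchangeable and
  ignores site multiplicity (`n_sites` is reported but not modelled).
* Enrichment uses flat gene sets; GO DAG propagation is treated as
  annotation preparation, upstream of this package.
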