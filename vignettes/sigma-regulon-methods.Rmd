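---
title: "Methods: sigma-factor regulon assignment from a deletion-strain panel"
author: "sigregulon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sigma-factor regulon assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigregulon)
```

## The scientific problem

Group 2 sigma factors of *Synechocystis* sp. PCC 6803 (SigB, SigC, SigD,
SigE) are dissociable RNA-polymerase subunits that re-target transcription
during stress acclimation. Their regulons — the genes whose expression
depends on each factor — are defined operationally from a deletion-strain
panel: the control strain CS (all four factors), single mutants ΔsigB and
ΔsigD, and the triple inactivation strains ΔsigBCE (retaining only SigD)
and ΔsigCDE (retaining only SigB). Because ΔsigC and ΔsigE single mutants
are not in the panel, SigC- and SigE-dependent genes are identifiable only
as a merged "SigC-or-E" class.

The package turns that design into a tested pipeline: differential
expression of each mutant against CS per condition, a rule engine that maps
the four-strain pattern of calls to a regulon label, and a simulator that
plants known sigma dependencies so the whole chain can be validated by
parameter recovery.

## The count model and the differential-expression stage

Counts are modelled as negative binomial with mean $\mu$ and dispersion
$\alpha$, variance $\mu + \alpha\mu^2$ — the standard overdispersed model
for biological replicate RNA-seq counts. The same parameterization is used
by the simulator and the test, so the test is exactly matched to the data
it is validated on.

The stage is deliberately self-contained and simple enough that every step
has an independent oracle:

* **Normalization.** Median-of-ratios size factors: the reference profile
  is the per-gene geometric mean over all samples, restricted to genes
  with no zero count; sample $j$'s factor is the median of
  $y_{ij}/\text{geomean}_i$. Identical columns give factors exactly 1.
  With no zero-free gene the function stops rather than inventing a
  pseudo-reference.
* **Dispersion.** Per-gene method of moments on normalized counts, pooling
  the within-group variance over all (strain, condition) replicate groups:
  $\hat\alpha_i = \max(\alpha_\text{floor}, (v_i - m_i)/m_i^2)$ with
  $\alpha_\text{floor} = 10^{-8}$. The floor keeps the Poisson limit
  numerically stable. In the full design the pooled estimate has 30
  degrees of freedom, which is what makes the downstream Wald test usable
  at $n = 3$ per group. No shrinkage toward a mean–dispersion trend is
  applied; that is a deliberate simplification, not an oversight.
* **Wald test.** Per gene, a two-group NB model with offsets
  $\log(\text{sf}_j)$ is fitted by Newton iteration on each group's
  log-mean (score $\sum_j (y_j-\mu_j)/(1+\alpha\mu_j)$, expected-information
  steps, convergence at $10^{-10}$). The reported `log2fc` is the
  test-over-reference log2 ratio; its standard error uses the observed
  information at the optimum; $p$ is the two-sided normal tail of
  `log2fc/se`. No fold-change shrinkage, no independent filtering, no
  outlier replacement.
* **Multiple testing.** Benjamini–Hochberg step-up within each contrast
  table separately, matching per-contrast gene lists. Untestable genes are
  excluded before adjustment.

### Degenerate inputs

A gene with all-zero counts in both groups is flagged `untestable`
(`log2fc = 0`, `p = 1`, FDR `NA`). With all zeros in exactly one group the
empty group's count total is replaced by 0.5 (a continuity correction that
keeps the Wald statistic finite) and the fold change is capped at ±10 log2
units; the flag `zero_group` marks these estimates as boundary values.

### Calibration

The pipeline's null behaviour was characterized by simulation (truth-free
panels, 2000 genes, $\alpha = 0.1$): the per-contrast fraction of raw
$p < 0.05$ averages about 6 %. Roughly 5.4 points of that come from the
normal approximation of the Wald statistic at three replicates per group
and the remainder from plug-in dispersion noise; at the FDR level the
procedure is strongly conservative under the null (≈ 0.1 % of genes at
FDR < 0.05). Users should treat raw p-values near 0.05 as approximate;
decisions in this package are taken on FDR.

## The regulon rule engine

A gene is *regulated* in a mutant when FDR < `fdr_threshold` (default
0.05), with direction from the sign of `log2fc`. A gene becomes a regulon
*candidate* when it is regulated **and** at least two-fold changed
(|log2fc| ≥ `lfc_threshold`, default 1) in at least one of the four
mutants; inside the rules, sub-two-fold but significant calls still count.
The candidate gate requires significance as well as fold change, so a
large but noisy fold change cannot seed a regulon — the operational
definition of "regulated" is FDR-based throughout.

For a candidate with statuses $(s_B, s_D, s_{BCE}, s_{CDE})$:

| label | pattern |
|---|---|
| SigB (down) | DOWN in ΔsigB and ΔsigBCE; ΔsigD NS; ΔsigCDE NS or UP |
| SigB (up) | mirrored, with DOWN tolerated in ΔsigCDE |
| SigD (down) | DOWN in ΔsigD and ΔsigCDE; ΔsigB NS; ΔsigBCE NS or UP |
| SigD (up) | mirrored, with DOWN tolerated in ΔsigBCE |
| SigCorE | same-direction call in both triple mutants; both single mutants NS |
| shared | any other pattern with ≥ 2 regulated strains |
| none | everything else |

"Not in the other strains" is read literally as NS in the other single
mutant; an opposite-direction call is tolerated only in the complementary
triple mutant, exactly where the definitions allow it. The strain that
retains the factor can plausibly over-shoot in the opposite direction
because the remaining factor is over-produced in triple mutants, which is
why the exception exists. `shared` is a reporting category, not a regulon.
The six specific rules are mutually exclusive by construction (each pins
a strain to incompatible statuses), so the labels partition the
candidates; the package verifies this, and agreement with an independently
written transliteration of the rules, over all $3^4 = 81$ patterns.

Sigma-factor genes deleted in a given strain are masked from that strain's
status calls (a deletion's own "expression change" is a genotype artifact).
A gene whose rule position is masked is flagged `unclassifiable` rather
than silently dropped.

Regulon genes are additionally annotated with the control strain's own
stress response (CS stress vs CS standard, FDR-and-sign rule without a
fold-change gate), and membership is compared across conditions as a tidy
overlap table.

## The synthetic-data generator

The simulator emulates the study design: 5 genotypes × 3 conditions × 3
biological replicates = 45 samples. Its defaults are the package's fixed
reference conditions:

| parameter | default | rationale |
|---|---|---|
| baseline mean $\mu_i$ | log-normal, median 200, sdlog 1 | typical bulk RNA-seq per-gene depth; spans ~2 orders of magnitude |
| dispersion $\alpha$ | 0.05 | mid-range biological-replicate overdispersion for bacterial cultures |
| size factors | uniform on [0.7, 1.4] | realistic library-size spread |
| replicates | 3 | the study design |
| planted effect | 2 log2 units | a four-fold change, typical of clearly regulated stress genes |

A planted effect (gene, sigma, condition, direction, effect size) acts
multiplicatively on the mean exactly in the genotypes lacking the
governing factor: a SigB effect applies in ΔsigB and ΔsigBCE; a SigD
effect in ΔsigD and ΔsigCDE; a SigC-or-E effect only where *both* C and E
are missing, i.e. in both triple mutants. "Activated" targets decrease
(multiplier $2^{-\text{effect}}$) and "repressed" targets increase when
the factor is absent. The control strain is never affected — a property
tested over every effect type. Output is a deterministic function of the
seed.

The generator reproduces the statistical structure the analysis assumes —
NB counts, library-size variation, condition-specific multiplicative
effects — and deliberately nothing else: no batch effects, no GC or
length bias, no correlated genes (operons), no uncertainty in the
genotype labels. Passing recovery tests therefore demonstrates that the
pipeline correctly inverts its own data model, not that it is robust to
everything real data can do; the deposited study data remain the ground
truth for biology.

## Validation results computed by the package

* Rule engine ≡ independent transliteration on all 81 patterns (exact).
* BH step-up ≡ brute-force $O(m^2)$ oracle on 500 random vectors
  ($\le 10^{-12}$).
* Normalization identities at $10^{-10}$: identical columns give unit
  factors; scaling a sample scales its factor by exactly $c$ relative to
  the others; contrasts not containing the scaled sample, and any global
  rescaling of the size-factor vector, leave every log2fc exactly
  unchanged. (Contrasts containing a rescaled sample shift slightly —
  rescaled counts are genuinely different data to a count model — so
  invariance is stated for the identities that actually express offset
  correctness.)
* Null calibration: per-contrast raw-p rate ≤ 7 %, FDR-level rate well
  below 5 % (2000 genes, $\alpha = 0.1$).
* End-to-end recovery: with 100 planted genes per class (six classes)
  among 3000 genes, ≥ 90 % of planted genes get their planted label and
  ≤ 5 % of unplanted genes get any label; observed ≈ 97–99 % and
  ≤ 0.1 % across seeds.

Problem sizes (2000–3000 genes, 45 samples) were chosen so a full
validation run completes in seconds while keeping per-class recovery
counts at 100, large enough for stable rates.

## Design choices and limitations

* The package implements its own DE stage rather than wrapping an
  existing one so that every step is small, documented and
  oracle-testable; installed reference implementations are used in the
  test suite as independent cross-checks (size factors, per-gene GLM
  fits). Exact replication of any particular DE tool's marginal calls is
  a non-goal, and published regulon sizes from the original sequencing
  data are not expected to be reproduced from synthetic panels.
* FDR and fold-change thresholds are configuration values (defaults 0.05
  and 1). The two-fold gate additionally requiring significance is a
  package decision; the alternative (fold change alone) admits noisy
  low-count genes as candidates.
* Reporter utilities implement the arithmetic only: luminescence/OD₇₃₀
  activities, background-free fold inductions by default (background
  subtraction is a flag, off because reporter-free background is
  negligible), dilution factors attaching to the measurement they
  immediately precede, and OLS log-linear growth rates over a window
  (≥ 3 points). Wet-lab fold values are measurements, not computable
  quantities.
* Growth-rate comparison between strains (testing, error bars) is out of
  scope, as are read alignment, counting and visual heat-map styling —
  heat maps are exported as log2FC matrices with literal `NA` sentinels.
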