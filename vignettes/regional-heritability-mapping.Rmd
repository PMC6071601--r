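---
title: "Two-stage regional heritability mapping for inbred crop panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage regional heritability mapping for inbred crop panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beanrhm)
```

## The problem

Diversity panels of inbred crop lines (the motivating case is common bean,
*Phaseolus vulgaris*, with its strongly divergent Andean and Mesoamerican
gene pools) are phenotyped in augmented field designs across environments
and genotyped with a mix of codominant SNPs (coded $-1/0/1$) and dominant
presence/absence DArT markers (coded $-1/1$). Single-marker GWAS in such
panels misses variance that is spread over several linked loci of small
effect. Regional heritability mapping (RHM) instead fits a variance
component for a sliding genomic window and asks how much heritability the
window carries, capturing both common and rare local variants.

`beanrhm` implements the full two-stage pipeline:

1. **Stage 1 — phenotype adjustment.** Per environment and jointly, the
   augmented-block mixed model
   $y = Xf + Zg + Sb + Tk + \varepsilon$
   is fitted by REML, where $f$ holds the fixed check means and
   per-environment population means, $g$ the random genotypic effects of
   the test accessions, $b$ the random block effects and $k$ the random
   accession-by-environment interaction (joint scope only). BLUPs
   $\hat g$ are deregressed by their reliabilities,
   $y^{*} = \hat g / r^2_{g\hat g}$, to undo shrinkage before mapping.
2. **Stage 2 — mapping on $y^{*}$.** A genomic relationship matrix
   $G = W W^\top / \sum_i 2 p_i (1 - p_i)$ is built from the centered
   marker codes. The association scan fits
   $y^{*} = X\beta + m_i + u + \varepsilon$, $u \sim N(0, G\sigma^2_u)$,
   per marker; the regional scan fits
   $y^{*} = X\beta + u + v + \varepsilon$,
   $v \sim N(0, G_{REG}\sigma^2_v)$, per 2-Mb window (1-Mb step) and
   tests $\sigma^2_v = 0$ by LRT. Both scans are calibrated by seeded
   permutation with Bonferroni correction at a global $\alpha = 0.05$.

## Design choices where the design was open

**Stage-1 kinship.** The genotypic covariance in stage 1 is the identity:
the panel is a pedigree-free diversity collection, and genomic kinship is
deliberately reserved for stage 2, so marker information is not used
twice.

**Across-site genetic correlation.** The correlation of genotypic values
across environments is computed as
$r_{gl} = \sigma^2_g / (\sigma^2_g + \sigma^2_k)$, the exact correlation
implied by the compound-symmetric interaction model. The
covariance-over-sum-of-variances form sometimes printed in field reports,
$\sigma_{g_1 g_2} / (\sigma^2_{g_1} + \sigma^2_{g_2})$, is not a
correlation (it does not equal 1 when the two sites agree perfectly); it
is exposed as `rgl_formula = "paper_literal"` in [genetic_params()] and
equals half the correlation form under compound symmetry.

**Joint-scope deregression** uses the joint-model $\hat g$, not an average
of per-environment BLUPs: the joint model already weights environments by
their information content.

**DArT columns in the GRM.** The $\sum 2p_i(1-p_i)$ denominator assumes
dosage coding. Dominant $-1/1$ codes have variance $4p(1-p)$ at presence
frequency $p$ (not $2p(1-p)$), so the literal construction under-scales
DArT-heavy panels. The literal form is the default for fidelity to the
standard construction; `scale = "empirical"` in [build_grm()] replaces
the denominator by the summed empirical column variances.

**Marker heritability.** No standard definition exists for the
heritability attached to one marker in this design. The implemented
convention is $h^2_{GWAS} = 2pq\,\hat m^2 / (2pq\,\hat m^2 + \sigma^2_u +
\sigma^2_\varepsilon)$, chosen because the reporting style prints $2pq$
alongside the marker heritability. For fully inbred panels the realized
code variance is about $4pq$, so this convention reports roughly half of
the variance a causal marker really contributes; [marker_h2()] accepts
`var_marker` to use the empirical code variance instead, and the test
suite verifies that this version recovers planted variance shares.

**Scan approximation.** Background variance components are estimated once
under the no-marker null and held fixed across markers (the standard
two-step mixed-model approximation); `exact_per_marker = TRUE`
re-estimates them per marker. The tested marker stays in $G$, and the
whole-genome $G$ is used for every window of the regional scan — both are
the conservative conventions; `exclude_region_from_G` implements the
alternative.

**Window grid.** Windows are half-open $[s, s + 2\,\mathrm{Mb})$ starting
at 0 with a 1-Mb step while $s < L - 1\,\mathrm{Mb}$, the last window
truncated at the chromosome end, and windows with fewer than 2 markers
dropped. Overlapping windows test correlated hypotheses; the Bonferroni
divisor still uses the raw window count, which is conservative.

**Permutation thresholds.** Window LRTs sit on a boundary under the null
(about half of the null statistics are exactly 0), so $\chi^2$
asymptotics are unreliable; significance always comes from the pooled
permutation null. The $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture
p-value is reported as a fast pre-screen only.

## The REML engine

All models above share one estimation core. The general path
([fit_reml()]) absorbs arbitrary PSD covariances $K_j$ by the
substitution $u_j = L_j \alpha_j$ and solves Henderson's mixed-model
equations with a sparse Cholesky factorization, profiling the residual
variance and optimizing log variance ratios from a deterministic
equal-split start (Brent for one ratio, Nelder–Mead with one restart
otherwise), with an explicit boundary refit at $\theta_j = 0$ whenever a
ratio is pinned below $10^{-6}$. Convergence is declared at a relative
criterion change below $10^{-10}$.

The scans use a specialized path: everything is rotated once into the
eigenbasis of $G$, where the null model's covariance is diagonal (one
$O(n)$ likelihood evaluation per step) and a window adds a low-rank block
handled by the Woodbury identity in compiled code, $O(n m^2)$ per
evaluation for $m$ window markers. A window whose profiled restricted
likelihood has non-positive slope in $\sigma^2_v$ at zero (given the
null's variance ratio) is reported at the boundary without optimization;
this is exact, not an approximation, because the null fit already
maximizes over the remaining parameter at $\sigma^2_v = 0$. The generic
and specialized paths use the same profiled criterion, and the test suite
asserts they agree to numerical tolerance (and match `lme4` and
closed-form estimators where those apply).

Degenerate inputs: a design with one plot per accession and no checks
leaves block and genotype variance confounded and is rejected; two random
terms with proportional marginal covariances trigger a
non-identifiability warning and typically a boundary fit; accessions with
non-positive reliability get a missing deregressed value with a warning.

## What the generator emulates — and what it does not

[sim_config()] defaults reproduce the emulated study conditions: 580
phenotyped accessions of which 181 are genotyped, 6677 markers (3234 SNP,
3443 DArT) on 11 chromosomes totalling 513.54 Mb, two gene pools with
Balding–Nichols divergence ($F = 0.4$, a strongly structured pair, split
69:112), five generations of selfing (heterozygosity decays by half per
generation, landing under 1%), two environments, 20 augmented blocks of
29 accessions plus 4 checks, and three traits configured at joint
heritabilities 0.81/0.79/0.43 with interaction coefficients
0.17/0.21/0.41. Where the study conditions do not pin a value, a
realistic one was chosen once: founder-mosaic recombination at 0.5
switches/Mb (LD decays on the Mb scale, matching the 2-Mb window
calibration), 30 founder haplotypes per pool, 2% missing calls, Gaussian
plot residuals, block variance 5% of the plot variance. The 1–9 ordinal
field scores are simulated as continuous, as they are analyzed.

Component effects are rescaled so realized sample variances hit the
configured shares exactly, which removes one layer of Monte-Carlo noise
from recovery tests. Causal markers are drawn from the genotyped panel
(`hidden_causal` drops them to study imperfect LD).

Real data differ in ways the generator does not model: domestication
bottlenecks and selection sweeps, heterogeneous recombination (the
centromeric marker deserts of real DArT panels), genotyping error,
spatial field trends, and non-Gaussian residuals for ordinal traits.
Passing recovery tests therefore demonstrates correctness of the
estimators under their assumed model, not robustness to all field
realities.

## Problem sizes used by the test suite

The distributional checks run at deliberately scaled designs chosen to
make their Monte-Carlo error small relative to the asserted margins:
family-wise error calibration at 200 accessions, 1000 markers, ~50
windows, 200 permutations and 10 null replicates (the exact binomial
acceptance region at $p = 0.05$ rejects at 3 or more false-positive
replicates); planted-window recovery at $n = 500$ over 20 seeds; stage-1
bias at $n = 500$, two environments, 20 seeds; the power contrast at
$n = 260$ (dispersed regime, dense 1200-marker map) and $n = 250$
(single-large-effect regime) with 100 permutations per method. The GRM
oracle check compares against a naive double loop on a simulated
100 × 1000 panel at $10^{-10}$.

The dispersed regime deserves one note: "many small effects" is
implemented as 30 equal-variance causal loci sharing the window's
regional heritability, under weak local LD, in an unrelated panel
scanned against a dense map. With markedly fewer loci the arithmetic
forces per-locus variance shares large enough that a
Bonferroni-thresholded single-marker scan detects them individually at
any sample size where the regional scan has power — the two methods then
rise and fall together and no clean contrast exists. Spreading the same
regional variance thinly, and letting the marker count raise the
single-marker threshold while the window count barely moves the regional
one, is what makes each marginal association small while the window
aggregate stays fully detectable.

## Known limitations

* Single-trait models only; no multivariate REML, no spatial field
  correction, no threshold models for ordinal scores.
* The regional scan fits one window at a time; adjacent significant
  windows are merged post hoc rather than modelled jointly.
* Bonferroni over correlated, overlapping windows is conservative.
* Dense algebra throughout: designed for panels of hundreds of
  accessions, not tens of thousands.
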