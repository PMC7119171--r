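---
title: "Ancestry-informative marker selection: models and methods"
author: "aimselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry-informative marker selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aimselect)
```

# The informativeness model

An ancestry-informative marker (AIM) is a biallelic variant whose allele
frequency differs strongly between ancestral populations. `aimselect`
quantifies this with the Lancaster estimator of independence (LEI), a
mean-square-contingency measure of dependence between two categorical
variables: genotype category $X \in \{mm, mM, MM\}$ and population
membership $Y \in \{y_1,\dots,y_k\}$.

The key modelling step is that the joint table of $X$ and $Y$ is not
observed but *reconstructed from allele frequencies under Hardy–Weinberg
equilibrium* (HWE). For population $j$ with reference-allele frequency
$f_j$ and sample weight $c_j$, the expected genotype counts are
$$\hat n_{1j} = c_j(1-f_j)^2,\quad \hat n_{2j} = 2c_jf_j(1-f_j),\quad
  \hat n_{3j} = c_jf_j^2,$$
which sum to $c_j$ by construction. With $n = \sum_j c_j$, the estimated
joint distribution is $\hat p_{ij} = \hat n_{ij}/n$ and the score is
$$\hat\theta^2 \;=\; \sum_{ij} \frac{\hat p_{ij}^2}{\hat p_{i+}\hat p_{+j}}
  \;-\; 1 .$$

Properties the test suite verifies: $\hat\theta^2 = 0$ exactly when all
$f_j$ coincide; $0 \le \hat\theta^2 \le \min(3,k)-1$ (at most 1 for two
populations, 2 for three or more); invariance to allele relabelling
($f \to 1-f$), to permuting populations with their weights, and to
rescaling all weights by a common factor; and equality with Pearson's
mean-square contingency $\phi^2$ computed independently on the same table.
Because only the relative weights matter, a frequency table without known
sample sizes defaults to equal weights $c_j = 1$; for the worked
three-population example (frequencies 0.79/0.17/0.99) equal weights give
0.7772 and realistic panel sizes (99/103/108) give 0.785 — identical at
the two decimals a display would show.

```{r worked}
lei(c(0.79, 0.17, 0.99), c("CEU", "CHB", "YRI"))
```

## Numerical choices

* The third HWE count is $c_jf_j^2$ — the homozygous-reference term —
  fixed so the three terms always sum to $c_j$.
* Terms with a zero genotype marginal $\hat p_{i+}$ contribute 0 (their
  cells are exactly 0), avoiding 0/0 at fixed alleles.
* The summed statistic carries round-off of order $10^{-16}$ from
  accumulating the marginals; residuals below $10^{-12}$ are therefore
  snapped to exact 0. Dependence that small is far beyond any biological
  resolution, and the snap makes the independence case return a clean 0.
* Missing frequencies yield a missing score and a warning; markers are
  never silently imputed on the frequency path, and missing-score markers
  are dropped at panel construction.
* A single population is a hard error: informativeness is undefined
  without a contrast.

# Genotype-based rankings

When individual-level genotypes (reference-allele counts 0/1/2) are
available, four rankings are offered. The LEI path first estimates
per-population frequencies by allele counting over non-missing samples —
the per-marker non-missing sample numbers are kept as the marker's
weights, so `leiFromGenotypes()` is *bit-identical* to
`leiTable(estimateFrequencies(G))`.

PCA, SVM and random forest have no canonical per-marker score, so the
package fixes standard embedded-feature-selection definitions and exposes
their tuning knobs:

* **PCA** — explained-variance-weighted sum of squared loadings over the
  top `nComponents` (default 2, the usual two-axis ancestry view) of the
  column-standardized matrix. Sign-invariant, hence deterministic.
* **SVM** — one-vs-rest linear soft-margin classifiers (cost default 1);
  score = maximum absolute hyperplane coefficient across populations.
* **RF** — total Gini impurity decrease of a `randomForest` classifier
  (default 500 trees, seed 1), normalised to sum to 1.

Markers with zero variance are dropped from the standardized fits and
scored 0. Missing genotypes are mean-imputed per marker for PCA/SVM/RF
only; the LEI path uses complete-case counts. On data whose structure is
driven by frequency differences, all four rankings agree strongly
(Spearman correlation with LEI above 0.7 in the seeded test).

# Panel construction

`buildPanel()` composes an inclusive score threshold (a marker exactly at
the threshold survives), greedy physical-distance thinning, and an
optional size cap. Thinning visits markers in descending score (ties:
ascending position, then lexicographic id) and keeps a marker only if it
lies at least `spacingKb` kilobases from every kept marker on the same
chromosome — a deterministic rule that maximises retained score per pass
and serves as a proxy for removing linkage-disequilibrium redundancy; no
actual LD ($r^2$/D′) is computed. The tie-break order is a package
convention fixed for reproducibility. The pipeline is idempotent, and
raising either the threshold or the spacing can only shrink the panel.

# The simulator

The generator exists so that the whole pipeline is testable without any
external download. Three layers:

1. **Ancestral frequencies** — each marker draws an ancestral frequency
   $p \sim \mathrm{Uniform}(0.05, 0.95)$ (avoiding near-monomorphic
   markers) and each population then draws
   $f_j \sim \mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$
   — the Balding–Nichols model, with $F$ playing the role of $F_{ST}$.
   $F = 0.15$ emulates strongly diverged continental panels
   (CEU–YRI–CHB-like); $F \approx 0.01$ emulates closely related European
   panels, and the LEI distribution at high $F$ stochastically dominates
   the low-$F$ one, mirroring that contrast.
2. **Ancestral genotypes** — independent $\mathrm{Binomial}(2, f_j)$ draws
   per sample and marker: exact HWE, unlinked markers.
3. **Admixed cohorts** — each sample draws ancestry proportions
   $q \sim \mathrm{Dirichlet}(\alpha)$ (default $\alpha = \mathbf 1$) and
   genotypes $\mathrm{Binomial}(2, \sum_j q_jf_{jm})$: a frequency-mixture
   model of admixture. The true $Q$ matrix is returned for exact error
   measurement.

Markers are laid on chromosome "1" at a fixed 10 kb ladder — enough to
exercise position-based thinning deterministically; tests that probe the
thinning rule itself build explicit coordinate tables instead.

What the simulator does *not* emulate: linkage disequilibrium,
local-ancestry tracts, genotyping error, ascertainment bias, or selection.
Passing tests therefore demonstrate correct behaviour under the
frequency-mixture, unlinked-marker model — not performance on real
genotype panels, where LD makes nearby markers redundant and spacing
filters matter more.

Every stochastic function takes its own integer seed and restores the
caller's RNG state on exit; pipelines derive per-stage seeds from one base
seed (e.g. `seed`, `seed + 1`, `seed + 2` for frequencies, genotypes,
admixture) so stages are independently reproducible.

# Ancestry-proportion estimation and panel validation

No single canonical estimator exists for supervised ancestry proportions;
the package uses the classical binomial-likelihood EM on the simplex,
chosen because it is deterministic, dependency-free, and exactly matched
to the frequency-mixture model above. Given known parental frequencies
$F$, each sample's $\hat q$ maximises
$\sum_m \log \mathrm{Binomial}\big(g_m \mid 2, \textstyle\sum_j q_jf_{jm}\big)$
via multiplicative EM updates from the uniform start, stopping when the
largest change drops below $10^{-6}$ or after 500 iterations. Parental
frequencies are clipped to $[10^{-6}, 1-10^{-6}]$ to keep likelihoods
finite at fixed alleles. With identical parental frequencies the data are
uninformative and the estimate remains uniform — the correct
non-identifiable limit. Missing genotypes drop out of the likelihood.

Panel quality is summarised two ways:

* **Entries-wise RMSE** over all $n \times k$ proportions,
  $\sqrt{\mathrm{mean}\,(Q_{\text{true}} - \hat Q)^2}$ (entries-wise
  rather than per-ancestry-averaged; both orderings of the mean give the
  same value for a full matrix). The standard adequacy bar is RMSE
  < 0.05. In the package's reference simulation — three ancestral
  populations at $F = 0.15$, 50,000 markers, 100 samples per population,
  LEI ranking from the ancestral cohorts, top 1,000 markers, 200 admixed
  samples with uniform Dirichlet truths — the acceptance script computes
  an RMSE of about 0.02, comfortably under the bar; the test suite also
  verifies that RMSE shrinks along the LEI ranking (panels of 50/200/1000)
  and that top-LEI panels beat random panels of equal size.
* **PCA separation** — explained-variance ratios of the leading components
  of the standardized panel genotypes plus the mean silhouette width of
  the true labels in the top-2 component space. Silhouette is the
  quantitative stand-in for "distinct clusters" in the usual PC1/PC2
  ancestry scatterplots: diverse simulated panels ($F=0.15$, top-100 LEI
  markers) score above 0.6, near-identical populations ($F=10^{-6}$)
  below 0.2.

# Problem sizes

The shipped tests run the reference simulation at its full size (50,000
markers, 300 ancestral + 200 admixed samples) once, and exercise all other
properties on smaller seeded instances: 1,000-case oracle and bound sweeps
for the statistic, a $101^3$ frequency grid for the $k=3$ bound,
5,000-sample draws for frequency-recovery checks, 20-replicate sign tests
for panel comparisons. These sizes were chosen to make sampling noise
negligible relative to each assertion's margin.

# Known limitations

* LEI assumes HWE within each population; strong inbreeding or genotyping
  artefacts violate the genotype expansion (the statistic is still
  defined, but its joint table no longer reflects the data).
* Spacing-based thinning is a distance heuristic, not LD pruning.
* The EM estimator is supervised: parental frequencies are taken as known,
  and no uncertainty is propagated from their estimation.
* Haplotype-based informativeness, Rosenberg's $I_n$, $F_{ST}$-based
  statistics and unsupervised joint estimation (STRUCTURE/ADMIXTURE-style)
  are out of scope.
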