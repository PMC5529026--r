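---
title: "Methods: stereology, simulation and longitudinal statistics in podometrics"
author: "podometrics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereology, simulation and longitudinal statistics in podometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podometrics)
```

# Scope

`podometrics` implements the quantitative core of a longitudinal
two-group (lean vs obese) rodent study of diabetic nephropathy: model-based
stereology of podocyte number from WT-1 stained glomerular cross-sections,
glomerular morphometry summaries, a bulk transcriptome stage, and
clinical-endpoint statistics. Every stage is driven by a synthetic-data
module with known ground truth, so each estimator can be validated by
parameter recovery without any external data.

# Weibel-Gomez stereology

## The estimation chain

A set of 2D glomerular tuft profiles, each with its tuft area
$A_{tuft}$ (µm²), WT-1⁺ nuclear profile count $n$ and WT-1 stained area
$A_{WT1}$ (µm²), is pooled into three areal statistics using ratios of
unweighted means over profiles (equivalently, ratios of totals):

$$N_A = \frac{\bar n}{\bar A_{tuft}}, \qquad
  A_A = \frac{\bar A_{WT1}}{\bar A_{tuft}}, \qquad
  \bar A = \bar A_{tuft}.$$

Ratio-of-means is used rather than mean-of-ratios because it is unbiased
under unequal profile areas (small grazing profiles otherwise receive
the same weight as equatorial ones). The Weibel-Gomez chain is then

$$N_V = \frac{K_{nuc}}{\beta_{nuc}} \sqrt{\frac{N_A^3}{A_A}}, \qquad
  V_{glom} = \bar A^{3/2} \frac{\beta_{glom}}{K_{glom}}, \qquad
  N_{pod} = N_V \cdot V_{glom},$$

with podocyte density reported per $10^6$ µm³. Defaults are the
conventional coefficients for podocyte nuclei ($K = 1.1$,
$\beta = 1.45$) and for a near-spherical glomerulus ($\beta = 1.38$,
$K = 1.01$). For an exactly spherical, monodisperse particle the
theoretical values are $K = 1$ and $\beta = \sqrt{6/\pi} \approx 1.382$;
the package exposes both through `stereologyCoefficients()`.

Two conventions deserve an explicit note. First, $A_A$ is implemented
as stained area over tuft area — an areal *fraction* in $(0, 1]$ — which
is the quantity the $N_V$ formula is dimensionally consistent with; the
inverse ratio is sometimes written in methods descriptions but cannot be
meant, because it would make the radicand's units wrong. Second,
podocyte density is stated in podocytes per $10^6$ µm³ and the output
headers carry the units explicitly, since density units are a common
source of typos in the field's supplementary material.

## What the closed forms predict

For a sphere of radius $R$ cut by planes at uniform offsets
$h \in (-R, R)$, the mean profile area is $\tfrac{2}{3}\pi R^2$. Feeding
that exact mean into the volume formula with the conventional
coefficients returns

$$\frac{V_{est}}{V_{true}} = \frac{1.38}{1.01 \cdot \sqrt{6/\pi}}
  \approx 0.9887,$$

i.e. a known ~1.1% underestimate of the sphere's volume. For nuclei of
radius $\rho$ fully interior to the sphere, $E[N_A] = 2\rho N_V$ and
$E[A_A] = \tfrac{4}{3}\pi\rho^3 N_V$, from which the sphere-exact
density estimator is unbiased with $K = 1$, $\beta = \sqrt{6/\pi}$, and
the conventional coefficients induce a net bias factor of
$(1.1/1.45)\cdot\sqrt{6/\pi} \times 0.9887 \approx 1.037$ on
$N_{pod}$. The test suite and the acceptance script verify both the
closed-form identity and the Monte-Carlo recovery (200 nuclei, $R = 50$
µm, $\rho = 3$ µm, $10^4$ sections per replicate, 6 replicates — sized
so the Monte-Carlo standard error on the bias factor is ~0.003).

# The synthetic sectioning model

`makeGlomerulus()` places equal spherical nuclei uniformly at random in
the sphere of radius $R - \rho$, so no nucleus is clipped by the
glomerular surface; this isolates estimator bias from edge-clipping
artifacts. Ellipsoidal or size-dispersed nuclei are deliberately out of
the default model: the chain's coefficients are exactly known only for
monodisperse spheres, and that is what the recovery tests require.
Section planes use a canonical orientation with uniform offsets, which
for spheres equals isotropic uniform-random sectioning by symmetry.
Nuclear profile overlap is ignored when accumulating stained area; at
the default ~5% nuclear volume fraction overlap is a second-order
effect, and the approximation is stated here rather than corrected.

`sampleProfiles()` can drop grazing profiles whose tuft area falls below
`minRelArea` times the equatorial area, mimicking the unstated manual
exclusion of tiny profiles during slide annotation. The default is 0
(no exclusion) because no exclusion rule is documented for the original
measurements; the parameter exists so its sensitivity can be explored,
and dropped counts are always reported.

# Morphometry

Stain-positive area per tuft is summarized three ways: mean stain area
per tuft (unweighted), percent of tuft area from pooled totals
($100\,\Sigma A_{stain}/\Sigma A_{tuft}$; a mean of per-tuft
percentages is exposed as an option but is fragile for tiny tufts), and
percent of a supplied whole-kidney reference area. "Every other
quadrat" tuft selection is implemented as a checkerboard: the plane is
tiled from the origin into squares of side $q$ and a centroid is kept
iff $\lfloor x/q\rfloor + \lfloor y/q\rfloor$ is even. The grid anchor
is arbitrary in the absence of a documented convention; the
checkerboard is deterministic, selects half the plane, and is unbiased
under random tuft placement.

The ordinal 1-5 trichrome fibrosis score is pathologist-judged in real
studies, so the package does not attempt an image-based scorer. The
simulator discretizes the latent fibrosis severity at fixed thresholds
(defaults equally spaced on the latent scale), and the only contract
validated — via the Spearman rank agreement in `scoreVsSeverity()` — is
that the score is a monotone transform of severity. The 5-level
discretization caps the achievable rank correlation slightly below 1.

# The longitudinal study simulator

`studyDesign()` encodes the study conditions: two groups, terminal
cohorts of 5 animals at 12, 20, 24, 29, 34 and 41 weeks. Each animal
carries a latent fibrosis severity $s \sim N(\mu_{g,a}, \sigma_s)$
(floored at 0) whose mean rises steeply with age in the obese group and
gently in lean animals. Endpoints are of two kinds:

* log-normal analytes (BUN, NGAL, Kim-1) with per-cell log-means chosen
  to rise moderately with age in lean animals and strongly in obese
  animals, at log-sd 0.12 (serum chemistry) to 0.30 (urinary markers) —
  typical coefficients of variation for rat clinical chemistry;
* severity-coupled analytes, $y = a + b\,s + \varepsilon$ with Gaussian
  noise, floored at 0 because concentrations are non-negative. The
  urinary collagen-III fragment (uC3M) uses a single global coupling, so
  pooled lean+obese regressions have the closed-form
  $R^2 = (b_1 b_2 V)^2 / ((b_1^2 V + \sigma_1^2)(b_2^2 V + \sigma_2^2))$
  used in the recovery tests. Microalbumin uses group-specific affine
  couplings calibrated so the expected week-41 cohort mean
  microalbumin/creatinine ratios sit at 47,121 (obese) and 526 (lean)
  µg/mg — the reported ~90-fold separation.

Urinary analyte values are stored as concentrations
(ratio × urine creatinine, with creatinine log-normal around 50 mg/dL),
so `normalizeToCreatinine()` recovers the programmed ratio; this keeps
the normalization step honest instead of tautological. The default
noise levels put the pooled uC3M-vs-albuminuria $R^2$ in the 0.7-0.9
band seen in real longitudinal fibrosis data; the high-coupling /
low-noise regime used by the coupling-recovery checks is constructed
explicitly via `studyDesign()` arguments.

# The count simulator

`simulateCounts()` draws
$\mathrm{count}_{g,s} \sim \mathrm{NB}(\mu = L\, p_g\, FC_{g,c(s)},\ \phi)$
with log-normal relative abundances $p_g$, library size $L = 2\times10^7$
reads (a realistic bulk RNA-seq depth; at this depth shot noise is
negligible against the default biological dispersion $\phi = 0.1$), and
per-cohort fold changes. Lean cohorts are the $FC = 1$ reference. The
five podocyte markers (Nephrin, Podocin, WT-1, Synaptopodin, GLEPP1)
are pinned at a high baseline abundance and decline along the
obese/lean ratio trajectory $(1, 0.9, 0.8, 0.7, 0.35, 0.25)$ — roughly
a 75% reduction by week 41, matching the reported per-gene declines of
74-79%. Default programmed DE blocks are balanced (40 genes 4-fold up,
40 down, 15 progressively up, 15 progressively down): fold changes are
applied without library renormalization, exactly as stated, so a
strongly unbalanced DE program would shift the library composition and
systematically shrink RPKM-based fold changes — a real property of
depth-normalized units that the balanced defaults keep mild. The truth
table in `metadata()` lists every non-null gene with its trajectory;
it is the module's contract for scoring downstream callers.

# Transcriptome statistics

* **RPKM**: $10^9 \cdot \mathrm{count} / (\mathrm{length_{bp}} \cdot
  \mathrm{libsize})$ with the raw column sum as library size.
* **DEG rule**: a gene is differentially expressed at an age iff fold
  change exceeds 2 (either direction), mean RPKM across the two cohorts
  exceeds 0.5, and the Benjamini-Hochberg adjusted p-value is below
  0.05. The underlying test is not documented for the original
  analysis; a Welch two-sample test on $\log_2(\mathrm{RPKM} + 0.25)$
  was chosen for determinism and small-$n$ robustness, with the
  pseudocount exposed. Fold change uses cohort mean RPKM with the same
  pseudocount. BH runs across all genes with no expression prefilter:
  the RPKM > 0.5 rule is a DEG criterion, not a test-universe filter.
  Because the test is unspecified upstream, absolute DEG counts from
  the original animals are not reproducible targets; the package is
  validated on FDR control and power against simulated truth instead.
* **BH step-up** is implemented directly (sorted $p_{(i)} m/i$, running
  minimum from the largest rank, capped at 1) and is property-tested
  against an independent brute-force implementation and `p.adjust`.
* **Podocyte composite**: per gene, cohort level = geometric mean of
  RPKM + ε (ε = 0.01; the markers are high-expressed, so ε only guards
  all-zero cohorts) normalized to the 12-week reference cohort; the
  composite per age is 100 × the gene-average obese/lean ratio, so 100%
  means no reduction relative to age-matched lean animals.
* **PCA** retains genes with overall mean RPKM > 0.5, applies
  $\log_2(x+1)$, centres genes, and uses the SVD; variance fractions
  sum to 1 by construction.
* **Longitudinal classes**: *early sustained* = significant at every
  age with |FC| ≥ 3 at every age; *progressive* = significant from the
  second age onward with a non-strictly monotone log2-FC sequence,
  tolerating 0.1 log2 units per step because strict monotonicity is
  fragile under sampling noise (both thresholds configurable).
* **Over-representation**: right-tailed Fisher via the hypergeometric
  upper tail, plus a simple direction score
  $(n_{up} - n_{down})/\sqrt{k}$. The direction score is a transparent
  concordance summary and is *not* equivalent to proprietary pathway
  activation z-scores.

# Endpoint statistics

Cohort fold change is the ratio of arithmetic cohort means, with a
headline value rounded to the nearest ten (the "90-fold" reporting
convention; the raw ratio is always retained). The two-way ANOVA with
Tukey's multiple comparisons is fitted over the group × age cells;
Tukey adjustment runs over the full cell-pair family, from which the
two reported families are extracted: obese vs age-matched lean at each
age, and each obese cohort vs the 12-week obese baseline. Correlations
(uC3M vs albuminuria, Col-IV area, trichrome score) are ordinary least
squares over all animals pooled — per-animal points, both groups —
reporting $R^2$; a per-group option exists because the pooling
convention is a genuine design choice.

# Numerical and reproducibility choices

All generators are bit-reproducible given their parameters and a seed;
the orchestrator fans one master seed out to per-stage substreams by
stable integer hashing so toggling one stage never perturbs another.
Degenerate inputs have defined behaviour rather than NaNs: zero nuclear
count gives a zero density estimate with an absent mean nuclear size,
ties-only ordinal scores give an absent rank correlation, an empty
gene-set overlap gives $p = 1$ and direction 0, and zero-variance rows
in the Welch test give $p = 1$ (equal means) or $p = 0$ (unequal).

Problem sizes in the tests and the acceptance script — e.g. $10^4$
sections per stereology replicate with 6 replicates, 2,000 genes with
5 animals per cohort, 20 null replicates for the false-discovery check,
4 replicate studies for the composite — were chosen so Monte-Carlo
standard errors sit comfortably inside each check's tolerance.

# Known limitations

* The sectioning model is a sphere with monodisperse spherical nuclei;
  real glomeruli are not spheres, nuclei are not monodisperse, and
  WT-1⁺ parietal epithelial cells are not separated from podocytes.
  Passing recovery tests therefore demonstrate correctness of the
  estimator chain under its own model assumptions, not unbiasedness on
  tissue.
* The count simulator programs smooth cohort-level fold changes with a
  single dispersion; real data have gene-specific dispersion trends,
  outlier samples and batch structure.
* The endpoint simulator's latent severity is one-dimensional; real
  fibrosis, albuminuria and tubular injury are not driven by a single
  factor, which is why the simulated correlation structure is a
  contract for the statistics, not a biological claim.
* Histology is never rendered; mask-based morphometry consumes binary
  rasters produced elsewhere.
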