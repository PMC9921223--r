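---
title: "Network-motif analysis of structural connectomes: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-motif analysis of structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectomotif)
```

## The model

The unit of data is a structural connectome: a square matrix $C$ on a
fixed cortical parcellation whose entry $C_{ij}$ counts probabilistic-
tractography streamlines seeded in region $i$ that enter region $j$. The
reference layout is one hemisphere of a 180-parcel multimodal cortical
atlas plus a five-parcel subdivision of the corpus callosum used as
tractography targets, i.e. $D = 185$ regions. Callosal parcels are
target-only, so all-zero rows are legal. The diagonal is always zeroed:
self-streamlines are a tractography artifact.

Each matrix is flattened to a feature vector. By default the matrix is
first symmetrized, $(C + C^\top)/2$, because streamline direction in
probabilistic tractography is a property of the seeding scheme, not of
the axons; the strict upper triangle is then taken in row-major order,
giving $p = D(D-1)/2 = 17{,}020$ features at $D = 185$. A `full` mode
(all $D(D-1) = 34{,}040$ off-diagonal entries) is retained for
sensitivity analysis. Raw counts are decomposed without normalization or
column centering (both available behind flags): the decomposition is a
plain SVD of the count matrix, not a PCA.

The feature vectors of all selected (subject, scan) pairs are stacked as
columns of $M$ (scan-major, then cohort subject order), and

$$M = U \Sigma V^\top.$$

The columns of $U$ are the **network motifs**: orthonormal signed
patterns of connection weights shared across subjects and scans. Beyond
the first, every motif necessarily mixes positive and negative entries
(orthogonality), so a higher motif prevalence means some connections
increase while others decrease. $\sigma_k^2 / \sum_j \sigma_j^2$ is
motif $k$'s **explained variance**, and row $k$ of $V^\top$ holds its
**prevalence weights**, one per stacked column. With full-rank data the
number of motifs equals the number of columns: 28 for a 28-subject
single-scan analysis, 56 when two scans are stacked.

Four hypotheses are then tested per hemisphere, always with two-sided
rank statistics (performance scores and streamline counts cannot be
assumed normal):

* **Q1** - Spearman correlation of each motif's scan-a weights with
  day-1 task performance, Bonferroni-corrected for the number of motifs.
* **Q2** - the same against the day-4 minus day-1 performance change.
* **Q3** - scans a and b are stacked jointly; each subject's per-motif
  weight change (b minus a) is correlated with the performance change,
  Bonferroni over the (doubled) motif family.
* **Q4** - a group-level control: one Mann-Whitney U test per
  connection comparing the scan-a and scan-b (and scan-c) value
  distributions, Bonferroni-corrected for the $\approx 17{,}000$
  connections. The family size is always computed from the feature map
  in use, never hard-coded.

The behavioral score is the proportion of correct first answers in a
center-embedded-sentence comprehension task,
$\#\text{correct} / (\#\text{correct} + \#\text{incorrect} +
\#\text{missed})$, 33 trials per sentence type per day. Double-embedded
sentences are the default analysis variable: single embeddings start
near ceiling, leaving little usable variance. Reading-span and
digit-span covariates (forward/backward averaged to one value each) can
be correlated with motif weights under the same family correction.

## Numerical choices

* **Rank truncation.** Components with
  $\sigma_k \le \max(\dim M)\,\varepsilon\,\sigma_1$ are dropped
  (machine-epsilon relative tolerance). An all-zero stack yields a
  rank-0 decomposition rather than an error.
* **Sign convention.** Singular-vector signs are arbitrary; each motif
  is flipped (together with its weight row) so its largest-absolute
  feature entry is positive. This makes decompositions bit-reproducible
  and signed edge lists and weight correlations stable across runs.
  Because the convention can still flip a recovered motif relative to an
  externally defined reference, validation code compares correlation
  signs after aligning by the sign of the inner product with the
  reference.
* **Spearman p-values.** Exact by full permutation enumeration for
  $n \le 8$ ($8! = 40{,}320$ permutations), the $t$ approximation
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ above. The boundary is a pragmatic
  one: enumeration at $n = 9, 10$ costs two further orders of magnitude
  for no study-scale benefit (all cohort analyses have $n = 28$ or 56).
  Ties receive mean ranks.
* **Mann-Whitney p-values.** Exact (via the exact null distribution of
  $U$, identical to enumerating rank assignments) when
  $n_1 n_2 \le 400$ with no ties; otherwise the normal approximation
  with tie correction. At the study scale ($28 \times 28$ per
  connection) the normal branch always applies, so edgewise results are
  reproducible bit-for-bit.
* **Q4 pairing.** The edgewise test compares the two scans as
  independent groups even though scans are paired within subject; a
  paired signed-rank variant exists behind `paired = TRUE` but is not
  the default, favoring fidelity to the established procedure over
  statistical optimality.
* **Degenerate inputs.** Constant behavioral vectors raise an error
  rather than returning NaN correlations. If every motif's prevalence
  change between two scans is zero to numerical precision (identical
  scans), Q3 reports "no testable change". Subjects missing a required
  scan are dropped per question with a warning and the family size
  adapts; behavioral days are never imputed.

## What the synthetic generator emulates

`generate_cohort()` builds cohorts with the statistical structure the
analysis assumes:

$$C^{(s,t)} = \text{base} + \textstyle\sum_k w_{s,t,k}\, m_k +
\text{noise},$$

clipped at zero and rounded to integer counts. Its defaults are the
study conditions: 28 subjects, 185 regions, scans a/b/c, day-1
double-embedding performance spanning 58-91% and single-embedding
67-100%, 33 trials per type per day.

* **Base connectome**: one draw per cohort from a log-normal
  distribution (meanlog $\log 200$, sdlog 1), matching the skewed
  dynamic range of probabilistic streamline counts, which reach
  $10^2$-$10^4$ at typical seeding densities. The base is the dominant
  first motif of every decomposition, exactly as the grand-mean
  connectome dominates real stacks.
* **Planted motifs**: unit-norm feature vectors on sparse (default 2%
  of pairs), disjoint supports - hence exactly orthogonal - mimicking
  localized motifs. Subject weights are Gaussian. Amplitudes decay by a
  factor 0.6 per motif, as in empirical SVD spectra; this is also an
  identifiability requirement, since spikes of equal amplitude are
  recoverable only up to a rotation of their pair (chance correlation
  $\sim 1/\sqrt{n}$ between their weight vectors mixes them freely when
  their singular values coincide).
* **Amplitude scale** is set through a signal-to-noise ratio: the
  planted singular value $w_{\text{sd}}\sqrt{n}$ divided by the
  Marchenko-Pastur noise edge
  $\sigma_{\text{eff}}(\sqrt{p} + \sqrt{n})$, where
  $\sigma_{\text{eff}}$ accounts for symmetrization and integer
  rounding. The spiked-model prediction for the recovered-vs-planted
  overlap, $\bigl(1 + p/(\text{snr}^2(\sqrt p + \sqrt n)^2)\bigr)^{-1/2}$,
  gives $\approx 0.95$ at snr 3 and $\approx 0.98$ at the default
  snr 5; the default was chosen from this closed form so that a lone
  planted motif sits clearly inside the recoverable regime.
* **Behavior coupling**: day-1 double-embedding performance is a
  monotone (probit) map of a latent normal correlated at $\rho = 0.7$
  (default) with the coupled motif's scan-a weight; the training gain
  is likewise coupled to the plasticity motif's scan-b-minus-a weight
  change. Monotone mapping preserves Spearman correlations by
  construction; the population Spearman value is attenuated to
  $(6/\pi)\arcsin(\rho/2) \approx 0.96\rho$, and quantization to 33
  trials adds ties. Null cohorts zero both couplings.

What the generator does **not** emulate - and what passing tests
therefore do not show about real data: spatial autocorrelation of
tractography errors, subject-level variation of the base connectome,
distance- and curvature-dependent streamline attrition, hemispheric
asymmetries, motion artifacts, and any anatomical meaning of the
generic region labels. Recovery and power results on synthetic cohorts
bound what the pipeline can do when its own model holds; they do not
certify sensitivity on real tractography.

## Validation design and problem sizes

The package's own checks run at these sizes, chosen to exercise the
study geometry while keeping the full suite in the low minutes:

* SVD correctness (orthonormality $<10^{-10}$, relative reconstruction
  error $\le 10^{-10}$, eigendecomposition oracle within $10^{-8}$ on
  matrices up to $10\times10$) on 185-region, 28/56-column stacks.
* Parameter recovery: 100 seeded single-motif cohorts at the full
  185-region, 28-subject geometry; the recovered best-match cosine
  exceeds 0.95 in at least 95 of them, and Q1 flags the planted motif
  with the aligned correlation sign in the majority.
* Type-I control: 100 seeded null cohorts for Q1's family-wise error
  (binomial 95% band around 0.05); the edgewise Q4 test on literally
  identical scans must flag nothing, deterministically.
* Power: 200 seeded cohorts at planted latent coupling 0.6, $n = 28$
  (60-region geometry for speed; power at fixed snr is governed by $n$
  and the coupling), detection rate asserted loosely at $\ge 40\%$ and
  logged.
* End-to-end determinism: a cohort written to disk, reloaded through
  its manifest, analyzed, and written again must produce byte-identical
  result tables across two runs.

Module interfaces deliberately mirror the analysis workflow under
`analysis/`: numbered driver scripts simulate a cohort, decompose it,
run Q1-Q4, and emit the figure-ready motif reports (top regions by
within-motif node strength, signed edge lists for chord plots,
prevalence/behavior regression pairs). Node strength is the sum of
absolute motif weights over a region's incident connections; the edge
list is cut at the smallest set of edges covering half the motif's
squared norm, and however many regions those edges touch are reported.

## Known limitations

* The symmetrization choice discards any genuine asymmetry in seeding
  statistics; `full` mode exists precisely to check robustness of a
  finding to that choice.
* Bonferroni across motifs treats the motif family as fixed, but the
  family size equals the stacked column count, so adding scans changes
  the correction; this is inherent to the design being mirrored.
* With planted spikes of similar amplitude, individual motif identity
  is not recoverable (only their span); real cohorts with nearly tied
  singular values inherit the same caveat, and motif-level findings
  near spectral degeneracies should be interpreted as subspace-level.
* The $t$ approximation for Spearman at $n = 28$ is slightly
  anti-conservative in the extreme tail; at the Bonferroni thresholds
  used here the family-wise error remains within the binomial band in
  simulation, but exact permutation p-values would be preferable if a
  result sat exactly at threshold.
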