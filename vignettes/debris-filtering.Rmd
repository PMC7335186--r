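---
title: "Filtering ambient-RNA debris from droplet snRNA-seq with debrisEM"
author: "debrisEM maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering ambient-RNA debris from droplet snRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(debrisEM)
```

## Why droplets need more than a count threshold

Single-nucleus RNA-seq lyses the plasma membrane during nuclei isolation,
releasing cytoplasmic and cell-free RNA into the suspension. Droplet
platforms then package this ambient RNA alongside — or instead of — a
nucleus, so the counts behind a barcode can be a clean nuclear profile, a
pure ambient profile, or any mixture in between. Ambient contamination is
not confined to low-count barcodes: contaminated droplets occur across the
barcode-rank curve, which is why a hard count threshold simultaneously
keeps ambient-dominated droplets and throws away real nuclei, and why
surviving contamination can later surface as spurious "cell types" in
clustering. debrisEM addresses this with a model of what droplets contain
rather than how many counts they have.

## The mixture model and its assumptions

Droplet $i$'s counts $x_i$ (total $u_i$) are modelled as a multinomial
draw with gene probabilities conditional on a latent component
$z_i \in \{1, \dots, K+1\}$: one *debris* component (index 1 throughout
the package) and $K$ cell types. The observed-data log-likelihood is

$$\log P(X) = \sum_{i=1}^N \log \sum_{k=1}^{K+1}
  \pi_k \, \mathrm{Mult}(x_i \mid \alpha_k, u_i).$$

The assumptions this buys and their costs:

* **Multinomial sampling** treats a droplet as $u_i$ independent draws
  from its component's gene distribution. There is no per-droplet
  overdispersion term, so biological within-type variability is absorbed
  into the component profiles.
* **One droplet, one component.** A contaminated nucleus is *assigned* to
  whichever single component explains it best; the continuous degree of
  contamination is recovered afterwards by the debris score, not by the
  mixture itself. Doublets are likewise not modelled.
* **Low-count droplets are ambient.** Droplets with $u_i < T$ (default
  $T = 100$) form the fixed debris set: their $z_i$ is pinned to the
  debris component at every EM iteration. This semi-supervision anchors
  the debris profile with thousands of cheap observations and is the main
  source of the model's stability; it fails only in the unusual situation
  where sub-$T$ barcodes are *not* predominantly ambient.

EM alternates the posterior computation (E-step, in log space with
max-subtraction) with closed-form updates (M-step): $\alpha_k$ is the
posterior-weighted mean of droplet counts plus a pseudocount of $10^{-10}$
per gene, renormalized; $\pi_k$ is the mean posterior membership. The
fixed labels are realized by overwriting the fixed rows of the posterior
with a one-hot vector — mathematically equivalent to constraining the
complete-data likelihood, and simpler. Convergence is declared when the
largest absolute change over all $\alpha$ and $\pi$ entries falls below
$\varepsilon = 10^{-4}$ (an infinity norm; the criterion is a parameter
norm, so it is independent of the likelihood's arbitrary additive
constant).

Two conventions worth knowing:

* The multinomial coefficient depends only on the counts and cancels in
  every posterior, so it is omitted from the fitted likelihood; reported
  log-likelihoods are comparable within a run, not across data sets.
  `multinomLogProb(..., includeCoef = TRUE)` and
  `observedLogLik(..., includeCoef = TRUE)` give the full pmf when
  absolute values are wanted.
* With fixed labels, the quantity EM monotonically increases is the
  *semi-supervised* objective — test droplets contribute their mixture
  term, fixed droplets their debris-component term. That is what the EM
  trace records; the unconstrained $\log P(X)$ need not be monotone under
  label fixing.

## Initialization

Mixtures of multinomials are sensitive to their starting point, so the
package initializes from a k-means clustering rather than at random:

1. restrict to expressed genes (nonzero total — equivalent to CPM > 0);
2. form the *cluster set*: test-set droplets with at least 200 genes
   detected, so near-empty droplets do not drag the initial centroids;
3. normalize each cluster-set droplet to the median depth and take
   $\log(x + 1)$;
4. select the top $V = 2000$ variable genes by standardized variance —
   observed log variance minus a LOESS fit (span 0.3, degree 2) of log
   variance on log mean of the *raw* counts, which removes the trivial
   mean–variance trend;
5. embed on the top 30 principal components (genes centered, not scaled)
   and run `stats::kmeans` (Hartigan–Wong, 10 restarts) under the
   user's seed.

The debris component starts from the pooled fixed-set counts; components
$2 \dots K+1$ from the pooled counts of each k-means cluster; mixing
weights from the labeled-droplet fractions. Empty k-means clusters are
dropped at this stage (never mid-EM — during EM the pseudocount keeps
low-mass components proper rather than pruning them, which would
discontinuously change the objective).

## Debris scoring and filtering

Hard assignment alone would discard the information in *how* contaminated
a kept droplet is, so droplets are scored:

1. **Debris clusters** = the fixed component plus any component whose
   assigned droplets average fewer than $d = 200$ genes detected.
2. **Debris-enriched genes**: Welch's unequal-variance t-test per gene
   between test-set droplets in debris vs cell-type clusters, on
   depth-invariant normalized expression $\log(x_g / u_i + 1)$; enriched
   means log fold change (difference of group means on that scale) > 0
   and Benjamini–Hochberg q < 0.05. Only the *sign* of the fold change
   gates enrichment, which keeps the result insensitive to the exact
   fold-change definition.
3. **Raw score** = sum of normalized expression over the enriched genes,
   for every droplet including fixed ones.
4. **Normalization**: with $m_{low}$ the smallest per-cluster mean raw
   score and $m_{deb}$ the mean over debris-cluster droplets, the
   normalized score is $(raw - m_{low}) / (m_{deb} - m_{low})$ — the
   cleanest cluster averages exactly 0 and the debris clusters exactly 1,
   so the cutoff $t$ has the same meaning across data sets. Dividing by
   the debris mean alone (available as `scoreNormMethod = "literal"`)
   anchors the debris average at 1 only when $m_{low} = 0$, so the
   anchored form is the default. Cluster means in the $m_{low}$ search
   use test-set droplets (fixed droplets belong to no cell-type
   cluster); the debris mean includes the fixed droplets, which
   constitute the fixed cluster.
5. **Filter**: keep test-set droplets with a normalized score below
   $t = 0.5$; fixed droplets are always removed. `filterMode =
   "cluster"` instead keeps droplets assigned outside the debris
   clusters, which works well when contamination within kept droplets is
   mild (typical of single-cell rather than single-nucleus data).

If the DE step finds *no* enriched genes the score is meaningless and the
pipeline stops with an explicit error rather than returning unreliable
calls; the same applies when the debris clusters do not actually score
above the cleanest cluster.

## Evaluation metrics

Contamination is measured independently of the model through
`contaminationMetrics()`:

* **Percent spliced** — ambient RNA is mostly mature (spliced) mRNA while
  nuclear RNA is rich in unspliced pre-mRNA, so
  $spliced / (spliced + unspliced)$ is low for nuclei and high for
  ambient droplets. Mitochondrial genes are excluded before aggregation
  (MT transcripts have no introns and would inflate the ratio);
  ambiguous reads never enter the denominator; a zero denominator gives
  an undefined value, never a silent 0.
* **MT%** and **MALAT1%** — the mitochondrial fraction rises with
  extranuclear content; the nuclear-retained lincRNA MALAT1 falls.
* The percent-spliced distribution is typically bimodal, so a
  two-component Gaussian mixture is fitted by EM (deterministically
  initialized at the 25th/75th percentiles) and the **midpoint** — the
  equal-weighted-density point between the means, the root of a quadratic
  — classifies droplets as background (above, ties included) or nuclear
  (below). When variances are very unequal the between-means root may not
  exist; the root nearest the means' midpoint is then used, with a
  warning. Near-unimodal data (means closer than twice the standard
  error, or a vanishing weight) warn and fall back to the overall mean.
  Clusters averaging at least 50% spliced are labelled debris.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `fixedThreshold` | 100 counts | below: fixed to the debris component |
| `k` | 20 | cell-type components (deliberately generous; surplus components stay small or split types without harming scoring) |
| `eps` | 1e-4 | EM stop on max parameter change |
| `pseudocount` | 1e-10 | per-gene floor in the M-step |
| `clusterSetMinGenes` | 200 genes | k-means cluster-set floor |
| `debrisClusterMinGenes` | 200 genes | mean genes-detected debris rule |
| `scoreCutoff` | 0.5 | keep below this normalized score |
| `variableGenes` | 2000 | genes entering the init PCA |
| `loessSpan` | 0.3 | mean–variance trend span |
| `nPCs` | 30 | components for k-means |
| `quantileTopC` / `quantileQ` / `quantileDivisor` | 3000 / 0.99 / 10 | baseline threshold rule |

Raising `scoreCutoff` monotonically admits more droplets; 0.5 sits halfway
between the clean-cluster and debris anchors. The quantile baseline uses
the 99th percentile rather than the maximum so that doublets do not set
the threshold, and R's default linear interpolation between order
statistics (type 7) as the quantile convention.

## The simulator: what it does and does not emulate

`makeProfiles()` + `simulateDroplets()` + `simulateSplice()` generate the
study conditions every test runs on. The default scenario: 1,000 genes,
3 cell types, 300 nuclei per type, 5,000 empty droplets.

* **Profiles.** Cell types are symmetric-Dirichlet draws with
  concentration 5, making them strongly correlated — real cell types
  share most of the transcriptome and differ in a minority of genes, and
  near-orthogonal profiles would both be unrealistic and make every
  fitted profile trivially separable. The ambient profile is its own
  draw with 50 marker genes boosted fivefold and renormalized,
  reflecting the strong compositional shift between debris and nuclear
  RNA. Because nuclei carry Beta(1, 9) contamination (mean 0.1), fitted
  cell-type profiles are biased toward ambient by roughly one tenth of
  the type–ambient distance; with correlated profiles that bias stays
  small in total-variation terms, which is the regime in which profile
  recovery is a meaningful check at all.
* **Sizes.** Nucleus totals are log-uniform on [150, 5000). Empty totals
  are log-uniform on [1, 1000): about two thirds fall below the fixed
  threshold of 100, and the rest form an ambient tail reaching well into
  the nucleus range — the defining feature of the problem (a count
  threshold that must pass small nuclei necessarily passes large ambient
  droplets). A simulation whose empties all sat below 100 counts would
  make the fixed threshold solve the problem by construction and test
  nothing.
* **Contamination.** Per-nucleus ambient fraction $\rho \sim
  \mathrm{Beta}(1, 9)$; the ambient molecule count is
  $\mathrm{Binomial}(u, \rho)$ and gene counts are drawn from the two
  profiles separately (marginally the mixed multinomial), so the realized
  ambient content of every droplet is known exactly.
* **Splicing.** Each molecule is spliced with probability 0.8 (ambient)
  or 0.25 (nuclear), giving the bimodal percent-spliced distribution the
  midpoint classifier expects.

Not emulated: gene-length and capture biases, UMI collisions, doublets,
batch effects, overdispersion beyond the contamination mixture, and any
real tissue's cell-type hierarchy. Passing tests therefore demonstrate
correctness of the algorithms under the stated generative assumptions,
not performance on any particular tissue.

When the mixture is fitted *for recovery comparisons against the
simulated truth*, `k = 4` is used: the test set contains four expression
populations (three types plus the ambient tail), and k-means with k = 3
would have to merge two of them at initialization. For scoring and
filtering checks the paper-default `k = 20` is used, which is the
recommended practical setting — surplus components are harmless there.

## Numerical choices and degenerate inputs

* All likelihood work is in log space; posteriors use max-subtraction.
* Argmax assignment breaks exact ties toward the lowest component index,
  so a tie with debris resolves to debris (the conservative call).
* `quantileThreshold` sorts decreasingly with ties broken stably; fewer
  droplets than `topC` uses all droplets with a warning.
* Genes with zero counts are excluded from variance modelling (log of a
  zero mean is undefined); constant genes in the DE step get p = 1.
* Zero-total droplets are retained in the object — they land in the fixed
  debris set and are always removed — but are excluded from
  normalizations that would divide by zero.
* The log transforms use natural log with offset 1 throughout, matching
  the scoring normalization's explicit "+1".
* Median depth for init normalization is computed over the droplets being
  normalized (the cluster set).

## Problem sizes used by the test suite

The shipped tests exercise EM on 50 random instances with up to 20 genes,
200 droplets and 5 components; module-level pipelines on a few hundred
genes and ~1,000 droplets; and the full default scenario (1,000 genes,
5,900 droplets) for recovery, scoring and filtering checks. These sizes
give stable statistics while keeping the whole suite fast enough to run
on every change; the algorithms scale to real matrices (tens of thousands
of genes, hundreds of thousands of barcodes) through sparse linear
algebra, where EM cost per iteration is proportional to the number of
nonzero entries times the number of components.

## Known limitations

* Debris scores are calibrated within a sample (the anchors are that
  sample's own clusters); scores are not comparable across samples, and
  multi-sample experiments should be filtered per sample.
* If the ambient pool barely differs from the cell types — few or no
  debris-enriched genes — the score is unreliable, and the pipeline says
  so rather than guessing.
* `K` is user-specified; the package deliberately ships no model
  selection over `K`. Overspecifying is safe for filtering; for
  interpretation of the fitted components it is not.
* The multinomial has no overdispersion; heavily structured within-type
  variability can siphon droplets into surplus components (harmless for
  filtering, visible in component counts).
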