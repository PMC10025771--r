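---
title: "Multimodal network fusion for spatial transcriptomics: methods"
author: "SpotFuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal network fusion for spatial transcriptomics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Capture-based spatial transcriptomics (ST) measures a gene x spot UMI matrix
on a regular array of barcoded spots, together with a brightfield H&E image
of the same section taken before permeabilization. Two noise processes
degrade the expression data: *diffusion* — during permeabilization mRNAs
migrate to neighboring spots, blurring spatial expression patterns and
depositing UMIs on blank (off-tissue) spots — and *dropout* — false zeros
from limited capture efficiency. The image is acquired before
permeabilization and is therefore diffusion-free, which is the motivation
for fusing it with the transcriptome: morphology carries region structure
that survives exactly the noise that damages the counts.

SpotFuse identifies spatial clusters (SCs: groups of spots coherent in
expression, morphology, and position) and enhances expression by
neighborhood smoothing, both on a single fused spot graph.

# The fused network

Three spot-wise similarity networks are built and combined.

**Histological network H.** The image is converted to grayscale
(BT.601 weights), tissue foreground is separated from the bright slide by a
two-component Gaussian mixture on the intensity histogram, and the
foreground pixels are grouped into $K$ clusters by a Markov random field:
per-cluster univariate Gaussian emissions on intensity plus a Potts
smoothness term $\beta \cdot \#\{\text{like-labeled neighbors}\}$ over the
8-pixel neighborhood. The field is fitted by hard-assignment EM — iterated
conditional modes scheduled over a 4-coloring of the lattice (so every
accepted move lowers the energy), alternating with closed-form Gaussian
updates. Each spot $u$ is then summarized by $w_u$, the label distribution
of the foreground pixels inside its circular footprint, and pairs are
compared by symmetric Kullback–Leibler divergence

$$L_{u,v} = \tfrac12\left[\mathrm{KL}(w_u\|w_v) + \mathrm{KL}(w_v\|w_u)\right],
\qquad H_{u,v} = 1 - \min(1, L_{u,v}).$$

**Transcriptomic network T.** Counts are depth-normalized
($x \mapsto \ln(1 + 10^4 x/\mathrm{colsum})$), the top 2000 highly variable
genes are selected by residual variance around a mean–variance trend, the
standardized HVG matrix is embedded by PCA (top 50 components), and spots
are joined by a shared-nearest-neighbor graph: $k=20$ Euclidean neighbors
(self included), Jaccard edge weights, weights $\le 1/15$ pruned. These are
the standard defaults of the SNN construction used across single-cell
toolkits, frozen here so results do not depend on an external package.

**Fusion.** With $A_{u,v}$ the Manhattan distance in array coordinates,

$$S_{u,v} = \frac{H_{u,v} + T_{u,v}\,I(T_{u,v}>0)}{2\,A_{u,v}},$$

min–max normalized over stored edges to $S^*_{u,v}\in[0,1]$. The support of
$S$ is the union of immediate spatial neighbors (array distance $\le 2$,
which covers the 6 hex neighbors of a Visium spot — plus the two spots two
rows straight up/down, which share that array distance) and all SNN edges;
the $1/A$ factor makes more distant pairs negligible, and a dense all-pairs
mode (`aMax = Inf`) exists to verify on small samples that sparse and dense
fusion cluster identically (they do on the bundled fixtures).

# Spatial cluster identification

With $P = D^{-1}S^*$ the random-walk transition matrix and $d$ the weighted
degrees, spots are compared by the degree-weighted distance between t-step
walk profiles,

$$W_{u,v} = \left\| D^{-1/2}(P^t)_{u\cdot} - D^{-1/2}(P^t)_{v\cdot} \right\|_2,$$

the classic random-walk community distance ($t = 4$ by default, the usual
choice in that literature). Starting from singletons, the adjacent pair of
communities whose merge least increases the mean squared profile-to-centroid
distance is merged (Ward increments, maintained exactly with Lance–Williams
updates; only communities sharing an edge may merge; ties resolve to the
smallest spot indices, so the procedure is deterministic). The merge tree is
cut either at a requested cluster count or at the level maximizing
modularity

$$Q = \sum_c \left[\frac{N^{\text{inner}}_c}{N} -
\left(\frac{2N^{\text{inner}}_c + N^{\text{outer}}_c}{2N}\right)^2\right]$$

with unweighted edge counts (a weighted variant is available). Clusters
smaller than `minSize` (default 5 spots) are absorbed into their
best-connected neighbor. Benchmarks in this package fix the cluster count to
the number of annotated regions, the usual protocol when ground truth is
available; the automatic Q cut is the default for unannotated data.

# Expression enhancement

Smoothing adds to each spot the $S^*$-weighted expression of its immediate
network neighbors, $E^*_u = E_u + \sum_{v} S^*_{u,v} E_v$. The formula as a
raw sum inflates depth, so by default the result is divided by
$1 + \sum_v S^*_{u,v}$, making $E^*_u$ a convex combination of the closed
neighborhood ("weighted average" behavior); `average = FALSE` gives the raw
sum. Smoothing operates on the log-normalized layer, where values are
depth-comparable. Dropout repair replaces each missing entry by the
unweighted mean of its neighbors' nonzero values, looping so that deeper
holes fill in later rounds; entries with no reachable nonzero neighbor stay
zero and are counted. Repair quality is the *recovery score*
$1 - L(\hat p, p)$, the symmetric KL divergence between the per-gene spot
profiles before/after, which is 1 exactly for a perfect restoration.

# Noise simulators

**Diffusion** follows Fick's first law spot-to-spot: material moves from
each source $u_0$ to every lower-total target $u$ with raw transfer
$J(u,u_0)\,k_G(u,u_0)\,C_{u_0}$, where $J = \varphi(\|C_{u_0}\|_1 -
\|C_u\|_1)$ and $k_G$ is a bivariate Gaussian kernel on array coordinates
($\sigma_1=\sigma_2=4$; the correlation defaults to $\rho=0$ because
$|\rho|=1$ makes the covariance singular; pairs beyond $3\sigma$ are
skipped). All transfers are computed from the original counts and applied
simultaneously, so pair ordering is irrelevant. Because the raw flux carries
count units, the summed outflow of a deep spot exceeds its content at every
$\varphi$ in the sweep; the outflow fraction is therefore passed through the
saturating map $1-e^{-\text{raw}}$, which matches the raw sum for small
transfers, never overdraws a spot, conserves mass exactly (the
redistribution matrix is row-stochastic), and keeps the transferred mass
strictly increasing in $\varphi$. Off-tissue spots participate as targets,
which is how blank-area UMIs arise; their UMI share is strictly increasing
in $\varphi$ on the bundled fixture. One consequence of the saturation is
that the sweep compresses at high $\varphi$: marker enrichment decays
strictly up to $\varphi\approx0.3$ and then flattens (tiny non-monotone
wobbles of order $10^{-3}$ can appear through the min–max normalization).

**Dropout** zeroes $\lfloor \mathrm{DR}\cdot\#\text{entries}\rfloor$
uniformly sampled entries of the raw count matrix, reproducibly under a
seed, and records the mask so that recovery can be scored against it.

# SDEGs and evaluation statistics

Per cluster, genes are tested by a two-sided Wilcoxon rank-sum test (cluster
spots vs. the rest; exact for small untied samples, otherwise normal
approximation with tie and continuity corrections), BH-adjusted within the
cluster, and ranked by log2 fold change of means (pseudo-expression
$10^{-9}$); both the fold-change and adjusted-p orderings are reported. The
spatial enrichment score of a gene is the quadratic form $x_g^\top N x_g$
over the binary k-nearest-neighbor spot adjacency (k = 6 matches hex
geometry; k = 1 is available), min–max normalized across genes.
Partitions are scored by ARI, NMI (mutual information normalized by the
arithmetic mean of the entropies), maximum-matching accuracy (optimal
one-to-one cluster assignment on the contingency table, in percent), and
modularity Q as above.

# The synthetic fixture

`makeTissue()` generates the standard test sample: a 20 x 25 hex
(Visium-parity) grid — 500 spots, the outer 2 rings off-tissue, 336
in-tissue — 4 Voronoi regions seeded among in-tissue spots, 200 genes of
which 10 per region are markers (mean count 5 in the home region over a
background of 1), per-spot depth factors from a negative binomial (size 10),
Poisson sampling, and a grayscale image whose regions have means
(80, 120, 160, 200) with noise sd 18 on a bright slide (235): the intensity
tails of adjacent regions overlap deliberately so segmentation is genuinely
exercised. Everything is reproducible from the spec seed, and the sample
writes/reads as a standard Visium-style directory.

What the generator does *not* emulate: real H&E color and texture (nuclei,
stain variation — the image model is intensity-shifted noise), cell-level
heterogeneity within spots, spatially smooth expression gradients, or
batch/section effects. Passing tests therefore demonstrate the correctness
and internal consistency of the algorithms under the stated model, not
performance on real tissue.

# Numerical choices and degenerate inputs

* KL divergences mix both distributions with $10^{-10}$ pseudo-mass and
  renormalize, keeping zeros finite.
* MRF: variances floored at $10^{-4}$; empty clusters re-seeded at the
  worst-explained pixel; convergence when fewer than 0.1% of pixels change;
  `maxIter = 30`; K is capped at the number of distinct foreground
  intensities. $\beta$ (default 1) trades off against emission precision —
  on 8-bit intensities with within-cluster variance $v$, the pairwise term
  overrides an outlier only once $8\beta \gtrsim (\text{gap})^2/2v$, so
  denoising demonstrations use $\beta = 10$. Images longer than 2000 px per
  side are block-averaged first.
* Constant-intensity images: all-foreground with a warning. Spots covering
  no foreground pixel get the uniform label distribution and a flag (they
  stay connected through it rather than being dropped).
* Min–max normalization over a constant edge set returns all-1 weights with
  a warning; zero-weight edges are dropped after normalization.
* Isolated spots are attached to their nearest array neighbor with the
  smallest positive weight before the random walk.
* All-zero spots (possible after heavy diffusion drains a spot to numerical
  zero) are dropped with a warning before normalization.
* PCA signs are fixed by making each component's largest-magnitude loading
  positive; HVG ties break by gene id; merge ties break by smallest index —
  the whole pipeline is deterministic given its seeds.
* HVG trend: loess (span 0.3, log10 scale) when at least 30 genes are
  usable, otherwise a straight-line fit.

# Problem sizes

The bundled analyses run on the 500-spot / 200-gene fixture and images up to
80–330 px per side; the complete pipeline (image segmentation, both
networks, fusion, clustering, enhancement, metrics) takes well under a
minute on one CPU at these sizes, and the test suite exercises it end to end
on clean, diffused ($\varphi = 0.3$) and dropout (DR = 0.3) versions of the
fixture.

# Known limitations

* The histological features are grayscale-intensity clusters only — no
  color deconvolution, nuclei, or learned features — so H is blind to
  structures that differ in texture but not intensity.
* The diffusion simulator is a single-pass Fick approximation with a
  saturating outflow, not a time-resolved PDE; at high $\varphi$ the sweep
  compresses (see above).
* The fused-graph support excludes pairs that are both spatially distant
  and transcriptomically unconnected; the dense mode exists to check this
  approximation but is quadratic in spots.
* Whether off-tissue spots belong in the networks is data-dependent; they
  are excluded by default (`includeOffTissue = TRUE` to keep them), as the
  blank-area analysis needs them but clustering does not.
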