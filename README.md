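# SpotFuse

Multimodal network fusion for spatial transcriptomics spot clustering and
expression enhancement.

Capture-based spatial transcriptomics yields a gene × spot UMI matrix on a
barcoded array plus a matched H&E image of the section. Two noise processes
blur the counts — mRNA **diffusion** during permeabilization and **dropout**
from limited capture — while the image, taken before permeabilization, is
diffusion-free. SpotFuse exploits that: it builds a histological similarity
network *H* (MRF pixel clustering of the grayscale image; spots compared by
symmetric KL divergence of their pixel-label distributions, H = 1 − min(1, L)),
a transcriptomic SNN network *T* (log-normalization → HVG → PCA → shared
nearest neighbors with Jaccard weights), and fuses them with spot adjacency
into a single weighted graph

    S(u,v) = ( H(u,v) + T(u,v)·I[T(u,v)>0] ) / ( 2·A(u,v) ),

with *A* the Manhattan distance in array coordinates, min–max normalized to
S\* ∈ [0,1]. Spatial clusters are found on S\* by random-walk community
detection — agglomerative merging under the degree-weighted distance between
t-step transition profiles ‖D^−1/2 (P^t)ᵤ − D^−1/2 (P^t)ᵥ‖₂, cut at a given
cluster count or at maximum modularity Q — and expression is enhanced by
neighborhood smoothing E\*ᵤ = Eᵤ + Σᵥ S\*(u,v)·Eᵥ (averaged by default).
The package also ships the two noise simulators (Fick's-law diffusion with a
Gaussian spatial kernel; uniform dropout with a recorded mask plus an
iterative neighbor-mean fill scored by 1 − symmetric KL), spatially
differentially expressed gene detection with a spatial enrichment score
x^T N x, the evaluation statistics (ARI, NMI, maximum-matching accuracy,
modularity Q), and a fully synthetic Visium-like fixture generator, so the
whole suite runs with no downloads.

Intended users: method developers and analysts working with Visium-style
data who want an image-aware clustering/enhancement pipeline with a
self-contained, testable implementation.

## Worked example

```r
library(SpotFuse)

x <- makeTissue()                 # 500-spot hex grid, 4 regions, 200 genes
x
#> class: SpotExperiment
#> dim: 200 500
#> in-tissue spots: 336 / 500
#> image: 226x330 px, spot diameter 9 px

res  <- clusterSpots(x, nClusters = 4, seed = 1)
part <- res$partition
part
#> SCPartition: 336 spots in 4 clusters (walktrap)
#> cluster
#>   1   2   3   4
#>  65 160  74  37
#> ground truth attached

adjustedRandIndex(part)           # vs. the planted regions
#> [1] 1
accuracyMaxMatch(part)
#> [1] 100
```

The fixture's planted regions are recovered exactly. Under simulated
permeabilization diffusion the counts blur, and the image keeps the fused
clustering ahead of an expression-only Louvain baseline run on the same
transcriptomic network:

```r
xd   <- simulateDiffusion(x, NoiseConfig(phi = 0.3))
resd <- clusterSpots(xd, nClusters = 4, seed = 1)
accuracyMaxMatch(resd$partition)                       # fused, phi = 0.3
#> [1] 59.40299
base <- louvainBaseline(resd$tNet, seed = 1)
accuracyMaxMatch(base, trueLabels(resd$partition))     # expression only
#> [1] 57.91045
```

Neighborhood smoothing then lifts the planted markers' normalized spatial
enrichment on the diffused data (0.5391 → 0.5399 on this fixture), and after
30% dropout the neighbor-mean fill raises the markers' median recovery score
(−1.756 → −1.686 against the clean counts).

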