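# swarmSpectra

Spectral analysis of spatiotemporal gene expression, phenotypes and
metabolites in exponentially expanding bacterial swarm colonies.

## The problem

A *Bacillus subtilis* swarm expands across an agar surface from ~1 mm to
~60 mm diameter within about six hours. Sampling transcriptomes, microscopy
videos and extracellular metabolites at many (time, radial position)
locations yields data on an *irregular, growing* space–time domain: later
times have more sampling positions, and replicate colonies grow from
different starting radii. Standard clustering of expression profiles does
not respect this geometry. `swarmSpectra` implements an analysis pipeline
for such data:

1. **Common domain.** The colony boundary is fitted jointly across
   replicates as `b(t) = b0 * exp(t / tau)` with one shared growth
   timescale τ, by minimising

   L(τ, b0⁽¹⁾, …) = Σₖ Σₗ ( bₗ⁽ᵏ⁾ − b0⁽ᵏ⁾ exp(tₗ⁽ᵏ⁾/τ) )².

   Per-replicate time shifts map all samples onto one non-dimensional
   domain { 0 ≤ t̃ ≤ T, 0 ≤ p̃ ≤ exp(t̃) }.

2. **Domain basis.** Gram–Schmidt orthogonalisation of the graded
   monomials {1, t̃, p̃, t̃², t̃p̃, p̃², …} under the weighted inner product

   ⟨f, g⟩ = ∫₀ᵀ dt̃ ∫₀^{exp(t̃)} dp̃ e^{−t̃} f g

   gives six orthonormal polynomials P₀,…,P₅ tailored to the expanding
   domain.

3. **Spectral scores.** Each gene's expression field is compressed into
   coefficients cₘ by stacked least squares across replicates. After
   standardisation (kₘ), genes are scored by the representation error 𝓔,
   the pattern energy 𝓟 = Σₘ≥₁ kₘ², and the space–time ranking
   𝓡 = 𝓟/𝓔; the genes jointly carrying at least half of the total
   ranking (a weighted-median cut-off) are called spatiotemporally
   patterned. Patterned genes are clustered by k-medoids (PAM) on the
   cosine distance of their k-vectors and embedded in 2-D by metric MDS.

4. **Phenotypes and metabolites.** Microscopy-derived metrics (local
   nematic order, rafting ratio, non-motile clusters, density
   fluctuations) are computed from per-frame cell tables and pushed
   through the identical spectral path; extracellular metabolite series
   are summarised, depletion and secrete-then-consume peak timing are
   extracted, and peak shifts are compared against the diffusion
   timescale τ_diff = L²/(4D).

A synthetic-data generator (`simSwarmStudy`, `simCellTable`,
`simMetaboliteSeries`, …) emulates the full study design — exponential
boundary growth, radial sampling grids, basis-derived expression fields,
overdispersed counts with unequal library sizes, raft/cluster cell
configurations, cross-feeding kinetics — so every stage is testable with
known ground truth and no external data.

## Worked example

```r
library(swarmSpectra)

st <- simSwarmStudy(nFlat = 60, nPatterned = 30, seed = 3)
counts <- simCounts(st$expression, librarySizes = 3e6, seed = 4)
res <- runTranscriptomeAnalysis(counts, st$annotations, st$boundaryObs,
                                k = 6, elbowRange = NULL)
res
```

```
SwarmAnalysis (transcriptome pipeline run)
  90 genes x 215 samples after filtering
SwarmDomain: shared exponential boundary fit
  tau        : 1.4654 h
  replicates : r1 (b0 = 0.500 mm), r2 (b0 = 0.550 mm), r3 (b0 = 0.600 mm)
  reference  : r3  (b0 common = 0.600 mm)
  T (common non-dimensional extent): 3.9120
  selected genes: 13; clusters: 6
```

The fitted growth timescale (1.465 h) is the generator's ground truth
6/log(60): a colony growing from 1 mm to 60 mm diameter in six hours. All
90 simulated genes survive the detection filters; the samples all fall in
the common non-dimensional domain (T ≈ 3.91); the weighted-median
cut-off selects the most strongly patterned genes, which are then split
into six k-medoid pattern clusters. `analysisReport(res)` returns the
same numbers as a JSON-ready list with a markdown rendering, and
`patternScores(res@fit)` holds 𝓔, 𝓟, 𝓡 and the selection flag per gene.

On the metabolite side:

```r
diffusionTimescale(10)   # 6.944 h to diffuse 10 mm at D = 1e-9 m^2/s
```

compared with the ~2 h peak shift between positions 10 mm apart produced
by a front moving at 5 mm/h (`simMetaboliteSeries` + `peakShift`):
transport by the moving swarm front, not diffusion, dominates the
secrete-then-consume dynamics.

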