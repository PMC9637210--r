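---
title: "Models and methods behind fretfish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretfish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fretfish)
```

`fretfish` quantifies local chromatin compaction from FRET-coupled DNA FISH
probes. This vignette explains the models implemented, the parameters that
matter, the synthetic-data generators used for validation, and the design
choices made where the methodology left the details open.

## The measurement model

A FRET-FISH probe is a set of ~300 primary oligos tiling a genomic locus,
carrying alternating donor (D) and acceptor (A) dyes via fluorophore-
conjugated detection oligos. When the chromatin fibre is compact,
neighbouring D and A dyes come within the Förster radius
(R₀ = 52 Å for Cy3/Cy5, 60 Å for AF488/AF594) and energy transfer occurs
with efficiency

$$E(r) = \frac{1}{1 + (r/R_0)^6}.$$

The intensity read-out is sensitized emission: excite the donor, measure in
the acceptor emission band (the *FRET channel*). The compaction score of a
dot pair is

$$\mathrm{score} = 100\,\frac{I_{\mathrm{FRET}}}{I_{\mathrm{FRET}} + I_D},$$

which is invariant under joint intensity scaling, bounded in $[0, 100]$ and
monotone in the transferred fraction. Raw scores are reported without
crosstalk subtraction; single-dye control hybridizations provide the
baseline against which test distributions are compared
(`crosstalk_baseline()`), and an opt-in correction exists for users who
want it.

## Probe design

Candidates are all windows of length $l$ (default 60 nt, 1-nt steps) over
the target. Filters:

* GC fraction within $[0.35, 0.80]$ — **bounds inclusive**; "off the
  range" is read permissively so an exactly-35% oligo survives.
* longest homopolymer run ≤ 6 nt (a run of 7 or more rejects the oligo);
* any `N` rejects the oligo;
* homology: hit scores per oligo are *summed* (`aggregate_homology()`);
  the hit corresponding to an oligo's own locus is excluded by default,
  since every oligo trivially matches itself. Penalties above
  `homology_max` mark the oligo bad. Hits come from a BLAST tabular file
  or from the internal exhaustive scan (`homology_oracle()`), which treats
  the ambiguous external-aligner thresholds as ≥ 80% identity over the
  full oligo length, ungapped.

A good oligo whose candidate neighbours on both sides are bad is also
removed; isolated survivors in repetitive neighbourhoods are usually
artefacts.

Window selection places `n_total` slots on an ideal grid: groups of
`group_size` same-dye oligos separated by `spacing_same_dye` nt, adjacent
groups (alternating dye) separated by `spacing_between_dyes` nt, and at
least `min_gap` = 5 nt between consecutive targets. The layout presets
(`G1S50` … `G4S300`) name `group_size` and the between-dye spacing. Because
the methodology specifies only that selection uses "the penalty score and
the distance distribution", the objective here is an explicit documented
choice:

$$\min_{\text{anchor}} \sum_k \text{penalty}(o_k)
  + \lambda \sum_k |\text{start}(o_k) - \text{ideal}_k|,$$

with λ = 1 penalty-unit/nt, each slot snapping to the best usable candidate
within ±l/2 nt of its grid position, up to `incomplete_group_tolerance`
slots left unfilled (cost λ·l each), and ties between anchors broken toward
the smaller start coordinate. Every integer anchor offset is evaluated, so
the search is exhaustive and deterministic; the test suite checks it
against an independently coded brute-force enumeration.

**Defaults.** `n_total = 300`: with 60-nt oligos and 5-nt gaps this is the
densest layout that fits a ~20 kb target region, the scale used for probe
optimisation experiments; larger values are reachable by argument for
larger regions. Coordinates are 0-based half-open internally (BED native);
FASTA headers display 1-based inclusive coordinates. Probes are designed
on the supplied strand.

Assembly: design 1 is `L + T + R` with 20-nt adapters per dye role;
design 2 adds the stabilization strings 5'-`TAATT` and `AATTA`-3' to the
primary oligos so that the 3' end of each oligo is the reverse complement
of the 5' end of the next; design 3 keeps design-1 primaries and moves the
stabilization strings onto the detection oligos (the reverse complements of
the adapters). The explicit 5-nt strings are used; `TAATT` is exactly
`revcomp(AATTA)`, so complementarity is structural. The default adapters
shipped with the package are synthetic orthogonal sequences fixed once for
reproducibility; production probes should use validated adapter sets, and
any pair sharing a ≥ 15-nt substring triggers a warning.

## Image quantification

Stacks are `[z, y, x]` arrays with 0.3 µm focal spacing and a lateral pitch
of 1.9/7 ≈ 0.271 µm (the pixel size implied by the 7 px ↔ 1.9 µm pairing
threshold equivalence).

* **Segmentation**: Otsu threshold on the axial max projection, hole
  filling, watershed on the distance map to split touching nuclei, minimum
  area 50 µm². The interactive threshold tuning of microscope-suite
  workflows is replaced by this automatic rule. In 3D mode the volume is
  thresholded (pooled-histogram Otsu) and voxels take the label of their
  2D footprint — nuclei may not overlap in projection, which holds for
  monolayer fibroblast-like fields and for the simulator.
* **Dot detection**: difference-of-Gaussians band-pass, 3D local maxima
  above `quality_k` = 5 robust noise units, the `expected_per_nucleus`
  most intense kept (2 for a diploid locus), three-point parabolic
  sub-voxel refinement per axis.
* **Intensity statistic**: the read-out at a dot is
  background-subtracted, with local background estimated as the median of
  a 2-voxel-thick shell around a PSF-sized core box. The default statistic
  integrates over the core box, which estimates total spot photons and is
  directly comparable to the simulator's ground truth; a peak-voxel
  variant is available (`statistic = "peak"`). The score is insensitive to
  the choice as long as both channels use the same statistic.
* **Pairing**: donor and acceptor dots are matched within nuclei at the
  radial threshold of 7 px (1.9 µm; threshold applied in µm when a voxel
  size is supplied). For up to 7 dots per channel the matching is the
  exact maximum-cardinality, minimum-total-distance assignment; beyond
  that a distance-ascending greedy matching is used. The exact matcher is
  preferred over pure greedy because greedy can mispair chained
  configurations; on typical diploid nuclei the two coincide.
* **Chromatic shift**: bead fields imaged in both channels give a rigid
  translation (mean matched-bead displacement, centre-of-mass refined);
  dot coordinates are corrected by subtraction.
* **FRET read-out**: `I_FRET` is measured at the *acceptor* dot position
  in the FRET channel, `I_D` at the donor dot in the donor channel, both
  clipped at zero after background subtraction.

## Radial geometry and cell-cycle gating

Normalized lamina distance uses an anisotropic 3D Euclidean distance
transform (separable lower-envelope algorithm, implemented in the package
because no installed routine offers anisotropic 3D EDT), rescaled per
nucleus so the boundary maps to 0 and the deepest interior point to 1.
Dots are then assigned to four layers at the empirical quartiles of the
distance distribution — layer 1 outermost — with boundary ties resolved by
stable input order; with $n$ divisible by 4 and distinct values each layer
holds exactly $n/4$ dots. The alternative reading of the layers as
equal-volume shells differs from the quantile definition; the quantile
definition is implemented as the default.

DNA-content gating finds the valley between the two highest kernel-density
modes of log total DNA-stain intensity (Silverman bandwidth); if no
resolvable second mode exists, a two-component Gaussian mixture
(`mclust`) provides the boundary, and failing that all nuclei are flagged
`unknown`. Nuclei below the threshold are G1; within G1 the top quartile
by intensity is Hoechst-high and the remainder low (a bottom-quartile-only
definition of "low" is selectable). Mitotic cells cannot be recognised
from integrated intensity alone and are accepted only via user-supplied
annotations.

## Score distributions and comparisons

`split_modes()` estimates the score density (Silverman bandwidth,
overridable), requires a secondary mode of at least 10% of the main peak
with a genuine valley (< 95% of the lower peak), and splits at the valley;
the reported fractions are empirical proportions on either side. A
literal inflection-point variant (second-derivative zero crossing nearest
the valley) is available behind `method = "inflection"`. Thresholds are
equivariant under shifts of the data; fractions always sum to one.
Condition comparisons use the two-sided Wilcoxon rank-sum test with a
Hodges–Lehmann shift estimate. ATAC-seq concordance counts reads by their
5' start within windows spanning each probe's first-to-last oligo, pools
per-pair scores into per-locus means, and reports Spearman and Pearson
coefficients — compaction and accessibility should correlate negatively.

## Lifetime fitting

Tail fits model the region after the histogram maximum (plus two IRF
sigmas when an IRF is attached) as
$y(t) = \sum_i A_i e^{-(t - t_0)/\tau_i} + \mathrm{Bkgr}$, maximising the
Poisson likelihood of the counts (the natural objective for photon data;
least squares available for comparison). Component intensities are
$I_k = A_k \tau_k$ normalized to the bin width, and the two standard
averages are the intensity-weighted mean arrival time
$\tau_{AvInt} = \sum I_k \tau_k / \sum I_k$ and the amplitude-weighted mean
decay time $\tau_{AvAmp} = \sum A_k \tau_k / \sum A_k$; the former never
falls below the latter. Optimisation uses Nelder–Mead with a BFGS polish
and five seeded restarts, keeping the best deviance. When the component
count is not given, 1 vs 2 components are compared by AIC. Fits warn when
lifetimes closer than a ratio of 1.5 are requested from fewer than 10⁴
photons.

FRET efficiency from lifetimes is $E = 1 - \tau_{DA}/\tau_D$ with the
unquenched donor lifetime fixed (3.057 ns for AF488 in situ); negative
estimates are clipped to zero with a warning. The donor-model fit
convolves (discretely, FFT-based on the histogram grid) the shifted IRF
plus its background with a two-component decay, freeing the quenched
lifetime, both amplitudes, the IRF shift (continuous, by interpolation)
and the backgrounds. When the fitted quenched amplitude is ≈ 0 *or* the
quenched lifetime is indistinguishable from the unquenched one (the two
components are then interchangeable), no quenched fraction is resolvable
and the efficiency is reported as `NA`. The excitation repetition period
is not modelled: for lifetimes ≤ 4 ns and a ~13 ns period the wrap-around
contribution is negligible, a documented approximation. The Förster
distance of the dye pair is carried as metadata only; it enters the
simulator, not the lifetime estimator.

## The synthetic-data generators

The generators define the study conditions for all tests; they are part of
the package, seeded, and bit-reproducible.

* `sim_genome()`: i.i.d. nucleotides at a target GC with optional planted
  duplications (ground truth for homology search).
* `sim_image_dataset()`: fields of ellipsoidal nuclei (semi-axes
  5 × 5 × 2.2 µm, 8% jitter) with two dots per nucleus. Donor–acceptor
  separations follow a two-state mixture: compact at 56 Å and open at
  87 Å (E ≈ 0.6 and ≈ 0.1 at R₀ = 60 Å), log-normal within-state spread
  8%. Emission follows the channel definitions of sensitized-emission
  imaging: donor channel $(1-E)N_D$, FRET channel
  $EN_D + \beta(1-E)N_D + \alpha N_A$, acceptor channel $N_A$, with
  crosstalk α = 0.05 and bleed-through β = 0.05 (plausible single-scalar
  defaults; the dye pairs differ qualitatively but no numeric values are
  established, and the Cy pair is known to leak more than the AF pair).
  Photon budgets of 4000 per dot and channel over a 10-count background
  give peak SNR ≈ 10–15. Dots are rendered as 3D Gaussian PSFs
  (σ = 1.3 px lateral, 1 plane axial) with Poisson and Gaussian read
  noise. DNA content is a 2N/4N mixture (30% 4N) driving the stain
  intensity; a condensation factor jointly raises stain density and
  shrinks the radii (ATP-depletion emulation), and a separation scale
  < 1 emulates global compaction. Photon conservation
  ($\text{donor} + \text{transferred} = N_D$ before noise) is tested.
* `sim_decay()`: exponential-mixture arrival times, optional Gaussian
  IRF, uniform binning over 50 ns at 0.05 ns; out-of-range arrivals are
  clamped into the edge bins so counts always sum to the photon budget.
* `sim_atac()`: expected window counts decay exponentially with the
  compaction parameter (rate 3, base 2000) under multiplicative
  log-normal noise; read starts are uniform within windows.

**What the simulations do not emulate**: optical aberrations and depth-
dependent PSF changes, spectral unmixing errors, chromatin polymer
structure (dot separations are drawn independently per dot), nuclear
shapes beyond ellipsoids, hybridization-efficiency variation between
oligos, and detector afterpulsing. Passing tests therefore demonstrate
correctness of the estimators under a faithful physical forward model of
FRET photometry — not robustness to every microscope artefact. Dot
positions between channels differ only by localization jitter (0.3 px)
plus any configured chromatic shift, so pairing performance on real
images with larger chromatic errors depends on prior bead correction.

## Problem sizes and numerical choices

Validation workloads are sized for a single CPU: the end-to-end
compaction sweep uses five mixture weights at 200 nuclei (≈ 380 scored
pairs) per point, the lifetime recovery uses ten 1000-photon histograms
(the per-signal photon target of FLIM acquisitions) and efficiency
round-trips at 10⁵ photons, and probe-design oracle comparisons run on
instances of ≤ 200 candidates where exhaustive enumeration is exact.
Convergence tolerances: `reltol` 10⁻¹⁴ in both optimiser stages (a
noiseless mono-exponential is recovered to 10⁻⁶ relative error); KDE
bandwidths are Silverman's rule throughout; degenerate inputs (blank
images, empty masks, constant score vectors, all-identical distances)
return empty results, `NA`s or warnings rather than errors wherever the
scientific meaning is "nothing to measure".

## Known limitations

* The 3D labelling assumes nuclei do not overlap in axial projection.
* The window-selection objective is a documented surrogate for an
  under-specified original; with `lambda_spacing = 0` it reduces to pure
  penalty minimisation.
* The homology oracle is ungapped and full-length; it is a validation
  tool and a conservative stand-in, not a replacement for a
  genome-scale aligner on real designs.
* Greedy pairing (used only above 7 dots per channel) is not guaranteed
  optimal.
* FLIM fitting addresses per-signal histograms, not per-pixel lifetime
  imaging.
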