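# fretfish

Chromatin is packaged at very different densities across the genome and
across the cell cycle, but most genome-wide accessibility assays report
population averages. FRET-coupled DNA FISH ("FRET-FISH") measures local
chromatin compaction at individual gene loci in single fixed cells: a probe
of interleaved oligos carrying alternating FRET donor (D) and acceptor (A)
dyes is hybridized to a target locus, and the efficiency of energy transfer
between neighbouring dyes — which falls with the sixth power of their
separation — reads out how densely the locus is packed.

`fretfish` implements the complete computational side of this assay for R:

* **Probe design** — sliding-window oligo enumeration over a target
  sequence; composition filters (GC content within 35–80%, homopolymer runs
  of at most 6 nt); summed homology penalties from BLAST-tabular hits or an
  internal exhaustive search; selection of the best probe window under
  donor/acceptor group and spacing constraints (minimum 5 nt between
  consecutive 60-nt targets); and assembly of full oligo sequences for three
  design variants, including the complementary `AATTA`/`TAATT`
  stabilization strings.
* **Image quantification** — nucleus segmentation (Otsu threshold on the
  axial max projection + watershed), 3D spot detection (difference of
  Gaussians, sub-voxel refinement), bead-based chromatic shift estimation,
  donor–acceptor pairing at a 7 px / 1.9 µm radial threshold, and
  local-background-subtracted intensity read-out.
* **Compaction scoring** — the sensitized-emission score
  `score = 100 · I_FRET / (I_FRET + I_D)`, single-dye crosstalk baselines,
  kernel-density splitting of bimodal score distributions, rank-test
  condition comparisons, normalized lamina distances with four radial
  nuclear layers, DNA-content cell-cycle gating, and concordance with
  ATAC-seq window read counts (expected to be inversely correlated).
* **Lifetime fitting (FLIM)** — Poisson maximum-likelihood
  multi-exponential tail fits of photon-decay histograms, intensity- and
  amplitude-weighted average lifetimes, and an IRF-convolved two-component
  donor model with fixed unquenched lifetime, giving
  `E = 1 − τ_DA / τ_D`.
* **Synthetic data** — seeded generators for genomes, multi-channel 3D
  image stacks with a physical Förster-law emission model
  (`E = 1 / (1 + (r/R₀)⁶)`, crosstalk α, bleed-through β, Poisson noise),
  decay histograms, and accessibility tracks coupled to a compaction
  parameter — so every stage of the pipeline is testable without microscope
  data.

## Worked example

Simulate a two-state compaction experiment (half the loci compact at
~56 Å separation, half open at ~87 Å; R₀ = 60 Å), quantify it, and split
the score distribution:

```r
library(fretfish)

cfg <- sim_imaging_config(n_nuclei = 40, w_compact = 0.5, seed = 11)
ds  <- sim_image_dataset(cfg)
q   <- quantify_fields(ds$fields)
head(dplyr::select(q$pairs, nucleus_label, separation_px,
                   i_fret, i_donor, score_pct), 4)
#> # A tibble: 4 × 5
#>   nucleus_label separation_px i_fret i_donor score_pct
#>           <int>         <dbl>  <dbl>   <dbl>     <dbl>
#> 1             1         0.172  2179.   2132.      50.6
#> 2             1         0.143  2823.   1400.      66.8
#> 3             2         0.251  2323.   2260.      50.7
#> 4             2         0.129  3086.   1816.      63.0

split_modes(q$pairs$score_pct)
#> <mode_split> bimodal; threshold 37.07, fractions 0.5 / 0.5
```

Each row is one donor–acceptor dot pair; `score_pct` is the compaction
score (open loci here score ~15–25%, compact loci ~55–70% under 5%
crosstalk and bleed-through). The mode split recovers the generating
50/50 mixture and places the threshold in the valley between the modes.

Fitting a simulated 1000-photon decay histogram generated at the in-situ
AF488 donor lifetime:

```r
h <- sim_decay(3.057, photons = 1000, seed = 1)
fit_tail_multiexp(h, n = 1)
#> <lifetime_fit> 1 component(s): tau = 3.157 ns; tau_av_int = 3.157 ns;
#>   tau_av_amp = 3.157 ns
```

Probe design on a synthetic 20 kb region:

```r
region <- sim_genome(20000, seed = 20)
cands  <- enumerate_oligos(region$seq, 60) |> composition_filter()
probe  <- select_best_window(cands, design_params()) |>
  assemble_oligos(variant = "design3")
glance(probe)   # oligo counts, span, minimum gap, objective
export_probe(probe, "out/myprobe")   # FASTA + BED + TSV
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/fretfish.R` with `design`, `simulate`, `flim` and `modes`
subcommands.

## Vignette

`vignettes/fretfish-methods.Rmd` documents the models, the estimation
choices, the synthetic-data generators and their limitations.
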