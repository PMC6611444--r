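---
title: "Correlating glycomics, metabolomics, and worm-size distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlating glycomics, metabolomics, and worm-size distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycorr)
```

## The problem

*C. elegans* cultures lose developmental synchrony as they grow, so a sample
collected at a fixed time holds a mixture of stages. Molecular measurements
on such samples (targeted LC-MS/MS glycomics, 1D ^1^H NMR metabolomics)
therefore average over stages, and relating an analyte to a developmental
stage requires an independent readout of the population's composition. A
large-particle flow cytometer (Biosorter) provides exactly that: each worm
passes the flow cell as one event with a time of flight (TOF, proportional
to length) and an extinction (EXT, optical density), so a sample's event
cloud in the TOF x EXT plane is a population distribution over sizes.

`glycorr` implements the statistical machinery for linking the three data
types when all are measured on the same biological replicates:

1. **Targeted glycan quantification** from MS2 scans, with a candidate list
   of permethylated N- and O-glycan compositions and their computed
   lithiated m/z values.
2. **Biosorter binning** into mass-normalized 2D population maps,
   linearizable into sample vectors.
3. **NMR feature integration** over declarative ppm regions after
   probabilistic quotient normalization.
4. **STOCSY/SHY correlation**: every column of a fused data matrix is
   correlated against a driver (an analyte, or a worm-size region), and
   Biosorter-block correlations reproject onto the 2D map.
5. **Network and clustergram summaries** of the thresholded correlation
   structure.

## Glycan masses

Compositions are epimer-blind — Hex, HexNAc, dHex, HexA — because epimers
are isobaric in MS. The permethylated monoisotopic mass is a linear form in
the residue counts plus an end-group adjustment:

$$ M = n_\mathrm{Hex}\,204.0998 + n_\mathrm{HexNAc}\,245.1263 +
       n_\mathrm{dHex}\,174.0892 + n_\mathrm{HexA}\,218.0790 + E $$

with $E = 46.0419$ Da for a free (hemiacetal) reducing end (enzymatically
released N-glycans) and $E = 62.0732$ Da for the reduced alditol produced
by reductive beta-elimination (O-glycans). The difference, 16.0313 Da, is
one CH~2~ plus two hydrogens: ring opening, reduction, and the extra methyl
gained on permethylation. HexA is treated as its methyl ester, its state
after permethylation. Lithium adducts give
$m/z = (M + z \cdot 7.0160)/z$; the electron mass is far below the 0.1 Da
reporting precision and is ignored. The packaged candidate table (29
reduced O-glycans, 49 free-end N-glycans) is regression-tested against its
reference masses at ±0.1 Da; two of the largest O-glycans sit 0.05 Da above
the computed value, which the one-decimal reporting convention absorbs.

```{r masses}
comp <- parse_composition("Hex5HexNAc2", end_state = "free", glycan_class = "N")
permethylated_mass(comp)
lithiated_mz(permethylated_mass(comp), z = 1:2)
```

## Targeted MS2 quantification

For each candidate, scans past the 20-minute mark (column equilibration and
loading) whose precursor m/z lies within an inclusive 3 Da window of any
charge state's lithiated m/z (z = 1–3) are matched. The window is applied
in m/z units per charge state; isomers of one composition are summed as one
species by construction.

The background is estimated from *all* matched precursors before any
filtering: a histogram over `[0, maxPreInt]` with
`max(1, round(maxPreInt / numPrecursors))` equal-width bins is accumulated,
and the background `bgInt` is the upper edge of the first bin at which the
cumulative fraction reaches 0.15. This binned definition is unusual but is
implemented literally (a plain percentile is available via
`binned = FALSE` for sensitivity analysis). Scans with precursor intensity
strictly below `1.5 * bgInt` are discarded — a scan at exactly the
threshold is retained — and `glycanTIC` is the summed fragment intensity
over the retained scans.

Two normalizations follow. Per run, `repSumTIC` sums the TICs of all
experimental glycans; within a time point the largest run defines
`maxRepSumTIC` and each run is scaled by
`repNormFactor = repSumTIC / maxRepSumTIC` (so the largest run has factor
1). The internal standard (^13^C-permethylated isomaltopentaose, DP5,
spiked at equal amount into every replicate) is then set, per replicate,
to the maximum standard TIC over its time point's replicates
(`stdNormTIC`), and every experimental glycan's normalized TIC is divided
by it. The standard is deliberately *not* multiplied by the replicate
factor first: if it were, the factor would cancel algebraically and the
first normalization would be a no-op. Because the question is genuinely
open, `normalize_quant(standard_per_replicate = TRUE)` provides the
cancelling variant.

## Biosorter maps

Events are binned on the raw TOF and EXT axes (half-open 1-unit bins by
default) up to an inclusive bound of 1600 units; larger values are clump
artifacts. log10(EXT) is a display transform only — binning a log axis
with unit bins would collapse the map to a handful of rows. By default an
event is excluded if *either* axis exceeds the bound (the conservative
reading; `exclude = "both"` is available).

Counts are converted to estimated mass by weighting each bin with the
product of its TOF and EXT bin centers — length times optical thickness as
a mass proxy — and the map is divided by its total so it sums to 1. With
unit bins the within-bin mean and the bin center coincide to the bin
width; centers are used. Linearization extracts rows (TOF-major) into one
vector and is exactly invertible, which is what lets correlation vectors
reproject onto the map.

Worm-size regions (WS1–WS4) are non-overlapping rectangles whose summed
normalized weights proxy size-class abundance per sample. They are supplied
as data (a tibble or YAML/TSV file), not hard-coded, because the original
regions were hand-selected from overlaid population plots;
`default_ws_rois()` provides rectangles matched to the synthetic stage
models.

## NMR features

The interactive point-and-click feature binner is replaced by declarative
regions of interest: each feature is the per-sample sum of intensities
between a left and right ppm boundary (regions may overlap). Features
without labels are named by the ppm (two decimals) of the mean-spectrum
maximum inside the region; a collision takes the closest unused two-decimal
value. Preprocessing: per-sample referencing of the DSS maximum to 0.0 ppm
(integer-point shift), solvent-region masking (boundaries are configurable
— the original water/methanol limits are not recorded), and probabilistic
quotient normalization against the point-wise median spectrum (the common
reference convention; each spectrum is divided by the median of its
point-wise ratios to the reference). A deliberately simple cross-correlation
segment aligner stands in for the original combination of three published
alignment algorithms, which is out of scope; its segment boundaries default
to the original three-region scheme (cuts at 3.3566 and 4.7651 ppm), ties
break toward zero shift, and vacated points take the edge value.

## Fusion, STOCSY/SHY, networks

Linearized Biosorter vectors are concatenated with analytical feature
vectors over the common samples. Bins empty in every sample carry no
correlation information and are not stored; the column catalog keeps 2D
indices so maps reconstruct exactly. STOCSY correlates every column with a
driver column (Pearson; two-sided t p-values; zero-variance columns are
masked rather than erroring, since most of a 1600 x 1600 grid is empty).
The inverse mode drives with a worm-size region's per-sample sum, and is
identical to SHY between that series and the feature table — an identity
the tests assert. p-values are reported raw, matching the original
analysis; Benjamini–Hochberg is available downstream via `p.adjust` if
wanted. Spearman is offered behind a flag for robustness checks only.

The network keeps an undirected edge wherever `|r| >= 0.5` (inclusive) and
types nodes as worm sizes, N-glycans (`NG_<id>`), O-glycans (`OG_<id>`),
or NMR features (ppm labels). Exports are GraphML and TSV tables,
re-importable losslessly. No display threshold is applied to correlation
maps by default (they show the full −1..1 scale); 0.5 is the network
default.

The clustergram standardizes each analyte's time-point profile to mean 0,
sd 1 (a constant profile is an error naming the analyte), then clusters
*both* dimensions of the standardized matrix with Euclidean distance and
average linkage — the row-standardize-first order is a choice the original
description leaves open, made here so that column distances reflect shape
rather than scale.

## The synthetic study

Real deposited data is not required: `make_study()` generates all three
platforms with known truth, under a fixed design of 5 time points x 7
replicates (35 samples). Five stage models (L1 to adult) are bivariate
Gaussians in (TOF, log10 EXT) with within-stage correlation 0.6; time
points drift from pure L1 at T1 to a bimodal adult-plus-offspring mixture
at T5, which is why T5 clusters next to T1 in the profile clustergram.
Per sample, stage weights are jittered (log-normal, sdlog 0.08) and analyte
truths follow a linear stage coupling plus a baseline of 0.5 with
log-normal noise (sdlog 0.15). MS runs draw a fixed number of scans per
detectable candidate with 0.2 Da precursor jitter (deterministic matching
at the 3 Da window), log-normal intensity noise, a per-run efficiency
factor (sdlog 0.1), near-isobaric low-intensity background scans in each
candidate window (the population the binned 15th-percentile background
estimator presupposes under Top-10 acquisition), and random-m/z decoys.
NMR spectra are sums of Lorentzians (area proportional to concentration)
with a DSS singlet at 0, baseline noise, and a per-sample dilution factor
that PQN must remove. The internal standard has constant true amount,
exercising the max-replacement rule. The default couplings plant positive
glycan–size, metabolite–size, and metabolite–glycan associations
(`attr(default_coupling(), "planted")`), including an adult-coupled
UDP-GlcNAc/charged-O-glycan block and an L1-coupled
phosphorylcholine/N-glycan block.

What the generator does *not* emulate: chromatographic peak shapes,
isotope envelopes, retention-time drift, NMR multiplets, pH-dependent
shift changes, or genuinely compositional acquisition effects beyond the
per-run efficiency factor. Passing tests therefore demonstrate the
statistical pipeline's correctness and sensitivity under a faithful but
idealized acquisition model, not instrument-level realism. The original
study also pooled its seven first-time-point NMR replicates for
sensitivity; the generator keeps a one-to-one sample correspondence across
platforms, since the pooling was a wet-lab workaround rather than part of
the method.

```{r study}
study <- make_study(seed = 1)
study
res <- analyze_study(study)
net <- build_network(res$features, res$types, threshold = 0.5)
glance(net)
head(tidy(net))
```

## Numerical choices and problem sizes

* Matching windows are inclusive (`<= 3` Da); the discard rule is strict
  (`< 1.5 x bgInt` discarded), both following the stated conventions.
* Zero-variance columns are masked (`NA`), never silently zero.
* Agglomeration is delegated to `stats::hclust` (average linkage) and is
  cross-checked in the tests against an explicit O(n^3) agglomeration.
* Tests and examples bin Biosorter maps at 10–25 units rather than 1, and
  simulate 600 events per sample: region sums and correlations are
  insensitive to the bin width well below the region size, and these sizes
  keep the full 35-sample pipeline fast enough to run many seeded
  replicates. The default `bin_size = 1` remains the instrument-workflow
  setting.
* Seeded generators restore the caller's RNG state; every stochastic test
  fixes its seed.

## Limitations

Fragment-level structure assignment, isomer resolution, natively
methylated and phosphorylcholine-modified species, deisotoping, and
retention alignment are out of scope on the MS side; peak picking,
deconvolution, and metabolite identification on the NMR side. Correlation
networks here are thresholded Pearson graphs — no partial correlations or
network inference. The worm-mass proxy (TOF x EXT) neglects bent worms and
stage-dependent optical properties.
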