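---
title: "Annotating DDA mass spectrometry imaging runs with msidda"
author: "msidda authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating DDA mass spectrometry imaging runs with msidda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msidda)
```

## The problem

MALDI mass spectrometry imaging (MSI) maps small molecules across a tissue
section, but annotation from MS1 exact mass alone is ambiguous: many
formulas, adducts and isomers fall within a few ppm of any observed peak.
Running data-dependent acquisition (DDA) during the imaging run itself
yields fragmentation (MS2) spectra for in-situ identification, at the price
of a scan stream in which many MS2 events are artifacts: spectra triggered
while the laser was off, or on precursors that were transient noise.

`msidda` processes such runs end to end: it reads the centroided mzML scan
stream and the stage position/laser log, filters MS2 spectra with a
two-criterion quality test, annotates the survivors against MS2 spectral
libraries, and reconstructs per-pixel ion images. A built-in DDA instrument
simulator generates complete synthetic runs with ground truth, so every
stage is testable without instrument data.

## Raster geometry

Acquisition uses constant-speed raster motion: the stage sweeps each line
at `plateVelocity` (µm/s) while the instrument cycles full scans every
`cyclePeriod` (s). One cycle therefore covers
`plateVelocity × cyclePeriod` µm, which is the natural along-track pixel
pitch; `rasterGeometry()` uses that product as the default pitch and only
decouples the two when the user overrides it. This keeps the geometry
internally consistent regardless of which pair of numbers (velocity, cycle
time, nominal resolution) an instrument method reports, since reported
trios are not always mutually consistent. Package defaults emulate 100 µm
pixels at a 0.6 s cycle (velocity 166.7 µm/s).

A scan at time *t* maps to the raster line whose half-open window
[t_start, t_end) contains *t* and to column
`floor((t − t_start) · v / pitch)`, clipped to the grid; serpentine
rastering (odd lines reversed) is a flag, off by default since both
conventions occur in practice. Geometry can be supplied explicitly or
derived from the position log (`geometryFromLog()`); both paths exist
because stage logs do not always carry enough metadata to reconstruct the
grid alone.

## The MS2 quality filter

A fragmentation spectrum is kept only if

1. **the laser was active** at the MS2 scan's start time (intervals are
   half-open: `t_on` is active, `t_off` is not), and
2. **the precursor is consistent**: a centroid within the ppm tolerance of
   the reported precursor m/z appears in each of the next *w* MS1 survey
   scans strictly after the scan in which the precursor was chosen —
   *w* = 2 for parallel (multi-analyzer) acquisition, *w* = 1 for
   sequential.

Three readings of criterion 2 were genuinely open and are resolved as
follows. "Scan events" are counted over MS1 full scans only, skipping
interleaved MS2 scans, because a precursor can only be re-observed in a
survey spectrum. Presence requires any matching centroid with no intensity
minimum (a configurable floor, default 0, is exposed). And an MS2 scan so
close to the end of the run that fewer than *w* surveys remain **fails**
the criterion rather than being skipped — conservative, so that "valid"
always means positively confirmed. Only following scans are inspected,
never preceding ones. The per-run summary reports the three nested counts
(total MS2, laser-active, fully valid) that characterize a run's quality.

## Annotation cascade

For each valid MS2 scan the pipeline:

1. forms one neutral-mass hypothesis per adduct of the run polarity,
   `M = m/z − shift`, using the common singly charged MALDI adducts —
   [M+H]⁺ and [M+Na]⁺ in positive mode, [M−H]⁻ and [M+Cl]⁻ in negative
   mode. Shifts are electron-mass corrected (+1.00727646, +22.98922070,
   −1.00727646, +34.96940126 Da); precursors are assumed singly charged,
   the overwhelmingly dominant state for MALDI small-molecule ions. The
   instrument-reported isolation target is used as-is (no recalibration
   step);
2. matches every hypothesis against every library entry whose exact
   neutral mass lies within the ppm tolerance (default 5 ppm). Entries
   declaring an adduct are restricted to the matching hypothesis; entries
   without one are eligible for all. No pre-filtering by formula
   plausibility is applied — candidate explosion (isomers, alternative
   adducts, repeated collision energies) is expected and resolved by
   scoring, not earlier;
3. scores each candidate by cosine similarity between the empirical and
   library spectra, and keeps **only the highest score**, with ties broken
   by smaller |ppm error| and then lexicographic compound id so output is
   deterministic. Predicted and experimental library spectra are scored
   identically; provenance is carried through to the output for the user
   to weigh.

### Cosine details

Peaks are paired greedily by nearest m/z: all cross-spectrum pairs within
tolerance are sorted by distance and assigned in order, each peak used at
most once — deterministic and order-independent. The score is
`Σ paired(a·b) / (‖a‖‖b‖)` over the full intensity vectors, so unpaired
peaks dilute the score through the norms; identical spectra give 1,
disjoint spectra 0, and the score is invariant to uniform intensity
scaling. The fragment-pairing tolerance is the wider of a ppm window at
the fragment m/z and an absolute floor of 0.01 Da, because MS2 may be
detected either in an Orbitrap (high resolution, ppm-limited) or in a
linear ion trap (low resolution, Da-limited). Plain cosine on raw
intensities is the default; square-root weighting is available but off.

## Imaging

An extracted ion map sums, per MS1 scan, the centroid intensities within a
symmetric ppm window (consistent with the pipeline's single ppm parameter)
and accumulates them into the scan's pixel. Multiple scans landing in one
pixel are **summed**, not averaged, so the grid total equals the total
extracted intensity (ion-count conservation). Pixels never visited are
missing (NA), not zero — zero means "visited, target absent". Optional TIC
normalization divides each pixel by its total ion current; pixels with
zero TIC become missing, and no global rescaling is applied afterwards.
Because cosine similarity is scale-invariant, TIC normalization affects
imaging only, never scoring. Percentile clipping (99.5%) for hot pixels is
applied at PNG export only; stored grids and CSV exports are never
display-scaled.

## The simulator

`simulateRun()` emulates the acquisition itself, not the physics: one MS1
scan per pixel built from planted compounds (abundance × phantom mask)
plus matrix background ions that are brighter off-tissue than on-tissue
(tissue acts as an insulator, so matrix ion yield — and hence TIC — is
higher outside the sample). The DDA engine then selects precursors per
cycle by descending intensity (standard TopN ordering) among peaks that
are above the minimum precursor intensity, not ppm-matched by the
exclusion list, and not dynamically excluded. Sequential mode emits up to
`topN` MS2 per cycle; parallel mode emits every eligible precursor, since
the second analyzer acquires MS2 without consuming cycle time (exact
multi-analyzer scheduling is not reproduced). Dynamic exclusion clusters
selected m/z values at the engine's ppm tolerance; a cluster selected
`max_occurrences` times within `occurrence_window_s` is ineligible for
`exclusion_duration_s`. Defaults are the acquisition regime the pipeline
targets: exclusion after 2 occurrences within 3 s for 5400 s, TopN 4,
isolation window 1 Th, m/z 150–900.

Noise is multiplicative log-normal on intensities (CV 0.1 by default) and
Gaussian ppm jitter on m/z (1 ppm), matching the ppm-based tolerances the
pipeline uses. Runs are deterministic for a fixed seed, down to
byte-identical mzML. `makeLibrary(decoy = TRUE)` redraws each fragment m/z
uniformly within the mass range while preserving intensities — a negative
control whose precursor masses still match but whose spectra should score
near zero.

What the simulator does **not** emulate — isotope fine structure (a single
monoisotopic peak per ion), in-source fragmentation, chimeric isolation of
co-eluting precursors, detector saturation, and spatial intensity
gradients beyond the phantom masks. Passing tests on simulated data
therefore demonstrate the correctness of the scan-stream bookkeeping, the
QC logic, the matching/scoring arithmetic and the imaging accumulation;
they do not demonstrate robustness to mixed spectra, which on real data is
the main cause of low MS2 scores.

## Numerical choices

* Pixel mapping adds a 1e-9 epsilon before `floor()` because simulated and
  real scans commonly start exactly on pixel boundaries.
* `Scan` validity requires strictly increasing centroid m/z and a TIC
  equal to the intensity sum within 1e-9 relative tolerance; the simulator
  nudges jitter-induced ties by 1e-10 relative.
* Exclusion-region masks use center-to-center pixel distances with the
  grid's physical pitch and line spacing; ROI pixels are never part of the
  mask, so a zero margin yields the exact complement of the ROI.
* Test and acceptance problem sizes (grids of a few hundred to a few
  thousand pixels, libraries of tens to hundreds of entries, 100-run QC
  randomization) were chosen as the smallest scenes that exercise every
  code path several times over; all results are seed-stable.

## Known limitations

Profile-mode spectra are rejected, never centroided. imzML and vendor raw
formats are out of scope (convert to mzML first). The position-log XML
dialect is a documented stand-in for stage-control logs whose schema is
vendor-specific; a real-world adapter can map onto it. Mixed MS2 spectra
from co-isolated isobars are scored as-is and typically produce low cosine
scores rather than being deconvolved.
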