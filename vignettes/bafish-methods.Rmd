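---
title: "Methods: break-apart FISH event calling and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: break-apart FISH event calling and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and its statistical model

Break-apart FISH labels the two ends of a candidate breakpoint region of one
gene ("gene A") with differently colored probes — here Green (5') and Red
(3') — so that an intact allele appears as a proximal Red/Green doublet and a
broken allele as two separated signals. A third probe in a far-red channel
marks the partner gene ("gene B"); a broken gene-A allele whose Red signal
lies next to a FarRed signal indicates a joined (translocated) locus. Because
the readout is per allele and per cell, rare events can be quantified by
imaging very many interphase nuclei and counting cells that carry at least
one event.

`bafish` implements the full measurement chain:

1. **Image analysis** — maximum z-projection per channel, DAPI-based nucleus
   segmentation with morphology filters, and spot detection constrained to
   nuclear regions of interest.
2. **Event calling** — per-nucleus quality control, per-Red-signal minimum
   distances to Green and FarRed signals (R-G~min~, R-FR~min~), and
   threshold-based classification.
3. **Statistics** — event-positive proportions with modified Wald
   (Agresti–Coull) 95% confidence intervals, pairwise Fisher exact tests
   between conditions, and empirical calibration of the proximity threshold.
4. **Synthetic imaging** — a generator that renders multi-channel z-stacks
   of nuclei with known allele states, so each stage above can be validated
   against exact ground truth.

### Event definitions

With a proximity threshold $t$ (default 4 px = 1.28 µm at 0.32 µm/px):

* a Red signal is a **breakage event** iff $RG_{\min} > t$;
* it is a **translocation event** iff additionally $RFR_{\min} \le t$;
* signals separated by $t$ or fewer pixels are proximal, so $RG_{\min} = t$
  exactly is intact.

A translocation satisfies the breakage condition and is counted in breakage
tallies. A nucleus is positive for an event class if it carries at least one
event of that class. Distances are center-to-center Euclidean distances in
2D, measured on maximum projections; this is a deliberate conflation of the
3D geometry (two signals overlapping in z project onto nearby 2D positions)
and is shared by design with the assay being modeled.

### Quality control

Only nuclei with at least two signals in each FISH channel *and* equal Red
and Green counts enter event calling. An intact or broken allele contributes
one Red and one Green signal either way, so unequal counts indicate missed
or spurious detections rather than biology. QC-failing nuclei are retained
in outputs with a reason, but contribute no events and are excluded from
denominators.

### Proportion intervals and comparisons

The modified Wald interval uses $\tilde p = (x+2)/(n+4)$ with half-width
$z\sqrt{\tilde p(1-\tilde p)/(n+4)}$ and $z = 1.96$ at the 95% level, clipped
to $[0,1]$. It behaves well for the rare-event proportions this assay
produces (empirical coverage stays above ~92% at $n = 1000$,
$p \in \{0.005, 0.02\}$ in the test suite's simulation; the method is
approximate, not exact). Pairwise condition comparisons use the two-sided
Fisher exact test in the standard count-data convention (sum of
hypergeometric probabilities of tables at most as probable as the observed
one) on positive/negative counts, with no multiple-testing correction —
comparisons are reported as unadjusted pairwise tests, and downstream users
can adjust as their design requires. One reproducibility note: the published
p-values this package's acceptance checks reproduce derive from 2×2 tables
whose second column held the *total* nuclei counted rather than the
negatives; feeding the printed count pairs directly reproduces those values
exactly, while the package's own comparisons use positives/negatives.

### Threshold calibration

`calibrate_threshold()` takes the per-Red $RG_{\min}$ distribution of a
negative-control condition (post-QC) and returns the smallest integer pixel
threshold covering a target fraction (default 99.8%) of it. On synthetic
unbroken populations with the default intact offset the calibrated threshold
is 3 px — at or below the canonical 4 px — and stable across seeds; the
default threshold stays at 4 px for comparability with the assay's
published calibration.

## The synthetic-imaging model

The generator emulates a 40× confocal screen: 0.32 µm pixels, seven z-planes
1.5 µm apart, DAPI plus Green/Red/FarRed acquired sequentially. Defaults are
chosen once to represent that regime:

* **Nuclei** are ellipses with semi-axes drawn uniformly from 4.5–6.0 µm
  (lymphoma-line scale), extruded in z with a Gaussian axial intensity
  profile (σ = 2 µm); no chromatin texture is modeled because the analysis
  contract only needs a segmentable DAPI mask. Nuclei are placed without
  overlap and with a 6 px minimum gap — sparse plating — so the default
  segmentation (no watershed) can separate them; watershed splitting of
  touching nuclei exists as an option.
* **Loci.** Each cell carries `n_alleles_A` break-apart loci (default 3) and
  `n_alleles_B` partner loci (default 2), matching the modal allele counts
  of the translocation-negative calibration line. Loci of the *same* gene
  are placed uniformly subject to a minimum pairwise distance of 2 µm,
  reflecting that distinct alleles occupy distinct chromosome territories
  and are practically never co-located within optical resolution. Loci of
  *different* genes are unconstrained, which preserves the substantial
  random Red/FarRed proximity background (order 10–20% of pairs within
  4 px) that makes the simultaneous breakage condition necessary for
  translocation calling.
* **Allele states.** Each gene-A allele breaks with probability `p_break`;
  a broken allele is translocated with probability
  `p_transloc_given_break`, in which case one FarRed locus (without
  duplication) relocates next to the separated Red signal. Red/Green
  offsets are Rayleigh-distributed with mean 0.32 µm (intact; median
  observed distance ≈ 1 px) or 3.2 µm (broken); the translocated Red/FarRed
  offset has mean 0.32 µm. The Rayleigh form is a modeling convenience —
  the parametric form of the real intact-distance distribution is not
  established — and all three means are configurable.
* **Optics and noise.** Spots are 3D Gaussians with lateral σ = 0.45 px
  (≈ 1 px FWHM, the diffraction limit of an NA 0.9 lens at these
  wavelengths and pixel size) and axial σ = 0.75 µm; in-focus peak
  amplitude 400 photons over a 20-photon background, with Poisson shot
  noise and Gaussian read noise (σ = 3). No field illumination gradients,
  aberrations, or hybridization variability are modeled.
* **Determinism.** One master seed; per-field seeds are derived by a fixed
  counter scheme (`(seed + 7919·k) mod 2³¹−1`), so any field regenerates
  independently and whole datasets are byte-reproducible.

### What the simulation does and does not show

Passing simulation-based tests demonstrates that segmentation, detection,
distance computation, classification and statistics are correct *given* the
generative model: isolated diffraction-limited spots, clean elliptical
nuclei, spatially uniform noise. Real screens add hybridization failures,
probe cross-talk, debris, uneven illumination and touching cells; the >99%
simulated detection accuracy is therefore a statement about the algorithm,
not a guarantee for any particular dataset. The QC filter and the excluded-
with-reason audit trail are the run-time defenses against those artifacts.

### Molecular truth versus measurable truth

The ground-truth tables record the *molecular* allele state (intact /
broken / translocated) and the true spot coordinates. These differ: a
broken allele whose ends happen to lie within 4 px (about 12% under the
default broken-offset distribution), or whose Red signal falls near an
unrelated Green signal, is molecularly broken but not measurable as such —
the same intrinsic false-negative mechanism that leaves a few percent of
clonally translocated cells undetected in the real assay. Parameter-recovery
tests therefore compare pipeline estimates against the *measurable* truth
(the event definitions applied to true coordinates); the molecular-to-
measurable gap is a property of the assay, visible in the ground-truth
tables, not a pipeline defect.

## Numerical and design choices

* **Segmentation**: Gaussian blur (σ = 2 px) → global Otsu → hole filling →
  connected components; filters on area (500–15 000 px²), roundness
  (4πA/P² ≥ 0.5, clipped at 1 against discrete-perimeter bias) and border
  contact. The nucleus-segmentation and spot-detection parameters of the
  original screen are not published; these defaults are declared, not
  claimed identical.
* **Spot detection**: difference of Gaussians (σ = 0.45/2.0 px) → local
  maxima on a 3× bilinearly upsampled band-passed image (on the original
  grid, two spots less than ~2.3 px apart cannot yield two 3×3 maxima) →
  robust threshold at median + 7·MAD of the band-passed signal inside the
  nucleus (floored against numerical residue on noise-free input) → minimum
  separation 0.9 px, brighter peak wins, with a second suppression pass on
  refined centroids to collapse plateau duplicates → sub-pixel centroid by
  DoG-weighted intensity in a 3×3 window.
* **Coordinates**: 0-based pixels, origin top-left, x = column; thresholds
  are configured in pixels and converted from µm-coordinates on input when
  a table declares micrometer units.
* **Percent formatting**: two significant figures below 1%, three above,
  with raw fractions always carried alongside.
* **Problem sizes in tests**: the suite validates detection on ~1000 nuclei
  per benchmark, parameter recovery on 5000 cells per condition at 192×192
  px fields with 10 cells per field, and a six-point titration
  (0–100% translocation-positive cells, 7200 cells total, larger samples at
  the low fractions where counting noise dominates). These sizes keep the
  binomial intervals decisive for the rates under test.

## Known limitations

* No 3D spot localization; z-overlap can merge distinct signals, exactly as
  in the 2D-projection analysis being modeled.
* The simulator does not model chromosome-territory statistics beyond the
  minimum-spacing rule, nor instrument-specific PSFs; its photon budget is
  representative, not fitted.
* `calibrate_threshold` assumes its input comes from a genuinely unbroken
  condition; contamination above the coverage quantile shifts the result.
* Fisher comparisons are unadjusted; with many conditions, control the
  family-wise error downstream.
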