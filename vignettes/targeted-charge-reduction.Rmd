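---
title: "Targeted charge reduction: models, parameters and their limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted charge reduction: models, parameters and their limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tptcr)
```

This vignette is the package's own account of the science it
implements: the models behind each module, the tunable parameters and
why their defaults are what they are, what the synthetic data generator
does and does not emulate, and the numerical choices that matter.

## The measurement problem

A non-covalent protein–drug complex formed in tissue — the running
example is liver fatty acid binding protein (FABP1, a ~14.3 kDa
β-barrel) bound 1:1 to the fibrate drug bezafibrate (C19H20ClNO4,
monoisotopic 361.108 Da) — is a trace species among abundant free
proteins. Detecting and imaging it by native ambient MS runs into three
walls at once:

1. **Abundance.** In a full scan the complex sits below the noise floor
   and under ion suppression from the co-sprayed proteome.
2. **Resolution.** Imaging-compatible acquisition is low-resolution:
   isotopes are unresolved, so a lone peak's charge (and hence mass) is
   unknown.
3. **Specificity.** Any background ion near the precursor *m/z*
   contaminates a precursor-window image.

The workflow answers each in turn: selected-ion-monitoring (SIM)
accumulation for abundance; charge-reduction ladders for mass;
product-ion-only imaging for specificity.

## Charge-state arithmetic

All *m/z* arithmetic uses the charge-carrier convention of native MS:
`m/z = (M + z·m_adduct)/z` with the proton fixed at 1.007276 Da. The
electron mass is neglected, an error below 0.01 Da per charge — two
orders of magnitude under the 0.5 Da tolerances relevant here. Protein
masses are treated as average-mass centroids (isotope envelopes are
unresolved at resolving power ~1000); ligand losses are matched
monoisotopically, because a small molecule's most abundant isotopologue
is the monoisotopic one and the observed 361 Da loss matches
bezafibrate's monoisotopic mass.

Adjacent charge states *z* and *z−1* of one species satisfy
`z = 1 + (mz_low − p)/(mz_high − mz_low)`. The implementation rounds
this real-valued estimate to the nearest integer but refuses to guess
when the estimate sits more than 0.3 from any integer
(`tptcr_ambiguous_charge`), and rejects inferred charges below 2
outright — a ladder can never contain charge 0. Note one genuine
degeneracy: the (1+, apparent 0+) positions of a mass M coincide
exactly with the (2+, 1+) pair of mass 2M, and the toolkit reads such a
pair as the latter, which is the only physically valid interpretation.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the rest of the package is validated under.

**Charge envelopes.** Folded proteins electrosprayed from
non-denaturing buffer carry few charges: intensity is spread over
integer charges with Gaussian weights around a centre `z0` (8 for the
~14–16 kDa species, 6 for ~10 kDa ACBP) with width `sigma_z = 0.7`.
That makes the 8+ state of the complex dominant, at *m/z* 1835.4.

**The liver mixture.** `liver_mixture()` carries apo-FABP1 (14314.3 Da,
abundance 1), the [FABP1+bezafibrate] complex (14675.4 Da, default
0.005 — a trace level chosen so the complex is *not* detectable in a
default full scan, which is precisely the regime the targeted workflow
exists for), heme-bound α-globin (15812.2 Da, 0.3, the vasculature
marker) and ACBP (nominal 9938.0 Da, 0.4). The protein masses are the
centroid values consistent with the charge-reduced ladders the workflow
targets; the ACBP mass is a nominal stand-in for a ~10 kDa cytosolic
protein.

**Rendering.** Centroid peaks become Gaussians of FWHM = *m/z*/R on a
uniform axis sampled at one fifth of the narrowest FWHM; each peak's
integral equals its centroid intensity. Noise is additive per-sample
Gaussian (`noise_sd`, default 0.002 in the mixture's abundance units)
plus multiplicative per-peak shot noise (`shot_cv = 0.02`). All
randomness is seeded; a fixed seed reproduces a spectrum or phantom
bit-identically, and the seed is recorded in output metadata.

**SIM.** Modelled as ion accumulation: restricting the scan window
multiplies peak intensities by the gain `g` (default 20) while the
noise floor is unchanged, so SNR improves by the factor g. The
alternative reading — noise averaging at fixed signal — was rejected:
accumulation is the stated mechanism of SIM on trapping instruments,
and the intensity-gain model makes the full-scan/SIM SNR ratio a
directly testable invariant.

**PTCR.** Ion/ion proton transfer is modelled by the number of
transfers per ion, k ~ Poisson(μ) truncated to 1 ≤ k < z for the
reacted fraction, with the precursor surviving with probability
P(k = 0). No kinetics are published for the modelled system, so the
memoryless event-count model is the simplest defensible choice, and
μ (default 1.5) is exposed. The partition is applied to intensities
deterministically — a peak is an ensemble of many ions, so the expected
partition is the observable; shot-to-shot randomness enters through the
rendering noise, which keeps the partition itself exactly
intensity-conserving.

**HCD.** Dissociation probability follows the saturating curve
p_d = 1 − exp(−NCE/5%), giving substantial but incomplete dissociation
at the 7 % NCE used for the complex. The observed (and unusual)
pathway is neutral ligand loss: the protein product retains the
precursor charge and *no* ion appears at the free ligand's *m/z*. A
charged-ligand pathway exists behind `charged_ligand_fraction` but is
off by default.

**The tissue phantom.** A row-major line-scan grid (default 64×64,
150 µm pixels) with three disjoint, covering regions: background
outside an inscribed tissue ellipse, a circular blood-vessel disc, and
bulk tissue. α-globin lives in the vessel; FABP1, the complex and ACBP
in bulk; each species' base abundance is modulated by seeded log-normal
texture (CV 0.15) with 1 % leakage into its non-home region (so
contrast ratios are finite and Pearson correlations well-defined). The
complex clears exponentially, base × 2^(−t/t½) with t½ = 4.5 h, the
midpoint of the 4–5 h plasma half-life reported for rats — so a 2 h
phantom carries 2^(4/4.5) ≈ 1.85× the complex of a 6 h phantom. When
dosed, protonated/sodiated/potassiated free drug is added to bulk
pixels. Per-pixel spectra are the profile rendering of the multiplexed
PTCR scan; because isolation-and-accumulation is the same mechanism the
SIM gain models, the configured gain applies to the targeted peaks,
which is what makes the trace complex imageable — as it is in the real
targeted experiment — while remaining invisible in full scans.

**What the phantom does not emulate.** Chemical background (lipids,
matrix clusters), ion-mobility and space-charge effects, detector
saturation, spatial partial-volume mixing at region boundaries, and
biological heterogeneity beyond log-normal texture. Passing the imaging
tests therefore shows that the *pipeline* is correct and specific under
controlled conditions, not that real tissue images of this quality are
guaranteed.

## Deconvolution

Centroiding takes local maxima above `snr_threshold` (default 3) times
a median-absolute-deviation noise estimate, then refines positions by
an intensity-weighted centroid over the half-height window. When the
spectrum records its resolving power, isolated peaks get a second
refinement: a matched Gaussian template fit at the known instrumental
width (amplitude solved linearly, position by one-dimensional
minimisation). This is the step that makes low-resolution ladders
mass-accurate — at SNR 20 it cuts position jitter about five-fold
relative to the weighted centroid, which is the difference between
~0.1 Da and ~1 Da mass errors at charge 7. Peaks measurably wider than
1.1× the instrumental FWHM (or with multiple apexes inside half a
FWHM) are flagged as unresolved composites and kept at the weighted
centroid.

Charge-series finding tries every centroid pair as a candidate
(z, z−1) pair, keeps those whose implied mass predicts the partner
within `mz_tol` (default 0.2 m/z, the low-resolution PTCR regime), and
grows each ladder greedily in both charge directions. Candidates score
`members − λ·spread/mz_tol` with λ = 1 — monotone in evidence, simple,
and sufficient to rank true ladders above the sub-mass harmonics that
pair enumeration inevitably produces. Overlapping ladders are all
reported, because multiplexed tPTCR scans genuinely interleave several
species. The reported mass is the *unweighted* mean of per-member
masses (product intensities reflect PTCR kinetics, not mass accuracy);
the max−min spread doubles as a self-consistency diagnostic. Charges
above 30 are not considered (native proteins well under 100 kDa).

## Targeted imaging

Target tables compute each species' precursor *m/z* and its first
`n_reduced` product *m/z* from the neutral mass; precursors at or above
the quadrupole isolation limit (default 2000, the instrument constraint
that in practice caps which species can be multiplexed) are rejected by
name. Product-ion images integrate fixed windows (half-width default
0.5 m/z) around the *product* positions only; the precursor window is
excluded by construction, which is the tPTCR specificity claim in
executable form — a 1+ background ion parked exactly on the complex
precursor *m/z* changes the product image by nothing beyond rendering
tails. Default normalisation is none (TIC normalisation can distort
native MSI when region chemistry differs; it is offered as an option,
computed on non-negative signal with near-empty pixels zeroed rather
than divided by a vanishing denominator). Composites min–max scale each
channel independently: the published rendering convention is
qualitative contrast, not absolute units.

## Numerical and degenerate-input choices

* Ambiguous charge estimates (> 0.3 from an integer) and sub-minimum
  peak spacings raise typed errors rather than guessing.
* A one-member ladder never reports a mass (`tptcr_insufficient_evidence`).
* Species matching ties break toward smaller |Δmass| then alphabetical
  name, and are flagged.
* All-zero spectra centroid to an empty peak list, not an error; empty
  extraction windows return 0 with a logged warning.
* Missing imaging pixels render as 0 and are flagged in a QC mask;
  duplicate pixel coordinates are an error naming the pixel.
* Fragment matching is greedy nearest-ppm with each observed peak and
  each theoretical fragment used at most once; coverage counts cleavage
  sites, not fragments.

## Problem sizes used in the tests

The shipped suite validates parameter recovery with 100 seeded
single-species PTCR runs at resolving power 1000 and SNR 20, imaging
recovery on the default 64×64 phantom plus 32×32 and 16×16 phantoms
for the comparative checks, and the no-hallucination rate on 60 pure
noise scans; these sizes were chosen as the smallest at which the
stochastic checks are stable.

## Known limitations

* The PTCR μ parameter is not calibrated to any instrument; only the
  shape of the product distribution is modelled.
* Absolute abundance units are arbitrary; only relative comparisons
  (2 h vs 6 h, vessel vs bulk, SIM vs full scan) are meaningful.
* The b/y fragment matcher is deliberately minimal (singly/doubly
  charged, no internal fragments, no PTMs) — protein identity
  confirmation, not proteoform search.
* The imzML writer emits the continuous-mode subset only, which is what
  the simulator produces.
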