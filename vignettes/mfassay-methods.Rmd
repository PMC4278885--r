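---
title: "Methods: models, defaults and design choices in mfassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and design choices in mfassay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfassay)
```

## The assay and what this package models

The Molecular Force Assay (MFA) measures the mechanical strength of a
protein–protein bond *relative to* a DNA reference duplex. Each Molecular
Force Probe (MFP) is a serial chain between a glass slide and a retractable
elastomer stamp: slide — protein A — protein B — DNA duplex — stamp. A Cy5
dye sits on the protein-proximal DNA strand and a Cy3 dye on the
stamp-proximal strand, so an intact probe shows FRET. Retracting the stamp
at constant speed ramps up the force until, statistically, the weaker of the
two central bonds ruptures: if the DNA reference breaks, the Cy5 stays on
the slide; if the protein complex breaks, the Cy5 leaves with the stamp.
Four fluorescence images per spot (RED and FRET channels, before and after
retraction) encode the outcome of ~10^7 single-molecule experiments in
parallel.

`mfassay` implements the complete computational side of this experiment:

1. **Rupture competition** (`bell_bond`, `serial_probe`,
   `first_rupture_prob`, `simulate_ruptures_kmc`) — which bond breaks first,
   and with what probability.
2. **Reference catalog** (`dna_reference`, `characteristic_force`,
   `effective_reference_bond`) — mapping duplex designs to rupture forces.
3. **Synthetic readout** (`simulate_spot_imageset`,
   `simulate_array_experiment`) — ground-truthed four-channel images.
4. **Quantification** (`quantify_spot` and friends) — the pixel-by-pixel
   Normalized Fluorescence with a Gaussian histogram fit.
5. **Pipeline** (`run_simulate`, `run_quantify`, `run_compare`, `run_demo`,
   `mfa_cli`) — reproducible end-to-end runs from one JSON config.

No raw experimental images are publicly deposited for this assay, so the
synthetic generator is a first-class, tested component: it is the only way
to exercise the quantification against a known truth.

## Rupture kinetics

Each bond is a single-barrier Bell bond with off-rate
$k(F) = k_0 \exp(F \Delta x / k_B T)$. The assay's verbal description fixes
no rate law; Bell kinetics is the minimal model consistent with the
dynamic-force-spectroscopy framework the assay builds on. Richer models
(Dudko–Hummer–Szabo, an explicit overstretching-plateau mechanism) are out
of scope. No published $(k_0, \Delta x)$ values exist for these particular
bonds — kinetic parameters are always user inputs or catalog defaults,
never experimental ground truth.

Both bonds see the same force (the series construction guarantees this; we
neglect linker dynamics), growing linearly at rate $r$. The probability
that the *reference* breaks first is

$$p_{\mathrm{ref}} = \int_0^\infty \frac{k_{\mathrm{ref}}(F)}{r}
  \exp\!\Big(-\tfrac{1}{r}\int_0^F [k_{\mathrm{ref}} + k_{\mathrm{prot}}]\,dF'\Big)\,dF ,$$

which equals the expected Normalized Fluorescence of a spot. The inner
integral has a closed form for Bell rates; the outer integral is evaluated
by adaptive quadrature at relative tolerance $10^{-6}$, truncated where the
joint survival drops below $10^{-12}$. When both bonds share $\Delta x$ the
hazards stay proportional at every force and
$p_{\mathrm{ref}} = k_{0,\mathrm{ref}} / (k_{0,\mathrm{ref}} +
k_{0,\mathrm{prot}})$ for *any* loading rate; the test suite asserts this to
$10^{-9}$, and in practice the quadrature agrees to ~$10^{-12}$.

`simulate_ruptures_kmc()` is the deliberately independent stochastic
oracle: it inverts the joint cumulative hazard (tabulated inverse plus a
vectorized Newton polish) to draw the rupture force, then splits the
outcome by the instantaneous hazard ratio. Quadrature and KMC are checked
against each other within three binomial standard errors at $n = 10^5$; the
two routes share no integration code.

Calibration helpers connect forces to rates: the most probable rupture
force of a single bond under a ramp is
$F^* = (k_B T/\Delta x)\ln(r\Delta x/(k_0 k_B T))$, and
`bond_from_characteristic_force()` inverts it. We parameterize nearly
everything through $F^*$ because forces, not off-rates, are the quantities
the field reports.

**Ramp defaults.** $k_B T = 4.11$ pN·nm (298 K). The default ramp is a
retraction speed of 1 µm/s with an effective stiffness of 100 pN/nm, i.e. a
loading rate of exactly $10^5$ pN/s — the stated operating regime of the
assay. (Note 1 µm/s × 0.1 pN/nm would be 100 pN/s; 100 pN/nm is the value
consistent with the published speed/rate pair.) The potential width default
is $\Delta x = 1$ nm everywhere a width is needed but unknown.

## The reference catalog

Anchors: a duplex opened in zipper mode ruptures at ~15 pN regardless of
length; a 40 bp duplex in shear mode ruptures at ~65 pN, the overstretching
(BS-transition) plateau that short oligonucleotides cannot exceed.
Intermediate shear forces are reached by varying length; the catalog uses
the simplest monotone rule honoring both anchors, **linear in base pairs
and capped at the plateau**: $F = 65 \cdot \min(L, 40)/40$ pN. This is a
documented placeholder, not a thermodynamic model (no nearest-neighbor
energetics, no melting prediction), and is replaceable per call.

Stabilization is additive on top of the geometric base force:

* **Propynyl bases**: +0.3 pN per substituted pyrimidine. The standard
  intrinsically stabilized reference substitutes 22 bases (13 C, 9 T) of a
  40 bp duplex, hence +6.6 pN.
* **Hairpin polyamides** (minor-groove ligands, binary occupancy):
  P3 +40 pN (K~D~ 1442 pM), P1 +45 pN (K~D~ 105 pM), P2 +55 pN
  (K~D~ 44 pM), all at 1 µM working concentration.

Two choices here were genuinely open and deserve their rationale:

* **Magnitudes.** Nothing quantitative is known about either stabilization
  mechanism, so the increments are *non-physical, user-tunable defaults*
  chosen once to reproduce the qualitative experimental ordering: every
  polyamide-stabilized 20 bp reference is mechanically stronger than the
  propynyl-stabilized 40 bp duplex (so each must add well over ~39 pN to
  the 32.5 pN base of a 20 bp duplex), P1 balances a nanobody–GFP-class
  bond closest to NF 0.5, P2 overshoots to NF ≈ 0.05–0.4, and stabilization
  strength follows binding affinity (P2 > P1 > P3). Small increments of a
  few pN, sometimes quoted as a starting point, cannot satisfy this
  ordering from a 20 bp base and were rejected.
* **Saturation rule.** Occupancy is binary. We call a ligand saturated at
  ≥ 100 × K~D~ (occupancy ≥ 99%). A stricter 1000 × K~D~ cutoff would
  paradoxically classify P3 as unbound at its standard 1 µM concentration
  (693 × K~D~, occupancy 99.9999%), contradicting how the ligand is
  actually used; sub-saturating binding kinetics are out of scope.

## The synthetic readout

`simulate_spot_imageset()` emulates one spot at desk scale: a 128 × 128 px
image with a centered circular spot of radius 48 px (7232 pixels) standing
in for the 1 mm spots, and a probe density of 50 probes/pixel standing in
for the real ~10^4 probes/µm². Per pixel inside the spot the probe count is
Poisson, split multinomially into unloaded (fraction $1-\mathrm{CE}$),
loaded-with-reference-broken ($\mathrm{CE}\cdot q$) and
loaded-with-protein-broken ($\mathrm{CE}\cdot(1-q)$). Crucially the *same*
per-pixel population underlies all four channels — that shared factor is
exactly what the pixel-by-pixel ratios cancel, along with the Gaussian
illumination profile and the channel gains. The noiseless expectations obey

$$\mathbb{E}[\mathrm{Ratio_{RED}}] = (1-\mathrm{CE}) + \mathrm{CE}\,q,
\qquad \mathbb{E}[\mathrm{Ratio_{FRET}}] = 1-\mathrm{CE},$$

asserted exactly in expectation mode (`sampling = FALSE`) and to sampling
error on realizations.

Invented, swept-in-tests (not trusted) optical defaults: gain 120 (RED) and
100 (FRET) counts per dye, FRET-channel efficiency 0.8, background offset
100 counts, Gaussian read noise SD 2 counts, Poisson shot noise on, and
optional per-channel bleaching between Start and Final exposures (default
off — the experimental protocol reports no bleaching correction). All
probes are assumed fully assembled at Start (the 1:2 pre-incubation
argument); protein-only sites are dark and therefore ignorable.

**What a green test does *not* establish.** The generator has no
point-spread function, no stage drift or registration error, no spectral
crosstalk, no surface defects, and its noise defaults are guesses. Passing
the recovery suite shows the *estimator* is correct and invariant under the
stated nuisances, not that real microscope data will be this clean.
Registration and flat-field calibration are explicitly out of scope.

## Quantification

Per spot: (1) each channel's background is estimated as the **median of
pixels outside the spot mask** and subtracted (the experimental method is
unspecified; the median is robust and exact for the constant-offset
generator); (2) per-pixel ratios and the Normalized Fluorescence

$$\mathrm{NF} = \frac{\mathrm{Ratio_{RED}} - \mathrm{Ratio_{FRET}}}
{1 - \mathrm{Ratio_{FRET}}}$$

are formed. This formula deserves a prominent caveat: the assay's published
normalization is described verbally (never-loaded probes, visible as
residual FRET, are subtracted from the RED ratio, and the result is
normalized to the coupling efficiency $\mathrm{CE} = 1 -
\mathrm{Ratio_{FRET}}$), and the form above is the reconstruction fixed by
that description together with the boundary semantics — NF = 0.5 iff the
bonds are equally strong, NF → 1 iff the protein always outlasts the
reference, and composing it with the generator identities returns $q$
exactly. Treat it as this package's documented convention.

Pixel validity: both Start signals must exceed a threshold (default 10
counts = 5 × the default read-noise SD), $\mathrm{Ratio_{FRET}} < 0.995$
(the denominator otherwise blows up — how such pixels are handled
experimentally is unstated, so exclusion is a config knob), ratios finite
and non-negative, NF inside the outlier window $[-0.25, 1.25]$. (3) The
most likely NF is the mean of a three-parameter Gaussian least-squares fit
to the 100-bin histogram of per-pixel NF values, initialized from the
median and scaled MAD; if the fit fails, the histogram is near-degenerate,
or the Gaussian explains < 50% of the histogram variance (a bimodal spot),
`fit_ok = FALSE` and the median/MAD fallback is reported — flagged, never
silent. We read "histogram of all pixel counts" as the histogram of
per-pixel NF values; fitting count ratios before division would forfeit the
inhomogeneity cancellation that motivates the pixel-by-pixel method.

The spot's coupling efficiency is reported as $1 - \mathrm{median}
(\mathrm{Ratio_{FRET}})$ over valid pixels (the median keeps the per-spot
summary robust); a spot with CE < 0.05 was essentially never under load and
is flagged invalid rather than dropped. Replicate spots aggregate to
mean ± sample SD (SD = 0 for a single spot, by convention), and two
conditions are *distinguishable* when $|\Delta \mathrm{NF}|$ exceeds the
maximal deviation $|\mathrm{SD}_a| + |\mathrm{SD}_b|$ — the assay's own
conservative rule, deliberately stricter than a t-test and independent of
pixel counts.

## Pipeline and demo

One JSON config defines the full experiment; one master seed expands
deterministically into per-spot seeds, so runs are bit-reproducible while
spots stay independent. Every run writes a provenance block (config, seed,
versions) beside its outputs. Images are written as uncompressed 16-bit
grayscale TIFFs via a minimal in-package reader/writer (cross-validated
against an independent TIFF library in the test suite), manifest and
tables as CSV.

The packaged demo (`run_demo()`, config at `demo_config_path()`) emulates a
published-style 4 × 4 array: three nanobody–GFP conditions in quadruplicate
against the P1-stabilized 20 bp reference — protein characteristic forces
73.1, 73.0 and 75.0 pN, chosen so the *expected* NF values echo the
published worked-example summaries (≈ 0.255, 0.253, 0.353); those printed
values are inputs to the design here, never reproduced outputs — plus a
four-spot reference sweep (unmodified 40 bp, propynyl, +P3, +P2) for one
fixed 75 pN bond, which reproduces the qualitative sensitivity story: NF
falls monotonically as the reference strengthens, and differences between
protein bonds are largest where NF is nearest 0.5.

## Numerical choices, degenerate inputs, limitations

* Quadrature: `stats::integrate`, rel.tol 1e-6, survival truncation 1e-12;
  probabilities clipped to [0, 1] against roundoff.
* KMC inversion: 4096-point tabulated inverse + ≤ 30 Newton steps
  (convex, monotone target — converges in a handful); one private seeded
  RNG stream per call, caller's RNG state restored.
* Unbreakable bonds: $k_0 = 0$ on one side short-circuits to $p \in
  \{0, 1\}$; on both sides it is an error ("no rupture possible").
* Gaussian fit: `nls` (port algorithm) with bounds; degenerate histograms
  (MAD below half a bin width) skip straight to the fallback.
* The NF reported per spot is clipped to [0, 1]; the unclipped fit mean is
  kept as `nf_raw`.
* Absolute force calibration from NF is a non-goal: NF only ranks the
  protein bond against the chosen reference. All stabilization increments
  are qualitative placeholders; do not interpret simulated forces for
  modified references as predictions.
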