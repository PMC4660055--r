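---
title: "Methods: NMR dynamics, binding and DNA geometry for a response regulator-promoter complex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMR dynamics, binding and DNA geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models behind `pmradyn`, the assumptions
they make, the tunable parameters, and the design decisions taken
where several defensible conventions exist. The package analyses how
the two-domain response regulator PmrA — a receiver domain (REC) dimer
connected by flexible linkers to two DNA-binding domains (DBDs) —
engages promoter DNA, combining solution NMR dynamics, binding assays
and duplex geometry.

## Chemical-shift perturbations

A resonance observed in the free and DNA-bound states reports on its
local chemical environment. The combined perturbation is the weighted
root-mean-square over the two dimensions:

- amide: $\Delta\delta = \sqrt{(\Delta\delta_{HN}^2 +
  (\Delta\delta_N/5)^2)/2}$ — ¹⁵N shifts disperse roughly five times
  wider than ¹H, so they are down-weighted;
- methyl: $\Delta\delta = \sqrt{(\Delta\delta_H^2 +
  (0.3\,\Delta\delta_C)^2)/2}$;
- Leu and Val carry two methyls; their per-residue CSP is the mean of
  the two methyl values.

Significance is flagged against mean + 1 SD over all observed deltas,
with strict exceedance. We use the *sample* (n−1) standard deviation:
the set of observed residues is a sample of the sequence, and the
sample SD is the conservative choice where the convention is not
fixed. Peaks present in one state only (`missing_in_bound`,
`appeared_in_bound`) carry no delta and never enter the threshold
statistics, but are always listed — disappearance upon DNA addition
is itself informative (exchange broadening at an interface). Doubled
bound-state peaks contribute their mean delta once, so a residue with
resolved variants is not double-weighted.

## Relaxation and correlation times

$R_2$ series are fit to $I(t) = A e^{-R_2 t}$ (two parameters — the
experiment measures a pure decay), $R_1$ inversion-recovery series to
$I(t) = I_\infty - (I_\infty - I_0)e^{-R_1 t}$ (three parameters).
Duplicate measurements are fit jointly rather than averaged first, so
replicate scatter stays in the residuals. Default schedules are the
standard ones used here: eleven recovery delays from 10 ms to 1.5 s
for $R_1$ and eight durations from 17.2 to 137.2 ms for $R_2$.

The rotational correlation time uses the single-field estimate

$$\tau_c \approx \frac{1}{4\pi\nu_N}\sqrt{6\,R_2/R_1 - 7},$$

valid for rigid isotropic tumbling with $\omega\tau_c \gg 1$, with
$\nu_N$ the ¹⁵N Larmor frequency ($|\gamma_N/\gamma_H| = 0.101329$).
A ratio of 40.1 at 850 MHz gives 14.1 ns; 72.5 gives 19.1 ns. Note
that 19.1 ns sits at the edge of a "20 ns" rounding; the estimator
behind a printed 20 ns cannot be reconstructed exactly, and we report
the formula value. Ratios at or below 7/6 have no real solution and
are rejected.

Bound/free peak intensity ratios are a light-weight proxy for the
apparent molecular weight of each domain when full $R_2$ measurement
is impractical in a large complex: slower-tumbling parts lose more
intensity. Ratios are $I_{bound}/I_{free}$ per assignment (doubled
bound peaks summed first); when a spectral noise floor $\sigma$ is
supplied, each ratio carries the quadrature error
$r\sqrt{(\sigma/I_b)^2 + (\sigma/I_f)^2}$. Domain statistics run over
REC and over the DBD excluding its C-terminal seven residues, whose
flexibility would bias the mean; the default domain map is REC 1–116,
linker 117–125, DBD 126–219 (statistics over 126–212), overridable.

## Multiple-quantum CPMG relaxation dispersion

Methyl ¹H–¹³C multiple-quantum (MQ) coherence in a constant-time CPMG
element of length $T$ (20 ms default) decays with an effective rate
$R_{2,\mathrm{eff}}(\nu_{CPMG}) = -(1/T)\ln[I(\nu)/I(0)]$, where
$I(0)$ comes from a reference spectrum without the CPMG interval. The
measurement grid is 50–1000 Hz with duplicates at 50, 100 and 700 Hz;
the pooled SD of $R_{2,\mathrm{eff}}$ over duplicated frequencies is
applied to every point (floored at 0.1 s⁻¹ — a pooled SD below the
floor with only three duplicate pairs is an underestimate, not a
precision claim).

Two-site exchange $A \rightleftharpoons B$ is parameterised by the
minor population $p_B$, the total rate $k_{ex} = k_{AB} + k_{BA}$
(detailed balance $p_A k_{AB} = p_B k_{BA}$), the shift differences
$\Delta\omega_H$ and $\Delta\omega_C$ (ppm, converted with
$|\gamma_C/\gamma_H| = 0.251450$), and an exchange-free rate $R_2^0$
per field. MQ coherence evolves at $\Delta\omega_H + \Delta\omega_C$
(double-quantum) and flips to $\Delta\omega_H - \Delta\omega_C$
(zero-quantum) at every ideal 180° ¹³C pulse; a single ¹H 180° pulse
at $T/2$ refocuses the net ¹H phase. Only the relative sign of the
two shift differences is observable, so fits constrain
$\Delta\omega_C \ge 0$.

Two model routes are implemented:

- `ns_mq_2site` — the reference: numerical propagation of the 2×2
  Bloch–McConnell equations through the explicit pulse train
  (compiled code; exact for ideal pulses). The number of two-pulse
  cycles is `round(nu * t_relax)`, exact on the default grid.
- `cr72_mq` — a Carver–Richards-type closed form: the per-cycle
  evolution is solved through the dominant eigenvalue of the 2×2
  cycle matrix (the classic cosh⁻¹ expression is this eigenvalue
  written out), plus the analytic asymptotic amplitude factor
  covering the central ¹H pulse and the element's end effects. It
  agrees with the numerical reference to ≤ 0.25 s⁻¹ whenever the
  sub-dominant exchange mode decays within a pulse spacing (roughly
  $k_{ex} \gtrsim 2\nu_{CPMG}$), and degrades gracefully in very slow
  exchange, where the numerical model is authoritative.

Conventions worth stating because they are easy to get subtly wrong:

- The detected peak is the major state A; the reference intensity is
  its equilibrium magnetisation. With the detected state fixed, the
  only exact label symmetry is simultaneous sign negation of both
  shift differences. The often-quoted "swap populations and negate
  shifts" symmetry describes relabelled detection and does not hold
  for a fixed detected peak.
- Dispersion profiles are *not* universally monotone in
  $\nu_{CPMG}$: in very slow exchange ($k_{ex} \ll \Delta\omega_C$)
  the propagation shows genuine scalloping of a few s⁻¹. Monotone
  non-increase holds (and is tested) for
  $k_{ex} \ge 0.5\,\Delta\omega_C$.

Fits minimise error-weighted residuals over both fields jointly.
`no_exchange` (one flat $R_2^0$ per field) is closed-form; exchange
models are optimised by bounded Levenberg–Marquardt from a multi-start
grid ($k_{ex} \in \{100, 400, 1200, 3000\}$ s⁻¹ ×
$p_B \in \{0.02, 0.10, 0.25, 0.45\}$) because dispersion objectives
are multimodal. Model choice uses AIC = χ² + 2k on the weighted
residual sum (the common convention in dispersion fitting), minimum
wins, ties to fewer parameters. Exchange parameters are reported only
for groups whose $R_{ex} = R_{2,\mathrm{eff}}(50\,\mathrm{Hz}) -
R_{2,\mathrm{eff}}(1000\,\mathrm{Hz})$ strictly exceeds 3 s⁻¹ at at
least one field — below that, a five-parameter model is fitting
noise. The global fit shares $p_B$ and $k_{ex}$ across groups with
per-group shift differences and per-group per-field $R_2^0$; errors
come from the covariance of the weighted fit scaled by the reduced
χ² — the duplicate-based point errors carry only a few degrees of
freedom, so the weights are treated as relative — optionally from
Monte-Carlo resampling of the $R_{2,\mathrm{eff}}$ data (200
resamples by default when enabled). The population labels in output
state both "minor population" and its percentage explicitly, since
literature labelling of $p_A$/$p_B$ varies.

## Binding and reporter assays

Fluorescence polarization titrations are fit to
$P(c) = p_{free} + (p_{bound} - p_{free})\,\theta$ with the exact
one-site ligand-depletion solution

$$\theta = \frac{(P + D + K_d) - \sqrt{(P + D + K_d)^2 - 4PD}}{2D},$$

where $D$ is the labelled-DNA concentration (6 nM default). With
$D \ll K_d$ depletion is nearly negligible, but the exact solution
costs nothing and matters for tight binders. Polarization is treated
as linear in bound fraction (standard FP assumption at constant
fluorescence intensity). A titration that never reaches
half-saturation is flagged: $K_d$ is then set by extrapolation and
poorly determined. Reporter activity is
$1000 \times A_{420}/(T \times V \times A_{600})$ Miller units, with
$T$ in minutes and $V$ in millilitres.

## Duplex geometry

An ideal B-form builder stacks standard base-pair geometries with
uniform rise and twist about a straight axis; the complementary
strand is generated by the pair dyad (180° rotation about the pair
x-axis). The base templates are idealized heavy-atom coordinates in
the standard reference frame; builder and frame-fitting share them,
so build→measure round trips are exact by construction. Backbone
phosphates sit at radius 9.0 Å, azimuth ±95°, axial offset ±2.0 Å in
the pair frame — placed once so that canonical B-DNA (3.32 Å, 36.0°)
reads a raw cross-strand P–P minor groove of ≈ 11.6 Å, matching the
≈ 12 Å raw-distance convention. 5′-terminal residues carry no
phosphate, as in real structures.

Base-pair frames come from least-squares (Kabsch) superposition of
the standard base onto each base's ring atoms; the strand-2 frame is
flipped into the strand-1 convention and the pair frame is the
orthonormalised average. Step twist is the signed angle between
consecutive x-axes projected onto the plane normal to the mid-step
z-axis (half-way rotation triad); rise is the origin displacement
along that axis. This mid-step convention is rotation- and
translation-invariant and recovers builder inputs to < 0.01.

Minor-groove width is the minimum raw cross-strand P–P distance
within a ±6-pair window — no van-der-Waals subtraction, consistent
with the ≈ 12 Å canonical reading; positions whose window is
truncated by the duplex ends are undefined and skipped. The global
bend is the angle between the first principal axes of the frame
origins of the two halves, each oriented along the 5′→3′ progression;
it reads 0° for a straight duplex and reproduces a constructed
two-arm bend within 1°. Buried interface area is the Shrake–Rupley
solvent-accessible surface area lost on complexation,
$(SASA_A + SASA_B - SASA_{A\cup B})/2$, with 960 deterministic
golden-spiral sphere points per atom, probe 1.4 Å, and radii C 1.70,
N 1.55, O 1.52, P 1.80, S 1.80, H 1.20 Å. Deposited complex
coordinates (4S04/4S05) are *not* bundled; the same pipeline applies
to them when supplied as a PDB file (`duplex_from_atoms` with the DNA
chain identifiers). Convention-sensitive quantities (groove width,
bend, interface areas) are expected to agree with other software only
within tolerance.

## Synthetic data

Every analysis stage has a seeded generator producing inputs with the
statistical structure the stage assumes; identical arguments give
bit-identical output, and at zero noise each generator/analysis pair
is an exact inverse.

- Relaxation: duplicate series on the standard schedules, Gaussian
  noise with σ = 1% of the reference intensity by default.
- Dispersion: the study condition is five interface methyl groups
  sharing one exchange process (minor population 11%, $k_{ex}$ =
  560 s⁻¹) at 600 and 850 MHz on the standard grid with duplicates,
  2% intensity noise. Per-group shift differences are fixed defaults
  chosen as typical methyl values — ¹³C 0.6–1.5 ppm, ¹H 0.02–0.06 ppm
  (methyl ¹H differences are characteristically small; larger values
  would invert the MQ profiles) — giving every group a clear positive
  $R_{ex}$, as observed for the interface methyls.
- FP titrations: 12-point log grid 10–3000 nM, triplicate, 2 mP
  Gaussian noise, 6 nM labelled DNA.
- Peak lists: prescribed perturbations, attenuations, doubling and
  omission applied to a free-state list.

Noise levels are defaults chosen once to yield uncertainties
comparable to typical reported error bars (e.g. fitted $k_{ex}$
scatter of a few tens of s⁻¹). What passing simulation tests shows is
that the estimators recover known truth under the stated noise model;
they do not certify behaviour under artefacts real spectra can have
(peak overlap, baseline distortions, off-resonance effects,
temperature drift), which are out of scope.

## Problem sizes and runtime choices

The recovery studies run at sizes that keep the full suite fast while
leaving the statistics meaningful: 20 seeds for the five-group global
dispersion fit (each a 22-parameter fit over 130 points at two
fields), 50 seeds for the $K_d$ recovery, 100 seeds for single-rate
relaxation recovery, 25-mer duplexes for geometry. The numerical
dispersion kernel is compiled; a global fit takes a few seconds per
seed on one core.

## Known limitations

- No model-free analysis, anisotropic diffusion or NOE handling for
  relaxation; $\tau_c$ is the single-field approximation.
- Exchange models are strictly two-site MQ; no 3-site, R1ρ or
  single-quantum variants.
- The DNA module measures twist/rise/groove/bend/area only — no
  roll/tilt/slide, no curvilinear axis, no sugar puckers, and no
  mmCIF input.
- Assignments are required; there is no peak picking or automated
  transfer between spectra.
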