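# pmradyn

Quantitative analysis of how the response regulator PmrA — an
OmpR/PhoB-family transcription factor controlling polymyxin-resistance
genes — engages its promoter DNA. PmrA couples a receiver domain (REC)
dimer to two DNA-binding domains (DBDs) through flexible linkers, and
the interesting biology lives in quantities that need careful
numerics: which residues feel DNA binding, how independently the
domains tumble, whether a lowly populated REC–DBD interface exists in
solution, how tightly the protein binds its operator, and how the
bound DNA is deformed.

The package implements that entire analysis chain as reusable,
tested R functions:

- **Chemical-shift perturbations** from assigned Sparky-style peak
  lists: weighted amide CSPs
  $\sqrt{(\Delta\delta_{HN}^2+(\Delta\delta_N/5)^2)/2}$ and methyl
  CSPs $\sqrt{(\Delta\delta_H^2+(0.3\Delta\delta_C)^2)/2}$ with the
  Leu/Val two-methyl mean rule, mean + 1 SD significance flagging,
  and doubled/missing-peak bookkeeping.
- **Relaxation**: joint fits of duplicate R1 inversion-recovery and
  R2 decay series, per-domain R2/R1 statistics, the single-field
  correlation-time estimate
  $\tau_c = \sqrt{6R_2/R_1-7}/(4\pi\nu_N)$, and bound/free intensity
  ratios with noise propagation.
- **Methyl MQ CPMG relaxation dispersion**: R2,eff from intensities,
  duplicate-based errors, two-site-exchange fitting with a
  Carver–Richards-type closed form (`cr72_mq`) cross-checked against
  numerical Bloch–McConnell propagation (`ns_mq_2site`, compiled),
  AIC model selection, the Rex > 3 s⁻¹ reporting filter, and global
  fits sharing one minor population and exchange rate across methyl
  groups.
- **Assays**: one-site fluorescence-polarization fits with the exact
  ligand-depletion quadratic, and Miller-unit conversion for
  β-galactosidase reporter data.
- **DNA geometry**: ideal B-DNA construction, base-pair reference
  frames, mid-step twist/rise, raw P–P minor-groove widths, two-arm
  bend angle, and Shrake–Rupley buried interface areas, from built
  duplexes or PDB files.
- **Synthetic data**: seeded generators for every input kind, so the
  whole pipeline is exercised end-to-end with no downloads.

## Worked example

Simulate the five-methyl-group dispersion experiment at its study
conditions (shared minor population 11%, kex = 560 s⁻¹, fields 600 and
850 MHz, 2% intensity noise) and fit it globally:

```r
library(pmradyn)

df <- gen_dispersion_dataset(dispersion_truth_defaults(), seed = 1)
profiles <- profiles_from_table(df)
curves <- lapply(profiles, function(pf) {
  lapply(pf, function(p) errors_from_duplicates(p, r2eff_from_intensities(p)))
})
global_fit(curves)
```

```
global two-site exchange fit (ns_mq_2site, 5 groups)
  minor population: 12.3% +/- 2.7
  kex: 616 +/- 67 s^-1
  chi2 = 804 (k = 22, AIC = 848)
```

The fitted minor population and exchange rate recover the generating
truth (11%, 560 s⁻¹) within their uncertainties — a single noise
realization scatters by a few tens of s⁻¹ (the errors estimated from
only three duplicated frequencies are themselves noisy, which the
reduced-chi-square scaling of the parameter errors absorbs); medians
over many seeds land on the truth (see below). The per-domain tumbling numbers work the
same way:

```r
tau_c_from_r2r1(72.5, 850)   # REC dimer:  19.11 ns
tau_c_from_r2r1(40.1, 850)   # DBD:        14.12 ns
```

A ratio of 72.5 corresponds to a ~19 ns correlation time (a stable
REC dimer), 40.1 to ~14 ns — the two domains of one molecule tumble
at different rates, which is only possible if the linkers leave them
effectively independent.

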