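---
title: "Freshwater ecotoxicity characterization factors for PFAS: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Freshwater ecotoxicity characterization factors for PFAS: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfascf)
```

## The model

`pfascf` computes freshwater ecotoxicity characterization factors (CFs) for
per- and polyfluoroalkyl substances (PFAS) in the fate-exposure-effect
tradition of multimedia consensus models:

$$\mathrm{CF} = \mathrm{FF} \times \mathrm{XF} \times \mathrm{EF}
\quad [\mathrm{PAF \cdot m^3 \cdot day / kg\ emitted}]$$

where FF (days) is the steady-state residence time of the chemical in the
freshwater compartment, XF (dimensionless) is its dissolved fraction, and EF
(PAF·m³/kg) is the slope of the potentially-affected-fraction response
derived from a species sensitivity distribution (SSD). Two effect
methodologies are supported,

$$\mathrm{EF} = 0.5/\mathrm{HC50}_{\mathrm{EC50eq}}, \qquad
  \mathrm{EF} = 0.2/\mathrm{HC20}_{\mathrm{EC10eq}},$$

and two fate/exposure variants: *standard*, which derives partitioning from
log K~ow~ regressions, and *PFAS-adapted*, which partitions through K~oc~
directly because surface-active perfluoroalkyl acids are simultaneously
hydrophobic and lipophobic and K~ow~-driven models do not describe them.
Crossing the two effect methodologies with the two fate/exposure variants
gives four CFs per chemical. Because the effect factors are computed once
and shared between variants, the HC20/HC50 CF ratio is identical across
variants by construction — a property the test suite asserts to machine
precision.

## Harmonization of raw ecotoxicity records

Raw exports (REACH-style or ToxValDB-style) pass through a fixed four-step
sequence, and every excluded record carries exactly one drop reason, so the
audit satisfies `n_in = n_out + sum(drops)` for every run:

1. **Chemical identity.** CAS numbers are canonicalized and validated by
   check digit; records without a valid CAS are excluded.
2. **Reliability.** REACH records are kept iff Klimisch score is 1 or 2;
   CompTox records iff QC status equals the pass token (default `"pass"`,
   case-insensitive).
3. **Uniformity.** Only `"="`-qualified values are kept; species names are
   mapped, exactly and case-insensitively, against a bundled table of
   common freshwater test species (unmatched names are dropped, never
   guessed); durations are converted to days and classified acute/chronic
   per species group; effect values are converted to mg/L; endpoint labels
   are consolidated into EC10, EC50 and NOEC.
4. **Consistency.** Exact duplicates — identical chemical, species,
   endpoint, regime, and value rounded to 6 significant digits — are
   removed, keeping the first record in input order.

Decisions a user may want to revisit, all exposed in
`harmonization_config()`:

- **Chronic thresholds** (days): fish and amphibians 21, algae 1, all other
  groups 7. These are conventional regulatory chronic-test durations (21-d
  *Daphnia* reproduction, 96-h fish acute, 72-h algal growth inhibition
  spanning several generations). The boundary is inclusive (`>=`).
- **Absent qualifiers** are read as `"="` because REACH exports frequently
  omit the field; `strict_qualifier = TRUE` drops them instead.
- **LOEC** labels are rejected by default (they are not one of the three
  harmonized endpoint classes); `loec_as` can fold them into a class.
- **Records without a usable duration** are dropped because the regime is
  unassignable; `regime_from_label = TRUE` falls back to "chronic"/"acute"
  text in the labels.
- The **6-significant-digit deduplication key** absorbs re-export float
  noise without merging genuinely distinct tests.
- An extra drop reason, `bad_endpoint`, covers endpoint labels outside the
  harmonized classes; without it the audit could not conserve record
  counts.

Averaging of replicate values is deliberately *not* done here: the
harmonizer only removes exact duplicates, keeping the raw spread available
for the SSD fit. Replicates are aggregated geometrically at the effect
stage.

## Effect factors

Harmonized values are extrapolated to chronic EC10 and chronic EC50
equivalents with a multiplier table (`default_extrapolation_factors()`).
The defaults encode an acute-to-chronic ratio of 2, an EC50-to-EC10 ratio
of 2, and NOEC treated as equivalent to chronic EC10. These are
order-of-magnitude-typical conversion ratios; the table is configuration
data, not code, and identity multipliers hold for values already at the
target endpoint.

Aggregation is two-stage: geometric mean per (chemical, species) within
each pool, then statistics across species. This prevents data-rich species
from dominating the SSD. The SSD is lognormal — normal in log10
concentration — with `mu` the arithmetic mean and `sigma` the sample
standard deviation (n−1) of the per-species log10 values; `sigma = 0` for
a single species. Then

$$\mathrm{HC20} = 10^{\mu - z_{0.8}\,\sigma}\ \mathrm{mg/L}, \qquad
  z_{0.8} = \Phi^{-1}(0.8) = 0.8416212,$$

and HC50 is the geometric mean of the chronic EC50-equivalent species
values (the SSD median). Concentrations are stored in mg/L throughout; the
single ×10⁻³ conversion to kg/m³ happens inside `hc20()`/`hc50()`, so the
EF identities `ef_hc20 * hc20 = 0.2` and `ef_hc50 * hc50 = 0.5` hold to
machine precision. A `method = "geomean"` alternative (HC20 = 10^µ) exists
for sensitivity checks. No minimum-species or minimum-trophic-level gate is
applied; coverage diagnostics (`n_species`, `n_species_groups`,
`n_trophic_levels` over producers / primary consumers / secondary
consumers) let callers filter. Species-richness weighting is intentionally
not part of the EF.

## Fate and exposure

A single well-mixed freshwater box is the default scope. Partitioning:

- standard: $K_{oc} = 10^{0.81 \log K_{ow} + 0.10}$ L/kg and
  $\mathrm{BCF} = 10^{0.85 \log K_{ow} - 0.70}$ L/kg (widely used
  organic-carbon and fish-BCF regressions, configuration data with these
  defaults);
- PFAS-adapted: the supplied K~oc~ is used directly,
  $K_p = f_{oc} K_{oc}$, $K_{doc} = 0.08\,K_{oc}$, and the BCF defaults
  to 1 L/kg — never the K~ow~ regression. A chemical missing the property
  a variant requires is skipped for that variant only.

The dissolved fraction is
$\mathrm{XF} = 1/(1 + K_p C_{susp} + K_{doc} C_{doc} + \mathrm{BCF}\,C_{bio})$,
always in (0, 1]. Removal combines degradation, advection
(1/residence-time), net sedimentation acting on the particle-bound fraction
(1 − XF), and optional two-film volatilization acting on the dissolved
fraction. Volatilization is off by default: the dominant PFAS species in
freshwater are anions with negligible vapor pressure, and this avoids
requiring an air-water constant for every chemical. Ionization triggers no
speciation correction in this version (the neutral-chemical assumption is
conservative when data are absent); the `pka_class` field is carried
through for auditing.

The closed-form fate factor is `FF = 1 / sum(k)`. A matrix mode
(`fate_factor_matrix()`, FF = −K⁻¹) exists for multi-compartment
configurations and is verified against the closed form (single
compartment, relative error < 10⁻¹⁰) and against brute-force steady-state
solves of the mass balance for a two-compartment water-sediment toy. The
full nested multi-scale consensus geometry is out of scope.

Default landscape values (`default_landscape()`, all overridable):
suspended solids 15 mg/L, DOC 5 mg/L, biota 1 mg/L, depth 2.5 m, hydraulic
residence time 20 d, net sedimentation 2.5×10⁻³ m/d, f~oc~ of suspended
solids 0.1 — typical mid-latitude freshwater parameterization of consensus
models.

## Comparisons and group analysis

`log_regression()` log10-transforms both series, then reports the Pearson
r, R² (for a simple regression of log y on log x this equals r² exactly;
both readings coincide), the root mean square error of that regression
(residual standard error, n−2 denominator), the sample covariance, and a
95% CI on r via the Fisher z-transform with standard error 1/√(n−3). The
regression is of the second argument on the first; RMSE is therefore not
symmetric, while r is. Pairs with a missing or non-positive member are
dropped; no imputation.

`count_perfluorinated_carbons()` parses SMILES (via ChemmineR/OpenBabel)
and counts carbons that carry at least one fluorine and whose non-carbon
substituents are exclusively fluorine, with no implicit hydrogens — the
CF, CF2 and CF3 units. Consequences worth noting: the carboxyl carbon of
PFOA does not count (seven perfluorinated carbons for PFOA), an aromatic
C–F carbon with two ring-carbon neighbours does count, and the alpha
carbon of a sulfonate bears sulfur and does not count (PFBS counts 3, PFOS
7). Ether-linked fluorocarbons likewise do not count, a strict reading
appropriate for auditable substructure counts. `group_by_pfc()` then
tabulates any log10 quantity per perfluorinated-carbon count (count, mean,
sample SD — absent for singletons — min, max), ordered by descending
count.

## The synthetic data generator

Real REACH/CompTox extracts cannot be redistributed, so the generator
produces structurally valid stand-ins with known ground truth:

- **Chemicals** follow the grammar CF3–(CF2)~k~–X, k ∈ 0..16, with head
  groups carboxylate, sulfonate, ethanol, amide — every molecule carries a
  saturated CF3 unit. True perfluorinated-carbon counts follow the
  structure (k+1 for carbon-linked heads, k for sulfonate whose alpha
  carbon bears sulfur). Properties: log K~ow~ ~ U(1, 7),
  K~oc~ ~ 10^N(3, 1) L/kg, k~deg~ log-uniform on (10⁻⁴, 10⁻¹)/day
  (persistent, as PFAS are), MW from the molecular formula.
- **Ecotoxicity records**: per chemical, a species-level SSD draw
  10^N(µ~i~, 0.7) over 8 mapped species, µ~i~ ~ U(−2, 2) log10 mg/L; 3
  test results per species with 0.2 log10 units within-species noise;
  endpoints emitted across all six endpoint-regime classes by *exact
  inversion* of the extrapolation table, so extrapolation is a bias-free
  round trip; benign unit variation (µg/L, g/m³) on 15% of records.
- **Corruptions** (10% of records by default: unreliable, non-"="
  qualifier, unmapped species, unconvertible unit, missing value, invalid
  CAS) are mutually exclusive per record and tagged with the intended drop
  reason, plus appended byte-identical duplicates — so harmonization's
  per-reason audit counts can be compared with the generator's intent
  *exactly*, giving sharp test oracles.

**What "truth" means here.** The drawn species sensitivities *are* the
species' true values in the synthetic world; within-species test noise is
measurement error on top of them. Per-chemical true HC20/HC50 are
therefore computed from the realized species draws, and recovery measures
pipeline fidelity (unit conversion, extrapolation, aggregation, fit), not
SSD sampling error. Against the distribution parameters themselves, an
8-species SSD has an irreducible sampling spread of roughly 0.2 log10
units in HC20 — that quantity characterizes the design of toxicity
testing programmes, not the correctness of this pipeline.

What the generator does **not** emulate: correlated endpoints within a
study, laboratory-to-laboratory bias, censored (">") values that carry
usable information, heterogeneous species pools per chemical class, or any
property-structure relationships (QSAR realism). Passing recovery tests on
synthetic data therefore shows the computational chain is faithful, not
that real-data CFs are accurate — those inherit every limitation of the
underlying databases.

## Problem sizes and numerical choices

The test suite and the acceptance script run the synthetic study at 200
chemicals × 8 species × 3 points (~4,900 records), the scale at which the
recovery criteria (median |log10 ĤC20/HC20| < 0.05, r > 0.98 between
estimated and true log10 CF) are sharp yet the whole suite completes in
well under a minute. The SSD quantile oracle is checked on a 10×10
(µ, σ) grid against `qlnorm`. Ties and degenerate inputs: empty
harmonization input returns an empty table with a zeroed audit; a
single-species chemical takes the σ = 0 path; an empty effect pool yields
`NA` for that pool only; a zero total removal rate is an error (infinite
residence time), as is a singular rate matrix.

## Limitations

- CFs computed here are screening-level indicators; per-chemical accuracy
  is bounded by the input databases and the extrapolation-factor table.
- Degradation products of PFAS (often themselves persistent and toxic) are
  not tracked.
- Marine, sediment and soil compartments, human toxicity, and
  species-richness-weighted effects are out of scope.
- The bundled species table covers ~80 common freshwater test species;
  rarely tested taxa fall out as unmapped (by design, never guessed).
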