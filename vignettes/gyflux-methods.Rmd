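---
title: "Dipeptide feed-media analysis for CHO fed-batch cultures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dipeptide feed-media analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gyflux)
```

# Scope

`gyflux` analyses graded-dose studies of glycyl-L-tyrosine (GY) dipeptide
feed media in IgG-producing CHO fed-batch cultures. The chain is: culture
profiles → per-phase specific rates → replicate outlier screening →
batch-level PLS nutrient ranking → enzyme-capacity-constrained FBA of a
dipeptide-augmented network → comparative flux analysis. This vignette
records the models, the tunable parameters with their units and defaults,
and the design decisions taken where the methodology was genuinely open.

# Specific rates

Rates are computed per culture phase over the sampling grid
(days 0, 2, 4, 5, 6, 7, 8, 10, 12, 14; nine consecutive phases). With VCD
in 10^6 cells/mL, concentrations in mM and titer in mg/L, the unit
identities 1 mM = 10^6 pmol/mL and 1 mg/L = 10^6 pg/mL make

$$\mathrm{IVCD}_{1,2} = \tfrac{VCD_1 + VCD_2}{2}(t_2-t_1), \qquad
Q_m = \frac{C_2 - (C_1 + C_{feed,1})}{\mathrm{IVCD}_{1,2}}, \qquad
Q_p = \frac{C_{p,2} - C_{p,1}}{\mathrm{IVCD}_{1,2}}$$

come out directly in pmol/cell/day and pg/cell/day. Negative $Q_m$ is net
consumption. The growth rate uses the standard exponential-phase
definition $\mathrm{SGR} = \ln(VCD_2/VCD_1)/(t_2-t_1)$ (no closed form is
canonical for fed-batch; the log-ratio is the batch-culture standard).

**Feed correction.** A bolus of volume fraction $f$ (default 4% v/v)
raises a metabolite by $C_{feed} = f\,C_{stock}/(1+f)$ *and* dilutes the
residual (and the cells, and the product) by $1/(1+f)$. The classical rate
equation only adds $C_{feed}$. By default `compute_phase_rates()` also
applies the dilution correction — dividing the phase-start VCD, titer and
concentration by $1+f$ — because the generator models the volume step and
exact rate recovery requires it. `eq2_strict = TRUE` restores the literal
reading (the ~4% bias this leaves is visible in the test suite). Feed
events at a phase-start day belong to that phase: cultures are fed after
sampling. Sampling-volume losses are not modelled.

Glucose is accepted in g/L and converted at ingest with a molar mass of
180.16 g/mol; internally everything is mM.

# Replicate outlier screening

The qualitative rule "a replicate whose VCD trend deviates beyond the
±1 SD band" is operationalized as: per condition, compute the
per-timepoint mean and SD of VCD across all replicates (candidate
included); flag a batch if it lies strictly outside
$\text{mean} \pm k\,\mathrm{SD}$ with $k = 1$, always on the same side, at
≥ 50% of timepoints. Both $k$ and the fraction are exposed
(`band_k`, `frac_threshold`). Identical replicates give a zero-width band
and, by strictness, no flags. Conditions with fewer than three replicates
are skipped with a warning — a majority vote needs three. Whether the
band should exclude the candidate is unknowable from the rule's prose;
including it is the more conservative choice (it can only shrink the
deviation). On the synthetic defaults the rule detects a planted 0.5×
trajectory in 100% of seeds with a false-flag rate well under 5%.

# Batch-level PLS and the nutrient ranking

The qualified dataset is unfolded batch-wise: one row per batch, columns
are (variable, day) pairs over the post-feeding days 4–14; the response is
the final-day titer normalized to the dataset maximum. Columns with zero
variance are dropped and logged. X and y are autoscaled.

The regression is NIPALS PLS1 (single response; deflation of X after each
component; for one response the weight vector is determined in a single
pass). Following standard chemometrics convention, coefficients are
reported in autoscaled space so sums across differently scaled variables
are comparable. The component count defaults to 2 in the bundled pipeline and
can be selected by leave-one-out Q² (capped at 5) when unset — the study
design (five doses, ~3 replicates) rarely supports more. Wold's VIP is
used; by construction the squared VIPs average to exactly 1, which the
suite asserts on every fit, and NIPALS coefficients are cross-checked to
1e-6 against an independent SIMPLS projection oracle.

The **coefficient-sum ranking** sums, per variable, the autoscaled
coefficients over timepoints whose column VIP ≥ 1.00 (threshold
configurable), and sorts by signed sum, most negative first; ties break
lexicographically. The profile variables VCD, viability and titer are
excluded from the ranking by default — they are predictors, not candidate
media components. Magnitude cutoffs (such as a top-10 selection) are
dataset-specific reporting choices, not portable constants, and are left
to the caller.

# The synthetic study generator

The generator emulates the *statistical shape* of a graded-GY fed-batch
study, not its mechanism: 14 days, triplicate bioreactors, inoculation at
0.3×10^6 cells/mL in 12 mL, boluses of 4% v/v on days 4, 6, 8, 10, 12,
glucose top-ups to 6 g/L (days 4–8) and 7 g/L (days 9–12), daily VCD and
sampling-day metabolite panels. Growth is logistic to a peak near day 8
followed by first-order decline; dose effects enter through a unimodal
log-normal-shaped factor peaking at the 0.5× dose which scales the growth
rate, carrying capacity, productivity and decline. Defaults put the peak
VCD near 34×10^6 cells/mL at the optimum and near 13 at the dose extremes,
with the low-dose condition losing most of its titer — the qualitative
pattern expected of such a study. Byproduct formation (lactate, ammonia,
glutamate) scales *down* toward the optimum and amino-acid consumption
slightly up (`dose_scaled_rates()`); glucose uptake (−0.9 pmol/cell/day)
is dose-independent, matching a design that holds glucose comparable
across conditions. Late-culture glucose depletion between two-day top-ups
is accepted and clipped at zero, as are genuinely depleted amino acids
(e.g. Gln, Tyr at low GY) — depletion is a real feature of such data.

Two choices matter for testability:

* **Noise sits on measurements, not dynamics** — multiplicative lognormal
  with CV 5% by default — so planted rates are exactly recoverable at zero
  noise.
* **Concentrations advance between sampling days through the same
  trapezoidal IVCD the rate equations invert** (with pre-feed sampling and
  post-feed dilution bookkeeping). Cell density itself evolves on a
  0.1-day grid; piecewise-planted growth rates use exact exponential
  steps. Round-trip recovery of planted $Q_m$, $Q_p$ and SGR is therefore
  exact to round-off, and the 2% acceptance margin covers only numerical
  slack.

Planted **outliers** scale one batch's VCD trajectory. Planted
**nutrient–titer correlations** shift the metabolite's specific rate by
$-\mathrm{sign}\cdot s\,(1-f_d)$ pmol/cell/day ($f_d$ the dose factor):
extra formation away from the optimum for a negative plant. The signal
thus accumulates through the culture's own mass balance rather than being
pasted onto the profiles. The demo strength 0.3 pmol/cell/day — the order
of the larger amino-acid rates — makes the plant the dominant correlate;
at strength 0 the generator is untouched. What the generator does *not*
emulate: pH/DO dynamics, osmolality, mechanistic metabolite coupling,
elemental-balance closure of the panels, and measurement dropout; passing
tests say nothing about those aspects of real data.

# The reduced CHO-like network

`toy_cho_network()` is a ~70-reaction, three-compartment (e/c/m) stand-in
for a CHO genome-scale model covering the pathways the comparison
interrogates: glycolysis (lumped below G6P), oxidative PPP entry via G6PDH
(2 NADPH per G6P, with a lumped transketolase/transaldolase return
releasing one phosphate), full TCA cycle (PDHm, CSm, ICDHxm, AKGD,
SUCOASm, SUCD, FUMm, MDH), pyruvate carboxylase anaplerosis, lumped
oxidative phosphorylation (P/O 2.5 and 1.5), a malate–aspartate-style NADH
shuttle, glutamate/glutamine metabolism (GLUD, GLNS, GLUN, glutamate
decarboxylation to 4abut with secretion), asparagine metabolism (ASNN,
ASNS), the transaminases ASPTA/ALATA/ORNTA/LEUTA draining cytosolic akg,
arginase-to-ornithine, exchanges for all 20 amino acids, glucose, lactate,
ammonia, phosphate, O2/CO2/water/urea, and biomass plus antibody
synthesis. Cofactor pairs are balanced; protons are not tracked;
mitochondrial substrate-level and oxidative phosphorylation draw on the
single cytosolic adenylate pool (a deliberate lumping). Tyrosine enters
only through its own exchange or, after `augment_with_gy()`, through
dipeptide hydrolysis — so tyrosine-source essentiality is a testable
property. With all exchanges closed the only steady state is zero flux.

About twenty central reactions carry kcat (10^4–10^6 1/h) and MW
(35–980 g/mmol) annotations of realistic magnitude for the pooled
enzyme-capacity constraint; the default budget `P_total = 0.05` g/gDCW is
mildly binding and the suite sweeps it down to strongly binding values.
The ATP maintenance floor is 0.3 mmol/gDCW/h, scaled to the network's
exchange-flux magnitudes. The **antibody reaction** uses the
sequence-derived residue composition (serine 13.25 mol%, valine
8.89 mol%, …, methionine 0.90 mol%); the printed values sum to 100.10 and
are renormalized to an exact simplex so the reaction is mass-balanced.
Peptide-bond energetics default to 4.3 ATP per residue (configurable) —
a standard estimate covering activation, proofreading and secretion; the
source analysis does not state its energy term.

Models round-trip through a cobra-like JSON dialect and through SBML
Level 3 with FBC flux bounds (subsystem/kcat/MW carried in reaction
notes); a full genome-scale SBML model passes through the same machinery
unmodified.

# ecFBA

Measured day 6–7 rates (the phase with the most distinct growth and
productivity) are converted per replicate to mmol/gDCW/h with a cell dry
weight of 250 pg/cell (configurable; the unit bridge is
rate × 10⁻⁹ / (DCW × 10⁻¹²) / 24). Specific productivity converts to the
residue-based antibody flux via a mean residue mass of 0.110 g/mmol. Each
measured rate, relaxed ±20%, becomes the exchange's bounds; a measured
zero is widened by an absolute ε = 10⁻⁶ mmol/gDCW/h to avoid artificial
infeasibility. The pipeline bounds exactly the measured set it is given —
here glucose, lactate, ammonia, Glu, Gln, Asn, Asp, Ala and the GY
dipeptide — leaving other amino-acid exchanges at modest default uptake
bounds. The antibody flux is fixed (lb = ub), growth is *not* fixed:
biomass is the maximized objective (an optional cap at measured SGR ×1.2
exists). Replicates whose measured band is unsatisfiable — for example a
noise-induced "glucose secretion" — are skipped with a warning and the
condition flux is the reaction-wise mean of the remaining replicate
solutions.

Because FBA optima are typically degenerate, a parsimonious second stage
minimizes total flux at the fixed optimum, making fold changes
well-defined; repeated solves return identical vectors. The enzyme
constraint is a single pooled GECKO-style row over annotated reactions.
The LP itself is solved by the package's bounded-variable two-phase
revised simplex with Bland's anti-cycling rule — flux-balance problems
are small but fully degenerate (all equality right-hand sides are zero),
so the implementation favours determinism and robustness; it is verified
against exhaustive enumeration of basic feasible solutions on small
networks to 1e-9, and every returned solution is asserted to satisfy
S·v = 0 within 1e-6 and bounds within 1e-8.

# Comparative flux analysis

Comparisons run over the split (irreversible) reaction set, counting
forward and backward directions separately — consistent with how the flux
states are reported. The reference condition (0.5×) sits in the
numerator, so "more than 20% higher flux in the reference" is exactly
FC > 1.2 (strict). Reactions with both fluxes below the 0.0001 mmol/gDCW/h
floor are excluded; if only the denominator is below the floor the FC is
+∞, kept and flagged — the floor applies to the pair so on/off switches
stay visible. Selections from the two comparisons are intersected and
tallied by subsystem. Cofactor summaries total the producing flux
(positive stoichiometry × flux) of cytosolic NADPH, mitochondrial NADH and
FADH2; the transaminase summary reports each enzyme's share of the akg
drain; substrate partitions divide each sink's drain by the substrate's
total consumption, with the remainder reported as other/secreted.

# Problem sizes and runtime

The bundled demo — 15 batches, 9 phases, a 15 × ~213 PLS matrix, three
conditions × three replicates of ecFBA on the ~120-variable split network
— completes in a few seconds on one CPU and is byte-for-byte
rerun-deterministic under a fixed seed. The Monte-Carlo test campaigns
(100-seed outlier screen, 50-seed ranking recovery, 20-matrix PLS oracle)
keep the full suite under a minute.

# Known limitations

* The reduced network is a pathway-coverage fixture: absolute fluxes and
  percentage summaries are not comparable to genome-scale results, only
  the machinery that produces them is.
* The generator's dose–response and noise model are phenomenological;
  effect sizes were chosen for qualitative realism, not fitted to data.
* The outlier rule's SD band includes the candidate batch; with two
  replicates no screening occurs.
* Reversible-reaction fold changes depend on the split convention; net
  fluxes are available via `net_fluxes()` when the alternative reading is
  wanted.
* The LP is dense and intended for desk-scale networks (hundreds of
  reactions); genome-scale models will solve, but slowly.
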