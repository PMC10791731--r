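# gyflux

Analysis pipeline for studying how a glycyl-L-tyrosine (GY) dipeptide in
concentrated feed media affects IgG-producing CHO fed-batch cultures.
Tyrosine is poorly soluble at neutral pH, so concentrated feeds carry it as
a dipeptide; the dose of that dipeptide shifts growth, titer and the whole
metabolic state of the culture. `gyflux` implements the full analysis chain
used to dissect such a study:

1. **Specific rates.** Culture profiles (VCD, titer, metabolite
   concentrations over 14 days) are transformed per phase into the
   integrated viable cell density, specific growth rate, specific
   productivity and specific metabolite rates, with feed correction:

   ```
   IVCD(t1,t2) = (VCD1 + VCD2)/2 * (t2 - t1)              [10^6 cell.day/mL]
   Qm  = (C2 - (C1 + C_feed)) / IVCD                      [pmol/cell/day]
   Qp  = (Cp2 - Cp1) / IVCD                               [pg/cell/day]
   SGR = ln(VCD2/VCD1) / (t2 - t1)                        [1/day]
   ```

2. **Replicate QC.** Batches whose VCD trend sits outside the replicate
   mean ± 1 SD band, on one consistent side, for at least half the
   timepoints are flagged as outliers and excluded.

3. **Batch-level PLS.** The qualified dataset is unfolded into one row per
   batch (variables × post-feeding days 4–14) and regressed onto the
   normalized final titer with NIPALS PLS1. Nutrients are ranked by the sum
   of autoscaled regression coefficients at timepoints whose VIP ≥ 1.00 —
   the most negative sums mark residual nutrients consistently associated
   with lower titer.

4. **ecFBA.** Day 6–7 measured rates (±20% relaxation) bound the exchanges
   of a reduced CHO-like metabolic network augmented with GY uptake,
   transport and hydrolysis (`h2o[c] + glytyr[c] → gly[c] + tyr_L[c]`).
   With the antibody synthesis flux fixed to its measured value, biomass is
   maximized under a pooled enzyme-capacity constraint
   `Σ (MW_i/kcat_i)·v_i ≤ P_total`, followed by a parsimonious
   total-flux minimization so the reported flux vector is unique.

5. **Comparative flux analysis.** Condition flux states are compared to the
   optimal-dose reference via fold changes `FC = v_ref/v_other` over the
   split (irreversible) reaction set, with a 0.0001 mmol/gDCW/h flux floor
   and an FC > 1.2 selection; summaries cover NADPH/NADH/FADH2 generation,
   alpha-ketoglutarate drain by transaminases, and substrate partitioning.

A synthetic fed-batch generator (graded GY doses with a unimodal optimum at
0.5×, plantable outliers and nutrient–titer correlations) and the reduced
network make the whole pipeline runnable and testable without proprietary
data; a user-supplied genome-scale model in SBML (FBC) or the package's
JSON dialect passes through the same machinery.

## Worked example

The numbered scripts under `analysis/` run the study end to end
(`Rscript analysis/01_simulate.R` … `05_flux_comparison.R`), writing tables
under `results/`. Stage 1 prints the simulated dose–response:

```
simulated 15 batches; peak VCD by condition (1e6 cells/mL):
GY_0.125x  GY_0.25x   GY_0.5x     GY_1x     GY_2x
    13.32     24.19     34.00     24.91     12.45
-> the dose-response is unimodal with its optimum at 0.5x GY
```

Stage 3 recovers the planted glutamate signal as the strongest negative
correlate of final titer:

```
batch-level matrix: 15 batches x 213 columns; R2Y = 0.999
top nutrients by most-negative coefficient-sum:
  variable    coef_sum n_significant rank
1      Glu -0.06219519             7    1
2      Val -0.04875978             6    2
3      Met -0.03454781             4    3
```

and stage 4 solves the condition-level flux states:

```
GY_0.125x : biomass 0.0486 1/h from 3 replicates; G6PDH flux 0.1214
GY_0.5x   : biomass 0.0552 1/h from 3 replicates; G6PDH flux 0.1381
```

The same pipeline is available as one call:

```r
library(gyflux)
res <- run_pipeline(default_config())   # writes results/run/, returns stages
head(res$ranking)
```

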