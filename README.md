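# scpdyn

Receptor stimulation can trigger a whole-cell response — here, neurite
outgrowth (NOG) — by nudging many biochemical pathways at once, most of
them "deep" constitutive processes far from the signalling network
itself.  scpdyn implements the computational chain for dissecting such a
response into interacting **subcellular processes (SCPs)**: it filters
treated-vs-control transcriptomics and proteomics into differential
gene/protein lists, runs standard and *dynamic* ontology enrichment to
build context-specific SCP networks, quantifies neurite outgrowth from
microfluidic-chamber fluorescence line scans under siRNA knockdown, and
couples the findings to a compartmental ODE model of vesicle transport
with an analytical feasibility solution.  It is aimed at systems
biologists who want each stage as a tested, reusable function rather
than a one-off script.

## The methods in brief

* **Differential calls.**  DEGs require FDR-adjusted p ≤ 0.05 and
  |log2((FPKM_treated+1)/(FPKM_control+1))| ≥ log2(1.5) (stringent) or
  log2(1.3) (relaxed).  DEPs require ≥ 2 peptides, within-run
  normalization against untreated references, an equal-variance
  two-sided t-test at nominal p ≤ 0.05 and |mean log2 ratio| ≥
  log2(1.1).
* **Dynamic enrichment.**  For a query list, SCPs of one ontology level
  containing ≥ 1 list gene are combined into pairs/triples connected by
  the top 20% (level 2) or 25% (level 3) of same-level horizontal
  interactions; singles and combinations compete in one one-sided
  Fisher (hypergeometric upper-tail) ranking, and the top 3 / top 5
  predictions define SCP networks whose edges are certified by
  co-prediction.
* **Outgrowth statistics.**  Line scans are resampled to 0.1 µm; a
  cell-body damage QC requires a ≥ 85% normalized tubulin peak within
  50 µm of the microgroove wall; intensities are normalized to the
  control mean at 100 µm; knockdown and control are compared where the
  control first decays to 75/50/25%, with Dixon's Q (r10, confidence
  0.9, n ≥ 4) screening outliers before a one-sample t-test against
  each level (significant: any p ≤ 0.05; may-influence: any p ≤ 0.1).
* **Vesicle model.**  Membrane and v-SNARE/kinesin-receptor fluxes
  cycle between TGN and growth cone; only 10% of shaft vesicles are
  microtubule-bound (reservoir constraint); the analytic steady-flux
  solution maps (velocity, back-transport rate) to the cargo totals
  required at simulation start, flags infeasible constellations, and a
  grid scan extracts the stall and rapid-increase thresholds that rise
  with outgrowth velocity.

All pipeline inputs can be generated synthetically with known ground
truth (`synth_ontology()`, `synth_expression()`, `synth_proteomics()`,
`synth_profiles()`, `default_model_params()`), so every stage is
testable without downloads.

## Worked example

Plant a weak two-SCP signal (three upregulated genes in each member of
a strongly interacting level-2 pair) and let dynamic enrichment find
the combination that neither member supports alone:

```r
library(scpdyn)
so <- synth_ontology(seed = 42)
se <- synth_expression(
  so$ontology,
  expression_spec(planted = planted_pair_spec(so$truth)),
  seed = 7
)
degs <- call_degs(se$table, min_abs_log2fc = log2(1.5))
up6 <- degs$feature[degs$time_h == 6 & degs$direction == "up"]
dynamic_enrichment(up6, so$ontology, level = 2)
#>    rank unit_id       overlap unit_size  p_value
#> 1     1 L2_001+L2_012       5        40 2.53e-11
#> 2     2 L2_012              3        20 5.45e- 7
#> 3     3 L2_001              2        20 1.51e- 4
```

The planted pair `L2_001+L2_012` outranks both singles by four orders
of magnitude: five of the six planted genes survived the DEG filters,
and the union unit concentrates them in one Fisher table.

The vesicle model closes the loop between the analytic solution and the
simulation:

```r
params <- default_model_params("feasible", seed = 1)
traj <- simulate_outgrowth(params, duration = 48)
#> velocity 1.9063 um/h (target 1.9062); bound vesicles 9.99%
```

The integrated trajectory grows at the analytically demanded velocity
to four digits and holds the 10% microtubule-bound reservoir
constraint.

## The analysis workflow

`analysis/01_synthesize_inputs.R` … `05_vesicle_model.R` run the whole
chain on a seeded synthetic study and write their tables under
`results/`: generated inputs, DEG/DEP calls scored against ground
truth, dynamic predictions with the SCP network and timelines, the
outgrowth screen (QC, measurements, per-gene classification), and the
model trajectory with the threshold scan.  Step 4's output is a useful
honest caveat: at the default seed the null gene comes out significant
— the documented inflation of the screen-then-test procedure (see the
methods vignette) in action.

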