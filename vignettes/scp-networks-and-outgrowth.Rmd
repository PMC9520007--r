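---
title: "Methods: SCP networks, outgrowth statistics and the vesicle-transport model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SCP networks, outgrowth statistics and the vesicle-transport model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

scpdyn implements the computational chain behind a systems-biology study
of receptor-stimulated neurite outgrowth (NOG): which subcellular
processes (SCPs) a cell mobilises when a G-protein-coupled receptor
triggers the whole-cell response of growing a neurite.  The chain has
four scientific stages -- differential-expression filtering, ontology
enrichment with SCP-network construction, image-profile quantification
of outgrowth under gene knockdown, and a dynamical model of vesicle
transport -- plus a seedable synthetic-data layer that generates every
input with known ground truth.  This vignette explains the models, the
tunable parameters and the design decisions; it states no result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The SCP ontology

SCPs are organised in four levels, level 1 the most general.  Each SCP
carries a gene annotation; same-level *horizontal* interactions with
real-valued strengths encode which processes work together.  All Fisher
tables are built over an explicit *background* gene universe, and before
any enrichment the ontology is restricted to the genes the assay could
actually have observed (`restrict_to_background()`): keeping
non-measurable genes in the universe would deflate every enrichment
p-value.

Percentile cutoffs over interaction strengths
(`interaction_strength_cutoff()`) are inclusive at the threshold: the
top-$q$ set is every interaction with strength at least the
$\lceil qn\rceil$-th largest value, so ties expand the set rather than
being broken arbitrarily.  Composite SCPs (e.g. an umbrella process
gathering mitochondria-related branches) take the union of their
members' genes and, by default, do not participate in the percentile
computation -- adding a synthetic node should not shift the strength
cutoffs of the level it joins (`include_in_interactions` switches
this).

Gene symbols are matched case-insensitively after upper-casing, because
mouse/rat/human symbol casings differ across assays; ortholog
translation is a plain two-column lookup (`map_orthologs()`) applied
before restriction.

## Differential expression and proteomics filters

DEGs require both an adjusted p-value at most the FDR level (default
0.05) and a minimum absolute pseudocounted fold change

$$\left|\log_2\frac{\mathrm{FPKM}_\text{treated}+1}
{\mathrm{FPKM}_\text{control}+1}\right| \ge c,$$

with $c = \log_2 1.5$ for the stringent list that feeds dynamic
enrichment and $c = \log_2 1.3$ for the relaxed list behind standard
enrichment and timelines.  All cutoffs are inclusive ("minimum", "at
least").  The differential test itself is consumed as input (adjusted
p-values, or raw p-values passed through Benjamini-Hochberg via
`stats::p.adjust`); re-implementing an RNA-seq DE engine is not this
package's contribution.

Proteomics uses the two-run reference design: each run carries
untreated reference samples, and every treated/vehicle value is divided
by the run's mean untreated value for that protein, which cancels
run-level batch factors exactly.  DEP calls then require at least two
distinct peptides, a two-sided equal-variance t-test
p $\le 0.05$ (nominal -- the modest fold changes expected when only a
small fraction of the proteome is routed into the nascent neurite
justify the lenient cutoff), and a mean log2 ratio of at least
$\log_2 1.1$ in absolute value.  Replicates are pooled across the two
runs by default (`per_run` switches to within-run testing); the fold
change is the difference of group means on the log2 scale, which is
symmetric under direction.

## Standard and dynamic enrichment

Single-SCP enrichment is the one-sided (over-representation) Fisher
exact test: with list size $n$, unit size $m$, background $N$ and
overlap $k$, the p-value is the hypergeometric upper tail
$P(X \ge k)$.  Up- and down-regulated lists are tested separately at
every time point, which is why a one-sided test is the right shape.  No
multiple-testing correction is applied to enrichment p-values --
results are ranked and read at nominal significance.  A list gene
annotated to no SCP still counts in the list margin, keeping the 2x2
table consistent with the background.

Dynamic enrichment adds *function-specific* units: the SCPs of one
level that contain at least one list gene (the seeds) are combined into
pairs joined by an above-cutoff horizontal interaction (top 20% of the
level's interactions for level 2, top 25% for level 3) and into triples
whose members are connected by at least two above-cutoff edges
(`require_clique` demands all three; connectedness is the weaker and
default reading of "strongly connected").  Singles and combinations
compete in one ranking ordered by p-value with a deterministic
tie-break -- fewer member SCPs first (a single explaining the overlap
is the more parsimonious unit), then larger overlap, then lexicographic
id -- and the top 3 (level 2) or top 5 (level 3) predictions are
retained.  The percentile is computed over *all* interactions of the
level, not only among seeds, so the cutoff does not drift with the
query.  Combination gene sets are unions (no double counting), which
keeps the Fisher margins valid.

Retained predictions become SCP networks: nodes are all member SCPs,
and two nodes are joined when they were predicted as part of the same
function-specific unit, a triple contributing its full clique.  Every
edge is therefore certified by a retained prediction.  Standard
enrichment results across time points are reshaped into per-SCP
timelines of $-\log_{10} p$ for the up and down lists, with untested
combinations recorded as absent (not zero) and the significance line
$-\log_{10} 0.05$ carried as metadata.

## Neurite outgrowth quantification

Chamber line scans (ImageJ Plot-Profile style: distance, mean gray
value) are linearly interpolated onto a uniform 0.1 um grid, and
multiple images of one chamber are merged by averaging each grid point
over the images covering it -- overlap is counted once per image, and a
gap in coverage is an error rather than a silent split.

**Damage QC.**  An axotomy that nicks the cell-body side pulls the
intense tubulin line away from the microgroove wall.  The check
normalises the cell-body profile to its maximum within the first 100 um
(two-thirds of the 150 um groove width), defines a peak as a strict
maximum of the 5 um window centred on a grid point (window truncated at
the boundaries; ties yield no peak, so a flat stretch never counts),
and passes iff the highest peak within 50 um of the wall reaches at
least 85% -- inclusive, per "at least".  Chambers that fail drop all
their profiles; an experiment whose every control fails is dropped
entirely; genes left with fewer than two replicates are dropped.

**Normalization and reference distances.**  Outgrowth intensity varies
strongly between experiments, so profiles are scaled so the
experiment's control mean equals 100 at 100 um (the interpolated grid
value anchors the scale), and knockdowns are compared to controls at
the three distances where the control mean first falls to 75%, 50% and
25% -- searched from the 100 um anchor outward (intensities left of the
anchor reflect cell bodies, not outgrowth), with the exact crossing
linearly interpolated between bracketing grid points.  On a strictly
decreasing control the three distances are strictly ordered.

**Statistics.**  Per gene and level, replicate intensities are screened
with Dixon's Q (classical r10: gap of the more suspect extreme to its
neighbour over the range), two-sided, single pass, at most one removal,
only for $n \ge 4$; critical values are the classical Dean-Dixon table
at confidence 0.9 (0.941, 0.765, 0.642, 0.560, 0.507, ... for
$n = 3..30$), which a Monte-Carlo null of the two-sided statistic
reproduces at the 90th percentile.  The survivors are tested against
the level constant with a two-sided one-sample t-test (the "equal
variance" qualifier in the source procedure is vacuous for one sample,
so a standard one-sample t is the only coherent reading).
Classification: *significant* if any level's p $\le 0.05$,
*may influence* if none is but some p $\le 0.1$, otherwise *none*;
direction comes from the sign of the mean deviation at the most
significant level.

**A calibration caveat the tests quantify.**  Data-dependent outlier
removal followed by a t-test on the survivors is anticonservative: on
perfectly iid normal replicates the composed Dixon(0.9)-then-t
procedure rejects at roughly 0.10 at $n = 4$ rather than the nominal
0.05, because pruning the extreme value shrinks the sample standard
deviation more than it moves the mean.  The suite demonstrates both
halves: without the screen the per-level t-test on null knockdowns is
calibrated at the nominal rate; with the screen (the faithful
procedure) the rate is elevated.  Users comparing against the nominal
level should read borderline calls accordingly.

## The vesicle-transport model

The model tracks membrane area and two cargo species (v-SNAREs and
kinesin receptors) through a TGN-to-growth-cone cycle during neurite
elongation:

* membrane (rate $\sigma_m$, um^2/h) and cargo proteins (copies/h) are
  synthesised into the TGN;
* anterograde vesicles (area $a$ each) bud first-order in the limiting
  TGN resource, and each must be fully equipped with `snares_per_vesicle`
  v-SNAREs and `receptors_per_vesicle` kinesin receptors -- budding is
  limited by membrane AND free cargo;
* in the shaft, only a fraction `bound_fraction` (default 0.10, the
  literature-curated reservoir constraint) of anterograde vesicles is
  microtubule-bound and moving; binding/unbinding relax fast
  (`exchange_rate`) so the bound share tracks the constraint; transit
  rate is `kinesin_speed / L` for current length $L$;
* fusion at the growth cone deposits membrane and cargo; excess cone
  membrane converts to shaft length, $dL/dt = \text{flux}/(2\pi r)$;
* endocytosis consumes cone membrane at the back-transport rate $b$
  (area/h) and loads each retrograde vesicle with
  $\min(\text{cap}, \gamma \cdot \text{cone pool})$ copies of each cargo
  ($\gamma$ = `recovery_efficiency`); dynein returns membrane and cargo
  to the TGN at `dynein_speed / L`.

Default magnitudes (shaft radius 0.5 um, vesicle diameter 100 nm, motor
speeds 3600 um/h = 1 um/s, target velocity 2 um/h, caps 40/20 copies
per vesicle against an equipment of 10/5) are desk-scale placeholders
of the right order, declared as such, not measured claims; all are
plain config entries.  Integration uses `deSolve::lsoda` (stiff-capable)
at relative tolerance 1e-8; the model is deterministic.  Membrane and
cargo conservation are tracked explicitly in the output
(`membrane_total` etc. must stay constant to integrator tolerance).

**Analytic steady-flux solution.**  For a demanded velocity $v$ and
back rate $b$, balancing all fluxes at quasi-steady state (constant
fluxes; shaft reservoir and retrograde pools growing linearly as the
neurite elongates) gives closed forms for every standing pool, for the
required membrane synthesis, and for the cargo each retrograde vesicle
must recover:

$$s_\text{ret} = \frac{s_A B - \beta}{J_\text{ret}},$$

where $s_A B$ is the budding consumption, $\beta$ the synthesis rate
and $J_\text{ret}$ the retrograde vesicle flux.  The *required total at
simulation start* -- the reported quantity -- sums the TGN pool, the
in-transit equipment, the growth-cone pool $s_\text{ret}/\gamma$ and
the retrograde load.  A constellation is infeasible when
$s_\text{ret}$ exceeds the per-vesicle cap or a total exceeds its
configured maximum (`exceeds_max`), or when any derived quantity is
negative (`negative_parameter`); infeasibility is a reported outcome,
not an error.  Simulations initialised from a feasible solution
reproduce the demanded velocity within a percent and hold the 10%
bound-vesicle share.

**Thresholds.**  Because $s_\text{ret} \propto 1/b$ near the stall
bound, lowering back transport below a first threshold makes the
required totals rise steeply, and below a second threshold (where
$s_\text{ret}$ would exceed the cap) growth is impossible -- the wall
with a feasibility edge.  The steep-rise threshold needs an operational
definition; the scan uses *smallest feasible back rate at which the
required total has fallen to at most twice its value at the largest
scanned back rate*, recorded in the scan metadata and configurable.
Both thresholds move to higher back rates at higher velocities.  One
model property worth knowing: far above the thresholds the standing
equipment of vesicles in transit (which grows with total anterograde
flux, hence with $b$) eventually outweighs the recycling saving, so the
required totals have a shallow optimum in $b$; the monotone-decrease
statement holds in the recycling-limited window around the thresholds,
which is what the scan covers (back rates 0.5-5 um^2/h against
velocities 0.5-2.5 um/h in the shipped analysis).

## The synthetic study

The generators produce exactly what the pipeline consumes, with ground
truth recorded, and are deterministic per seed without touching the
caller's RNG stream.

* `synth_ontology()`: 5/20/40/80 SCPs over levels 1-4 with 0/20/15/10
  genes each from a 5000-gene background, overlapping annotations,
  uniform interaction strengths, and a designated strongest level-2
  pair for planting combination signals.
* `synth_expression()`: log-normal FPKM-like abundances, uniform raw
  p-values for nulls (BH-compatible), planted SCP genes shifted with
  small p-values at chosen times/directions; a configurable fraction of
  plants lands between log2(1.3) and log2(1.5) to exercise the
  two-cutoff design.  Null tables almost never survive the joint
  FDR-and-fold-change filter, which is what makes the downstream null
  calibration of dynamic enrichment sharp.
* `synth_proteomics()`: two runs with untreated references,
  multiplicative run batch factors (default 1 and 3), planted log2(1.2)
  shifts, and log2-scale noise of 0.015 -- technical-replicate-level
  precision, chosen so that effects at the pipeline's own fold-change
  cutoff are recoverable with the paper-style 2+2 design; biological
  variability in real cultures is larger, and recovery rates on real
  data will be correspondingly lower.
* `synth_profiles()`: neurite-side controls decaying as
  $100\,e^{-(d-100)/\lambda}$ ($\lambda$ = 200 um, which admits
  closed-form reference distances for test oracles), knockdowns scaled
  by an effect multiplier, and cell-body profiles whose tubulin ridge
  the damage flag displaces past 50 um or attenuates below 85%.  Noise
  is a smooth Gaussian process (independent knots every 100 um,
  linearly interpolated, sd 5) rather than white noise per grid point:
  averaged fluorescence line scans deviate slowly (cell density,
  staining), and grid-resolution white noise would bias the
  first-crossing reference-distance estimator early by first-passage
  selection.
* `default_model_params()`: parameter sets verified to land in the
  feasible / near-stall / stalled zones, with the velocity jittered up
  to 10% by the seed.

What the generators do *not* emulate: read-level count noise (no
negative-binomial RNA-seq simulation), spectral/reporter-level
proteomics, image formation, spatial chamber artefacts, or biological
replicate heterogeneity beyond the smooth intensity noise.  Passing
tests therefore certify the *rules* -- filters, combination logic,
crossing search, outlier screen, model algebra -- not robustness to
every failure mode of real data.

## Problem sizes and numerical choices

The shipped tests and analysis run at desk scale: a 5000-gene
background, single-time-point expression tables for the repeated-seed
studies (100 planted / 1000 null seeds for the enrichment calibration,
100 seeds each for DEG/DEP recovery), 1000 simulated null genes in
independent 4-experiment batches for the knockdown calibration, 48 h
model runs and a 5x20 threshold scan.  Degenerate inputs are handled
explicitly rather than by convention: empty gene lists skip their
stratum with a warning, a flat profile has no peak, zero-range samples
skip the Q test, infeasible model constellations return a flagged
solution, and profile grids are snapped to the 0.1 um lattice through
integer indices to keep floating-point drift out of coverage logic.

## Known limitations

* The ODE model is a minimal faithful realisation of the verbal
  compartment description (first-order budding/fusion, length-dependent
  transit, full-equipment budding, capped retrograde recovery); the
  source model's exact published equations live in its own repository
  and are not reproduced verbatim.
* The Dixon-then-t inflation discussed above is a property of the
  mirrored procedure, kept for fidelity.
* Enrichment p-values are nominal by design; users wanting FDR control
  across thousands of SCP tests must add it downstream.
* The per-vesicle retrograde recovery law ($\gamma$ times the cone
  pool, capped) is the simplest saturating choice; the paper is silent
  on sub-cap loading.
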