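---
title: "Methods: quantitative mapping of receptor-chemokine binding and signaling determinants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative mapping of receptor-chemokine binding and signaling determinants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccr9map)
```

## Scope

`ccr9map` implements the quantitative analysis layer used to map the
determinants of chemokine receptor activation across three experimental
modalities — calcium mobilization (G-protein pathway), BRET-based
arrestin-3 recruitment, and flow-cytometry chemokine binding — together
with geometric metrics on structural model ensembles of the
receptor-chemokine complex. The package was developed around the
CCR9-CCL25 system (the built-in sequences and residue conventions follow
it), but every stage is parameterized and works on any receptor-ligand
panel laid out in the same table formats.

The package deliberately does not perform structure prediction, scoring-
network inference, kinetic model fitting, or cytometry gating: inputs are
plate-reader trace exports, pre-gated median fluorescence intensities
(MFIs), and model coordinate files.

## Kinetic normalization

Raw fluorescence or luminescence wells are processed in a fixed order:

1. **Rolling average** over 10 acquisition points (5 s at the default
   0.5 s spacing). The window is trailing (causal), matching on-line
   plate-reader processing; at the left edge the window shrinks so the
   series length is preserved.
2. **Baseline normalization**: division by the mean of the 10 samples
   immediately preceding the injection. With two injections (antagonist
   mode) each segment is normalized to its own pre-injection window.
3. **Vehicle normalization**: pointwise division by the identically
   processed buffer well of the same cell line and replicate.

The calcium response is the post-injection maximum of the doubly
normalized ratio (ties resolve to the first occurrence); a
buffer-vs-buffer well scores exactly 1. The BRET response first forms the
acceptor/donor emission ratio $R(t) = \mathrm{em}_{540}(t) /
\mathrm{em}_{470}(t)$, then applies the same smoothing and normalization,
and integrates by trapezoids over a 600 s horizon. Arrestin recruitment
uses the area under $(R_{\text{norm}}(t) - 1)$ so a buffer well scores 0;
G-protein dissociation (where the ratio falls) uses the area over the
curve, $\int (1 - R_{\text{norm}})\,dt$, positive for dissociation.

Whether the unity baseline should be subtracted before integrating the
BRET signal is genuinely ambiguous; we subtract it by default — so that
vehicle wells score zero and mutant:WT ratios remain meaningful — and
expose the unsubtracted variant behind `subtract_baseline = FALSE`.

All responses are invariant to rescaling the raw traces by any positive
constant, which the test suite checks directly.

## Binding ratios

Flow-cytometry readouts are compared on the log-MFI scale. Surface
expression of a mutant relative to WT is

$$\frac{\log \mathrm{MFI}_{mut} - \log \mathrm{MFI}_{parental}}
       {\log \mathrm{MFI}_{WT} - \log \mathrm{MFI}_{parental}},$$

and chemokine binding relative to WT is

$$\frac{\log \mathrm{MFI}_{mut} - \log \mathrm{AF}_{mut}}
       {\log \mathrm{MFI}_{WT} - \log \mathrm{AF}_{WT}},$$

where AF is the autofluorescence of the same cell line in the same
experiment without ligand. Both are quotients of log differences and
therefore invariant to the log base (base 10 internally) and to common
multiplicative rescaling of all MFIs. The binding impact readout uses the
highest tested concentration (300 nM by default), where discrimination
between receptor-specific binding and the linear nonspecific
(proteoglycan-like) component is strongest; ratios are computed within
each experiment and then averaged across experiments. Specific-binding
curves subtract the parental-line MFI at matching concentrations on the
linear scale; negative values arising from noise are retained and flagged
rather than clipped, so standard errors stay honest.

## Concentration-response summaries

Signaling activity is summarized as the area under the
concentration-response curve over $\log_{10}$ concentration (AUCRC),
computed by trapezoids on the tested grid. Mutant:WT AUCRC ratios are
formed within each experiment and averaged across experiments.

One convention deserves emphasis: AUCRC ratios equal efficacy ratios
exactly only when the integrated response is zero at rest. Peak-type
calcium responses rest at 1 (vehicle level), so curve assembly
(`assemble_crc()`) subtracts the resting level (1 for peak ratios, 0 for
area-based responses) before integration. Without this, a
signaling-dead mutant would score roughly the ratio of baseline areas
rather than approaching 0, and ratios would no longer be interpretable
as fractional signaling output.

Potency is estimated with a four-parameter logistic,

$$y = \mathrm{floor} + \frac{\mathrm{ceiling} - \mathrm{floor}}
      {1 + 10^{\,h(\log_{10}\mathrm{EC}_{50} - \log_{10} c)}},$$

fit by Levenberg-Marquardt with 8 deterministic multi-starts on a
log-spaced EC50 grid (best SSE wins), bounds $\mathrm{floor} \ge 0$ and
$h \in [0.3, 5]$. Fits whose EC50 leaves the tested range by more than
two orders of magnitude, and flat curves, are flagged unconverged rather
than raising. EC50 mutant:WT ratios are computed per experiment and
combined with a geometric mean (potency ratios are log-normal); an
arithmetic mean is available behind a flag.

## Impact statistics

Per-assay mutant:WT ratios are log-transformed and compared by one-way
ANOVA. For within-experiment normalized signaling ratios the experiment
enters as a blocking factor (repeated-measures layout with a single
pooled error variance); binding ratios from independent experiments use
the plain one-way layout. Post-hoc comparisons of each mutant against WT
use the pooled residual variance and two-sided t statistics, adjusted by
the Holm-Sidak step-down: for ordered raw p-values the j-th adjusted
value is the running maximum of $1-(1-p_{(j)})^{m-j+1}$. `p.adjust()`
offers the Holm-Bonferroni step-down but not the Sidak form, so the
adjustment is implemented here (and Monte-Carlo calibrated in the tests:
familywise error under a 12-mutant null stays below 0.06).

The per-variant **bias index** quantifies disproportionate pathway
impact as $|\log_{10} r_{Ca} - \log_{10} r_{Arr3}|$ of the two signaling
ratios. The underlying visual criterion (scalene radar contours) has no
canonical numeric form; this absolute log-ratio difference is our
declared surrogate, recorded in the output metadata, with 0 meaning
both pathways were affected equally and 1 a tenfold disproportion.

Constitutive activity is summarized as the basal BRET fold-change versus
WT, with correlation diagnostics against donor luminescence and acceptor
level (a genuine constitutive signal should not simply track expression)
and a surface:total expression ratio; variants below a configurable
threshold (default 0.5) are flagged as predominantly intracellular.

## Structural-ensemble metrics

All metrics operate on plain atom tables read from PDB (via bio3d) or
mmCIF (a minimal `atom_site` reader written for this package, since no
installed R package parses mmCIF). Model confidence (pLDDT-style) is
taken from the B column.

* **Superposition** is closed-form least squares (Kabsch/SVD) on
  C-alpha selections; the test suite cross-checks the RMSD against
  bio3d's independent implementation.
* **Activation distance** is measured from the tyrosine hydroxyl oxygen
  at the pocket floor (BW 3.32; residue 126 by default) to the *nearest*
  heavy atom of the asparagine carboxamide at BW 6.52 (residue 271,
  ND2/OD1) — nearest-atom because carboxamide orientation is often
  ambiguous in models (amide flips). Ensembles are ranked by this
  distance; the "most active" model is the one with the largest
  separation, with secondary diagnostics (outward movement of the TM6
  intracellular end, cross-pocket C-alpha distance, TM5 depth) reported
  alongside and ties broken by model id.
* **Helix displacement** between active and inactive states superposes
  on all TM C-alphas *excluding* the measured segment (so the moving part
  cannot bias the frame) and decomposes the displacement of the segment
  midpoint C-alpha along the bundle axis (first principal axis of the
  frame C-alpha cloud, signed toward declared intracellular marker
  residues) and perpendicular to it. The reference measurement this
  reproduces (~6 Å intracellular slide of TM5) was published without an
  explicit frame convention, so ours is declared and tested with a
  generous tolerance.
* **Contacts** are heavy-atom distances at a 4.5 Å cutoff, receptor side
  chains only when the side-chain flag is set. Contact strength is
  defined as (fraction of ensemble models showing the contact) × (mean
  number of atom pairs within the cutoff); mutagenesis-site selection
  ranks receptor residues by summed strength within a declared TM residue
  set, breaking ties toward lower residue numbers. The strength formula
  is an invented operationalization of "strongest contacts in multiple
  models"; both factors and the cutoff are configurable.
* **Hydrogen bonds** use heavy-atom geometry: N/O donor-acceptor pairs
  with distance in (2.5, 3.5] Å, excluding same-residue pairs and
  sequence-adjacent backbone-backbone pairs; a D-H-A angle ≥ 120° is
  additionally required only when hydrogens are present (predicted models
  usually lack them, in which case the angle is reported as missing). No
  energy function is used, and the criteria are echoed in outputs.
* **Disulfides** pair cysteine SG atoms below 2.5 Å greedily by
  increasing distance, each cysteine used at most once.
* **Atom-score aggregation** sums externally supplied per-atom scores
  over backbone (N, CA, C, O, OXT) and side-chain atoms per residue, with
  optional averaging across the top-n models of an ensemble. The scoring
  itself is out of scope; only the aggregation is provided.

Residue numbering is 1-based mature-protein numbering throughout,
matching the printed sequences; Ballesteros-Weinstein labels and TM
boundaries are supplied as configuration tables, not computed by
alignment. The built-in CCL25 record follows the printed mature sequence
verbatim: its first residue is the pyroglutamate (cyclized from Gln),
printed as "P"; for all sequence-level operations it is treated as a
standard residue since cyclization affects structural interpretation
only.

## The synthetic-data generator

The generator exists so every pipeline stage is testable end to end with
known ground truth; it makes no attempt at biophysical realism beyond
the features the pipeline measures.

* **Calcium traces**: flat baseline (1000 a.u., optional linear drift),
  then a transient shaped as a difference of exponentials (rise 3 s,
  decay 40 s — chosen to visually match typical FDSS dual-injection
  traces) with amplitude `emax_scale * 1.5 * c^h/(c^h + EC50^h)` (Hill
  coefficient 1 by default; no cooperativity is asserted anywhere, and
  the coefficient is configurable). Per-point multiplicative Gaussian
  noise with the given CV.
* **BRET traces**: a constant donor channel scaled by expression, and an
  acceptor channel equal to donor × ratio, where the ratio is the basal
  value (0.8) plus the variant's constitutive offset plus an
  occupancy-driven saturating change (time constant 60 s), positive for
  arrestin recruitment and negative for G-protein dissociation.
* **Flow tables**: MFI = AF + specific saturable component
  (`Bmax * scale * expression * c/(c+Kd)`) + linear nonspecific component
  (`k_ns * c`, present in all lines, emulating proteoglycan binding),
  with lognormal noise. Parental cells carry the nonspecific component
  only.
* **Toy ensembles**: seven parallel helix analogs (24 residues each,
  residue ranges loosely echoing TM1-TM7 numbering) around a bundle
  axis, a chemokine-analog chain above the pocket, and planted features
  with exact ground truth: an activation-distance atom pair at controlled
  separation per model (placed on an isolated spur so the planted
  distance cannot collide with other features), long-side-chain contact
  pairs reaching into the pocket, a lysine-analog side chain donating
  three hydrogen bonds to loop backbone oxygens (residues 32, 33, 35), a
  C7-C35 SG-SG disulfide, and a 6 Å intracellular slide of the TM5
  analog relative to the inactive reference. Gaussian coordinate jitter
  (0.05 Å) is applied to non-planted atoms only. Geometries whose
  non-bonded atoms fall below 0.4 Å are rejected as infeasible.

All generators are pure functions of their parameters and a seed;
plate-level wrappers seed once and let wells draw sequentially.

What passing tests on these fixtures demonstrates is that the *analysis
math* is correct under its stated assumptions — not that the
pipeline is robust to features of real data the generator omits
(receptor reserve and amplification differences between pathways,
non-Gaussian plate artifacts, well-to-well carryover, hemiequilibria at
low concentrations, realistic protein packing, ensemble heterogeneity
beyond isotropic jitter).

## Statistical design of the validation suites

The parameter-recovery checks use the study design the experimental
tables follow: 6 concentrations (log-spaced from 0.03 to 10 nM around an
EC50 of 3 nM), triplicate wells, 3 independent experiments, 3% trace
noise. Under this design, recovered AUCRC mutant:WT ratios correlate
with planted efficacy scales at r > 0.95, and the recovered EC50 ratio
for a planted twofold potency loss is within 15% of truth (median over
100 seeded repetitions). The twofold shift keeps the shifted EC50
bracketed by the tested concentrations; larger shifts push the mutant
EC50 outside the tested range, where any method's potency estimate is
unidentifiable — a property of the design, not of the estimator. The
null calibration simulates 12 mutants at WT level across 3 experiments
(1000 repetitions) and requires the familywise error of the adjusted
comparisons to stay at or below 0.06.

These problem sizes (8-variant recovery panels, 100 seeds, 1000 null
simulations) are the package's chosen validation scale: large enough for
stable estimates of correlations and error rates, small enough that the
whole suite runs in a few minutes on one CPU.

## Known limitations

* The bias index and the contact-strength score are declared surrogates
  for criteria that were published only visually or verbally.
* Repeated-measures ANOVA is implemented as experiment blocking with one
  pooled variance; no sphericity correction or mixed-effects modeling.
* The mmCIF reader handles coordinate `atom_site` loops only (no
  multi-model blocks, no quoted multi-token values beyond simple
  quoting).
* H-bond detection without hydrogens cannot distinguish donor from
  acceptor for O-O pairs; the nitrogen end is assigned donor when the
  pair is N/O, otherwise assignment is positional.
* EC50 estimates are meaningful only when the tested concentration range
  brackets the EC50; the `converged` flag catches gross failures but not
  mild edge bias.
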