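---
title: "Methods: efficacy gating, interaction energetics, sonification and chimera design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: efficacy gating, interaction energetics, sonification and chimera design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantavax)
```

This vignette documents the models behind each stage of the package, the
parameters that matter, the numerical conventions, and the design
decisions taken where the underlying procedures left genuine freedom.
It states no empirical result beyond what the test suite and the
analysis drivers themselves compute.

## Vaccine efficacy with significance gating

A tick-infestation trial records four fitness metrics per animal: the
count of engorged female ticks (`nt`), mean engorged female weight
(`wt`, mg/tick), oviposition (`pat`, mg eggs/tick) and egg fertility
(`pplo`, larvae weight over egg weight). For a vaccinated group V
against a control C, the percent effect on each metric is
$100\,[1 - \bar{x}_V/\bar{x}_C]$, reported clipped at 0 (a vaccine is
not credited with increasing tick fitness) but retained unclipped
internally. Efficacy combines three of the four metrics:

$$E = 100\,[1 - CRT \cdot CRO \cdot CRF]$$

where $CRT$, $CRO$ and $CRF$ are the vaccinated-to-control mean ratios
of tick number, oviposition and fertility. Tick weight is reported but
never enters $E$: weight effects are transient and double-count the
oviposition effect.

**Gating.** Each ratio enters the product only when its Welch
unequal-variance $t$-test is significant at $\alpha$ (default 0.05);
otherwise the ratio is replaced by exactly 1 — not by a clipped or
shrunk ratio — so a non-significant metric contributes no efficacy.
The test is **one-sided** (alternative: vaccinated mean below control)
by default. With three animals per arm a two-sided test roughly doubles
the p-values and changes which metrics gate in; the one-sided reduction
alternative is the reading consistent with the per-animal data this
pipeline is calibrated against, and a `sided = "two"` flag exposes the
alternative convention. Degenerate arms with zero variance in both
groups and equal means return $p = 0.5$ by convention.

**Rounding.** Percentages and counts display rounded to the nearest
integer with ties away from zero; ratio-valued metrics to two decimals.
Gating and $E$ always use unrounded values.

**Known limitation.** The gated-product rule reproduces the packaged
SUB column exactly (E = 62%), but published efficacy figures for other
groups of the same trial (52% and 12%) are not derivable from this rule
with any gating combination we tried; the package implements the stated
rule and makes no attempt to reverse-engineer those two figures.

The 2^−ΔΔCt helper (`ddct_relative_expression`) implements the standard
relative-quantification transform for biomarker expression; it is
deliberately minimal (no amplification-efficiency correction).

## Residue-pair interaction energetics

For a two-chain complex, the inter-chain interaction energy is a sum
over all atom pairs of an electrostatic and a Lennard-Jones term:

$$E_{el} = k_e \frac{q_i q_j}{\varepsilon(r)\, r}, \qquad
  E_{vdw} = \frac{A_{ij}}{r^{12}} - \frac{B_{ij}}{r^{6}}$$

Units are Å, elementary charges and kcal/mol; the Coulomb factor
$k_e = 332.0637$ kcal·Å/(mol·e²) follows the AMBER convention, chosen
for consistency with AMBER-style force-field parameters (the per-atom
`rmin_half`/`epsilon` inputs combine by Lorentz–Berthelot rules in
`lj_pair_from_atoms`). Solvent screening uses the sigmoidal
distance-dependent dielectric

$$\varepsilon(r) = A + \frac{B}{1 + k\,e^{-\lambda B r}}, \qquad
  B = \varepsilon_0 - A$$

with defaults $\varepsilon_0 = 78.4$, $A = -8.5525$,
$\lambda = 0.003627$, $k = 7.7839$. The printed grouping of this
expression is typographically ambiguous; the sigmoidal screened form
above is the only reading under which these constants produce a
physically sensible dielectric (≈1.35 at contact, strictly increasing,
saturating at bulk water), and the package adopts it.

```{r dielectric}
dielectric_eps(c(0, 5, 10, 50, 1e6))
```

**Conventions.** No distance cutoff is applied by default — every
inter-chain atom pair contributes (an optional `cutoff` exists for very
large systems). No 1–4 scaling or exclusion lists apply: those concern
bonded neighbours, and no bonds cross the chain–chain interface.
Intra-chain pairs never contribute. Atom-pair energies are attributed
to their (chain-1 residue, chain-2 residue) pair and averaged
elementwise over snapshots; matrices carry residue numbers (1-based,
as in PDB numbering) as dimnames.

**Region extraction.** The per-residue score is the row (or column) sum
of the averaged total-energy matrix. Residues scoring at or below
mean − z·SD (default z = 1; more favourable tail) seed regions, seeds
separated by at most `merge_gap` (default 2) residues merge, and regions
rank by mean per-residue energy. Threshold and merging are this
package's own plumbing — the underlying protocol states only the goal
of flagging the most probable interacting regions — so both knobs are
exposed and documented. A zero-variance score vector (e.g. an all-zero
matrix) yields no regions and a warning rather than an error.

## Codon sonification

Each codon maps to one 3/4 measure: a "base" of one or two pitches,
optionally followed by one or two more, with durations summing to
exactly three quarter-note beats. Ten codon formulas are fixed by the
published model (UGC, CAA, UCG, UCC, GCG, GCC, GGA, GGC, UCA, UCU);
e.g. UGC is a dotted-half-note B and acts as a cadence. Solfège
spellings in those formulas (S = sol, L = la, R = re) are canonicalised
to letter names at table load so the token alphabet is exactly the seven
letters and exports are bijective.

**Extrapolated table.** The remaining 54 codons are filled by a
deterministic scheme that is explicitly *not* canonical: each synonymous
family receives a base letter from a fixed rotation of the seven
letters, and the rhythm pattern follows the third codon base (A:
full-measure base, G: half + quarter, C: half + two eighths, U: two
dotted quarters). Stop codons map to a full-measure rest and are
dropped by default at transcription (a CDS of N amino acids scores N
measures). The full table ships as YAML and can be overridden wholesale
via `read_codon_table()`.

**Cadence segmentation.** Every full-measure single-note bar closes a
segment, so segments always partition measures 1..N; with no cadences
the score is one segment, and consecutive cadences yield singleton
segments (the mechanical reading consistent with "every cadence is a
resting point"). Each segment reports its modal pitch token with
earliest-first tie-breaking. Musical judgments beyond this mechanical
rule — e.g. grouping segments into larger parts by pitch insistence —
are out of scope.

**Exports.** ABC (quarter-note unit, one bar per measure) round-trips
losslessly through `import_abc`; MusicXML uses divisions = 2 so eighth
notes are exact; MIDI is a format-0 file at 480 ticks per quarter. The
concrete pitch map (default: letters onto C4..B4) is configurable;
analyses operate on tokens, not concrete pitches.

## Consensus epitopes and chimera assembly

Evidence is stored as residue *sets* per model, not intervals, so
models reporting scattered pairwise contacts integrate cleanly; an
empty set represents a model predicting no interface. The support
profile counts models per residue; consensus intervals are maximal runs
with support ≥ `min_support` (default 2, "agreement of at least two
models"), bridging gaps of at most `merge_gap` (default 2 — no
published gap rule exists, and 2 residues is below the length of any
epitope of interest). Raising `min_support` can only shrink intervals,
a property the test suite checks against a brute-force scan.

Published consensus peptide boundaries can be wider than the strict
model-agreement core (editorial context, e.g. inclusion of flanking
protective-epitope sequence); the package therefore separates the two:
`consensus_intervals` returns the algorithmic core, and
`extract_epitope` slices any user-specified interval. The packaged
protein fixtures are *synthetic*: the published interface peptides
placed at their true coordinates with glycine filler flanks, sufficient
for coordinate arithmetic but not real flanking sequence.

Chimera assembly joins ordered uppercase blocks with a lowercase linker
(default `GGGS`), making linker positions recoverable from case alone;
`split_chimera` inverts the operation and `verify_chimera` reports
exact/case-insensitive matches and the first mismatch position.

## Synthetic-data generators

All generators require an explicit seed, use one local RNG stream and
restore the caller's RNG state.

- `gen_trial`: zero-truncated normal per-animal metrics. Defaults
  emulate a control herd with 1459 ± 206 engorged females, 273 ± 17
  mg/tick, 109 ± 12 mg eggs/tick and fertility 0.52 ± 0.11 — the scale
  of a three-animal pen trial with a 10,000-larvae challenge — and a
  vaccinated arm with multiplicative effects (defaults 0.57 on tick
  number and 0.67 on fertility, i.e. a SUB-like antigen). Truncated
  normals are the simplest family matching the reported mean/SD
  summaries; real counts are likely overdispersed, so passing tests
  show estimator consistency under the assumed noise, not robustness to
  overdispersion.
- `gen_complex`: residues on two parallel lines (5 Å spacing, 30 Å
  apart) with a configurable contact patch moved to 4 Å and given
  opposite unit charges; all atoms share mild LJ parameters
  (rmin/2 = 1.908 Å, ε = 0.1094 kcal/mol). Snapshots add isotropic
  Gaussian jitter (default 0.1 Å). This is a point-charge toy with the
  geometry the scoring assumes — patch pairs dominate the energy — not
  realistic protein geometry.
- `gen_codon_sequence`: random non-cadential sense codons with TGC
  planted every `cys_period` positions, so cadences land exactly at the
  planted cysteines.
- `gen_evidence`: each model keeps each true-interval residue with
  probability `retain_prob` (default 0.8) and adds spurious outside
  residues at `spurious_rate` (default 0.1). With four models,
  per-residue support ≥ 2 has probability ≈ 0.97 before gap-merging,
  which is what makes the ≥ 90% mean-coverage recovery property hold.

## Problem sizes and numerical checks

The test suite and drivers run at desk scale by design: toy complexes
of ≤ 200 atoms and ≤ 10 snapshots (checked against a brute-force
atom-pair double loop to 10⁻⁶ kcal/mol), 1,000 random sequences of up
to ~50 codons for the sonification invariants, 200 replicates of
50-animal-per-arm trials for efficacy recovery (mean estimate within 3
percentage points of the generating value) and 100 replicates for
evidence recovery. Snapshot ensembles of real MD scale (1,000 frames)
are supported by the same code path — the averaging is linear in
frames — but are not exercised in tests.

## Known limitations

- The gated-efficacy rule cannot reproduce all published group figures
  (see above); the discrepancy is documented, not patched.
- The extrapolated 54-codon portion of the sonification table is a
  placeholder scheme, clearly marked; only the ten published formulas
  are canonical.
- Packaged evidence encodes only the residue sets printed in the main
  text of the source trial reports; full per-model lists live in
  supplementary material and can be supplied by the user as JSON.
- The energy model is an implicit-solvent, pairwise-additive post-hoc
  score; it does not replace PME electrostatics or explicit solvent and
  carries no force-field derivation of its own.
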