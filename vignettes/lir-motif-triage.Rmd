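---
title: "Methods: LIR motif discovery and triage"
author: "lirtriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LIR motif discovery and triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lirtriage)
```

## The problem

ATG8-family proteins (LC3A/B/C and the GABARAP subfamily) are recruited to
cargo and membranes through short linear motifs, the LC3-interacting
regions (LIRs). A LIR is a four-residue core Θ-X₁-X₂-Γ whose aromatic Θ
and aliphatic Γ side chains insert into two hydrophobic pockets of the
ATG8 surface. The canonical consensus is `[W/F/Y]-X-X-[L/V/I]`; the
GABARAP interaction motif (GIM) `[W/F]-[V/I]-X-V` is the refinement
associated with GABARAP-subfamily selectivity. Because four loosely
constrained residues match often by chance, raw scanning over-calls
heavily; the practical question is always triage: of all
pattern-compatible windows, which are conserved, structurally available,
and supported by binding data?

`lirtriage` implements that workflow as composable, testable pieces. Two
commitments run through the package:

* **Pattern ≠ binding.** Every consensus result is reported as
  *consensus-compatible* only. The package exposes a documented example of
  why this matters: a Θ-position substitution ablates the pattern, but an
  X₂ substitution leaves the pattern intact even when binding is lost
  experimentally. Nothing in the API converts a match into an affinity
  claim.
* **Coordinates are computed, never transcribed.** All motif coordinates
  are produced by scanning the actual sequence; nothing is hard-coded
  from literature tables, which protects the package from the off-by-one
  errata such tables occasionally carry. All coordinates are 1-based and
  inclusive; the conversion to R's internal indexing is confined to the
  I/O layer.

## Consensus scanning and flank scoring

`scan_motifs()` tests **every** window of four residues, so overlapping
and directly adjacent candidates are all reported; non-overlapping regex
semantics would silently drop the second of two adjacent hits, which real
proteins do produce. Each hit records membership in both built-in classes.
Because every GIM position set is a subset of the corresponding canonical
set, GIM hits are provably a subset of canonical hits — the suite checks
this as a property on random sequences.

Flanks are fixed windows X₋₅..X₋₁ and X₄..X₁₀, truncated (never padded)
at the termini. Acidic (D/E) and phosphorylatable (S/T) residues there
enhance ATG8 binding; since that enhancement is qualitative, the score is
a plain count with no positional weighting — any weight vector would be
invented precision. The unknown residue `X` is accepted by the parsers but
fails every consensus position, including wildcards: an unknown residue is
never evidence for a motif.

The ATG8-paralog preference is deliberately modest. Without user-supplied
position weight tables the only defensible statement is that a
GIM-compatible core favors the GABARAP subfamily; canonical-only cores are
reported as an indeterminate six-way tie. With tables, paralogs are ranked
by a log-odds sum over the 16-position window.

## Conservation

`map_ref_positions()` transfers reference coordinates onto alignment
columns (the map is defined exactly for the reference's non-gap
positions). Presence per taxon (`motif_presence()`) is a pattern call on
the four homologous columns: any gap means `absent`; otherwise GIM is
tested before canonical. Presence is deliberately *not* percent identity —
the biological question is whether the functional residues survived, not
how similar the neighborhood is.

Logo profiles use the plain information content `IC = log₂20 − H` in
bits, gaps excluded from the denominator, with no small-sample correction
and no background weighting; the degenerate endpoints (fully conserved
column ⇒ exactly `log₂20`; uniform column ⇒ exactly 0) are asserted in
the tests.

Gain/loss reconstruction (`fitch_gain_loss()`) treats presence as a binary
character and computes ancestral state sets bottom-up with Hartigan's
majority-set rule: keep the states carried by the largest number of child
sets and add the deficit to the change count. On bifurcating trees this
is exactly classic Fitch (intersection if non-empty, else union with one
change); we chose the majority-set generalization because the pairwise
rule undercounts on polytomies (four children scored
present, present, absent, absent cost one change under intersect/union
but truly require two), and the package promises a *minimal* change
count. That promise is enforced by brute force: tests enumerate all
ancestral labelings on random bifurcating and multifurcating trees up to
12 leaves (200 + 50 trials) and on an independent parsimony
implementation (`phangorn`). Root-state ties resolve to `absent` by
default — conservative against inferring anciently present motifs — and
the preference is a documented argument.

## Structural accessibility

`shrake_rupley()` places a golden-spiral (Fibonacci) lattice of test
points on each atom's solvent-expanded sphere and counts the fraction not
buried inside any neighbor's expanded sphere. Defaults: probe 1.4 Å (a
water-sized probe), 960 points, and an element-based van der Waals table
(C 1.70, N 1.55, O 1.52, S 1.80 Å) with hydrogens ignored — predicted and
crystallographic protein structures typically lack them. The point set is
deterministic, so SASA is reproducible bit-for-bit at a given point
count. Accuracy is pinned to closed forms: an isolated sphere is exact to
< 1 % and a two-sphere cap system to < 2 % at 960 points, and doubling
the lattice moves total SASA on a toy helix by < 1 %.

Relative SASA divides by the theoretical Gly-X-Gly maxima of Tien et al.
(2013, PLoS ONE 8:e80635). Values can slightly exceed 1 at extended
termini; the raw value is kept and a capped copy reported alongside.

`motif_accessibility()` evaluates the mean core relative SASA twice — the
motif's chain isolated, and the full assembly — and applies two
thresholds: exposure at relative SASA ≥ 0.20 (a common exposed/buried
convention, configurable) and oligomer occlusion at a monomer→assembly
drop ≥ 0.05. A motif overlapping a user-declared transmembrane interval
is forced to `buried` with reason `"transmembrane"`: membrane topology
cannot be computed from coordinates alone, so it enters as configuration,
never as inference.

## Peptide arrays

`design_tiling()` emits the standard SPOT scheme — 15-mers at a 3-residue
offset — as a regular grid plus, by default, one C-terminal anchor spot so
every residue is covered (membrane layouts differ in whether they include
it; covering the terminus is the safer default for design). Consecutive
grid spots overlap by L − k = 12 residues, and a 4-residue core is fully
contained in at most ⌊(15−4)/3⌋+1 = 4 spots.

`call_interactions()` implements the run rule: an interaction is positive
when at least `run_threshold = 3` consecutive covering spots are
positive. Runs are computed over the spots that **fully contain** the
core (strictest reading; a partial-overlap mode is available behind the
`mode` flag, since the looser reading is also defensible). Binarization
defaults to background mean + 2 SD, making calls invariant under common
intensity rescaling. The call also records whether the N-flank-truncated
covering spot (the last one, where the core sits closest to the peptide's
own N-terminus) is negative — a positive motif whose flank-truncated spot
goes dark is the array's way of saying the N-terminal flank contributes
to affinity.

## Triage

`rank_candidates()` is a lexicographic ordering, not a weighted score:
the upstream evidence is largely qualitative, and a numeric weighting
would manufacture precision the inputs do not have. The default order is
(1) structurally plausible (not TM-excluded, exposed in ≥ 1 context),
(2) GIM before canonical-only, (3) higher ortholog retention,
(4) higher total flank acidity, ties broken by start coordinate. The key
order is configurable, every comparison is written into a rationale
string, and reruns are byte-identical. Array evidence is annotated but
not ranked on by default — it is orthogonal confirmation, not a triage
axis. Missing layers stay `NA` and rank conservatively (unknown exposure
is not exposure).

## Synthetic ground truth, and what the tests do not show

The generators exist so every stage can be tested against known truth
without downloads:

* `simulate_ortholog_family()` evolves a reference down a tree by
  independent per-site replacement (probability `1 − exp(−b·rate)` per
  branch of length `b`, uniform over the 19 alternatives), then resolves
  each motif per leaf with retention probability θ: retained cores are
  kept consensus-valid; non-retained cores get their Θ anchor forced
  outside the full canonical anchor set so they violate *both* consensus
  classes — otherwise a "lost" GIM could still read as canonical and bias
  retention estimates. Deletions (optional, default off) are irreversible
  per site, so the known homology yields an exact gapped alignment;
  insertions are not modeled. Tests recover θ ∈ {0.2, 0.5, 0.8} within
  exact binomial 99 % intervals on 200-leaf trees.
* `make_toy_structure()` builds ideal poly-alanine helices (rise 1.5 Å,
  100° twist, Cα+Cβ atoms) and sphere systems; the dimer is a rigid
  +x translation (default 9 Å axis separation) with interface truth
  defined geometrically (Cβ within 8 Å of the partner). Motif windows are
  restricted to the helix core because frayed termini dominate SASA
  regardless of orientation. One honest caveat: four *consecutive*
  residues on an ideal helix span 300° of phase, so a contiguous window
  can never face a single direction the way real interface motifs (on
  curved or extended segments) do — the dimer toy therefore demonstrates
  occlusion, not fine-grained face selection.
* `simulate_array_signals()` flips covering spots with rate 1 − FN and
  background spots with rate FP; recovery of a 4-spot binder matches the
  exact run-length enumeration over the 2⁴ patterns.

Each generator runs on its own explicitly seeded PRNG stream and restores
the caller's RNG state, so identical specs are byte-identical and
generators never perturb user code.

What passing these tests shows is that the algorithms are correct on
their own contracts. What they do not show: real ortholog families evolve
under site-heterogeneous, substitution-biased processes with insertions
and alignment error; real membranes have spatial artifacts, edge effects
and cross-reactivity; real structures have side chains, and exposure
thresholds tuned on toy Cα/Cβ helices transfer only qualitatively.
Conclusions about any real protein still require the user's own
alignment, tree, structure and array data.

## Numerical and policy choices

* Tie-breaking: Fitch root ties → `absent` (configurable); triage ties →
  ascending start; GIM is tested before canonical in presence calls.
* Degenerate inputs: sequences shorter than 4 residues scan to an empty
  hit table with a warning; an all-gap reference row or column is an
  error / `NA`, never silently 0; unknown structure elements are skipped
  with a warning (or an error on request).
* Problem sizes in the shipped tests (chosen to exercise the algorithms
  while keeping the suite quick): 200-trial parsimony brute force at
  ≤ 12 leaves, 200-leaf retention recovery, 960/1920-point SASA
  convergence on 24-residue helices, 400-replicate array recovery.
* The demo's conservation/accessibility columns come from a curated
  qualitative evidence table shipped as demo *input* and clearly labeled
  as such; the demo's scan, flank scores, GIM call, mutant logic and
  ranking are computed live.

## Known limitations

* No PSSM training and no replication of web-tool scoring schemes;
  paralog preference beyond the GIM/GABARAP statement requires
  user-provided tables.
* Alignment and tree inference are consumed, not performed.
* SASA supports the PDB fixed-column dialect; mmCIF users should convert
  first.
* Parsimony is unweighted and binary; maximum-likelihood ancestral
  reconstruction is out of scope.
* Membrane topology (which face of a membrane a motif sees) is user
  configuration, not computation.
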