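---
title: "Ranking PTM hotspots by Function Potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking PTM hotspots by Function Potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmfp)
```

## The problem

High-throughput proteomics has catalogued hundreds of thousands of
post-translational modifications (PTMs), but only a small minority have a
documented biological function. Prioritising which sites to study
experimentally is the bottleneck. `ptmfp` ranks PTM sites by pooling
evidence across a protein family: modifications observed independently on
different family members are layered onto the columns of a multiple
sequence alignment (MSA), producing *hotspots*, and each hotspot is scored
by how plausible a regulatory role is for a residue in the folded protein.

A hotspot is a single alignment column — deliberately not a window of
neighbouring columns — carrying one or more experimentally observed PTMs
from any member. Its *intensity* is the total PTM count; a hotspot may mix
modification types (e.g. phosphorylation and ubiquitination at the same
column).

## The Function Potential model

Each hotspot receives a Function Potential (FP) score built from four
multiplicative criteria, each of which should *increase* the plausibility
of function:

1. **Intensity.** `PS = total_ptms` (the PTM score). A log-damped variant
   `PS = 1 + ln(total_ptms)` is selectable for corpora where a few sites
   are observed hundreds of times.
2. **Interface residence.** `IS = PS * (1 + w_if)` if the residue sits at
   an inter-chain protein interface, else `IS = PS`. Default `w_if = 1`:
   interface residence doubles the weight, since PTMs at interfaces can
   rewire protein–protein interactions.
3. **Solvent accessibility.** The relative solvent-accessible surface
   area (SASA) of the residue on a family-representative structure,
   computed on the *isolated* chain so that binding partners present in
   the crystal cannot mask genuinely accessible surface. Enzymatic
   writers need access to the residue in the folded state.
4. **Conservation.** `CS`, the column conservation of the alignment
   position, and `PRC`, the fraction of members carrying a residue
   *chemically modifiable* by the hotspot's PTM types (S/T/Y for
   phosphorylation, K for ubiquitination or acetylation, K/R for
   methylation, C for palmitoylation, S-nitrosylation and prenylation,
   G for myristoylation).

For exposed residues (relative SASA at or above the burial threshold, or
disordered unresolved residues):

```
FP = IS x relative_sasa x (cs_scale x CS) x (prc_scale x PRC)
```

For buried residues the accessibility factor is replaced by a fixed
`buried_penalty`, giving the buried branch `FP_b`. With the default
`buried_penalty = burial_threshold` the two branches join continuously at
the threshold. `prc_scale = 100` expresses PRC as a percent; absolute FP
magnitudes therefore carry no meaning across weight settings — only the
induced ranking does, and the ranking is invariant to rescaling the
weights by a common positive constant (a property the test suite checks).

The published description of this scoring scheme constrains it only
qualitatively (the four monotone criteria, the separate exposed/buried
branches, PRC as a percent); the explicit functional form above is this
package's definition, with every constant exposed in `fp_weights()`.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `w_if` | 1 | — | interface doubles IS; 0 disables the boost |
| `burial_threshold` | 0.05 | relative SASA | conventional buried/exposed split |
| `buried_penalty` | 0.05 | relative SASA | continuity at the threshold |
| `prc_scale` | 100 | — | PRC as percent |
| `cs_scale` | 1 | — | CS weighting hook |
| `probe_radius` | 1.4 | Å | water probe |
| `n_points` | 960 | — | SASA lattice density (see below) |
| `contact_cutoff` | 5.0 | Å | heavy-atom inter-chain contact |

## Numerical and design choices

**SASA.** Shrake–Rupley sphere sampling with a deterministic
golden-section spiral lattice: no random numbers, so identical inputs give
byte-identical outputs. At the default 960 points per atom an isolated
atom's SASA matches the closed form `4*pi*(r + probe)^2` to well under 1%,
and random 20-atom clusters agree with a 10,000-point reference lattice
within 2% (both asserted in the tests). Neighbour search uses a uniform
spatial grid whose contract — identical results to the all-pairs scan —
is tested rather than assumed.

**Conservation.** The published account calls CS a "weighted" conservation
score without defining the weighting, so the default here is the modal
non-gap residue frequency, with two explicit knobs: `count_gaps` (whether
gapped rows stay in the denominator; default they do not, and an all-gap
column scores 0) and a pluggable `scorer` function for similarity-class
weighting. PRC for an `other:<label>` type, which has no entry in the
modifiable-residue table, falls back to the residues actually observed
modified at that column.

**Validation against the alignment.** A PTM record whose residue letter
disagrees with the member sequence at that position is excluded rather
than trusting either source — this catches isoform numbering and
off-by-one errors. Deduplication is by `(protein, residue, mod_type)`
with OR-merge of the known-function flag; the merge rule is this
package's choice since cross-database conflict resolution is not
specified by the sources.

**Disordered unresolved residues.** Residues absent from the structure
but annotated as intrinsically disordered (input TSV of ranges, or the
`assume_terminal_disorder` heuristic for unresolved terminal runs of at
most 30 residues) are assigned the theoretical maximum SASA of their
residue type — a disordered tail is fully solvent-exposed in vivo even
though the crystal cannot see it. Unresolved residues *without* a
disorder annotation are excluded from scoring with a warning. The
maximum-SASA table is the standard theoretical per-residue maxima
(e.g. ALA 129, GLY 104, SER 155 Å²).

**Interfaces.** A residue is an interface residue iff any heavy atom lies
within 5.0 Å of a heavy atom in a *different* chain. Same-chain contacts
never count, which excludes crystallographic same-chain artefacts by
construction; chimeric-structure filtering is the user's responsibility
when choosing projection targets.

**Ranking.** Descending FP with deterministic tie-breaks (total PTMs
descending, then column ascending). The median used for
`fold_over_median` follows an explicit `group_by` argument — per family
or pooled — because both groupings are scientifically meaningful and
silently mixing them would be misleading.

**Separation statistics.** Known-vs-unknown comparisons default to raw
factor values normalised to the unknown-class mean (an ordinal-rank mode
is available behind `use_ranks` for sensitivity analysis, since averages
of raw scores and of ranks answer slightly different questions). The
Mann–Whitney test enumerates the exact permutation null for samples of up
to 8 per class — ties handled exactly — and otherwise uses the
tie-corrected normal approximation with continuity correction; the two
agree within 0.02 in p for balanced tie-free samples of 8, and the
large-sample branch reproduces `stats::wilcox.test`. Tests are two-sided
throughout and reported per factor without multiple-testing correction.

## What the synthetic fixtures emulate — and what they do not

`fixture_spec()` and its generators produce a complete toy study: a
family of 30 members descending from a random ancestor by i.i.d.
substitution with occasional short deletions; 10 "known-function" and 40
"unknown" hotspot columns, the known class held more conserved (retention
0.95 vs 0.6) and more intensely modified (planted counts `1 +
Poisson(mean - 1)` with means 5 vs 1.5); hotspot columns seeded with
residues modifiable by their assigned PTM type; an idealised α-helix
structure for the first member (backbone plus Cβ, 100° twist / 1.5 Å
rise, CA–CA ≈ 3.8 Å) with a 12-residue disordered N-terminal tail omitted
from the coordinates and listed in a disorder annotation — emulating the
phosphorylation-rich flexible tails seen in real signalling families.
Fixture sizes were chosen as the smallest family in which class
separation, per-family medians and threshold curves are all
well-populated.

The planted signal makes FP-based recovery a *parameter-recovery*
experiment rather than a tautology: a null mode generates both classes
from identical distributions, and the validation suite checks that no
separation is then detected (p > 0.05 in at least 15 of 20 null
fixtures), alongside the positive checks (at least 90% of known hotspots
above the family-median FP; the combined FP fold-difference exceeding the
intensity-only fold-difference in at least 18 of 20 fixtures). The
validation harness (`validate_planted_signal()`) runs 20 signal and 20
null fixtures at these sizes.

Real data differ in ways the generator does not model: substitution is
not i.i.d. (phylogenetic structure, rate variation), alignments contain
errors precisely in the disordered regions where many PTMs live, real
structures have side chains and crystal-packing artefacts, PTM detection
is biased toward well-studied proteins, and "unknown function" labels are
censored rather than negative. Passing the synthetic checks therefore
demonstrates correctness of the machinery and recoverability of a planted
signal — not performance on any real corpus.

## Degenerate inputs

Empty PTM tables read as empty record sets (not errors); all-gap columns
score CS = 0; single-chain structures have no interface; a single scored
hotspot is rank 1 with fold 1; thresholds beyond the maximum FP report
undefined (NA) known fractions; a zero family-median FP leaves
`fold_over_median` undefined rather than infinite.

## Known limitations

Hotspots are single columns, so closely spaced functional clusters appear
as separate peaks; conservation is family-global (no branch-restricted
scoring); one projection target per run (no averaging over multiple
structures); mmCIF input is not parsed (convert upstream); and the
disorder fallback heuristic is deliberately crude — supply a real
disorder annotation when one is available.
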