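---
title: "Designing and validating species-diagnostic multiplex PCR panels in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating species-diagnostic multiplex PCR panels in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multipcr)
```

## The problem

Field surveys of wildlife parasites rely on faecal samples whose host
species is usually inferred from pellet morphology, and morphology is
unreliable: diet, season, age and health all change pellet shape. A
molecular alternative is a multiplex end-point PCR on a mitochondrial
marker — here cytochrome *b* (*cytb*), which is abundant in faecal
extracts and divergent between, but not within, the mammal species of
interest. Each species in a panel gets a primer pair whose product has a
distinctive length, so a single reaction resolved on an agarose gel
identifies the host by band size. A common trick is a *shared reverse
primer*: one reverse oligo serves several species-specific forward
primers, and the species differ in where their forward primer sits, hence
in product size.

`multipcr` implements the full computational side of this workflow:

1. a degenerate, mismatch-tolerant **virtual PCR engine** for linear and
   circular templates (`find_binding_sites()`, `predict_amplicons()`,
   `run_multiplex()`);
2. **design machinery** that profiles a species-labelled alignment,
   finds variable cores flanked by conserved blocks, enumerates primer
   candidates and selects a size-spaced, Tm-compatible, dimer-clean panel
   (`column_profiles()`, `find_diagnostic_windows()`,
   `enumerate_candidates()`, `select_panel()`, `design_panel()`);
3. a **virtual gel and classifier** turning band sizes into species
   calls and survey-level morphology-versus-molecular summaries
   (`gel_model()`, `bands_to_call()`, `summarize_survey()`);
4. a seeded **synthetic-data generator** so the whole loop is testable
   offline (`simulate_species_genomes()`, `simulate_survey()`).

The two published panels this package models ship as data:
`mmars_panel()` (eastern grey kangaroo 250 bp, swamp wallaby 425 bp,
common wombat 289 bp, with marR shared by kangaroo and wallaby) and
`mdeer_panel()` (fallow deer 197 bp, red deer 482 bp, sambar deer
161 bp, with CERUR shared by red and sambar deer).

## The virtual PCR model

A primer binds wherever its IUPAC pattern matches the template within a
`match_policy()`. Matching is set-intersection on the degenerate codes:
`Y` matches `C` or `T`; an `N` on either side matches anything. This is
deliberate on the template side too — an ambiguous base in a draft genome
never causes a false negative, at the cost of being permissive where the
sequence is uncertain. The default policy allows **2 mismatches overall
and 0 in the 3'-terminal 5 nt**. The 3' clamp is the mechanistically
important part: a polymerase extends from the 3' end, so mismatches there
suppress amplification far more than internal ones. This all-or-nothing
policy reproduces clean species-specific amplification on diverged
off-target genomes without modelling extension thermodynamics, which is
out of scope.

Coordinates are 0-based, half-open, always on the forward strand of the
stored template. Product length is **primer-inclusive** — from the 5' end
of the forward site to the 3' end of the reverse site — which is the
convention behind gel-readable product sizes. A constructed template
`F + spacer + revcomp(R)` therefore yields `|F| + |spacer| + |R|`
exactly, a property the test suite asserts for arbitrary spacers.

Mitochondrial genomes are circular. The engine scans the template plus a
copy of its first `max_product_len + primer length` bases and drops
duplicate sites, so origin-spanning binding sites and products are found
exactly once; results are invariant under rotation of the sequence
origin, and wrapped products carry `wraps_origin = TRUE` with
`rev_end` beyond the template length.

`run_multiplex()` pairs **every** forward primer with **every** reverse
primer, not only the intended pairs, deduplicating products by
coordinates. This is what makes shared-reverse designs work and what
exposes unintended cross-pair products; no "dominant band" heuristic is
applied — all products are reported and the classification layer decides
interpretability.

The engine is verified against an independently written brute-force
scanner (explicit per-position set-intersection loops) on a thousand
random template/primer/policy instances, linear and circular, in the
acceptance suite.

## Design machinery

**Column profiles.** For every alignment column and species we record the
within-species conservation (fraction of rows carrying the majority
code) and a species consensus code: the majority code where conservation
is at least 0.95, otherwise the degenerate union of observed codes. The
0.95 default reflects how sparingly degenerate bases should enter
primers — every shipped panel primer has degeneracy at most 4. A column
*discriminates* species *s* when the consensus base set of *s* is
disjoint from every other species' set.

**Diagnostic windows.** Maximal runs of cross-species conserved columns
at least `min_flank_len` (default 20 nt) long are flank candidates;
every ordered pair of runs whose span fits in `max_product_len` brackets
a core, and the window is reported for each species with at least one
discriminating core column. Pairing all runs, not only adjacent ones,
keeps the window set monotone in the flank threshold: weakening it can
only add windows.

**Candidates.** Within a window, every admissible subsequence of the
species consensus (18–25 nt by default; forward over left flank plus
core, reverse-complemented over core plus right flank) becomes a
candidate if it satisfies the per-primer constraints: degeneracy at most
`max_degeneracy` (default 8), GC midpoint in 0.30–0.70, Tm inside
`tm_range`, and a concrete 3' base (`three_prime_clamp`). Candidates
lying entirely in conserved columns are labelled `"shared"` and usable
by any species; species-specific candidates must be unable to *prime*
any other species under the binding policy — either more total
mismatches against that species' consensus than the policy tolerates, or
at least one mismatch inside the 3'-terminal window, where a mismatch
blocks extension. Requiring a mere one-mismatch margin would not be
enough: the default policy tolerates two mismatches, so such a candidate
would still amplify the wrong species. A shared forward primer may be
combined with a species-specific reverse (or vice versa), but a fully
shared pair is excluded outright — it would band in every species'
lane and can never be diagnostic.

**Melting temperature.** Two estimators: the Wallace rule
2(A+T) + 4(G+C) — crude but adequate for ranking and fast enough for
exhaustive enumeration — and the unified nearest-neighbor model
(enthalpy/entropy per stacked dinucleotide, duplex initiation with
terminal penalties, and a 0.368·(N−1)·ln[Na⁺] entropy salt correction)
at 50 mM monovalent cation and 0.25 µM primer, the documented default
conditions. Degenerate primers get an **interval** over their concrete
expansions rather than a point value; compatibility between primers is
tested as interval distance at most `max_tm_spread` (default 5 °C).
This interval view is also why merging two panels can be impossible even
when each panel is internally consistent: the union of six intervals can
exceed any workable annealing window even though no single pair does.

**Cross-dimers.** `cross_dimer_score()` returns the longest run of
consecutive complementary bases, over all antiparallel offsets, that
terminates at either primer's 3' end — the geometry a polymerase can
extend into an artefact. Degenerate positions count as complementary if
any expansion pairs (worst case). The default ceiling is 8 nt, a common
screening heuristic: short 3' overlaps are ubiquitous and harmless,
extended 3'-anchored duplexes are not.

**Selection.** `select_panel()` picks one pair per species maximising
the minimum pairwise product-size gap subject to: sizes at most
`max_product_len` (500 bp — short products amplify reliably from
degraded faecal DNA), gap at least `min_size_gap`, pairwise Tm
compatibility and dimer cleanliness. The search is depth-first
branch-and-bound; since adding members can only shrink the partial
minimum gap, pruning on it is exact, and on small candidate sets the
search degenerates to exhaustive enumeration (the test suite checks the
reported gap against brute force). Ties break deterministically: fewer
distinct oligos (shared primers preferred), then smaller total amplicon
length, then lexicographic primer names. `min_size_gap` defaults to
30 bp with a warning below 40: the stated aim of this kind of design is
40–50 bp spacing, but the published panels themselves realise minimum
gaps of 39 and 36 bp, so a hard 40 would reject working designs.

Because a one-mismatch specificity margin on paper can still be within
the two-mismatch binding policy in practice, every complete assignment
that would become the incumbent is additionally **verified by in-silico
multiplex** against per-species consensus templates under the
classification layer's own (longer-range) policy: each species must
yield exactly its intended band across all forward × reverse
combinations. This catches shared-primer combinations that amplify more
than one locus and cross-pair products longer than the design's size
budget. Binding sites are cached per primer and template, so the check
is cheap arithmetic at the search leaves.

To keep enumeration tractable on genome-scale alignments,
`design_panel()` restricts itself to the `max_windows_per_species = 2`
windows with the most discriminating columns, and `select_panel()`
considers a deterministic, size-diverse subset of at most
`max_pairs_per_species = 40` pairs per species (one per distinct size,
preferring pairs whose Tm midpoints sit near the centre of the
admissible range). Both caps are exposed as arguments.

**Validation.** `validate_panel()` is the specificity contract: each
target genome must give exactly one product, of the expected size, from
the intended pair; off-targets must give nothing. An empty off-target
set reports "not assessed" rather than silently passing — absence of
evidence is flagged as such.

## The virtual gel and classification

`gel_model()` maps fragment size to a ± tolerance; the default
max(5 bp, 5 % of size) represents what is resolvable on a 1.5 % agarose
gel against a 100-bp ladder. Band resolution is never quantified in the
wet-lab protocol this models, so the default was chosen to keep the
closest published bands (161 vs 197 bp, 36 bp apart) distinguishable
while refusing sub-5-bp distinctions anywhere; it is configurable per
analysis. The boundary case — a difference exactly equal to the
tolerance — counts as *not* distinguishable, the conservative reading.

`bands_to_call()` assigns each observed band to the unique expected size
within tolerance: one assigned band is a species call, none is
`no_amplification`, several species or an unassignable band yield
`ambiguous`/`uninterpretable` with diagnostics. A panel whose expected
sizes are not pairwise distinguishable is rejected when first used — a
configuration error, not a per-sample outcome. Samples are expected to
run against the panel matching their morphological class; if both panels
were run and both amplified, `reconcile_panels()` flags the sample
uninterpretable rather than guessing.

`summarize_survey()` builds the morphology × molecular-outcome confusion
table with marginals and a mismatch count. Labels beginning with
"unknown" never count as mismatches: an unknown-morphology sample is
*resolved* by the molecular call, not contradicted by it.

## The synthetic generator, and what passing tests mean

`simulate_species_genomes()` emulates the premise the design rests on:
an ancestor genome mutated independently per species, with implanted
cassettes — conserved flanks kept identical across species around cores
forced to differ per species. Individuals are drawn per species at
`within_species_identity` (default 0.999, i.e. per-site variation around
0.1 %). Choices worth knowing:

* Each species branch is mutated at **half** the requested
  between-species divergence, so the *pairwise* difference between
  species comes out at approximately the requested value (the quantity a
  user would measure); a generator test checks the realised divergence
  within ±20 % relative.
* Cassette columns are excluded from within-species mutation. That is
  the biological premise — diagnostic regions vary among but not within
  species — and it is what makes molecular calling error-free on clean
  synthetic data, so that the survey loop can demand *exact* recovery of
  injected morphology errors rather than approximate recovery.
* Substitution-only by default (no indels): *cytb* is length-conserved
  within each clade modelled here (1146 bp in the marsupials, 1140 bp in
  the deer), so equal-length genomes that align column-for-column are a
  faithful simplification, and `sim_alignment()` exploits it.
* All randomness flows from one mandatory seed through a scoped RNG
  (`with_seed()`), leaving the caller's random state untouched; the same
  seed gives byte-identical output.

What the generator does **not** emulate: indel-driven length variants
(an optional mechanism deliberately left out of the default), PCR
stochasticity and drop-out, mixed-template (contaminated) samples,
heteroplasmy, and sequencing error. A pipeline that passes on this
generator is therefore shown to be *algorithmically* correct — windows
found, panels feasible, bands interpreted, books balanced — not robust
to every artefact of real faecal extracts.

## Synthetic reference stand-ins

The package is built to run entirely offline, so the six reference
mitochondrial genomes are represented by `synthetic_reference_genomes()`:
circular ~16.8 kb stand-ins, one per species, carrying the published
primer binding sites at exactly the published spacings (multiplex
products 250/425/289 and 197/482/161 bp; sequencing products 692/662 and
877/784 bp; a cytb CDS of 1146/1140 bp annotated in writable GenBank
records), on species-specific random backgrounds. The red deer locus is
placed across the sequence origin so the origin-wrapping code path is
exercised by a "real" target, not only by rotation tests. Construction
verifies that no spurious binding site exists anywhere under the default
policy and that each panel is silent on the other clade and on the
goat/rabbit stand-ins.

These are stand-ins, clearly labelled as such (`syn_*` identifiers).
Results on them validate the *engine and workflow* — degenerate
matching, strand handling, shared primers, the primer-inclusive length
convention, circular wrap-around, multiplex cross-pairing, specificity
logic, GenBank round-tripping — not sequence identity to the real
GenBank accessions, which would require network access to test.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 16 kb genomes with 3
species and 2 diagnostic cassettes, 500-sample surveys at a 5 %
morphology error rate and 10 % unknown-label rate, and 1000 random
instances for the oracle-equivalence check — sizes chosen to exercise
every code path at genome-realistic scale while keeping a full run in
the low minutes on one core. Determinism is enforced everywhere results
could depend on iteration order: candidate names encode their
coordinates, selection ties break lexicographically, survey summaries
sort rows and columns, and identical CLI invocations hash identically.
The degeneracy expansion cap (64) bounds worst-case cost and is far
above the shipped panels' maximum of 4.

## Known limitations

* Specificity is purely sequence-based; there is no thermodynamic
  extension-efficiency or secondary-structure (hairpin) model, and no
  qPCR quantification.
* Analytical sensitivity (template picograms) is a wet-lab property and
  is intentionally not computed anywhere in the package.
* The classifier models band positions, not intensities; faint or
  smeared bands have no representation.
* `enumerate_candidates()` introduces degeneracy only as observed
  within-species variation demands; it does not design degenerate
  primers against *unsampled* variation.
* Alignments are consumed, never computed — inputs are expected to come
  from an external aligner.
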