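---
title: "Modeling breakage-fusion-bridge repair of a conditional dicentric yeast chromosome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling breakage-fusion-bridge repair of a conditional dicentric yeast chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfbsim)
```

## The system being modeled

A chromosome with two active centromeres (a dicentric) is torn apart when
the two centromeres on one chromatid attach to opposite spindle poles: the
anaphase bridge is severed at cytokinesis, and the broken chromosome enters
the breakage-fusion-bridge (BFB) cycle until repair produces a stable
monocentric derivative. `bfbsim` models the classic budding-yeast
implementation of this system: a conditional centromere (`GALCEN3`, a copy
of *CEN3* placed under the *GAL1* promoter, active on glucose and silenced
on galactose) integrated on chromosome III at one of six positions upstream
of the endogenous centromere `eCEN3` (coordinate 114,300), giving
centromere separations of 6.5, 9.8, 12.3, 18.2, 46.3 and 57.7 kb
(insertions at 107,830 / 104,458 / 101,976 / 96,020 / 68,000 / 56,740).

Because `GALCEN3` is a copy of *CEN3*, the two centromere regions share
336 bp of identical sequence containing the 125 bp functional core. That
shared block is the substrate for the homology-based repair routes, and its
loss or retention — together with four diagnostic PCR assays — is what lets
a colony's repair history be read off its DNA.

The package has three layers:

1. **`genome_model` / `synthetic_data`** — build an annotated synthetic
   reference chromosome for any of the six configurations, plus fixtures
   (cohort PCR tables, junction sequence pairs) with planted ground truth.
2. **`bfb_simulator`** — simulate division cycles of a founder lineage:
   breakage, pathway choice, product structures, colony fate.
3. **`insilico_assay` / `junction_analysis` / `reporting_stats`** — genotype
   karyotypes by in-silico PCR, classify colonies with the presence/absence
   decision key, decompose sequenced deletion junctions, and aggregate
   viability statistics.

## The synthetic reference

No sequence accession is required: the background is random DNA with
configurable GC content (default 0.38, yeast-like), and every feature the
analysis depends on is placed at its true printed coordinate. The reference
is deterministic given `(config, seed)`.

The `GALCEN3` cassette is laid out so that the printed assay geometry holds
exactly:

* `GC1` priming site — `GAL1` promoter — 336 bp homology block (copied
  verbatim from the `eCEN3` region, core as its final 125 bp) — 50 bp
  spacer — `GC2` priming site, with the `GC1`–`GC2` amplicon exactly 932 bp;
* the bases flanking both homology-block copies are forced to mismatch, so
  the longest shared substring between cassette and `eCEN3` region is
  *exactly* 336 bp;
* `eC1`/`eC2` bracket `eCEN3` with a 900 bp amplicon (this size is not a
  fixed property of the assay; it is a configurable default);
* the essential genes *RRP7* and *NFS1* and the fitness gene *PGS1* sit at
  the midpoints of the intervals that bracket them between insertion sites
  (their exact coordinates do not matter to the audit, only interval
  membership); the Ty2-1 element spans 84,811–90,769 (5,959 bp ≈ 6 kb).

```{r reference}
ref <- build_reference(genome_config(insertion_pos = 107830, seed = 7))
ref
longest_shared_substring(cassette_sequence(ref), ecen_region_sequence(ref))
```

Coordinates are 1-based inclusive throughout the API (matching
genome-database convention); BED export converts to 0-based half-open.
A minimum separation of 1 kb between insertion and `eCEN3` is enforced —
closer insertions would collide with the `eCEN3` diagnostic amplicon — and
insertion at the centromere itself is a configuration error.

## The division/repair model

Each division, every dicentric chromosome breaks with probability
`p_break = 0.5` (the two orientations of non-sister kinetochores are
equally likely). The break position is drawn from a mixture: with weight
0.5, uniform over the union of the 10 kb windows flanking each centromere
(clipped to the span — for the 6.5 kb strain the windows cover everything
and the mixture degenerates to uniform); otherwise uniform over the whole
inter-centromeric interval. This reproduces the observation that about half
of dicentric breaks fall within 10 kb of a centromere.

A break resolves through one of four routes:

* **SSA** — the two 336 bp homology blocks anneal; the product is a linear
  monocentric chromosome missing exactly the DNA between the blocks
  (telomeric ends intact). At 6.5 kb this removes *PGS1*, which the
  viability audit flags as `slow_growth`; at 46.3/57.7 kb it removes
  *NFS1* (and *RRP7* at 57.7), so the linear product alone is lethal.
* **RCO** — reciprocal crossover at the homology blocks, modeled as one
  composite event: the same linear deletion chromosome *plus* a circular
  monocentric derivative carrying the full inter-centromeric segment (the
  separate circularization exchange is not modeled stochastically; only
  the product structures are observable downstream). The circle rescues
  the essential genes at the arm distances. Whether such products arise
  from a single crossover or two independent SSA events is not
  distinguishable from the products, and the simulator does not claim a
  mechanism.
* **EJ** — end-joining after two cuts flanking one centromere (the
  two-cut abscission model): a deletion of 278–585 bp removes the entire
  125 bp core, joined with 1–9 bp of microhomology. `GALCEN3` is the
  deleted centromere with probability 0.7. The deletion is placed
  uniformly among positions that cover the whole core *and* keep both
  priming sites of the diagnostic amplicon intact — the sequenced deletion
  products are, by construction of the assay, amplifiable, so products
  that would destroy a priming site are not part of the modeled
  observable class. The drawn microhomology length is recorded on the
  event as a model parameter (it is not edited into the fixed reference
  sequence; sequence-level microhomology with exact recovery is the job
  of the junction fixture generator below).
* **refusion** — the ends rejoin and the dicentric persists; the BFB
  cycle continues. No quantitative refusion rate is published; its weight
  is a free calibration parameter.

Pathway choice is drawn proportionally to per-distance propensity weights
times genotype modifiers. The propensity table is **calibration, not
prediction**: the defaults are chosen to reproduce the observed regime at
each separation (SSA-dominant at 6.5 kb, >90% end-joining at 9.8–18.2 kb,
crossover-dominant at 46.3 kb, mixed with frequent refusion at 57.7 kb).
The mechanistic basis of the distance dependence (resection kinetics,
replication-fork effects) is out of scope. Genotypes: `rad52` zeroes
SSA and RCO; `lif1` zeroes EJ; `mrc1` is a phenomenological stand-in that
multiplies the homology pathways by 0.1 only beyond 20 kb separation (its
mechanism is explicitly not inferred).

A colony is a **founder lineage**: one surviving line of descent determines
the colony's final karyotype, matching the single-colony PCR readout.
The lineage iterates divisions until no dicentric remains, death, or
`max_cycles = 20` divisions. Death occurs through essential-gene loss,
through an unrepairable break (all propensities zero), or by exhaustion —
still dicentric at `max_cycles` after at least one breakage/refusion round.
A lineage whose dicentric simply never broke survives and types as
`unrearranged`; this keeps the degenerate `p_break = 0` limit sensible
(every colony viable and unrearranged). Nondisjunction (probability 0.01
per division) duplicates a chromosome in the followed daughter, which is
how multi-chromosome `aneuploid` patterns arise.

Per-colony RNG substreams are derived from `(seed, colony index)`, so
cohorts are reproducible and order-independent.

## In-silico PCR and the decision key

`insilico_pcr()` does exact-match primer search (both orientations) and
reports every convergent pair within `max_amplicon = 6000` bp; circular
templates are scanned across the origin. Exact matching is appropriate
because the synthetic references embed exact sites; mismatch tolerance and
thermodynamics are out of scope. The matcher is verified in the test suite
against an independent exhaustive substring-scan oracle.

`genotype_colony()` runs the four assays on every chromosome of the
karyotype and pools results. A parental product within 50 bp of its
expected size scores `wildtype_size`; shorter products score
`reduced_size` (the sequenced deletion products are 932 minus 278–585 =
347–654 bp); hybrids score `present`/`absent`. `classify_pattern()` then
applies a fixed-precedence decision list (HR, aneuploid, SSA, SSA+EJ,
unrearranged, EJ, unclassified). The published key does not state an
order; the order here is chosen so that every key-listed pattern maps to
its stated class and overlapping patterns go to the more information-rich
class (e.g. rearrangement + parental is `aneuploid` even if the reciprocal
product is also present). Patterns the key does not define —
e.g. reciprocal + `GALCEN3` — are emitted as `unclassified` rather than
forced.

The test suite closes the loop end-to-end: each simulated pathway's
product karyotype classifies back to its matching class (SSA→SSA, RCO→HR,
EJ→EJ, terminal refusion→unrearranged, nondisjunction plus mixed
repair→aneuploid).

`circle_contiguity()` emulates the overlapping-amplicon walk used to
establish that a candidate circular derivative is contiguous DNA: tiling
primer pairs taken from the realized circle are amplified in silico and
the union of products is checked to cover the full circumference.

## Junction analysis

`find_deletion()` compares a derivative allele to its reference by longest
common prefix and suffix. When prefix + suffix reconstruct the derivative,
the junction is a pure deletion reported at its **leftmost** equivalent
placement (the VCF left-alignment convention; published junction
alignments carry no placement convention). Otherwise the unexplained
middle of the derivative is reported verbatim as inserted bases; junction
mismatches are handled only as insertions of the mismatched run — full
gap/mismatch realignment is out of scope and large insertions are refused
with an explicit error.

`microhomology()` decomposes the flanks: `mh_right` is the longest common
prefix of the deleted sequence and what follows it, `mh_left` the mirror
on the left, and a junction with `mh_total` bases of homology has
`mh_total + 1` equivalent placements. This identity is verified
property-style against brute-force enumeration of all equal-size deletions
on short random alleles. The core-removal audit accounts for placement
ambiguity: a junction passes if *any* equivalent placement covers the
core.

`label_mechanism()` calls `MMEJ` at ≥ 5 bp of homology, `NHEJ` at ≤ 1 bp
with no insertion, `ambiguous` between — a convention choice (the observed
1–9 bp range does not dichotomize naturally), exposed as a parameter.

The fixture generator `random_junction()` plants a junction with *exactly*
the drawn microhomology by copying the mh bases across the junction before
deleting and then pinning the single bases that could extend the homology
on either side (these pins live inside the deleted interval, so the
derivative is unaffected). Because the reference allele is locally
modified, the generator returns it alongside the derivative; round-trip
recovery of size, microhomology and insertion is then exact, and the test
suite asserts it on 1,000 generated junctions. Deletion sizes default to
278–585 bp (the observed envelope of this dataset; 230 bp is a known
lower bound in pooled earlier data and can be configured), microhomology
to 1–9 bp with an optional zero-inflation mass for junctions with no
identifiable homology.

## Viability statistics

Viability is colonies on glucose divided by colonies on galactose, in
percent, uncapped (plating noise can push it above 100). Group comparisons
use Student's pooled-variance t test by default — matching the published
analysis — with Welch available; no multiple-testing correction is applied
(none was applied in the source analysis), and the replicate rows of the
plating table are the unit of analysis. Degenerate zero-variance inputs
with equal means return p = 1 by convention. The reporting module is
purely deterministic; re-rendering identical inputs is byte-identical.

## What the synthetic data can and cannot show

The generator reproduces the *geometry* of the system (coordinates,
amplicon sizes, homology structure, deletion envelopes) and the *logic* of
the assays exactly; passing tests demonstrate that the decision key,
junction arithmetic and simulator bookkeeping are internally consistent
and match the printed quantities they encode. They do not validate the
biology: backgrounds are i.i.d. random rather than real chromosome III
sequence (no repeats, no base composition structure beyond GC), PCR is
idealized (no mismatch priming, no size-estimation error), colonies are
founder lineages rather than populations, and the pathway propensities are
calibrated to the observed distributions rather than derived from
mechanism. Consequently the mutant viability percentages and the
non-fixture class distributions are treated as experimental outcomes:
tests assert only their direction (end-joining dominance at intermediate
distances, the homology shift when ligase IV scaffold Lif1 is removed,
declining homology-deficient viability with distance), never their printed
values. The one distribution asserted exactly — 40% EJ / 33% HR /
20% SSA+EJ / 7% unrearranged at 57.7 kb — is carried as a packaged
30-colony fixture (12/10/6/2) and recovered by classification, a
round-trip check of the key, not a simulation result.

## Problem sizes and numerical choices

Default problem sizes keep the full suite fast while leaving binomial
noise well inside the asserted tolerances: 10,000 divisions for the
breakage fraction (SE ≈ 0.5 points), ≥ 2,000 end-joining events for the
70:30 centromere bias (SE ≈ 1 point), 1,000 junctions for exact
round-trip recovery, brute-force placement enumeration up to 60 bp
alleles. kb labels round half-up to one decimal (two printed labels,
18.2 and 57.7, deviate from their computed values 18.3 and 57.6 by 0.1;
computed values are reported). Ties and degenerate ranges in all integer
draws are handled by a dedicated sampler to avoid R's scalar `sample()`
pitfall.

## Known limitations

Telomere addition, break-induced replication, Ty-mediated interchromosomal
repair, population-level colony heterogeneity, galactose/glucose promoter
kinetics, primer thermodynamics and Sanger trace artifacts are all out of
scope. The `mrc1` modifier set is a placeholder shaped like the observed
distance dependence, not an inference about mechanism. The refusion weight
is unconstrained by published data.
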