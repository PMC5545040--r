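---
title: "Evaluating long-range scaffolding technologies with scaffeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating long-range scaffolding technologies with scaffeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffeval)
```

## The problem

Long-read assemblies of plant genomes typically arrive as a thousand or so
gap-free contigs. Long-range scaffolding technologies — optical
(restriction-site) maps and proximity-ligation (Chicago/Hi-C style)
libraries — order and orient those contigs into scaffolds, but they differ
in ways that matter for downstream analysis: the minimum scaffold they can
incorporate, the maximum distance they can bridge, whether they estimate gap
sizes or emit a fixed 100-N placeholder, and whether they split suspected
chimeric sequences automatically or merely report them.

`scaffeval` evaluates and compares scaffolding rounds along the axes a
genome project actually inspects:

* **continuity statistics** — scaffold/contig counts, lengths, N50/N90/N10,
  and the *adjusted* N50 computed against a fixed genome size so that
  assemblies of different total length are comparable;
* **captured-gap accounting** — counts, extremes, gap N50 and total gap
  length per gap dialect, plus before/after deltas for gap filling;
* **join/break lineage** — which input scaffolds each technology joined or
  broke, recovered from sequence alone;
* **synteny validation** — whether joined pieces map to a single chromosome
  of a related reference genome, with rates stratified by cross-technology
  support;
* **rearrangement breakpoints** — reference intervals where synteny switches
  chromosome, strand or position;
* **novel sequence** — assembly sequence absent from the reference after
  low-complexity and tandem filtering, and the genes it contains;
* **flank repeat enrichment** — a permutation test for repeat content around
  the gaps each technology introduced.

Because real scaffolding runs are expensive and proprietary-scale, the
package ships a simulator that generates every input with known ground
truth, so every claim the evaluation code makes can be checked against what
was planted.

## Key statistics

For lengths $\ell_1 \ge \ell_2 \ge \dots$ and a denominator $G$, the Nx
statistic is the smallest $\ell_i$ with
$\sum_{j \le i} \ell_j \ge \frac{x}{100}\,G$. With $G$ equal to the assembly
total this is the classical N50/N90/N10; with a fixed $G$ (default
400 Mb) it is the adjusted variant, which is 0 when the assembly covers
less than $x\%$ of $G$. `nxx()` implements the whole family and is tested
against a brute-force cumulative-sum oracle.

All percentages in reports are rounded to two decimals with ties away from
zero (`round_half_away()`), the convention that recovers quoted
two-decimal percentages from their exact ratios.

## Join and break lineage without alignment

Scaffolding reorders, joins and breaks scaffolds but never edits the
sequence inside contigs. `place_inputs()` exploits this: unique exact
64-mers sampled along each input contig are matched against the output on
both strands; anchors hitting more than one locus (repeats) are discarded;
anchor clusters sharing a diagonal seed a placement that is then extended
base by base to the maximal exact match, so placement boundaries — and
therefore inferred break positions — are exact up to the immediate
neighbourhood of the breakpoint. A refinement pass re-anchors any contig
region the first pass left uncovered (for example the short half of a
chimera), at one anchor per 64 nt. Contigs whose anchors support
conflicting loci are reported as ambiguous and excluded from join/break
calls rather than guessed at; on repeat-free simulations precision and
recall of both calls are 1.0 by construction and verified by test.

Two readings of "average scaffolds per join" are possible (per join event
or per output scaffold); `join_summary()` reports both.
`compare_join_sets()` defines a shared join as a directly adjacent,
unordered pair of input scaffolds joined by both technologies, and
separately reports the count of input scaffolds scaffolded by both
(co-membership), which is the quantity usually quoted.

## Synteny blocks, validation and breakpoints

Alignments are consumed as PAF-like records; the package never invokes an
aligner, which keeps this module deterministic and testable from records
alone. `chain_blocks()` chains records per (query, target, strand) by
dynamic programming on aligned bases under a `max_join_gap` constraint
(default 100 kb). Two "fixing" rules mirror chain/net practice: a chain may
not bridge a query gap that is mostly (>50%) covered by other alignments of
the same query — this is what keeps an inversion or a translocated segment
as its own block — and final blocks are single-coverage on the query, with
lower-scoring overlaps trimmed (dropped if more than half covered).

`classify_joins()` assigns each join member the chromosome holding more
than half of its synteny-aligned bases (threshold exposed as
`majority_fraction`; the dominant-chromosome rule is the natural reading
when no threshold is stated). When members carry placement intervals, the
blocks are weighted by overlap with the placed interval, so a scaffold of
which only one part entered the join is judged on that part. A member on
the unplaced pseudo-chromosome `U`, or without a majority, makes the
verdict `unknown`; joins whose assigned members disagree are `different` —
note that a genuine translocation produces exactly one correct `different`
call, so rates should be read as evidence, not error counts.
`validation_rates()` excludes `unknown` from denominators and reports
stratum differences as differences of the rounded percentages, the usual way
such increases are quoted.

`find_breakpoints()` walks each query's blocks in query order; any
adjacent pair that changes chromosome or strand, or violates collinearity
(target overlap, wrong direction, or a target gap above 100 kb), is a
transition. For each transition side the breakpoint is the reference
interval between the flanking block and the nearest block beyond it on that
chromosome, under 1-based inclusive arithmetic (a flank pair abutting at
positions $a$ and $b$ yields the interval $[a+1, b-1]$ of length $b-a-1$).
Perfectly abutting flanks produce an empty interval and are skipped; in
practice alignments fray near rearrangement junctions, which is also how
the simulator emits them (100 nt trimmed per segment edge by default).

## Novel sequence

`novel_sequence()` subtracts all aligned intervals from the gap-removed
(contig) space and classifies each unaligned segment. Segments shorter than
100 nt are set aside; tandem periodicity is detected from 5-mer start
spacings (a constant period of 2–100 nt repeated at least five times, with
more than half the segment covered) — period 1 is deliberately excluded so
homopolymers fall through to the complexity filter; low complexity is a
DUST-style triplet score over 64-nt windows (a uniform random window scores
about 0.5, a homopolymer 31, a dinucleotide run about 15; the threshold of
4 with half the windows required flags those while leaving random sequence
untouched — calibrated on constructed strings, not on any external
binary). The partition identity (aligned + novel + removed + gaps = total
bases) is asserted on every simulation. `novel_genes()` applies a strict
">50% of CDS length in novel segments" rule. Contaminant screening is out
of scope; an exclusion BED can be subtracted upstream where needed.

## Flank repeat enrichment

`flank_repeat_enrichment()` pools up to 10 kb of sequence on each side of
every event (truncated at scaffold ends, excluding N), measures the repeat
fraction (union of interval annotation and softmasked runs), and compares
it with the genome background by a one-sided permutation test: the same
number of events with the same widths is re-drawn uniformly over contig
space, and `p = (1 + #(null >= observed)) / (1 + n_perm)`. The test is
one-sided because the scientific claim is directional (technologies bridge
repeats that long reads cannot). Seeded runs are bit-reproducible, and the
pooled statistic is the default (a per-event table is also returned) since
per-event fractions are noisy at 10 kb. Type-I error is verified by test to
sit inside the binomial 95% interval when events are drawn from the null
itself.

## The simulator

`simulate_reference()` builds chromosomes as alternating unique blocks and
repeat insertions — diverged copies (5% substitution) of a 3 kb
interspersed consensus plus 2 kb tandem arrays (50 nt unit × 40 copies,
one fifth of insertions) — hitting a 25% repeat fraction in expectation,
with toy single-exon-style gene models every 20 kb. The repeat fraction and
divergence are typical of a compact plant genome; the genes carry just
enough structure (1–5 CDS) to exercise the 50%-CDS rule.

`simulate_accession()` applies a reciprocal arm translocation between two
chromosomes (arms exchanged at 55% of their length), inserts novel
sequence at both junctions (125 kb and 46 kb — about 0.25% and 0.09% of
the genome, proportions typical of junction-adjacent
insertions in accession comparisons), plants a 150 kb inversion 200 kb
downstream of the acceptor junction, and diverges syntenic sequence at 1%
SNPs and 0.05% small indels. That yields exactly four planted breakpoints
— one on the donor chromosome and three on the acceptor side (junction
plus two inversion edges) — matching the asymmetric breakpoint structure
such translocations show in practice. Truth tables (segment map, novel
segments, breakpoints) are recorded in both coordinate systems.

`fragment_assembly()` cuts each accession chromosome at roughly one break
per 500 kb, with breaks landing inside repeats with five-fold elevated
probability. Each break loses surrounding sequence with probability 0.5,
log-normally distributed (median 50 kb, sdlog 1.3) — a broad distribution
chosen so that some spans exceed a proximity-ligation technology's reach
(100 kb) while an optical map can still bridge most of them, giving both
realistic sized-gap distributions and chains that stop. Pieces below 1 kb
are treated as unassembled. Cut positions are drawn directly (unbiased
cuts are exactly uniform, which the tests verify by KS test); fragment
lengths are therefore approximately exponential around the mean rather
than literally log-normal — the positional repeat bias is the property the
analyses depend on, so it was kept exact. Eight chimeric contigs are
planted by concatenating fragments from different chromosomes, and each
fragment is stored in random orientation.

`simulate_scaffolding()` joins truly-adjacent contigs subject to a
technology profile. The two presets are parameterised from the observed
extremes of the two technology families: `"opticalmap"` (minimum joinable
scaffold 100 kb, maximum span 650 kb, sized gaps with 10% multiplicative
error floored at 500 nt, chimeras only logged) and `"proximity"` (minimum
4.5 kb, maximum span 100 kb, fixed 100-N gaps, chimeras broken). Both are
labels for behaviour, not claims about any vendor's software.

What the simulator does **not** emulate: read-level errors, coverage or
mappability variation, collapsed segmental duplications, polyploidy, and
scaffolding errors other than the configurable false-join rate. Passing
tests therefore demonstrate correctness of the evaluation logic under
realistic genome structure, not robustness to every artefact of real data.

## Numerical and design choices

* Coordinates are 1-based inclusive in every report; breakpoint lengths are
  `end - start + 1`.
* `detect_gaps()` treats sub-200 nt islands between two gaps as gap content
  (one join, one gap — the convention needed when an optical-map pipeline
  leaves restriction-site fragments inside its sized gaps); terminal short
  contigs are never merged because they cannot lie between gaps. Whether
  free-standing scaffolds under 200 nt should also be excluded from
  statistics is genuinely underdetermined; `assembly_stats(keep_short =)`
  exposes the choice and defaults to keeping them.
* The minimum gap size defaults to a single N because both simulated
  dialects emit gaps of at least 100 N; it is configurable for dialects
  with ambiguous single-N calls.
* Placement ties (a contig whose clusters overlap by more than two anchor
  lengths) mark the contig ambiguous rather than picking a side; overlaps
  within two anchor lengths are split at the midpoint.
* The AGP writer preserves merged-island bases in `# island` comments so
  that AGP plus component FASTA reconstructs the scaffold FASTA byte for
  byte.
* Problem sizes: unit tests simulate 3–6 Mb genomes; the lineage
  precision/recall property runs one 50 Mb repeat-free genome; the bundled
  acceptance script runs the full pipeline at 30 Mb over 4 chromosomes.
  These sizes exercise every code path at full realism while a complete
  check remains a coffee-break affair.

## Known limitations

* Placement requires exact contig preservation; a scaffolder that polishes
  sequence during scaffolding would need alignment-based placements (the
  `Placement` table is aligner-agnostic, so such records can be supplied).
* Repeat liftover from reference to accession is linear within segments
  and therefore approximate in the presence of indels (sub-0.1% coordinate
  error at default rates).
* Breakpoint intervals are bounded by the nearest flanking blocks; a
  breakpoint at a chromosome end (no flank beyond it) is not reported.
* `gapfill_delta()` anchors each contig by its 10 kb prefix; two contigs in
  one scaffold sharing an identical 10 kb prefix (not observed in
  simulations) could confuse the lift.
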