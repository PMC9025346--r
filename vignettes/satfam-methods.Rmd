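---
title: "Methods: tandem-repeat family discovery, comparison and probe design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tandem-repeat family discovery, comparison and probe design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satfam)
```

## The problem

Satellite DNA consists of monomers (roughly 6–2000 bp here) repeated
head-to-tail into arrays that can span tens of kilobases. Arrays of the
same underlying monomer — a *family* — concentrate in centromeric,
pericentromeric and subtelomeric heterochromatin, evolve quickly, and are
the natural targets for chromosome-painting FISH probes. `satfam` turns a
set of genome assemblies (plus, optionally, raw reads and a repeat
library) into a named, annotated, cross-assembly-compared family catalog
and a panel of candidate oligo probes.

## Detection by wraparound alignment

The detector scores a candidate array against tandem copies of its own
consensus monomer with TRF-style linear scoring: match `+2`, mismatch
`−5`, indel `−7`; an array is emitted when the best local wraparound
alignment reaches `minscore = 50`, and monomers up to `maxperiod = 2000`
bp are considered. These defaults are the parameterization long used for
satellite discovery in rodent genomes and are exposed via
`detector_params()`.

Candidate monomer lengths come from exact k-mer recurrence: a k-mer
re-occurring at distance *d* votes for period *d* (k = 5 for periods up to
29 bp, k = 7 above — short monomers need shorter seeds to survive
divergence). For each voted lag the per-base self-match profile
`s[i] == s[i+d]` is segmented into runs, runs closer than one period are
merged, and a merged window survives only if its self-match fraction
reaches `max(0.45, (pm/100)^2 − 0.10)` — with the assumed copy-to-copy
match probability `pm = 80`, two independently diverged copies agree at
about `0.8² = 64%` of positions, so the gate sits one margin below that.
Windows are then verified by the wraparound dynamic program
(`src/wrap_align.cpp`): the column index runs over the monomer cyclically,
so one alignment may traverse it any number of times; begin/end and
match/mismatch/indel counts are propagated through the recurrence rather
than recovered by traceback, keeping memory at two rows. Two refinement
passes re-derive the consensus from the trimmed interval.

Verified periods collapse to the smallest divisor whose score stays within
95% of the best, so a 21-mer found at lag 42 is reported near-primitive,
as period 21. The `minscore` filter is applied last, which makes the
emitted set monotone in `minscore` by construction. Detection uses only
self-comparison at positive lags, so it is strand-symmetric and arrays
carry no strand.

`percent_match` / `percent_indel` are derived from the alignment against
the consensus (not from adjacent-copy comparison); for the homogeneity
ranking used downstream only the ordering matters.

## Non-redundancy rules

Raw detections are reduced to the field catalog in two coordinate-wise
steps, applied in an order that makes them disjoint: first, among arrays
with identical coordinates only the smallest monomer survives (ties:
higher score, then lexicographically smaller consensus — an arbitrary but
fixed order); second, any array contained in a strictly larger interval on
the same contig is discarded. Partially overlapping arrays are independent
fields and both survive; total bp in `catalog_stats()` therefore counts
each field once and may double-cover genomic bases. Containment is
contig-local. The operation is idempotent and input-order independent,
and is tested against a brute-force quadratic scan.

## Pair scoring, E-values and single-linkage families

Array pairs are scored by Smith–Waterman local alignment under
blastn-default scoring (reward +2, mismatch −3, gap open 5, extend 2; a
gap of length L costs 5 + 2L), with no low-complexity masking — satellite
arrays *are* low-complexity-adjacent, and masking would delete the signal.
The alignment engine is `Biostrings::pairwiseAlignment`; an independent
textbook dynamic program in the test suite checks score equality. The
Karlin–Altschul λ for this scoring at uniform base composition is solved
numerically (`uniroot`); the prefactor K is fixed at 0.3, an ungapped-
regime approximation — adequate because the E ≤ 1e−15 gate only has to
separate megabase-scale random similarity from true family links, and the
decisive threshold is the score itself. Pairs scoring strictly above 200
(about 100 aligned bases at perfect identity) connect arrays; families
are the connected components (single linkage). Arrays shorter than ~150 bp
cannot reach the threshold against anything, which matches the intent:
fragmentary detections become singletons rather than gluing families
together.

The manual curation step such catalogs usually receive is replaced by
`family_diagnostics()`: families whose members span more than 30
percentage points of pairwise identity are flagged for review, never
silently edited.

## Naming

`<prefix><L><letter>`, with `L` the minimum detector-reported period among
the family's arrays (the detector period, not the consensus length, since
the two may differ by indels). Letters order same-`L` families by first
genomic occurrence — assembly id, contig id, start of the earliest member —
because abundance ordering is unstable across re-runs and no other
convention is canonical; more than 26 families per numeral continue AA,
AB, … The prefix (e.g. `CG`) is empty by default for single-species work.

## Repeat-library annotation

A family is annotated with a library entry when the entry covers at least
80% of some member array. Coverage is measured on 50 bp tiles of the
array: a tile counts as covered when its best local alignment against the
entry (either strand) reaches half the perfect score — breakeven at about
80% identity over the whole tile, or higher identity over a shorter span.
Random 50 bp tiles against few-hundred-bp entries score far below this
(empirically ≤ ~25), so the gate is not reachable by chance. The
ambiguity of whether the 80% applies to the array or to the library entry
is resolved toward the array, which is the quantity that decides whether
the *family* is essentially TE-derived. Library classes follow the
RepeatMasker `name#class/subclass` dialect; SINE/LINE/LTR/DNA/RC classes
mark a family as TE (`is_te`), while satellite or gene-fragment hits
(e.g. a Zn-finger array) are recorded but do not disqualify the family
from probe design.

## Cross-assembly comparison

Families from different assemblies are equivalent when their
representative arrays — the full array sequence of each family's most
homogeneous member, not the monomer, because a 20 bp monomer could never
reach the 200-score criterion — align above the same score threshold,
either strand. Each family keeps one best reciprocal link per other
assembly; equivalence groups are components over the link graph, and each
group's class is its assembly set (all-3, each pair, private). The classes
are disjoint and exhaustive by construction, and `table3_report()` prints
them with the grand "at least two assemblies" total.

## Abundance from reads

A read is counted as belonging to a family when at least half of its
21-mers (either strand) occur in the k-mer set of the family's arrays; the
family's genome share is the percentage of such reads. The contract —
most of the read must be family sequence — mirrors a sensitive-local read
alignment without requiring an aligner; both k and the fraction are
configurable, and externally computed counts can be injected through
`abundance_from_counts()`. Reads shorter than k are excluded from the
denominator with a warning. At 21 bp, one substitution error kills up to
21 k-mers of a 100 bp read, so the 0.5 fraction tolerates roughly two
errors per read; boundary reads (straddling an array edge) are the main
source of the small negative bias visible in the calibration tests.

## Probe design

Families are first screened: no TE similarity, monomer at least 10 bp (and
dinucleotide entropy of the representative at least 1 bit — a pure (AT)n
array reported with a degenerate 12 bp period is still "simple"), and
presence in at least two assemblies. Long low-abundance families remain
visible through the reported maximum array length rather than a hard
length gate, since a fixed cutoff would be arbitrary where the printed
evidence conflicts.

For each selected family the most homogeneous array (highest
`percent_match`, ties to the longer array, then coordinate) provides the
consensus template. All windows of 18–27 nt — wrapping across the monomer
junction, with sub-18 bp monomers tandem-doubled — are filtered on GC
(35–65%), homopolymer runs (≤ 4), ungapped antiparallel
self-complementarity (+1/−1 score ≤ 8), and cross-family uniqueness (no
occurrence within 2 mismatches in another family's doubled representative;
representatives only, not whole genomes — the families are the competing
hybridization targets of interest at desk scale). Among survivors the
window hitting the most family arrays within 2 mismatches wins; ties go to
the earlier monomer position, then the shorter window, so the search is a
pure function of its inputs. Melting-temperature screening is not modeled;
the GC window stands in for it, and `validate_probe()` re-checks any
sequence against every gate independently.

## The synthetic-data generator

`make_assemblies()` draws iid background at a chosen GC, draws each
family's monomer once (shared across assemblies; drawn monomers honor the
requested GC exactly, since short monomers pin the composition of every
probe window), mutates each copy independently (substitutions to a
different base at `sub_rate`; indels at `indel_rate`, half insertions,
half deletions), and implants arrays at uniform non-overlapping positions
by replacing background segments — contig lengths are therefore exactly as
specified and truth fractions are exact arithmetic. Placement failure
after bounded retries, or implants exceeding half the genome, is an
explicit packing error. One integer seed drives derived per-stage streams,
so assemblies, monomers and reads can be regenerated independently.
`make_reads()` draws uniform starts, both strands, iid substitution
errors, and labels reads that lie at least half inside an implanted array.

What the generator emulates: families as divergent tandem arrays sharing a
monomer, assembly-restricted families, TE-derived tandemized fragments,
and error-bearing shotgun reads at known coverage. What it does not:
higher-order repeat structure, GC-correlated background (an order-1 Markov
background is a natural extension), indel-rich satellite evolution,
assembly collapse of long arrays, and read-quality structure. Passing
tests therefore demonstrate correctness of the pipeline's logic under the
stated repeat model, not detector completeness on real, HOR-bearing
centromeres.

## Numerical choices and degenerate inputs

* N bases match nothing anywhere (detector, pair scoring, probe windows);
  all-N columns vote an N into the consensus.
* Consensus ties break by the fixed base order A < C < G < T.
* The divisor-collapse tolerance (95% of best score) trades a small risk
  of over-collapsing genuinely higher-order periods for near-primitive
  reporting.
* Empty inputs: an empty `.dat` yields an empty, well-formed table; an
  empty family set writes a header-only TSV; an empty catalog refuses to
  cluster.
* Coordinates are 0-based half-open everywhere inside the package; TRF
  `.dat` (1-based inclusive) and BED conventions are converted only at the
  I/O boundary.

## Problem sizes used in the packaged checks

The bundled test-and-acceptance scenario uses three assemblies of 50 kb
each (two contigs), five families (monomers 20–120 bp, divergence 2–10%,
one family tandemized from an LTR library fragment, one family restricted
to two assemblies), and 4× read coverage at 100 bp with 0.2% error —
sizes at which every stage's behaviour is exercised and exact truth
accounting is still convenient to audit by hand. Oracle-equivalence checks
run 500 random interval sets, 500 random match graphs, and 20 random
alignment pairs against brute-force references.

## Known limitations

* The detector is a principled simplification of probabilistic tandem
  finders: k-mer seeded, consensus-verified. It does not attempt bit-exact
  agreement with TRF, and heavily indel-mutated arrays (rates well above a
  few percent) can fragment or shift the reported period.
* Family linkage at score > 200 is length-dependent by design; very short
  genuine arrays become singletons.
* The Karlin–Altschul K is approximate; E-values are gates, not
  publication-grade statistics.
* Cross-assembly matching via one representative array per family can, in
  principle, miss an equivalence that only a non-representative member
  would reveal.
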