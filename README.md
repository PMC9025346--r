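# satfam

Discovery, classification and FISH-probe design for satellite DNA (large
tandem repeat) families in genome assemblies.

Satellite DNA is built from monomers repeated head-to-tail into long arrays
("fields") that dominate centromeric and pericentromeric heterochromatin.
`satfam` implements the full in-silico workflow used to characterize such
repeats in the Chinese hamster (*Cricetulus griseus*) and similar genomes:

1. **Detection** — candidate monomer lengths are proposed from the distances
   at which exact k-mers re-occur, and each candidate window is verified by
   wraparound dynamic programming of the array against its own phase
   consensus (match +2, mismatch −5, indel −7; minimum score 50; maximum
   monomer 2000 bp). Tandem Repeats Finder `.dat` output can be ingested
   instead at the same seam.
2. **Non-redundant catalog** — embedded (contained) arrays are discarded;
   among coordinate-identical arrays only the smallest monomer survives;
   partially overlapping arrays are kept as independent fields.
3. **Family clustering** — all array pairs are scored by Smith–Waterman
   local alignment under blastn-default scoring (+2/−3, gap 5/2, no
   low-complexity masking, E ≤ 1e−15); arrays joined by a score > 200 are
   merged by single linkage into families.
4. **Nomenclature** — a family is named `<prefix><L><letter>` where `L` is
   the minimum monomer length among its arrays and letters disambiguate
   families sharing `L` in order of first genomic occurrence (e.g. `33A`,
   `24B`).
5. **Annotation** — families covered ≥ 80% by a repeat-library entry are
   labelled with it; transposable-element classes disqualify a family from
   probe design, satellite or gene-fragment hits do not.
6. **Comparison** — family sets from several assemblies are matched by the
   same similarity criterion and reported as co-occurrence classes
   (all assemblies / each pair / private); chromosome-sorted assemblies get
   in-silico chromosome assignments via a contig→chromosome map.
7. **Abundance** — the percent of raw reads whose k-mers are mostly
   (≥ 50% of 21-mers) contained in a family's arrays estimates that
   family's share of the genome.
8. **Probe design** — the most homogeneous array of each selected family
   provides the consensus from which 18–27 nt oligos are enumerated and
   filtered (GC 35–65%, homopolymer ≤ 4, self-complementarity ≤ 8,
   cross-family uniqueness), maximizing the fraction of family arrays hit
   within 2 mismatches.

A synthetic-genome generator (`make_assemblies()`, `make_reads()`) implants
families with known monomers, copy numbers, divergence and assembly
memberships, so every stage is testable against exact ground truth without
downloading anything. The package also ships the published *C. griseus*
reference tables: the 21-family catalog, the assembly co-occurrence
classes, and the validated 13-probe panel.

## Worked example

```r
library(satfam)

# one diverged family implanted into a 20 kb synthetic contig
sim <- make_assemblies(
  list(implant_spec("fam", monomer_length = 40, copies = 30,
                    sub_rate = 0.08, n_arrays = 3)),
  n_assemblies = 1, contig_lengths = 20000, seed = 7)

arrays  <- detect_arrays(sim$assemblies$asm1, assembly_id = "asm1")
catalog <- remove_redundant(arrays)
fams    <- assign_names(cluster_families(catalog, score_pairs(catalog)))
fams$families[, c("name", "min_monomer", "n_members", "max_array_len")]
#>   name min_monomer n_members max_array_len
#> 1  40A          40         3          1202
probe <- design_probe(fams, "40A")
probe[, c("sequence", "gc_percent", "array_coverage")]
#>             sequence gc_percent array_coverage
#> 1 AGTTGAGGCTGTTGGGGT       55.6              1
```

All three implanted arrays are recovered as one family named `40A` (its
minimum monomer is 40 bp), and the designed 18-mer probe has a within-range
GC and hits 100% of the family's arrays within 2 mismatches.

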