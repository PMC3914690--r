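# symdegen

Comparative analysis of genome degeneration in nascent bacterial
endosymbionts.

When a bacterium becomes locked into an intracellular, host-restricted
lifestyle, its genome starts to decay long before it shrinks: nearly half
of its protein-coding genes can be pseudogenized by frameshifts,
premature stops and truncations while the chromosome is still large;
insertion-sequence (IS) elements expand epidemically, cluster in
intergenic DNA and catalyse duplications and rearrangements; those
rearrangements scramble the replication-linked chromosome architecture
(GC skew polarity, KOPS motif orientation, the *dif* terminus site); and
even the 16S rRNA accumulates structurally disruptive substitutions.
With a closely related free-living genome as the ancestral proxy — at
only a few percent synonymous divergence — every one of these processes
is directly measurable, lesion by lesion. `symdegen` packages that
comparative workflow for R, and ships a genome-degeneration simulator
with a replayable ground-truth ledger so each detector is validated by
recovery, not by assertion.

## What it computes

| Analysis | Functions |
|---|---|
| Genome + annotation I/O (FASTA+GFF3, GenBank), masking, rotation | `read_genome()`, `write_genome()`, `mask_features()`, `rotate_genome()` |
| Reciprocal-best-hit orthology (global protein alignment, BLOSUM62) | `find_orthologs()` |
| Pseudogene classification: 90%/80% fast path, ±2,500 nt extended search, 99%/90% span rules; mutation typing (frameshift, premature stop, truncation, IS interruption) | `classify_genome()`, `classify_cds()`, `detect_mutations()` |
| Nei–Gojobori dN/dS with Jukes–Cantor correction; cryptic-pseudogene screen at dN/dS ≥ 0.3 | `estimate_dnds()`, `dnds_pairs()`, `screen_cryptic()` |
| Exact 20-mer synteny blocks and replichore-symmetry violations | `kmer_matches()`, `chain_blocks()`, `classify_symmetry()`, `synteny_map()` |
| GC skew, cumulative-skew ori/ter, polarization index, KOPS (`GGGNAGGG`) polarity, *dif* search | `gc_skew()`, `cumulative_skew_extrema()`, `skew_polarization_index()`, `find_kops()`, `find_dif()`, `chromosome_architecture()` |
| IS annotation from a consensus library, intergenic-clustering permutation test, IS-bounded duplication detection | `annotate_is()`, `intergenic_clustering_test()`, `detect_duplications()` |
| 16S rRNA stem-mutation (conservative/disruptive) and variability-class classification | `classify_stem_mutations()`, `classify_variability()` |
| Genome degeneration simulator with byte-exact replayable truth ledger | `generate_ancestor()`, `degenerate()`, `replay_ledger()`, `simulate_selection_pairs()` |
| End-to-end orchestration | `run_pipeline()`, `simulate_and_analyse()` |

The central statistic of the selection screen is, per ortholog pair,

    omega = dN / dS,   dX = -(3/4) ln(1 - (4/3) pX)

with synonymous/nonsynonymous sites and differences counted per codon by
NG86 pathway enumeration (stop-passing pathways excluded). Genes with
omega ≥ 0.3 and no inactivating lesion are candidate *cryptic
pseudogenes* — ORFs evolving under relaxed selection that mutation has
not yet caught.

## Worked example

Simulate a free-living-like ancestor, degenerate it, and analyse the
pair (about a minute at this size):

```r
library(symdegen)

anc <- generate_ancestor(ancestor_config(n_genes = 100, seed = 42))
deg <- degenerate(anc$genome,
                  degeneration_params(p_pseudo = 0.4,
                                      n_is_insertions = 15, seed = 42))

run <- run_pipeline(anc$genome, deg$genome,
                    is_library = deg$is_library,
                    pairing_map = anc$meta$pairing_map,
                    variability_map = anc$meta$variability_map)
run$classification
#> <classification_report> 100 CDS: 56 intact, 44 pseudogenes (44.0%), 0 unresolved
dplyr::glimpse(glance(run)[, c("fraction_pseudo", "violation_fraction",
                               "n_is", "is_intergenic_fraction",
                               "is_clustering_p")])
#> $ fraction_pseudo        <dbl> 0.44
#> $ violation_fraction     <dbl> 0.1556008
#> $ n_is                   <int> 15
#> $ is_intergenic_fraction <dbl> 0.8666667
#> $ is_clustering_p        <dbl> 9.999e-05
```

Reading the numbers: 44 of 100 genes carry an inactivating lesion —
exactly the simulator ledger's truth at this seed (the injected per-gene
inactivation probability was 0.4, and the classifier recovered every
lesioned gene with no false calls); about 16% of syntenic k-mers sit in
blocks that violate replichore symmetry after the injected
rearrangements; all 15 inserted IS elements were recovered, 13 of them
in intergenic DNA, which the permutation test calls highly enriched
(p ≈ 1e-4 at 10,000 permutations). `tidy(run$classification)` lists each
gene with its typed mutations, and `plot_dnds()`, `plot_synteny()`,
`plot_gc_skew()` draw the standard figures.

Real genome pairs enter the same way via
`read_genome(path, "genbank")` or `read_genome(prefix, "fasta+gff3")`
followed by `run_pipeline(ref, der, ...)`.

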