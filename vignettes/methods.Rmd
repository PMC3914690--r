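---
title: "Methods: measuring genome degeneration against a free-living relative"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring genome degeneration against a free-living relative}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific setting

When a free-living bacterium becomes a host-restricted endosymbiont, its
genome begins to decay: genes accumulate frameshifts, premature stops and
truncations; insertion-sequence (IS) elements expand and catalyse
rearrangements, duplications and deletions; chromosome-scale replication
signals (GC skew, KOPS motifs, the *dif* site) are scrambled; and even
ribosomal RNA accumulates structurally disruptive substitutions. When a
close free-living relative is available, almost every one of these
processes can be measured by direct comparison: the relative's gene
complement serves as a proxy for the ancestral state, and at only a few
percent nucleotide divergence each inactivating lesion can be identified
individually rather than inferred statistically.

`symdegen` implements that comparative workflow as a reusable, tested
pipeline, together with a genome-degeneration simulator that produces
ancestor/derived pairs with a complete ground-truth ledger, so every
detector in the package can be validated by recovery rather than by
assertion.

# Pseudogene classification

Orthology between the derived and reference CDS complements is
established by reciprocal best hits under global protein alignment
(Needleman–Wunsch, BLOSUM62). Candidate pairs are pre-selected by exact
24-nt probe matching purely to avoid the quadratic all-vs-all alignment
cost; best hits are decided on alignment score with deterministic
tie-breaking (higher identity, then lexicographic locus tag). The
function's default reporting thresholds (protein identity 0.9, reference
coverage 0.8) mirror the intactness rule below. For *anchoring
classification*, however, `run_pipeline()` uses unfiltered reciprocal
best hits: a gene disrupted early by a frameshift or interrupted by an IS
element can fall to arbitrarily low protein identity while remaining
unambiguous at the nucleotide level, and excluding it would silently
convert detectable pseudogenes into unclassified genes. The strict
0.9/0.8 filter is instead applied to the dN/dS input set, which must
contain only cleanly alignable, in-frame pairs.

Each derived CDS is then classified against its reference ortholog by a
three-stage rule:

1. **Fast path** — intact if protein identity exceeds 90% over more than
   80% of the reference length with no inactivating mutation.
2. **Extended search** — otherwise the derived locus is re-examined with
   2,500 nt of flanking context on either end, recovering ORFs whose
   annotated boundaries are wrong. As an optimisation, the extension is
   skipped when the annotated sequence already spans the reference ORF
   beyond the span threshold, in which case the extension cannot change
   the verdict.
3. **Span rule** — intact only if the derived sequence spans more than
   99% of the reference ORF (more than 90% for references under 300 nt)
   and carries no inactivating mutation; otherwise pseudogene.

Inactivating mutations are typed from a reference-anchored nucleotide
alignment (global in the reference, local in the derived sequence):
indels of length not divisible by three are frameshifts, reported at the
first affected reference codon (compensating indel pairs are reported
individually — the intervening peptide is still garbled); in-frame stop
codons upstream of the reference stop are premature stops, except within
the final three codons, where apparent stops are usually alternative stop
usage rather than inactivation; a premature stop followed by a diverged
3' remainder, or a long (≥ 60 nt) terminal deletion, is typed as a
truncation. Terminal deletions are never typed as frameshifts: nothing
downstream of them is shifted out of frame, and the span rule governs
those cases. IS interruptions are recognised *before* alignment by exact
k-mer seeding against the IS consensus library and excised: a linear-gap
aligner will not open a kilobase-scale gap, so homology search, not
alignment, is the reliable detector of embedded elements.

# dN/dS estimation and the cryptic-pseudogene screen

Genes not yet disrupted by any lesion may still be evolving with little
constraint — "cryptic pseudogenes". The screen estimates per-gene
synonymous (dS) and nonsynonymous (dN) substitution rates by unweighted
pathway counting (the classical Nei–Gojobori scheme): synonymous *sites*
are counted per codon by enumerating all nine single-nucleotide changes
and taking the synonymous fraction among those not creating a stop;
*differences* between codons differing at more than one position are
averaged over all minimal mutational pathways, excluding pathways that
pass through a stop codon (falling back to all pathways when every one is
blocked). Proportions are corrected for multiple hits with
$d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$. Site counts satisfy
$S + N = 3 \times$ codons exactly, which the tests assert for every gene.

This estimator was chosen over maximum-likelihood codon models because it
is fully specifiable and oracle-checkable: the test suite contains an
independent brute-force pathway enumerator and verifies exact agreement
on all single-codon pairs with up to two differences and on sampled
two-codon alignments. At the ~2% divergence typical of a nascent symbiont
the counting and ML estimators nearly coincide, but per-gene values are
*noisy*: dS is estimated from a handful of events, so per-gene omega
(dN/dS) carries large standard errors (codon-bootstrap standard errors
are available via `dnds_bootstrap()`), and the mean of per-gene ratios is
biased upward at very low divergence simply because a noisy denominator
enters a ratio. The package's neutral-limit validation therefore runs at
a substitution-attempt rate of 0.2/site (dS ≈ 0.19, far below
Jukes–Cantor saturation), where that ratio bias is negligible; this is a
property of ratio estimators, not of the implementation.

The screen flags genes with omega ≥ 0.3 as candidate cryptic pseudogenes
and labels genes at ≥ 0.4 with their products; it reports the mean ORF
length of the flagged and unflagged sets, because genes under relaxed
selection that survive undamaged tend to be short (small mutational
targets). Infinite omega (dS = 0, dN > 0) counts as flagged but is
excluded from mean omega.

# Synteny and replichore symmetry

Whole-genome correspondence is computed from exact 20-mers after masking
IS elements and prophage: every k-mer occurring exactly once in each
genome (on either strand) yields a match, and matches collinear within a
1,000-nt gap and a 20-nt diagonal tolerance are chained into blocks. The
unique-in-both filter removes residual repeat ambiguity deterministically
— a k-mer present twice anywhere simply cannot anchor an unambiguous
correspondence.

Replication symmetry requires same-strand blocks to remain on the same
replichore and opposite-strand blocks to switch replichore. Each block is
probed at two interior points (25% and 75% of its span, mapped
orientation-aware between the genomes): `symmetric` when both probes obey
the rule, `violating` when both break it, `indeterminate` when they
disagree (a block genuinely spanning ori or ter in one genome only). The
probe formulation handles the instructive edge case correctly: an
inversion centred on the ori–ter axis swaps replichores and is symmetric,
while the same inversion confined to one replichore is violating. The
genome-level violation fraction is k-mer-weighted over classified blocks.

# Chromosome architecture

GC skew, $(G-C)/(G+C)$, is computed in 10-kb windows stepped by 5 kb
(configurable; the defaults smooth single-gene composition noise at
chromosome scale while retaining a couple of windows of resolution around
ori and ter). Ori and ter are placed at the global minimum and maximum of
cumulative skew. The *polarization index* quantifies the qualitative
"polarized vs disrupted" judgment as the fraction of windows whose skew
sign matches the two-replichore model, orientation chosen to maximize
agreement, so 1.0 is perfect polarization and ~0.5 is no signal. Callers
can override ori/ter — necessary for a rearranged genome whose own skew
no longer identifies them, where the anchors are better carried over from
the syntenic relative.

KOPS motifs (`GGGNAGGG`, IUPAC-aware, both strands) are polarized
ori-to-ter on each replichore in an unrearranged chromosome; the polarity
statistic is the fraction of sites so oriented. The *dif* site is located
by ungapped best-placement search of the canonical 28-nt enterobacterial
query on both strands with at most 4 mismatches (ties resolved leftmost);
a genome that has lost its terminus region correctly returns no placement.

# IS elements and duplications

IS copies are annotated from a consensus library by exact 20-mer seeding
and per-candidate global alignment, keeping hits at ≥ 94% identity
(identity computed over all alignment columns, so indels count as
differences) covering ≥ 80% of the consensus; each copy's transposase ORF
is classified intact/disrupted with the same mutation detector used for
host genes. Library-based discovery is deliberate: de novo repeat
classification belongs to dedicated external resources, while the
analyses downstream of annotation are what this package owns.

Intergenic clustering is tested by permutation: the observed fraction of
IS midpoints in intergenic space (complement of CDS/pseudogene/rRNA/tRNA)
against a null placing the same number of midpoints uniformly on the
chromosome, one-sided for enrichment, p computed as
$(1 + \text{exceedances})/(B + 1)$ and bit-reproducible given a seed. The
null deliberately ignores IS–IS overlap constraints (the simplest
exchangeable null; a nearest-neighbour spatial statistic is intentionally
out of scope). Calibration is validated by simulation: with 80 elements
on a ~15% intergenic chromosome the discrete null admits a rejection
region of mass 0.048 at nominal 0.05, so the empirical type-I error over
1,000 null draws is expected inside [0.03, 0.07]; with many fewer
elements the discreteness of the binomial null makes the nominal level
unattainable for *any* exact test, which drove the choice of 80 elements
for the calibration design.

Segmental duplications are found as pairs of long, highly similar
repeats: k-mers occurring exactly twice in the masked genome are chained
by diagonal, pairs ≥ 2.5 kb at ≥ 99% identity are kept, and the
substitutions and indels between copies are counted by aligning only the
short unanchored gaps between consecutive k-mer anchors — exact for the
isolated differences that characterise a recent duplication, and far
cheaper than aligning two 13-kb copies in full. A pair is "IS-bounded"
when both flanks of both copies carry same-family IS annotations within
2 kb. A duplication internally interrupted by a later IS insertion is
reported as multiple colinear pairs; merging across such interruptions is
left to the caller.

# 16S rRNA mutation classification

Substituted positions are classified against a stem pairing map:
unpaired positions are loops; at paired positions the *realized* pair —
both members taken from the query — is evaluated, conservative if
Watson–Crick or G·U wobble (G·T in DNA representation), disruptive
otherwise. Using the realized pair means a compensatory double
substitution scores conservative at both positions: the folded molecule
is what selection sees. Positions gapped in the query (or with a gapped
partner) are excluded from stem classification and counted separately;
indels are reported, never dropped. A second classification bins each
substitution by a per-position variability class (1 = invariant … 6 =
hypervariable); an excess in classes 1–2 indicates relaxed constraint.
Both maps are plain TSV inputs — the package ships no structure or
variability database, and the simulator fabricates internally consistent
toy maps.

# The degeneration simulator

`generate_ancestor()` builds a gene-dense circular chromosome with the
signals the analyses assume: valid ORFs (start codon, internal-stop-free,
terminal stop) whose codons are sampled with leading-strand G enrichment
(default excess G probability b = 0.05 per base), biased spacers, planted
polarized KOPS motifs, a dif site at the terminus, and identical 16S
copies with a consistent stem map. Chance KOPS motif occurrences are
scrubbed (synonymous codon swaps inside genes, direct substitutions in
free DNA) so the planted polarity is exact. Defaults — 200 genes of mean
900 nt, 15% intergenic space, 55% GC, two rRNA copies — emulate an
enterobacterial free-living relative at desk scale. The KOPS density (150
sites on a ~200-kb chromosome) is deliberately higher than real genomes
per-kb so that polarity statistics are stable at this scale; note that
G-rich polarized motifs themselves contribute to GC skew, exactly as they
do in real chromosomes.

`degenerate()` applies events in a fixed order — background
substitutions, gene inactivations, duplications, IS insertions,
inversions, translocations, deletions — recording each applied operation
in a ledger whose replay reproduces the derived genome byte-exactly
(tested property). Design choices worth stating:

* **Background substitutions are synonymous-only inside CDS** (random
  synonymous codon exchange at per-codon probability 3μ, default μ =
  0.005 giving roughly the 2% synonymous divergence of a nascent
  symbiont): background divergence can then never inactivate a gene, so
  classifier precision/recall against the ledger is exactly defined.
  rRNA and intergenic DNA receive unconstrained substitutions.
* **Inactivation types**: frameshifts are 1–2-nt indels at interior
  codons; premature stops convert an interior codon to a stop by minimal
  substitution; truncations are a premature stop plus a scrambled 3'
  remainder, so both the mutation detector and the span/extension logic
  are exercised.
* **Rearrangement breakpoints fall in feature-free DNA**, so ground
  truth stays clean: no gene is bisected by an inversion whose effect
  would then be ambiguous to score. Segment lengths are drawn at the
  IS-pair spacing scale (inversions 2-10 kb, translocations 1-15 kb):
  IS-mediated recombination acts between nearby elements, and
  chromosome-arm-scale inversions would make recovery statistics
  saturate (repeated overlapping flips cancel) rather than accumulate.
* **Duplications** copy a region between feature-free points as close as
  possible to the requested length, diverge the copy by the requested
  substitution and single-nt indel counts, and insert it in tandem
  bracketed by same-family IS copies (with a third IS before the
  original), producing the IS-bounded signature.
* **Genic IS insertions** extend the host gene's annotated feature and
  are recorded as `is_interruption` ground truth.

What the simulator does **not** emulate — codon-usage realism, selection
on intergenic DNA, transposition bursts in trans, gene conversion between
rRNA operons, replication-associated mutational gradients — bounds what
passing tests show: recovery results demonstrate that the detectors
measure what they claim on genomes whose signal structure is known, not
that real genomes contain no further complications.

# Validation design and problem sizes

The recovery suite runs at sizes chosen to keep the full test round
desk-scale while leaving no detector untested: classification on three
500-gene pairs at p_pseudo = 0.4 (recall and precision ≥ 0.99 against the
ledger); the NG86 oracle checks described above plus neutral (200 × 500
codons) and constrained (300 × 300 codons, 30% neutral) calibrations;
breakpoint recovery on 10-kb constructed and ~200-kb simulated
rearrangements with violation-fraction monotonicity over 0/2/4/8
inversions × 10 seeds; ori/ter recovery within two windows and
sign-tests for polarity decay over 10 seeds; 1,000-draw calibration of
the permutation test; and the 13,476-nt duplication round trip with
exactly 13 substitutions and 4 indels. `scripts/acceptance.R` recomputes
all of these from scratch with a caller-supplied seed.

# Known limitations

* Orthology is pairwise RBH; multi-species ortholog groups, synteny-aware
  orthology and Markov clustering are out of scope.
* The dN/dS module reports counting-method estimates; no ML codon models
  or branch models.
* `detect_duplications()` only reports same-strand (tandem-style) repeat
  pairs and splits duplications at internal interruptions.
* The GenBank reader covers the single-record, simple/complement/join
  location subset this package writes — not the full flat-file grammar.
* Circular-origin handling assumes features are stored unwrapped
  (`wraps_origin`) and that analyses receive a rotation without
  origin-spanning features; `rotate_genome()` provides that.
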