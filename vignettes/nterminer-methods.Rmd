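---
title: "NterMiner: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NterMiner: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Standard proteomics searches can only identify peptides present in the
reference protein database, so translation products of unannotated
genes, alternative translation initiation sites (TIS), N-terminal
extensions and products of near-cognate start codons (CUG, GUG) remain
invisible. N-terminomics protocols such as N-terminal COFRADIC enrich
precisely the peptides that witness where translation starts: the
protein N-terminal peptide. NterMiner implements the computational side
of an N-terminomics-driven proteogenomics workflow:

1. enumerate every candidate translation product of a genome
   (six-frame ORFs from AUG/CUG/GUG starts, downstream-AUG
   truncations, and spliced predicted gene models);
2. reduce them to the N-terminal peptides a given protease can
   actually produce, and assemble a target–decoy search database;
3. combine the PSM output of several search engines into
   engine-independent FDR scores and apply multistage filters;
4. annotate the surviving novel N termini (modification state, NME
   compliance, genomic category, ribo-seq support, spectral
   correlation);
5. score the TIS nucleotide context and test start-codon conservation
   in whole-genome alignments.

## Library construction

**ORF model.** An ORF is delineated by a start and a stop codon and
must encode at least `minAa = 8` amino acids (stop excluded); this is
the 24-nt minimum commonly used for six-frame databases. Start codons
default to ATG plus the near-cognate CTG and GTG, all decoded to
initiator Met, as near-cognate initiation is decoded to iMet in
eukaryotes. Every qualifying start is emitted (getorf-like "every
start" semantics) rather than only the 5'-most per stop: nested
N-termini are distinct hypotheses here, and redundancy is resolved at
the peptide level. ORFs running off a contig end without a stop are
dropped — an ORF without a delineating stop has an undefined product.
`everyStart = FALSE` restores longest-per-stop behaviour.

**Downstream AUG truncations.** Within each six-frame ORF, every
internal in-frame ATG nucleates a truncated product sharing the
parent's stop. Only ATG re-initiates; internal CTG/GTG do not. Because
ATG is the only Met codon, internal Met residues of the parent protein
identify these starts exactly.

**Digestion.** The four protease specs mirror an Nt-COFRADIC
experiment in which lysines are chemically acetylated, so trypsin
cleaves after Arg only (ArgC behaviour). Library-stage missed-cleavage
allowances are 0 (ArgC) and 1 (GluC, chymotrypsin, AspN); the larger
reference-search allowances (2/3) are available via
`proteaseSpec(name, reference = TRUE)`. A peptide for missed-cleavage
count *k* runs from the N terminus through the (*k*+1)-th cleavage
boundary. When a protein has fewer boundaries than allowed, the
full-length N-terminal peptide is emitted once and flagged
`ctermIsProteinEnd`; without this rule, short near-cognate ORF products
with no internal cleavage site would be unrepresentable. When residue 2
has a small gyration radius (Ala, Cys, Gly, Pro, Ser, Thr, Val) — the
substrate rule of methionine aminopeptidases — the position-2 series
with the initiator Met excised is *additionally* emitted; both forms
are kept because either N terminus can be observed. Peptides are
bounded to 8–30 residues (longer peptides contribute little to
N-terminal identification and inflate the search space) and
X-containing peptides (from ambiguity codes) are dropped at this stage,
keeping ORF discovery annotation-free.

**Reference subtraction.** A peptide is removed iff its sequence
occurs as a substring of any reference proteome or contaminant protein,
with Ile/Leu collapsed on both sides before matching — the two residues
are isobaric and indistinguishable by MS. Matching is
position-independent: a library peptide identical to an internal
reference tryptic peptide would be claimed by the reference search
anyway.

**Decoys.** One decoy per target by full sequence reversal, at the
peptide level rather than the protein level: the customized search runs
with "no cleavage" enzyme settings, so the peptide is the search unit
and peptide-level reversal preserves the search-space statistics. A
decoy whose I/L-collapsed sequence collides with a target or reference
substring is re-derived by seeded shuffling (25 attempts, then the
pair is dropped with a warning). The build is byte-deterministic given
inputs and seed.

**Deduplication** is by exact sequence, merging ORF ids and TIS loci;
whether deduplication happens before or after reference subtraction
does not change the final set, so subtraction runs on the deduplicated
(smaller) set.

## FDR scoring across engines

Each engine's PSMs (one best hit per spectrum, selected at ingest) are
ranked by raw score — XCorr-style scores descending, e-value-style
ascending, decoys after targets on ties (the conservative choice). The
target–decoy FDR at each rank is #decoys / max(1, #targets); the
q-value is the minimum FDR at or beyond the rank, a non-decreasing
step function that a brute-force threshold sweep reproduces exactly
(this equivalence is asserted in the tests). The *FDR score* then
interpolates linearly in rank between the decoy anchors (0 before the
first anchor, constant after the last), giving PSMs within a q-value
plateau graded, engine-independent scores in [0, 1]. Interpolation is
in rank rather than raw-score space — rank is scale-free across
engines — with raw-score tie groups sharing their tie-average rank.

Keys (spectrum, peptide, modifications) are matched across engines;
including modifications keeps in vivo and in vitro Nt-acetyl forms
distinct identifications. The combined raw score of a key is the
arithmetic mean of its engine FDR scores. Because PSM sets shared by a
given subset of engines may contain no decoys of their own, the
combined FDR score is re-estimated *within each engine-set partition*
by the same FDR → q-value → interpolation procedure; a partition
without decoys correctly yields zeros. Partitions smaller than 10 PSMs
are flagged (`smallPartition`) rather than merged upward — the
contract favours transparency over smoothing; single-engine keys have
no combined score (`NA`).

The multistage filter retains a PSM iff (minimum engine FDR score ≤
0.01 OR combined FDR score ≤ 0.01) AND at least one engine scored it ≤
0.05; the safeguard blocks decoy-free partitions from laundering weak
hits. The novel stage additionally requires agreement of ≥ 2 engines.
The spectra *not* retained at the reference stage are exposed as the
unidentified set handed to the novel (customized-database) search.

## N-terminus annotation

Modification state is read from the N-terminal mass delta within ±0.02
Da of the catalog values: +42.01 (in vivo acetyl), +47.04 (in vitro
trideutero-acetyl), −17.03 (pyroGlu of Nt-Gln); no N-terminal
modification is a free N terminus. Out-of-catalog N-terminal deltas
raise an error rather than silently classifying. NME compliance uses
the small-gyration-radius rule only (excision iff residue 2 ∈
{A,C,G,P,S,T,V}); full acetylation-propensity prediction as offered by
dedicated NME predictors is deliberately not reimplemented — the
observed modification is available instead, and the rule is documented
as an approximation.

TIS categorization intersects the 3-nt start codon with transcript
footprints, strand-agnostic by default (an antisense TIS inside a gene
span is still "intragenic" in the genome-browser sense); both the
footprint (transcript span vs exon bases) and strandedness are
exposed as flags since either convention is defensible. Overlaps of
several biotypes resolve by priority protein_coding >
transposable_element > pseudogene — reported category counts are
disjoint, and a TIS inside a protein-coding model is the more
conservative (least novel) call.

Ribo-seq TIS support requires a called initiation site on the same
contig and strand within a tolerance (default 0 nt, exact) of the TIS
first base. Spectral-correlation filtering compares each novel PSM's
predicted-vs-observed correlation with the *median* of the annotated
peptides in the same (tryptic?, charge) stratum, ties counting as
high; a peptide is high-confidence if any of its PSMs is.

## TIS context score

The frequency matrix holds integer-percent nucleotide frequencies at
positions −5..−1 and +1..+4 around annotated start codons (position +1
is the first codon base; there is no position 0, so the context is a
9-mer). Loci shared by alternative transcripts are counted once,
collapsing on (contig, first base, strand) rather than transcript id.
The context score sums the percent frequencies of the bases observed
at −5..−1 and +4 — the start codon itself never contributes — giving a
0–600 range. Percents are rounded to integers *before* summation so
that scores are exact integer sums (`round = FALSE` gives unrounded
percents for sensitivity checks). For proteins starting with
consecutive Met residues only the first start codon's context is
scored, and peptides mapping to multiple genomic loci are not scored;
both are caller responsibilities because only the peptide/ORF pairing
knows the locus structure.

## Conservation in whole-genome alignments

For each TIS the first alignment block (by reference coordinate)
covering its first base is used; blocks are never stitched, so an ORF
truncated at a block edge counts as not encoding the peptide — the
conservative reading of "present in an alignment block". The query row
is taken from the TIS column to the block end (to the block start,
reverse-complemented, for minus-strand TIS) with query gaps removed;
reference-row insertion columns shift the column index but not the
parsed query. The aligned start codon is canonical (ATG), near-cognate
(by default any of the nine single-substitution neighbours of ATG; a
flag restricts to CUG/GUG, the subset used for library construction),
or absent. Orthologous coding capacity translates the query in frame 0
from the conserved start (initiator → Met) until stop or sequence end
and requires at least the length of the identified peptide (or of its
first-exon part for junction-spanning peptides, supplied by the
caller).

## Synthetic data: what it emulates, and what it does not

`synthGenome()` plants stop-free ORFs with configurable start-codon
mix (default 70% ATG, 15% CTG, 15% GTG) and an A-rich −5..−1 context
with probability 0.7 — mimicking the A-richness that favours plant
translation initiation — on i.i.d. background, and wraps a
configurable fraction in protein-coding / transposable-element /
pseudogene annotation (default 30/20/10%, the rest unannotated
"novel"). `synthPsmTables()` draws correct matches from targets with a
high-scoring Normal and incorrect matches — split evenly between
targets and decoys, the assumption underlying target–decoy FDR — from
a null Normal (latent quality N(3.6, 0.45) vs N(1.3, 0.45), engine
jitter sd 0.18, e-values 10^−(2.5·q−1.5) for the lower-better engine,
15% per-engine dropout); the parameters were chosen once for analytic
tractability of the expected false discovery proportion. `synthMaf()`
writes one block per TIS and species with a planted start-codon fate
(keep / near_cognate / destroy / unaligned) and configurable
substitution and query-gap rates outside the codon.

What the simulators do *not* emulate: genome composition bias and
repeats, splice structure in planted models (single-exon only; spliced
models are exercised by hand-built fixtures in the tests), correlated
engine score distributions beyond a shared latent quality, retention
times or fragmentation spectra, and alignment blocks spanning
rearrangements. Passing tests therefore demonstrate correctness of the
algorithms under the stated error model, not performance on real
tissues or genomes.

## Problem sizes and numerical choices

The test suite runs the library oracle on a 100-kb genome with 50
planted ORFs (all four proteases, set-identical to a quadratic
brute-force digestion oracle), ORF-enumeration equivalence on 500
random 2-kb contigs, FDR calibration on 20,000 simulated PSMs at 30%
incorrect (realized FDP within [0, 0.03] at the 0.01 combined filter),
and q-value agreement against a threshold-sweep oracle on 200 random
lists of up to 1,000 PSMs — sizes chosen so the whole suite exercises
every contract at meaningful scale while remaining quick to run.
Mass-delta matching tolerance is ±0.02 Da against rounded catalog
deltas. Decoy reshuffling is bounded at 25 attempts. Coordinates are
1-based inclusive internally (GFF convention); BED export converts to
0-based half-open.

## Known limitations

- Internal (position > 2) peptides and proteolytic neo-N-termini are
  out of scope by design; the library encodes position-1/2 peptides
  only.
- The NME rule is a deterministic approximation; borderline substrates
  (e.g. Val) are treated as always excised.
- Biotype mapping from annotation is convention-based (feature types
  and `biotype`/`gene_biotype` attributes); annotations using other
  encodings fall back to `other`.
- MAF handling assumes forward-strand reference rows (the layout of
  standard pairwise genome alignment exports) and does not stitch
  blocks.
- The combined FDR score for partitions with very few PSMs is noisy;
  such partitions are flagged, not reweighted.
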