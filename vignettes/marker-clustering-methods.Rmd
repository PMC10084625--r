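---
title: "Detecting eukaryotes from marker-gene alignments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting eukaryotes from marker-gene alignments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Microbial eukaryotes (fungi, protists, helminths) are rare in shotgun
metagenomes relative to bacteria. A practical detection strategy aligns
reads to a reference of universal single-copy orthologs (BUSCO-style
marker genes), where each reference sequence belongs to one taxon. The
difficulty is multi-mapping: closely related taxa share marker sequence,
so a read often aligns almost equally well to several taxa. Pipelines
that keep only the best alignment and filter on mapping quality (MAPQ)
buy specificity at a steep, species-biased cost in sensitivity, because
MAPQ collapses whenever a close second-best alignment exists — precisely
the situation for any taxon with a sequenced relative.

`eukscreen` instead keeps *all* alignments of every read and resolves
ambiguity structurally, by clustering the graph of shared alignments,
then reporting taxa either as unambiguous hits or as merged,
explicitly-uncertain `"?"` hits.

## The decision procedure

Input is one alignment table: one row per (read, marker) pair, with the
identity computed from the edit-distance tag as
$(\ell - \mathrm{NM})/\ell$ over the aligned query length $\ell$, and the
fraction of the marker covered. Mates of a pair count as separate reads;
duplicate alignments of a read to the same marker keep the best identity.

1. **Length filter.** Keep alignments with aligned query length ≥ 60 nt
   (inclusive). Shorter matches carry too little information to be
   marker-specific. The filter applies to the alignment, not the read.
2. **Marker clustering.** Build a graph with markers as nodes and the
   number of distinct shared reads as edge weights; run Markov clustering
   (MCL).
3. **Identity aggregation.** Average identity per marker, then per marker
   cluster. The cluster average is the *unweighted* mean of member
   markers' averages (an alignment-weighted mean is available via
   `marker_stats(weighted = TRUE)`): each marker is one summary
   observation, regardless of read depth.
4. **Inferior-marker rejection.** A marker strictly below its cluster
   average is an inferior representation of the signal in the sample —
   the more plausible explanation is that the reads came from a relative.
   A taxon with ≥ 50% inferior markers (boundary inclusive) is rejected.
   The denominator is the taxon's *aligned* markers, since unaligned
   reference markers carry no signal either way. Equality is not
   "lower": a singleton cluster's marker equals its own average and is
   never inferior.
5. **Taxon clustering.** MCL again, on surviving taxa, with counts of
   multiply-aligned reads as edge weights.
6. **Unambiguous calls.** A taxon with average identity ≥ 97% and at
   least 2 distinct reads on at least 2 distinct markers is reported.
   The identity criterion is evaluated per taxon (the published wording
   leaves per-taxon vs per-cluster open; per-taxon is the stricter and
   more local reading). Other taxa in a cluster containing an
   unambiguous member are rejected.
7. **Strong ambiguous calls.** A cluster with no unambiguous member is
   reported as a single hit when the *union* of its evidence spans ≥ 4
   markers and ≥ 8 reads, labelled with the member taxa sorted
   lexicographically, comma-joined, prefixed `"?"`. The published
   Results wording (4 markers / 8 reads) is used over the transposed
   Methods phrasing; both numbers are configurable.

All thresholds live in `default_thresholds()` and are overridable from
the CLI; raising any of them can only reduce the number of calls.

### Quantification

Abundance is reported as copies per million (CPM), in the
reads-per-kilobase-over-depth convention used by integrated profilers:

$$\mathrm{CPM} = \frac{R/(L/1000)}{D/10^6}$$

with $R$ the distinct reads assigned to the call, $L$ the summed length
of its evidence markers (union across members for `"?"` calls) and $D$
the sequencing depth in reads. Because a SAM of marker alignments
usually lacks the unmapped bulk of the sample, $D$ defaults to the reads
seen in the file but should be supplied with `--total-reads` for real
samples. The exact published formula is not printed; this HUMAnN-style
definition is the documented default, and a community-relative dialect
(`cpm_mode = "sum-normalized"`, reads-per-kilobase rescaled to sum to
$10^6$) is switchable.

## Markov clustering: numerical choices

The published workflow names no MCL parameters, so the defaults of the
commonly cited implementation are used: expansion 2, inflation 2.0,
self-loop weight 1, tolerance $10^{-6}$ on the maximum entrywise change,
at most 100 iterations, entries below $10^{-8}$ pruned. Non-convergence
returns the current partition with a warning. Attractor supports that
overlap are resolved deterministically: a node goes to the cluster where
its attractor value is largest, ties to the cluster with the smallest
representative, so the output is always a partition. Nodes are processed
in sorted order, making the result invariant to input permutation.

One structural property deserves emphasis: on an *isolated two-node
pair*, standard MCL converges to two singletons whenever the self-loop
weight differs from the edge weight — after one expansion the diagonal
of $M^2$ strictly dominates ($c^2 + w^2 > 2cw$ for $c \ne w$) and
inflation amplifies it. This is not an implementation quirk; the
independent reference implementation agrees. Consequently a sample
containing exactly two mutually confusable taxa and nothing else will
yield two singleton taxon clusters, and merged `"?"` calls arise in
practice from richer shared-alignment structure than a bare pair.

## The simulator and what fixtures establish

`sample_reads()` emulates the published protocol: 100 bp reads, base
error rate 0 (reads are exact substrings), uniform starts, read counts
per marker from Lander–Waterman $N = cL/\ell$ rounded half away from
zero, markers shorter than the read skipped and flagged.
`mutate_reads()` applies independent per-base substitution (no indels —
at the granularity of a mutation-rate sweep the indel contribution is
negligible, and substitutions keep alignment identity analytically
predictable). Read names encode `taxon:marker:start:index` for truth
tracking; everything is reproducible from an explicit seed.

`generate_fixture()` fabricates internally consistent worlds — marker
FASTA, taxonomy TSV, truth table and SAM with controlled identity (via
NM), alignment length and MAPQ — without running an aligner. Fixture
defaults reflect the stated simulation conditions: 100 bp reads, 1 kb
markers (typical BUSCO exon-fragment scale), perfect identity unless a
scenario says otherwise, MAPQ 42 for unique alignments and a
low-MAPQ primary (3) for reads with competitive secondary alignments,
which is how end-to-end aligners report them. A green test on a fixture
establishes that the decision procedure implements its rules exactly; it
does not establish performance on real communities, where reference
incompleteness, chimeras and coverage bias are in play, nor the
published full-database figures, which require the external marker
reference.

## Benchmarking and confusability

`score_mappings()` computes read-level precision (correct/mapped) and
recall (correct/all) with a read's match taken from its best-identity
alignment; ties are resolved favourably (any correct tied match counts),
since an aligner's best-mode output would have reported one of the tied
records. With nothing mapped, precision is reported as a flagged missing
value rather than 0 or 1. Correctness is lineage agreement at species
rank, or genus for holdout (unrepresented species) scenarios, where the
benchmark driver selects genus automatically.

Pairwise confusability summarizes, for a pair (A, B), eight rates: each
member's propensity to emit reads to its partner or to outside taxa, and
to accept reads from its partner or from outside. The accept-rate
denominators are the source side's read totals, chosen for symmetry with
the emit rates (the published figures do not print the formulas); with
no outside reads the outside-accept rate is defined as 0. PCA of the
feature table is mean-centered but *not* variance-scaled — the features
are already commensurable rates on $[0,1]$ (scaling is available via
`scale. = TRUE`); component signs are fixed so loadings sum positive,
making PC1 an overall-confusability axis. The greedy geospatial
subsample keeps the seed pair, then visits points by ascending distance
from the seed (ties by label) keeping any point at least the minimum
distance from everything kept — the visit order is a determinism choice,
as the published one is unstated. An externally supplied per-pair
feature or coordinate table can be fed directly to `pca_embed()` /
`greedy_subsample()` to reproduce published embeddings.

## Known limitations

- CRAM input, streaming memory guarantees and aligner invocation are out
  of scope; tests consume pre-made SAM.
- Genus-level collapsing of `"?"` labels is a presentation rule left to
  downstream consumers.
- The simulator models substitutions only; indel divergence and quality
  scores are extensions.
- Dense-matrix MCL is adequate for per-sample marker graphs (thousands
  of nodes at most) but is not tuned for larger graphs.
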