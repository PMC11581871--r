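---
title: "Separating mixed host/parasite reads: the model behind dualmapsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating mixed host/parasite reads: the model behind dualmapsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualmapsim)
```

## What is being modelled

A dual RNA-seq sample from a host plant–parasitic plant interface mixes
transcripts of two organisms. Separation is done by competitive read
mapping, and its two systematic failure modes are what this package
quantifies:

* **within-genome multimapping**, caused by gene duplication (paralogy);
* **cross-mapping between genomes**, caused by homologous loci whose
  divergence is too small for the mismatch filter to tell apart. A read
  can cross-map on *one side* only (it maps solely to the wrong genome —
  in real data usually a symptom of an incomplete assembly of its own
  genome) or on *two sides* (it maps validly in both genomes).

Everything downstream — the sequential and combined assignment
strategies, the dual label taxonomy, the confusion-matrix metrics, the
one-/two-side extraction and locus summaries — is implemented against a
synthetic genome pair in which the *true* origin of every read is known,
so each property can be checked exactly rather than estimated.

## The synthetic genome pair

`genome_pair_spec()` describes two genomes as arrays of single-exon genes
separated by random intergenic spacers. Each gene slot plays one role:

| role | mechanism emulated | knob (default) |
|---|---|---|
| diverged homolog | orthologs between host and parasite | `divergence` (0.10 per base) |
| conserved homolog | organelle-like ultra-conserved loci; the two-side cross-mapping source | `conserved_fraction` (0.05) |
| private gene | genes with no counterpart; with the read-planting helpers, also assembly gaps (one-side source) | `host_/parasite_private_fraction` (0.10) |
| paralog copy | within-genome duplication; the multimapping source | `paralog_fraction` (0.10), `paralog_divergence` (0.02) |

Homologous pairs share a random base sequence; the parasite copy is
mutated at each position independently with probability `divergence`, so
the realised per-base divergence of a pair is Binomial and converges to
the nominal rate as genes grow (one of the test-suite oracles recomputes
it position by position). Conserved pairs are copied verbatim (realised
divergence exactly 0). The default divergence of 0.10 is of the order of
what separates coding sequence of plant families that are
phylogenetically close but distinct; the conserved class stands in for
rRNA/organelle-like loci that remain near-identical at any taxonomic
distance. These defaults were fixed once, for testability of all
categories at desk scale, and are not tuned per analysis.

Reads are simulated in FR orientation from gene bodies (minus-strand
genes contribute the reverse complement of their genomic interval), with
Gaussian fragment lengths clamped to the gene, uniform gene sampling (an
optional per-gene weight exists but defaults to uniform), and independent
per-base substitution errors. Defaults mirror a common real setup: 150 nt
host reads, 100 nt parasite reads, 300 ± 30 bp fragments, error rate
0.005. Ground truth is carried inside the read name
(`readNNNNNN|organism|gene|start`), so it survives FASTQ round trips
without sidecar files.

What the generator deliberately does **not** emulate: indels and
structural variants, splicing (genes are single-exon by design, so
contiguous alignment is exact and splice-awareness is orthogonal to the
cross-mapping question), base-quality structure (FASTQ qualities are a
constant 'I'), and expression heterogeneity beyond the optional gene
weights. Consequently, passing tests demonstrate the *logic* of the
strategies and metrics under controlled homology — not performance on
real libraries with indel error, splicing or skewed expression.

## The mapper

The paired-end mapper is a deterministic k-mer seed-and-extend Hamming
aligner:

* candidate loci come from exact (error-free) k-mer anchors of either
  mate (k = 15 by default), extended to a full contiguous comparison of
  both mates within the allowed fragment span (`insert_min` 100,
  `insert_max` 500 bp — generous around the simulated 300 ± 30);
* a placement qualifies if the *pair-total* mismatch count is at most
  `max_mismatch` (default 5; the relaxed remapping mode uses 10). The cap
  is deliberately a single per-pair knob;
* all qualifying placements are retained up to `max_multimap` (default
  10) — there is no best-hit selection and ties are never broken. One
  over the cap, the pair's hit list is emptied (`TOO_MANY`) and the pair
  counts as unmapped downstream, which keeps every report row summing to
  the processed total with only unique/multiple/unmapped columns;
* a pair with qualifying placements for only one mate is unmapped (the
  mate-discard rule); in this model that is inherent, since a placement
  is defined on the pair;
* identical placements are deduplicated by (chromosome, mate-1 start,
  strand), which collapses palindromic overlaps.

Seed anchoring is the mapper's one declared approximation: a placement
none of whose mates contains a single error-free k-mer cannot be found.
By pigeonhole, a mate of length L with m mismatches always contains a
clean k-mer when (L − m)/(m + 1) ≥ k, so with the strict cap (m ≤ 5),
k = 15 and mates ≥ 100 nt candidate generation is provably exhaustive —
the acceptance suite checks equality with a brute-force
all-positions enumeration oracle on 500 error-free reads. Under the
relaxed cap (10 mismatches) exhaustiveness is no longer guaranteed; the
planted-recovery fixtures therefore concentrate mismatches so that
recoverability is by construction, and this limitation is declared rather
than hidden.

Mismatch counting, index lookup and the brute-force oracle operate on raw
byte vectors; the oracle in the test suite shares no candidate-generation
code with the mapper.

## Strategies and the label taxonomy

`assign_sequential()` is greedy by order: pairs assigned in step 1
(uniquely or multiply) never consult the second genome; only
unmapped/over-cap pairs are forwarded. `assign_combined()` maps once over
the `host::`/`parasite::`-namespaced concatenated reference, with the
multimap cap applied to the hit count *across both genomes jointly* —
that is what a single aligner invocation on a concatenated index does,
and it produces a documented cap-boundary divergence between strategies:
a read with, say, 6 identical loci per genome is `MULTI` sequentially
(6 ≤ 10) but unmapped in the combined run (12 > 10). A test constructs
exactly this case.

Every outcome carries two labels, one per reference, that name the same
event (a host-origin pair assigned to the host in step 1 of a host-first
run is `S-TP_h1` for the host and `S-TN_p1` for the parasite; the
subscript is the assignment step). The duality — TP on one side is TN on
the other, FP is FN — is enforced at aggregation time, and implies
accuracy(host) = accuracy(parasite), sensitivity(host) =
specificity(parasite), and so on; tests assert all of these on every run.

Three genuinely open points were resolved as follows, each behind a
single, visible switch or function:

* **Two-side reads in the combined run** count as FN for their origin
  organism and FP for the other. The alternative (excluding them from the
  confusion matrix) would make the two-side column invisible to the
  metrics; counting them against the origin is the reading consistent
  with treating "assigned also to the wrong genome" as a separation
  failure.
* **Wholly unmapped pairs are outside the confusion matrix.** Metrics of
  runs with a sizeable unmapped fraction stay near 1 only under this
  convention; including unmapped pairs as FN would conflate mappability
  with separability.
* **Counting is per read pair**, with a discarded-mate pair one unmapped
  unit. An undefined metric (0/0) is reported as missing (`NA`), never as
  0 or 1.

The mismatch cap is interpreted per pair rather than per mate (the
aligner parameter it models is ambiguous on this point); per pair is the
single-knob choice and is applied identically in both strategies, so the
comparison between strategies is unaffected.

## Cross-mapping analysis

One-side sets are the step-2 false negatives of each sequential order
(`S-FN_h2`, `S-FN_p2`), and, for the combined run, the `C-FN` reads minus
the two-side roster ("reads hitting only the wrong genome" — the
complement is read as an exact set difference). Remapping them to their
own genome under the relaxed cap splits over-stringent filtering
(recovered) from genuine locus absence (not recovered); the rate is
reported per pair, with an empty set yielding missing, not 0.

Two-side rosters are computed by two independent routes — the first-step
intersection of the two sequential orders, and the combined `TWO_SIDE`
category — and the package proves on synthetic data that they coincide
whenever every read's joint hit count is within the cap (they can differ
only at the cap boundary, where the sequential route can only be larger).

Locus summarisation uses union-mode counting with ambiguous discard
(the defaults of the usual gene-level counters): a pair counts for a gene
only if *every* retained placement overlaps exactly that one annotated
gene, considering either mate's aligned interval; pairs overlapping no
gene are `no_feature`; more than one gene — within a placement, across
placements, or a mix of genic and intergenic placements — is
`ambiguous`. The three groups partition the read set, which is asserted
in tests.

## Numerical and I/O choices

Internal coordinates are 0-based half-open; GFF3 output is 1-based
inclusive; SAM output is minimal (MAPQ 255, full-length `M` CIGAR,
per-mate `NM`, per-pair `NH`) and round-trips through `ingest_alignments()`,
which also accepts external SAM/BAM and groups records by name in memory,
so name-sorting is not required. All randomness flows from explicit
integer seeds (`withr::with_seed`), and identical spec + seed yields
byte-identical FASTA/GFF3/FASTQ output — tested literally by comparing
written files.

## Problem sizes used by the test and acceptance suites

The suites run on genomes of roughly 4–25 kb per side and libraries of
80–700 read pairs (500 error-free pairs for the mapper–oracle
equivalence check; 10 seeds × 3 divergence levels × 160 pairs for the
monotonicity property that the two-side count shrinks as divergence
grows; the default acceptance benchmark uses 3 500 pairs). These sizes
were chosen so every property is checked against exhaustive oracles; the
magnitudes of real libraries enter only through the bundled published
per-replicate counts, on which the report arithmetic (percentages,
replicate averages as mean count over mean processed, millions rendering)
is reproduced bit-exactly.

## Known limitations

* Hamming-only alignment: an indel in a read shifts everything downstream
  and usually unmaps the pair; real aligners tolerate it. Score-based hit
  retention (as opposed to mismatch-count thresholds) also cannot be
  represented, so a real aligner's suppression of a worse-scoring hit in
  the other genome has no analogue here.
* The relaxed-cap regime loses the exhaustiveness guarantee (see above).
* Metrics carry no uncertainty estimates; runs report point values.
* The locus summariser reports product strings only; functional
  interpretation of cross-mapped loci is out of scope.
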