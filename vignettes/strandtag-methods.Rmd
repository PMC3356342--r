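---
title: "Methods: stranded tag RNA-seq annotation and antisense discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stranded tag RNA-seq annotation and antisense discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`strandtag` re-implements, as a tested toolkit, the bespoke computational
procedures used in compact-yeast genome/transcriptome projects of the
*Candida utilis* type: a hybrid-assembled intronless genome annotated by
two *ab initio* predictors and profiled with strand-specific 50-bp tag
RNA-seq across a log-phase and a stationary-phase culture. This vignette
records the models, the tunable parameters, and the design decisions that
were genuinely open.

## The consensus annotation model

Two predictors propose flat gene models. Candidates are kept when they
span fewer than 10 consecutive `N` bases and encode at least 60 amino
acids (180 nt). Models identical in contig, strand, start and end are
*common* (predictor evidence `AB`); remaining single-predictor models are
kept unless they partially overlap, on the same strand, a model from the
other predictor with a higher accuracy class — then the less accurate one
is discarded.

Accuracy classes are monotone in homology evidence: *conserved* (best
BLASTP e-value ≤ 1e-10), *slightly conserved* (1e-10 < e ≤ 1e-5),
*hypothetical* (no qualifying hit, but called by both predictors), and
*predicted* (everything else). The two anchor e-values are the ones the
analysis is defined with; the band between them is this package's
reading, fixed so the classification is reproducible. Ties in overlap
resolution go to the longer model, then to predictor A, making the merge
deterministic; swapping the predictors swaps only the labels.

**Frameshift artifacts.** Pyrosequencing over/under-calls in homopolymer
runs insert or delete single bases in the assembly, splitting one true
gene into two predicted ORFs. Among homolog-bearing genes (best e-value ≤
1e-10; the count of genes with *any* hit is also reported, since both
denominators are in circulation), a pair sharing a best-homolog subject
is *interrupted* when the two ORFs are co-oriented on one contig with
fewer than 600 intergenic bases between them (stop-of-upstream to
start-of-downstream, exclusive) and are not mutually orthologous (mutual
e-value > 1e-5, or no mutual hit); same-homolog pairs whose intervals
intersect are *overlapping*. Rates are pair-member counts over the
homolog-bearing denominator.

## Protein families

All-vs-all similarity hits are aggregated per query–subject pair (minimum
e-value, summed HSP lengths — the aggregation is fixed here because a
"total HSP length" over multiple local alignments is otherwise
ambiguous). An edge joins two proteins when e ≤ 1e-20 and the summed HSP
length exceeds 50% (strictly) of the *shorter* sequence; the denominator
choice is this package's decision — it is symmetric and standard for
ortholog calling. Families are seeded from 3-cliques (true triangles, all
three edges required; two-edge "triangles" reduce to stars and
over-merge) and clusters sharing ≥ 2 members are merged iteratively to a
fixpoint. The merge is implemented on a derived graph whose nodes are
clusters, iterated because a merge can create new sharing relations; the
result is provably order-independent and is tested against a brute-force
enumeration-and-merge oracle. "Shares ≥ 2" (not exactly 2) is used; the
threshold is an argument of `triangle_cluster()`.

## Split-read tag mapping

The mapping contract for a 50-bp stranded tag: the 5′ 25-mer must align
with at most 2 substitutions and no indels; the tag is kept only when
exactly one such locus exists genome-wide; whether the 3′ 25-mer also
matches contiguously is recorded, never required (the 3′ half's role is
deliberately an output, exposed per alignment, because the contract's
source specifies only the 5′-half criterion and uniqueness). Multi-mapped
tags are dropped entirely rather than placed randomly.

The implementation seeds on three exact segments of the 5′ half
(8 + 8 + 9 bp): two mismatches spread over three segments always leave
one segment exact, so the seeded search is complete — note that with only
two halves a 1+1 mismatch split would defeat the pigeonhole, which is why
three seeds are used. Candidates are verified by direct comparison and
acceptance is checked against an exhaustive independent scan in the test
suite. Tags are assigned to genes by their 5′ position (a single
unambiguous rule; with 50-bp tags against ≥ 180-bp genes boundary effects
are negligible), as sense when tag and gene strands agree, antisense
otherwise; per-base depth is tracked per strand over the full footprint.

## Expression quantification

Counts are normalized per sample by the upper quartile (75th percentile)
of sense counts over *retained* genes — genes with a nonzero sense count
in at least one sample; all-zero genes are excluded from the quartile but
still reported (at 0). The percentile convention is linear interpolation
between order statistics (`quantile` type 7); the convention matters at
desk scale and is therefore pinned and mirrored by the sort-and-index
oracle in the tests. Antisense values share the sample's sense-derived
quartile: sense and antisense are reported on one comparable scale, and a
per-strand quartile would make the antisense columns incommensurable.

A gene is a *high-expression gene* (HEG) when its normalized sense value
strictly exceeds 10 — roughly the top 2% of genes under a realistic
heavy-tailed expression law. Pathways are flagged when strictly more than
10% of their members are HEGs. Cross-phase comparisons are ratioed on
normalized values; within-phase antisense:sense comparisons on raw tag
counts — each ratio is computed on the quantities it is meaningful for.
Zero denominators yield `NA` with an `infinite`/`undefined` flag rather
than a division.

## Transcript discovery

A transcribed contig is a maximal run of bases with per-base depth ≥ 2 on
one strand; a single sub-threshold base ends the run (no gap bridging —
the simplest monotone rule; the threshold is `min_expressed_depth` in the
config so sensitivity can be swept). Contigs strictly longer than 180 bp
are kept and classified: overlapping a gene on the same strand →
*genic sense*; only on the opposite strand → *antisense*; no gene →
*intergenic*. When a contig overlaps genes on both strands the
same-strand call wins, a conservative choice against antisense false
positives. The "non-coding" tally counts intergenic + antisense contigs
only. Genome expression coverage is the fraction of stranded bases with
any depth, out of single-strand length, so its ceiling is 200%.

The per-gene antisense report flags the repressive-antisense signature:
an antisense contig over the gene plus an inverse correlation (sense
down, antisense up) between the phases.

## The synthetic study system

`make_genome()` builds the study conditions every test runs under:

* **Genome.** Intronless genes (ATG start, one terminal stop, length a
  multiple of 3, ≥ 180 bp) on both strands, intergenic gaps ≥ 200 bp,
  genome GC steered to 45% through the intergenic base composition
  (matching the ~45% GC of the target genome). Gene lengths are a bimodal
  mixture (180–240 bp and 390–480 bp) so that 200 genes pack into 100 kb
  with the required gaps while long genes can host split fragments and
  antisense transcripts that survive the 60-aa filter.
* **Codon usage.** Sense codons are drawn with a mild third-position bias
  (C 1.6, T 1.2, A 0.8, G 0.6), giving a recoverable signature (e.g. TTC
  preferred over TTT) for the codon-usage oracle test.
* **Frameshifts.** A fraction (default 10%) of long genes gets a planted
  `AAAAAA` homopolymer mid-gene from which one base is deleted — the
  pyrosequencing under-call. The deletion is applied while the contig is
  being assembled, so no downstream coordinates shift; the broken gene
  keeps its span (one base shorter). These genes are deliberately
  untranslatable past the indel, and they are forced to be
  homolog-bearing: the interrupted-ORF detector is homology-driven, so
  frameshifts in homology-free genes are undetectable in principle.
* **Predictors.** Each predictor independently misses genes (default 5%),
  jitters 5′ boundaries on a 20% subset (codon-preserving, ≥ 60 aa kept),
  and emits split genes as two in-frame fragments separated by a
  sub-600-bp gap. Splitting models the broken assembly, so both
  predictors see the same fragment pair; planted frameshift genes are
  split at their indel.
* **Expression.** Per-gene relative levels are log-normal (sdlog 1.7,
  normalized to mean 1) with log-normal between-condition factors (sdlog
  0.6); counts are Poisson. The sdlog 1.7 tail analytically puts about 2%
  of genes above normalized value 10, reproducing the "top ≈ 2%" HEG
  band. Planted antisense genes are chosen as the most strongly expressed
  eligible long genes (an ADH1-like abundant transcript) and follow a
  deterministic program — sense 10× suppressed in stationary phase,
  antisense (level U(0.8, 2)) in stationary only — so the planted
  inversion is a property of the truth set, not of a noise draw, while
  selecting (rather than overwriting) expression levels leaves the
  genome's log-normal calibration intact.
* **Tags.** 50-bp single-end reads drawn uniformly inside their gene on
  the transcript strand; 2% of reads get 1–3 substitutions; ~2% of reads
  come from reserved rRNA intervals. Reads carry no indels — indel errors
  live in the assembly, not the tags, matching the mapping contract — and
  no quality model (color-space encoding is out of scope; the contract
  operates in base space).

**What passing tests do and do not show.** The synthetic system exercises
every contract end to end with known truth, but it is idealized: genes do
not overlap, expression is uniform within a gene (no 3′ bias, no UTRs),
reads never span gene boundaries, and homology is noise-free. Passing
recall/precision targets here demonstrates correctness of the machinery,
not expected performance on real libraries.

## Problem sizes and numerical choices

The test suite and the acceptance script run the end-to-end system at a
1 × 100-kb genome with 200 genes (20 antisense-planted, 20 frameshifted)
at 20× depth — small enough to map in seconds, large enough that the
upper-quartile, the HEG tail and the contig geometry are all
non-degenerate; the HEG band check uses 2,000 genes drawn directly from
the expression model, where the ~2% tail is stable. Mapping equivalence
is checked on 10⁴ mixed reads over a 20-kb genome with a planted
duplication against an exhaustive-scan oracle; triangle clustering
against a brute-force oracle on 100 random graphs of ≤ 40 vertices.
Determinism is byte-level: a pipeline rerun under one seed reproduces
identical output files (the only volatile output, a GFF3 date directive,
is stripped at write time).

Degenerate inputs are errors, not guesses: a sample whose upper quartile
is 0, reads that are not 50 bp, unknown strand symbols, negative
e-values, infeasible genome packings (the error names the limiting
parameter). Ratios with zero denominators are flagged, never computed.

## Known limitations

Hierarchical GFF3 (gene/mRNA/CDS) is out of scope — flat gene features
only. No spliced mapping (the genome is intronless; annotation-defined
junctions degenerate to genomic mapping). No differential-expression
testing beyond fold changes, and no isoform or UTR reconstruction. The
mapper is exact for its contract but is a reference implementation in R:
it maps tens of thousands of tags per second at toy-genome scale, not
hundreds of millions against a 14-Mb genome.
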