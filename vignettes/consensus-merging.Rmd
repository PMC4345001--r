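---
title: "Consensus merging of ab initio and evidence-based gene predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus merging of ab initio and evidence-based gene predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genemerge)
library(dplyr)
```

## The problem

Ab initio gene finders (GeneMark- or GLIMMER-style HMMs applied to the
genomic sequence alone) are sensitive but report genes regardless of whether
they are expressed, and their accuracy depends on their training data.
Evidence-based predictors (RNA-seq assemblers, EST or protein-homology
methods) only report what the external evidence supports, but inherit its
noise and incompleteness. The two error modes are largely complementary: a
false positive produced by one strategy is rarely reproduced by the other,
while genuinely expressed genes tend to appear in both. `genemerge`
exploits this by iterating over the ab initio ("leading") predictions,
asking for each whether any evidence-based prediction supports it, and
emitting a consensus annotation in which each accepted transcript carries a
reliability class. It is a post-processor of gene-finder output, not a gene
finder: it cannot recover a gene no input method predicted.

## Data model

All coordinates are held 0-based half-open internally, so exon length is
always `end - start`; conversion to GTF's 1-based inclusive convention
happens only at file input/output. A *gene* is a locus with one or more
*transcripts*; a transcript is an ordered chain of disjoint *exons* on one
strand of one sequence. CDS/UTR substructure is deliberately out of scope
because gene finders disagree wildly about whether and how they report it;
the exon feature carries the coding region. Exons that touch or overlap
within one transcript are fused on input (with a warning) because every
downstream computation assumes disjoint chains.

The *exonic length* of a transcript — the denominator of every supporting
overlap — is the sum of its exon lengths, not its genomic span. This
matters for spliced genes: a prediction covering the introns of a leading
transcript but none of its exons supports nothing.

## The support test

With threshold $t$ (default 0.8), an evidence transcript supports a leading
transcript in **prokaryotic mode** when the exonic nucleotides shared by the
two transcripts strictly exceed $t$ of the leading transcript's exonic
length. The comparison is asymmetric by design: the denominator is always
the ab initio prediction being tested, so a long evidence transcript
containing the leading gene still counts as full support of that gene.
Support with identical boundaries is classed `PERFECT`; support above
threshold but not identical is `SUPPORTED`; anything else is `UNSUPPORTED`.
Boundary identity, not overlap fraction 1.0, defines `PERFECT`: a
containing prediction also achieves fraction 1.0, but agreement should be
symmetric. This also makes $t = 1$ behave as "accept only perfect
overlaps" rather than rejecting everything under a strict inequality.

Two intentional asymmetries in threshold arithmetic are preserved exactly
as the method defines them:

* the nucleotide-fraction test is **strictly greater than** $t$ — a locus
  whose best overlap is exactly $0.8$ at $t = 0.8$ is unsupported;
* the exon-count rule (below) is $k \ge \lfloor t \cdot n \rfloor$ —
  greater-or-equal, with a floor.

## Eukaryotic mode: exon chains

Splicing makes per-locus overlap insufficient: an overlapping exon only
counts if it sits in a *similar exon chain*, otherwise the overlap probably
comes from a different isoform. Each leading transcript is therefore
compared to each overlapping evidence transcript by pairing exons under
three constraints: pairs must overlap genomically, each exon pairs at most
once, and pairs may not cross (order is preserved). A pair is `EXACT` when
both boundaries agree and `PARTIAL` when the shared nucleotides exceed $t$
of the leading exon's length — the global threshold is reused per exon
rather than introducing a second tunable. The pairing itself is computed by
a small dynamic programme that maximises, lexicographically, the number of
matched pairs, then exact pairs, then shared nucleotides. A greedy sweep
was rejected because a candidate exon spanning two leading exons can trick
it into a sub-maximal matching; the DP is exact and the exon counts are
tiny, so cost is irrelevant.

The classification ladder per leading transcript is:

1. `PERFECT` — some evidence transcript pairs every exon exactly and has no
   extra exons (symmetric identity);
2. `SUPPORTED` — some evidence transcript matches every leading exon within
   threshold (minor boundary wobble allowed, lower score);
3. conflict resolution (below) when two or more evidence methods overlap;
4. `PARTIAL_ACCEPTED` — with a single overlapping candidate, the exon-count
   rule $k \ge \lfloor t\,n \rfloor$ must hold **on both sides**: for the
   leading transcript ($n$ = its exon count) and for the candidate ($n$ =
   the candidate's exon count), with at least one exon actually matched;
5. `UNSUPPORTED` otherwise — the transcript goes to the side file.

Step 4 also covers a case the method description leaves open: a leading
transcript overlapped by exactly one disagreeing evidence transcript, where
conflict resolution (which needs two) cannot apply. We apply the both-sides
exon-count rule directly; this is an interpretation, and it is the
configurable threshold that controls its strictness.

## Conflict resolution

When no evidence transcript fully supports the leading transcript but
several (from distinct methods) overlap it, the engine asks whether the
evidence agrees *with itself*: if two candidates from different methods
mutually match each other's full chains while each fails against the
leading transcript, the leading prediction is judged incorrect and the
concordant evidence structure is emitted instead (class `SUPPORTED`, all
agreeing methods as sources, each structure at most once per run). If the
evidence also disagrees internally, the leading transcript survives as
`PARTIAL_ACCEPTED` if the both-sides exon-count rule holds against one of
the candidates; otherwise nothing is emitted for this locus. The agreement
group is seeded deterministically with the first mutually matching
cross-method pair in (method, transcript) order and extended with every
candidate consistent with all chosen members, so results do not depend on
input order.

## Novel genes

With at least two evidence sets, transcripts that no ab initio prediction
overlaps above threshold but that at least `min_evidence_for_novel`
(default 2) distinct evidence methods predict concordantly are appended as
`NOVEL_EVIDENCE` records. Mutually supporting transcripts are emitted once
with all supporters as sources. Requiring two independent evidence methods
is what distinguishes a candidate novel gene from a single method's
artifact; it is also why calling this with one evidence set is an error
rather than a silent no-op.

## Scores and outputs

Classes map to a numeric score written to the GTF score column:
`PERFECT` 1.0, `SUPPORTED` 0.75, `PARTIAL_ACCEPTED` 0.5, `NOVEL_EVIDENCE`
0.5. Only the ordering `PERFECT > SUPPORTED` is semantically meaningful;
the values are conventions and configurable via `merge_config(score_map=)`.
A merge returns four artifacts: the consensus records, a tracking table
linking every record to the original predictions that generated it, and two
side sets (ab initio transcripts without support; evidence transcripts that
supported nothing) for downstream analysis of unexpressed or candidate
novel genes. The engine contains no randomness: identical inputs and
configuration give byte-identical files.

## Strand policy

Strand handling is configurable because converted formats differ:
`require_match` (default) only compares equal strands; `ignore_unstranded`
lets `"."` records (e.g. Glimmer3 conversions, whose strand is inferred
from the frame sign and may be missing) match either strand; `ignore_all`
disables the restriction. Cross-strand "support" is biologically dubious,
which is why the strict policy is the default.

## Evaluation conventions

`evaluate_predictions()` reports sensitivity, specificity and F-measure at
exon and transcript level. **"Specificity" here is precision**,
TP/(TP+FP), following the convention of transcript-assembly evaluation
tools; a true-negative rate is not defined on open genomic coordinates.
Exon-level true positives require boundary-identical exons, with identical
coordinates deduplicated on each side first so shared exons of isoforms are
counted once. Transcript-level matching requires the full chain: internal
boundaries exactly, terminal boundaries within `terminal_tolerance`
(default 0). The tolerance exists because assemblers that do not model
start/stop codons systematically miss terminal boundaries while getting
every internal splice site right; at tolerance 0 such transcripts count as
both a false positive and a false negative. `missed`/`novel` count
features with no overlap whatsoever. F is defined as 0 when sensitivity
and specificity are both 0, and ratios with zero denominators are `NA`.

## The simulator

`simulate_truth()` emulates the *annotation* layer of a simulation study:
non-overlapping loci placed left to right with uniform intergenic gaps
(200–2000 nt), prokaryotic genes 300–3000 nt, eukaryotic exons 50–400 nt
and introns 50–2000 nt, 1–3 isoforms built by skipping one internal exon.
Uniform length distributions are the least-assumption choice where nothing
better is specified, and all ranges are arguments. `sample_expressed()`
retains a seeded 70% of genes by default, reflecting that only part of an
annotation is expressed under any one condition; the retained subset is the
ground truth for anything evidence-derived. `perturb_predictions()` then
derives one simulated gene finder per `error_profile()`: whole-gene drops
(exact seeded counts), Gaussian boundary jitter, internal exon drops
(partial transcripts from thin coverage), a fixed 3' terminal extension
(the characteristic wrong-terminal-exon error of hybrid ab initio
predictors), and spurious single-exon genes placed in intergenic gaps with
a 50 nt margin. Giving each method a disjoint gap pool (`fp_pools()`)
makes false positives method-unique *by construction*, which turns the
central filtering claim — consensus removes method-unique errors — into an
exact property rather than a statistical tendency, testable as merged
specificity equal to 1.

What the simulator does **not** emulate: nucleotide sequence, read-level
coverage profiles, mapping artifacts, overlapping genes, operons,
trans-splicing, or correlated errors between methods. Passing tests on
these fixtures therefore demonstrate the combination logic, not the
performance of any real gene finder; on real data the inputs' error modes
are only approximately complementary and merged specificity will be high
but not exactly 1.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 200 prokaryotic genes
(70% expressed → 140; ab initio profile: 5% drop, 30% false positives;
evidence profile: 10% drop, 30% false positives) and 40–60 eukaryotic genes
with 4 nt boundary jitter and 5% exon drops — large enough that every
class and both side files are populated, small enough that brute-force
oracles (position-set overlap counts, exhaustive non-crossing matchings)
can verify the optimised paths on hundreds of random instances. Under the
exact drop counts, merged sensitivity on the prokaryotic fixture is bounded
below by $(140 - 14 - 10)/140 \approx 0.83$, and the observed value sits
above it. All randomness flows through explicit seeds via `withr`;
threshold comparisons use plain floating arithmetic since $t$ enters only
via one multiplication.

## Known limitations

* Multi-transcript loci in prokaryotic mode are processed per transcript
  with a warning rather than rejected.
* Replacement emission can, in principle, output two near-identical
  structures when two evidence methods agree only within threshold rather
  than exactly; structures are deduplicated per run by identity, not by
  similarity.
* The evaluator implements exon- and transcript-level metrics only — no
  intron-chain or base-level metrics, and none of the per-transcript class
  codes of full assembly-evaluation suites.
* Genes wrapping around a circular prokaryotic origin are out of scope.
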