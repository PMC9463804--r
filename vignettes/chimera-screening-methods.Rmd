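---
title: "Screening, classifying and quantifying chimeric RNA candidates"
author: "chimeraScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening, classifying and quantifying chimeric RNA candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeraScreen)
```

## The problem

Fusion callers applied to bulk RNA-seq emit large candidate lists in
which genuine chimeric RNAs — transcripts joining exonic sequence from
two parental genes, whether by genomic rearrangement, read-through
transcription of adjacent genes (cis-SAGe), or trans-splicing — are
buried among alignment artifacts. Studies that compare chimeric-RNA
repertoires across conditions (for instance across hormone-sensitive,
castration-resistant and neuroendocrine prostate cancer cell lines)
follow a common recipe: filter the candidate list, characterise what
remains along a small set of biological axes, derive condition-specific
sets, re-quantify selected chimeras in independent read sets by junction
probe matching, and examine the protein product of the most interesting
fusion. chimeraScreen implements that recipe as composable, tested R
functions with a deterministic synthetic-data generator underneath.

## The coordinate model

All coordinates are 1-based, fully closed intervals — the GTF convention
— and every reader converts at the boundary, so a single convention holds
internally. Exons and CDS segments are stored 5′→3′ in transcription
direction; on the minus strand that is descending genomic coordinate, and
the *donor* edge of an exon (the 5′ side of a junction) is its
genomically smallest base. A junction is the pair (`pos5`, `pos3`):
`pos5` the last transcribed base of the 5′ segment, `pos3` the first base
of the 3′ segment.

Exon-boundary matching is exact-position against **any** transcript of
the gene. The alternative — one canonical transcript per gene — would
make the E/E call depend on an arbitrary canonical choice; the
any-transcript rule is deterministic and matches how "known exon
boundaries" are used in practice. Caller imprecision of a few bases is
*not* absorbed: a ±1 bp junction becomes E/M or M/E and the call is
logged, never silently shifted.

## The filtering cascade

Stages run in a fixed order (score → M/M → blacklist → normal-sample →
homology), each appending `(input, removed, output)` to a trace with the
invariant `output = input − removed`; the blacklist and normal-sample
stages are pure set subtractions and commute.

* **Score filter.** Candidates with caller confidence below 0.6 are
  discarded; the threshold is inclusive on the keep side (0.60 is kept)
  because the discard rule is "score < 0.6".
* **M/M removal.** Both-sides-mid-exon junctions validate poorly and are
  removed wholesale. Calls whose junctions fall outside annotated exons
  entirely cannot be classified; they are removed at this stage too, but
  logged separately rather than silently merged into M/M.
* **Blacklist.** Matching is by **ordered** 5′→3′ symbol pair: chimera
  directionality is biologically meaningful, and an A→B chimera in
  normal tissue says nothing about B→A.
* **Normal-sample subtraction.** A chimera (gene pair + exact junction)
  seen in any designated normal sample is removed from *all* samples.
* **Flank homology.** The published pipelines run BLAT here; no BLAT
  parameters are ever given, so chimeraScreen ships a self-contained
  local-alignment screen that captures the intent (junctions explainable
  by paralogy or self-homology are artifacts): align the 50 nt upstream
  of `pos5` (transcription direction) against the 50 nt downstream of
  `pos3` with match +1, mismatch −1, gap −2, and drop when identity over
  the aligned span is ≥ 0.8 with span ≥ 20 nt. All four numbers are
  configuration keys. The span floor stops short perfect seeds (common by
  chance) from triggering a drop; with these scores an alignment passing
  both thresholds scores ≥ 8, far above what unrelated 50-mers reach.
  Flanks truncated by a contig end are used as-is with a warning; if both
  flanks end up below 20 nt the call is kept with a warning rather than
  silently screened.

Chimera identity across samples is the exact junction coordinate pair. A
±5 bp near-duplicate merge exists behind the `merge_window` configuration
key but defaults to off — exact identity is reproducible and the
simulator never generates near-duplicates.

## Reading-frame prediction

For coding transcript pairs whose CDS contains the respective junction
site, let `L5` = CDS bases of the 5′ transcript at or upstream of `pos5`
(inclusive) and `phase3` = CDS offset of `pos3` modulo 3. The fused
coding sequence preserves the 3′ parent's downstream codons exactly when
`L5 mod 3 == phase3`; that is the in-frame test, applied over **any**
pair of coding transcripts (optimistic, order-free). `NA` is returned
when *either* parent lacks CDS *or* either junction site falls in a UTR
of every coding transcript. The published category description conflates
the two conditions in one sentence; the disjunctive reading is the only
one under which the large NA fractions reported for real cohorts
(70–85%) are reachable, and it is the biologically sensible one — a
junction in a UTR has no defined reading frame regardless of the
partner's biotype.

## Junction-spanning read counting

The probe is the last 30 transcribed bases of the 5′ segment plus the
first 30 of the 3′ segment (truncated to what exists; a caller-provided
junction sequence is used verbatim). 30 + 30 was chosen to sit inside a
typical ≥ 75 nt read while remaining specific; it is the `flank`
configuration key. Probes shorter than 20 nt are refused as unspecific.

A read counts when the **full probe** matches some substring of the read
or of its reverse complement within `k` edit operations
(substitutions + indels — the agrep cost model; a substitutions-only mode
would undercount reads with a single indel). Each read counts at most
once. The matcher is Myers' bit-parallel semi-global algorithm (O(n) per
read for probes ≤ 64 nt, one 64-bit word; plain dynamic programming above
that), with `N` on either side matching nothing. The test suite and the
acceptance script verify the matcher against an independent
dynamic-programming oracle on ≥ 1000 random instances.

Counts are normalised as CPM over **total reads** in the sample — the
published analyses say only "normalized read counts" without naming the
denominator, and total reads is the only denominator computable without
an alignment step. Detection bins follow the published footnote scale:
`−` for mean reads < 1, `+` for [1, 5), `++` for [5, 10), `+++` for
≥ 10, with boundaries verified at 1 − ε, 1, 5 − ε, 5, 10 − ε, 10.

## Product scores

NE activity is the plain product CHGA × NSE × SYP of raw marker read
counts — deliberately without the zero → 1 substitution, which the
published formula states only for the chimeric-RNA score. The
chimeric-RNA score multiplies the 15-panel raw counts with every zero
replaced by 1 (an all-zero panel scores 1, the empty product); the panel
is a configuration list, and the size is enforced so a truncated panel
cannot silently change the score's scale. HIGH is `score ≥ 1000`,
inclusive as printed. Raw (not normalised) counts are the default input,
matching the formula's wording. The group comparison is descriptive
(n, mean, median) — with three or four samples per group a hypothesis
test would be theatre.

## Fusion ORF prediction

A fused transcript is the first `n5` exons of the 5′ transcript plus
exons `first3`…end of the 3′ transcript, spliced in transcription
orientation. Translation starts at the 5′ parent's annotated start codon
when it lies in the retained portion (and still reads ATG); otherwise at
the first ATG of the fused sequence — no Kozak scoring, because a
deterministic rule is testable and the one documented case (a 5′-UTR-only
fusion translated from the 3′ gene's own start) is exactly what first-ATG
produces when the upstream region is start-free. Translation uses the
standard code, single forward frame, stopping at the first stop codon.

The e2e4-vs-e1e4 comparison — the two-exon fusion isoform encodes a
31-residue N-terminal extension over the one-exon isoform, 5 residues
from the 5′ gene's exon-2 ORF and 26 from the 3′ gene's exon 4 upstream
of its own start — is reproduced on `example_tmprss2_erg()`, a synthetic
miniature of the relevant exon/CDS architecture: exon 1 entirely UTR, the
start codon 15 nt before the exon-2 donor edge, and 78 nt of exon 4
upstream of the 3′ gene's start codon. The real human transcripts would
need a reference download the package deliberately avoids; the exact
TMPRSS2 transcript behind the published 5 + 26 split is not pinned in the
source material, so the synthetic fixture encodes the split by
construction and is labelled synthetic everywhere.

## What the simulator emulates — and what it does not

`simulate_genome()` packs non-overlapping genes with a deterministic
strand pattern (`+ + − −`) and a deterministic coding/lncRNA pattern per
block of ten genes, so that same-strand adjacent pairs of both biotypes
always exist and every junction × relation × frame combination is
plantable. Coding genes carry one transcript with a well-formed CDS
(starts ATG, ends stop, length divisible by 3, no internal in-frame
stop). Default dimensions — 2 chromosomes × 20 genes, 3–6 exons of
90–240 nt, introns 60–200 nt, UTRs 30–80 nt — are miniature but
structurally faithful: large enough that every category is satisfiable
many times over, small enough that the full suite runs in about a minute.

`plant_fusions()` chooses gene pairs and junction positions satisfying
each requested category exactly, emits caller-style rows (scores uniform
in [0, 1] unless pinned) and ground-truth records, and plants two decoy
types: *normal decoys* (the same chimera emitted additionally in a
normal sample, so normal-sample subtraction must remove it everywhere)
and *homology decoys* (the genome is edited so the two 50-nt junction
flanks are identical; the genes involved are reserved so the edit cannot
corrupt another plant). `simulate_reads()` draws background reads from
unfused transcripts — by construction they never span a planted junction
— and exactly `read_depth` junction-straddling reads per fusion with ≥ 30
nt on each side, i.i.d. substitution errors at the configured rate
(indels available but default 0, keeping the k = 1 recovery bound clean),
and every second read reverse-complemented. The seed fully determines
every output byte.

What passing tests on this cohort show: the classifiers, cascade,
counter and scorer are *correct* against known truth. What they do not
show: robustness to realistic expression dispersion, GC and positional
bias, quality-score-correlated errors, paired-end structure, caller
coordinate jitter, or annotation incompleteness — none of which the
generator models.

## Numerical and degenerate-input choices

* Fractions in category profiles sum to 1 within 1e−12 per axis and
  group; empty groups report `NA`, never 0.
* The M/M row is omitted from junction-axis profiles once the cascade
  has removed the class, so fractions describe the categories actually
  present.
* Duplicate call rows (same gene pair, junction and sample) collapse
  with a warning on ingest; conflicting transcript-to-gene assignments
  and overlapping duplicate exons are hard errors with line numbers.
* Scores are validated into [0, 1]; intragenic candidates
  (`gene5 == gene3`) are rejected by default.
* Product scores use double precision; a saturated 15-panel of counts
  ~10³ stays far below overflow.
* Run reports serialise with fixed key order so identical runs are
  byte-identical.

## Problem sizes used by the tests and acceptance script

Matcher-vs-oracle: 1000 random (probe 20–60 nt, read 50–150 nt)
instances. Category recovery: 216 planted fusions (6 per combination).
Cascade check: 36 plants + 4 normal + 3 homology decoys. Read recovery:
4 fusions × 40 spanning reads per seed, five seeds at 0.5% substitutions.
These sizes give exact or tightly concentrated expectations (at 0.5%
error the probability that a 60-nt probe window carries ≥ 2 errors is
≈ 3.7%, so the expected k = 1 recovery is ≈ 96%, comfortably above the
95% requirement) while keeping the whole suite near one minute.

## Known limitations

Single-end reads only; no BAM/SAM path (counting is alignment-free by
design); GTF only (no GFF3); no splice-motif scoring or novel splice-site
prediction; the homology screen is a local-alignment surrogate with its
own parameters, not a BLAT re-implementation; survival/correlation
analyses on clinical cohorts are out of scope — standard tools
(`survival`, `stats::cor.test`) already do them.
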