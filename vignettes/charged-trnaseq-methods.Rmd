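---
title: "Methods: charged tRNA-seq analysis and coverage-based expression assessment"
author: "tRNAcharge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: charged tRNA-seq analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, parameter choices and numerical
conventions behind `tRNAcharge`, in the spirit of a methods section:
what each stage assumes, which knobs matter, and what the simulation
framework does and does not establish about real data.

## 1. The periodate readout

Aminoacylation esterifies an amino acid to the 3'-terminal adenosine of
a mature tRNA. Sodium periodate oxidizes the free 2',3'-diol of an
*uncharged* terminus; beta-elimination then removes that terminal
nucleotide. A charged terminus is protected. After treatment, an
uncharged molecule ends `...CC` (one nucleotide short of the CCA tail)
while a charged one retains `...CCA`. The analysis therefore reduces
charging to 3'-endpoint classification of aligned reads, and the
per-gene charged percentage is

```
charged% = 100 * n(CCA_intact) / (n(CCA_intact) + n(CC_minus1))
```

**Exclusions.** Reads missing two or more 3' nucleotides are excluded
from numerator and denominator: a single-nucleotide loss is the
chemistry's signature, anything deeper reflects exonucleolytic
degradation or incomplete synthesis and carries no charging
information. The estimator is by construction invariant to the amount
of deep truncation (a tested property).

**Read threshold.** A per-library minimum of more than 30
post-exclusion reads gates each estimate. The threshold is applied to
the post-exclusion denominator — the reads the percentage is actually
computed from — which is the conservative of the two possible readings.

**Replicate averaging.** The replicate summary is an unweighted mean of
per-library percentages over qualifying libraries (not a pooled-count
ratio), so one deep library cannot dominate; the per-library estimates
remain available for pooled analyses.

**Spike-in validation.** A synthetic spike-in tRNA is uncharged by
construction, so its treated-library charged percentage estimates the
periodate *escape* rate. Any treated library whose spike-in exceeds 10%
(configurable) fails validation and its estimates are flagged
unreliable downstream. The simulator's default periodate efficiency is
0.98 — "near complete" removal — a modeling choice, configurable, since
the chemistry's efficiency is protocol-dependent and rarely quantified.

## 2. References, collapsing, and unique mapping

References are mature gene bodies *without* the post-transcriptional
CCA (a `cca_encoded` flag handles the uncommon genomically encoded
case). Metadata travel in a sidecar TSV rather than FASTA headers,
keeping the FASTA standard-compliant.

Multi-copy genes with byte-identical sequence are indistinguishable in
mapping, so references are collapsed into groups by exact full-length
string equality before alignment; a read hitting a two-member group is
still uniquely mapped at group level. Near-identical copies (for
example two gene copies differing by a single substitution at the
discriminator base) are *not* merged: they are mapped competitively,
and a read carrying no discriminating information lands on neither
(tie, ambiguous). Whether competitive or separate mapping better
matches any particular external protocol is surfaced in the
configuration rather than hidden. References identical to a competing
genome's sequence (for example mitochondrial gene copies identical to
their plastid counterparts) can be excluded up front, since no read
can be attributed to either locus.

## 3. Alignment

Reads are aligned to each group's CCA-extended model with semi-global
("fit") alignment: the read aligns end to end, reference overhangs are
free. This makes the 3' alignment endpoint — the quantity the entire
charging readout depends on — a first-class alignment result rather
than an artifact of soft-clipping heuristics. Scoring defaults are
match +2, mismatch -3, gap of length *k* costing 5 + 2*k*; reads
scoring below 0.6 x (2 x read length) are unmapped. These defaults are
strict enough to separate tRNA isoacceptors (60-90 nt, typically well
diverged) while tolerating the elevated mismatch rates that
modification-induced misincorporation produces. Up to 3 bases may be
clipped from the read 5' end without penalty, absorbing
reverse-transcriptase terminal-transferase additions; the smallest
sufficient clip is chosen deterministically.

Ties in best score across distinct groups are never broken arbitrarily:
the read is ambiguous and excluded from every downstream count, both
numerator and denominator. The production aligner is Biostrings'
pairwise alignment; its scores are checked against an independent
full-matrix affine-gap dynamic program in the test suite, and
externally produced SAM (CIGAR + MD) can be ingested into the same
event representation.

## 4. Tail classification

Classification is endpoint-based. With model length `L` (gene body +
CCA), `missing = L - ref_end`:

* `missing = 0` — `CCA_intact`;
* `missing = 1` — `CC_minus1`, the periodate signature, *unless* the
  gene's discriminator is C and the read's terminal bases are `CCA`, in
  which case the read is a post-transcriptional **CA addition**: with a
  C discriminator, CA and CCA additions both read `...CCA` and only the
  endpoint separates them;
* `missing >= 2` — `truncated_k`.

Endpoint-based primary classification is robust to internal errors;
terminal base content is consulted only for the CA diagnosis, and for
non-C-discriminator genes an endpoint one short is always `CC_minus1`.
The classifier is tested exhaustively against a string-suffix oracle
over all deletion depths 0-10 for both tail types and all discriminator
bases.

**The CA corner case.** A CA-tailed molecule that lost its terminal A
(uncharged, treated) ends at `L - 2` — structurally indistinguishable
from a CCA-tailed read truncated by two. The CA-cohort estimator
therefore uses endpoint `L - 1` (terminal A) as its intact state and
the endpoint-truncation-2 class as its loss state, and this
reclassification is explicit in the output (`tail_class_context`).
In libraries where deep truncation of CCA-tailed molecules is common,
the CA-cohort denominator is contaminated by that class; the census
keeps both interpretations' raw counts visible. The CA/CCA fold
comparison reports both the ratio of replicate-averaged percentages and
per-library ratios with their mean, flagging infinite ratios.

## 5. Modification profiles

Per-position depth, mismatch and deletion rates are computed from
uniquely mapped reads after excluding reads lacking more than 7
3' nucleotides, on linear 0-based coordinates of the representative
sequence. Canonical (structural) tRNA numbering is deliberately out of
scope — it requires structural alignment — so the canonical "position
37" hotspot is operationalized as *anticodon-relative offset +1* (the
position immediately 3' of the anticodon's last base). The anticodon
coordinate comes from metadata when provided, else from a unique
occurrence of the anticodon trimer in the central half of the gene
body; if neither is available the profile is emitted with the offset
missing and a warning.

Variant flagging uses combined mismatch + deletion rate >= 0.10 at
depth >= 50 by default; both are configurable since published analyses
report qualitative "increases in sequence variants" rather than a
threshold. The three 5'-terminal positions are never flagged
(terminal-transferase artifacts produce 5' mismatches). Gap placement
within homopolymer runs is ambiguous — an aligner may left- or
right-align a deletion — so positional deletion rates should be read
over a small window, as the tests do.

Hard-stop detection reports positions whose depth falls below half
(configurable) of the running median of the next 10 positions on the
3' side: reverse transcription proceeds 3'->5', so a blocking
modification collapses coverage 5' of the stop while gradual decay from
ordinary truncation does not trigger the criterion.

## 6. Expression quantification

Expression is reads per million uniquely mapped *to this reference
set*: ambiguous and unmapped reads enter neither numerator nor
denominator, per-library totals are exactly 10^6, and the measure is
scale invariant. Spike-in reads are exogenous and excluded from the
denominator by default (a flag includes them); whether nuclear-subset
reads belong in the denominator is likewise configuration, defaulting
to all mapped-to-reference unique reads. Expression is reported from
untreated control libraries, since periodate treatment distorts
abundance. Locus families (e.g. several gene copies of one
isoacceptor) are aggregated by summing counts and tpm, with each
group's share of the family reported — this is what resolves how reads
distribute between identical duplicates and a near-identical third
copy. tRNA-seq ligation and RT biases are not corrected; between-gene
abundance comparisons should be read cautiously, as in any tRNA-seq
quantification.

## 7. mRNA coverage and the intergenic percentile

Coverage is per-position read count, split by transcript strand
(`read1-forward` convention by default, flippable for dUTP-style
protocols). Windows are non-overlapping 100 bp means, the final partial
window averaged over its true length, reverse-strand values negated for
plotting. Internally coordinates are 0-based half-open; GFF/BED input
is converted at the boundary by rtracklayer.

The intergenic site set is every position not covered by any annotated
gene on either strand, with a configurable flank exclusion (default 0,
since published analyses seldom state their mask). The query region's
median per-site depth is ranked in the intergenic per-site depth
distribution with the mid-rank tie rule — ties count half, making the
percentile symmetric. Depth is strand-summed by default (the question
is total transcription of a region); strand-specific modes exist. The
top-5% statistic counts region sites strictly above the intergenic
95th percentile. With integer depths, ties at the threshold push the
*null* occupancy below 0.05; the report therefore also carries the
intergenic set's own above-threshold fraction as the proper null
reference, and the acceptance checks compare against it. Replicate
agreement is the Pearson correlation of log(depth + 1) across windows,
both strands concatenated, undefined (NA) for zero-variance input.

## 8. The simulator: what it models and what it does not

The tRNA-seq generator draws, per read: gene (by abundance weight),
tail (CCA, or CA with per-gene probability; genes with genomic CCA get
no addition), charging state (per-gene fraction, separately
configurable for CA-tailed molecules, forced to 0 for spike-ins),
periodate removal of one terminal nucleotide for unprotected molecules
in treated libraries (efficiency 0.98 by default), additional 3'
truncation from a configurable distribution, site-specific
misincorporation/deletion, 5' untemplated extension of 1-3 nt, and
uniform base-call error. Periodate chemistry removes *exactly one*
nucleotide — the readout only distinguishes intact from shortened
tails — and deeper chemical degradation is delegated to the generic
truncation channel. Quality strings are constant (`I`); the pipeline
does not use qualities. The mRNA generator places uniform reads within
features at per-feature depth plus uniform background on both strands
and emits alignments (optionally SAM) directly, so coverage statistics
are tested independently of any aligner.

Not modeled: realistic quality profiles, PCR duplication, and the
ligation/RT sequence biases known to distort tRNA-seq abundances.
Passing simulation-based tests therefore demonstrates that the
*inference machinery* is correct under the stated generative model; it
does not certify abundance accuracy on real libraries, where bias
correction is out of scope. Both generators are byte-deterministic
given a seed, and the caller's RNG state is left untouched.

## 9. Problem sizes and numerical conventions

The test suite and acceptance script run entirely on simulated data at
sizes chosen to keep binomial/Poisson sampling error well inside the
asserted tolerances on a single CPU: 2,000 reads per gene for the
charging-recovery grid (99% exact binomial acceptance bounds), 5,000
reads per cohort for the CA/CCA fold comparison, 500 random pairs for
the aligner-vs-DP equivalence, 100 random instances for the percentile
oracle, and 10-20 replicate simulations of a 12-kb gene-dense scaffold
for the coverage statistics. Score comparisons use an absolute
tolerance of 1e-9; percentile and share computations are exact integer
arithmetic. Group ids, member lists and table orderings use radix
(C-locale) sorting so outputs are locale-independent and runs are
byte-reproducible, which the manifest-bearing pipeline tests assert.

## 10. Known limitations

* Canonical tRNA numbering (and hence literature positions like "26G")
  is not computed; positions are linear or anticodon-relative.
* The CA-cohort loss class is confounded with doubly truncated
  CCA-tailed reads (section 4); interpret CA-cohort charging where deep
  truncation is rare, or inspect the census directly.
* Competitive mapping between near-identical references discards
  genuinely uninformative reads by design; separate-mapping protocols
  will report higher per-copy counts.
* Absolute charging levels are endpoint proportions, not calibrated
  against chemical deacylation series, and the method does not identify
  which amino acid is loaded.
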