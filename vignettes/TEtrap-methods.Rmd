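---
title: "Characterizing an expanding transposon as a young piRNA cluster"
author: "TEtrap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing an expanding transposon as a young piRNA cluster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

Some transposable elements are not quiet remnants: a full-length LTR
retrotransposon can be actively mobilizing in a cell population while at the
same time behaving like a piRNA cluster — producing abundant 23–32 nt
PIWI-interacting RNAs with the ping-pong and phased-biogenesis signatures,
trapping other mobile elements inside its copies, and carrying open-chromatin
marks. TEtrap implements the computational workflow needed to characterize
such an element from sequencing data:

1. novel-insertion discovery from long-read structural-variant breakends;
2. homology-based grouping of the discovered insert sequences and an
   activity ranking (new vs old genomic area);
3. piRNA ping-pong and phasing z-score statistics with stranded coverage;
4. SNP-based attribution of small RNAs and mRNAs to individual element
   copies;
5. long-read genotyping of insertion sites (insertion-allele ratio);
6. RPKM expression and ChIP-enrichment quantification across conditions.

Because the real measurements require cell-line sequencing libraries, the
package ships a first-class synthetic-data module that generates toy
genomes, element expansions, breakends, long reads and small-RNA libraries
with a complete truth channel, so that every stage can be validated against
known answers. All empirical statements in this vignette are the ones the
package's test-suite and acceptance script compute.

## Data model and coordinate convention

All genomic positions inside the package are 1-based closed intervals, the
native convention of `GRanges`/`IRanges`/`Biostrings`, which the package
uses as its containers. Conversion happens only at format boundaries: BED
input/output shifts by one (via `rtracklayer`), VCF and SAM are already
1-based. Keeping a single convention end-to-end eliminates off-by-one drift;
choosing the Bioconductor convention (rather than 0-based half-open) means
no conversions at all between internal modules.

One derived quantity needs care: the *length* of a called insert is defined
as the span between its two donor junction coordinates
(`donor_end - donor_start`), mirroring how junction coordinates are
reported by SV callers; the width of the donor interval as a closed
interval is one larger. The size filter operates on the junction span; the
"new area" of a group sums the insert *sequence* lengths.

## Insert calling from breakends

A breakend (VCF 4.2 `BND`) joins two genomic positions, each with a side
flag naming the side of the coordinate on which the junction lies. Two
breakends are called as one insertion when

* their acceptor-side coordinates lie on the same chromosome **less than**
  `maxGap` (default 100) bp apart — the bound is strict;
* the two acceptor side flags oppose (one `right`: the junction after the
  left flank; one `left`: the junction before the right flank);
* the two donor-side positions share a chromosome and their flags are
  consistent with a single inserted segment: for the same orientation the
  junction linked to the acceptor-`right` flank carries the donor's lower
  coordinate with flag `left` and the other the higher coordinate with flag
  `right`; for an inverted insertion both relations flip.

The figure-style geometry does not dictate a tie-break when several
pairings compete, so one had to be chosen: candidates are ranked by
smallest acceptor gap, then smallest donor span, and resolved greedily with
each breakend participating in at most one call. This is deterministic,
order-invariant (ties beyond the ranking keys can only occur between
identical records), and equals exhaustive all-pairs pairing on random
instances — a property the tests check against an independently coded
brute-force oracle. Unpairable breakends are retained in a residual table,
never dropped silently.

Size filtering keeps calls with span in `[100, 10000]` bp by default. The
bounds are inclusive: the source range is quoted only as "10^2 to 10^4",
and inclusive bounds are the least surprising reading.

## Homology grouping and the activity ratio

Insert sequences are compared all-vs-all with the package's seed-and-extend
local aligner: exact 11-mer seeds (via `matchPDict`) define diagonals, each
diagonal is scanned for its maximal-scoring ungapped segment (a vectorized
Kadane scan with match +1 / mismatch −2), and candidate hits are refined by
a gapped local `pairwiseAlignment` (gap open −5, extend −2) over a padded
window. Both query strands are searched. Significance uses the
Karlin–Altschul expectation `E = K·m·n·exp(−λS)` with `(K, λ) = (0.28,
1.07)` fixed for this scoring scheme, applying ungapped statistics to
gapped scores. These constants are a calibration of the built-in aligner,
config-overridable; only the decision threshold, e-value strictly below
`1e-100`, is a scientific parameter of the workflow. Because e-values this
small underflow double precision, `log10_evalue` is the authoritative
significance measure and the `evalue` column saturates at `1e-320`. The
aligner is a pluggable seam: any tool producing the same hit table can be
substituted without changing downstream stages.

Groups are the connected components of the undirected graph whose edges are
significant hits in either direction — transitive bridging is intentional:
two inserts without direct homology that both hit a longer third insert
belong to one family. Groups are numbered by descending member count
(group 1 = largest), ties by smallest member id; groups with ≥ 5 members
are flagged as focus groups. The representative of a group is its longest
member, ties broken by lexicographically smallest id.

The activity ratio of a group is `new_area / old_area`, where `old_area`
is the total genomic length covered by the **union** of the
representative's significant hits against the reference genome (regions,
hence merged), and `new_area` is the **plain sum** of the member insert
lengths (distinct sequences, not genome intervals). A group with no
significant genomic homology is flagged with an infinite ratio rather than
an error: it is precisely the "entirely new" case worth surfacing. No
minimum alignment length is imposed beyond the e-value threshold; this is
noted as a sensitivity knob.

## Ping-pong and phasing statistics

Reads of ≥ 23 nt are treated as piRNAs; the ping-pong statistic is
computed on the 23–32 nt subset. Both statistics are built from weighted
pair enumeration over mapped placements, with each (upstream, downstream)
placement pair contributing weight 1:

* **Ping-pong**: for every opposite-strand pair, the 5'–5' overlap
  `k = (minus-strand 5') − (plus-strand 5') + 1` is accumulated over
  `k ∈ 1..20`; frequencies are the normalized histogram; the z-score is
  taken at `k = 10` against the background positions `{1..9, 11..20}`.
* **Phasing**: for every same-strand ordered pair, the distance from the
  upstream read's 3' end to the downstream read's 5' end is accumulated
  over `d ∈ 0..19`; immediately head-to-tail reads give `d = 1` (the focal
  position) and a 1-nt overlap gives `d = 0`; background `{0, 2..19}`.

`z = (f(focal) − mean(f(background))) / sd(f(background))`, with `sd` the
sample standard deviation (n−1 denominator) over the background positions
— the definition of "standard deviation of the background" is not more
specific than that, and the sample form is the conventional choice.
Degenerate cases are flagged, not propagated as NaN: a library with no
pair events inside the window has an undefined histogram, and a histogram
with all mass at the focal position (background sd 0) has an undefined z.

Pair weighting makes the frequencies — and hence z — exactly invariant
under uniform duplication of the library, which the tests assert.
Multi-mapped placements all contribute, matching the workflow's permissive
multi-mapping; a `uniqueOnly` flag enables the restrictive variant for
sensitivity analyses. The implementation accumulates products of 5'/3'
end-position tallies rather than looping over pairs; it is checked for
exact equality against a quadratic brute-force pair scan on hundreds of
random libraries.

Stranded per-nucleotide coverage counts each placement once, clips reads to
the region, and reports sense and antisense separately (antisense is
conventionally plotted negative; the vectors themselves are nonnegative).

## SNP sites and allele composition across copies

Recently expanded copies are near-identical, so they can be aligned
pairwise to one reference copy and projected onto its coordinate system:
the copy alignment is a matrix with one column per reference position, a
deletion shown as a gap, and copy insertions (which carry no reference
coordinate and can never be substitution SNPs) dropped. A copy below 90 %
identity to the reference aborts with an error — the method's assumptions
do not hold outside the near-identical regime. A column is a SNP site iff
it holds at least two distinct nucleotides and **no** gap: the sites are
substitution polymorphisms only.

Long RNA reads are tiled into non-overlapping 33-nt windows (terminal
remainders dropped), and small reads/tiles are placed on the single
reference copy by ungapped matching on both strands with at most 2
mismatches — reads from sibling copies map within this allowance precisely
because copies are near-identical. Multi-mapped reads contribute once per
read at their best placement by default (fewest mismatches, then leftmost,
plus strand first); a `perPlacement` switch counts every placement. At
each site, overlapping reads contribute the base their sequence places
there, complement-corrected for antisense reads so the table lives in
reference-sense space; reads with `N` at a site are excluded from that
site only; reads exceeding the mismatch allowance are excluded entirely.
The readout of multi-copy origin is a site showing both alleles at
appreciable frequency.

## Genotyping insertion sites

For a candidate site, two allele sequences are built: with and without the
insertion. Each long read is locally aligned to both (both orientations;
match +1, mismatch −2, gap open −5, extend −2), and counts for an allele
iff its alignment covers at least 100 bp on **both** sides of the junction
on that allele and scores strictly better than on the other allele; score
ties count for neither. The genotype is `ratio = n_with / (n_with +
n_without)`, undefined (flagged) when no read is informative. The strict
better-score rule is the package's disambiguation choice on top of the
coverage criterion, which alone cannot classify error-bearing reads.

## Nested insertions

A transposon trapped inside a focal element is detected from single-end
evidence: any breakend with one side within a focal-element interval and
the other side within 100 bp of a terminus of a transposon reference
sequence is reported, with the terminus (5' or 3') and the offset inside
the focal element. Unlike insert calling, one junction suffices here.

## Expression and chromatin

`RPKM = count / (feature_kb × library_millions)`; the expressed-element
filter keeps features with RPKM **strictly** greater than 10 in at least
one of the named libraries; relative expression divides by the day-0
(baseline) RPKM, flagging zero-baseline features as undefined rather than
infinite. Split gene models can be merged before quantification (summed
counts, summed lengths). ChIP enrichment is `log2(chip_rpkm /
control_rpkm)` per feature; group-level summaries use the ratio of pooled
length-corrected counts, not the mean of per-feature ratios — pooling is
robust to zero-count members. Read-feature overlap counting uses any
overlap ≥ 1 bp. No differential-expression testing is performed; the
summaries are descriptive (box-plot statistics use median, quartiles and
1.5 × IQR whiskers).

## The synthetic-data module

The simulators emulate the statistical structure the analysis assumes,
with every parameter explicit and a truth object sufficient to predict all
downstream answers:

* **Genome**: i.i.d. sequence at a configurable GC fraction (default 0.42,
  a typical insect-genome value).
* **Element expansion**: an `ElementModel` holds a consensus, class (LTR /
  non-LTR / ITR), LTR length, and per-copy substitution rate. LTR and ITR
  copies are planted full length; non-LTR copies are 5'-truncated with a
  Beta-distributed retained fraction — mirroring the biology in which LTR
  elements retain full-length copies while non-LTR elements leave 5'
  fragments. New copies are heterozygous (one haplotype) or homozygous
  per a configurable mix; the default is fully heterozygous, as newly
  arising insertions are.
* **Breakends**: each planted insert emits its two junctions with optional
  rounded-Gaussian coordinate jitter and Poisson false junctions per Mb.
* **Long reads**: uniform sampling from both haplotypes with a
  substitution-only error model. Indels are deliberately not modeled: the
  junction-pairing and genotyping logic being tested is exercised fully by
  substitutions, and indel realism would only add CIGAR bookkeeping.
  Target-site duplications are likewise not simulated — the ≤ 100 bp
  junction-gap tolerance of the caller subsumes TSD-scale offsets.
* **Small RNA**: read lengths are drawn from a discrete distribution over
  23–35 nt whose default weights put the mode in 26–32 nt (window fraction
  ≈ 0.75); ping-pong pairs are planted as exact 10-nt 5' overlaps with the
  initiating strand a fair coin, phased reads as head-to-tail runs of five,
  the remainder uniform; 5'-U and position-10-A biases are imposable on
  the read sequences. The truth labels each read's generative class.
* **Expression/ChIP**: counts are Poisson at
  `rpkm_target × feature_kb × library_size / 1e6`; ChIP counts scale a
  base rate by a per-feature enrichment against a matched control.

What passing tests on these simulations do *not* show: robustness to
realistic nanopore error profiles (indel-rich), to chimeric reads, PCR
duplicates, reference mis-assembly, or to repeat families whose divergence
breaks the ≤ 2-mismatch single-reference mapping assumption. The
simulations validate the logic of each rule and the statistical behaviour
of each estimator, not platform-specific noise models.

## Numerical and design choices

* E-values are tracked in log10 space; the grouping threshold is strict
  (`< 1e-100`).
* Greedy pairing ties, representative ties and group ordering are all
  resolved by explicit deterministic keys (documented above), so every
  stage is reproducible and order-invariant.
* Degenerate statistics (empty histograms, zero background sd, zero
  baseline RPKM, zero control RPKM, 0/0 genotype) are flagged `NA`/`Inf`
  values with documented meaning, never silent NaNs.
* All simulators take a seed and restore the caller's RNG state; the
  pipeline derives per-stage seeds from one master seed so stages stay
  reproducible independently.

## Problem sizes

The test-suite and acceptance script run at desk scale, chosen so the full
validation completes in minutes while keeping every statistical check
well-powered: toy genomes of 0.1–1 Mb, elements of 1–3 kb, 5–50 planted
copies, small-RNA libraries of 600–2000 reads, 20-seed replication for
noise and null-band checks, and brute-force oracles up to a few hundred
reads or 50 graph nodes. The headline numbers of the original study
(hundreds of size-filtered inserts, tens of groups, 61 SNP positions)
depend on cell-line sequencing libraries and are not reproducible at this
scale; what is validated instead is exact oracle agreement and
truth-recovery of every rule under the stated conditions.

## Limitations

* The built-in aligner is tuned for near-identical, desk-scale homology;
  for genome-scale production searches an external tool can stand behind
  the same hit-table interface.
* SNP calling ignores copy insertions relative to the reference copy by
  construction; polymorphic insertions between copies are out of scope.
* The genotype ratio is a per-site allele fraction, not a copy-number
  estimate in polyploid genomes.
* Manual exclusions of pathological sites (e.g. a locus with ambiguous PCR
  support) are configuration, not code.
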