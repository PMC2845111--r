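---
title: "The Identical Repeated Backbone: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Identical Repeated Backbone: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irbkit)
```

## The problem

Sequences that are 100% identical over roughly 300 bp or more are the
minimal substrates of non-allelic homologous recombination (NAHR), the
mechanism behind many recurrent deletions, duplications and inversions.
`irbkit` maps every such substrate in an assembly: it finds all maximal
identical repeat pairs at or above a length threshold, collapses their
members into a non-redundant set of *Identical Core sequences* (ICs), and
merges overlapping ICs into non-overlapping *Identical Sequence Tracks*
(ISTs). The union of the ISTs is the *Identical Repeated Backbone* (IRB) of
the assembly. Downstream, the package measures how the IRB intersects
annotation (segmental duplications, CNV catalogues), infers and audits sets
of identical gene copies embedded in it, and screens raw sequencing reads
for gene copy-number changes against the IRB's gene complement.

## Definitions and the matching model

A **repeat pair** is a pair of distinct, equal-length intervals $X$, $Y$
with $\mathrm{seq}(X) = \mathrm{seq}(Y)$ (direct orientation) or
$\mathrm{seq}(X) = \mathrm{revcomp}(\mathrm{seq}(Y))$ (inverted), of length
$\ge L_{\min}$, that is **maximal**: extending both members one base outward
in the orientation-appropriate geometry (left/left and right/right for
direct pairs; left-of-$X$/right-of-$Y$ and right-of-$X$/left-of-$Y$ for
inverted pairs) either breaks identity or leaves the eligible region.
Equivalently, direct pairs are maximal runs along diagonals of the
self-comparison matrix and inverted pairs are maximal runs along
anti-diagonals.

Two consequences of this definition are worth spelling out:

* On an anti-diagonal, the set of matching positions is symmetric about its
  centre, so a maximal run either is symmetric — a reverse-complement
  palindrome matching *itself*, $X = Y$, which is a self-pair and excluded —
  or comes with a disjoint mirror image, in which case the two arms form one
  inverted pair, reported once. A perfect hairpin therefore contributes no
  pair; two distinct-but-overlapping intervals (tandem structure) are
  allowed and do occur in satellite-like sequence.
* Only A/C/G/T positions outside user-supplied exclusion intervals are
  eligible. Assembly gaps (N runs), IUPAC ambiguity codes and excluded
  regions (e.g. the pseudoautosomal regions, whose X/Y identity reflects
  shared ancestry rather than duplication) can neither seed, extend nor be
  contained in a match. Soft-masked lowercase is uppercased on load and
  stays eligible: identity, not repeat class, is the criterion.

The finder (C++, seeded rolling hash) indexes every eligible window of
length $L_{\min}$, pairs windows with equal hashes (forward vs forward for
direct, forward vs reverse-complement for inverted), verifies seed equality
explicitly, and extends only *leftmost* seeds — seeds whose one-base left
shift also matches are covered by the seed to their left, which bounds the
work per maximal pair by its length. Correctness is established against an
independent oracle (an exhaustive vectorized per-diagonal run scan,
implemented separately in the test suite) over dozens of seeded random
genomes with planted direct/inverted, intra-/interchromosomal duplications:
the two outputs are required to be identical.

## IC decomposition and IST assembly

Pair members with the exact same span collapse to a single IC; each IC
records every pair it participates in. ICs whose canonical sequences (the
lexicographic minimum of the sequence and its reverse complement) are equal
form an *IC family*, which makes every original pair recoverable as an
intra-family relation.

ISTs are the connected components of the IC overlap graph, where overlap
means **at least one shared bp**: cores that merely abut are *not* fused.
This follows from reading "sharing a segment of chromosomal positions" as
true overlap; it also keeps IST assembly consistent with interval merging
everywhere else in the package. An IST with a single member core is
*simple*, with two or more *complex*. IST identifiers are assigned in
(chromosome, start) order, so outputs are deterministic.

Per-window densities (1 Mb windows by default; the trailing partial window
keeps its natural size) are reported as raw bp of IST coverage. Gap
statistics between consecutive ISTs are computed within chromosomes only —
an interchromosomal "gap" has no physical meaning — and a gap of $g$ means
$g$ bp separate the tracks (two tracks separated by a single base have gap
1).

## Coordinates

Internally everything is a 1-based closed `GRanges`/`IRanges`, the native
convention of the Bioconductor container stack this package is built on.
BED input and output are converted at the boundary by `rtracklayer`
(BED being 0-based half-open), GFF3 is 1-based inclusive as usual, and
tabular reports carry 1-based inclusive columns for human reading. Write
followed by read is the identity for both formats.

## Overlap analysis

`overlap_bp()` reports the symmetric bp overlap of two interval sets (each
merged first), the fraction of each set involved, and embedding counts —
an interval is *embedded* when its whole span lies inside a single merged
interval of the other set (span containment, not reciprocal overlap).
`stratified_overlap()` splits the overlap with a percent-identity-annotated
set (typically segmental duplications) into identity bins; a bp covered by
annotations in several bins is credited to the **highest**-identity bin
only, so bins always sum to the unstratified overlap and nothing is double
counted. Identity values are taken verbatim from the input attribute.

## Identical gene-copy sets

Genes with biotype in
`r paste(gene_probe_biotypes(), collapse = ", ")`
(pseudogenes and uncategorized entries are never probes) whose whole span
lies inside an IC are projected through every pair of that IC — same offset
for direct pairs, reflected offset with flipped strand for inverted ones —
and transitively through pairs containing the projected loci. Loci related
by projection, or overlapping each other on the same chromosome (an
annotation shorter than the projected span describes the same copy), form
one set; within each copy location only the widest locus is kept, which is
how "the shortest element is adjusted to the largest" before comparison.

Each member locus is resolved against the full annotation (including
pseudogenes) by maximum overlap, and each set receives exactly one category
by decreasing precedence:

1. `unannotated_member` — some member has no annotation at all;
2. `description_inconsistent` — some member is annotated as a pseudogene or
   with a different (name, biotype, description) tuple, compared
   case-insensitively after whitespace normalization;
3. `size_inconsistent` — same description, but some member's annotated span
   differs from its projected span;
4. `consistent`.

Absence is ranked the strongest annotation defect; the precedence gives
each set one label even when several defects co-occur. Verification
(`verify_gene_sets()`) is exact string equality of the members' oriented
sequences on their projection-harmonized spans — at 100% identity this is
equivalent to a global alignment and much cheaper. `extend_and_regroup()`
then scans the whole genome for exact occurrences (both strands,
overlapping allowed) of each set's sequence, adding copies whose
surrounding context falls short of $L_{\min}$ as `genome_scan` members, and
merges sets with equal canonical sequence into one group; the operation is
idempotent, and group categories keep the precedence-maximum of the
constituent sets' categories (genome-scan members, which are by definition
outside the annotated IC context, do not reclassify a set).

## The copy-number screen

The screen asks, for a probe $p$ (a short gene sequence): how many reads of
a sample contain $p$ — full-length, 100% identity, either strand, at most
once per read — relative to the probe's copy number in the reference? The
statistic is the **hit ratio**

$$ r_p = \frac{\text{reads hit by } p}{\text{occurrences of } p
  \text{ in the reference (both strands)}}, $$

i.e. per-copy read support. Significance is judged against an empirical
null: `n_fragments` (default 220) fragments of the probes' average length,
drawn uniformly from the reference and rejection-resampled until each
occurs exactly once in it, are scored the same way; their mean and sample
standard deviation define the band. With the default multiplier of 2,
probes above mean + 2 sd flag `amplified`, probes with hits below
mean − 2 sd flag `reduced`, and probes with **zero** hits flag `absent`
rather than `reduced` — absence of exact hits can reflect sequencing error
or polymorphism rather than deletion, so it is deliberately reported apart.
Reported ratios are rounded half-up to one decimal (55/9 prints as 6.1).

A "hit" is full-length exact containment in a read, counted once per read
however many times the probe occurs in it; this deterministic reading
replaces alignment-based searching, which at 100% identity over short
probes finds exactly the same reads. Under uniform coverage $c$ and read
length $R$, a single-copy probe of length $\ell$ expects
$c\,(R-\ell+1)/R$ hits, which the simulators reproduce to within sampling
error and the tests assert.

## The simulators and what passing tests show

`simulate_genome()` draws i.i.d. uniform A/C/G/T background, verifies it is
repeat-free at the configured $L_{\min}$ (regenerating on failure, so the
planted truth is the only truth), then copies source segments to
destination segments exactly (direct or reverse-complemented).
`plant_gene_copies()` embeds a gene at a fixed offset inside $n$ identical
duplication blocks and corrupts exactly one copy's annotation (`drop`,
`shrink`, `pseudogenize`, or `none`), giving planted ground truth for each
consistency category. `simulate_reads()` applies a copy-number spec to the
reference (copy 0 deletes the locus; copy $k \ge 2$ gains $k-1$ extra
copies), then draws reads of fixed length with uniform starts, equiprobable
strands and i.i.d. per-base substitutions. Everything is deterministic
under its seed, down to the bytes of the FASTA/FASTQ written.

Extra copies are *dispersed* by default — each becomes its own contig,
with no junction to any flanking sequence. A tandem mode exists, but a
tandem junction (locus end abutting locus start) can by base coincidence
recreate a few bases of the sequence adjacent to the locus, silently
amplifying near-edge fragments that were single-copy in the reference;
that would violate the generator's contract that the planted copy numbers
are the only copy-number truth, which is why dispersed is the default.

The error model is substitutions only (default $10^{-3}$ per base, a
realistic Sanger-scale point-error rate): because the screen uses exact
matching, substitutions are the binding error mode, and indels would act on
hit counts the same way (a corrupted read simply stops matching). Real data
differ from these simulations in ways the tests therefore cannot certify:
non-uniform coverage, assembly errors in the reference, true polymorphism
between sample and reference, and read-length heterogeneity all widen the
null in practice; the worked-example regression (52 published probe rows
rescored to the printed ratios and flags) anchors the arithmetic, not those
field conditions.

### Problem sizes and operating characteristics

The validation suite runs at desk scale by design: oracle-equivalence
genomes of up to ~1.5 kb across 50 seeds (the oracle is quadratic),
planted-recovery genomes of ~4.5–9 kb over 30+ seeds, and a screen scenario
on a 24 kb reference at 20× coverage with 250 bp reads. Amplification and
deletion are planted in separate samples per replicate: a deleted locus in
the sample used to build the null would contribute zero-hit fragments,
widening the null band and eroding the very threshold under test (the
absence flag itself does not involve the null). In the screen
scenario the doubled gene is planted at 8 reference copies doubled to 16 —
the regime the screen targets (the published flagged cases were multi-copy
rRNAs with 16 reference copies). The choice is also a power decision made
a priori: with per-copy expectation $m \approx 12$ hits, the ratio of an
8-copy probe has standard deviation $\sqrt{16m}/8 \approx 1.7$, putting a
doubling 2–2.7 sd beyond the 2-sd flag threshold even after the mild
overdispersion of the empirical null (fragments overlap reads they share,
and chromosome-end fragments see truncated coverage), whereas a 1→2 copy
design sits near 1 sd and could not support a ≥90%-of-replicates
requirement. Specificity of the two-sided 2-sd
rule is nominally ≈95.4% under the Poisson/normal approximation; the suite
asserts ≥93% pooled over 600 unchanged probe tests, i.e. the nominal value
minus ~3 binomial standard errors.

## Numerical and degenerate-input choices

* `min_len` must be ≥ 2; the default 300 bp is the canonical NAHR substrate
  length. Lowering it can only add cores, so total IRB bp is monotone
  non-increasing in `min_len` (asserted as a property test).
* An empty genome, a repeat-free genome, or an empty probe table all return
  empty results, not errors; duplicate FASTA record names, empty records,
  malformed interval lines, out-of-bounds exclusions, biotypes outside the
  closed vocabulary, and a probe with zero reference occurrences are hard
  errors.
* Ties: canonical pair order is lexicographic by (chromosome record order,
  start, end) with the smaller member first; family/set/group identifiers
  follow first-appearance in that order; in the identity stratification the
  highest bin wins; in copy-location pruning the widest locus wins (first
  by position on ties).
* Rounding of reported ratios is half *up* (away from zero) at one decimal,
  not banker's rounding — the convention the worked example requires.
* The null builder rejects fragments containing non-A/C/G/T characters or
  with reference occurrence ≠ 1, and fails loudly if it cannot fill its
  quota within a bounded number of attempts.

## Known limitations

* Approximate (<100% identity) repeat detection, repeat classification and
  palindrome-arm analysis are out of scope; so are alignment (SAM/BAM)
  workflows and statistical enrichment testing of overlaps.
* The genome-wide inventory of a mammalian assembly is beyond the test
  suite's desk-scale runs; the algorithms are the same, but memory/time at
  gigabase scale would want a compressed index and chunked seeding.
* The screen's `reduced`/`absent` side is intentionally conservative: exact
  matching cannot distinguish a deletion from a diverged allele, so
  deletions should be treated as hypotheses for orthogonal validation.
* When members of a size-inconsistent set disagree on length with no
  majority, the report carries both candidate spans (the projected and the
  annotated one) rather than choosing a "true" size.
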