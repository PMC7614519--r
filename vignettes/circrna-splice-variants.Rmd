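---
title: "Methods: cataloging circRNA splice variants and their translation potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cataloging circRNA splice variants and their translation potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circvariants)
library(dplyr)
```

## The problem

Circular RNAs (circRNAs) arise when a downstream splice donor joins an
upstream splice acceptor — backsplicing — producing a covalently closed,
single-stranded RNA. The backsplice junction (BSJ) is the diagnostic
signature of a circRNA, but it does not determine the molecule: several
isoforms sharing an identical BSJ can differ in which internal exons they
retain. We call circRNAs sharing a BSJ *splice variants* of one another,
and a BSJ with two or more variants a *splice-variant family*. Because a
circle has no ends, variants also differ in properties that only exist on
circular topology: open reading frames that read through the junction,
frames with no stop codon at all (translated indefinitely by
rolling-circle translation), and regulatory motifs that straddle the
junction. This package takes a BSJ-caller's annotation output
(CIRCexplorer2's 18-column BED12+6 dialect) plus a genome and computes the
catalog, sequence, ORF, motif, amplicon-size and RT-qPCR layers of that
analysis, each as a tibble-in/tibble-out operation.

## Coordinate and anchoring conventions

All genomic coordinates are BED-convention 0-based half-open, the
convention of the input dialect; BSJ keys render as
`chrom|start|end|strand` in those units, and keys printed in that form by
upstream tools are taken as already 0-based. On the circle, positions are
0-based and taken modulo the mature length `L`: position 0 is the first
base of the mature transcript downstream of the BSJ (acceptor side) and
`L - 1` the last base before it (donor side). For minus-strand variants
position 0 corresponds to the genomic *end* coordinate, so "the junction
sits between `L - 1` and 0" holds on both strands. Mature sequences are
genome slices concatenated in block order and reverse-complemented for
minus-strand variants; `N` bases propagate without imputation.

## The catalog layer

`group_by_bsj()` keys isoforms by their BSJ. Duplicate rows (identical
BSJ *and* identical blocks, as arise when two libraries call the same
isoform) are kept at parse time and merged only when
`collapse_identical = TRUE`, summing read counts — both the collapsed and
uncollapsed counts are meaningful, so the choice is the caller's.
`catalog_summary()` computes the descriptive statistics used for this
kind of annotation set; the mature-length bins default to 400-nt steps up
to 2000 nt with an open top class, but they are an explicit parameter
because no canonical binning exists. `filter_candidates()` implements the
selection used before bench validation: read count **strictly** greater
than 20 (a literal reading of "more than 20 reads": a variant with
exactly 20 supporting reads is excluded), mature length at most 1500 nt,
at most 5 exons, and membership in a splice-variant family judged on the
*unfiltered* catalog — family status is a property of the biology, not of
the abundance threshold, so it is decided before the other predicates.

## Circular ORF enumeration

`find_circ_orfs()` enumerates exactly. From each `ATG` (start codons may
straddle the junction — a circle has no privileged break), codons are
read modulo `L` until a stop or until the codon-start cycle closes. The
cycle arithmetic is the crux: stepping by 3 modulo `L` visits `L/3`
distinct codon starts when `3 | L` and all `L` otherwise, so a stop-free
frame yields an *infinite* ORF whose repeat unit is `L/3` amino acids
when `L` is divisible by 3 (e.g. 73 aa on a 219-nt circle, 88 aa on a
264-nt circle — a 15-residue difference) and `L` amino acids otherwise.
Start codons are `ATG` only and stops the standard three; near-cognate
starts are out of scope. Codons containing `N` are opaque: translated as
`X`, never treated as start or stop. Finite ORFs report
`peptide_aa = length_nt/3 - 1` and a junction-crossing count
`floor((start + length_nt - 1)/L)`; each distinct start is reported once.
Downstream in-frame ATGs sharing a stop produce C-terminal fragments of
the same peptide; these are *marked* nested rather than merged, because
suffix identity does not prove a shared translation event.

`find_orfs_tripled()` is the linearized method used widely in practice:
concatenate the sequence three times, run a linear scan, map starts
modulo `L`, deduplicate. It is retained as a named cross-check mode, not
the default engine, because it has two structural blind spots the exact
scanner does not: it cannot represent infinite ORFs (no stop is ever
found, so the linear scan reports nothing), and finite ORFs longer than
`2L` may be truncated by the end of the third copy (flagged
`truncation_risk`). The test suite holds the two engines to mutual
consistency — every tripled-scan ORF must appear in the exact scan with
an identical peptide — and holds the exact scanner to an independent
brute-force reader over an explicitly repeated string.

`min_peptide_aa` defaults to 20: deliberately permissive, since validated
circRNA-derived polypeptides run down to ~47 aa and silently hiding small
ORFs would be worse than over-reporting. Whether non-junction-spanning
ORFs should be discarded is exposed as `require_junction_spanning` rather
than decided, since published practice varies.

## Motif and amplicon layers

`scan_drach()` matches the m6A consensus DRACH (`[AGT][AG]AC[ACT]`, the
methylated adenosine at the central position) at every circular start, so
junction-wrapping sites are found. This is a transparent consensus
enumeration, *not* a trained m6A site predictor: tools like SRAMP score
sequence context with learned models, and their output is not
reproducible as a formula. Reports should treat DRACH hits as candidate
sites. `scan_motifs()` generalizes to arbitrary IUPAC motifs (RNA
alphabet accepted, `U` transcoded once on input) and scans the sense
strand only — the mature circRNA is single-stranded sense RNA. Both scans
are validated against a doubled-string linear oracle and for rotation
covariance.

`plan_amplicons()` does placement arithmetic only (no primer
thermodynamics): the divergent-primer BSJ product is the circular walk
from the forward primer's start to the far end of the reverse primer's
site, and rolling-circle amplification adds `L` per extra lap, giving the
concatamer ladder `bsj_amplicon + (k-1)·L`. With back-to-back full-length
primers the ladder is `L, 2L, 3L, …` — which is why monomer RCA bands
read out variant lengths directly. Overlapping primer sites are rejected
as having no product.

## Quantification layer

`delta_ct()` is `2^-(Ct_target - Ct_ref)`; `fraction_distribution()`
takes the 12 sucrose-gradient fractions as *linear* levels (already
delta-Ct transformed — keeping the two formulas separate avoids silently
normalizing twice; a Ct convenience path exists), pools them pairwise
into 6, and normalizes to percentages. The monosome/polysome split is
fixed at pools 1–3 versus 4–6, matching how gradient fractions are
interpreted: the first three pools hold ribosome-free material and
monosomes, the last three translating polysomes. `ip_enrichment()` is the
two-stage delta-Ct ratio used for RIP and m6A pulldown readouts. No
statistical testing is attached to these quantities; none is specified
for them, and inventing one here would overstate what the arithmetic
supports.

## The synthetic-data generator

`simulate_circ_dataset()` exists so every layer can be tested end-to-end
against known truth. It emulates the statistical structure the analysis
assumes: a categorical variants-per-BSJ distribution with its mode at 1
and a configurable multi-variant tail (default 37% of junctions in
families, matching the catalog composition this analysis targets),
negative-binomial read counts (mean 15, dispersion 0.6 — overdispersed
low counts typical of BSJ-supporting reads), ~3% intronic single-interval
records, ~79% of junctions carrying a "known" label, exon sizes of
60–400 nt, and a uniform-composition toy genome. Families are built by
exon-subset construction on a shared parent block set (first and last
exon always retained), which guarantees an identical BSJ with differing
internal composition — the defining property of a splice-variant family.

Planted features each get a *dedicated singleton host locus*, placed
after the family loci, so no plant can overwrite another plant or a
shared family exon. Finite-ORF plants write `ATG`, sense codons and a
stop across the junction (default: a 47-aa junction-spanning ORF in a
395-nt host); infinite-ORF plants rewrite a whole frame stop-free in
hosts of 219 and 264 nt (lengths divisible by 3, mirroring the validated
rolling-circle case); the DRACH plant writes the consensus across the
junction of a 300-nt host. The truth ledger records every plant, and the
pipeline must recover 100% of it at zero noise. `simulate_qpcr()` turns
per-target fraction shapes into Ct tables with Gaussian noise on the Ct
scale, storing the noise-free percentages as truth.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: read-level sequencing error and alignment
ambiguity (records are consumed downstream of a caller), non-uniform
genome composition beyond an optional plant, splice-site motif realism,
correlated family abundances, and RNase R enrichment biology. Tests on
this generator validate the *arithmetic and bookkeeping* of the pipeline,
not the upstream caller.

## Numerical choices and degenerate inputs

Parsing is strict by default (first malformed row aborts with its row
number); lenient mode skips with a warning but never emits a partial
record. Ties in within-family ordering break by exon count, then isoform
label, so output order is total and reproducible. Percentages are exact
to 1e-9 by construction; the only stochastic tolerance in the suite is
the Monte-Carlo bound on noisy qPCR recovery (means within ~2–3 standard
errors over 100 replicates). Validation problem sizes were chosen to keep
the full suite under a minute on a laptop while still exercising every
code path: 200 random sequences of 30–600 nt for the scanner-equivalence
check, 1000 random variants for grouping oracles, 2000 junctions for
distribution recovery.

## Known limitations

The exon blocks attached to the packaged validated-variant set are
schematic (the source table prints lengths and exon counts, not block
coordinates), so that fixture supports grouping and length arithmetic
but not sequence retrieval. DRACH scanning is a stand-in for model-based
m6A prediction, and motif scanning for database-backed RBP site calls;
both are labelled as such. Genome-scale catalog counts require the
upstream aligner/caller runs this package deliberately does not perform.
IRES prediction, RNA secondary structure, protein structure and domain
annotation are out of scope.
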