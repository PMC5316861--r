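---
title: "Quantifying CRISPR/Cas9 editing outcomes from amplicon deep sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CRISPR/Cas9 editing outcomes from amplicon deep sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampedit)
```

## The analysis problem

Amplicon deep sequencing is the standard way to genotype the outcome of a
CRISPR/Cas9 editing experiment at single-molecule resolution: a 200–250 bp
PCR product is generated across the nuclease target site, sequenced deeply,
and each read is classified by comparing it with the reference amplicon.
`ampedit` implements this classification for a dystrophin-correction style
experiment in which several outcome classes coexist on the same amplicon:

* **unmodified** reads;
* **NHEJ** reads carrying an insertion or deletion (indel) at a cut site,
  from error-prone end joining;
* **HDR** reads carrying two silent marker substitutions installed by a
  donor template (plus the corrected pathogenic base), with no indel;
* **mixed** reads carrying the HDR markers *and* a cut-site indel —
  molecules repaired by a combination of both pathways;
* **excision-junction** reads produced when two cuts release the
  intervening segment (a multi-exon genomic deletion, or its spliced
  transcript product);
* **exon-skip** transcript reads in which an entire exon is absent from
  the mRNA because indels disrupted its splicing signals;
* **donor-template contamination**, i.e. reads amplified from residual
  repair-template DNA rather than the genome.

The scientific context is a mouse model carrying a nonsense C→T mutation
that creates a premature TAA stop codon in an exon of the dystrophin gene.
Two repair strategies are modelled: excision of two exons whose joint
length is a multiple of three (frame-neutral removal of the stop), and
direct targeting of the mutant exon with two guides flanking the stop
codon plus an HDR donor. Because a dystrophin open reading frame (ORF) is
only useful if the frame survives and the premature stop is gone, the
package also classifies each edited read by its reading-frame consequence
and rolls the frame-preserving, stop-removing categories up into a
*functional-ORF* fraction.

## Quantification rules and their parameters

The per-read rules follow the conventions of established amplicon-editing
quantifiers:

| parameter | default | meaning |
|---|---|---|
| `quant_halfwidth` | 5 nt | an indel counts as editing only if it overlaps the window of ±5 nt around a predicted cut site |
| `end_exclusion` | 25 nt | variants in the 25 nt at either amplicon end are ignored (primer and end-artifact zone) |
| `homology` | 0.98 | minimum alignment identity for a read to be accepted as HDR |
| `q_threshold` | Q30 | phred33 threshold for 3' quality trimming |
| `min_sub_run` | 2 | a lone substitution in the window is ignored; runs of ≥ 2 contiguous substituted bases count as editing |
| `junction_k`, `junction_mismatch` | 24 nt, 1 | length of the fusion k-mer diagnostic of an excision/skip junction, and the mismatches tolerated in it |

Cut sites are inter-base coordinates (0-based throughout, half-open
intervals), annotated 3 nt 5' of the PAM — the prototypical blunt cut for
both SpCas9 (NGG) and SaCas9 (NNGRRT) nucleases.

Reads are aligned to their amplicon globally (end-gap-free for the read,
locally on the amplicon) under affine gap scoring: match +5, mismatch −4,
gap open −12, gap extend −1. These scores deliberately favour one
contiguous indel over scattered gaps, which is what nuclease editing of a
short amplicon produces. Reads below 60% alignment identity (matches over
alignment columns) are discarded as unalignable; the threshold is low by
design so that large (up to 60 nt) deletions remain classifiable.

### Placement-invariant window overlap

Indel placement inside a repeat is ambiguous: a deletion of one `A` from
`AAAA` can be written at four positions. All calls are therefore
left-normalized, and the window-overlap test uses the indel's entire
placement-equivalence envelope (leftmost to rightmost equivalent
placement). A call is then invariant to where the aligner happened to put
the gap, and an indel that genuinely touches the quantification window is
never lost to normalization. The left normalization itself is verified
against an exhaustive placement oracle in the test suite.

### Anti-contamination anchor

When an HDR donor template is used, reads amplified from the template
itself would masquerade as perfect HDR. The amplicon model therefore
carries a `template_span`, and the classifier discards any read that fails
to cover at least one base outside it — the in-silico equivalent of the
nested PCR design in which one primer anneals outside the region shared
with the donor. Discarded reads (unalignable, anchor-failing, ambiguous
junction) are excluded from every denominator; all reported percentages
are percentages of *classified* reads.

### Mixed reads and partial markers

Mixed reads count toward total editing and toward neither the pure-HDR nor
the pure-NHEJ tallies. In the frame analysis they are resolved by their
indels, with the markers treated as reverting the pathogenic base, and
folded into the frameshift/in-frame categories; only pure HDR reads appear
in the HDR bar. A read carrying exactly one of the two markers is
classified by its indel status and flagged `partial_hdr` — the upstream
definition of HDR requires both markers, and a single-marker read is more
parsimoniously a partial conversion or an error.

## The fixture locus

All tests and simulations run against a synthetic multi-exon locus built
by `build_fixture_locus()`, emulating the geometry of the real target:

* surrogate exons of 119, 118, 212 and 120 nt — the middle two sum to
  330 nt, so their joint excision removes exactly 110 codons and is
  frame-neutral (both facts are asserted by tests);
* a premature TAA stop planted in the third exon, created by a C→T change
  at its first base, sitting between two guide sites whose codon-aligned
  `AGG` PAMs each admit a silent third-position G→A edit — these two
  G→A substitutions are simultaneously the donor's PAM-killing edits and
  the HDR markers, mirroring the experimental design;
* intron surrogates of configurable length (default 1 kb). The real
  excised region spans ~45 kb, which matters to PCR but not to any
  downstream rule: only the junction sequence is diagnostic, so the span
  is scaled down to desk size;
* junction signature k-mers for the genomic excision, its transcript
  product, and the exon-skip transcript, validated at build time to occur
  nowhere in the unedited locus.

Exon lengths other than the constrained 330 nt sum, and the exact guide
layout inside the mutant exon, are free fixture parameters; the chosen
values keep every feature (both windows, both markers, the stop) inside a
single 230 nt amplicon with its 25 nt end exclusions intact.

`derive_amplicons()` then produces the study's amplicon set: one genomic
amplicon per intron target site (cut centred), the strategy-2 nested
amplicon across the mutant exon (with the template-span anchor at its 5'
end), and transcript amplicons across the exon 52/53 region and the exon
51/54 boundary.

## What the simulator emulates — and what it does not

`simulate_amplicon_reads()` draws reads i.i.d. from an `outcome_mix`:
per-category fractions, a signed indel-length law, a uniform per-base
substitution error rate, and a seed. NHEJ indels are placed uniformly
within ±5 nt of their cut site (deletion midpoints clamped inside the
quantifiable region); HDR reads carry both markers and the reverted
variant; junction reads are built from the locus around the junction
point; contaminant reads cover exactly the template span. Byte-identical
output for identical inputs is asserted by tests, and every seed in the
package derives from a single run seed via stable string hashing of stage
names (`stage_seed()`), so adding a stage never perturbs the others.

The default indel-length law is geometric over |length| with p = 0.35,
truncated at 60 nt, with a 0.7 probability of deletion — a typical Cas9
spectrum shape. The source data constrain the quantification rules, not
the spectrum, so the law is fully overridable;
`indel_law_with_frame_mass()` reweights it to any desired
frame-preserving (multiple-of-3) mass, which is how the frame-analysis
set points are simulated.

Deliberate non-goals of the simulator: PCR chimera formation, coupling of
error rate to quality scores, platform-specific error profiles, indel
sequencing errors (substitution errors only), and any model of pooling
beyond mixing read sets. Passing the recovery tests therefore shows that
the pipeline is correct *under these generative assumptions*; it does not
certify performance on real data with, e.g., heavy homopolymer indel
error.

Where only category totals are printed in the source material, the
generator's composition splits them once, as fixed defaults: genomic
strategy-2 editing of 2.3% is NHEJ 1.05% per site + HDR 0.18% + mixed
0.02%; transcript editing of 9.2% is NHEJ 3.6% per site + HDR 0.8% +
exon-skip 1.0% + mixed 0.2%. The mixed fractions are kept small (the
published mixed bars are barely visible) and the exon-skip fraction
modest, consistent with a minority skip product.

## Frame and functional-ORF accounting

`frame_consequence()` classifies each edited read: HDR reads are their own
category; otherwise the net coding-length change decides frameshift
(mod 3 ≠ 0); in-frame reads are re-translated from the reconstructed
edited coding sequence, and a read whose translation no longer contains an
in-frame stop within the amplicon's coding span is `inframe_del_no_stop`
(the pΔ-style partial deletion). Removal of the stop is thus
operationalized sequence-level — a deletion covering any part of the TAA,
or substitution of the pathogenic base, qualifies, provided no new
in-frame stop appears. New stops are only sought within the amplicon
coding span: an amplicon assay cannot see the rest of the transcript.
`functional_orf_fraction()` is the sum of the `inframe_del_no_stop` and
pure-HDR percentages of edited reads.

## Problem sizes and numerical choices

The acceptance computations simulate 50,000 reads per amplicon per set
point (100,000 for the rare-HDR recovery, 20,000 all-edited reads for the
frame-mass recoveries), sizes at which the 3σ binomial band around each
set point is a small fraction of the value while a full run stays within a
few minutes on one CPU. Recovery tests compare the pipeline's output with
the simulation's own truth table within 3σ binomial error.

Numerical details worth knowing:

* identity is matches / alignment columns (gaps included), so large
  deletions lower identity smoothly instead of inflating it;
* full-length reads whose direct comparison to the amplicon shows ≤ 8
  mismatches are called without dynamic programming (the gapless
  alignment is provably optimal at these scores for so few mismatches) —
  this fast path carries most of a typical run;
* ties in off-target bulge alignment prefer no bulge, then the smaller
  bulge; silent PAM-killing substitutions prefer transitions
  (purine↔purine), matching the G→A edits such designs use in practice;
* degenerate (non-ACGT) bases anywhere in an off-target subject are
  rejected with a position report rather than silently skipped.

## Known limitations

* An indel that reaches into a marker base makes marker status genuinely
  ambiguous (the aligner may absorb the marker substitution into the gap);
  such reads — a few percent of *mixed* reads, invisible at realistic
  mixed fractions — can be classified NHEJ. The simulator's truth table
  accounts for marker-deleting deletions, but representation ambiguity
  immediately adjacent to a marker cannot be fully resolved at the
  single-read level.
* Indels whose placement-equivalence envelope touches an amplicon end are
  indistinguishable from shorter exact substrings under end-gap-free
  alignment; they fall inside the end-exclusion zone in any sane amplicon
  design, and the oracle tests therefore restrict themselves to interior
  placements.
* Frame analysis reconstructs coding sequence per amplicon coding
  interval; multi-interval (spliced) amplicons are translated per
  interval, which is exact for the package's fixtures but approximate for
  an amplicon in which a single indel spans a splice boundary.
* The fixture locus uses surrogate random sequence, not real genomic
  coordinates; nothing in the package retrieves or depends on a reference
  genome.

## A minimal end-to-end run

```{r example, eval = FALSE}
locus <- build_fixture_locus(seed = 1)
amps <- derive_amplicons(locus)

mix <- outcome_mix(nhej = c(0.0105, 0.0105), hdr = 0.0018, mixed = 0.0002,
                   substitution_error_rate = 0.001)
sim <- simulate_amplicon_reads(amps$ex53, mix, 50000, seed = 1, locus = locus)

cfg <- run_config(amps$ex53, locus = locus, seed = 1)
res <- run_pipeline(cfg, sim$reads, sim$quals)
res$summary
res$frame$report
```
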