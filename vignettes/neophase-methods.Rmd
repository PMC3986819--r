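---
title: "Separating neo-X and neo-Y transcripts: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating neo-X and neo-Y transcripts: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A young sex-chromosome pair (a "neo-X"/"neo-Y") that formed one or two
million years ago is still ~98.5% identical in coding sequence. A de novo
transcriptome assembled from male RNA-seq therefore contains chimeric
transcripts: stretches of X-haplotype and Y-haplotype sequence joined
through undifferentiated regions, because short reads from the two
haplotypes are frequently indistinguishable. `neophase` reconstructs the
Y-haplotype (and, symmetrically, the X-haplotype) transcriptome from such a
mixed assembly using one key observation: **male genomic reads sample both
haplotypes at equal depth, while female genomic reads sample only the X.**

## The phasing model

For each candidate transcript the pipeline:

1. **Splits it into exons.** Male genomic reads are placed on the
   transcript with zero mismatches. Where adjacent tiling reads overlap by
   fewer than 6 bp, the transcript is cut: genomic reads cannot span an
   exon-exon junction, so a thin overlap marks one. Uncovered stretches are
   dropped. The cut convention (at the end of the left-hand read, overlap
   bases staying with the left piece) is a free choice: any consistent
   convention works because pieces are processed independently
   thereafter.
2. **Calls variants per sex.** Male and female genomic reads are remapped
   with an affine-gap scorer (gap open 10, gap extend 6.6, mismatch -5;
   the match score defaults to 10 and, like everything else, is exposed in
   the configuration). An allele is called from a pileup when at least 3
   quality-passing reads (base quality strictly above 13) support it, or 2
   when total depth is at most 9.
3. **Categorizes sites.** CAT1: males polymorphic, females fixed for a
   non-reference variant (transcript already carries the Y allele). CAT2:
   both sexes show a variant (noise, polymorphism, or collapsed paralogs) —
   left unchanged. CAT3: males polymorphic, females show nothing
   non-reference (transcript carries the X allele; the male-specific allele
   is the Y variant). CAT1 and CAT3 are *diagnostic*: they distinguish the
   haplotypes.
4. **Rewrites** every CAT3 site to the Y allele (SNVs and indels; indels
   are left-aligned so site keys are stable, and downstream coordinates are
   tracked through an offset map).
5. **Filters for RNA support.** Male RNA reads are remapped with zero
   mismatches against the rewritten sequence. Maximal covered runs are kept
   only if they contain a diagnostic site. This one rule removes
   homomorphic regions, silenced Y copies, and Y-deleted genes from the Y
   assembly: X-derived RNA reads can never cover a diagnostic position of
   the rewritten sequence without a mismatch.
6. **Merges, assigns, scaffolds.** Kept fragments are merged greedily where
   they overlap by at least 40 bp at 99% identity, assigned reference IDs by
   reciprocal best hit against the outgroup CDS set, and ordered/joined
   along the reference with `N` runs sized to the unaligned reference gap.

Downstream, the package annotates ORF integrity (frameshifts and premature
termination codons by a codon walk along a reference-CDS alignment),
measures 3'UTRs from the first and the ancestral stop, quantifies
allele-resolved expression by EM over ambiguous zero-mismatch RNA
placements (FPKM), computes uncorrected divergence on block-filtered
three-way alignments, and screens coverage for gene loss.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| junction overlap | < 6 bp | tiling reads overlapping less are treated as exon junctions |
| allele support | 3 (2 if depth <= 9), base quality > 13 | calling thresholds balancing sensitivity against noise at 45-62x |
| gap open / extend / mismatch | 10 / 6.6 / -5 | mapper penalties; scores are kept real-valued |
| match score | 10 | our choice, configurable |
| min score fraction | 0.4 | drops reads whose best placement explains less than 40% of the maximum score (mostly junction-spanning genomic reads) |
| merge overlap / identity | 40 bp / 0.99 | fragment merging thresholds |
| block filter | blocks >= 100 columns, non-conserved runs <= 4 | alignment segments entering divergence estimates |
| identity floor | 0.6 | reference alignments below it are "unalignable"; identity is measured over all alignment columns (gaps included, terminal gaps trimmed), which cleanly separates true ~98% alignments from gapped random ones |
| screen ratio bands | < 0.7 deleted, >= 0.85 present | male/female normalized coverage ratio cutoffs; the underlying expectation is 0.5 vs 1.0 copies, the bands are our choice and configurable |

## The synthetic world

The generator states the data regime the pipeline was built for, with full
ground truth:

* 200 neo-sex genes plus 50 autosomal control genes; CDS lengths normal
  around 400 codons (floor 150), 2 introns where the CDS is long enough
  (shorter genes get none — an all-or-nothing rule that keeps every exon
  mappable), log-normal 3'UTRs with median ~300 bp.
* X and Y derive from an ancestor by independent per-site substitution at
  half of 1.5% each; the outgroup at a rate chosen so its expected distance
  to the Y is 2.1%. Substitutions inside a CDS are resampled if they would
  create an in-frame stop — purifying selection against nonsense changes —
  so premature stops arise only from injected lesions. Indels between the
  haplotypes are placed only outside CDS for the same reason.
* Lesions on the Y: 9% of genes get a premature stop codon (a uniform
  CDS codon overwritten with a stop), 19% a frameshift indel (length 1, 2
  or 4), drawn independently, matching the observed 164/1863 and 356/1863
  marginals. When both land in one gene, the frameshift is placed
  downstream of the stop so both lesions remain recoverable.
* Gene states: 16.7% of Y copies silenced (zero expression, intact genome),
  1.6% Y-deleted — the observed (387-30)/2141 and 30/1863 rates. X-deletion
  defaults to 2%: the observed rate (4/2141) would yield zero or one
  positive in a 200-gene world, leaving the screen untested, so the rate is
  scaled up and documented here; it was fixed before any acceptance
  measurement.
* Reads: 100 bp, error-free by default; male genomic depth 45 split 50/50
  across the haplotypes, female 62 on the X only; RNA at 50x of the
  transcriptome with per-gene log-normal levels, lesioned Y copies
  down-weighted by 0.5, silenced copies at zero.

**What a green test does not establish.** The simulator has no sequencing
error by default (an error mode exists: errors substitute a random base and
drop its quality below the caller's bound), no quality-score profiles, no
PCR duplicates, no paired-end structure, no transposable elements or
collapsed paralogy, and no transcription-level splice variation. The
pipeline's behavior on those real-data phenomena is exercised only
qualitatively (e.g. CAT2 absorbing shared noise), not measured.

## Numerical choices

* Coordinates are 0-based half-open everywhere internally; 1-based numbers
  appear only in rendered report text.
* Alignment scores are real-valued (the 6.6 gap extension is kept as
  stated, not rounded). Score ties report all top placements, because the
  quantification EM feeds on ambiguity.
* A gapless placement with at most one mismatch is accepted without dynamic
  programming: with these penalties the cheapest gap (16.6) costs more than
  recovering one mismatch (15), so the shortcut is provably optimal.
* The reference-CDS aligner used for ORF annotation raises the gap-open
  cost to 25 (the read mapper keeps 10): under the mapper's penalties a
  pair of spurious 1-bp gaps is cheaper than three clustered mismatches,
  and such fake frameshifts would shift every downstream codon index by
  one. True frameshift indels still align as gaps by a large margin.
* The EM uses effective length = transcript length (no fragment-length
  correction, single-end fragments), uniform initialization, and no
  randomness; its fixed points on clean configurations are closed-form and
  tested to 1e-6. Reads hitting more than 50 transcripts are dropped as
  repetitive and reported.
* The N50 convention is the standard one (first length at which the
  descending cumulative sum reaches half the total); the strict-inequality
  phrasing sometimes used elsewhere is ambiguous at ties.
* `rewrite_haplotype` is idempotent on SNV site lists (a base already equal
  to the substitution is skipped); indel sites whose reference context no
  longer matches are skipped rather than reapplied, so rewriting is safe
  but only SNV idempotence is guaranteed.

## Open design points, resolved

* **"Polymorphic" males** require the reference allele itself to pass the
  caller's rule, distinguishing heterozygosity-like signal (CAT3) from
  fixed divergence from the reference (CAT1).
* **Multi-allelic male sites** (two non-reference alleles called) become
  CAT2: no unique Y allele exists.
* **The diagnostic set for filtering is CAT1 together with CAT3**, since both are
  divergent sites between the haplotypes.
* **Scaffolding and merging group fragments by their parent transcript**
  (provenance is known in this pipeline), then anchor them on the
  reference CDS; a general overlap-graph assembler is intentionally out of
  scope. Fragments whose reference anchors interleave are left unscaffolded
  with a warning.
* **X-ward rewriting** (for male-specific genes absent from the female
  assembly) is provided by `rewrite_haplotype(..., direction = "toX")`. The
  default pipeline does not auto-invoke it: in the synthetic world such
  genes are X-deleted, monomorphic in males, and carry no CAT1 sites, so
  the rewrite is the identity; the function is tested directly instead.
* **The caller is a pure threshold rule** — no ploidy priors or population
  model; the support thresholds above fully determine its behavior, which
  keeps it exhaustively testable.
* **Frameshift/PTC joint status is kept separable** (`frameshift_and_ptc`),
  so all three marginals (frameshift carriers, PTC carriers, either) are
  reportable without deciding an unstated precedence.

## Known limitations

* The scored mapper evaluates candidate diagonals found by exact 20-mer
  seeds; a read whose every seed is hit by a variant goes unmapped. At 1.5%
  divergence and five seed offsets this loss is negligible, but it grows
  with divergence.
* Coverage at exon edges decays over one read length, so diagnostic sites
  within ~10 bp of a junction can fall below the caller's support rule;
  this accounts for most of the few-percent recovery shortfall on the
  default world.
* Genes whose CDS is too short for introns contribute no junction-splitting
  signal (by construction of the generator, not the pipeline).
* The EM makes no claim of equivalence with richer quantification models
  (fragment-length and error models are absent by design).
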