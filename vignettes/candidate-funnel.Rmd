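---
title: "From differential staining to verified variant candidates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From differential staining to verified variant candidates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varfunnel)
```

# The problem

Deep sequencing of tumor DNA produces far more candidate variants than any
laboratory can verify orthogonally. `varfunnel` implements an *up-front
filtering* strategy for biomarker discovery in multiplexed targeted capture
experiments: instead of sequencing everything and filtering afterwards, the
gene set itself is first restricted to proteins with clearly differential
antibody staining between healthy and tumor tissue, a capture design is
built over just those genes, and the variants that survive the downstream
filter cascade (coding, non-synonymous, absent from the known-variant
catalog) form a candidate list small enough to verify completely by
bidirectional capillary re-sequencing. The package models every dry-lab
stage of that workflow, and ships a synthetic-data generator whose manifest
plays the role of the re-sequencing ground truth, so the entire funnel can
be exercised and audited end to end without any external data.

# The pipeline

## Staining-based gene selection

Input is an antibody tissue-profiling table (one record per protein,
tissue and patient) on the ordinal scale none < weak < moderate < strong.
The default *up-in-tumor* criteria select proteins with **no staining in
breast glandular (normal) tissue** and **strong staining in at least five
tumor patients**; the complementary *down-in-tumor* search requires strong
normal staining and at least ten tumor patients with weak or no staining.
Two genuinely open points are resolved as follows:

* *How many normal records must be unstained?* The source material is
  ambiguous between "any" and "all"; the package defaults to **all**
  normal-tissue records at the required level, with a `normal_mode = "any"`
  switch.
* *Antibody validation scores* are treated as a soft screen: they are
  carried through and an optional minimum can be set, but no hard filter is
  applied by default.

Proteins with tumor records but no normal records cannot be judged and are
excluded with a warning. Literature-derived additions are merged as an
order-preserving union (`merge_with_literature()`), database selections
first.

## Capture design

For every selected gene the design extracts one interval per coding-exon
segment, one per UTR exon segment, and a **promoter window of 1,000 bases
strand-upstream of the transcript start** (the 5′UTR start). Introns are
excluded. Short regions are then **padded to a minimum of 250 bases** and
**strictly overlapping regions are fused**. Three numerical choices matter:

* Padding is symmetric: the deficit is split equally, the odd base goes to
  the right in chromosome coordinates, and padding clamped at a chromosome
  bound is redistributed to the other side, so the minimum length is always
  reached on any chromosome at least that long. Whether the original
  expansion was symmetric or downstream-only is not recorded anywhere; the
  symmetric rule was chosen as the least biased.
* Fusion merges only *strictly* overlapping intervals; merely bookended
  regions stay separate. A `merge_adjacent` flag provides the other
  behaviour.
* Region strand is dropped at design time (hybridization capture is
  strand-agnostic), and the manufacturer's proprietary repetitive-region
  filtering is out of scope — an optional user-supplied exclusion BED is
  subtracted instead (`subtract_regions()`).

The design summary counts regions, total bases and coding bases, where a
base is *coding* exactly when the class-precedence rule (below) classifies
it CDS.

## Coordinates and region classification

All internal coordinates are 0-based half-open; BED output keeps that
convention and VCF/GFF3 output converts to 1-based at the I/O boundary
only. Each position receives exactly one class per gene — PROMOTER, UTR5,
CDS, UTR3, INTRON or INTERGENIC — and positions claimed by overlapping
genes are resolved with the precedence **CDS > UTR5 > UTR3 > PROMOTER >
INTRON > INTERGENIC**, i.e. the most consequence-bearing class wins. The
promoter is anchored at the transcript start and is strand-aware. The
classification is an exhaustive partition (a property test checks the
per-class base counts sum to the chromosome length, and that minus-strand
classification equals the coordinate-mirrored plus-strand construction).

## Calling, annotation, novelty, recurrence

Reads carry their true origin (the simulator emits them that way), so no
aligner is implemented or needed; mapping fidelity is explicitly out of
scope. After exact-match demultiplexing of the MID barcode tags, per-sample
pileups are tallied over target positions only, and an SNV is called for
every (sample, position, alternative base) with

* depth ≥ `min_depth` (default 5), and
* alternative-allele fraction **strictly greater than** `min_fraction`
  (default 0.20, reading "frequencies above 20% of the reads" literally).

The original mapper's internal definition of a "high-confidence" variant
was never published; this caller is a documented stand-in, and the
depth floor of 5 is an artifact choice. Multi-allelic positions emit one
call per alternative allele; position-keyed summaries count positions, not
alleles. Reference-N positions are skipped.

CDS calls are annotated by rebuilding the affected codon strand-aware from
the spliced coding sequence and translating reference and alternative
codons with the standard nuclear genetic code; a variant is synonymous
exactly when the amino acid is unchanged (a property test cross-checks the
single-codon shortcut against full-protein translation of the mutated
CDS). Genes whose CDS length is not divisible by 3 are kept but their
variants are flagged unannotatable and excluded from coding counts with a
warning.

Novelty defaults to full-allele matching (`chrom`, `pos`, `ref`, `alt`)
against the catalog; a position-only mode is provided because early
variant-catalog matching was positional. Recurrence is the number of
distinct samples carrying an allele. Verification is modelled as a *total
oracle* over the candidate list: every candidate is either confirmed as a
planted germline heterozygous variant or declared a false positive —
mirroring orthogonal re-sequencing of tumor and matched normal tissue,
where real heterozygous germline variants appear in both.

## The funnel

`build_funnel()` reduces the annotated variants to the standard cascade:
unique positions, gene-associated positions (split into exons-including-UTR,
introns, and promoter), CDS vs non-coding, non-synonymous, novel
non-synonymous, verified, recurrent. One design point deserves a note: the
funnel's gene-association partition is kept *exact* by carrying an explicit
promoter count, so

```
in_exons_incl_utr + in_introns + in_promoter = in_target_genes
```

always holds. Published funnel tables of this kind typically have no
promoter row, in which case the promoter term is zero and the partition
reduces to the familiar two-term sum. Positions in padded flanks outside
any gene span count as off-gene.

Per-base variation rates are **per-sample averages**: total per-sample SNV
calls divided by the number of samples, then by the relevant base count,
expressed in percent to two decimals. This interpretation is adopted
because it is the one under which pooled per-sample call counts reproduce
printed per-base rates exactly. Mean coverages round half away from zero
to integers; rates to two decimals.

# The synthetic study

The generator produces every input the pipeline needs, deterministically
from one seed (each stage seeds its own stream at a fixed small offset, so
stages are individually reproducible).

What it emulates, and the default conditions:

* **Ten barcoded libraries with unequal abundance.** The per-sample mean
  coverage vector is `r paste(simulation_config()$sample_coverage, collapse = ", ")`
  — the uneven profile of a real pooled run, including a near-dropout
  library at 3× (a failed amplification) and an underloaded one at 7×.
  The pooled total is 228×.
* **Germline heterozygous variants** at 0.05% of coding and 0.07% of
  non-coding target bases per sample — the per-base variation rates
  reported for this kind of target — each emitted at read fraction 0.5
  with binomial noise. With probability 0.1 a draw reuses an allele
  already planted in another sample, producing recurrent variants.
* **A systematic-error process**: six coding sites (chosen to be
  non-synonymous where possible) emit a non-reference allele at 35% of the
  reads in 1–3 random samples each — above the calling threshold, so they
  survive every filter and are only caught at verification, reproducing
  the observed phenomenon of a substantial false-positive fraction among
  fully filtered candidates despite high coverage.
* **Sequencing error** as uniform substitutions at 0.1% per base.
  Homopolymer/flowgram error structure of the original platform is *not*
  modelled; the uniform-plus-systematic model is the minimal mechanism
  that yields threshold-passing artifacts.
* **Off-target reads** at 77% of each library (echoing the ~23% on-target
  fraction typical of first-generation capture arrays). They exercise
  demultiplexing and bookkeeping and are dropped at pileup time; they are
  drawn from the complement of the (read-length-expanded) target so they
  never contribute target coverage, and no errors are injected into them
  since nothing downstream reads their bases.
* **A known-variant catalog** covering 77% of planted alleles (so roughly
  a quarter of true variants are novel, as in dbSNP-era coding variation)
  plus 50 background entries, never at a systematic site.
* The **staining table** plants exactly 41 qualifying proteins among 200,
  so the selection plus ten literature additions reproduces a 51-gene
  design.

Problem sizes are the package's own desk-scale choice: 12 genes on two
60 kb chromosomes give a ~20 kb target, ~120,000 reads and ~120 planted
variant–sample pairs per run — large enough for the binomial checks below, small
enough that a full run with oracle comparison takes seconds. Somatic-only
variants are not planted by default (a flag exists for extension): in this
workflow every verified candidate is a germline heterozygote visible in
both tumor and normal tissue.

Read starts are drawn uniformly from the target expanded one read length
upstream, which makes expected coverage uniform across every target base
(no edge effects) and exactly equal to the configured per-sample coverage.

## What passing tests do and do not show

The simulator's reads carry known origins, error is substitution-only and
uniform, and the truth oracle is total. Passing tests therefore demonstrate
that the *filtering logic* — classification, design arithmetic, the calling
rule, effect annotation, novelty/recurrence bookkeeping, funnel accounting
and verification bookkeeping — is correct, and that planted signal at the
configured depths is recovered with the expected binomial behaviour
(sensitivity ≥ 0.95 in samples at ≥ 20×; called planted variants have
allele fractions in [0.25, 0.75] up to a ≤1% binomial tail). They say
nothing about alignment error, mapping ambiguity, platform-specific error
structure, capture bias or contamination in real data; the near-dropout
library shows how silently a sample can vanish from a pooled design, not
why amplification fails.

# Reproducing the arithmetic of a published-style run

The package ships a ten-sample example run summary
(`inst/extdata/example_run_tallies.tsv`, with design constants in
`example_run_meta.tsv`). From those inputs the reporting functions
reproduce the familiar headline numbers:

```{r}
tallies <- read.delim(system.file("extdata", "example_run_tallies.tsv",
                                  package = "varfunnel"))
meta_df <- read.delim(system.file("extdata", "example_run_meta.tsv",
                                  package = "varfunnel"))
meta <- setNames(as.numeric(meta_df$value), meta_df$key)

coverage_table(tallies, target_bases = meta[["tiled_target_bases"]])
variation_rates(meta[["total_snvs"]], meta[["coding_snvs"]],
                meta[["n_samples"]], meta[["design_total_bases"]],
                meta[["design_coding_bases"]])
false_positive_rate(meta[["novel_non_synonymous"]], meta[["verified_novel"]])
```

# A complete synthetic run

```{r}
cfg <- simulation_config(seed = 1)
sim <- simulate_study(cfg)
res <- run_pipeline(sim$reads, sim$genome, sim$genes, sim$design,
                    sim$catalog, sim$oracle, mids = cfg$sample_ids)
res$coverage
res$rates
res$funnel
res$fp_rate_pct
```

# Known limitations

* One transcript per gene; isoform-aware annotation is out of scope.
* No indels, structural variants, base qualities or somatic/germline
  statistical classification; the caller is a fixed-threshold rule.
* A single reference sequence throughout — no liftover between assembly
  versions (workflows that design on one assembly and map on another must
  reconcile coordinates before using this package).
* The GFF3 dialect is a documented subset (gene/exon/CDS, one transcript);
  arbitrary third-party GFF3 will not round-trip.
* The verification oracle is binary and total; real orthogonal
  re-sequencing can itself fail or be ambiguous.
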