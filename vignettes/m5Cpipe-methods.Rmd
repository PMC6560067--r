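---
title: "Methods: conversion-aware alignment and m5C dependence calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conversion-aware alignment and m5C dependence calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay and the model

RNA bisulfite sequencing reads out 5-methylcytosine (m5C) chemically:
bisulfite deaminates unmethylated cytosine to uracil, which sequencing
reports as T, while methylated cytosine resists conversion and is read as C.
At a cytosine with true methylation level $m$ and conversion efficiency
$e$, an informative read therefore shows C with probability

$$p = m + (1 - m)(1 - e),$$

and the methylation level estimate at a site is the methylated read count
over the informative (C + T) coverage. Everything downstream of the
chemistry — alignment, filtering, testing — exists to estimate $p$ per
cytosine honestly and to decide which sites depend on the
methyltransferase NSUN2.

`m5Cpipe` implements the complete analysis as composable stages:

1. **Simulation** (`simulate_study()`): bisulfite reads with known truth.
2. **Trimming** (`trim_fastq()`): 3' adapter removal, minimum length 20.
3. **Alignment** (`align_reads()`): three conversion-aware passes.
4. **Extraction** (`call_reads()`, `filter_artifact_reads()`, `pileup()`).
5. **Testing** (`call_dependent_sites()`, `select_comparison_sites()`,
   `global_level_comparison()`).

`run_pipeline()` chains them with a machine-readable log that asserts
read-count conservation at every hand-off.

## Conversion-aware alignment

A read position matches the reference when the bases agree **or** when the
reference base is C and the read base is T. The rule is asymmetric — a read
C over a reference T is a mismatch, because conversion only ever turns C
into T — and an N in the read matches nothing. Alignment is end-to-end
(no indels, no soft clipping) with at most 2 such mismatches, scanning
every offset of every locus exhaustively; with a reference of at most a
few hundred kilobases, exhaustive scanning is simpler to reason about than
an index and fast enough by orders of magnitude.

The scan runs over *unspliced sense-strand locus views*: the genomic
sequence under each transcript locus, padded 50 nt into the genomic
flanks. This mirrors a genome-wide aligner where it matters:

* a tRNA's post-transcriptional CCA tail is absent from the genome, so
  tailed 3' reads fail pass 1;
* splice junctions are absent from the unspliced view, so
  junction-spanning reads fail passes 1 and 2;
* reads overhanging a transcript end align against real flanking sequence
  rather than falling off the edge of the reference.

A read with a single best locus is `unique`; ties at the best score are
`ambiguous` (tied hits are first deduplicated by genomic coordinate, since
two locus views can expose the same position); anything beyond the
mismatch budget is `unaligned`. The three passes are:

1. end-to-end genomic alignment;
2. the same after removing the last 3 bases (a potential CCA tail) from
   pass-1 unaligned **and** ambiguous reads — products shorter than 20 nt
   are discarded;
3. alignment of reads still unaligned after pass 2 against a junction
   library (50 nt flanks on each side of every annotated junction,
   clamped to exon length). Only hits straddling the boundary by at least
   one base per flank count; unique hits are converted back to genomic
   coordinates with the intron written as a `D` cigar operation
   (`10M50D17M` style), the convention the methylation extractor expects.
   Abutting blocks (gap 0) merge into a single `M`.

Pass-2 ambiguous reads are *not* forwarded to pass 3; only unaligned ones
are, reading the rescue cascade literally. Junction-spanning reads whose
overhang on one flank is 1–2 nt can legitimately resolve in pass 1 (the
overhang fits inside the mismatch budget against intronic sequence) and
ones with a post-clip overhang under 3 nt resolve in pass 2 as ungapped
genomic records; both behaviors match what a genome-wide aligner produces,
and the exactness guarantees in the test suite are therefore asserted
over spanning reads with at least 3 nt left and 6 nt right overhang — the
set that deterministically reaches pass 3.

## Methylation extraction and the artifact filter

For every reference C under an `M` cigar operation: read C → methylated,
read T → unmethylated, anything else (or a `D`-spanned position) →
uninformative. All cytosines are reported regardless of dinucleotide
context — RNA methylation has no CpG special-casing.

Highly structured RNA regions can escape conversion wholesale, mimicking
dense methylation. Reads in which strictly more than 1/3 of the
informative cytosines read as methylated are discarded. Two choices here
were genuinely open:

* **Denominator.** We count informative reference-C calls in the read,
  not raw read length. This is scale-free and matches the artifact
  mechanism (non-conversion affects cytosines, not other bases).
* **Zero-informative reads.** A read covering no cytosine carries no
  evidence of an artifact and is kept.

The boundary is strict: exactly 1/3 methylated is kept. The comparison
`n_meth / informative > 1/3` is exact in floating point for every integer
pair (correctly rounded division against the same literal), so no epsilon
is needed.

The filter has a known side effect: at heavily methylated sites, genuine
reads covering few cytosines can exceed the threshold. With realistic
cytosine density (a 30 nt read covering 6+ cytosines) the induced bias is
well below one binomial standard error at the coverages analyzed here;
the level-recovery tests run at exactly this density.

## Site selection and dependence testing

Sites are testable when their coverage is **strictly above 10 in every
replicate of every tested condition**. Dependence on NSUN2 is assessed by
comparing the rescue condition against each of two comparators (empty
vector, enzymatic dead K190M) with Welch's unequal-variance t-test on the
per-replicate methylation levels (five bisulfite conversion replicates per
condition), untransformed — the analysis contract names the test on levels
directly, with no arcsine or logit transform. P-values are
Benjamini–Hochberg adjusted within each contrast across sites, and a site
is called **dependent** when both contrasts reach padj < 0.05 *and* the
rescue mean exceeds both comparator means.

Zero-variance groups make Welch's statistic undefined; we resolve them by
convention: constant and equal groups give $t = 0, p = 1$; constant but
unequal groups are tested with variance replaced by machine epsilon and
the site is flagged for audit. With only 5 replicates of a bounded
proportion, all-identical levels are not rare, so the convention matters.

For the two-condition (e.g. undifferentiated vs differentiated)
comparison, sites are kept when at least one condition shows pooled
coverage strictly above 100 reads together with at least 20% pooled
methylation; counts are pooled across replicates because a depth threshold
phrased in reads naturally refers to pooled depth (the
per-replicate alternative is exposed through the `min_cov` /`min_level`
arguments). The global comparison of level distributions uses the
two-sided Mann–Whitney U test: exact for small untied samples (both
n ≤ 8), otherwise the normal approximation with tie correction; fully
tied inputs give $p = 1$ by convention.

## The simulator: what it emulates, and what it does not

The generator reproduces the statistical structure of the study design:

| parameter | default | meaning |
|---|---|---|
| `conversion_efficiency` | 0.99 | P(unmethylated C reads as T); ~1% incomplete conversion |
| `artifact_rate` | 0.01 | fraction of reads that are wholesale non-converted |
| `read_length` | 30 nt | small-RNA library read length |
| `mean_coverage` | 300 | mean per-base coverage per transcript |
| `replicates_per_condition` | 5 | independent bisulfite conversions |
| `adapter` | `TGGAATTCTCGGGTGCCAAGGA` | 3' adapter, appended to short inserts |
| `seq_error_rate` | 0 | per-base substitution errors |

Reads start uniformly along each mature transcript (CCA tails included);
per-read, per-site methylation states are drawn independently at the
profiled level (background 0 elsewhere); artifact reads emit every C as C,
supplying the correlated non-conversion failure mode the >1/3 filter
targets; inserts shorter than the read length are padded with adapter and
then random bases; coverage is Poisson. Conversion efficiency is a
convention (a typical value for a well-behaved conversion), not a
measured quantity. Quality strings are constant because the pipeline does
no quality trimming.

Deliberately not modelled: PCR duplicates, GC bias, quality decay along
the read, molecule-level methylation correlation beyond artifact reads,
and reverse-strand conversion states (the assay converts the RNA molecule
itself; the library is stranded, and alignment is sense-strand only).
Passing tests therefore demonstrate correctness of the analysis logic
under this generative model — they do not certify behavior on real
libraries with, say, M-bias or duplicated fragments.

`simulate_site_counts()` exposes the simulator's per-site marginal
(binomial counts at $p = m + (1-m)(1-e)$, Poisson coverage): large
replicated designs — the 500-site null calibration and the 100-seed power
check — run at the count level, which is exact for those quantities and
keeps the whole suite inside a desk-scale budget. A dedicated test
verifies that the count-level marginal agrees with the read-level
pipeline's site estimates.

## The bundled demonstration reference

All sequences are synthetic. The VTRNA1.1 entry is a 98 nt placeholder
with annotated C69 and C88 positions (the data model accepts the real
sequence wherever available; the pipeline only requires that annotated
sites be cytosines). Two fixture choices make alignment-pass boundaries
deterministic rather than probabilistic: the genomic bases immediately 3'
of the tRNA locus are GGG, so a converted (TTA) or retained (CCA) tail can
never fit inside the two-mismatch budget at pass 1; and the demo intron is
poly-G with non-G exon boundaries, so junction overhangs of 3+ nt always
mismatch. The unit-test reference additionally carries a minus-strand
locus and a duplicated 40-mer pair to pin down strand handling and
ambiguity calls.

## Numerical and scale choices

* Coordinates are 0-based half-open internally; biological labels (C69)
  are 1-based. The internal alphabet is DNA (U→T on ingest); outputs that
  echo RNA input restore U.
* Adapter trimming scans for the earliest read position whose remainder
  matches an adapter prefix with overlap ≥ 3 and mismatch fraction ≤ 0.2
  (Hamming, no indels), and iterates to a fixpoint so that trimming is
  idempotent — a newly exposed 3' end can itself qualify.
* Minus-strand multi-exon transcripts are rejected at `build_reference()`
  (junction back-conversion is implemented for plus-strand junctions);
  single-exon minus-strand loci are fully supported.
* Test problem sizes: the aligner-vs-oracle equivalence runs 1,000 reads
  against a 2.5 kb reference; level recovery runs 100 simulated libraries
  at coverage 1,000; the null false-discovery calibration runs 50
  replicated designs of 500 sites; power runs 100 seeds at coverage 200.
  These sizes make every stochastic bound in the suite a >3-sigma event
  under the model while keeping the full test run in minutes.

## Known limitations

* Exhaustive scanning is O(reads × reference); the design target is a
  mini-transcriptome (kilobases), not a genome.
* No indel alignment: a real indel-bearing read ends up unaligned.
* The >1/3 filter's residual bias at high methylation with sparse
  cytosines is documented above but not corrected.
* Dependence calling assumes exactly one rescue condition against two
  comparators; other designs need the lower-level `welch_test()` /
  `bh_fdr()` building blocks.
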