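---
title: "Methods: validating methylation array manifests with epicval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating methylation array manifests with epicval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicval)
```

## What the package computes

When a new Infinium methylation array version is released (as when the
MethylationEPIC family moved from its ~850K-probe to its ~900K-probe
manifest), its computational validation has a standard shape: characterize
where the probes fall in the genome, compare the new manifest against the
old one, verify that technical replicates and FFPE-derived samples give
concordant beta values, check that unsupervised structure (tissue of origin,
normal vs tumour) is preserved — including on small random probe subsets —
and test the gene sets newly reachable by the array for functional
over-representation. `epicval` implements that workflow as composable,
tested functions plus a synthetic-data generator, so the whole pipeline runs
and is verified without downloading any manifest, GTF, track or GEO series.

All coordinates are handled 1-based inclusive internally: array manifests
and GTF are already 1-based, so only BED input (0-based half-open) is
converted, on read (`start + 1`, `end`). Chromosome names are normalized to
the "chr"-prefixed hg38 convention; anything that is not chr1..chr22,
chrX/Y/M after normalization is preserved verbatim and flagged, never
dropped — how multi-mapping or non-canonical-contig probes should be treated
is a downstream decision, not a parser's.

## Probe annotation

Each probe is classified by the single interrogated cytosine position, not
by the 50-mer probe footprint, along four independent dimensions.

**Gene-relative regions.** For every transcript on the probe's chromosome,
the probe can fall in: TSS200 (within ±200 bp of the transcript start site,
strand-aware), TSS1500 (±1,500 bp, *excluding* the TSS200 band), 5'UTR
(between transcript start and first-exon start), first exon, gene body
(between first-exon end and last-exon end) and 3'UTR (between last-exon end
and transcript end). Two deliberate decisions deserve emphasis:

* *TSS band nesting.* The cross-category priority used for flattening is
  TSS1500 > TSS200 > 5'UTR > first exon > body > 3'UTR (5' to 3'). Taken
  literally within one transcript, a TSS1500 window that contains the TSS200
  window would annihilate the TSS200 category entirely — yet both categories
  are populated in every published manifest summary. We therefore assign
  TSS200 for |d| ≤ 200 and TSS1500 only for 200 < |d| ≤ 1500 *per
  transcript*, and apply the printed priority only across transcripts. The
  windows are symmetric (±) around the TSS; legacy Illumina annotation used
  upstream-only windows, and this divergence is intentional and documented.
* *Literal UTR definitions.* "Between the transcript start and the
  first-exon start" is empty for most transcripts (they coincide); we
  implement it literally (default `utr_mode = "literal"`), because that is
  the stated rule, and offer `utr_mode = "cds_based"` (5'UTR = transcript
  start to CDS start) for CDS-bearing GTFs as a usability escape hatch.

A probe's flat label is the highest-priority per-transcript label, or
`Intergenic` when no transcript contributes any label; the associated
transcript types are the union over contributing transcripts, with a
priority-resolved single type (mRNA > lncRNA > other) reported alongside.
Ties between transcripts achieving the flat label are reported via the
lexicographically smallest transcript ID; all per-transcript labels are
retained.

**CpG-island context.** Distance bands from the nearest island: inside
(`Island`), within 2 kb of an edge (`Shore`), within the next 2 kb
(`Shelf`), beyond 4 kb (`OpenSea`). Where flanks of nearby islands overlap,
the minimum-distance rule automatically awards the higher-priority context
(Island > Shore > Shelf > OpenSea).

**Chromatin state and CTCF.** The label of the containing interval of the
supplied 15-state segmentation (overlaps resolved first-by-coordinate, a
documented deterministic tie rule), and a boolean for CTCF-binding overlap.

The annotation engine is validated against an exhaustive per-base
brute-force oracle on seeded 100 kb genomes (every single position, 100%
agreement required) and against a mirror-symmetry property: reversing the
genome and flipping strands must leave every label unchanged.

## Manifest comparison

Probes are matched between manifests by *base ID*: EPIC-v2-style IDs carry
replicate/build suffixes (`cg00000029_TC21`), stripped after the first
underscore (configurable, since the suffix grammar is conventional rather
than specified). Position matching `(chrom, pos, strand)` is available as a
cross-check. Shared/removed/added sets are reported at row level and at
unique-position level (replicate probes interrogate one cytosine from
several bead designs, so the two differ); conservation
(|old| = shared + removed, |new| = shared + added) and diff symmetry are
property-tested. Accounting tables stratify by probe class — `cg` (CpG),
`ch` (CpH), `rs` (SNP genotyping), inferred from the ID prefix so the rule
is dialect-invariant — by chromosome (karyotype order), by Infinium design
chemistry, and by probe density in fixed 1 Mb windows (window *w* covers
`[(w-1)·W+1, w·W]`; truncated final window; totals conserved).

## QC and concordance

QC removes, in order: masked probes, genotyping (`rs`) probes,
X/Y-chromosome probes, then probes failing detection p > 0.01. Each probe is
counted under the first rule that removed it, so the report categories
partition the removals exactly. The detection-p rule defaults to the strict
"fails in any sample" convention, with `all` and `fraction` alternatives,
because the source analysis does not state which convention it used and
strictness is the common array-QC default. Whether concordance is computed
before or after QC is likewise unstated; QC-first is the default and both
orders are possible by construction.

Replicate/FFPE concordance is the Spearman rank correlation over paired,
non-missing betas (average ranks on ties), with the large-sample t
approximation `t = rho·sqrt((n-2)/(1-rho^2))`, df = n-2, two-sided, for the
p-value; the exact value is retained and only the display rounds to bounds
like "<1e-04". Zero-variance inputs yield a flagged degenerate result rather
than a number. Paired beta differences are binned over [-1, 1] with
count conservation.

## Unsupervised structure

* **PCA** runs on beta values as they are (mean-centred, not scaled); an
  M-value transform (`log2(beta/(1-beta))`, clamped) is available behind a
  flag, off by default. Identical samples give a flagged degenerate result.
* **Hierarchical clustering** uses Euclidean distances between samples and
  the classic `ward.D` linkage — the Lance–Williams update applied to
  *unsquared* input distances. This is deliberate: `ward.D` and `ward.D2`
  differ in merge heights, and the variant is named explicitly so results
  are comparable. Probes with missing values are dropped before distances.
* **Bootstrap support** resamples probes (features) with replacement B = 100
  times, re-clusters, and scores each internal node of the full-data tree by
  the fraction of bootstrap trees containing an identical leaf set — the
  plain bootstrap proportion (BP). Multiscale (AU) support is out of scope:
  published figures of this kind print no support values, so guessing AU
  would be unfounded.
* **Dendrogram comparison** matches internal nodes by leaf-set equality;
  `common_fraction` = shared internal nodes / (n-1) and the per-tree
  unmatched-node counts are the "distinct edges". The exact edge-counting
  convention behind published tanglegrams is not defined anywhere; leaf-set
  equality is the convention here and is stated as such.
* **t-SNE** is an exact (quadratic) implementation — per-sample Gaussian
  affinity calibration to the target perplexity by bisection, Student-t
  output kernel, momentum gradient descent with adaptive gains and early
  exaggeration — deterministic for a fixed seed. With tens of samples the
  quadratic algorithm is the appropriate tool; the contract tested is
  deterministic reproducibility plus separation of planted groups
  (mean silhouette > 0.5), not any specific layout.

## Over-representation

Gene sets (GMT) are tested one-sided for enrichment: p = hypergeometric
upper tail P(X ≥ k), equal to the one-sided Fisher exact test; a two-sided
variant sits behind a flag. The background population defaults to the union
of all set members, overridable — the background of online GO tools at any
given date is not recoverable, so an explicit, stated default is the
reproducible choice. FDR control is Benjamini–Hochberg; significance is the
strict q < 0.05 cut (q exactly 0.05 is excluded). The tail probability is
verified against exhaustive enumeration for every table with N ≤ 30. Note
that BH is *not* idempotent in general (BH of an already-adjusted vector can
grow: p = (0.2, 0.9) adjusts to (0.4, 0.9), which re-adjusts to (0.8, 0.9));
the tested guarantees are agreement with the hand step-up rule,
monotonicity in p-rank and q ≥ p.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the *inputs* of a
manifest-validation study so every stage runs offline.

* `make_genome()`: chromosomes (default 100 kb) carrying non-overlapping
  CpG islands (200–2,000 bp), 1–5-exon transcripts on both strands (40% of
  transcripts extend past their terminal exons so literal UTR intervals are
  non-empty), a complete 15-state chromatin tiling and sparse CTCF
  intervals; serialized to BED/GTF.
* `make_manifest_pair()` plants exact shared/removed/added counts at
  distinct genome positions, attaches v2-style ID suffixes to a random 30%
  of new-manifest probes, and can plant position-replicate probes; the
  planted sets are returned as machine-readable truth.
* `make_beta_matrix()` draws per-probe baselines from the bimodal Beta
  mixture 0.5·Beta(2,18) + 0.5·Beta(18,2) (modes near 0.1 and 0.9, the
  canonical beta-value density shape), plants a nested 2×2 group structure
  (default: haematological/solid × normal/tumour, 5 samples per group) on
  the logit scale — two thirds of informative probes carry the top-level
  effect, one third the nested effect, both of size 3 logits on 10% of
  probes by default — and adds i.i.d. Gaussian logit-scale noise
  (default sd 0.05 for replicate-level noise; the clustering analyses in
  the tests use 0.5 to represent realistic biological-plus-technical
  spread). Back-transforming through the logistic keeps betas in [0, 1]
  with no truncation artefacts. The standard-normal noise draws do not
  depend on the noise sd, so runs with the same seed and different sd share
  noise directions — replicate concordance is then exactly monotone in the
  noise level, which the suite exploits. Replicate columns share their
  source's signal with independent noise; detection p-values exceed 0.01 at
  a configurable rate. Everything is deterministic given the seed.

What the generator does **not** emulate: Infinium chemistry and dye bias,
batch effects, cell-type heterogeneity, correlated (co-methylated) probe
blocks, and genome-scale probe counts. Passing tests therefore demonstrate
the correctness of the computations and the recoverability of planted
structure, not performance on real arrays.

## Problem sizes, numerical choices, known limitations

The suite and the acceptance script run at desk scale: 100 kb genomes for
the per-base oracle, hundreds of probes for manifest diffing, and a
20,000-probe beta matrix (20 samples in four nested groups, B = 100
bootstrap replications) for the clustering analyses — sizes chosen so a full
run is comfortable on one CPU while preserving every tested property.

One limitation matters when interpreting the 1%-fraction clustering result:
1% of 20,000 probes is 200 probes (~13 carrying the top-level effect),
whereas 1% of a real ~900K manifest is ~9,000. At the tested seed the
planted top-level split is recovered with bootstrap support ≥ 0.95 at both
fractions, but across other seeds the 1%-fraction support ranges roughly
0.83–1.0 — the desk-scale analogue of the "1% of CpGs preserves biological
clustering" claim is intrinsically noisier than the full-scale analysis it
mirrors. The 100%-fraction result is stable.

Other numerical conventions: agglomeration ties are broken deterministically
(lowest pair index); island distance uses merged islands so nested or
adjacent islands cannot confuse the banding; empty gene-region intervals are
dropped rather than clamped into existence; beta parsing rejects values
outside [0, 1] rather than clamping; probes beyond a stated chromosome size
go to the last density window with a warning. Seeds are mandatory for every
stochastic stage — there is no silent nondeterminism anywhere in the
pipeline.
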