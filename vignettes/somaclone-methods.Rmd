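---
title: "Detecting and characterizing somatic mutations in cloned animals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing somatic mutations in cloned animals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaclone)
```

## The problem

Somatic cell nuclear transfer (SCNT) produces animals that are, in
principle, genetic copies of their nucleus donor. In practice the cloning
process and early development introduce de novo somatic mutations, and any
site where a clone differs from its donor is a candidate for such a
mutation. Because whole-genome variant calls are noisy, a single
donor/clone difference is weak evidence; a site that differs from the donor
in *two independently cloned* animals, at high read depth, is much stronger
evidence that the call is real (each clone is an independent sequencing and
calling experiment against the same donor genome).

`somaclone` implements this analysis as a reusable pipeline:

1. **Candidate filtering** — from donor/clone VCFs, keep sites that are
   heterozygous in a clone while homozygous reference in the donor, pass a
   read-depth threshold, and are found in at least two clones; then
   annotate each survivor with its frequency in a population panel.
2. **Effect annotation** — SnpEff `ANN` parsing where available, otherwise
   an internal codon-level classifier, with selection of moderate/high
   impact candidates.
3. **Mutational signature** — the 96-channel trinucleotide-context
   substitution spectrum, compared to reference signatures by cosine
   similarity and summarized by a flatness (normalized entropy) statistic.
4. **Per-gene mutation rates** — counts per gene divided by gene span
   length, ranked.
5. **Enrichment statistics** — a Yates-corrected chi-squared test of
   aging-list membership against mutation-bearing status, and a generic
   hypergeometric over-representation test with Benjamini–Hochberg FDR over
   user-supplied gene-set collections.
6. **Synthetic data** — a deterministic generator that emits every input
   the pipeline consumes, with a ground-truth manifest, so the whole
   cascade can be validated against planted truth.

## The filtering model

A *somatic mutation* is operationalized as a site where the clone sample
is heterozygous and the donor is homozygous reference. Donor-heterozygous
sites are inherited variation, not somatic change; donor hom-alt with a
clone het is a different event class (allele loss) and is excluded. The
cascade is:

* **Clone-specific heterozygosity** per clone. Missing donor genotypes are
  excluded — absence of evidence of donor hom-ref is not evidence.
* **Depth**: sites with clone read depth of 50 or less are removed
  (`min_depth = 51`). The depth is evaluated on the clone sample in each
  per-clone set; the donor depth is not thresholded. Missing DP removes
  the site (a conservative choice: un-evidenced depth cannot pass a depth
  filter).
* **Cross-clone intersection** on (chrom, pos, ref, alt): a candidate must
  appear in at least `min_shared_clones = 2` per-clone sets.
* **Population-frequency annotation**: each candidate gains its alternate
  allele frequency in a reference panel (0 when absent) and a `rare` flag
  (frequency < 0.01). Sites whose panel genotype missing rate exceeds 10%
  get an *undefined* frequency — the panel cannot be trusted there. This
  stage removes nothing; rarity is reported, not filtered, because a
  candidate present at low frequency in the population may still be a
  recurrent artifact and the analyst should see it.

Every stage count is recorded, so monotone shrinkage of the candidate set
is visible in the run report.

Multi-allelic VCF records are split per alternate allele before any of
this; a `1/2` genotype is heterozygous for each split allele, and a `0/1`
genotype is heterozygous for allele 1 and homozygous reference for allele
2. This preserves per-allele heterozygosity semantics through the split.
All coordinates are 1-based inclusive, the native convention of VCF and
GFF3; no half-open coordinates appear anywhere in the package.

## The spectrum model

Each SNV is mapped to one of 96 channels defined by its substitution and
its 5'/3' flanking bases, after pyrimidine normalization: if the reference
base is a purine, the trinucleotide and both alleles are
reverse-complemented, so `TGG` with `G>A` becomes `C[C>T]A`. Channels are
ordered substitution-class major (C>A, C>G, C>T, T>A, T>C, T>G), then by
5' and 3' flank alphabetically — the conventional catalog plotting order,
chosen for interoperability with published signature matrices.

SNVs at chromosome edges or with `N` in their context are tallied as
`dropped`, never silently discarded: `total + dropped` always equals the
number of SNVs submitted. Spectra are compared to reference signatures by
cosine similarity on the 96-vectors, and summarized by *flatness*, the
Shannon entropy of the channel proportions divided by `log(96)` (1 =
perfectly uniform, 0 = single channel). A flat spectrum is the shape of
the clock-like, aging-associated SBS5 signature; a spectrum concentrated
in C>T channels is the shape of UV-driven mutagenesis.

No genome-context normalization is applied by default: proportions are
raw channel shares of the observed catalog. On the near-uniform synthetic
genomes this makes no practical difference; on real genomes an analyst can
normalize externally if desired.

Two built-in signatures ship with the package. `flat` is exactly uniform.
`uv_ct` places 90% of its mass on the eight C>T channels with a pyrimidine
5' flank — UV photoproducts form at dipyrimidines — and spreads the rest
uniformly; its flatness is about 0.58, giving a clear qualitative contrast
with the flat profile (flatness 1.0) in both the C>T class share and the
entropy statistic.

## Mutation rates and enrichment

A candidate is assigned to *every* gene whose genomic span contains it
(overlapping genes each count it once — span-based annotation conserves
per-gene evidence), and sites outside all spans are tallied as intergenic.
The per-gene rate is `count / length`, with length the genomic span
`end − start + 1` in bp, not summed exon length; genes with fewer than
`min_count = 2` mutations are dropped before ranking, and ties in rate are
broken by symbol for determinism. Reported rates are formatted to 3
significant figures in scientific notation; full precision is kept
internally.

The aging-gene association uses a 2×2 table of list membership versus
mutation-bearing status over the annotated-gene background, tested with
the chi-squared statistic under Yates' continuity correction,

$$\chi^2 = \sum_{cells} \frac{(|O - E| - \min(0.5, |O - E|))^2}{E},$$

with the correction clamped at $|O - E|$ so it never over-corrects — the
behavior of mainstream statistical software, and required to reproduce
published values computed with it. Gene-set over-representation uses the
hypergeometric upper tail $P(X \ge k)$, accumulated in log space for
stability, with Benjamini–Hochberg adjustment across all tested sets; a
set is significant when its adjusted p-value is below `alpha = 0.01` *and*
it overlaps the query in at least `min_overlap = 2` genes. Gene identity
is by case-insensitive, whitespace-trimmed symbol.

## What the simulator emulates — and what it does not

The generator emits a complete, internally consistent study at desk
scale. Its defaults describe one fixed set of conditions:

* a 4-chromosome, 1 Mb genome of i.i.d. uniform bases;
* 200 non-overlapping genes of 0.8–4 kb, each with a single CDS covering
  the central 60% of its span, half on the minus strand;
* 2,000 germline heterozygous sites shared by donor and clones;
* 300 shared somatic SNVs (heterozygous in both clones, hom-ref in the
  donor), 200/150 clone-private SNVs, and 40 shared low-depth decoys;
* read depths Poisson around 80 for passing sites, truncated at the
  51 floor, and Poisson around 25 truncated at the 50 ceiling for decoys
  — truncation removes boundary flakiness from tests by construction;
* somatic substitutions and contexts drawn from a chosen 96-channel
  signature and placed by matching the genome context on either strand
  through a pre-built trinucleotide index;
* a 196-sample population panel holding most germline sites at common
  frequencies, none of the somatic sites except 5 rare colliders
  (frequency < 0.01) and 3 high-missing colliders (missing rate > 0.10);
* an aging gene list sampled at 2-fold odds toward mutation-bearing genes
  (the magnitude of association reported for real clones), and a gene-set
  collection with one set planted at 8-fold odds among 50 null sets.

Every draw derives from one master seed (sub-stages use fixed offsets from
it), so a seed reproduces every emitted file byte-for-byte.

The enrichment ground truth is implemented at the *gene-list* level:
aging-list membership is sampled conditional on a gene's mutation-bearing
status, rather than biasing where mutations land on the genome. The two
formulations induce the same 2×2 association; conditioning the list keeps
mutation placement purely context-driven, so the same planted sites serve
the spectrum and the enrichment checks without interference.

The simulator works at the *post-calling VCF level*, which is where this
analysis begins. It does not model sequencing errors, mapping artifacts,
local assembly, indel realignment, GC or mappability bias, linkage in the
panel, or realistic canine genome composition. Passing tests therefore
demonstrate that the *pipeline logic* is correct — exact recovery of
planted truth, correct statistics against oracles — not that upstream
variant calling on real reads would be error-free.

## Numerical and degenerate-input choices

* An empty spectrum is valid; normalizing it (proportions, flatness,
  cosine) is an error rather than a silent NaN.
* Cosine similarity on a zero-norm vector, a chi-squared table with a zero
  margin, and infeasible hypergeometric margins are all errors with
  explicit messages.
* `hypergeom_overrep` returns exactly 1 at zero overlap and accumulates
  the tail from log densities via a max-shifted sum.
* The depth threshold, rarity threshold, missing-rate threshold, minimum
  count, top-n, alpha and minimum overlap are all exposed configuration
  with the published analysis values as defaults.
* Unknown SnpEff effect terms map to `other`/MODIFIER with a warning
  rather than an error, so an annotated VCF from a newer SnpEff does not
  abort a run.
* Transcript selection for CDS attachment keeps the longest transcript
  per gene (by summed CDS width) and is logged in the gene table; splice
  classification is limited to ±2 bp of CDS segment boundaries.

## Problem sizes used in the test-suite

The validation suite runs the full cascade on the default fixture above,
repeats cascade invariants (monotone stage counts, idempotence) over 20
seeds of a compact 120 kb configuration, recovers planted signatures from
5,000 draws on a 400 kb two-chromosome genome, checks the chi-squared
engine against 1,000 random tables and the hypergeometric tail against
exhaustive subset enumeration for every feasible configuration with a
background of at most 12 genes, and checks null-set p-value uniformity on
200 sets of 50 genes over a 1,000-gene background — sizes chosen so that
each check has statistical resolution while the whole suite stays fast.

## Known limitations

* The internal effect classifier handles SNVs only; indels pass the
  cascade but are classed `other` unless an `ANN` field is present, and
  are excluded from spectrum building by the SNV-only contract.
* Gene length is the genomic span, so rates are not coding-normalized;
  burden significance (e.g. dN/dS-style models) is out of scope.
* The over-representation engine tests user-supplied set files; it does
  not reproduce any hosted database's curation, GO graph propagation, or
  expression-based analyses.
* With only two clones, "found in both" is the strongest available
  replication; the package does not attempt to distinguish early
  developmental mutations from cell-line mutations carried in from the
  donor fibroblast culture, which requires additional samples.
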