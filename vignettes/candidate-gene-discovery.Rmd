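---
title: "Candidate dwarfing-gene discovery from EMS mutant RNA-seq"
author: "emscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate dwarfing-gene discovery from EMS mutant RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emscan)
```

## The problem

Ethylmethanesulfonate (EMS) mutagenesis is a standard route to new crop
alleles: it alkylates guanine and therefore induces predominantly G:C to
A:T transitions scattered through the genome.  After several generations
of selfing, a stable mutant line differs from its progenitor cultivar at
a few dozen to a few hundred homozygous sites, one (or a few) of which
causes the phenotype of interest — here, a dwarf, lodging-resistant
habit in Tartary buckwheat.  When no mapping population is available,
RNA-seq of mutant and wild-type replicates can serve double duty: the
reads carry both expression levels and expressed-SNP genotypes, so a
candidate gene can be nominated as one that (a) carries a homozygous
protein-altering SNP that distinguishes the two lines and (b) is itself
differentially expressed.

emscan implements that analysis as a tested pipeline over standard
formats (FASTA, GFF3, VCF 4.2, TSV count matrices), together with a
seeded synthetic-study generator that stands in for raw data that no
archive provides.

## The pipeline stage by stage

### Homozygous-SNP filtering

Variant calls arrive as one record per site with per-replicate genotype
(GT) and depth (DP).  `filterHomozygousDifferences()` applies, in order:

1. **Depth.** Calls with depth $\le$ 10 are removed; a surviving call
   needs depth $\ge$ 11.  The rule is deliberately strict at the
   boundary (a depth-10 call is discarded).
2. **Replicate support.** A locus needs a passing call in at least three
   biological replicates of *each* group.  With the default three
   replicates per group this means all of them.
3. **Heterozygosity.** Any retained heterozygous call discards the
   locus: a selfed, genetically stable line should be homozygous, so
   heterozygosity is read as a calling artifact.

Two further conditions make the survivors *informative*: each group
must be unanimous (any within-group genotype conflict discards the
locus — the conservative reading of a protocol that is otherwise silent
on conflicts), and the two groups' homozygous genotypes must differ.
Background cultivar-vs-reference polymorphisms are homozygous alternate
in both groups and are therefore removed by the group-difference
condition, which is what collapses a genome-wide SNP survey (tens of
thousands of sites) to a candidate set of order one hundred.

### Substitution spectrum

`spectrumSummary()` tabulates the 12 ordered substitution types on the
forward reference strand; complementary pairs (A>G vs T>C) are kept
distinct because that is how strand-agnostic variant callers report
them.  Transitions are {A>G, G>A, C>T, T>C}; everything else is a
transversion.  Note that some screen reports label C>G or G>T changes
"transitions"; emscan follows the standard purine/pyrimidine
definition.  Percentages are rounded half-up to two decimals (one
decimal where a report prints one), and the Ts/Tv ratio is reported
both half-up and *truncated* to two decimals — fold changes in this
literature are conventionally truncated (17393/10615 = 1.6385… is
reported as 1.63-fold).

### Coding-effect annotation

For a variant inside a CDS, `annotateCodingEffect()` splices the CDS out
of the genome, reverse-complements it for minus-strand genes, locates
the affected codon and offset, substitutes the (strand-corrected)
alternate base and translates both codons with the standard nuclear
code.  Effects are `synonymous`, `nonsynonymous`, `stop_gain` or
`stop_loss`; positions outside any CDS are `noncoding` with a region
label (`exon` > `intron` > `upstream` > `downstream` > `intergenic`, in
that precedence).  The flank window for upstream/downstream is 2,000
bases on the gene's own strand; reports rarely define this window, so
the value is an explicit, documented parameter rather than an implicit
constant.  UTRs are not modelled: gene models carry exon and CDS
intervals only.

The unit tests hold this annotator to a *full-protein oracle*: mutate
the genome base, re-extract and translate the entire protein, and diff
it against the reference protein.  Codon-local annotation must agree
with the full-protein diff on every CDS variant, on both strands.

### Differential expression

No DE method is canonical for a 3-vs-3 pooled-library design, and the
protocol this pipeline mirrors names none.  emscan uses an exact
conditional binomial contrast (in the style of Audic–Claverie): counts
are pooled within each group, and the mutant pool $b$ out of the total
$a+b$ is tested two-sided against $p_0 = N_m/(N_m+N_w)$, the mutant
share of the summed library sizes.  Benjamini–Hochberg FDR is applied
over all tested genes, and a gene is a DEG when FDR < 0.001 and
$|\log_2 \text{ratio}| \ge 1$ (log2 ratios use CPM group means with a
pseudocount of 1; all-zero genes are reported untested).

This choice has a known, documented consequence: a pooled binomial test
carries no replicate-variance term, so its type-I error is calibrated
only when biological variability between replicates is small (the
variance of a negative-binomial count is $\mu + d\mu^2$; any
appreciable dispersion $d$ inflates the pooled test for well-expressed
genes).  It is a stand-in appropriate for a genetically uniform inbred
line under controlled conditions — not a reproduction of a specific
published method, and not a replacement for dispersion-aware models
(edgeR, DESeq2) on designs with real biological spread.

### Pathway enrichment, qPCR, and phenotype arithmetic

`enrich()` is an upper-tail hypergeometric test per pathway with
Bonferroni correction ($Q = \min(1, p \times \#\text{pathways})$,
significant at $Q \le 0.05$; BH is available behind a flag).  The
universe is the set of genes with at least one count.  `ddct()`
implements $2^{-\Delta\Delta Ct}$ against a reference ("histone"-role)
gene and a calibrator condition.  `lodgingIndex()` computes
$LI = FW(g) \times PH(cm) / (BF \times 10)$; breaking-force units are
gauge-specific, so LI is treated as unitless.  `percentOf()` and
`foldRatio()` centralize the reporting rounding modes (half-up and
truncate) so that published worked examples are reproduced exactly.

### Candidate selection

`selectCandidates()` intersects genes carrying at least one filtered,
protein-altering SNP with the DEG set.  Stop-gain SNPs count as
evidence alongside nonsynonymous ones (a premature stop is at least as
disruptive as a missense change); the `includeStopGain` flag turns this
off for a strictly-missense reading.  Candidates are ranked by (FDR
ascending, $|\log_2|$ descending, gene id) purely for stable output —
the source analyses do not rank their candidates.

## The synthetic study

`simulationConfig()` / `simulateStudy()` generate a complete toy study:
genome, gene models, planted truth, per-replicate variant calls,
counts, and a qPCR Ct table.  Defaults encode the emulated design —
they are study conditions, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `nChromosomes`, `chromLength` | 2 × 100 kb | desk-scale genome |
| `nGenes` | 60 | ATG-initiated, stop-terminated, stop-free CDSs on both strands |
| `nTrueMutations` | 40 | mutant-line substitutions drawn from the EMS spectrum |
| `emsSpectrum` | 0.45 C>T, 0.45 G>A, 0.025 A>G/T>C, rest split | ≥ 0.9 mass on C>T+G>A |
| `nBackgroundSnps` | 30 | shared homozygous polymorphisms (exercise the group-difference rule) |
| `replicatesPerGroup` | 3 | the two-groups-of-three design |
| `meanDepth`, `depthDispersion` | 50, size 25 | negative-binomial site depth |
| `genotypeErrorRate` | 0.02 | per-locus call corruption (below) |
| `nDeGenes`, `lfcEffect` | 20, 2 | planted four-fold expression shifts |
| `pathwaySize` | 16 | co-downregulated "GA biosynthesis"-style gene set |
| `nbDispersion` | 0.001 | count dispersion (below) |

The causal mutation is a spectrum-drawn nonsynonymous CDS change in a
randomly chosen gene; that gene is also planted as differentially
expressed (down by default) with a fixed base mean of 300 counts —
expressed-SNP calling only works in expressed genes, so a silent causal
gene would be unrealistic for this design.  One truth record per
simulation is flagged causal.

Two generator choices deserve explanation:

* **Genotype error model.** Errors are applied per *locus*: with
  probability `genotypeErrorRate` one randomly chosen replicate call is
  set to heterozygous or missing.  With six calls per locus and
  unanimity filtering, a per-*call* model at the same nominal rate
  would discard $1-(1-e)^6 \approx 11\%$ of true loci at $e = 0.02$,
  which does not match the intended high retention of a stable-line
  screen; the per-locus model keeps every filter rule exercised while
  retaining ~98% of true loci.
* **Count dispersion.** The default `nbDispersion = 0.001` sits at the
  near-Poisson end.  This is deliberate: the pooled binomial DE test is
  exactly calibrated under Poisson sampling with library-size offsets,
  and the generator's job is to test the pipeline under the variance
  model the test assumes.  Raising the dispersion demonstrates the
  test's documented type-I inflation rather than a pipeline defect.
  Real tissue replicates typically show dispersions of 0.01–0.1; the
  suite's null-control test is therefore a statement about the
  generator's conditions, not about arbitrary real data.

What the generator does **not** emulate: read-level artifacts
(alignment error, strand bias, PCR duplicates), indels, multi-allelic
sites, splice isoforms, batch effects, and composition-driven
normalization problems (library sizes vary ±30% but TMM-style
normalization is out of scope).  Passing tests show the pipeline's
logic is correct under the stated statistical structure — not that a
specific field study's numbers are reproducible from its reads.

## Numerical and degenerate-input choices

* Coordinates are 1-based and closed everywhere (GFF3/VCF convention).
* Rounding: half-up for percentages (`roundHalfUp()`), truncation for
  fold ratios (`truncateTo()`); both carry a one-ulp epsilon so decimal
  halves stored in binary round the way a spreadsheet would.
* A spectrum of a single substitution type reports that type as 100.00%
  and flags the Ts/Tv ratio `NA` (undefined denominator).
* An empty DEG set yields an empty enrichment table with a warning; an
  all-zero gene is "untested", never a DEG.
* A VCF record that is not a biallelic SNP fails loudly with its line
  number; a truncated header names the missing column.
* If the locus's chromosome is missing from the annotation, the region
  is `intergenic` with a warning, not an error.
* When GT is absent for a record the genotype is `missing` and when DP
  is absent the depth is 0 (and a zero-depth call is itself reported
  missing by the generator).

## Problem sizes

The test-suite simulations use the default 2 × 100 kb genome with 60
genes; recovery and null-control properties are measured over 10–20
seeds, and the annotation oracle over ~600 CDS variants across both
strands.  These sizes were chosen so the whole suite exercises every
stage in a few minutes on a laptop while keeping Monte-Carlo margins
(e.g. ≥ 18/20 recovery at ~96% expected per-seed success) comfortable.

## Worked example

```{r example, eval = FALSE}
library(emscan)
run <- runPipeline(simulationConfig(seed = 7), quiet = TRUE)
pipelineReport(run)
#> emscan run (seed 7)
#> SNP filter: 100 loci -> 39 homozygous group differences
#> Spectrum: 38 transitions (97.44%), 1 transversions (2.56%), Ts/Tv 38.00-fold
#> Effects: 2 nonsynonymous, 0 stop-gain, 1 synonymous (of 39)
#> DEGs: 20 (FDR < 0.001, |log2 ratio| >= 1)
#> Enriched: ga_biosynthesis (k=16, 80.00% of DEGs, Q=1.62e-10)
#> Candidates: 2 gene(s) (0 up, 2 down): gene004, gene057
```

The planted causal gene (`gene004` at this seed) appears in the
candidate list with direction `down`; the second candidate is a gene
whose spectrum-drawn mutation happened to be nonsynonymous and which
was also planted as differentially expressed — exactly the kind of
coincidental co-hit a real screen must triage by follow-up biology.

## Known limitations

* The DE contrast is a pooled exact test; see above for its variance
  assumptions.  It is the package's documented stand-in, selectable
  thresholds notwithstanding.
* The filter's unanimity rule is conservative; a lenient majority-vote
  variant would retain more loci at higher risk of artifacts.
* Enrichment treats pathways as flat gene sets (no hierarchy or
  overlap correction beyond Bonferroni).
* The candidate intersection cannot distinguish causal from linked or
  coincidental co-hits; it nominates, it does not prove.
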