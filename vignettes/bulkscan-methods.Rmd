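---
title: "Models and methods behind bulkscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bulkscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the synthetic-data
generator, the numerical choices and the known limitations of the
package. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The experimental design being modelled

A biparental cross (parents XAP1 and AYP1) yields an F2 of 200 plants
segregating for a single, fully penetrant recessive sterility locus, so
phenotypes appear in the Mendelian 3:1 ratio. Thirty plants of each
extreme phenotype are pooled: KY (fertile) and BY (sterile). Both parents
(~10x) and both pools (~30x) are sequenced, and only the per-sample
allelic depths at biallelic SNPs enter the analysis — alignment and
variant calling are upstream of this package, whose first real input is a
VCF with per-sample `AD`. The RNA counterpart is a gene-level count
matrix for the four groups with three replicates each.

## SNP index, filtering and the scan statistic

At a site where the parents are homozygous for different alleles, a
bulk's SNP index is the fraction of its reads carrying the *high
parent's* allele. The high parent is a user choice (`high_parent`): the
reference genome is a third line, so ref/alt identity carries no
information about parental origin; defining the index through parental
read majorities fixes the sign convention downstream. Swapping the high
parent maps every index to its complement and negates every delta
without changing which sites are extreme.

Filters are applied in a fixed order and tallied per reason:

1. **parent** — a parent's minor-allele read fraction exceeds `het_tol`
   (default 0.1), or both parents show the same majority allele. Since
   the input is depths rather than genotype calls, the read-fraction
   tolerance stands in for a homozygosity call. The alternative reading
   of the heterozygosity rule — dropping sites that look heterozygous in
   the *bulks* — is implemented behind `homozygous_filter = "bulks"` but
   is not the default, because an F2 bulk is expected to be mixed at
   unlinked loci and the rule would discard most genuine sites.
2. **depth** — fewer than `min_depth = 7` reads in either bulk.
3. **low-index-both** — index below `low_index = 0.3` in *both* bulks,
   the standard QTL-seq artifact filter; a site low in only one bulk may
   be a real signal and is kept.
4. **missing** — remaining no-coverage samples.

Both thresholds are strict inequalities. The scan statistic is
`delta = index_BY - index_KY`. Under the recessive model the sterile
bulk is fixed for the carrier parent's allele (index 1) while fertile
plants are AA:Aa = 1:2, giving expected index 1/3 and an expected delta
of 2/3 at the causal site when the carrier parent is the high parent.

## The null band ("1,000 permutation tests")

Permuting two pooled samples is undefined at a single site, so the null
is simulated, conditional on depth, in the QTL-seq tradition. One
replicate draws, independently per bulk,

* an allele count `k ~ Binomial(2 n_bulk, 1/2)` — the composition of an
  unselected bulk of `n_bulk` F2 plants (each of the 2·n_bulk chromosome
  copies is an independent fair draw between the parents),
* observed reads `r ~ Binomial(depth, k / (2 n_bulk))` at the site's own
  depth,

and forms `delta = r_BY/depth_BY - r_KY/depth_KY`. The band is the
empirical 2.5/97.5 percentile pair over `n_reps = 1000` replicates at
`level = 0.95`, computed once per distinct `(depth_BY, depth_KY)` pair
and cached; each pair's replicate stream is derived deterministically
from the seed, so results do not depend on evaluation order. Type-1
(inverse-ECDF) quantiles are used so that band endpoints lie on the
discrete support of delta and agree exactly with exhaustive enumeration,
which the tests verify for `n_bulk <= 2`, `depth <= 3`. A site is a
candidate when its delta is strictly outside the band; with discrete
read counts this makes the scan slightly conservative (the true outside
probability is at most, not exactly, 5%).

Candidate sites are merged into regions when successive gaps are at most
`merge_gap = 1 Mb`, and regions with fewer than `min_sites = 3` sites
are dropped. These two values are declared assumptions of this package —
the merging rule behind published region counts is typically unstated —
and both are exposed as arguments.

Calibration is checked on no-QTL experiments (random disjoint bulks). A
design point worth recording: sites on one chromosome share the bulk's
60 chromosome draws and are therefore positively correlated, so the
Monte-Carlo standard error of the flagged fraction is estimated across
independent replicate genomes (six in the acceptance suite), not by a
binomial formula across sites, which would understate it.

## Variant-effect annotation

Gene models carry one transcript per gene. A site is located as
intergenic, intronic (including the splice dinucleotides — splice
effects are not modelled), UTR (exonic but outside the CDS), or coding.
For coding sites the alternate base is substituted into the spliced,
strand-oriented CDS — minus-strand alleles complemented — and the
affected codon is translated under the standard genetic code:
synonymous, nonsynonymous, stop-gain (non-stop to stop) or stop-loss
(stop to non-stop). GFF3 and VCF are 1-based inclusive on disk and the
internal tables keep those coordinates; the only 0-based conversion in
the package is the BED export of regions. The tests prove the
codon-local rule equivalent to retranslating the whole mutated protein,
and invariant under reverse-complementing the genome. UTR and coding
exon hits are kept distinct in output (published "exonic" counts often
conflate them; both rollups can be formed from the per-site table).

## Differential expression

The DE stage is deliberately written from scratch rather than wrapped
around a shrinkage-based package: with a known NB simulator and 3
replicates per group, a transparent estimator that the test suite can
check against truth was preferred. The components:

* **Normalization** — median-of-ratios size factors over genes nonzero
  in every library, rescaled to geometric mean 1, with upper-quartile
  fallback. An independent implementation (DESeq2's
  `estimateSizeFactorsForMatrix`) is used in the tests as a cross-check
  only.
* **Dispersion** — per gene, method-of-moments `(s² − m)/m²` per group,
  pooled across the two contrast groups weighted by degrees of freedom,
  floored at 1e-8. Pooling the *estimates* rather than the samples keeps
  the group mean difference out of the dispersion.
* **Test** — Wald statistic on the normalized mean difference with
  `v = m + phi m²`, two-sided normal p; log2 fold change uses a 0.5
  pseudocount to avoid infinities at zero means. All-zero genes are
  untestable (p = 1, lfc = 0, flagged).
* **Calls** — BH within contrast; up/down requires adjusted p < 0.05
  and |log2FC| > 1. The printed threshold in the motivating study reads
  "p-value > 0.05", which is taken as a typo for "<"; and because its
  methods state BH control of the FDR, the adjusted p is used by
  default, with `adjust = FALSE` available. "Up" means higher in the
  sterile bulk BY.
* **Shared DEGs** — same direction in all three contrasts (BY against
  KY, AYP1, XAP1). Since the simulator perturbs only the BY group, any
  true DE gene is differential in all three contrasts, which is what
  makes shared-DEG recovery a meaningful truth-based check.

At n = 3 the moments dispersion is noisy and the normal approximation
liberal for weak signals; the BH step at the gene-list level restores
calibration (the null acceptance check is on the adjusted scale). This
estimator is not recommended over dedicated DE packages for real data;
it exists to make the pipeline self-contained and provable.

## Enrichment, segregation and qPCR arithmetic

Over-representation uses the one-sided hypergeometric upper tail
`P(X >= k)` against user-supplied flat term-to-gene maps, BH across
terms; significance is flagged on the raw p (the convention of the
motivating analysis) with adjusted p reported alongside. Ontology DAG
propagation and length-bias weighting are out of scope. The segregation
test is plain Pearson chi-square against 3:1, df = 1, no continuity
correction (a Yates flag exists); the critical value is computed from
`qchisq`, not hard-coded. `relative_expression_ddct()` implements
2^-ddCt, mapping the calibrator condition to 1.

## The synthetic-data generator

The generator's defaults are the study conditions: F2 of 200, bulks of
30+30, parent depth 10x, bulk depth 30x, one recessive causal locus.
Choices the design left open, decided once here:

* **Map function** — Haldane (crossovers Poisson with mean equal to the
  map length in Morgans, positions uniform, no interference): the
  simplest model consistent with an F2 design.
* **Which parent carries the sterile allele** — unknowable from the
  motivating study; `causal_origin` is a free parameter, default AYP1.
* **Penetrance** — full by default; `phenotype_error` exposes the
  realistic failure mode (bulk contamination by misphenotyped plants).
* **Terminal output** — allelic depths, not reads or BAMs: the
  pipeline's first real input is the AD table, so read-level synthesis
  would add no testable structure.
* **Genome shape** — desk-scale defaults of one 5-Mb chromosome at
  4e-4 SNPs/bp (~2,000 informative SNPs); the calibration experiments
  use nine 5-Mb chromosomes, echoing the foxtail millet karyotype at
  roughly 1/9 physical scale. `genes_per_mb` (default 10) controls gene
  density; gene structures (CDS 240–900 bp, 1–3 exons, GT..AG introns,
  ATG start, clean stop) are constructed so every model translates.
* **Causal gene** — a forward-strand gene is always placed over
  `causal_pos` with an engineered wildtype codon (CAA, TGG or TAT
  depending on codon offset) whose single-base substitution creates a
  stop codon, so the truth the annotation stage must find is a
  stop-gain. The expression spec spikes the causal gene down in BY
  (default lfc −3) plus a configurable number of random DE genes.
* **Sequencing** — depths Poisson; reads Binomial with the true bulk
  allele frequency perturbed by `seq_error` (default 1e-3); parents
  sequenced as homozygotes. One global seed is split deterministically
  per stage (genome, population, bulks, expression, null band), so each
  stage is reproducible alone and whole runs are byte-identical.

What the generator does **not** emulate: read-level artifacts (mapping
bias, base-quality structure, PCR duplicates), indels and structural
variants, segregation distortion, multi-locus or incompletely penetrant
traits, isoform-level expression, and library-preparation batch
effects. Passing tests therefore demonstrate correctness of the
statistics under the stated model, not robustness to these real-data
pathologies.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own desk-scale study conditions: calibration on
six replicate no-QTL genomes of ~2,000 SNPs each; causal-locus recovery
over 50 replicate experiments (one 5-Mb chromosome, ~2,000 SNPs, 30+30
bulks at 30x) with 1,000 null replicates per depth pair; DE calibration
and spike recovery on 2,000-gene matrices (50 spiked genes at lfc 3);
oracle equivalence by exhaustive enumeration at tiny sizes. On these
sizes the full suite runs in a few minutes on one core.

## Known limitations

* The NB Wald test trades power and small-sample rigor for
  transparency; real analyses should prefer established DE packages.
* Region boundaries depend on `merge_gap`/`min_sites`; with a single
  short chromosome fully linked to the causal locus, the "region" can
  legitimately span most of the chromosome.
* One transcript per gene; no splice-effect or frameshift annotation.
* Enrichment assumes the supplied term maps and universe are complete
  and flat.
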