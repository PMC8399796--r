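---
title: "Methods: trio partitioning, transmission inference and conservation scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio partitioning, transmission inference and conservation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analytical problem

A mother (M), an affected offspring (H) and an unaffected sibling (S) are
sequenced; the father is not. Variants present in H but absent from both M
and S ("proband-specific") can have only two origins: a paternal homolog
that was transmitted to H but not to S, or a de novo germline mutation.
Because de novo mutations number in the tens per generation (rate around
1e-8 per nucleotide) while two parental homologs differ at millions of
sites, the chromosomal distribution of proband-specific variants is
dominated by paternal transmission. `limbtrace` exploits this to (i) call
the proband-specific set, (ii) infer which paternal chromosomes were
differentially transmitted, and (iii) rank candidate genes at those
chromosomes by evolutionary conservation.

# Variant model and quality filter

Records are one row per alternate allele (multi-allelic rows are
decomposed; zygosity is computed against the specific allele index).
The quality filter requires read depth strictly greater than 10 and
alternate-supporting reads strictly greater than 3; records with unknown
depth or allele depth *fail* the filter, because admitting unsupported
calls inflates the specific set, the quantity everything downstream relies
on. The sequencing-error check is the one-sided binomial tail
P(X &ge; alt) with X ~ Binomial(depth, error rate); at the typical depth of
20 with 10 alternate reads and a 1% error rate this tail is below 1e-10,
so filtered calls are essentially never base-calling artifacts. We report
the computed tail itself rather than any fixed headline bound.

# Partitioning and category contrasts

A proband record is specific when no matching record exists in M or S.
Matching defaults to the full allele key (chrom, pos, ref, alt); a
position-only mode is available because presence of *any* variant at the
site is arguably enough to disqualify de novo status. Presence in M or S
counts regardless of genotype: the contrast is about presence in the
pedigree, not about zygosity. Two-level contrasts (het/hom, Indel/SNP,
missense/synonymous) use Pearson's chi-square on the 2x2 table without
continuity correction (the correction is available by flag); degenerate
margins flag the p-value as undefined rather than erroring.

# Transmission inference

For chromosome *i*, F_Hi is its share of all specific variants and F_Ni
its share of all non-specific variants; the enrichment is F_Hi/F_Ni, with
1 the neutral reference line. Significance per chromosome comes from the
2x2 chi-square of (chromosome *i* vs all others) x (specific vs
non-specific). A chromosome is called transmitted when enrichment exceeds
1 and p < 0.05. Following the source analysis we do not correct across the
~19 chromosomes by default (a Bonferroni flag exists); de novo mutations
are not subtracted first because their count is negligible against the
haplotype-scale signal.

# Divergence scoring

Between-species divergence per gene uses the Nei-Gojobori (1986) counting
estimator on pre-aligned, in-frame ortholog CDS pairs. Synonymous sites
per codon are the fraction of the nine single-nucleotide changes that
preserve the amino acid; changes to stop codons count as nonsynonymous, so
synonymous plus nonsynonymous sites are exactly 3 per codon. Differences
in multiply-hit codons are averaged over all shortest substitution
pathways, dropping pathways through stop codons (if every pathway is
dropped, all are kept with stop steps scored nonsynonymous). Proportions
are Jukes-Cantor corrected, d = -(3/4) log(1 - (4/3) p); p &ge; 3/4 is
reported as saturated (NA). A counting estimator was chosen over
codon-model maximum likelihood deliberately: it is deterministic,
verifiable by hand enumeration, and fully adequate for *ranking* genes by
conservation, which is all the downstream analysis needs. The per-gene
mis/syn ratio uses only proband-specific SNPs and is emitted only for
genes carrying both a missense and a synonymous specific SNP (the
restriction can be relaxed to a synonymous anchor only). Distribution
comparisons use the two-sample Kolmogorov-Smirnov test (asymptotic
p-values) and Spearman rank correlation with average ranks on ties.

# Conservation mapping

Orthologous sites are mapped through a minimal block table
(source chrom/start, target chrom/start, length, strand) rather than UCSC
chain files: the block format is bit-exactly testable, inverts cleanly,
and carries none of the chain format's score and gap machinery, which this
analysis never uses. A site is conserved when the anchor-species reference
base equals the orthologous base; ambiguity codes are excluded and
counted. Variants are attached to genes directly or, within a 50 kb
window, as associated intergenic sites; 50 kb is a conventional
cis-regulatory neighborhood, and the window is a parameter because no
principled single value exists. Clade codon profiles call a clade
conserved when at least 90% of its species carry the clade's majority
codon; the majority anchor means one derived lineage (e.g. the proband's
own substitution) cannot flip its clade to variable. The 0.9 default is a
conventional choice for "nearly invariant" and is configurable, as is the
focal clade. Clade branch rates are model-free mean root-to-tip path
lengths per clade on a user-supplied tree, reported relative to the focal
(mammal) clade.

# The synthetic trio generator

The generator is first-class, tested code: it defines the conditions every
inference stage is validated under.

* **Genome**: 18 autosomes plus X, 130 Mb each (~2.5 Gb haploid), matching
  the scale at which the de novo arithmetic is usually quoted.
* **Variant classes** per chromosome: 5,000 father-private and 5,000
  mother-private variants, plus population variants shared by both parents
  at 10x the per-parent private count. Carrier parents are heterozygous
  with probability 0.7 (population) or 0.9 (private); heterozygous
  variants sit on one random haplotype, homozygous ones on both.
* **Assortment**: each offspring draws one maternal haplotype per
  chromosome independently (probability 0.5). The paternal homolog is
  drawn once per chromosome -- independently *across* chromosomes, which
  is what Mendel's independent assortment asserts -- and shared by the two
  offspring, except on the designated causal chromosomes, where the
  proband is forced to homolog A and the sibling to homolog B. This
  mirrors the inferred scenario the pipeline is meant to recover: the two
  sperm complements coincide except at the causal chromosomes. Had the two
  offspring drawn paternal homologs independently on every chromosome,
  roughly half of the non-causal chromosomes would be genuinely
  differentially inherited as well, and with a single sequenced sibling
  those would be statistically indistinguishable from causal ones -- the
  method would be validated against an unidentifiable target. Marginally,
  every homolog is still transmitted with probability 0.5, which is the
  property the meiosis-level check measures.
* **De novo mutations**: Poisson(rate x diploid length), default rate
  1e-8, placed uniformly, always heterozygous, recorded only in the truth
  sidecar.
* **Read support**: depth ~ Poisson(20); heterozygous alternate reads
  ~ Binomial(depth, 0.5) (mean 10), homozygous alternate reads are depth
  minus Binomial(depth, 0.01) miscalls.
* **Ortholog pairs**: per codon, a synonymous change with probability
  pS x S_c and a stop-free nonsynonymous change with probability pN x N_c,
  where pS/pN are the difference proportions whose Jukes-Cantor correction
  hits the target dS/dN. This makes the expected NG86 difference counts
  exactly match the targets, so estimator recovery is a genuine
  round-trip.
* **Clade columns**: one ancestral codon per column, substituted per
  species at 0.02 (mammals) or 0.5 (other clades). Default clade sizes
  (12/8/6/6/10) keep every non-focal clade large enough that a fully
  variable clade rarely looks conserved by chance.

What the generator does *not* emulate: alignment and calling artifacts
beyond Poisson/binomial read support, recombination within chromosomes
(whole-chromosome assortment is the modeled regime; an offspring
recombination would dilute, not relocate, the enrichment signal), linkage
between variants, and mutation-rate heterogeneity along the genome.
Passing tests therefore demonstrate correctness of the inference given the
assortment model, not robustness to real-data artifacts.

# Numerical choices and problem sizes

Deterministic seeding: a config's seed fixes all draws, and identical
configs produce byte-identical VCFs. The test suite validates estimator
equalities against independent oracles (pmf summation, expected-count
chi-square, ECDF sweeps, rank-then-Pearson, hand-enumerated codon
pathways) at 1e-12; stochastic checks use bands fixed in advance
(3-sigma binomial for the 0.5 transmission frequency at 10,000 meioses;
15% relative error for dN/dS recovery on 10 kb pairs; 0.05 +/- 0.025 for
the per-chromosome null rejection rate, widened beyond 3 sigma to cover
ten simultaneous per-chromosome checks at 1,000 replicates). End-to-end
recovery uses 100 full-genome trios at the default generator parameters.

The null calibration deserves a note, because the obvious null is not
null. At realistic depths a small fraction of the mother's genotypes fail
the quality filter, so some inherited variants masquerade as
proband-specific; the rate of this dropout leak on a given chromosome
depends on whether the sibling happened to draw the same parental
homologs there, which makes leak counts genuinely heterogeneous across
chromosomes -- the chi-square then rejects massively, and correctly so.
(At default parameters this leak sits two orders of magnitude below the
haplotype-scale causal signal, so it does not disturb recovery.) The
calibration experiment therefore uses a design in which the null actually
holds: a reduced genome (10 chromosomes x 30 Mb, 1,000 private variants
per parent and 10,000 population variants per chromosome), sequencing
depth 60 so dropout essentially never occurs, and a de novo rate of 5e-7
so that each chromosome expects ~30 uniformly placed specific calls --
enough for the chi-square approximation while 1,000 replicates stay
cheap. The packaged pipeline demo runs 19 chromosomes with 2,000 private
variants per parent and a 3x population factor -- a lower shared:private
ratio than the generator default so that proband-specific *genes* (which
must be free of non-specific variants) occur at demo scale.

# Known limitations

* With one sequenced sibling, "differentially transmitted" is only
  identifiable under the assumption that the two paternal complements
  coincide off the causal chromosomes; more siblings would relax this.
* The NG86 estimator underestimates rates at high divergence (saturation
  is flagged, not corrected) and ignores transition/transversion bias and
  codon usage.
* Effect annotation is consumed, not computed: the classifier maps
  annotation terms and trusts the upstream annotator.
* The conserved-site contrast treats sites as independent, which real
  linkage violates.
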