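# limbtrace

Trio comparative genomics for an affected offspring: proband-specific
variant discovery, paternal chromosome-transmission inference, and
candidate-gene prioritization by evolutionary conservation.

## The problem

A mother (M), an affected offspring (H, the proband) and an unaffected
sibling (S) are whole-genome sequenced; the father is not. Variants
present in H but absent from both M and S ("H-specific") can arise only
from a paternal homolog transmitted to H but not to S, or from de novo
mutation. Since de novo mutations number in the tens per generation
(~1e-8 per nucleotide per generation) while two parental homologs differ
at millions of sites, the chromosomal distribution of H-specific variants
reveals which paternal chromosomes were differentially inherited. With
specific frequency `F_Hi = H_i / Σ H` and non-specific frequency
`F_Ni = N_i / Σ N` for chromosome *i*, the enrichment

```
E_i = F_Hi / F_Ni
```

is tested per chromosome by a 2x2 Pearson chi-square (chromosome *i* vs
all others, specific vs non-specific); chromosomes with `E_i > 1` and
`p < 0.05` are called differentially transmitted. Candidate genes on the
called chromosomes are then ranked by conservation: Nei-Gojobori (1986)
dN/dS against ortholog coding sequences with Jukes-Cantor correction
`d = -(3/4)·ln(1 - (4/3)p)`, per-gene missense/synonymous ratios of
H-specific SNPs, orthologous-site conservation through a coordinate block
map, clade-partitioned codon conservation patterns, and per-clade mean
root-to-tip rates on a supplied tree.

A seeded synthetic trio generator (diploid parents, whole-chromosome
Mendelian assortment, de novo mutations, Poisson/binomial read support)
makes every stage testable by parameter recovery; see the methods
vignette (`vignettes/limbtrace-methods.Rmd`) for the model and its
assumptions.

## Worked example

```r
library(limbtrace)
cfg <- default_pipeline_config(seed = 1, out_dir = "demo_run")
report <- run_pipeline(cfg)
print(report)
#> limbtrace run report
#>   specific: 2587 of 139672 (1.9%)
#>   transmitted call: chr7, chr17
#>   clade codon pattern: clade_conserved
```

The demo simulates a trio in which the proband received a private set of
paternal chromosomes 7 and 17, writes `M.vcf`, `S.vcf`, `H.vcf` and a toy
gene annotation to `demo_run/`, reads them back, quality-filters
(depth > 10, alternate reads > 3), partitions, and infers transmission.
The enrichment table shows why the call is made:

```r
e <- report$enrich$enrichment
head(e[order(-e$enrichment), c("chrom", "H_i", "N_i", "enrichment", "p_value")], 4)
#>    chrom H_i  N_i enrichment  p_value
#> 16  chr7 926 6394      7.674 0.00e+00
#> 9  chr17 908 6399      7.519 0.00e+00
#> 8  chr16  63 7341      0.455 5.15e-11
#> 2  chr10  61 7209      0.448 4.69e-11
```

Chromosomes 7 and 17 carry ~7.6x their expected share of H-specific
variants (the proband's untransmitted-to-sibling paternal haplotypes);
every other chromosome sits below the `E = 1` reference line. The
zygosity contrast behaves as inheritance predicts -- H-specific variants
are almost all heterozygous (2565 of 2587) because they sit on a single
paternal haplotype, while shared variants are often homozygous:

```r
report$classify$contrasts$zygosity$table
#>               het   hom
#> specific     2565    22
#> nonspecific 89445 47640
```

and a typical specific call (depth 20, 10 alternate reads) has a
sequencing-error binomial tail of `1.7e-15`, far below any plausible
artifact rate. Per-stage tables (enrichment per variant type, per-gene
dN/dS, conserved-fraction contrast, clade branch rates) are written under
`demo_run/tables/`, and `demo_run/report.json` holds the machine-readable
report. A thin command-line wrapper with `simulate`, `classify`,
`enrich` and `all` subcommands is installed at `inst/cli/limbtrace`.

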