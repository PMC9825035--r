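# organellotype

Polymorphism, haplotype and heteroplasmy analysis for plant organelle
(chloroplast and mitochondrial) genomes, starting from a multi-sample VCF
with per-sample allele depths.

Organelle genomes are effectively haploid and maternally inherited, so a
resequenced crop panel carries a small set of *cytoplasm lineages*: most
accessions fall into a handful of organelle haplotypes with strongly
skewed frequencies, and domesticated and wild gene pools share few of
them. `organellotype` reconstructs that structure:

- **Repeat masking** — duplicated regions of the (circular) reference are
  found by seeded, X-drop-extended self-comparison (`find_repeats`,
  defaults `min_len = 100` bp, `min_identity = 0.95`) and variants whose
  REF span overlaps the mask are removed (`filter_variants`).
- **Variant statistics** — SNP/InDel and bi-/multi-allelic
  classification (`classify_site`), the transition/transversion ratio
  over biallelic SNPs (`ts_tv_ratio`), and a translation-based coding
  effect predictor (`annotate_effect`: synonymous/missense/nonsense/
  frameshift/inframe_indel with low/moderate/high/modifier impacts).
- **Haplotyping** — polymorphic sites are reduced to **tag sites** by
  *perfect linkage*: two sites are grouped iff they induce identical
  accession partitions on their common observed accessions (r² = 1),
  closed transitively (`linkage_partition`). Accessions are assigned the
  exact allele vector they carry over the tags (`assign_haplotypes`),
  haplotypes are named by frequency rank in a naming population
  (`name_haplotypes`: CT1, CT2, ... / MT1, ...), connected in a minimum
  spanning network over Hamming distances with equal-length alternative
  edges retained (`build_network`), and clustered into groups by
  average-linkage at a chosen k (`cluster_groups`: CTG1, ...).
- **Cytoplasm typing** — chloroplast and mitochondrial assignments are
  joined into types like `CT1/MT1` (`join_assignments`) and tabulated by
  country/region/province with half-up one-decimal percentages
  (`distribution_table`), shared wild/cultivated haplotypes
  (`shared_haplotypes`) and unbiased haplotype diversity
  H = n/(n−1)(1 − Σpᵢ²) (`diversity_summary`).
- **Heteroplasmy** — per-accession reference allele frequency
  RAF = AD_ref/(AD_ref+AD_alt) at designated sites (`compute_raf`,
  undefined below 10 reads), per-site medians and het-band fractions
  (`site_profile`), and Wilcoxon rank-sum comparisons between accession
  strata (`compare_strata`).
- **Synthetic data with planted truth** — `generate_reference`,
  `simulate_panel`, `emit_vcf` and `write_truth` produce FASTA/GFF3/VCF/
  TSV/JSON inputs whose every property is known, so each stage above has
  a recovery test with no external data.

## Worked example

```r
library(organellotype)
res <- run_pipeline(default_config(seed = 1, n_accessions = 300L),
                    out_dir = "demo_out", verbose = FALSE)
res$recovery
#> CHL MIT
#>   1   1
res$summary$CHL
#> masked_fraction         n_sites           ts_tv
#>       0.2000000      20.0000000       0.5384615
```

The pipeline simulated two organelle references (a 15 kb chloroplast-like
contig with one 1.5 kb repeat pair — hence masked fraction 0.200 — and a
30 kb mitochondrion-like contig), a 300-accession panel per organelle,
and recovered the planted haplotype assignment for 100% of accessions
(`res$recovery`). The output directory holds plain tables ready for
plotting, e.g. the haplotype definitions (tag-site alleles per named
haplotype):

```r
read.table("demo_out/CHL_haplotypes.tsv", header = TRUE, sep = "\t")[1:5, 1:6]
#>   haplotype   n p.605 p.1476 p.1727 p.2145
#> 1       CT1 202     A      C      C      T
#> 2       CT2  61     A      T      C      T
#> 3       CT3   9     G      C      C      A
#> 4       CT4   7     G      C      G      T
#> 5       CT5   4     G      T      G      T
```

CT1 carries 202 of 300 accessions — the frequency skew the generator
plants by default. The heteroplasmy profile recovers the planted mixed
signal at the two declared mitochondrial sites (target RAFs 0.664 and
0.700 at mean depth 60):

```r
read.table("demo_out/raf_profiles.tsv", header = TRUE, sep = "\t")
#>    site n_defined median_raf fraction_heterozygous
#> 1   p.3       300  0.6619634                     1
#> 2 p.896       300  0.6964286                     1
```

A command-line front end with `mask`, `stats`, `haplotype`, `raf`,
`simulate` and `all` subcommands is installed under
`system.file("cli", "organellotype.R", package = "organellotype")`.

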