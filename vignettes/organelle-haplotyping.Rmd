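---
title: "Organelle haplotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organelle haplotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organellotype)
```

## The problem

Plant chloroplast and mitochondrial genomes are effectively haploid and
(almost always) maternally inherited. In a resequenced crop panel their
variant calls therefore encode a small number of *cytoplasm lineages*:
most accessions carry one of a handful of organelle haplotypes, with
strongly skewed frequencies and near-disjoint haplotype sets between a
domesticated crop and its wild relative. This package turns a
multi-sample VCF (with per-sample allele depths), a reference FASTA, gene
models and an accession metadata table into:

1. a repeat mask for the reference (organelle genomes are repeat-rich and
   reads in duplicated regions cannot be placed uniquely),
2. variant classification, Ts/Tv, and coding-effect calls,
3. tag sites, haplotype assignments, a haplotype network and haplotype
   groups per organelle,
4. joint cytoplasm types with geographic composition and diversity
   tables, and
5. per-accession reference allele frequencies (RAF) at designated sites,
   the working signal for heteroplasmy.

Every stage is also exercised against a synthetic-data generator that
plants fully known truth, so the pipeline has recovery tests that need no
external download.

## Repeat detection and masking

`find_repeats()` is a deterministic stand-in for a blastn self-search:
exact k-mer seeds (k = 21 by default, reduced to `min_len` on toy inputs)
select diagonals of the self-comparison (and of the comparison against
the reverse complement for inverted repeats); on each diagonal, exact
match runs of at least k bases are extended by an X-drop walk. The
mismatch penalty is `min_identity / (1 - min_identity)`, which makes any
segment ending at the running score maximum satisfy the identity floor by
construction; the X-drop allowance (`5 * mu + 10`) is large enough to
cross small mismatch clusters inside a degraded repeat copy but stops
within a few bases of random flanking sequence. At `min_identity = 1`
the procedure reduces exactly to maximal exact match runs, which is what
the brute-force O(n^2) oracle in the test suite enumerates.

Defaults `min_len = 100`, `min_identity = 0.95` express "long,
near-identical duplication". E-values, gapped alignment and repeat
families are out of scope. Circular genomes are handled by doubling the
sequence and collapsing shifted duplicates, so repeats crossing the
origin are found; masks wrap origin-crossing intervals. A variant is
masked when its *reference allele span* overlaps any masked base — the
conservative any-overlap rule, so a long deletion touching a repeat edge
is removed.

## Variant classification and effect annotation

A site is a SNP iff ref and all alts have length 1; an InDel iff every
alt changes length; alt alleles that disagree are `"mixed"`. Ts/Tv is
computed over biallelic SNPs only, with `NaN` as the sentinel when none
exist and `Inf` when there are transitions but no transversions.

Effect calls substitute each alt allele into the CDS, translate
(strand-aware, minus-strand alleles reverse-complemented with the CDS)
and compare proteins. Substitutions are resolved codon-locally; indels by
full-protein comparison. A coding indel with length change not divisible
by 3 is a frameshift. Start-loss, stop-gain and stop-loss are all folded
into `"nonsense"` to keep the impact map small: frameshift/nonsense are
high impact, missense/inframe_indel moderate, synonymous low, everything
else modifier. A variant partially overlapping a CDS boundary, or a gene
with inconsistent phase, yields `"non_coding"` (with a warning for the
phase case) rather than a guessed protein change.

The genetic code is configurable: table 1 (standard; also used by plant
mitochondria) is the default, table 11 fits plastids. All translation
uses `no.init.codon = TRUE`; initiator-codon semantics are handled by an
explicit ATG check, not by the translator (otherwise alternative
initiation codons such as CTG would silently translate as Met in codon 1
and corrupt codon-local comparisons).

## Tag sites by perfect linkage

The spec of a "tag SNP" here is lossless compression: two sites belong to
the same linkage group iff, over the accessions where both are observed,
they induce *identical partitions* of accessions (allele labels
irrelevant; r² = 1 on complete pairs). Anything weaker would change the
haplotype count unpredictably, so no threshold parameter is offered. With
missing data the pairwise relation need not be transitive, so the
relation is closed transitively (union-find over pairwise checks). The
tag of a group is its leftmost biallelic SNP, falling back to the
leftmost site in groups without one — SNPs genotype more reliably than
indels, and the choice matches the convention of reporting "tag SNPs".
Sites observed in fewer than two accessions, and monomorphic columns, are
excluded with warnings.

Haplotype assignment is exact matching over the tag sites: an accession
with any missing tag call is *unassigned and reported*, never imputed —
imputation would silently create haplotypes. Heterozygous diploid GT
calls (heteroplasmy) collapse to the majority allele by allele depth;
depth ties become missing.

## Naming, network, groups

Haplotypes are named `prefix + rank` (CT1, CT2, ... / MT1, ...) by
descending carrier count within a *naming population* — the cultivated
accessions by default, since lineage names in domesticated panels are
conventionally anchored on the crop; ties break by full-panel count, then
by lexicographic allele vector, making naming permutation-invariant.

The network is a minimum spanning tree over pairwise Hamming distances
(Kruskal with edges sorted by length, then by endpoint frequency ranks —
fully deterministic), plus every non-tree edge whose length equals the
maximum edge weight on the tree path it would shortcut; such edges belong
to some equally minimal spanning tree and are retained as
`alternative_edges`, which is what a haplotype-network figure draws as
dashed ties. Haplotype groups come from average-linkage hierarchical
clustering of the same distance matrix cut at `k` clusters; `k` is a
parameter (no claim that a particular k "emerges" from the data), and
groups are labeled by descending total accession count.

## Cytoplasm typing and summaries

Joint types are the inner join of the two organelle assignments
(`"CT1/MT1"`); accessions unassigned in either organelle are excluded
*and counted*. Percentages in composition tables are rounded half-up to
one decimal, matching how such tables are conventionally printed
(1712/2473 prints as 69.2) and making the worked examples
bit-reproducible; base R's round-half-to-even would print 18.2 where a
published table says 18.1 often enough to matter. Accessions with empty
metadata fields become an explicit `"unknown"` category so totals always
reconcile. Haplotype diversity is the unbiased estimator
H = n/(n−1) · (1 − Σ pᵢ²), undefined below n = 2.

A contingency chi-square (`composition_test()`) is provided for
questions like "are the top haplotypes distributed differently between
two regions"; it is a utility, not a claim about which test any
particular study used.

## Heteroplasmy as reference allele frequency

For designated sites, RAF = AD_ref / (AD_ref + AD_alt) per accession,
using only the designated alt allele at multi-allelic sites. RAF is
undefined below `min_depth = 10` reads — below that the ratio is mostly
sampling noise; the threshold is this package's choice. A defined RAF
strictly inside the het band (default (0.05, 0.95)) counts as
heteroplasmy-like mixed signal; the band separates sequencing-error tails
from genuine mixture and is likewise a package default, not a published
constant. Strata are compared with a two-sided Wilcoxon rank-sum test
(again: a documented choice, the underlying studies typically say only
"significantly higher"); strata with fewer than 3 defined values are
flagged and not tested. Whether intermediate RAF reflects true
heteroplasmy or nuclear insertions of organelle DNA is explicitly not
modeled — the module measures the signal only.

## The synthetic world

`generate_reference()` draws a uniform-random circular genome, copies
repeat units into non-overlapping positions (optionally inverted,
optionally mutated down to a target identity) and plants single-CDS genes
(ATG, internal-stop-free codons, terminal stop) clear of the repeats so
translation is well defined. `simulate_panel()` draws accession
haplotypes i.i.d. from the stated frequency vector; the default demo skew
(leading haplotypes at roughly 70% and 18%, the remainder geometric)
mirrors a domesticated-crop organelle panel, and the default geography
table is China-majority with an explicit unknown-origin share — shapes,
not claims of realism. `emit_vcf()` uses Poisson(mean depth) total depth
per call, a 0.002 per-read error rate (enough to make RAF estimation
nontrivial, small enough not to flip majority calls at depth 60), and
Binomial(depth, RAF) reference counts at declared heteroplasmic sites.

Two generator decisions deserve emphasis. First, a declared heteroplasmic
site carries *no* between-haplotype variation: its column of the
haplotype matrix is forced to REF, because its variation is
within-individual, and a site whose calls collapse to the majority allele
for everyone cannot (and should not) discriminate haplotypes; the
generator refuses specs whose haplotypes become indistinguishable after
this. Second, the per-accession "true RAF" is the target itself, with no
extra accession-level jitter, so the binomial recovery bounds used in the
tests are exact statements about the generated world.

What a green test establishes: recovery of planted truth under i.i.d.
sampling, independent sites, uniform depth and a symmetric error model.
What it does not: linkage generated by a coalescent, reference bias,
mapping artifacts in repeat regions, batch effects between sequencing
projects, or real organelle sequence composition. Read-level simulation
is out of scope.

## Numerical and tie-breaking choices

- Coordinates are 0-based half-open internally and at BED interfaces,
  1-based inclusive in VCF/GFF3.
- All RNG flows from a single seed via a stable string hash
  (`derive_seed()`), so each stage reproduces independently; derived
  seeds stay below 2³¹.
- MST ties: edge order (length, rank of endpoint A, rank of endpoint B).
- Naming ties: naming-population count, full-panel count, lexicographic
  allele vector.
- Group labels: total accession count, then smallest member rank.
- Degenerate inputs: empty variant sets give all-zero summaries; a
  single haplotype gives a one-node network and one group; `ts_tv_ratio`
  returns `NaN`/`Inf` sentinels rather than dividing by zero.

## Known limitations

- The repeat finder is ungapped; a duplication interrupted by an
  insertion is reported as two pairs.
- Effect annotation handles single-CDS gene models only (organelle genes
  here are modeled without introns); multi-exon support would need a
  spliced-coordinate layer.
- Perfect-linkage grouping is transitively closed, so with missing data
  two sites can share a group without being pairwise verified on any
  common accession.
- At `k` far from the natural cluster structure, average-linkage groups
  are a partition of convenience, as with any cut of a dendrogram.
- In the demo pipeline the two organelles' panels are simulated
  independently, so joint cytoplasm types show no CT–MT co-inheritance
  (a real panel is dominated by a few correlated joint types) and the
  species metadata, taken from the chloroplast panel, is independent of
  the mitochondrial haplotype labels. The `cytoplasm` module itself is
  indifferent to this; to emulate co-inheritance, drive both organelles
  from one `simulate_panel()` truth.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(default_config(seed = 1), out_dir = "demo_out")
res$recovery   # fraction of accessions recovered per organelle
res$summary    # masked fraction, site counts, Ts/Tv per organelle
```

On the default 300-accession demo this completes in well under a minute
on one CPU and reports 100% haplotype assignment accuracy against the
planted truth; the same numbers are asserted by the test suite.
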