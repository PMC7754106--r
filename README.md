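# locusrank

Candidate-gene prioritization at GWAS risk loci.

After a genome-wide association study, each significant signal tags a region
containing many genes, and the nearest gene is often not the causal one.
`locusrank` implements, as a reusable R pipeline, the evidence-aggregation
approach used by public post-GWAS gene-prioritization browsers for
Parkinson's disease:

1. **Locus partitioning.** Per chromosome, the variant with the smallest P
   below the genome-wide threshold (P < 5×10⁻⁸) is taken as a lead, it and
   all variants within 1 Mb are extracted, and the region lead ± 1 Mb is
   recorded; this repeats until no significant variant remains, then regions
   whose edges lie within 100 kb are merged transitively.
2. **LD from a reference panel.** Pairwise D, D′ and r² are estimated from
   unphased diploid genotypes by EM over the four two-locus haplotype
   frequencies (only the double heterozygote is phase-ambiguous). Proxy
   variants are those with r² > 0.7 to the risk variant.
3. **eQTL colocalization by correlation.** For every gene × eQTL dataset
   (brain eQTL, blood eQTL, brain isoQTL), GWAS and eQTL −log₁₀ P values are
   paired over shared variants; a locus-compare plot is *eligible* if it
   contains the risk variant or a good proxy, and the Pearson correlation r
   of the paired columns is reported when at least 10 variants are shared.
4. **Evidence bits.** Each data source maps to a 0/1/NA column per gene:
   expression above 5 TPM in brain, substantia nigra, and nigral
   dopaminergic neurons; QTL-brain / QTL-blood plot eligibility; |r| > 0.3
   for QTL-correl; ≥ 5 disease-specific literature hits; gnomAD-style
   constraint (90% CI upper bound of any observed/expected ratio < 0.35);
   rare-variant burden significance after per-source Bonferroni correction;
   and membership flags for meta-analysis-nominated, monogenic-PD, and
   Mendelian disease gene lists.
5. **Conclusion score.** The ranking statistic per gene is

   score(g) = Σ_c w_c · bit_c(g),  w_c ∈ {0, 1, 2, 3, 4},  NA → 0

   with unit weights by default, so the score is simply the number of
   evidence columns set to 1.

A seeded synthetic-data generator (haplotype-block panel with planted LD,
z-score-scale summary statistics with planted causal variants, colocalized
and non-colocalized eQTL genes with known truth) makes the whole pipeline
testable offline, and a `plb` command-line driver wraps the stages.

## Worked example

```r
library(locusrank)

cfg    <- sim_config(seed = 7)           # 400 diploids, 60 variants, 1 locus
panel  <- simulate_panel(cfg)
ss     <- simulate_sumstats(cfg, panel)
loci   <- partition_loci(ss)
tidy(loci)
#> # A tibble: 1 × 7
#>   locus_id chrom   start     end n_leads lead_rsids    min_p
#>      <int> <chr>   <dbl>   <dbl>   <int> <chr>         <dbl>
#> 1        1 1     3957627 5957627       1 rs1_28     2.45e-67
```

One locus: the lead variant rs1_28 sits in the causal variant's haplotype
block, and the region spans lead ± 1 Mb. Evidence assembly and ranking:

```r
eqtl  <- simulate_eqtl(cfg, panel, ss)
prox  <- find_proxies(loci$leads[[1]]$variant_id[1], panel)
nrow(prox)
#> [1] 9          # panel variants with r2 > 0.7 to the lead

# ... load expression/constraint/burden/flag/literature tables, then:
# ev <- assemble_evidence(loci[1, ], genes, ss, eqtl, expression,
#                         literature, constraint, burden, flags,
#                         panel = panel)
# rank_genes(ev)
```

In a run with colocalized and non-colocalized genes planted at the locus
(see `vignettes/locusrank.Rmd`), the ranked evidence table looks like:

```
  locus_id gene  brain_expr ... qtl_brain qtl_blood qtl_correl ... conclusion rank
1        1 L1C1           1             1         1          1             7    1
2        1 L1C2           1             1         1          1             6    2
3        1 L1N1           1             1         1          0             5    3
4        1 L1N2           1             1         1          0             5    4
```

The planted colocalized genes (`L1C*`) receive the QTL-correl point (their
eQTL profile shares the GWAS causal variant, so the −log₁₀ P correlation
exceeds 0.3); the non-colocalized genes (`L1N*`) have eligible plots but low
correlation, and rank below them.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/plb simulate --seed 7 -o bundle/
Rscript inst/cli/plb partition --sumstats bundle/sumstats.tsv -o out/
Rscript inst/cli/plb score --sumstats bundle/sumstats.tsv \
  --genes bundle/genes.bed --panel bundle/panel.vcf \
  --eqtl-brain bundle/eqtl_brain.tsv --eqtl-blood bundle/eqtl_blood.tsv \
  --isoqtl bundle/eqtl_isoqtl.tsv --expression bundle/expression.tsv \
  --constraint bundle/constraint.tsv --burden bundle/burden.tsv \
  --flags bundle/flags.yaml --literature bundle/literature.tsv -o out/
```

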