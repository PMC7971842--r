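# poescan

Parent-of-origin (imprinting) effect scans from case-parent family
genotypes, using a log-linear model over trio genotype categories.

## The problem

For some birth defects the risk conferred by a variant allele depends on
which parent transmitted it — a parent-of-origin effect, most often caused
by genomic imprinting. Case-parent designs detect this without controls: an
affected child and (where available) both parents are genotyped, and among
heterozygous case children one asks whether the single minor allele was
inherited paternally more or less often than maternally, beyond what Mendel
predicts. `poescan` implements this analysis end to end for candidate-gene
SNP panels typed in case families (e.g. the NBDPS obstructive-heart-defect
families: 569 case families, 877 SNPs in folate, homocysteine and
transsulfuration pathway genes, only 38.7% of them full trios), and, because
such genotype data are access-restricted, ships a generator that simulates
panels with the same structure.

## The model

For a biallelic SNP, every Mendelian-consistent (mother, father, child)
minor-allele dosage combination is a cell of a multinomial over case trios;
the ambiguous cell (all three heterozygous) splits by the origin of the
child's minor allele, giving 16 cells over 15 observable categories. The
expected cell count is log-linear:

    E[n_cell] ∝ μ_j · t · R_c · S_m · W^{1[paternal]}

where `μ_1..μ_6` are mating-type stratum weights (the six unordered parental
genotype pairs; `μ_6 = 1` as gauge) absorbing population structure, `t` is
the Mendelian transmission factor (1, ½ or ¼), `R_1, R_2` are child genotype
relative risks, `S_1, S_2` maternal genotype relative risks, and `W` is the
parent-of-origin relative risk: disease risk when a heterozygous child's
minor allele is paternally derived, relative to maternally derived. Families
missing a parent contribute through the sum of compatible cells
(marginalisation under the same μ). `W` is estimated by maximum likelihood;
the imprinting test is the likelihood-ratio statistic of `W = 1` against
χ²(1), with a Wald 95% CI on log W; a panel scan applies a Bonferroni
threshold `α / n_tested`.

Upstream, SNPs are filtered as in standard family-panel QC: no-call rate
> 10%, trio Mendelian-error rate > 5%, founder MAF < 5%, or exact
Hardy-Weinberg p below `hwe_alpha` in any population stratum.

## Worked example

```r
library(poescan)
cfg <- sim_config(n_families = 569, n_snps = 6, mafs = rep(0.3, 6),
                  signal_snps = list("3" = poe_params(W = 0.3)), seed = 11)
panel <- simulate_panel(cfg)
panel
#> trio_panel: 569 families x 6 SNPs (232 full trios)

run_scan(panel, config = scan_config())
#> Parent-of-origin scan: 6 SNPs tested, threshold 0.00833
#>   significant SNPs: 1
#>    snp_id  gene          pathway    rr_poe      p_value significant
#> 1 snp0003 GENE1 transsulfuration 0.2824388 0.0002577449        TRUE
#> 2 snp0005 GENE1           folate 1.4946560 0.2207833628       FALSE
#> 3 snp0004 GENE1            other 1.2882955 0.3609443855       FALSE
#> 4 snp0001 GENE1           folate 1.2052162 0.5619952563       FALSE
#> 5 snp0006 GENE2     homocysteine 1.0535299 0.8466957681       FALSE

fit_snp(panel_trios(panel, "snp0003")[, c("m", "f", "c")])
#> Parent-of-origin log-linear fit
#>   families: 569 (187 origin-informative)
#>   RR (paternal vs maternal origin) = 0.282 (95% CI 0.143, 0.557)
#>   LRT = 13.355, p = 0.000258
```

The planted SNP (true `W = 0.3`: paternal copies of the minor allele carry
0.3 times the risk of maternal copies) is recovered at `RR = 0.28` and is
the only SNP below the Bonferroni threshold `0.05 / 6`; the other five SNPs
were simulated under the null. `write_scan()` serialises the ranked results
table, Manhattan-plot data, the RR-by-pathway table and the QC report as
TSV. A command-line wrapper with `simulate`, `qc`, `fit` and `scan`
subcommands is installed under `exec/poescan`.

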