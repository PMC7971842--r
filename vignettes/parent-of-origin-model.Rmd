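---
title: "The case-parent trio log-linear model behind poescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The case-parent trio log-linear model behind poescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poescan)
```

## The design and the model

`poescan` analyses *case-parent families*: an affected child plus whichever
biological parents could be genotyped, with no control sample. The question
it answers per SNP is whether a heterozygous case child's single minor
allele comes from the father more or less often than from the mother, after
accounting for Mendelian transmission, parental mating structure and a
possible direct maternal genotype effect. A systematic excess or deficit of
paternal transmissions is the signature of a parent-of-origin effect,
classically produced by genomic imprinting (silencing of one parental
copy).

Enumerating every Mendelian-consistent combination of mother, father and
child minor-allele dosage yields 15 observable trio categories; exactly one
— all three members heterozygous — is ambiguous about the origin of the
child's minor allele and is split into a maternal-origin and a
paternal-origin cell, so the model's support has 16 cells
(`build_cell_table()` derives this by walking allele transmissions rather
than hard-coding it). The expected count in a cell is log-linear:

$$ E[n_{\text{cell}}] \propto \mu_j \, t \, R_c \, S_m \, W^{\,[\text{paternal}]} $$

* $\mu_1,\dots,\mu_6$ — *mating-type stratum weights*, one per unordered
  parental genotype pair $\{2,2\},\{2,1\},\{2,0\},\{1,1\},\{1,0\},\{0,0\}$.
  They are nuisance parameters conditioning on parental genotypes, which is
  what protects the design against population stratification. $\mu_6 = 1$
  is the identifiability gauge. Ordered heterogeneous pairs within a
  stratum share a weight (*parental mating symmetry*); without that
  assumption, $W$ would be confounded with parental asymmetry.
* $t \in \{1, \tfrac12, \tfrac14\}$ — the Mendelian transmission factor of
  the cell within its ordered parental pair; factors sum to one over child
  outcomes, which the tests verify by enumeration.
* $R_1, R_2$ — relative risks for a child carrying 1 or 2 minor alleles
  (versus 0). Dimensionless; default 1.
* $S_1, S_2$ — relative risks attached to the *mother's* genotype,
  capturing prenatal maternal genetic effects. Fitted by default
  (`maternal = TRUE`); constraining $S_1 = S_2 = 1$ gives the reduced
  model. We default to fitting maternal and imprinting effects jointly
  because the maternal effect is part of the model family the package
  implements, and omitting it biases $W$ when a true maternal effect
  exists; the constraint is one flag away.
* $W$ — the parent-of-origin relative risk: the risk multiplier when a
  heterozygous child's minor allele is paternally derived, relative to
  maternally derived. $W$ applies only to heterozygous children; a
  homozygous child carries one copy from each parent, and any such effect
  is absorbed by $R_2$. The reported RR is $\hat W$ itself.

Conditional on the number of ascertained families, the Poisson log-linear
formulation for counts is a multinomial over cells, which is how the
likelihood is implemented; the MLEs of the structural parameters coincide,
so only the multinomial route is coded.

Only 6 of the 16 cells pin the origin of a heterozygous child's allele
unambiguously, and only those (plus, weakly, the split cell) identify $W$.
`fit_snp()` counts the families whose compatible cells include an
origin-tagged cell (`n_informative`) and refuses to estimate $W$ when that
count is zero, returning `rr_poe = NA`, `p = 1` and a warning instead of a
number from a flat likelihood ridge.

## Missing parents

Only a minority of case families are full trios (38.7% in the study design
the defaults mirror). A family with a missing parent contributes the *sum*
of the probabilities of all cells compatible with its observed members —
marginalisation under the same $\mu$ parameters, with no external
allele-frequency or Hardy-Weinberg assumption about the missing parent.
This is the conservative choice: it costs information relative to assuming
HWE for parental genotypes but cannot be biased by that assumption failing.
Child-only families are accepted and contribute almost nothing to $W$.
`loglik_observed()` equals `loglik_complete()` whenever nothing is missing;
the test suite checks it against brute-force compatibility sums over
enumerated cells at 1,000 random parameter/missingness instances
(agreement within 1e-10) and checks marginalisation consistency by summing
hidden-parent values explicitly.

## Quality control conventions

The per-SNP filters and their defaults:

| filter | default | convention |
|---|---|---|
| no-call rate | > 0.10 fails | missing calls / slots of *study-genotyped* members. A parent absent from the pedigree (or uncalled at every SNP) is structurally absent, not a no-call: with ~61% incomplete families, counting absent parents would push every SNP past 10% and void the filter's intent. |
| Mendelian-error rate | > 0.05 fails | inconsistent complete trios plus impossible parent-child duos (opposite homozygotes), over complete trios plus duos. Restricting to informative comparisons is the standard choice where none is dictated. |
| founder MAF | < 0.05 fails | parents only, pooled across strata — case children are ascertainment-biased. |
| HWE | p < `hwe_alpha` in *any* stratum fails | exact two-sided test (probability-ordering convention) on founder genotype counts within each population stratum. |

`hwe_alpha` defaults to 1e-4: at a few-hundred-to-thousand SNP panel scale
a nominal 0.05 would discard sound SNPs by multiplicity alone, while 1e-4
still catches genotyping artefacts; it is a tunable, not a claim about any
particular study's unstated choice. The exact HWE test is implemented in
the package (enumeration over heterozygote counts conditional on allele
counts) because no installed dependency provides it; it is validated
against an independent full-enumeration oracle.

Failing SNPs are dropped before modelling, never imputed, and every input
SNP appears in the QC report with its failure reasons.

## Fitting numerics

Both models (full, and null with $W \equiv 1$) are maximised with BFGS on
log-scale parameters using analytic gradients (cell log-weights are linear
in the log parameters), relative tolerance 1e-14, at most 1,000 iterations,
and 3 restarts from deterministically jittered starts (the jitter uses a
private RNG stream so fits never perturb the caller's random state). Mating
strata with no compatible observation are removed from the support — the
boundary MLE $\mu_j \to 0$ — with the gauge moved to the highest-index
active stratum; both models share the active set, preserving LRT nesting.
Standard errors come from the finite-difference observed information at the
optimum (`stats::optimHess`), with a pseudo-inverse fallback for
near-singular cases; zero counts in informative categories receive no
continuity correction, since the multinomial handles structural zeros
naturally. The LRT statistic is clipped at 0 (tolerance −1e-8) and referred
to $\chi^2_1$; p-values are from the LRT, while the 95% CI is Wald on
$\log W$ — the two can disagree in borderline cases, which is inherent to
reporting that pair. Stationary-point tests require recovery of a known
parameter vector from exactly proportional counts to 1e-4 relative error.

## What the simulator emulates — and what it does not

`simulate_panel()` draws parental genotypes under random mating at the
SNP's MAF (HWE, or inbred with coefficient $F$ in the optional second
stratum), transmits alleles fairly while tracking origin, and *ascertains*
case families by rejection sampling with acceptance probability
proportional to $R_c S_m W^{[\text{paternal}]}$ — the generative inverse of
the fitted model; the origin tag is then discarded, as it is unobservable.
Defaults mirror the study design the package targets: 569 families, 38.7%
full trios, the father being the missing parent in 90% of incomplete
families (the real missingness mechanism is undocumented; this is a
configurable default, not a claim), MAF bounded below at 0.05. Family
completeness is assigned once per family so missingness is consistent
across SNPs; per-genotype no-calls are added independently at
`nocall_rate`.

Deliberately not emulated: linkage disequilibrium between SNPs (columns are
independent), genotyping-error confusion beyond no-calls, admixture beyond
the two-stratum option, multiple affected siblings, and phenocopy or
penetrance scales (a case-only family design identifies relative risks
only). Passing tests therefore demonstrate correctness of the estimator
under its own model assumptions, not robustness to LD, batch artefacts or
cryptic relatedness in real panels.

Because the simulator satisfies HWE random mating, the implied mating-type
weights are products of genotype frequencies and the tests can (and do)
compare empirical category frequencies against `cell_probs()` with those
implied $\mu$ (total-variation distance < 0.01 at 100,000 families).

## Validation problem sizes

The shipped test suite validates, beyond the unit oracles: null calibration
of the imprinting LRT on 2,000 simulated panels of 500 families at MAF 0.3
under the default completeness mix (Kolmogorov–Smirnov agreement with
$\chi^2_1$ and empirical type-I error within the binomial band
[0.040, 0.060] at $\alpha = 0.05$); and parameter recovery at the study's
own scale — 200 replicates of 569 families, 38.7% full trios, MAF 0.3, true
$W = 0.3$ — requiring the median $\hat W$ within Monte-Carlo error of the
truth and 95% CI coverage in [0.92, 0.98]. MAF 0.3 is used for these
Monte-Carlo suites as a representative common-variant frequency giving a
healthy supply of origin-informative cells.

## Scan and multiplicity

`run_scan()` fits every SNP surviving QC, sorts by p (ties by chromosome,
then position) and applies the Bonferroni threshold $\alpha / n$ with $n$
the number of SNPs *actually tested* post-QC — the published 877-SNP
threshold $0.05/877 = 5.70\times10^{-5}$ is the reference case. Exact
division is kept internally; rounding is display-only. The scan emits
plot-ready tables (Manhattan coordinates, RR by pathway) rather than
figures.

## Known limitations

* Autosomal biallelic SNPs only; no X-linked dosage conventions, phased
  data or multi-allelic markers.
* One case child per family; additional affected siblings are dropped with
  a warning rather than modelled as sibships.
* The Wald CI can be poorly calibrated when origin-informative counts are
  very sparse even though the LRT p-value remains usable; `n_informative`
  is reported so users can judge.
* Bonferroni control is the only multiplicity correction offered, by
  design.
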