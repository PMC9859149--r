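# mkgblup

Multi-kernel Bayesian GBLUP for genomic prediction in populations with
subpopulation structure, where SNP marker effects may differ between
groups.

## The problem

When a genomic-prediction training population is assembled by merging
subpopulations — breeds, lines, or regional groups of one breed with
partly separate breeding histories — the linkage-disequilibrium phase
between markers and causal variants is not fully persistent across
groups, so a marker's allele substitution effect can differ between
groups. The motivating setting is beef-cattle carcass evaluation with
fattened steers marketed into three regions (group sizes 1036/733/279),
one group descending from a more closed, diverged subpopulation, with
two traits: cold carcass weight (kg) and marbling score (ordinal 1–12).

`mkgblup` is for quantitative geneticists who want to fit and compare the
model family that handles this: marker effects partitioned into a part
**common** to all groups and **group-specific** parts, which at the
breeding-value level becomes a GBLUP with one relationship kernel per
component,

    y = Xb + g1 + g2 + e,   g1 ~ N(0, G1 σg1²),  g2 ~ N(0, Gk σg2²),
    e ~ N(0, I σe²),

with `G1 = ZZ'/c` the VanRaden method-1 genomic relationship matrix
(`c = Σ 2pᵢ(1−pᵢ)`, pooled frequencies) and `Gk` a copy of `G1` with
cross-group blocks zeroed — either only the blocks linking one isolated
group to the rest (`G2`) or all cross-group blocks (`G3`). Five variants
are compared by DIC: `G1` alone (model 1), `G1+G2` (2), `G2` alone (3),
`G1+G3` (4), `G3` alone (5). From the variance components,

    σp² = σg1² + σg2² + σe²,   h² = (σg1² + σg2²)/σp²,
    r_g = σg1²/(σg1² + σg2²),

where `r_g` is the between-group genetic correlation. Estimation is by
Gibbs sampling (flat priors on fixed effects, scaled-inverse-chi-square
priors on variances, kernels handled in their eigenbases; the core loop
is C++). SNP effects are back-solved from breeding values as
`Z' K⁻ ĝ / c`, and per-group breeding-value reports expose the
confounding between group fixed effects and group means of breeding
values. A Balding–Nichols generator simulates group-structured genotypes
and phenotypes so the whole pipeline is testable without the (private)
cattle data.

See `vignettes/multikernel-gblup.Rmd` for the methods in full.

## Worked example

```r
library(mkgblup)

cfg  <- sim_config(seed = 42)            # 253/179/68 animals, 3000 SNPs
dat  <- simulate_dataset(cfg)
print(dat$truth)
#> sim_truth: expected vg1 = 0.343, vg2 = 0.147, rg = 0.70;
#>            realized vg1 = 0.315, vg2 = 0.15, rg = 0.68, h2 = 0.48

qc <- qc_filter(dat$genotypes)           # MAF > 0.01, HWE p > 0.001
#> qc_result: kept 2979 / 3000 SNPs (dropped: 1 maf, 20 hwe)

G1 <- vanraden1(qc$genotypes, groups = dat$groups)
G3 <- block_kernel(G1, "per-group")
X  <- build_design(dat$pheno, groups = dat$groups)

ch   <- function(s) chain_config(20000, 2000, 10, seed = s)
fit1 <- run_chain(dat$pheno$trait, X, make_model(1, common = G1),
                  chain = ch(101))
fit4 <- run_chain(dat$pheno$trait, X,
                  make_model(4, common = G1, specific = G3),
                  chain = ch(104))
summarize_run(fit4, baseline = fit1, trait = "trait")
#> model 4 (trait)
#>   delta DIC = -59.0
#>   DIC = 1224.4 (pD = 292.8)
#>            parameter   mean      sd
#>          sigma_g1_sq 0.3416 0.10740
#>          sigma_g2_sq 0.3163 0.09897
#>           sigma_e_sq 0.3930 0.09403
#>           sigma_p_sq 1.0510 0.06663
#>         heritability 0.6255 0.08844
#>  genetic_correlation 0.5176 0.13000
```

Reading the output: the two-kernel model improves the DIC over the
single-kernel baseline by 59 units; the trait has an estimated
heritability of 0.63 ± 0.09, and the estimated between-group genetic
correlation 0.52 ± 0.13 — pulled toward the middle of its range, as
expected on data whose groups share no relatedness (the vignette's
limitations section explains why the common/specific split is only weakly
identified in that case; the generating value here was 0.70). Derived
parameters are per-draw posterior means; the ratio-of-means arithmetic on
a published component table is available directly, e.g.

```r
round(genetic_correlation(941.1, 390.9), 2)
#> [1] 0.71
```

`run_pipeline()` chains all stages (simulate → QC → kernels → models →
summaries → SNP-effect and GBV reports) from one config and writes CSV
reports plus a JSON run manifest.

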