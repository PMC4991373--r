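# vitreomiR

Efficiency-aware qPCR quantification and ratio-biomarker analysis of
ocular-fluid microRNAs.

## What it is for

Neovascular age-related macular degeneration (NV AMD) has no established
non-invasive molecular biomarker. Small cohort studies that profile
microRNAs in vitreous humour and plasma by TaqMan qPCR need a quantification
chain that is rarely available as tested, reusable code: threshold-cycle
(Ct) handling with a 40-cycle detection limit, amplification-efficiency
estimation from raw fluorescence, quality-control exclusions (efficiency
cutoff, hemolysis index, clinical flags, Grubbs outliers), ddCt fold
changes corrected for measured efficiency against a weighted-mean
endogenous reference, per-patient ratio biomarkers with ROC analysis, and a
phased filter of GWAS summary statistics against miRNA binding-site motifs.
vitreomiR implements that chain for analysts working with ocular-fluid (or
any biofluid) miRNA qPCR panels, together with a synthetic cohort generator
so every stage is testable against known ground truth.

## The model

For each sample and miRNA, with a per-sample endogenous reference Ct0:

    dCt  = Ct_miR − Ct0
    ddCt = dCt − mean(dCt over control samples)
    FC   = E^(−ddCt)

where `E ∈ (1, 2]` is the measured per-cycle amplification factor (1.75 for
individual TaqMan qPCR, 1.7 for the array stage; the percent convention is
`100·E/2`, so 1.75 ≙ 88%). In vitreous humour, where no housekeeping miRNA
is established, Ct0 is a weighted mean of several member miRNAs with
weights `w_j ∝ (1/SD_j)^wmp`; in plasma, Ct0 is the single reference
miR-16. Log2 fold changes are centered so the control mean is zero, group
comparison is a Student t-test on centered log2 values, and the
miR-146a/miR-106b per-patient ratio is evaluated as a classifier by
Mann-Whitney AUC with a Hanley-McNeil confidence interval (untruncated at
1) and a normal-approximation p-value against AUC = 0.5.

## Worked example

```r
library(vitreomiR)

cohort <- simulate_cohort(sim_config(seed = 42))   # 13 controls vs 13 cases
fit <- ddct_fit(cohort$records, cohort$meta,
                reference = "single_mir", reference_mir = "miR-16")
summary(fit)
#> Per-miRNA fold-change summary (FC = base^(-ddCt), base = 1.75 )
#> Reference: single_mir (miR-16)
#>
#>    mir_id n_control n_case mean_linear_fc_case sem_linear_case mean_log2_case
#>  miR-106b        13     13              0.1929         0.01830        -2.4815
#>  miR-146a        13     13              2.8031         0.21584         1.4371
#>   miR-152        13     13              0.3113         0.02926        -1.7725
#>    miR-16        13     13              1.0000         0.00000         0.0000
#>   miR-205        13     13              0.9463         0.10041        -0.1781
#>  miR-548a        13     13              1.2282         0.13055         0.1797
#>  sem_log2 t_statistic df   p_value evaluable
#>    0.1773    -10.3591 24 2.457e-10      TRUE
#>    0.1093      6.9241 24 3.682e-07      TRUE
#>    0.1522     -8.5702 24 9.133e-09      TRUE
#>    0.0000      0.0000 24 1.000e+00      TRUE
#>    0.1556     -0.7326 24 4.709e-01      TRUE
#>    0.1753      0.8604 24 3.981e-01      TRUE
```

The generator planted fold effects of 3.02, 0.23 and 0.33 on miR-146a,
miR-106b and miR-152 (1 cycle of Ct noise, technical triplicates); the fit
recovers 2.80, 0.19 and 0.31 in this cohort, the three regulated miRNAs are
highly significant, and the unregulated panel members are not.

```r
ratios <- ratio_values(fit$fc, "miR-146a", "miR-106b")
roc_curve(ratios$ratio, ratios$group)
#> ROC: AUC = 1.0000 (SE 0.0000; 95% CI 1.0000 to 1.0000), p = 1.469e-05
#>   n_case = 13 , n_control = 13
```

The per-patient fold-change ratio separates the groups completely in this
cohort. `run_pipeline(pipeline_config(...))` runs the same chain from CSV
inputs and writes TSV/JSON reports; `run_phases()` filters SNP association
tables against binding-site motifs with Bonferroni and Storey-q adjustment.
See the vignette in `vignettes/mirna-quantification.Rmd` for the model,
its assumptions, and the design choices.

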