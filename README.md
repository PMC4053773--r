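# mirti — miRNA target interactions from AGO2 PAR-CLIP and paired tumor expression

miRNA repression in tumors is real but subtle: across thousands of
predicted miRNA–target pairs, expression correlations barely separate from
background unless the analysis is anchored in biochemistry and restricted
to well-measured transcripts. `mirti` is an R package for that anchored
analysis, written for computational biologists working with paired
miRNA/mRNA patient cohorts and an AGO2 PAR-CLIP library:

1. **Binding-site identification.** Overlapping PAR-CLIP reads (>20 nt) are
   clustered; clusters with <5 reads or <20% crosslinked (T-to-C) reads are
   dropped. Each cluster yields a 41-nt crosslink-centered region (CCR)
   around its major T-to-C position. All 16,384 7-mers are scored in CCRs
   against dinucleotide-preserving shuffles (z-score, add-one empirical p,
   BH q), and canonical seed sites (8mer, 7mer-m8, 7mer-1A, 1–7 match) are
   called per miRNA family with a most-specific-type rule.
2. **Abundance-thresholded correlation shift.** With miRNA relative read
   frequency (RRF > 1e-4) and mRNA abundance (A > 6.5, or detection filters
   for sequencing data), the package computes Pearson correlations for all
   (family, gene) pairs and the difference of medians between target-pair
   and background-pair correlation distributions, tested by Wilcoxon
   rank-sum — overall, across threshold grids, and within molecular
   subtypes.
3. **PAR-CLIP-like classifier (MP-PCLIP).** A binomial elastic net over 16
   prediction- and expression-derived features learns to separate
   crosslinked seed-matched pairs from crosslinked unmatched pairs, scores
   all expressed predictions, and forms the MP-PCLIP set as the union of
   biochemical and model-predicted interactions at a 0.5 posterior cutoff.
4. **Association and prioritization.** A permutation-calibrated global test
   `Q = (1/m) Σ_j (x_jᵀ r)²` (linear, logistic, multinomial and Cox
   residuals) associates family expression with its targets, gene sets and
   a cancer-gene set; equal-weight mean-rank aggregation with permutation
   significance ranks miRNA regulatory activity and phenotype association;
   Cox-mode tests score target prognostic signatures, optionally adjusted
   for clinical covariates.
5. **Synthetic studies.** A generator emits every pipeline input (FASTA,
   BED, TSV, GMT, reads) with planted repression, planted seed sites in
   crosslinked clusters, classifier feature shifts and Cox-generated
   survival, plus ground truth for recovery testing.

## Worked example

```r
library(mirti)

study <- synth_study(synth_config(seed = 7))      # all inputs + ground truth
cfg <- write_synth_study(study, "synth_inputs")   # materialize as files
cfg$seed <- 11
res <- run_pipeline(cfg, out_dir = "results_dir")

res$shift
#>   group_label median_target_r median_background_r median_difference
#> 1         all     -0.01944309        0.0002677499       -0.01971084
#>     wilcoxon_p n_target_pairs n_background_pairs
#> 1 0.0008305387            454               1206

attr(res$mp_pclip, "counts")
#>         n_predicted n_parclip_supported        n_additional
#>                  36                  24                  12

head(res$activity$ranking, 3)
#>   family_id rank_target rank_pathway rank_cancer_genes combined_score rank_test_p
#> 1    miR-10           1            1                 3       1.666667       0.002
#> 2    miR-12           4            3                 1       2.666667       0.010
#> 3     miR-1           6            2                 4       4.000000       0.028
```

The shift is negative (target pairs more anti-correlated than background,
Wilcoxon p = 8.3e-4) because the generator plants repression for the active
families; the MP-PCLIP set unions 24 PAR-CLIP-supported predictions with 12
model-only interactions; and the activity ranking's top entries include
planted active families (`miR-10` here), with permutation rank-test
p-values. Per-stage TSVs (clusters, CCRs, seed sites, k-mer statistics,
correlations, model evaluation, pathway associations, rankings, survival
signatures) land in `results_dir/`.

A thin command-line wrapper is included at `inst/scripts/mirti.R`
(`Rscript mirti.R all --config config.yaml --out results_dir --seed 11`).

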