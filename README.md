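# ThermoPainAssoc

Machine-learned association of next-generation-sequencing-derived
ion-channel gene variants with thermal pain sensitivity phenotypes, as a
tested, reusable R pipeline.

## The problem

Healthy volunteers have no diagnosis, so the pain phenotype must be
discovered before genetics can be mapped onto it. Given z-scored heat
and cold pain thresholds (`zHPT`, `zCPT`), measured at baseline and
after UV-B skin hypersensitization, and biallelic variant calls coded
as non-reference allele dosages `x ∈ {0, 1, 2}` for candidate
thermosensitive ion-channel genes (ASIC and TRP families), the pipeline

1. **discovers phenotype clusters** — derives UV-B effects
   (`UVBEff = z_UVB − z_baseline`), PCA-decorrelates variable blocks
   with |r| > 0.8 (eigenvalue-> 1 retention; a 2-variable block at
   r = 0.812 has eigenvalues 1.812/0.188), projects subjects onto a
   toroidal 50 × 80 emergent self-organizing map (Gaussian
   neighborhood, 20 epochs), and extracts clusters from the U-matrix by
   an automated watershed, validated by the silhouette index and
   explained by RIPPER-style threshold rules;
2. **filters variants** — exact Hardy–Weinberg test (conditional
   enumeration of heterozygote counts), Shannon information
   `Info = −p₀ ln p₀ − p₁ ln p₁` of carrying a variant allele, and
   allelic 2 × 2 χ² effect size against the clusters, the last two with
   data-driven cutoffs from **computed ABC analysis** (set "A" = items
   closest to the ideal point of the cumulative yield curve);
3. **associates genotype with phenotype** — 10 Monte-Carlo repetitions
   of stratified 2/3–1/3 splits, 1500-tree random forests with
   `ceil(0.2·√d)` features per split, balanced accuracy and
   vote-fraction AUC-ROC, out-of-bag permutation importance averaged
   over runs, and a final ABC partition selecting the most informative
   variant set "A" — audited by permuted-genotype controls (expected
   to perform at chance) and by negative-control cytochrome-P450 genes
   (expected never to be selected).

Because the original cohort is not deposited, a synthetic-cohort
generator (`cohortSpec()`, `generatePhenotypes()`,
`generateGenotypes()`) reproduces the statistical structure the
analysis assumes — two phenotype clusters, a correlated cold-threshold
pair (r = 0.812), Hardy–Weinberg-conforming null loci, rare and
HWE-violating loci, cluster-associated loci with allele-frequency
differentials of 0.25–0.35, and flagged control-gene loci.

## Worked example

```r
library(ThermoPainAssoc)

spec <- cohortSpec(seed = 2)           # 82 subjects, 181 loci
ph   <- generatePhenotypes(spec)
gd   <- generateGenotypes(spec, ph$labels)
gd
#> GenotypeData: 181 loci x 82 subjects
#>   classes: SNV=181
#>   control loci: 51; missing calls: 0

report <- runPipeline(pipelineConfig(seed = 2))
report
#> Genotype-phenotype association pipeline
#>   subjects clustered: 82 (silhouette 0.372)
#>   locus funnel: initial=181 -> post_hwe=167 -> post_shannon=77 -> post_chi2=16 -> set_A=6
#> AssociationReport: 10 repetitions
#>   balanced accuracy 0.750 [0.608, 0.861]
#>   AUC-ROC           0.892 [0.832, 0.943]
#>   permuted control  0.500 [0.451, 0.556] (accuracy)
#>   final set 'A': 6 loci; control audit: pass
```

Reading the output: 82 subjects fall into two U-matrix clusters
(silhouette 0.37, a moderate but genuine separation); the locus funnel
shows how many variants survive each filter stage down to the final
most-informative set "A"; the forests assign held-out subjects to their
phenotype cluster clearly better than their own permuted-training
control, which sits at the chance level of ~0.5 — the signature that
the genotypes carry phenotype-relevant information rather than
overfitting. Stage functions (`phenotypeStage()`, `prepareStage()`,
`runAssociation()`, `compareScoreSets()`) are callable individually,
and `inst/scripts/run_pipeline.R` wraps them in a small CLI with
`simulate`, `phenotype`, `prepare`, `associate`, `compare-scores` and
`report` subcommands.

The numbers in the block above are the package's own printed output for
`seed = 2`; values for other seeds differ within the reported
intervals.

## Package layout

- `R/` — S4 containers (`GenotypeData` on SummarizedExperiment,
  `EsomModel`, `AbcPartition`) and the stage functions.
- `inst/extdata/final_set_A_variants.tsv` — the published
  final-selection table (38 variants with gene, rank, locus id, dbSNP
  id and per-cluster allelic frequencies) used as a reference fixture.
- `vignettes/methods.Rmd` — model, assumptions, parameter rationale,
  numerical choices and limitations.
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles.
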