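# cdscan

Coeliac disease (CD) is an immune-mediated enteropathy whose genetic risk
is dominated by the HLA-DQ2.5, DQ2.2 and DQ8 haplotypes, but HLA typing
alone is a poor screen: the high-risk DQ2.5-containing genotypes are
specific (~93%) yet miss more than half of patients (~45% sensitivity).
`cdscan` re-implements, as a tested R package, an analysis chain that
improves on this by combining HLA tag-SNP typing with a single non-HLA
variant in *MSH5* (rs3130484) found by a pooled-DNA allelotyping GWAS:

* **HLA tag-SNP diplotype calling** — rs2187668 (DQ2.5), rs7454108 (DQ8),
  rs7775228 + rs2395182 (DQ2.2) → diplotype categories and risk labels;
* **pooled allelotyping scan** — relative allele signal
  RAS = A/(A+B) per SNP per pool-array; per-chip MAPD QC; two-sided Welch
  t-test of case vs control arrays, t = (x̄₁−x̄₂)/√(s₁²/n₁+s₂²/n₂) with
  Welch–Satterthwaite df; Benjamini–Hochberg adjustment; hit selection at
  p < 5×10⁻⁸ with supporting SNPs at p < 10⁻⁵ within 150 kb;
* **case-control statistics** — Pearson χ² on genotype/allele tables,
  OR = ad/bc with Wald CI exp(ln OR ± 1.959964·√(1/a+1/b+1/c+1/d)),
  and a logistic cross-term test of MSH5×HLA independence under dominant
  and recessive codings;
* **risk rules** — HLA-only, HLA-or-MSH5, MSH5-and-DQA1 (rs9272346),
  scored by sensitivity/specificity with a constrained rule search
  (maximise sensitivity subject to specificity ≥ 80%).

A synthetic-cohort and pooled-array simulator with the study's statistical
structure (published diplotype frequency table, 9 + 6 pools of 33–44
samples, additive RAS noise) makes the whole chain runnable and testable
without any external data. See `vignettes/cdscan-methods.Rmd` for the
model, parameter choices and known limitations.

## Worked example

```r
library(cdscan)

cohort <- generateCohort(cohortSpec(seed = 1))   # 473 CD / 714 controls / 357 family
called <- callCohortDiplotypes(cohort)           # diplotypes + risk labels
evaluateRule(ruleHlaOnly(), called)
#> ConfusionMatrix for rule 'HLA-only'
#>   TP 193  FN 280   (cases    473)
#>   FP 54  TN 660   (controls 714)
#>   sensitivity 40.8%  specificity 92.4%

res <- replicationContrast(called, "CD", "control", "rs3130484")
#> rs3130484 allelic OR 5.31 (95% CI 4.21-6.70), p = 3.68e-51

waldP(interactionTest(called, "dominant"))["msh5:hla"]
#> 0.72
```

The confusion matrix shows one sampled cohort at the published frequency
table: the HLA-only rule recovers 193 of 473 patients (40.8% here; the
population value is 45.5%) while rejecting 92.4% of controls. The MSH5
odds ratio is drawn around the generating value 6.10, and the
non-significant cross-term (p = 0.72) reflects the multiplicative
independence of the MSH5 and HLA effects in the generator.

`runPipeline(defaultRunConfig(seed = 1), "run1")` executes the full chain
(simulate → pools → scan → HLA calling → association → classification) and
writes every intermediate table, `summary.yaml` and a log of all seeds and
dialect switches into `run1/`; reruns are bit-identical.

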