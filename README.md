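# lopdkit

Clinical severity scoring and family-based modifier-gene prioritization
for late-onset Pompe disease (LOPD).

Siblings carrying identical *GAA* genotypes can differ dramatically in
LOPD severity, which points at modifier genes elsewhere in the genome.
`lopdkit` implements, as one tested pipeline, the two computations used
to study this in an 11-sibling, two-family cohort:

1. **Severity Index (SI)** — a 14-item ordinal rubric (age at onset,
   muscle strength, six-minute walk, GSGC, spirometry, BMI, vitamin D,
   bone density, fractures, vascular and valvular findings, immune
   response to enzyme replacement). Each item is graded on published
   bins, the grades are summed (`SI = Σ grade_i`, structural range
   1–41, nominal 1–47), the SI maps to severity classes (very mild …
   very severe), and the cohort is dichotomized at SI > 20 into
   mild (VM/M) vs moderate-or-worse (M/S) groups.
2. **Modifier-gene cascade** — annotated exome variants are filtered by
   quality control (minor allele count, call rate ≥ 0.95), functional
   class (splicing + protein-altering; synonymous excluded), rarity
   (max population MAF < 0.2; unreported = novel = kept) and
   deleteriousness (CADD phred ≥ 20, with an indel exception), then
   screened for carrier sharing between families (Analysis I) or within
   a family (Analysis II), cosegregation with dichotomized clinical
   traits, and hypergeometric gene-set enrichment
   (`P(X ≥ k), X ~ Hypergeom(N, K, n)`).

Group comparisons at this sample size use an **exact Mann–Whitney U**
(full enumeration of all `C(n1+n2, n1)` label assignments with mid-rank
ties), 2×2 chi-square for qualitative variables, and Pearson
correlation. A seeded **synthetic generator** produces cohorts and
variant tables with planted ground truth so every stage is testable
without patient data. The published cohort tables ship as fixtures.

## Worked example

```r
library(lopdkit)

ds     <- bundled_fixture("table1")            # the 11-sibling cohort
scheme <- default_scheme()
ov     <- bundled_fixture("table2_overrides")  # printed-matrix overrides
grades <- score_cohort(scheme, ds, overrides = ov)
si     <- colSums(grades)
grp    <- dichotomize(si)
data.frame(SI = si, class = classify_severity(si), group = unname(grp))
#>         SI    class group
#> F1II-4  21 moderate   M_S
#> F1II-5  23 moderate   M_S
#> F1II-7  17     mild  VM_M
#> F1II-8  17     mild  VM_M
#> F1II-9  21 moderate   M_S
#> F1II-12 15     mild  VM_M
#> F1II-13 16     mild  VM_M
#> F2II-1  12     mild  VM_M
#> F2II-3  11     mild  VM_M
#> F2II-4  28 moderate   M_S
#> F2II-5  28 moderate   M_S
```

Six patients are mild or very mild, five moderate or worse — the 6/5
split behind all group statistics. (Two SIs differ by one from the
published table, whose printed SI row is internally inconsistent for
those columns; the package reports the exact sums. See the methods
vignette.) The group comparison:

```r
severity_association_report(ds, grp, c("6MWT", "FVC", "VDD", "GSGC"))
#>  variable group n   mean     sd       p   method
#>      6MWT  VM_M 6 324.33  69.16 0.02165 mw_exact
#>      6MWT   M_S 5 180.00 116.67 0.02165 mw_exact
#>       FVC  VM_M 6  90.50   9.73 0.02165 mw_exact
#>       FVC   M_S 5  60.40  21.17 0.02165 mw_exact
#>       VDD  VM_M 6  27.90  12.53 0.01732 mw_exact
#>       VDD   M_S 5   9.29   2.72 0.01732 mw_exact
#>      GSGC  VM_M 6   7.00   1.41 0.00649 mw_exact
#>      GSGC   M_S 5  16.00   7.18 0.00649 mw_exact
```

Severe patients walk 144 m less, lose 30 points of vital capacity, have
deeply deficient vitamin D and double the motor-disability score; all
four exact p-values are below 0.05. The 16 published candidate variants
all survive the rarity and deleteriousness filters:

```r
t5 <- bundled_fixture("table5")
nrow(deleteriousness_filter(rarity_filter(t5)))
#> [1] 16
```

And a synthetic exome with three planted modifiers shrinks through the
cascade to a candidate set containing exactly the satisfiable plants:

```r
b   <- simulate_bundle(sim_params(seed = 1))
res <- prioritize(b$variants, b$genotypes, b$pedigree)
res$report
#>             stage n_variants
#>            loaded       1003
#>                qc        550
#>  functional_class        294
#>            rarity        213
#>   deleteriousness         35
#>           sharing         15
```

A subcommand CLI wraps the same functions
(`inst/cli/lopdkit score|stats|simulate|prioritize|run`), and
`run_pipeline()` drives score → stats → prioritize from one YAML/JSON
config with byte-reproducible outputs.

## Layout

- `R/` — clinical records & fixtures, severity index, cohort statistics,
  variant prioritization, synthetic data, workflow/CLI
- `inst/extdata/` — cohort table, grade matrix (+ overrides), candidate
  variant table, vitamin-D genotypes, gene sets, default grading scheme
- `vignettes/lopdkit-methods.Rmd` — model, numerical choices at the bin
  edges, the documented publication-internal discrepancies, simulator
  design, limitations
- `tests/testthat/` — unit, property and oracle tests;
  `test-acceptance.R` holds the acceptance criteria
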