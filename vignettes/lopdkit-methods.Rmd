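---
title: "Methods: the LOPD Severity Index and the modifier-gene cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the LOPD Severity Index and the modifier-gene cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lopdkit)
```

## The problem

Late-onset Pompe disease (LOPD) is caused by biallelic mutations of *GAA*,
the gene for lysosomal acid alpha-glucosidase. Siblings who carry the very
same *GAA* genotype can nevertheless present anywhere from mild proximal
weakness to wheelchair- and ventilator-dependence, which makes the *GAA*
genotype alone a poor predictor of course. `lopdkit` implements the two
computations used to study this variability in an 11-sibling, two-family
cohort: (1) a composite ordinal **Severity Index (SI)** that collapses a
heterogeneous clinical workup into one score, and (2) a family-based
**rare-variant prioritization cascade** that searches exome data for
candidate *modifier* genes whose rare, deleterious variants track the
severe phenotypes.

## The Severity Index

Fourteen clinical items are each graded on an ordinal scale and the grades
are summed. The items and their grade ranges:

| item | measurement | grades |
|---|---|---|
| AAO | age at onset (years) | 1–6 (younger is worse; never 0) |
| MMT | manual muscle testing, MRC % | 0–4 |
| 6MWT | six-minute walk distance (m) | 0–6, sex-stratified |
| GSGC | gait/stairs/Gowers/chair score | 0–4 |
| FVC | upright forced vital capacity (% predicted) | 0–4 |
| ΔFVC | upright→supine FVC drop (%) | 0–4 |
| BMI | body mass index (kg/m²) | 0–4 |
| VDD | serum 25-OH vitamin D (ng/mL) | 0–2 |
| BMD | bone density T-scores, 3 districts | 0–2 (composite) |
| BF / BAD / MVP / ERT-AE | fractures, basilar dolichoectasia, mitral prolapse, adverse ERT reaction | 0–1 each |
| IgG | anti-rhGAA IgG | 0–1 (presence) |

Severity classes: very mild 1–10, mild 11–20, moderate 21–29, severe
30–39, very severe ≥ 40. All group statistics use the dichotomy
**VM/M** (SI ≤ 20) vs **M/S** (SI > 20).

### Numerical choices at the bin edges

The published bin lists contain gaps and shared endpoints ("grade 1: >50;
grade 2: 49–40"; "grade 1: 10–15; grade 2: 15–20"). The engine therefore
(a) snaps each measurement to the precision of the printed edges —
integers for the motor and respiratory items, one decimal for BMI and
vitamin D — using *half-up* rounding (deterministic, unlike banker's
rounding), and (b) uses closed bins in those units, resolving every
shared edge the way the published grade matrix resolves it: the milder
grade wins (onset at 50 → grade 1, ΔFVC of 20 → grade 2, FVC of 80 →
grade 0, vitamin D of 30 → grade 0). Each resolved edge is a regression
test.

The BMD text says only "osteopenia (grade 1) or osteoporosis (grade 2)"
for three district T-scores. The composite rule implemented — grade 2
iff ≥ 2 districts ≤ −2.5, else grade 1 iff ≥ 1 district ≤ −1.0, else
0 — is the unique simple rule consistent with all eleven published
grades (one patient has a single district at −2.6 yet grade 1; another
has median T-score above −1 yet grade 1).

Missing values carry a *reason*. Spirometry marked "np" (not performed —
the patients could not tolerate supine testing) grades at the **worst**
grade: inability to perform the test is the severe finding, and the
published matrix grades exactly those cells 4. Values missing for any
other reason refuse to grade unless the caller opts into grade 0 with a
warning.

### Where the publication disagrees with itself

Re-deriving every cell of the published grade matrix from the published
clinical table exposes ten discrepant cells, all asserted (never hidden)
in the tests:

* **IgG (7 cells)** — the stated rule is presence/absence, but every
  patient has a positive titre while the matrix grades seven of them 0.
  No titre threshold separates the 0s from the 1s (a titre of 600 is
  graded 1, 1200 graded 0). The default scheme implements the stated
  rule; a shipped per-patient override file reproduces the printed
  grades.
* **one BMI cell** — BMI 21.4 falls in the printed normal bin but is
  graded 1.
* **one AAO cell** — onset at 29 falls in the printed "29–15" bin
  (grade 4) but is graded 3.
* **one MVP cell** — the clinical table and the running text both report
  no prolapse for that patient, yet the matrix grades 1.

Separately, the printed SI row of the grade matrix is one lower than its
own column sum for two patients (16 vs 17, and 11 vs 12);
`compute_severity_index` returns the exact sum. And the stated maximum
SI of 47 is not reproducible: the published per-item maxima sum to 41
(45 if BMD were counted per district). The scheme stores the structural
maximum 41 and keeps the nominal 1–47 range only for the class bins,
whose top class (≥ 40) remains reachable. An SI of 0 is representable
(all-normal record) but flagged, since age at onset always grades ≥ 1.

## Cohort statistics

At n = 11 the only defensible Mann–Whitney p-value is the exact one:
`mann_whitney()` enumerates all `choose(n1+n2, n1)` assignments of the
pooled observations to the group labels, computes U from mid-ranks, and
reports the point-symmetric two-sided tail `P(|U − E[U]| ≥ |U_obs −
E[U]|)` — well defined under ties, and identical to the classical
doubling rule without them. `auto` mode falls back to the tie-corrected
normal approximation with continuity correction above a configurable
enumeration cap. The implementation is oracle-tested against an
independent brute-force enumeration that computes U by direct pair
counting.

Means are reported with both SD conventions because the published group
table mixes them (its vitamin-D SDs match divisor *n*, its GSGC and FVC
SDs divisor *n − 1*); means are the canonical comparison surface.
Qualitative variables use the closed-form 2×2 chi-square (optional Yates
correction), which warns whenever an expected count is below 5 — always
true at this cohort size. Benjamini–Hochberg q-values are available but
off by default, mirroring the published analysis, which applied no
multiplicity correction.

Two published group-table cells are not reconstructible from the
published per-patient data under any divisor or grouping tried (the ΔFVC
VM/M mean/SD and the femoral-neck M/S mean); the tests assert the
recomputed values and assert that they differ from the printed ones.

## The prioritization cascade

Stages, in order, each idempotent and order-exchangeable where
mathematically expected (property-tested):

1. **QC** — drop variants with minor allele count 0 in the cohort or
   call rate < 0.95; multi-allelic records are refused at load time
   (they must be pre-split upstream).
2. **Functional class** — keep splicing and protein-altering exonic
   classes; drop synonymous and everything else.
3. **Rarity** — keep variants whose *maximum* frequency over all
   annotated populations is < 0.2; variants reported in no population
   are novel and kept.
4. **Deleteriousness** — keep CADD phred ≥ 20; an absent CADD passes
   only for indel classes (CADD is undefined for many indels, and the
   published candidate list retains one such insertion).
5. **Sharing** — Analysis I keeps variants with ≥ 1 carrier (dosage ≥ 1,
   a dominant modifier model) in every family; Analysis II keeps
   variants carried by every member of a caller-specified subset of one
   family, with no carriers elsewhere. Whether "shared among relatives"
   means all affected siblings or all sharing a particular sign is not
   decidable from the source; both subset modes are exposed and the
   subset is always explicit.
6. **Cosegregation** — per dichotomized clinical trait, concordance =
   fraction of samples whose carrier status equals the trait;
   concordance 1 flags perfect cosegregation, 0 a perfect inverse.
7. **Enrichment** — upper-tail hypergeometric test of the candidate
   genes against user-supplied GMT gene sets, the generic stand-in for
   database-backed protein-interaction enrichment services (same null:
   a random draw of n genes from the universe). SIFT/PolyPhen calls are
   carried through but never filtered on.

Compound-heterozygous carriage is flagged at the gene level (≥ 2
distinct candidate variants in one sample's gene); phasing is not
attempted. Sample-level QC (identity-by-descent, sex mismatch) needs
genome-wide data and is out of scope; the loader accepts a precomputed
exclusion list instead. The published exome-wide stage counts
(101,756 → 16,230 → 2,806 → 589 genes) depend on undeposited raw data
and are deliberately **not** acceptance targets; the cascade's behaviour
is instead verified by planted-truth recovery on synthetic data.

## The synthetic generator

`simulate_cohort()` draws a latent severity `s ~ Beta(2, 2)` per patient
(two families of 7 and 4 siblings by default, the published layout),
maps `s` onto each item's grade range, samples the measurement uniformly
inside the target-grade bin and adds noise bounded by a quarter of the
bin width. The bound makes the recovery guarantee *provable* rather than
tuned: a measurement's grade can differ from its target by at most one
bin, so scoring the simulated cohort recovers the latent severity
ranking (Spearman ≥ 0.8 is asserted, 0.95 observed at seed 1). Severities
of exactly 0 or 1 are placed deterministically at the bin midpoint so the
rubric floor (SI = 1) and structural ceiling (SI = 41) are hit exactly.
Boolean findings are Bernoulli(`s`).

`simulate_variants()` draws background frequencies from Beta(0.5, 5)
truncated to [0, 0.5], CADD from Gamma(2, 6), class labels from a stated
mixture (half synonymous), and genotypes Binomial(2, MAF) independently
per sibling — deliberately *no* linkage disequilibrium and no Mendelian
transmission, so a "green" recovery test establishes correctness of the
cascade logic, not calibration against real exomes. Planted modifiers
receive genotypes matching their carrier rule exactly. A rule that is
structurally impossible (a both-families rule with one family) errors; a
rule left without eligible carriers by the particular cohort draw (e.g.
no moderate-or-worse patient in one family) is recorded in the truth
file as unsatisfiable and not emitted — recovery statistics count
satisfiable plants only.

All randomness flows through per-component substreams derived from the
single master seed, so adding a component never perturbs the draws of
another, and identical parameters give byte-identical bundle files.

## Known limitations

* The grading scheme hard-wires the 14 published items; alternative
  Pompe scales and longitudinal trajectories are out of scope.
* The exact Mann–Whitney enumerates up to the configured cap
  (default 2×10⁵ assignments) before falling back to the normal
  approximation.
* The enrichment stand-in tests overlap only; it does not model
  interaction topology as database-backed services do.
* The simulator's marginal distributions are stated, not fitted; it
  validates logic, not epidemiology.
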