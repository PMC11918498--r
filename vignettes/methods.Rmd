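---
title: "Ranking candidate disease genes with weighted likelihood ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking candidate disease genes with weighted likelihood ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrprio)
```

## The model

For a proband with phenotype term set $X_p$ and a candidate disease $D$
(gene $g$, mode of inheritance $m$), three likelihood ratios are computed
and combined on the log scale:

$$S(D) = \log_{10} LR_{pheno} + c_1 \log_{10} LR_{geno} + c_2 \log_{10} LR_{seg}$$

Each LR compares the probability of the observed evidence under "the
patient has $D$" against "the patient does not have $D$". With
$c_1 = c_2 = 1$ and prior odds applied directly, $10^S$ is a plain product
of independent-evidence LRs; the exponents deliberately depart from that
interpretation to absorb the unequal reliability of the three heuristic
components, and a calibration step restores an interpretable posterior.

### Phenotype concordance

Disease–phenotype annotations are sparse. The ontology's "is a" DAG lets
a term inherit evidence from its descendants: if a child occurs in 40% of
patients, its parent occurs in *at least* 40%. `build_frequency_table()`
therefore assigns every term in the ancestral closure of the annotated set
the **maximum** annotated frequency among its own annotation and its
annotated descendants — the tightest provable lower bound, since
co-occurrence frequencies are unavailable. The table is monotone
non-decreasing from child to parent by construction.

```{r}
g <- ontology_graph(list(
  "phenotypic abnormality" = character(0),
  "growth abnormality" = "phenotypic abnormality",
  "growth delay" = "growth abnormality",
  "abnormality of body height" = "growth delay",
  "short stature" = "abnormality of body height",
  "pituitary dwarfism" = "short stature",
  "birth length less than 3rd percentile" = "short stature"))
tab <- build_frequency_table(
  c("pituitary dwarfism" = 0.40,
    "birth length less than 3rd percentile" = 0.20), g)
tab$freq[["short stature"]]
```

Per patient term $x_p$, $\Pr(x_p \mid D)$ is the table value when $x_p$
falls inside the closed table; otherwise the common ancestor $x_{ca}^*$
with the highest table frequency is scaled down by the gene-annotation
count ratio $|G_{x_p}| / |G_{x_{ca}^*}|$, so a patient term far more
specific than anything the disease is annotated with contributes a small
but strictly positive probability. This matters clinically: a term
unexplainable by $D$ (a second diagnosis, a nongenetic finding) should
dilute, not veto, the candidate. $\Pr(x_p \mid \neg D)$ is the smoothed
fraction of corpus diseases whose closed table contains the term.

Terms are ranked by information content
$IC(x) = -\log_2(|G_x| / |\bigcap_{p \in pa(x)} G_p|)$ for clinician-curated
sets (specific terms first) or by text-occurrence counts for NLP-derived
sets, and `compute_pheno_lr()` maximizes the prefix product of per-term
LRs over subset sizes $1..s_{max}$. The maximum-over-prefixes construction
is what makes large, noisy computational phenotype sets usable: terms
ranked below the best subset cannot reduce the score.

### Genotype evidence

Preprocessing applies, in order: artifact-region removal (BED), QUAL/depth
thresholds, proband-carries-alternate validation, allele normalization,
then population frequency (> 1% in any gnomAD subpopulation), nonexonic
and synonymous filters. Canonical splice variants (±2 bp) are rescued from
the exonic requirement; ClinVar-pathogenic variants are retained
regardless of the three annotation filters (quality and proband checks
still apply). Pathogenicity heuristics: frameshift/start-loss/stop-loss →
1.0; missense → predictor probability; in-frame indels → predictor score
or a flat 0.5 when indel scoring is disabled (the shipped default, since
indel predictors are expensive); anything scoring below 0.5 is omitted —
more likely benign than pathogenic. ClinVar-pathogenic variants are floored
at 0.95 and never omitted; the floor keeps known-pathogenic alleles
competitive without hard-coding a rank.

Per gene, dominant diseases take the top-scoring variant and recessive
diseases require two predicted disease-causal alleles (homozygotes count
twice) and average the top two; genes associated with both modes are
treated as dominant. The gene-level ratio

$$LR_{geno} = \frac{\text{agg} \cdot f_{disease}}{\max(f_{pop}, f_{floor})}$$

uses the three stated inputs — aggregated pathogenicity, the highest
population frequency among contributing variants, and a per-disease
prevalence proxy (default $10^{-4}$; systematic prevalences do not exist).
The exact published closed form is not available in the source text; this
form is fixed and isolated in `compute_geno_lr()` so it can be replaced
without touching callers. Missing population frequency is treated as a
novel variant and floored at $f_{floor} = 10^{-6}$: absence from a large
population database is evidence of rarity, not missing data.

### Segregation

`classify_inheritance()` compares observed transmission to the annotated
mode of inheritance: de novo or affected-parent transmission matches a
dominant model, transmission from an unaffected parent does not; a
recessive homozygote matches when both parents carry; a compound
heterozygote matches in trans and mismatches in cis (phased by parental
genotypes only). $LR_{seg}$ is heuristic — 10 (match), 0.1 (mismatch,
tolerating incomplete penetrance), 1 (undeterminable) — and square-rooted
with a single parent, making the duo value the geometric mean of trio and
no-data values. A recessive homozygote with a non-carrier parent is
classified mismatch: uniparental disomy and deletions are out of scope,
and the 0.1 penalty is deliberately survivable.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `c1`, `c2` | 2.29, 3.69 | exponents on LR_geno / LR_seg (LR_pheno fixed at 1); defaults are the published optimization result, relearnable with `optimize_weights()` |
| `prior` | 0.3 | prior diagnostic probability (typical diagnostic yield ~28–31%; recalibrate locally) |
| `subset_max` | 10 | largest phenotype subset size; bounds runtime, exceeds best-subset sizes seen on fixtures |
| `gnomad_max` | 0.01 | population-frequency filter |
| `score_min` | 0.5 | pathogenicity omission threshold |
| `f_floor` | 1e-6 | novel-variant population-frequency floor |
| `clinvar_floor` | 0.95 | pathogenicity floor for ClinVar-pathogenic variants |
| `quality_min`, `depth_min` | 20, 10 | variant QC (cohort mode additionally drops QUAL < 50 and intracohort frequency > 2%) |

## Weight learning and calibration

`optimize_weights()` mirrors the published protocol: case-wise,
status-stratified cross-validation folds (deterministic assignment by
sorted case ID — reproducibility over randomization); within each training
partition a greedy hill-climb starts at the origin of $(c_1, c_2)$ space,
evaluates the four axis neighbors at step 0.1 in $[0, 10]^2$, moves to the
largest PR-AUC improvement and stops at a local optimum; fold optima are
averaged. The step size and bounds are our choices (unstated in the
source): 0.1 resolves the published optima to two decimals in ≲ 60 steps.
Ties among neighbors are broken in a fixed order (+c1, −c1, +c2, −c2) for
determinism. Because PR AUC is piecewise constant, the climb can halt on a
tied plateau whose *value* equals the lattice optimum while its
coordinates differ; the acceptance suite therefore checks objective-value
equality against `grid_search_weights()`.

`calibrate_posterior()` fits one Gaussian per class to training composite
scores and returns the Bayes posterior under the configured prior. The
Gaussian family is a choice (unstated in the source): two parameters per
class, stable on small cohorts, and isolated behind a function interface.
Without training data, `posterior_from_lr()` applies prior odds directly.

## The synthetic world

`fixture_spec()` defaults state the world the tests run in: 100 cases with
30% planted diagnoses (the typical diagnostic yield), a 60/20/20
trio/duo/singleton mix (pediatric sequencing is trio-heavy), an even AD/AR
split, 20 single-gene diseases over a 60-term, 40-gene layered ontology,
and per case ~8 uniform noise phenotype terms and ~4 noise variants
(inherited from unaffected parents, frequency-mixed so some trip each
filter). Planted variants are constructed to survive preprocessing:
de novo heterozygotes for dominant diseases, compound heterozygotes in
trans for recessive ones.

What the generator does **not** emulate: realistic allele-frequency
spectra, linkage between noise variants, ontology scale (17k+ terms),
multi-gene diseases, phenotype-term correlation structure, or NLP
occurrence counts. A green end-to-end test therefore establishes that the
machinery composes correctly and recovers a planted signal in a
stated-world regime — not clinical-cohort performance figures, which
require access-controlled data and are out of scope.

## Numerical choices and degenerate inputs

- Gene-annotation counts are floored at 1 inside probability ratios; a
  zero-annotation term would otherwise zero out a likelihood.
- Terms with no annotated genes get the maximum finite IC,
  $\log_2 |G_{root}|$: an unannotated term is maximally specific for
  ranking. An empty multi-parent gene-set intersection falls back to the
  root universe as denominator.
- Background disease counts use add-one smoothing, $(k+1)/(n+2)$, keeping
  per-term LRs finite in both directions; the candidate disease is not
  excluded from its own background count (with > 8000 OMIM entries the
  distinction is negligible; on small corpora exclusion would inflate
  every candidate symmetrically).
- "n/m" frequency annotations are used as plain ratios without a
  pseudocount — the propagation maximum makes small-denominator noise
  mostly harmless.
- Subset-size ties take the smallest subset (parsimony); candidate ranks
  break posterior ties by gene then disease ID; tied evaluation scores get
  the worst tied rank (conservative).
- Allele normalization trims shared affixes without a reference genome;
  records already atomized by an upstream normalizer pass through
  unchanged, and preprocessing is idempotent.

## Known limitations

Only autosomal dominant/recessive modes are modeled (no X-linked,
mitochondrial, or imprinting logic); compound-het phasing relies on
parental genotypes; CNV/SV and noncoding variation beyond canonical splice
sites are out of scope; the LR_geno closed form is a documented stand-in;
posteriors are only as calibrated as the training cohort is representative.
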