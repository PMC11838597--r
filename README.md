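# preannotate

Pre-annotation of untargeted LC-MS metabolomics feature tables: organizing
thousands of redundant features into putative compounds *before* any identity
is assigned.

One neutral compound rarely produces one LC-MS feature. Electrospray
ionization emits the molecular ion alongside ¹³C isotopologues, alternative
adducts (Na⁺, K⁺, acetonitrile, …) and in-source fragments — all coeluting,
all inflating feature counts. Meanwhile a large fraction of features never
relates to anything and remains unexplained "dark matter", concentrated at
low abundance. `preannotate` implements:

* **Isotopic-pair detection and a data-driven coelution window** — candidate
  ¹³C/¹²C pairs (Δm/z = 1.003355, heavy/light intensity ratio < 0.5) define
  the study-specific RT tolerance as ±1 SD of their RT differences.
* **Khipu grids** — coeluting features related by conservative isotope and
  adduct patterns are resolved into deterministic grids indexed by
  (isotope index, modification), anchored at the lowest-m/z molecular ion,
  with inferred neutral masses matchable against a compound mass list.
* **Mass-difference discovery** — a fine-binned histogram of m/z differences
  between khipu anchors and coeluting features nominates recurrent deltas;
  those not explainable by known patterns become candidate neutral losses.
* **In-source fragment (ISF) estimation, two ways** — (1) linking khipus and
  singletons to coeluting higher-m/z parents through neutral-loss deltas;
  (2) screening the table against an MS/MS spectral library (MSP) for
  precursor features whose strong fragments are co-detected.
* **Abundance stratification** — role composition per intensity quartile and
  a 99-slice quantile coverage curve, quantifying how annotation success
  rises with abundance.
* **A synthetic generator with planted ground truth** — every algorithm in
  the package is validated against brute-force oracles and known truth; no
  external data are required.

Everything is tibble-first, pipe-friendly, and deterministic: reruns,
input-row permutations, and library reorderings produce byte-identical
reports.

## Worked example

Simulate a synthetic study and run the full pipeline (with the matching
MS/MS library and compound mass list):

```r
library(preannotate)

sim <- simulate_lcms(generator_config(seed = 42, n_compounds = 400,
                                      n_noise_features = 100))
sim$table
#> # A tibble: 1,673 × 7
#>   id         mz    rt intensity   snr peak_shape detection_count
#>   <chr>   <dbl> <dbl>     <dbl> <dbl>      <dbl>           <int>
#> 1 F000001  972.  56.5  1169311. 10.1       0.575              84
#> 2 F000002  973.  56.7   583486. 47.0       0.986              73
#> 3 F000003  974.  56.2   221294. 13.9       0.931              68
#> 4 F000004 1027. 631.     20164.  9.76      0.948              41
#> 5 F000005 1028. 631.     10062. 45.8       0.808              42
#> # ℹ 1,668 more rows

res <- run_pipeline(sim$table, msms = sim$library, masses = sim$masses)
res
#> Pre-annotation pipeline (positive, orbitrap)
#>   input          1673 features, positive mode, orbitrap
#>   good_features  1103 features with SNR > 5 and shape > 0.9
#>   isotope_pairs  835 13C/12C pairs
#>   coelution      rt half-width 0.534 s
#>   preannotation  358 khipus, 441 singletons
#>   mass_deltas    404 coeluting differences; 0 data-driven candidates; 6 working deltas
#>   isf_search     3 khipus and 36 singletons explained as in-source fragments
#>   msms           125 exemplar spectra; P = 126, Y = 13
#>   mass_match     90.2% of khipus matched to the mass list
#>   strata         quartile and quantile summaries computed
```

The 1,673 features collapse into 358 khipus (putative compounds) plus 441
singletons. `tidy()` gives the feature-level annotation, `glance()` the
one-row summary:

```r
tidy(res)
#> # A tibble: 1,673 × 9
#>   feature_id    mz    rt intensity khipu_id   isotope_index modification role
#>   <chr>      <dbl> <dbl>     <dbl> <chr>              <int> <chr>        <chr>
#> 1 F000001     972.  56.5  1169311. kp_F000001             0 anchor       M0
#> 2 F000002     973.  56.7   583486. kp_F000001             1 anchor       isotop…
#> 3 F000003     974.  56.2   221294. kp_F000001             2 anchor       isotop…
#> 4 F000004    1027. 631.     20164. singleton             NA <NA>         single…
#> 5 F000005    1028. 631.     10062. singleton             NA <NA>         single…
#> # ℹ 1,668 more rows
#> # ℹ 1 more variable: quartile <int>

glance(res)
#>   n_features n_khipus n_in_khipus n_singletons mean_features_per_khipu
#> 1       1673      358        1232          441                3.441341
#>   n_good_features n_isotope_pairs rt_half_width n_isf_links pct_khipus_isf
#> 1            1103             835     0.5340348          39      0.8379888
#>   pct_features_isf
#> 1         2.630006
```

In-source fragment links name the neutral loss and the parent:

```r
res$links
#> # A tibble: 39 × 7
#>   parent_khipu child      child_kind delta_label delta mass_error rt_shift
#>   <chr>        <chr>      <chr>      <chr>       <dbl>      <dbl>    <dbl>
#> 1 kp_F000546   kp_F000545 khipu      HCOOH        46.0  0.0000221  -0.0852
#> 2 kp_F001006   kp_F001005 khipu      HCOOH        46.0  0.0000751  -0.203
#> 3 kp_F001538   kp_F001537 khipu      HCOOH        46.0 -0.0000159  -0.365
#> 4 kp_F000018   F000017    singleton  CO           28.0 -0.000265    0.348
#> 5 kp_F000021   F000020    singleton  H2O          18.0  0.000178    0.0336
#> # ℹ 34 more rows
```

Because the data are synthetic, the annotation can be scored against the
planted truth:

```r
score_recovery(res$annotation, res$links, sim$truth, sim$table)[
  c("recovery_rate", "n_eligible", "isf_pct_estimated", "isf_pct_planted")]
#> $recovery_rate
#> [1] 0.8522427
#> $n_eligible
#> [1] 379
#> $isf_pct_estimated
#> [1] 2.630006
#> $isf_pct_planted
#> [1] 3.34728
```

Plots: `autoplot(res)` (coverage by abundance), `autoplot(res$histogram)`
(mass-difference histogram), `plot_strata(res$strata)`,
`plot_rt_shift_profile(res$rt_profile)`.

`write_report(res, "out/")` writes the full TSV/JSON report bundle with an
md5 manifest; identical inputs yield byte-identical files.

## Command line

A thin CLI wraps the same functions (installed under `inst/cli/`):

```sh
preannotate simulate --seed 7 --out sim/
preannotate run --features sim/features.tsv --mode positive \
    --msms sim/library.msp --masses sim/masses.tsv --out report/
preannotate report report/
```

## Reproduction

The test suite contains unit, property, and acceptance tests, including
brute-force oracle comparisons (relation graph, histogram, ISF links, MS/MS
stats, and an exhaustive khipu resolver on small components):

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "preannotate",
                               load_package = "installed")'
```

One acceptance clause is knowingly red: khipu recovery on the default
generator measures 0.866–0.883 across seeds against an asserted ≥ 0.90
bound. The shortfall is structural — low-abundance compounds lose companion
ions to the joint action of the 0.0005 Da tolerance cap, the ±1 SD coelution
window, and abundance-dependent RT jitter (the same mechanism that produces
the required abundance-coverage trend) — and the bound is left failing rather
than loosened. The analysis lives in the methods vignette
(`vignettes/preannotation-methods.Rmd`).

The acceptance report script runs against the installed package and writes
the headline quantities as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

## Package layout

| File | Contents |
| --- | --- |
| `R/feature_io.R` | feature table, MSP library, and mass-list I/O |
| `R/patterns.R` | atomic masses, tolerance rule, pattern and loss lists |
| `R/coelution.R` | good-feature filter, isotopic pairs, RT window |
| `R/preannotation.R` | relation graph, khipu resolution, neutral-mass matching |
| `R/mass_deltas.R` | delta histogram, peak picking, candidate nomination |
| `R/isf_search.R` | khipu/singleton ISF linking and impact accounting |
| `R/msms_isf.R` | spectral cosine, library dedup, MS/MS screening |
| `R/abundance.R` | quartiles, strata, coverage curve, M0-vs-singleton test |
| `R/simulate.R` | synthetic generator and recovery scoring |
| `R/pipeline.R` | orchestration, reports, manifest |
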