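# felisotope

Stable-isotope trophic niche analysis for cat hair samples.

European wildcats (*Felis silvestris*) increasingly share landscapes — and
genes — with domestic cats. Bulk hair keratin records what an animal ate
over the months the hair grew: δ¹³C separates forest- from
open-land/agricultural food webs, δ¹⁵N tracks trophic level, and δ³⁴S can
flag anthropogenic or aquatic inputs. felisotope implements the full
analysis chain needed to turn a table of per-individual hair measurements
(wildcats, domestic cats, hybrids; several regions; collection years
spanning decades) into quality-controlled, corrected, comparable niche
statistics. It is written for ecologists running isotope-based niche
comparisons or retrospective monitoring of archived specimens.

## What it computes

* **Elemental QC** — atomic ratios C/N = (%C·14.011)/(%N·12.007) (and C/S,
  N/S); retention iff C/N ∈ [3.0, 4.05], %C ≤ 50, %N ≤ 20 and a region is
  assigned, with machine-readable exclusion reasons.
* **δ¹³C corrections** — lipid correction δ¹³C′ = 0.982·δ¹³C − 0.028,
  then a Suess-effect shift δ¹³C_cor = δ¹³C′ − (δ¹³C_atm(year) − b) to a
  pre-industrial baseline b = −6.4 ‰ (annual atmospheric series supplied
  as data, swappable).
* **Layman community metrics** — δ¹³C/δ¹⁵N ranges, convex-hull total area
  TA, centroid distance CD, nearest-neighbour distance NND and its SD.
* **Standard ellipse areas** — SEA = π√det Σ (the ≈40 % core niche),
  small-sample corrected SEAc = SEA·(n−1)/(n−2), and Bayesian posteriors
  (SEAb) from a conjugate Gibbs sampler (default 20,000 iterations,
  3 chains, burn-in 1,000, thinning 10).
* **Niche overlap** — intersection of two groups' SEAc-matched ellipses as
  a percentage of one group's ellipse.
* **Trend & covariate screens** — summer/winter hair-growth assignment
  from collection month, OLS and Huber-robust temporal slopes per
  region × taxon × season, pairwise Wilcoxon tests with Benjamini–Hochberg
  correction, pooled-variance sex t-tests, and a Pearson correlation
  screen against land-use, climate and morphometric covariates.
* **Synthetic data** — a generator with known ground truth emulating the
  study table's structure (group means/SDs, sex ratios, QC contaminants,
  year trends, covariate effects), plus a packaged study-emulation
  scenario.
* **Pipeline** — `run_pipeline()` chains everything, writes tidy CSVs, a
  JSON run report (config hash, seed fan-out, versions) and a log, and is
  byte-reproducible from a single seed. A thin CLI wrapper lives in
  `inst/scripts/felisotope.R`.

## Worked example

```r
library(felisotope)

scenario <- paper_like_scenario(seed = 42)   # packaged study emulation
gen <- generate_samples(scenario)            # 78 rows, 6 known contaminants
qc  <- apply_qc(gen$table)
qc$report
#> <qc_report> 78 in, 72 retained, 6 excluded
#> cn_out_of_range       pctC_high       pctN_high  missing_region
#>               5               1               0               0

tab <- correct_d13c(qc$table)                # lipid + Suess -> d13C_cor
wc  <- tab[tab$taxon == "wildcat", ]
hy  <- tab[tab$taxon == "hybrid", ]

layman_metrics(wc$d13C_cor, wc$d15N)
#> <layman_metrics> n=38  dC_range=4.38  dN_range=7.99  TA=23.98  CD=1.91  NND=0.46  SDNND=0.37

fw <- fit_standard_ellipse(wc$d13C_cor, wc$d15N)
fw
#> <ellipse_fit> n=38  centroid=(-20.39, 3.60)  SEA=7.078  SEAc=7.275

fh <- fit_standard_ellipse(hy$d13C_cor, hy$d15N)
ellipse_overlap(fh, fw)                      # hybrids onto the wildcat niche
#> <overlap_result> area_A=12.519  area_B=7.275  intersection=4.805  A occupies 66.0% of B

sample_seab(wc$d13C_cor, wc$d15N, mcmc_config(), seed = 99)
#> <seab_posterior> n=38 draws=5700  mean=7.171  mode=6.902  95% CI [5.252, 9.801]
```

Reading the numbers: 72 of 78 samples survive elemental QC (five C/N
failures, one %C failure). The pooled wildcats span a 24 ‰² convex hull
but a much tighter 7.3 ‰² core ellipse (SEAc); their low NND (0.46 ‰)
indicates high trophic redundancy. The hybrid ellipse is larger
(12.5 ‰²) and covers 66 % of the wildcat core niche — substantial trophic
overlap. The SEAb posterior mean (7.2 ‰²) brackets the
maximum-likelihood SEAc with a 5.3–9.8 ‰² credible interval.

To analyse real data, export the sample table to CSV (one row per
individual; columns `sample_id, taxon, region, case_study, year, month,
sex, d13C_measured, d15N, d34S, pctC, pctN, pctS`, plus any covariates)
and run:

```r
res <- run_pipeline(pipeline_config(input = "samples.csv",
                                    out_dir = "results", seed = 1))
```

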