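# ihcquant

Quantification of immunostained tissue area in histology images, by the
two routes pathologists actually use, plus the statistics to compare
them.

In immunohistochemistry (IHC), antibody-bound cells are revealed by the
brown DAB chromogen against a blue hematoxylin counterstain, and the
measurand is the **area fraction**: the percentage of a 400×-magnification
field occupied by specifically stained tissue. Two estimation routes are
common:

* **Manual counting (MC)** — stereological point counting. A systematic
  grid of *n* points is superimposed on the field and the points falling
  on brown-stained cytoplasm or membrane are counted:

  `AA = 100 · (hits / n)`,  default *n* = 594 (a 27 × 22 grid).

  With uniformly random points this is a binomial estimator: unbiased,
  with SD `100·√(p(1−p)/n)`.

* **Digital counting (DC)** — color-range pixel selection. A reference
  stain color is sampled from a marked cell; every pixel whose color lies
  within a *fuzziness* tolerance `F` (default 100, Chebyshev distance in
  8-bit RGB) of a sampled color is selected, and

  `AA = 100 · (selected pixels / total pixels)`.

Whether the fast digital route can replace the manual one is a
method-agreement question. `ihcquant` provides both estimators, a
synthetic IHC image generator with *exact* ground-truth masks — in a
clean (**GOOD**) regime and a diffuse brown-background (**NOISE**) regime —
and the full agreement/comparison toolkit: one-way intraclass correlation
(ICC) with Fleiss-style labels, Bland–Altman bias and 95% limits of
agreement, Pearson correlation, D'Agostino–Pearson normality,
Mann–Whitney and Wilcoxon signed-rank tests, and an in-silico study
runner that replays a complete two-observer, two-timepoint agreement
design (100 GOOD + 100 NOISE pictures) and a two-group
(peri-implantitis vs periodontitis, 11 + 11 patients, 7 CD markers,
4 fields per sample) cohort comparison.

## Worked example

```r
library(ihcquant)

field <- generate_field(field_gen_params(extent = c(256, 256),
                                         target_fraction = 12, seed = 42))
field
#> <synthetic_field F0001> 256x256 px, regime GOOD, marker CD3, true fraction 12.000%

grid <- build_grid(grid_spec(), c(256, 256))          # 27 x 22 = 594 points
mc <- mc_area_fraction(field, grid, hit_classifier("oracle_mask"))
#> MC (594-point grid): 11.95%  (71 hits / 594 points)

dc <- dc_area_fraction(field, color_range_spec(fuzziness = 100))
#> DC (fuzziness 100):  12.00%  (7864 / 65536 pixels)

noisy <- add_background_noise(field, 0.5, seed = 1)
dc_area_fraction(noisy, color_range_spec())
#> DC on NOISE field:   28.01%
```

The true fraction is 12.000% by construction. The grid estimate (11.95%)
is off by less than one grid-point granularity (100/594 ≈ 0.17
percentage points); color selection recovers the truth exactly on the
clean field because the generator's palette keeps every non-stained
color outside the brown family at fuzziness 100. On the NOISE field the
same selection rule sweeps up background haze and overshoots (28.01%) —
while the point-count route, which reads tissue rather than raw color,
is unaffected. That asymmetry is the package's central reproducible
finding: digital counting is accurate and fast on clean slides but needs
a pathologist's supervision when non-specific background staining is
present.

A full study replay:

```r
rep <- run_study(study_config(n_good = 20, n_noise = 20,
                              extent = c(128, 128), seed = 1))
rep$icc_inter
#>  method regime      comparison       icc variance     error      p_value     label
#>      MC   GOOD obs1_vs_obs2_T1 0.9964097 50.53667 0.1820959 3.660226e-23 excellent
#>      DC   GOOD obs1_vs_obs2_T1 1.0000000 51.62824 0.0000000 0.000000e+00 excellent
#>      MC  NOISE obs1_vs_obs2_T1 0.9978987 68.30805 0.1438345 1.736894e-25 excellent
#>      DC  NOISE obs1_vs_obs2_T1 0.9928680 86.04562 0.6180843 3.448450e-20 excellent
rep$bland_altman
#>  regime       bias  sd_diff   loa_low   loa_high coverage  n sign_convention
#>    GOOD -0.6307757 0.593753 -1.794532  0.5329801      100 20         DC - MC
#>   NOISE  8.4560294 3.430387  1.732471 15.1795881       95 20         DC - MC
```

Interobserver agreement for DC is systematically lower on NOISE than on
GOOD fields, and the DC − MC bias inflates under noise.

A thin command-line wrapper over the same functions ships in
`inst/cli/ihcquant.R` (subcommands `mc`, `dc`, `agree`, `cohort`,
`study`).

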