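# mitomorph

Quantitative morphometry of the mitochondrial network (MN) in single-cell
fluorescence micrographs, with the ROS/membrane-potential kinetics and the
statistical workflow that typically accompany it in patient-fibroblast
studies of Parkinson's-disease mutations (PINK1, Parkin, LRRK2,
α-synuclein).

Mitochondria in adherent cells form a branched tubular network that is
remodelled by fission and fusion; its morphology — total area, tubule
length, branching, the balance between networked and free organelles — is a
read-out of mitochondrial (dys)function. `mitomorph` turns a calibrated
micrograph of a TMRM-stained cell (default 23.4 px/µm) into per-cell
parameters via a fixed chain:

```
rolling-ball background subtraction (disc opening, r = 50 px)
  → 3×3 median filter
  → CLAHE (64-px tiles, clip 0.01)
  → Otsu threshold (256 bins, foreground strictly above)
  → 8-connected particle analysis (areas, moment ellipses)
  → Zhang–Suen skeletonization
  → skeleton-graph analysis (junctions, endpoints, branches;
    1 px orthogonal / √2 px diagonal steps)
  → two-class filter:
      network     ⇔ > 1 branch and ≥ 1 junction
      individual  ⇔ exactly 1 branch, 0 junctions
      (loops/"donuts" and other shapes stay unclassified)
```

Per cell it reports the **mitochondrial footprint** (µm²), the **median
network branch length** (µm), the **individual : network count ratio**, the
**median individual length** (µm), the **connectivity** (mean junctions per
network) and the **median aspect ratio of individuals** (spherical, swollen
organelles → 1).

The kinetics layer fits ROS production rates as OLS slopes of fluorescence
vs time (reported per minute, normalized so the pooled control mean is
100%) and measures the membrane-potential proxy ΔΨm as the TMRM plateau
minus the post-FCCP plateau. The statistics layer provides the Shapiro–Wilk
normality gate, one/two-way ANOVA with Tukey comparisons judged against a
Bonferroni-adjusted alpha (0.05 / C(k,2) = 0.005 for five lines), unpaired
Student t-tests for before/after-stress contrasts, ANCOVA with donor
age/sex covariates (with confound detection), and half-up-rounded
fold-change tables.

Because studies of this kind rarely deposit raw images, the package ships a
synthetic-scene generator (`generate_scene()`) that grows branched tubes
and individual rods/spheres on the pixel grid, renders them with a Gaussian
PSF and Poisson+Gaussian camera noise, and records exact ground truth
(class, branch lengths, junction/endpoint counts, areas) for every object —
the basis of all validation.

## A worked example

```r
library(mitomorph)

sc  <- generate_scene(scene_spec(n_networks = 3, n_individuals = 8,
                                 seed = 42))
res <- analyze_cell(sc$image, cell_id = "demo")
res$cell
#> <mito_cell> demo
#>   footprint                3.04 um2
#>   network branch len      1.197 um (median)
#>   individual : network     2.67 (8 : 3, 0 unclassified)
#>   individual length       0.702 um (median)
#>   connectivity             1.00 junctions/network
#>   individual aspect        4.74 (median)
```

The scene was generated with 3 networks and 8 individuals; the analysis
recovers the 8 : 3 split exactly (`ratio` 2.67), a median network branch of
1.20 µm against a median individual of 0.70 µm (individuals are generated
shorter, as observed in real fibroblasts), one junction per network (the
generated trees here are simple Ys), and rod-like individuals
(aspect ≈ 4.7). `summary(sc)` prints the ground truth to compare against.

The statistics layer reproduces the worked arithmetic used in such studies:

```r
fold_change(c(Control = 2.9, PINK1 = 6.1, PinkParkin = 7.6), "Control")
#>        group mean fold_change
#> 1    Control  2.9         1.0
#> 2      PINK1  6.1         2.1
#> 3 PinkParkin  7.6         2.6
adjusted_alpha(5)
#> [1] 0.005
```

Batch runs are driven by one YAML config — `run_morphology()`,
`run_traces()`, `run_stats()`, `run_full()` — writing per-cell and
per-object CSVs plus a manifest with the config hash and seed. A thin CLI
(`inst/cli/mitomorph`) exposes the same stages as `synth`,
`analyze-images`, `analyze-traces`, `stats` and `run-all` subcommands.

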