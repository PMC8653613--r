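# optica

Independent component analysis (ICA) decomposes a gene-expression
compendium `X` (genes × samples, log scale) into a linear mixture

    X ≈ M A

of statistically independent gene-weight sources (columns of `M`) and
their condition-dependent activities (rows of `A`).  Each source's
significantly weighted genes form an **iModulon** — a data-driven
counterpart of a regulon.  The one free choice in this model is the
dimensionality `k`: too small and independent regulatory signals are
merged, too large and they shatter into meaningless single-gene
components.

`optica` is for computational biologists building iModulon-style
decompositions of bulk or single-cell transcriptomic compendia.  It
implements the full model-order selection workflow:

* **robust ICA** — multi-restart FastICA (logcosh contrast, tolerance
  1e-7), DBSCAN clustering of the pooled restart components on the
  sign-invariant distance `d(x, y) = 1 − |ρ(x, y)|` (eps 0.1, minimum
  cluster seed of half the restarts), sign-aligned cluster centroids as
  the robust components;
* **dimensionality tree and conservation** — components linked across
  adjacent grid dimensions by absolute-cosine correlation > 0.3;
  final-dimension components back-correlated to every preceding
  dimension, with a conserved/not-conserved threshold placed at the
  Kneedle knee of the pooled best-correlation distribution;
* **classification** — single-gene detection (top |weight| strictly more
  than twice the next), iModulon extraction by exact 1-D k-means on
  |weights| (top two of three clusters), regulon enrichment by two-sided
  Fisher's exact test with Benjamini–Hochberg FDR < 1e-5, with
  precision/recall/F1 per component;
* **selection rules** — **OptICA** (the dimension where the number of
  non-single-gene components equals the number of conserved components),
  **PC-VA** (principal components to 99% cumulative variance), and an
  approximate **MSTD** stability baseline;
* **synthetic compendia** — a ground-truthed sparse-source generator with
  matched regulon tables, so the entire pipeline is testable offline.

OptICA needs no prior knowledge of the regulatory network; a TRN, when
supplied, only adds the regulatory/F1 columns.

## Worked example

Simulate a 500-gene × 150-sample compendium with 20 planted sources and
Gaussian noise, scan dimensionalities 5–50, classify, and select:

```r
library(optica)

comp <- generate_compendium(n_genes = 500, n_samples = 150, k_true = 20,
                            noise_sigma = 0.1, seed = 1)
x    <- center_genes(comp$expr)
grid <- make_grid(150, step = 5, min_dim = 5, max_dim_offset = 100)
scan <- run_scan(x, grid, optica_config(n_runs = 10, base_seed = 201))
summ <- summarize_scan(scan, db = comp$truth$regulons)
sel  <- select_dimensions(summ, x, scan$cfg)
summ
sel
```

The per-dimension census (abridged) and selection this prints:

```
dimension n_robust n_single_gene n_non_single_gene n_regulatory n_conserved mean_f1
        5        5             0                 5            5           1   0.637
       10       10             0                10           10           4   0.734
       15       15             0                15           15          10   0.866
       20       20             1                19           20          20   0.956
       25       25             1                24           20          20   0.958
       ...
       50       26             1                25           20          26   0.955

<optica_selection> OptICA 20 | PC-VA 20 | MSTD not converged
```

Reading the table: the non-single-gene count climbs while sources are
still being discovered and the conserved count chases it from below; the
curves meet at dimension 20 — the true number of planted sources — which
OptICA selects.  Above it, robust components keep appearing but they are
reorganisations and artifacts, not new conserved signals.  `mean_f1` is
the average F1 between each regulatory component's iModulon and its best
regulon (0.956 at the selected dimension);
`score_against_truth(scan$decompositions[["20"]], comp$truth)` confirms
all 20 sources recovered.  MSTD reports "not converged" when the stable
fraction never collapses — a documented outcome seen on real compendia
as well.

`run_pipeline()` chains the same steps from files on disk and writes
`summary.csv`, `tree.json`, `conservation.csv`, `enrichments.csv` and
`selection.json`; `inst/scripts/optica.R` wraps it for the shell
(`simulate`, `scan`, `select`, `run` subcommands).  Outputs are
bit-reproducible from the configuration and seed.  `autoplot()` on the
summary draws the classification curves; `plot_conservation()` draws the
conservation heat map; `tidy()`/`glance()` return tibbles.

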