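# lucifold

Analysis of dual-luciferase reporter assays: internal-control
normalization, fold change against a reference condition, summary tables
and publication-grade dot plots — as a scriptable R package with a
command-line interface.

## The problem

Reporter gene assays measure the transcriptional activity of a DNA
sequence by placing it upstream of a firefly luciferase gene and reading
luminescence in a 96-well plate. Raw firefly counts confound the biology
with well-to-well technical variation (cell density, transfection
efficiency), so a co-transfected renilla luciferase under a constitutive
promoter serves as an internal control. For each well the normalized
signal is the ratio

```
ratio_w = firefly_w / renilla_w
```

and, after choosing a reference condition (typically the empty-vector
control), each well's activity is expressed as a fold change relative to
the mean reference ratio:

```
fold change_w = ratio_w / mean( ratio | reference wells )
```

With a multi-factor design (vector x drug x cell type, say) the reference
can be applied *within each stratum* of the non-reference factors, so
every treatment combination is normalized against its own control wells.
The reference group's mean fold change is exactly 1 by construction.

`lucifold` covers the whole path from instrument file to figure:

- **`read_glomax()` / `write_glomax()`** — plate-reader workbooks (XLSX)
  holding firefly and renilla as two 8x12 tables, with automatic block
  detection that ignores instrument metadata rows;
- **`read_design()` / `merge_design()` / `read_tidy()` / `write_tidy()`** —
  per-well design CSVs and single-file tidy uploads;
- **`compute_ratios()` / `fold_change()` / `summarize_experiment()`** —
  the analysis core, with well/condition filtering
  (`filter_experiment()`), global or stratified referencing, and
  per-condition n / mean / sd / sem / median / 95% CI;
- **`plate_heatmap()` / `dot_plot()` / `export_figure()`** — a
  false-colour plate overview and faceted dot plots that keep every
  individual data point, exportable to PNG or PDF;
- **`simulation_spec()` / `generate_experiment()` /
  `write_fixture_bundle()`** — a synthetic-experiment generator with a
  log-normal transfection-noise model and known ground truth.

## Worked example

Simulate a 72-well screen (3 vectors x 4 drugs x 2 cell types, 3
replicate wells each; the `control` vector is the reference, `geneA` and
`geneB` have true fold changes 2.5 and 0.4) and analyse it:

```r
library(lucifold)

sim <- generate_experiment(simulation_spec(seed = 7))
exp <- fold_change(sim$experiment, "vector=control")   # stratified by drug x cell
exp
#> <tidy_experiment> 72 wells; factors: vector, drug, cell
#> # A tibble: 72 × 8
#>   well  vector  drug  cell   firefly renilla ratio fold_change
#>   <chr> <chr>   <chr> <chr>    <dbl>   <dbl> <dbl>       <dbl>
#> 1 A01   control none  Hek    203459. 192590.  1.06       1.01
#> 2 A02   control none  Hek     69585.  66874.  1.04       0.996
#> 3 A03   control none  Hek     77667.  74807.  1.04       0.993
#> 4 A04   control none  neuron  90539.  82698.  1.09       1.05
#> # ℹ 68 more rows
```

Each row is one well: raw counts in both channels, the internal-control
ratio, and the fold change relative to that well's own drug-and-cell
stratum of control wells. Control wells hover around 1; `geneA` wells
around 2.5. Summaries and the figure:

```r
summarize_experiment(exp)
#> # A tibble: 24 × 11
#>   condition                n  mean      sd median ...
#> 1 control_none_Hek         3     1 0.00948  0.996
#> 2 control_none_neuron      3     1 0.0604   1.02
#> 3 control_drug1_Hek        3     1 0.0290   0.985
#> # ...

p <- dot_plot(exp, x = "vector", facets = c("drug", "cell"))
export_figure(p, "fold_change.png")
```

The control rows have mean exactly 1 (self-normalization); `sd` is the
sample standard deviation over the 3 replicate wells. The dot plot shows
one panel per drug-by-cell combination (8 panels), every well as a point,
and the per-group median as a horizontal bar.

The same analysis from a shell, starting from an instrument workbook and
a design CSV:

```sh
inst/cli/lucifold convert --workbook plate.xlsx --design design.csv --out tidy.csv
inst/cli/lucifold analyze --tidy tidy.csv --reference vector=control \
    --stratified --out results/
```

`analyze` writes `experiment_tidy.csv`, `summary.csv` and
`dot_plot.png`, and logs dropped wells, exclusions and the denominators
used.

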