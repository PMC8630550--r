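---
title: "Dual-luciferase reporter analysis: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-luciferase reporter analysis: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lucifold)
```

## The measurement and its model

A dual-luciferase assay reads two luminescence channels per well of a
96-well plate. The firefly channel reports the activity of the regulatory
sequence under study; the renilla channel, driven by a constitutive
promoter on a co-transfected plasmid, reports everything the experimenter
did not intend to vary — cell number, lysis efficiency, transfection
efficiency. The working assumption of the assay, which this package
inherits, is that those nuisance effects act *multiplicatively and
equally on both channels*. Under that assumption the per-well ratio

$$r_w = \frac{\text{firefly}_w}{\text{renilla}_w}$$

is free of transfection noise, and the fold change of well $w$ relative
to a reference condition $R$ is

$$\text{FC}_w = \frac{r_w}{\overline{r}_R}, \qquad
  \overline{r}_R = \frac{1}{|R|}\sum_{w' \in R} r_{w'}.$$

Two properties follow directly and are enforced by tests: the reference
group's mean fold change is exactly 1, and rescaling both channels of
every well by a common positive constant leaves every fold change
unchanged.

## Choices the formula does not make for you

**The denominator is the reference group's arithmetic mean ratio.** One
could instead divide each well by a paired reference well, or by the
geometric mean. We use the group mean: it is the convention in reporter
assays, it requires no pairing structure, and it keeps the per-condition
means identical to what averaging-first would give. Because per-well
ratios are approximately log-normal, a geometric-mean denominator is
available via `fold_change(..., geometric = TRUE)`; it self-normalizes in
log space (mean log fold change of the reference is 0) rather than in
linear space.

**Fold change is computed per well, then summarized** — never on
pre-averaged ratios. The two orders give identical condition means but
different per-point spreads; computing per well preserves the individual
observations for the dot plot, which is the point of showing dot plots
at all. The per-point spread therefore includes the reference-mean
estimation error, which is worth remembering when reading error bars.

**Global versus stratified referencing.** With a multi-factor design
(vector x drug x cell type) the control vector usually appears within
every drug-by-cell combination, and each combination should be
normalized against its own controls. `fold_change()` therefore defaults
to stratified mode when the reference selector is a single
`factor=level` pair and more than one design factor exists; a full
condition key, or `stratified = FALSE`, gives one global denominator. A
stratum without reference wells is a hard error naming the stratum —
silently borrowing a denominator from elsewhere would change the
scientific meaning of the number.

**Condition keys.** Multi-factor conditions are identified by joining
the factor labels in declared column order with `"_"` (configurable). A
separator occurring inside a label triggers a warning because the key is
then not injective. Designs with a single condition column work
unchanged; the join is the identity there.

**Missing internal control.** A tidy upload may omit the renilla column.
The ratio is then the raw firefly signal and every downstream step is
unchanged, but outputs are labelled unnormalized (the dot-plot axis says
so). Negative counts — possible after instrument background
subtraction — are rejected by default and accepted with
`allow_negative = TRUE`.

**Summary statistics.** Per condition: n, mean, sample standard
deviation (n−1), SEM, median, and a 95% t-interval on the mean with n−1
degrees of freedom. The t-interval is a choice, not a given; with n = 3
replicates it is wide and that is the honest width. Spread statistics
are `NA` for n = 1 rather than 0.

## Reading and writing the instrument format

Plate workbooks store each channel as an 8x12 table with row labels A–H
and column headers 1–12, surrounded by metadata the instrument writes
wherever it pleases. `read_glomax()` scans the sheet for exactly such
labelled 8x12 blocks and takes the first two in reading order as firefly
then renilla — the channel order of the export dialect — so preamble
rows do not matter. When auto-detection is wrong (unusual dialects),
`workbook_layout()` pins the anchors explicitly; swapping the two
anchors swaps the channels. A well blank in both channels is skipped
with a message (an unused well); blank in only one channel is an error,
because an unpaired reading means the file is damaged. Fidelity of the
auto-detector to every instrument firmware revision cannot be promised;
the layout override exists for exactly that case.

The package also *writes* this dialect (`write_glomax()`), using a
minimal deterministic XLSX writer (numbers at full double precision,
pinned archive timestamps). That makes round-trip testing possible
offline and gives the simulator a way to emit instrument-like files;
two writes of the same plate are byte-identical.

CSV inputs are comma-delimited UTF-8 with `.` decimals; a
semicolon-delimited European dialect (with `,` decimals) is auto-detected
from the header line. Column roles in tidy uploads resolve as explicit
argument > header name (`firefly`; `renilla`/`control`/`reference`) >
position (first numeric column is the signal).

## What the simulator emulates — and what it does not

`generate_experiment()` draws, for well $w$ in condition $c$:

$$t_w \sim \text{LogNormal}(0, \sigma_t), \quad
  \text{renilla}_w = \mu_R\, t_w\, \varepsilon_w, \quad
  \text{firefly}_w = \mu_R\, F(c)\, t_w\, \varepsilon'_w,$$

with $\varepsilon, \varepsilon' \sim \text{LogNormal}(0, \sigma_m)$
independent, $F(c)$ the true fold change (reference fixed at 1), and
wells filled in row-major plate order. Log-normal multiplicative noise
matches strictly positive luminescence counts and the multiplicative
nuisance model above. The defaults encode a realistic screen: 3 vectors
x 4 drugs x 2 cell types x 3 replicates = 72 wells, $\mu_R = 10^5$
counts, $\sigma_t = 0.3$ (transfection efficiency varying by ±30-ish
percent well to well), $\sigma_m = 0.05$ (a few percent photometric
noise), and true effects control = 1, geneA = 2.5, geneB = 0.4.

Because $t_w$ multiplies both channels exactly, the simulator realizes
the assay's own idealization. Passing tests on simulated data therefore
demonstrate that the *computation* is correct under the model, not that
the model holds on a bench: real plates have edge effects, channel
cross-talk, substrate decay over the read sequence, saturation at high
counts, and controls whose promoter is not perfectly constitutive. None
of these are modelled, and none are corrected by the package (by
design — they are assay-development problems, not data-processing ones).
One property the simulation *does* establish: inflating $\sigma_t$ by an
order of magnitude inflates raw firefly variance several-fold while
leaving fold-change variance essentially unchanged — the quantitative
case for carrying an internal control at all.

## Numerical and degenerate-input behaviour

- Zero renilla in any well is an error naming the wells (no silent
  infinities); `drop_zero_control = TRUE` drops them with a warning.
- A reference whose mean ratio is zero is an error (the fold change is
  undefined), as is a reference selector matching no rows — the message
  lists the available condition keys.
- Well identifiers are canonicalized (`"a1"` → `"A01"`) at every
  boundary; duplicate wells in a plate or design are errors listing the
  duplicates.
- Excluding a well or condition that is not present warns instead of
  erroring, so one exclusion list can serve many plates.
- Dot-plot jitter is deterministic (fixed seed in `plot_options()`), so
  re-exported figures are pixel-identical; points are never dropped, and
  non-finite plotted values error before plotting.
- File writers are deterministic; equality tolerances in round-trip
  tests are 1e−9 (text-format round-trip) while algebraic identities are
  held to 1e−12 relative.

## Problem sizes used in the test suite

The suite simulates plates of 9–96 wells; the property sweeps use 50
seeds for file round-trips and 500 seeds for the noise-cancellation
contrast; the bias check runs 1000 simulated experiments of 12 wells
(true effects 0.5, 1, 2, 5; $\sigma_t = 0.3$, $\sigma_m = 0.05$, n = 3)
and requires the Monte-Carlo mean within 3 standard errors of truth.
These sizes give stable verdicts while keeping a full run in tens of
seconds on a laptop.

## Known limitations

- One plate per analysis; no multi-plate batch effects or plate-edge
  correction.
- Import is limited to the one workbook dialect described above plus
  tidy/design CSVs; other manufacturers' exports need conversion.
- No hypothesis testing between conditions: the outputs are estimates
  and descriptive summaries. The tidy CSV is deliberately easy to feed
  into whatever inferential machinery fits the design.
- The fold-change estimator divides by an *estimated* reference mean;
  with few reference wells it is slightly biased upward (convexity of
  $1/\bar{r}$). At the default noise levels the bias is far below the
  replicate-to-replicate spread, and the acceptance checks bound it
  empirically.
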