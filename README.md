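# mixqc

Data-driven quality control for single-cell RNA-seq, based on jointly
modeling the two standard per-cell QC metrics — the percent of counts
mapping to mitochondrially encoded genes and the library complexity (number
of detected genes) — instead of thresholding each one independently.

## The problem

Compromised cells (broken membranes, degraded libraries, cells dead at
dissociation) show a high mitochondrial fraction and few detected genes.
The common fixes — a uniform cutoff such as "remove everything above 5% (or
10%) mitochondrial", or a median-absolute-deviation outlier rule on the
mitochondrial fraction alone — are either far too aggressive on
high-mitochondria tissues (tumors, kidney, heart) or far too permissive on
low-quality samples. `mixqc` instead learns, per sample, where the intact
and compromised populations sit.

## The model

For cell *i* with detected genes *x<sub>i</sub>* and percent-mitochondrial
*Y<sub>i</sub>*, a latent state *Z<sub>i</sub>* ∈ {0 = intact,
1 = compromised} is drawn with Pr(*Z<sub>i</sub>* = 1) = π₁, and

> E[*Y<sub>i</sub>* | *Z<sub>i</sub>* = z, *x<sub>i</sub>*] =
> f<sub>z</sub>(*x<sub>i</sub>*),  ε<sub>iz</sub> ~ N(0, σ²<sub>z</sub>)

with f<sub>z</sub> linear by default (β<sub>0z</sub> + β<sub>1z</sub>x, a
two-component mixture of linear regressions / latent class regression), or
a B-spline smooth, or a constant (a plain univariate Gaussian mixture).
Parameters are estimated by EM; the component with the greater y-intercept
is labeled compromised. Cells are removed when their posterior probability
of being compromised,

> γ<sub>i</sub>(1) = π₁ N(Y<sub>i</sub> | f₁(x<sub>i</sub>), σ₁²) /
> [π₁ N(Y<sub>i</sub> | f₁(x<sub>i</sub>), σ₁²) +
> π₀ N(Y<sub>i</sub> | f₀(x<sub>i</sub>), σ₀²)],

is at least 0.75 (configurable), with two default corrections: every cell
below the fitted intact line is kept, and cells that are worse in both
metrics than the lowest-mitochondrial removed cell are also removed.
Uniform-percent and 3-MAD baseline filters are included for comparison, and
an unconditional prefilter drops unambiguous failures (fewer than 500 total
counts or fewer than 100 detected genes) before fitting.

## Worked example

```r
library(mixqc)
cells <- simulate_qc_metrics(synthetic_params(n_cells = 5000, seed = 1))
pf    <- prefilter(cells)                 # 500 total counts / 100 genes
fit   <- fit_mixture(pf$retained)
print(fit)
decisions <- filter_cells(pf$retained, fit)
table(decisions$reason)
```

prints

```
Two-component mixture of regressions (mixqc_fit)
  cells: 5000, iterations: 13, converged: TRUE, restarts: 1
  intact:      pi = 0.684, coefficients = (1.498, 0.0004836), sd = 1.357
  compromised: pi = 0.316, coefficients = (49.21, -0.01568), sd = 7.916

left_cutoff_removal      posterior_fail      posterior_pass
                  1                1329                3670
```

The intact population sits on a flat line near 1.5% mitochondrial; the
compromised population starts near 49% at low complexity and declines with
x. 3670 of 5000 cells are kept; on this labeled synthetic sample the
decisions agree with the generator's true states for 99.7% of cells.

The same pipeline runs from the shell via the installed `exec/mixqc`
script:

```sh
mixqc simulate --n-cells 5000 --matrix --outdir sim --seed 1
mixqc filter --input sim/mtx --input-kind mtx_dir --seed 1 --outdir out
mixqc baseline --method mad --input sim/metrics.tsv --input-kind metrics_table --outdir out_mad
```

which writes `decisions.tsv`, `metrics.tsv`, `model.json` and
`run_log.json` into the output directory.

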