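---
title: "Optimizing SHELXL-style weights: model, algorithm and design notes"
author: "weightopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing SHELXL-style weights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weightopt)
```

## The weighting model

Refinement on F² minimizes Σ w (Fo² − Fc²)². The six-parameter
SHELXL-style weight implemented here is

$$ w = \frac{q}{\sigma^2(F_o^2) + (aP)^2 + bP + d + e\,\sin\theta/\lambda},
\qquad P = f\,\max(F_o^2, 0) + (1-f)\,F_c^2 . $$

The denominator is a variance model: the reported measurement variance
σ², augmented by a fractional-intensity error (aP)² (dominant for strong
reflections — scale, extinction, model inadequacy), a shot-noise-like
term bP, a flat offset d and a resolution ramp e·sinθ/λ. The factor q
depends on the sign of c: q = 1 for c = 0, q = exp(c·s²) for c > 0 and
q = 1 − exp(c·s²) for c < 0, with s = sinθ/λ. The resolution term uses
the first power of s; q with c < 0 is undefined at s = 0 (it would give
zero weight) and is rejected.

Only a and b are optimized; c = d = e = 0 are held fixed and f = 1/3
blends Fo² and Fc² with the conventional bias-reducing fraction. With
a = b = 0 the weight reduces exactly to the statistical w = 1/σ².
Negative measured Fo² are legitimate for weak reflections and are kept;
they are clamped to zero only inside P and inside |Fo| for R1. All
values stay on the file's native refinement scale — no rescaling between
Fo² and Fc², and no σ re-estimation, is ever applied.

### Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| a, b | – | searched | variance inflation, fractional and linear in P |
| c | – | 0 | resolution factor q (sign-switched) |
| d | – | 0 | flat variance offset (may make w undefined if < 0) |
| e | Å | 0 | linear resolution term in the denominator |
| f | – | 1/3 | Fo²/Fc² blend in P |
| `aStop`, `bStop` | – | 1e-4, 5e-3 | grid-search stopping step sizes |
| `nBins` | – | 10 | Fc-ordered bins of the objective |
| `gridSide` | – | 9 | candidates per axis per iteration |
| `shrinkFactor` | – | 0.5 | per-axis step reduction |

## The objective

Reflections are sorted by Fc² (the same ordering as Fc) and split into
`nBins` contiguous bins; when n is not divisible the larger bins come
first, so sizes differ by at most one. Per bin the statistic

$$ t_k = \sqrt{\tfrac{n}{n-p}\; \mathrm{mean}_{i \in k}\!\left(w_i \Delta_i^2\right)} $$

is a bin-resolved weighted goodness of fit: computed over one whole-set
bin it equals the global wGooF. The objective minimized over (a, b) is

$$ V(a, b) = \frac{1}{n_\mathrm{bins}} \sum_k (t_k - 1)^2
           = \mathrm{Var}_\mathrm{pop}(t_k) + (\bar t - 1)^2 , $$

the variance of the bin goodnesses about their ideal value 1. The
anchor at 1 is not cosmetic: the overall weight scale is a direction of
pure flatness (w → κw rescales every t_k identically), so a variance
about the bin mean alone is driven to zero by arbitrarily large a and
the edge-walking search would diverge. Anchoring at 1 demands both
flatness across intensity bins and a correct absolute scale, which is
what pins (a, b) to the data's actual variance inflation — and lands
the optimized wGooF near 1 as a side effect.

The n/(n−p) scaling uses whole-set degrees of freedom. A per-bin
alternative (n_k − p/n_bins) is available via `binDof = "perbin"`, but
for parameter-rich multipolar models p/n_bins can exceed a bin's size
and the degrees of freedom go negative, so the whole-set form is the
default and the per-bin form validates its denominator.

## The grid search

Each iteration evaluates V on a `gridSide` × `gridSide` lattice centred
on the current (a, b) with per-axis spacings (Δa, Δb); candidates are
clipped at zero (a, b < 0 are meaningless variances). The search then:

* recentres on the grid minimum; ties resolve to the lexicographically
  smallest (a, b) — the smaller correction — and a centre that already
  ties the minimum is kept, so a flat objective converges in place
  rather than drifting;
* halves an axis's step (`shrinkFactor`) when that axis's minimum is
  interior; a minimum on the grid edge leaves the step alone and the
  grid walks. A minimum pinned at the a = 0 or b = 0 clip boundary is
  treated as interior — there is nothing to walk into — otherwise the
  search would stall against the constraint;
* stops when Δa < `aStop` **and** Δb < `bStop` (the conservative
  reading of a per-axis stopping rule), or at `maxIterations`.

The best point ever evaluated is returned with the full per-iteration
trace and every evaluation, so the objective surface can be inspected
or exported (`writeTrace()`) for contour plots.

### Starting point and the stopping-point guard

Initial steps derive from the starts as Δ₀ = max(start/2, 2·stop). In
`strict` mode the floor is dropped (Δ₀ = start/2 for a positive start;
a zero start carries no scale and keeps 2·stop), and a step that starts
below its stopping size is a configuration error rather than a silent
non-search. This matters in practice: computed starts on multipolar
data can be of order 1e-5, far below the reference `aStop` = 1e-4, so a
strict search aborts immediately with instructions — raise the starts
or lower the stops (1e-7 and 1e-6 work). The default mode's 2·stop
floor makes the same configuration run.

When no starts are given they are computed by a SHELXL-style heuristic:
the excess of the residual scale over the reported variances is
attributed to the (aP)² term,

$$ a_\mathrm{start} = \frac{\sqrt{\max\!\big(\mathrm{med}(\Delta^2)/q_{0.5} -
   \mathrm{med}(\sigma^2),\, 0\big)}}{\mathrm{med}(P)}, \qquad
   b_\mathrm{start} = 0, $$

floored at 0.01 (unfloored in strict mode). The division by
q₀.₅ = qchisq(0.5, 1) ≈ 0.455 corrects the median of squared normal
residuals to a variance scale; without it the excess is systematically
negative and the heuristic collapses to the floor even on strongly
inflated data. Medians, not means, keep the estimate outlier-safe.
Degenerate inputs (zero residuals) fall back to (0.1, 0).

## Normal probability plots

The weighted deviates √w·(Fo² − Fc²) are sorted and plotted against the
expected normal order statistics Φ⁻¹((i − 0.5)/n) — the simplest widely
used plotting position; alternatives differ far below the tolerances
used anywhere in this package. Every reflection contributes one point
and keeps its identity (h, k, l, Fo², Fc², σ, w) for outlier
inspection via `writeNppTable()`.

The summary line is an ordinary least-squares fit restricted to the
central half of the *ranks* (n/4 < i ≤ 3n/4): quartile membership by
rank, not by value, is deterministic under ties, and anything outside
the central ranks can never move the fit — large outliers are excluded
by construction. Deviates are deliberately *not* divided by the overall
wGooF: an un-normalized plot lets the slope carry the scale information
(slope ≈ wGooF for well-shaped misfit), which is exactly the diagnostic
one wants next to the intercept.

At n = 10⁴ genuinely normal deviates give a slope within about ±0.02 of
1 and an intercept within ±0.02 of 0 at typical seeds; this calibration
is what `scripts/acceptance.R` recomputes.

## The synthetic generator

`generateReflections()` emulates a finished refinement whose errors
follow the scheme's own variance model: indices drawn without
repetition from the lattice inside s ≤ `sMax`; true intensities Fc²
exponential with mean `intensityScale` (acentric Wilson statistics;
lognormal alternatives change nothing structural and the exponential is
the standard acentric form); reported
σ = `sigmaFloor`·√(1 + Fc²/`intensityScale`); and observations
Fo² = Fc² + ε with ε ~ N(0, σ² + (aTrue·P)² + bTrue·P), P = Fc² on the
generator side (Fo² does not yet exist when ε is drawn — the same
circularity real weights face; setting f = 0 on the analysis side
reproduces the generator's P exactly, which the tests exploit).

What it does **not** emulate: centric/acentric mixtures and space-group
symmetry, anomalous scattering, correlated errors between reflections,
extinction, and genuinely non-normal error components. Passing tests
therefore show the machinery is correct under the stated variance
model, not that any particular experimental dataset satisfies it — on
real data the normal probability plot itself is the check, and a
non-normal plot should be investigated for systematic errors before any
weight is trusted.

Default generator conditions — cubic 10 Å cell, `sMax` = 1 Å⁻¹,
`intensityScale` = 100, `sigmaFloor` = 1 — give a lattice of ~33,000
reflections and I/σ ratios spanning weak to strong, a realistic shape
for a small-molecule data set on an arbitrary refinement scale.

## Problem sizes and tolerances

The parameter-recovery study uses n = 5000 reflections with
aTrue = 0.05, bTrue = 0.5 and stops (1e-5, 5e-4), recovering (a, b)
within 25% relative error — the generator/analysis P mismatch and
finite-sample noise set that scale, not the search, which locates the
minimum of its own objective to stopping resolution (verified against a
dense brute-force grid at half-stop spacing, tolerance 1e-10).
Calibration checks (residual standardization, goodness near 1) run at
n = 2000–5000 with ±5% bands. These sizes keep the whole suite under
half a minute while leaving Monte-Carlo noise well inside the asserted
bands.

## File-format notes

`.fcf` parsing is CIF-tag driven — permuting loop columns never changes
a value — and restricted to the refln loop plus cell/wavelength scalars.
An observed-status column (LIST 8) drops rows not flagged `o` unless
`keepUnobserved = TRUE`. `.fco` tables are read after skipping the
header: the body starts at the first line with exactly six all-numeric
fields whose h, k, l positions hold integers; the default column order
h k l Fc² Fo² σ(Fo²) can be overridden because XD variants differ.
Whether `.fco` sigmas follow the same scale convention as `.fcf` sigmas
is not knowable from the files; they are treated identically and both
are used exactly as read. Fortran D exponents are accepted everywhere.
Resolution values are recomputed on demand from the stored cell rather
than cached per reflection — the vectorized metric form is O(n) and a
cache invalidated by cell replacement would buy nothing but state.

## Known limitations

* Only a and b are searched; c, d, e are accepted in the scheme and
  honoured by the weight evaluation but never optimized.
* No symmetry merging, absorption/extinction handling or raw-intensity
  formats; inputs are finished-refinement structure factors.
* The objective assumes the model is essentially correct; weights can
  mask, not fix, an inadequate model, and statistical weights should be
  used while systematic errors are being hunted.
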