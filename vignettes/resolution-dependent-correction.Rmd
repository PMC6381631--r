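---
title: "Resolution-dependent natural abundance correction: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolution-dependent natural abundance correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoresolve)
```

## The correction model

A stable isotope labeling experiment measures, for each metabolite, the
fractional abundances of its isotopolog channels M+0 … M+Nt (the FAM vector
$z$, normalized to sum 1).  The quantity of biological interest is the mass
distribution vector (MDV, $x$): the fraction of molecules carrying 0, 1, …,
Nt tracer atoms.  The two differ because every atom carries naturally
occurring heavy isotopes and because the tracer nutrient is not isotopically
pure.  Both effects are linear in $x$:

$$ C\,x' = z, \qquad x = x' / \lVert x' \rVert_1 , $$

with $C$ the product, in fixed order, of

1. one lower-triangular Toeplitz factor per **non-tracer element** whose
   columns hold the element's isotopolog natural abundances at the channel
   shifts (`buildNontracerMatrix`),
2. the **tracer-element factor** whose column $j$ holds the natural-
   abundance pattern of the $N_t - j$ not-yet-labeled positions
   (`buildTracerMatrix`; binomial in the two-isotope case, iterative
   convolution otherwise),
3. the upper-triangular **impurity factor**
   $r_{i,j} = \binom{j}{i}\beta^{j-i}(1-\beta)^i$ with $\beta = 1 -$ atomic
   purity (`buildImpurityMatrix`).

All factors are built directly at $(N_t+1)\times(N_t+1)$: probability mass
beyond the last retained channel is dropped, never renormalized
(truncate-then-multiply).  Renormalizing would distort the ratios within a
column; dropping reflects that the missing isotopologs are simply not
measured.  $x'$ is obtained by Lawson–Hanson non-negative least squares
(`pracma::lsqnonneg`), which removes the negative MDV entries that plain
inversion produces on noisy data, and enrichment is reported as
$\sum_i i\,x_i / N_t$.  The $1/N_t$ normalization makes a 20 %-labeled
compound read 0.20 regardless of its size; `enrichment(..., normalized =
FALSE)` returns the bare weighted sum for users who want the mean number of
labeled atoms instead.

## Why resolution matters, and the two corrections

The classical matrix above (exposed as `totalMatrixNre`, the
no-resolution-effect baseline) assumes every same-nominal-mass contaminant
lands in the measured channel.  An FT analyzer resolves two ions when their
mass difference exceeds
$$\Delta M_{\min} = 1.66\,M^{1.5}/(R\sqrt{M_R}) \;\;\text{(Orbitrap)},
\qquad 1.66\,M^{2}/(R\,M_R)\;\;\text{(FT-ICR)},$$
with $R$ the nominal resolving power defined at reference m/z $M_R$
(defaults 200 and 400).  At $R = 100{,}000$ a glutamine ¹⁵N peak is
2.07·10⁻³ Da wide in this sense, while ¹⁵N-for-¹³C substitution differs by
6.32·10⁻³ Da — resolved, so ¹⁵N contamination must *not* be corrected for in
a ¹³C experiment at that resolution.  Applying the naive matrix anyway
overcorrects, often by more than the labeling signal itself.

**MDT** (`totalMatrixMdt`) rebuilds the natural-abundance part keeping only
unresolvable contributions.  Two modes:

* `mode = "original"` applies per-isotope *correction limits*
  $\lfloor \Delta M_{\min} / |\delta| \rfloor$ (capped at the atom count),
  where $\delta$ is the per-atom signed mass difference between the heavy
  isotope and the nominally equivalent tracer labeling.
* `mode = "combined"` (default) tests each isotope *combination* by the sum
  of its signed per-atom differences.  This admits sign-canceling
  combinations the limits reject: for glutamine/¹³C at 100k, ¹⁷O has limit
  2 and ¹⁸O limit 0, yet ¹⁷O₂¹⁸O₁ nets only 7.4·10⁻⁴ Da from ¹³C₄ and
  belongs in the matrix.  `enumerateUnresolvedCombinations` exposes the
  combination lists for inspection.

Resolved probability mass is excluded without renormalization: a resolved
contaminant is a separate observable peak, not part of the channel signal.
Consequently MDT column sums are at most the NRE ones, every entry is
non-increasing in $R$, and at $R \to \infty$ the matrix collapses to the
tracer ladder times the all-light probability of the non-tracer elements.

**ULS** (`ulsCorrectionMatrix`) builds the natural-abundance part from the
measured FAM of an unlabeled sample.  Since an unlabeled sample has
$x = (1, 0, \dots, 0)^T$, its FAM is (up to scale) column 0 of the
natural-abundance matrix; and because neighboring columns differ by exactly
one convolution with the tracer element's single-atom abundance vector,
column $j$ follows by dividing $j$ times (polynomial long division,
`deconvolveOnce`).  Negative intermediates — noise artifacts — are clamped
to zero after each pass and never renormalized; if the clamped (non-
physical) mass exceeds 10 % of a column's norm the compound is flagged as
likely measured near the limit of detection.  The impurity factor cannot be
inferred from unlabeled data and is always applied theoretically.
`naiveUlsMatrix` reproduces, for comparison only, the defective variant that
reuses the unlabeled vector unchanged for every column; deconvolution
visibly raises the main diagonal relative to it (the leading divisor
coefficient is $1-\alpha < 1$), which is exactly the defect's signature.

## Channel conventions and +2 tracers

The MDV index always counts *labeled atoms*.  For +1 tracers (¹³C, ²H, ¹⁵N)
channels sit at consecutive nominal masses.  For +2 tracers (¹⁸O, ³⁴S)
channel $i$ sits at nominal shift $2i$; table labels remain `M+k` with $k$
counting labeled atoms.  Species at odd nominal shifts (a single ³³S, a
single ¹⁷O under an ¹⁸O tracer) lie ≈1 Da from every channel — far beyond
any realistic $\Delta M_{\min}$ — and are treated as separate peaks outside
the measured ladder in every construction, including the baseline.

For the tracer element itself the package models natural abundance *per
atom*: each unlabeled tracer atom contributes its channel-mapped single-atom
vector, and a minor isotope (e.g. ³⁶S under a ³⁴S tracer) is retained only
when its own single-atom mass difference is unresolvable.  Multi-atom
combination terms of tracer minors (³³S₂ mimicking ³⁴S₁) are *not*
enumerated.  This is a deliberate design choice: a per-atom model is exactly
what a deconvolution ladder can represent, so the MDT matrix, the simulator
and the ULS construction agree to machine precision and validate one
another; the neglected terms are of order $p_{33}^2 \approx 6\cdot10^{-5}$
and only matter for compounds with several tracer-element atoms at low
resolving power.  Non-tracer elements always use the full combined-sum
enumeration, so the sign-canceling oxygen combinations above are unaffected.
The NRE baseline's tracer factor, by contrast, stays the faithful
multinomial over all isotopes (it is the defined comparison point and is
validated against brute-force enumeration), so for multi-isotope tracers
MDT at $R \to 0^+$ matches NRE exactly only in the two-isotope-tracer case —
the regime where that identity is asserted in the tests.

## The simulator and what passing tests mean

`simulateFam` is the package's validation-data generator and oracle.  It
draws the labeled-atom count from the binomial mixture
$x_i = \binom{N_t}{i}(1-e)^{N_t-i}e^i$ (independent incorporation), reverts
each nominally labeled atom with probability $\beta$, enumerates the joint
isotope fine structure of everything else exactly on a (nominal shift ×
mass defect) grid — per-element multinomial enumeration, cross-element
convolution, peaks merged at 10⁻⁹ Da, contributions below 10⁻¹⁸ pruned —
and bins each fine peak to the channel sharing its nominal mass when its
exact mass lies within $\Delta M_{\min}$ of the channel reference
$M_0 + i\,\Delta_T$; everything else is dropped as a separate peak.  A
multiplicative, seeded Gaussian noise knob (truncated at zero, off by
default) supports robustness checks of the ULS ladder.

Default study conditions mirror the validation design: 20 % enrichment,
99 % atomic purity, Orbitrap $R = 140{,}000$ for the small-metabolite
panels (24 nitrogen compounds, 10 sulfur compounds) and $R = 280{,}000$ for
the four coenzyme-A species (`metaboliteFormulas()`; standard neutral
formulas).  Under these conditions the test suite verifies, at tolerance
10⁻⁶ or tighter: exact forward/backward round trips for MDT, entrywise
(10⁻⁹) agreement between ULS-from-simulated-unlabeled and MDT matrices, and
strictly larger NRE error on at least one compound per panel.

What this does *not* show: agreement with any vendor simulator's internal
binning, behavior under chromatographic or peak-shape effects, partial
(near-resolved) peak overlap — the criterion is binary, as in the theory —
or instrument drift between labeled and unlabeled runs beyond what the
measured unlabeled FAM captures.  Real measured data add noise and spectral
bias that only the ULS route can partially absorb.

## Numerical conventions

* **Mass in $\Delta M_{\min}$**: the monoisotopic neutral mass of the
  *unlabeled* compound.  This convention reproduces the theory's worked
  values (2.07·10⁻³ Da for glutamine at 100k); using the labeled isotopolog
  mass instead changes it to 2.09·10⁻³ and is available via
  `useLabeledMass = TRUE`.  Mass and m/z are treated as equal (singly
  charged, no electron/proton adjustment).
* **Ties**: a combination at exactly $\Delta M_{\min}$ is resolved (strict
  inequality, tie tolerance 10⁻¹² Da); an exact isobar ($\Delta M = 0$,
  e.g. the tracer isotope itself) is never resolved.
* **Scale of the ULS matrix**: a measured, normalized unlabeled FAM equals
  the theoretical matrix column only up to the retained-mass fraction,
  which is not identifiable from the measurement.  Since the corrected MDV
  is invariant to any positive rescaling of $C$ (a property under test),
  `ulsCorrectionMatrix` keeps the scale of its input; `normalize = FALSE`
  plus `simulateFam(..., normalize = FALSE)` exposes the exact entrywise
  identity with MDT.
* **Degenerate inputs**: all-zero measured vectors, all-zero unlabeled
  vectors (with advice to fall back to MDT), inputs with more channels than
  $N_t + 1$ (rejected, never silently truncated) and formulas missing the
  tracer element are errors; short inputs are zero-padded; batch runs
  collect per-compound failures instead of aborting.
* **Isotope constants** are an embedded standard table (H, C, N, O, P, S)
  overridable at run time (`setIsotopeTable`, `readIsotopeTable`) — printed
  reference mass differences constrain the masses to ~10⁻⁶ Da, which the
  standard compilation satisfies.
* **Problem sizes in the checks**: the brute-force oracle enumerates all
  isotope assignments up to 10 atoms per element; recovery batteries run
  all 38 panel compounds noise-free at $e = 0.2$.  These sizes make the
  full suite complete in well under a minute while covering the largest
  formulas (C₂₇ CoA species) the methods target.

## Known limitations

* Adducts and fragments carrying only part of the formula are out of scope,
  as are flux fitting and vendor raw-file parsing — MDVs are exported for
  downstream tools.
* The original-MDT comparison mode applies per-isotope limits to all
  supported elements rather than restricting tracers to ¹³C/²H/¹⁵N as the
  historical implementation did; it is a documented comparison mode, not a
  faithful re-release of that tool.
* ULS needs $N_t$; it comes from the formula when present, else from the
  table's channel count.  Without a formula and resolution specification
  the ULS divisor cannot prune resolvable tracer-minor isotopes (relevant
  for ³⁴S/¹⁸O tracers only) and falls back to the full natural vector.
* The `.xlsx` spreadsheet dialect of the historical tool is not
  implemented; CSV/TSV are the normative formats here.
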