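---
title: "Quantifying single-cell isotope incorporation from nanoSIMS images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell isotope incorporation from nanoSIMS images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosipr)
```

## The measurement and the model

nanoSIMS imaging of cells incubated with ¹³C/¹⁵N-labeled substrates
produces, per analysis area, a stack of raster cycles with per-pixel
counts for four secondary ions: ¹²C₂⁻, ¹³C¹²C⁻, ¹²C¹⁴N⁻ and ¹²C¹⁵N⁻. Two
molecular-ion conventions connect count ratios to atom fractions: the CN
monomer ratio equals the ¹⁵N/¹⁴N atom ratio directly, while the C₂ dimer
ratio ¹³C¹²C⁻/¹²C₂⁻ equals twice the ¹³C/¹²C atom ratio (a ¹³C¹²C
molecule forms two ways). `ratio_to_fraction()` and `fraction_to_ratio()`
encode both, bijectively on ratio ≥ 0 ↔ fraction ∈ [0, 1).

Net incorporation of element X by one cell is

$$X_{net}\% = 100\,\frac{f_{X_f} - f_{X_i}}{f_{X_s} - f_{X_i}}$$

with $f_{X_f}$ the cell's measured final fraction, $f_{X_i}$ the initial
fraction and $f_{X_s}$ the effective substrate fraction. It reads as the
fraction of the cell's final biomass newly built from the labeled
substrate: 0% at baseline, 100% if the cell were made entirely of
substrate at its labeling level. Three modeling commitments deserve
notice:

- **$f_{X_i}$ comes from killed controls, per cell kind.** Formalin-killed
  parallel incubations define zero incorporation; we use the median
  fraction of killed cells of the same kind (bacterial vs algal) as the
  baseline, falling back to pooled killed cells when a kind has fewer
  than 3 controls. Whether to pool kinds is genuinely open; per-kind is
  chosen because instrumental offsets can differ with cell size and
  matrix.
- **$f_{X_s}$ carries explicit dilution bookkeeping.** When the labeled
  substrate mixes with an unlabeled pool (e.g. exudate released during
  the incubation), $f_s = (1-d) f_{labeled} + d f_{nat}$. The default
  experiment design uses $d = 0.5$; designs with undiluted substrate set
  $d = 0$. The dilution is a config value, not a constant, because the
  available evidence for it is indirect.
- **Daily rates assume linear accumulation.** `daily_rate()` divides by
  the incubation length. For growing cells this understates true uptake
  (exponential accumulation would compound), so fluxes derived from these
  rates are conservative; no correction is applied.

Negative $X_{net}$ values (counting noise below baseline) are retained in
distributions and summaries but floored at zero in flux calculations,
where a negative mass flux is physically meaningless.

A cell is called **enriched** when its fraction exceeds the
killed-control median by more than three killed-control standard
deviations, strictly. Under pure counting noise this keeps the
false-positive rate far below the 2% budget the test suite enforces.

Cell-to-cell variability is summarized by the quartile coefficient of
dispersion $CD = (Q_3 - Q_1)/(Q_3 + Q_1)$, robust to the heavy right
tails these distributions show. Quartiles use linear interpolation
between order statistics (R's default type 7); the choice is stated
because no convention was given with the definition, and CD values shift
by a few percent between conventions at small n.

## From raw stacks to per-cell records

**Dead time.** Pulse-counting electron multipliers are blind for a time
τ after each ion, so observed rates m under-report true rates as
n = m/(1 − mτ). `correct_dead_time()` applies the standard inversion per
pixel per cycle; τ defaults to 44 ns, a typical EM dead time, and is
configurable because the instrument value was not published. Pixels at
mτ ≥ 1 are a hard error naming the offending count — silent saturation
would corrupt ratios downstream.

**Registration.** Stage drift between cycles is estimated on the
¹²C¹⁴N⁻ image (the structural channel) by maximizing normalized
cross-correlation over integer shifts within a small search radius, ties
broken toward zero so featureless cycles stay put. Sub-pixel alignment
is deliberately out of scope: ROIs are tens of pixels across and the
per-cycle ratio statistics are insensitive to half-pixel residuals. The
original processing used proprietary software whose registration metric
is unknown; NCC is a stated replacement, validated in the test suite
against an exhaustive search oracle on planted shifts, not a
reproduction.

**Ratio images** are formed from cycle-accumulated counts with a
minimum-denominator validity mask (default 100 counts), so low-signal
background pixels never produce spurious ratios.

**Segmentation** mirrors the dual strategy used in practice: all cells
are found on the accumulated ¹²C¹⁴N⁻ image (Otsu threshold, 8-connected
components, size filter); bacteria of enriched strains can additionally
be detected on the ¹⁵N/¹⁴N ratio image as pixels above the killed median
+ 3 SD. One subtlety matters: ratio-detected components that overlap a
CN component are discarded in favor of the CN footprint. Keeping the
ratio-selected pixel subset would retain only noise-elevated pixels of
weakly enriched cells and bias their ratios upward — a ~2× median
inflation in early versions of this pipeline. The CN channel defines
*where* a cell is; ratios are then averaged over that full footprint.
Classification is by an inclusive area gate (default: components ≥ 80 px
at the 20 µm / 256 px scale are algal), and a bacterial ROI is flagged
attached when any pixel lies within 2 px (Chebyshev) of an algal ROI;
bacterial pixels dilated by 1 px are subtracted from algal ROIs so
attached bacteria do not contaminate algal ratios. The original algal
ROIs were drawn by hand; equivalence is claimed only on synthetic
fixtures, and a label-map import path exists for real manual masks.

**Per-cell statistics** follow the ratios-by-cycle convention: for each
ROI and element, minor and major counts are summed over the ROI within
each cycle, the per-cycle ratios averaged arithmetically, and the SEM
taken as the SD over cycles divided by √cycles. Cycles whose ROI-summed
major counts are zero are dropped and counted. The cell's fraction is
the converted mean-of-cycle-ratios; the SEM is stored for diagnostics
but does not enter enrichment calls, which use the killed-population SD.

## The synthetic world

The generator exists so that every downstream stage has ground truth. It
emulates the stated acquisition: 20 × 20 µm areas, 256 × 256 px, ~24
cycles at 1 ms dwell, four species imaged simultaneously. Within-cell
expected counts are set by major-ion yields (defaults: 45 C₂⁻ and 50
CN⁻ counts px⁻¹ cycle⁻¹, chosen so a bacterial ROI accumulates ≳ 10⁴ CN
counts — usable SIMS statistics); minor-ion means follow from each
cell's planted fractions through the ion conventions, so the scene is
isotopically consistent by construction. Every pixel in every cycle is
an independent Poisson draw; same config + seed is bit-identical.

Cell-to-cell variability is lognormal on $X_{net}$: the observed
distributions are positive and right-skewed and were characterized only
by quartiles, so the simplest positive skewed two-parameter family is a
stated choice, not an inference. Parameterizing by (median, CD) has a
closed form: for $X = m e^{\sigma Z}$,
$Q_{3,1} = m e^{\pm \sigma z_{0.75}}$, hence $CD = \tanh(\sigma z_{0.75})$
and $\sigma = \operatorname{atanh}(CD)/z_{0.75}$ — no numeric solve is
needed. Per-cell fractions are then obtained by inverting the
$X_{net}$ relation.

Defaults are calibrated to the printed ranges of the motivating
experiments: strain medians spanning ~0.4–16 %/d for N and ~0.9–5.4 %/d
for C, CDs of 0.15–0.6, substrate labeling 18% ¹³C / 45% ¹⁵N, killed
controls at the fixed natural-abundance constants (¹³C/¹²C = 0.011237,
¹⁵N/¹⁴N = 0.003676). Bacteria are 0.35 µm-radius disks, algae 3 × 1.2 µm
ellipses; attached bacteria are placed with their boundary within 2 px
of a host algal boundary, free-living cells with ≥ 3 px clearance.
Optional planted integer per-cycle shifts exercise registration.

What the generator does **not** model — and therefore what a green test
does not establish — includes quasi-simultaneous-arrival and matrix
effects, EM aging, charging, topography, beam point-spread (cells have
hard edges), overlapping cells, and real within-cell heterogeneity.
Green tests establish that the pipeline's estimators are unbiased and
correctly calibrated under ideal counting statistics, not that they are
robust to instrumental artifacts.

## Population statistics

Strain-vs-control comparisons pool cells across replicate fields and use
rank statistics: the tie-corrected Kruskal–Wallis H (chi-squared p on
k − 1 df), then Dunn's test of each strain against the control with
Dunn–Šidák adjustment $p_{adj} = 1-(1-p)^m$ over the each-vs-control
family (not all pairs — m is the number of strains). Dunn's z is
implemented from its rank formulation with explicit tie correction so
the permutation oracles in the test suite exercise the exact statistic.
A calibration caveat the tests document honestly: at very small n (≤ 8)
the chi-squared and normal approximations track exhaustive permutation
p-values to ~0.01 in the rejection region but can deviate by ~0.05–0.1
for mid-range p; at the pooled sample sizes the pipeline actually uses
(tens of cells per group) the approximations are accurate, and the
type-I error of the KW test at α = 0.05 is verified to sit inside the
99% binomial interval over 1000 null simulations.

Strain-level coupling of C and N acquisition is summarized by OLS of
median daily N_net on median daily C_net (slope, R², two-sided p).

## Fluxes

Volumetric incorporation combines three factors, each config-exposed:
abundance (cells mL⁻¹), per-cell element content, and the median daily
rate: flux = (cells mL⁻¹ · 10³) × (content_fg · 10⁻⁹ µg) ×
(X_net,daily/100), in µg element L⁻¹ d⁻¹. Content comes from the median
bacterial ROI area via projected-area → biovolume (sphere by default; a
capped-rod option degenerates exactly to the sphere at aspect ratio 1)
and the allometric law C = aV^b with a = 120 fg µm⁻³ᵇ, b = 0.72,
C:N = 4 — common bacterioplankton values, exposed because the
size-to-content literature does not agree on one relation; absolute
fluxes therefore carry that structural uncertainty even when rates are
exact. The microscopy density formula (mean per field × filter/FOV area
ratio / volume × dilution) is included for abundance inputs derived from
epifluorescence counts.

## Guild clustering

Strains are clustered on four features: bacterial median daily C_net and
N_net (incorporation) and algal median daily C_net and N_net in the same
co-culture (remineralization feedback). Features are z-standardized —
they span an order of magnitude, and unstandardized K-means would be
dominated by the N axis; whether the original analysis standardized is
unstated, so this is a documented package choice. Strains with any
missing feature are dropped before clustering (mirroring the removal of
a strain with missing data in the motivating study). K-means uses
k-means++ seeding and Lloyd iterations, best of n_init = 10 restarts,
deterministic given a seed; cluster-recovery assertions always use the
adjusted Rand index, never raw label equality.

The elbow method is operationalized as the k maximizing the second
forward difference of the inertia curve (maximum curvature), ties toward
smaller k. This criterion has a known sensitivity worth recording: with
three clusters of very unequal mutual separation (one far outlier
cluster), the 1 → 2 inertia drop dwarfs the 2 → 3 drop and the elbow
lands at k = 2. The bundled three-archetype fixture therefore places its
archetypes roughly equidistant after standardization — which is also the
structure under which "three guilds" is a well-posed claim at all. On
that fixture (14 strains, one dropped for missing data, between-archetype
separation ≥ 5× within-archetype SD) the chosen k is 3 with ARI = 1
across 20 clustering seeds.

## Ancillary rules

Two self-contained filters complete the scope. The proteomics detection
filter retains a protein iff some biological replicate of its own
co-culture detects it in both technical replicates AND ≥ 80% (inclusive)
of its counts fall in the correct samples; it is monotone in detections
and verified against brute-force enumeration of all 2¹⁰ single-protein
patterns. Pathway completeness is the fraction of required reaction
steps present in a genome (alternate reactions as OR-groups), complete
at ≥ 75% (inclusive — draft genomes make perfect recovery unrealistic).

## Numerical and degenerate-input policy

- Dead-time correction errors at saturation; τ = 0 is the exact identity.
- Constant images segment to zero ROIs with a warning, not an error.
- All-dropped cycle sets, < 3 killed controls, < 4 values for CD,
  non-positive CD scale, empty required gene sets, zero-variance
  regression predictors: all hard errors with specific messages.
- CD of a strain with no detectable incorporation is reported NA
  (matching the "n/a" convention for unenriched strains) rather than a
  noise-driven number.
- The pipeline writes stage outputs atomically and records an md5
  manifest; identical config + seed reproduce identical hashes. Every
  generated cell is either summarized or listed in `rejects.csv` with a
  reason.

## Known limitations

Integer-pixel registration only; no QSA/dead-layer/matrix corrections or
instrumental mass-bias calibration; segmentation equivalence to manual
ROIs is claimed only on synthetic fixtures; flux absolute scale inherits
the allometric parameters; the linearity assumption biases rates low for
fast growers. The acceptance suite is property-based throughout: the
motivating study's printed headline values calibrate the synthetic world
but are never asserted as expected outputs, because they derive from raw
measurements that cannot be recomputed from text.
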