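---
title: "Models and methods behind dhrecomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dhrecomb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dhrecomb` analyses meiotic recombination in doubled-haploid (DH)
populations: genetic map construction, Marey maps and recombination
landscapes, between-population comparisons, and crossover-interference
estimation. This vignette is the package's own account of the models it
implements, the constants it exposes, and the choices made where the
methodology was genuinely open.

## 1. The data and its observable

One DH line preserves one female gamete, so a line's genotype vector over a
chromosome's markers is a direct read-out of a single meiosis: maternal and
paternal alleles (coded `A` for the central parent of a cross and `B` for
the founder) alternate at each crossover (CO). Everything downstream rests
on this observable. The package works on three tabular objects: a genotype
matrix (lines × markers, `A`/`B`/`NA`), a marker table (id, chromosome,
1-based physical bp), and the crossover-event table derived from them.

## 2. Genetic maps and crossover extraction

Marker order is taken from physical positions; the package deliberately
performs no de novo marker ordering. For each adjacent marker pair the
recombination fraction r is the proportion of lines with different
non-missing alleles among lines informative at both markers
(pairwise-complete denominators), converted to additive distance with
Haldane's function d = −50·ln(1 − 2r) cM and accumulated. Sampling noise
can push r past 0.5 for weakly informative pairs; such pairs are capped at
r = 0.499 with a warning rather than failing.

**Error cleaning.** An isolated genotyping error in the middle of a parental
segment creates two phantom recombination events; at a per-call error rate
ε each error inflates two adjacent r's, so the Haldane map inflates by
roughly 2ε per interval — tens of percent at realistic array error rates.
The cleaning rule treats maximal chains of single-marker runs, flanked on
both sides by at least two consistent calls, as errors and sets them to
missing, provided the flank-to-flank genetic span is at most
`clean_window_cm` (default 10 cM). The window logic: a genuine double CO
producing a single-marker segment requires two COs within a couple of
marker intervals, and crossover interference makes such pairs vanishingly
rare (under gamma interference with shape ν = 2 the chance of a second
same-pathway CO within 10 cM is already >5-fold suppressed, and >2,000-fold
at ν = 6), while a genotyping error produces exactly this pattern at rate ε
per call. The window must span several marker intervals to be usable; at
~1 marker/cM densities a 2 cM window would never fire. Chains (not just
single singletons) matter because an error adjacent to a true CO boundary
yields two consecutive unit runs; removing the whole chain collapses the
pattern to the single true switch. Cleaning is applied iteratively
(`clean_genotype_errors()`, up to three passes in `run_pipeline()`): each
pass deflates the map, tightening the genetic window for the next. On
simulated data (150 lines, 1 marker/Mbp, ε = 0.002) the uncleaned map is
~50 % too long, and uncleaned errors inflate the estimated non-interfering
crossover fraction p because spurious singleton events are indistinguishable
from Poisson-sprinkled COs; after iterated cleaning the map is within ~2 %
of truth and (ν, p) are recovered within one standard error (measured in
the test suite). The rule is configurable and can be disabled
(`clean = FALSE`) for organisms with weak interference, where tight double
COs are genuinely common.

Crossover events are reported as half-open physical intervals
[left_bp, right_bp) between the flanking informative markers, with genetic
position at the flanking-marker midpoint. Missing calls are spanned, and
two true COs falling inside one marker interval cancel and are unobservable
in principle — the test suite therefore scores extraction recall against
simulator truth restricted to the region between the terminal markers,
where it exceeds 99 % at 1 marker/Mbp.

## 3. Marey maps and landscapes

A Marey map plots genetic against physical position; its derivative is the
local recombination rate. `fit_bare_marey()` fits a cubic smoothing spline,
iteratively rejects gross outliers (|residual| > 4 robust MADs, at most 5
rounds, with an absolute floor of 0.001 cM below which residuals are
treated as numerical), evaluates on a uniform grid (default step 0.5 Mbp,
below array marker spacing but above numerical noise), projects onto the
nearest nondecreasing sequence with isotonic regression, and anchors the
first grid value at 0 cM.

**Smoothing parameter.** Generalized cross-validation assumes independent
errors, but cumulative map positions carry random-walk noise (each
interval's estimation error propagates to all downstream positions), so
GCV systematically undersmooths — on simulated chromosomes it selects ~140
degrees of freedom where a dozen suffice, and the derivative becomes
unusable. The package therefore caps the effective degrees of freedom at
one per 10 Mbp (at least 8, never more than 0.8·n). With the cap, the
fitted landscape correlates with the simulator's true landscape at r > 0.95
(1,000 markers, 200 lines, 1 Mbp grid; tested).

Monotonicity is enforced by isotonic projection *after* the spline fit
rather than by a shape-constrained spline: it is simple, deterministic and
order-preserving, and the projection is a no-op wherever the fit is already
increasing. Because the projected map is monotone, the landscape
(central finite differences, one-sided at the ends) is nonnegative, and the
trapezoidal integral of the landscape telescopes exactly to the map's
genetic span — a conservation law asserted to 0.1 % on every map in the
tests.

**Masks and imputation.** Regions without mapping information — parental
IBD segments (detected as sliding 10 Mbp windows with ≥ 0.97 parental
similarity, stepped 2 Mbp) or regions with fewer than 1 polymorphic marker
per 2 Mbp — are masked. Both thresholds are configuration: the criteria are
qualitative in the field, and the defaults are chosen so that a simulated
IBD segment is covered ≥ 95 % while 50 %-similar dense regions never
trigger. For between-population comparisons, a masked segment is filled
with the genetic-increment profile of the comparison partner (or the
equal-weight average of all unmasked donor maps if the partner is masked
too), rescaled by the ratio of target-to-donor mean rate over the shared
unmasked support, then re-accumulated — so missing data never manufacture
artificial differences. Masking a map and imputing it from itself is the
identity to grid tolerance (tested), and imputed maps obey the same
conservation law.

## 4. Rates, pooling and comparison tests

GWRR is genetic length over physical span (cM/Mbp), per chromosome and
genome-wide; pooled populations use the line-number-weighted mean of member
lengths. Map-length differences are tested with Welch's unequal-variance t
on per-line genome-wide CO counts — for DH gametes the map length in cM is
100 × the mean per-line count, and the per-line counts supply the variance
the test needs. Landscape *shape* is compared by counting the two
populations' COs in 10 bins of equal genetic length on the shared reference
map (so overall length differences cancel) and applying a chi-squared test
on the 2 × 10 table; bins with expected counts below 1 are merged pairwise.
Chromosomes combine additively (`combine_landscape_comparisons()`) into a
population-level test. All p-values are reported raw and
Bonferroni-adjusted with the declared family size (all unordered pairs of
populations in a full run), and pairwise −log10(p) matrices are ordered by
average-linkage hierarchical clustering on Euclidean distances.

Calibration, measured in the test suite over 1,000 same-model replicate
pairs: the Welch test rejects at 5–6 % under the interfering model, and the
chi-squared test at 5–6 % when crossovers are Poisson (ν = 1), where its
multinomial sampling assumption holds exactly. Under strong interference
the per-bin counts are underdispersed relative to multinomial and the
chi-squared test becomes conservative (~1 % rejection at ν = 5) — a bias in
the safe direction, shared by any landscape comparison that bins correlated
crossovers, and worth remembering when interpreting non-significant shape
differences.

**Parental effects.** Under an additive model in which a cross's GWRR is the
mean of two parental effects, a half-sib design with a shared reference
founder identifies each founder's effect as GWRR(central × founder) −
GWRR(central × reference), up to a common constant that cancels in any
correlation analysis (e.g. regressing effects on group-membership
probabilities with `structure_regression()`, ordinary least squares with
the F-test p-value).

## 5. The two-pathway interference model

Crossovers form through an interfering pathway P1 and a non-interfering
pathway P2 contributing a proportion p of events. On the bivalent
(four-chromatid) scale P1 is a stationary renewal process with
inter-arrival Gamma(shape ν, rate 2ν(1−p)) — mean spacing 1/(2(1−p))
Morgan — and each event is inherited by a given gamete with probability 1/2
with no chromatid interference. The thinned gamete process is again a
stationary renewal process whose inter-arrival density is the geometric
mixture g(d) = Σ_{m≥1} 2^(−m)·Gamma(d; mν, 2ν(1−p)); P2 superposes an
independent Poisson process of intensity p per Morgan. The total intensity
is exactly 1 CO per Morgan, which is what defines the genetic scale. At
ν = 1 the model collapses to a single Poisson process and the likelihood
is provably independent of p (asserted to 1e−8 in the tests).

**Simulation** draws the first bivalent event from the analytic
forward-recurrence distribution (closed form via the gamma CDF identity
F_e(x) = (β/ν)·x·(1 − F_ν(x)) + F_{ν+1}(x), inverted by vectorised
bisection), so stationarity is exact without burn-in, then accumulates
gamma inter-arrivals to the chromosome end, thins to the gamete, and
superposes the Poisson P2 points. Edge effects are handled by stationarity,
not by simulating beyond the chromosome.

**Likelihood.** For a gamete with ordered COs y₁ < … < y_k on (0, L) the
likelihood sums over all 2^k assignments of observed COs to P2: each
assignment contributes p^|A|·e^(−pL) times the stationary ordered-point
density of the P1 complement, h(y₁)·Π g(gaps)·(1 − G(L − y_last)), with
h(x) = (1−p)(1 − G(x)) and the empty complement contributing the void
probability V(L) = 1 − (1−p)∫₀^L (1 − G). The subset sum is exhaustive and
refused beyond k = 20 (with chromosomes of a few Morgan, such gametes are
astronomically improbable). The mixture series is truncated at 40 terms
(geometric tail < 1e−12) with early exit once terms past the gamma mode are
negligible; ∫(1 − G) uses the same closed-form gamma-CDF identity as the
equilibrium distribution, cross-checked against adaptive quadrature in the
tests. The per-gamete computation is implemented in C++ (Rcpp), with void
probabilities cached across gametes sharing a chromosome length.

**Fitting** maximises the summed log-likelihood over ν ∈ [1, 50],
p ∈ [0, 0.5] (bounds generous for plant data) with a deterministic
13 × 11 coarse grid (ν log-spaced) followed by Nelder–Mead refinement on
(log ν, p). Variances come from the inverse observed information (central
differences, relative step 1e−3); a non-positive-definite Hessian or an
optimum within numerical distance of a bound flags the fit and reports NA
variances rather than fabricating precision. Two fits are compared with a
Welch statistic using these Fisher variances and a Welch–Satterthwaite
approximation on the gamete counts. A model-free check is also provided:
Monte-Carlo tests of the CO-count variance and the mean nearest inter-CO
distance against a Poisson null at the data's own rates.

On 100 replicate populations of 2,000 gametes (L = 1.5 Morgan, ν = 6,
p = 0.1) the fit recovers both parameters within their 95 % Fisher
intervals in ≥ 90 replicates, with |bias(ν)| < 10 % and |bias(p)| < 0.02,
and the Fisher variances shrink as 1/n across n = 500–8,000 (all measured
in the acceptance tests).

**The proximity reduction factor** summarises what a fitted ν means: the
probability that the next P1 crossover falls within distance d of a given
one, without interference ((1 − e^(−d))) relative to gamma(ν)-spaced
crossovers with unit mean (F_Gamma(d; ν, ν)). It is 1 at ν = 1,
nonincreasing in d and nondecreasing in ν.

## 6. The synthetic-data generator

The default genome mimics a large-genome cereal: 10 chromosomes of 150–301
Mbp (2,058 Mbp total), genome-wide rate 0.73 cM/Mbp (about 15 Morgan
total, i.e. ~15 COs per DH line), and sigmoid Marey curves with a flat
pericentromeric plateau (half-width 8 % of the chromosome) and
quadratically increasing rates towards the telomeres, plus a 2 % baseline
so the curve stays strictly increasing and invertible. Default meiosis
parameters are ν = 5, p = 0.1, mid-range for the interference strengths
and P2 fractions reported in maize; observation noise defaults to 2 %
missing calls and 0.2 % allele flips, array-like post-QC rates. Start
alleles are uniform per line and chromosome. Segregation distortion is
produced by per-line acceptance sampling keyed to the gamete's allele at
the distortion locus (accept with probability t if `A`, 1 − t otherwise),
which yields the target local transmission rate with the natural
recombination-distance decay toward 0.5 and leaves CO formation itself
untouched — the generator deliberately treats distortion and crossover
formation as independent.

What the generator does *not* emulate: chromatid interference, an enforced
obligate crossover beyond what the renewal model implies, male/female rate
differences, non-colinear or duplicated genomic segments (these enter only
as user-supplied masks), marker-specific error rates, and linkage
disequilibrium structure among founder genomes. Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
robustness to every artefact of real array data.

## 7. Numerical and degenerate-input policy

Monotone curves are interpolated piecewise-linearly between control points;
exact plateaus are tilted by 1e−12 per point before inversion. Equal-genetic
bins invert the reference map at genetic quantiles, resolving plateau ties
to the leftmost position. Zero-variance Welch inputs return p = 1 (equal
means) with a note. Marey fits refuse fewer than 10 markers and return a
flat map with a warning when all genetic positions coincide. Crossover
positions enter the interference likelihood in the genetic coordinates of
the population's own map, with interval censoring ignored — at the marker
densities for which the package is intended the flanking-midpoint error is
small, and the end-to-end recovery test quantifies the residual bias.
Identical seeds give bit-identical outputs everywhere, including the run
manifest of `run_pipeline()` (which records versions, seed, config hash and
per-stage row counts, but deliberately no timestamps).

## 8. Problem sizes in the shipped tests

The test suite simulates at sizes chosen to make the statistical assertions
sharp while remaining routine on a laptop: 10⁵ gametes for distribution-
level oracle checks, 100 replicate fits of 2,000 gametes for parameter
recovery, 1,000 replicate pairs for test calibration, and populations of
100–200 lines at 1–3.3 markers/Mbp for pipeline-level checks.

## 9. Known limitations

Haldane distances ignore interference by construction, so on strongly
interfering data the additive map is mildly contracted relative to the true
genetic length between distant markers; the package measures this on
simulations rather than correcting it, as the bias largely cancels in
between-population comparisons on shared marker panels. The chi-squared
landscape test is conservative under interference (Section 4). The additive
parental-effect decomposition assumes effects combine as means and is
identified only up to the reference founder. The interference likelihood
assumes the marker panel is dense enough that midpoint positions are
accurate; sparse panels (< 0.3 markers/cM) will bias ν downward.
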