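---
title: "Modelling avian discrimination of egg colour within and between clutches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling avian discrimination of egg colour within and between clutches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clutchvis)
library(dplyr)
```

## The problem

Hosts of brood-parasitic birds can defend themselves by rejecting foreign
eggs, and one long-standing hypothesis holds that a female whose own eggs
are very uniform (low intraclutch variation) should find a mismatched egg
easier to detect. Testing that idea needs two ingredients: a
physiologically grounded measure of how discriminable two eggs are *to a
bird*, and a clean statistical treatment of a three-arm rejection
experiment (increased variation, IV; decreased variation, DV; unmanipulated
controls, UNM). `clutchvis` implements both halves as a pipeline over
tibbles, with a seeded synthetic-data generator so that every stage can be
exercised and calibrated without field data.

## The receptor-noise-limited visual model

Birds are tetrachromats; songbird retinas carry ultraviolet- (UVS),
short- (SWS), medium- (MWS) and long-wavelength-sensitive (LWS) single
cones. For an egg with reflectance $R(\lambda)$ viewed under irradiance
$I(\lambda)$, the quantum catch of cone class $i$ with sensitivity
$S_i(\lambda)$ is

$$Q_i = \sum_{\lambda=300}^{700} R(\lambda)\, I(\lambda)\, S_i(\lambda)\,
\Delta\lambda ,$$

computed as a rectangular sum on the working grid (300--700 nm, 1 nm by
default; the trapezoid rule differs negligibly at this resolution and the
rectangular rule matches how the classic desktop tools do it). The
achromatic catch $Q_A$ uses the summed MWS + LWS sensitivity as a
double-cone / luminance proxy.

Discriminability follows the receptor-noise-limited model. Log receptor
contrasts $\Delta f_i = \ln(Q_i^{(a)}/Q_i^{(b)})$ are weighted by channel
noises $\omega_i$, and the tetrachromatic distance $\Delta S$ (in
just-noticeable differences, JND) is the standard opponent form whose
numerator sums the six receptor-pair terms $(e_i e_j)^2(\Delta f_k -
\Delta f_l)^2$ and whose denominator sums the four receptor-triple noise
products. $\Delta S > 1$ is conventionally discriminable. Channel noise
scales inversely with the square root of relative cone density,

$$\omega_i = w \sqrt{\eta_{\mathrm{ref}} / \eta_i},$$

with defaults $\eta = (1.0, 1.78, 2.21, 1.96)$ for UVS:SWS:MWS:LWS and
Weber fraction $w = 0.1$, values typical for thrush-like UVS species.

Three conventions deserve comment because the literature is not uniform:

* **Reference cone.** A single Weber fraction plus relative densities does
  not determine which cone's noise equals $w$. We anchor the most abundant
  cone (LWS), the dominant convention; the choice rescales *every*
  pairwise $\Delta S$ by one global constant, so rank orders — and the
  within- versus between-clutch comparison — are unaffected. The
  acceptance suite asserts this invariance explicitly.
* **Chromatic adaptation.** No von Kries step is applied: both spectra in
  a comparison share one illuminant, under which any per-receptor
  multiplicative adaptation cancels in $\Delta f_i$.
* **Achromatic Weber fraction.** Set to 0.1 by default (configurable);
  the achromatic contrast is $\Delta L = |\ln(Q_A^{(a)}/Q_A^{(b)})| / w_A$.

Because absolute JND magnitudes depend on these conventions, analyses in
this package should lean on comparisons (within vs between clutch, ranked
distances) rather than on absolute values.

## Spectra processing

Field reflectance data arrive as replicate measurements (by default nine
per egg: three at each of the blunt pole, middle and sharp pole).
Processing is: pointwise averaging to one spectrum per egg (a flat mean
over all replicates — identical to the mean of per-position means for
balanced designs), linear interpolation onto the working grid (no
extrapolation), then triangular smoothing over a 30 nm base width to
attenuate spectrometer noise. The kernel's weights decay linearly to zero
at $\pm$ 15 nm and are renormalised to unit mass near the boundaries, so a
constant spectrum is a fixed point, affine ramps are preserved in the
interior, and the integral of an interior-supported spectrum is conserved.
The exact kernel convention of the desktop tools this emulates is
undocumented, so the width is a parameter rather than a constant.

Reflectance units are auto-detected: any value above 2 flags a percent
scale and the file is divided by 100 (override with `unit =`). Sensitivity
curves digitised from 330 nm upward are completed down to 300 nm with
zeros via `pad_sensitivity()`, mirroring standard practice when a model
requires the full 300--700 nm range.

## Within- versus between-clutch variation

Per egg, catches are normalised to proportions $Pr_i = Q_i / \sum_j Q_j$
(single cones only), removing intensity and leaving chromatic composition.
Each proportion, and the achromatic catch, is compared across clutches
with Welch's heteroscedastic one-way test; egg colour variances differ
markedly between clutches, and the non-integer denominator degrees of
freedom of the Welch statistic are the natural choice (a classical
equal-variance ANOVA is available via `var_equal = TRUE` for comparison).
Clutches contributing fewer than two eggs are excluded from these tests
and counted in the report's attributes. No multiple-testing correction is
applied across the six responses; they are reported as six independent
tests.

For discriminability, JNDs are computed for *every* unordered egg pair and
then thinned to a disjoint pairing in which each egg appears at most once,
avoiding pseudoreplication. `sample_disjoint_pairs()` offers two schemes:

* `"uniform"` — a uniformly random greedy maximal matching, the simplest
  defensible null scheme. Its weakness is structural: with $e$ eggs, any
  given pair is matched with probability $\approx 1/(e-1)$, and
  within-clutch pairs are such a small fraction of all pairs that a
  uniform matching of, say, 69 eggs in 23 clutches contains on average
  about *one* within-clutch comparison — too few to compare groups.
* `"balanced"` — one uniformly drawn within-clutch pair per clutch, with
  the remaining eggs matched uniformly across clutches. Still a maximal
  matching of $\lfloor e/2 \rfloor$ pairs, still seed-deterministic, but
  both comparison types are represented. `clutch_variation_report()` uses
  this scheme; any leftover odd egg is dropped and recorded.

The within/between comparison itself is a two-group Welch test on the
matched pairs' $\Delta S$ values.

```{r variation-example}
raw <- simulate_egg_spectra(n_clutches = 8, eggs_per_clutch = 3,
                            replicates = 3, grid = wl_grid(300, 700, 5),
                            seed = 42)
receptors <- receptor_set(simulate_sensitivities(grid = wl_grid(300, 700, 5)))
processed <- raw |> average_replicates() |> smooth_triangular(30)
clutch_variation_report(processed, receptors, seed = 42) |>
  tibble::as_tibble()
```

## The rejection experiment

Nest-level outcomes (reject/accept by treatment IV/DV/UNM) collapse to a
3 x 2 contingency table with fixed level order. Analyses:

* **Fisher's exact test** (probability-ordering two-sided rule), delegated
  to `stats::fisher.test` and cross-checked in the test suite against a
  hand enumeration of margin-fixed tables.
* **Monte-Carlo Fisher** with 2000 replicates by default: margin-fixed
  tables are sampled (equivalent to uniformly permuting column labels
  against row labels) and the p-value is estimated as $(1 + B)/(B_{\max} +
  1)$, which never returns exactly zero and is deterministic given a seed.
  Ties with the observed table's probability are counted as at least as
  extreme, with a $10^{-10}$ log-scale tolerance, matching the exact
  enumeration convention.
* **Effect size and power.** Cramér's $V = \sqrt{\chi^2 / (N
  (\min(r,c)-1))}$ (equal to the $\chi^2$ effect size $w$ for any
  two-column table), and power from the noncentral $\chi^2$ distribution
  with noncentrality $N w^2$. At $w = 0$ the power is $\alpha$ exactly, by
  construction. `required_n()` root-solves the continuous power curve and
  reports both the unrounded solution and its ceiling — rounding an
  observed $V$ to two decimals before solving can shift the required
  sample size by tens of nests, so solve from the unrounded value.
* **Binomial logistic GLM** of rejection on treatment (reference level DV,
  so the reported contrasts are IV and the unmanipulated control), nesting
  stage (laying = 0, incubation = 1), Julian date, clutch size, and year
  as a nominal fixed effect, fitted by IRLS to a relative deviance change
  below $10^{-8}$ (at most 100 iterations). A year factor with a single
  observed level is dropped; suspiciously huge standard errors (> 50 on
  the log-odds scale) are treated as separation and coefficients are
  withheld. A year *random* effect is deliberately out of scope: the
  fixed-effect model answers the same question here without pulling in a
  mixed-model dependency.

```{r rejection-example}
records <- simulate_outcomes(seed = 42)
tab <- tabulate_outcomes(records)
tab
tidy(fisher_mc_test(tab, seed = 42))
eff <- cramers_v(tab)
chisq_power(eff$w, eff$N, eff$df)
required_n(eff$w, 0.8, df = eff$df)$n
```

## The synthetic world

`simulate_egg_spectra()` states the conditions the pipeline is calibrated
under: 23 clutches of 3 eggs measured 9 times each (a realistic single
field season for a thrush-sized host); reflectance a 0.05 baseline plus a
Gaussian peak of height 0.55 and 50 nm width centred near 500 nm
(immaculate blue-green eggs, with hue — peak wavelength — as the varying
trait); clutch centres spread with 10 nm between-clutch and 4 nm
within-clutch standard deviation, echoing the common finding that
between-female variation dominates; replicate noise 0.005 on the
reflectance scale. `simulate_outcomes()` states a weak-effect three-arm
world: 15 nests per arm across three seasons with rejection probabilities
0.67 / 0.73 / 0.81 (IV / DV / UNM) — differences small enough that a
three-arm test of this size should usually *fail* to reject independence,
the situation that motivates the power analysis tools.

What the generator does **not** emulate: the ultraviolet shoulder of real
eggshell spectra, pigment chemistry (biliverdin/protoporphyrin), probe
position effects, maculation, and any dependence of rejection on the
covariates (they are simulated null, which is exactly what makes them
useful for calibration). A green test suite therefore establishes that the
machinery is correct and well calibrated on clutch-structured Gaussian
spectra and Bernoulli outcomes — not that any particular biological effect
size is true.

Template sensitivities come from `simulate_sensitivities()`: Gaussian or
A1 visual-pigment nomogram shapes peaking at configurable wavelengths
(thrush-like defaults 373/454/504/557 nm), unit peak height, optionally
zeroed over 300--330 nm. They are stand-ins; users with digitised
measured curves should load them with `read_sensitivities()` and pass them
to `receptor_set()` unchanged.

## Numerical choices and edge cases

* Integration: rectangular rule at the grid step; regridding is linear
  interpolation with no extrapolation (padding sensitivities is explicit).
* Smoothing widths below two grid steps return the input unchanged with a
  warning rather than pretending to smooth.
* `chromatic_jnd()` refuses non-positive catches (log contrasts undefined)
  and names the offending egg in pipeline contexts.
* Welch tests refuse zero-variance groups with advice to jitter or
  exclude; `clutch_variation_report()` refuses data with fewer than two
  clutches of two or more eggs.
* The Monte-Carlo Fisher estimator never returns 0; its tie tolerance is
  $10^{-10}$ on the log-probability scale.
* All generators and every randomised stage (pairing, Monte-Carlo tests)
  are deterministic given their `seed` argument and restore the caller's
  RNG state.

## Limitations

Absolute JND values depend on the reference-cone and Weber conventions
discussed above; compare, rank, and test rather than quoting magnitudes.
The flat default illuminant is a neutral stand-in — supply a measured
ambient irradiance (e.g. forest shade) via `read_illuminant()` for
habitat-specific results. Ocular-media transmittance, double-cone spatial
pooling and colour spaces other than receptor-noise distances are out of
scope, as are mixed (random-effect) models for the rejection data.
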