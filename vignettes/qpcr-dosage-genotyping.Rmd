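---
title: "Allele dosage genotyping of polyploids from qPCR: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele dosage genotyping of polyploids from qPCR: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polydose)
```

## The problem

Genotyping a polyploid at a biallelic locus requires more than detecting
presence or absence of each allele: a red-fleshed tetraploid loquat may be
AAAa, AAaa or Aaaa, and those heterozygotes segregate differently in
crosses. `polydose` estimates the *allele dosage* — the count of dominant
copies among the 2–5+ locus copies — from quantitative PCR of genomic DNA,
using three assays per sample: a reference amplicon with constant copy
number per haploid genome (input normalizer), an allele-A-specific
amplicon, and an amplicon shared by both alleles.

## The dosage model

Relative quantities follow the standard efficiency-corrected
$2^{-\Delta\Delta C_t}$ method. For assay $x$ on sample $s$ against
calibrator $c$,

$$ RQ_x = E^{-\left[(\bar{C_t}_{x,s} - \bar{C_t}_{\mathrm{ref},s}) -
(\bar{C_t}_{x,c} - \bar{C_t}_{\mathrm{ref},c})\right]}, $$

with $E$ the per-cycle amplification factor (default 2, i.e. perfect
doubling; configurable per panel, $1 < E \le 2$). Replicate $C_t$ values
are averaged *before* forming $\Delta\Delta C_t$; averaging per-replicate
quantities instead is a defensible alternative, but averaging in cycle
space is the convention we fix, and at the noise levels involved the two
differ negligibly.

Because the reference has constant copies per haploid genome at every
ploidy, normalizing by it puts quantities on a per-haploid scale. The
calibrator — a heterozygous diploid of known genotype — then anchors the
scale: its own signals are defined to read $a_1 = 1$ (allele A) and
$a_3 = 2$ (both alleles), so for any sample

$$ a_1 = 2\,RQ_A \cdot \tfrac{n_A^{cal}}{m_{cal}}, \qquad
   a_3 = 2\,RQ_{A+a}, \qquad a_2 = a_3 - a_1, $$

and the dosage statistics are

$$ b = \frac{a_1}{a_1 + a_2}, \qquad
   \theta = \tan^{-1}\!\left(\frac{a_2}{a_1}\right)\ \text{(degrees)}. $$

For a sample whose locus copies are a fraction $p$ allele A, the expected
value of $b$ is exactly $p$, independent of ploidy: a diploid Aa, a
tetraploid AAaa and a 1:1 DNA mixture of AA and aa pools all sit at
$b = 0.5$. $\theta$ maps pure-A to 0° and pure-a to 90°; it is related to
$b$ by $\theta = \tan^{-1}((1-b)/b)$ and is reported for diagnostic use,
but $b$ is the primary statistic (it is linear in $p$, so its calibration
fit is tighter).

Two boundary conventions matter in practice:

* **Undetected targets.** A well whose template is absent never crosses
  threshold; the instrument ceiling (`undetected_ct`, default cycle 40) is
  recorded, and a replicate-mean $C_t$ at or above it is treated as
  relative quantity zero. This makes white-fleshed homozygotes read
  exactly $b = 0$ rather than a noise-floor artifact.
* **Over-unity signals.** Real plates show $b > 1$ for some AA
  homozygotes (copy-number variation is the suspected cause). When the
  combined signal falls below the A-specific signal, $a_2 < 0$ is *kept*
  as computed and flagged (`negative_a2`); only $\theta$ is clamped to its
  [0°, 90°] range. No correction is applied, because none is established.

## Calling allelic configurations

A configuration with $k$ dominant copies at ploidy $m$ has expected
$b = k/m$, giving class centers $\{0, 1/m, \dots, 1\}$ (at 4x:
aaaa 0, Aaaa 0.25, AAaa 0.5, AAAa 0.75, AAAA 1). `call_genotype()` assigns
each observed $b$ to the nearest center; values outside $[0, 1]$ clamp to
the extreme classes, which is how an over-unity AA sample still calls AA.
An exact midpoint between two centers resolves to the *lower* dosage and
sets an `ambiguous` flag (tie tolerance `tie_tol`, default $10^{-8}$);
real data never sit on a midpoint, but the rule must be fixed for
determinism. The full class set is always supported — including recessive
homozygotes absent from any particular germplasm panel.

Separability of the classes is quantified two ways, matching common
practice for dosage assays: farthest-neighbor (complete-linkage)
hierarchical clustering of the scalar $b$ values cut at the class count,
and one-way ANOVA of $b$ by class. Both accept replicate-level values.
When every class has zero within-variance the F ratio is reported as
infinite with an explicit flag rather than dividing by zero. Whether the
original analyses used raw or standardized $b$ is immaterial for a scalar.

## The synthetic mixture library and plate simulator

The calibration experiment mixes two homozygous diploid DNA pools (AA and
aa) at 9:1, 5:1, 3:1, 2:1, 3:2, 1:1, 2:3, 1:2, 1:3, 1:5 and 1:9, plus the
two pure pools — 13 members whose allele-A fractions
$p = \mathrm{red}/(\mathrm{red}+\mathrm{white})$ span $[0, 1]$. The 2:1
and 1:2 mixtures mimic triploid heterozygotes; 3:1, 1:1 and 1:3 mimic
tetraploid ones. Mass mixing equals copy mixing under the assumption that
both pools share genome size and locus copy number per genome — true for
two diploid pools of one species.

`simulate_plate()` inverts the quantification model: a target present at
relative quantity $q$ per haploid genome gets
$C_t = C_t^{base} - \log_E q$ (with $C_t^{base} = 20$ at unit quantity, a
typical gDNA working concentration), plus Gaussian noise of standard
deviation `ct_sd` on every detected well. This synthesis model — baseline
$C_t$, log-linearity in copies, a shared baseline across assays — is the
package's own plumbing, not an empirical claim; the original data are
experimental plates. Its purpose is a round-trip contract: at
`ct_sd = 0`, `allele_signals()` recovers $b = p$ to within $10^{-9}$ for
every $p$, which the test suite checks on a 101-point grid.

Default `ct_sd` is 0.05 cycles. At a reference $C_t$ near 20 this gives
reference CVs around 0.25%, far inside the 3% stability bound expected of
a usable reference assay, and propagates to a $b$ spread of roughly 0.02 —
comparable to the per-class standard deviations observed on real plates
(0.01–0.08). What the simulator does *not* model: pipetting error,
inhibitor or efficiency drift between assays, copy-number variation, and
plate-position effects. Passing simulation tests therefore demonstrates
the correctness of the arithmetic and the separability of ideal classes,
not robustness to every real-plate pathology — the over-unity AA
observations are exactly the kind of feature the simulator will never
produce.

The proportion–dosage relationship is summarized by OLS of $b$ on $p$ and
of $\theta$ on $p$, with $R^2$ the squared Pearson correlation. $\theta$
responds through an arctan, so even noise-free data give a linear
$\theta$ fit below 1; a linear fit is used for both because the reference
analysis reports a single correlation per statistic, and the choice only
affects the diagnostic $\theta$ fit.

## Polysomic inheritance and segregation tests

Autopolyploid gametes are modeled by random chromosome segregation: a
gamete of $g$ copies from a parent with $n_A$ dominant among $m$ carries
$k$ dominant copies with hypergeometric probability

$$ P(k) = \frac{\binom{n_A}{k}\binom{m-n_A}{g-k}}{\binom{m}{g}}, $$

computed in exact integer arithmetic (numerators summing to the
denominator) before conversion to doubles. Double reduction and
preferential pairing are deliberately out of scope: they require pairing
parameters no loquat estimate exists for, and the random-segregation null
is the model against which the published ratios were derived.

**Gamete-ploidy allocation.** For a progeny-ploidy class of a
polyploid × diploid cross, the diploid parent contributes a normal haploid
gamete ($g = 1$) and the polyploid parent contributes
$g = \text{progeny ploidy} - 1$. One rule thus covers 2x, 3x, 4x and 5x
progeny of a 4x × 2x cross via tetraploid gametes of ploidy 1–4
(pentaploids arising from unreduced 4n gametes). Other routes are
expressible explicitly: `cross_spec()` accepts per-parent gamete ploidies
and a `doubled` flag for whole-genome doubling of the zygote. The doubled
route is what reproduces a 1:1 expectation for tetraploid progeny of
aa × AAaa (n + n zygotes Aa:aa doubling to AAaa:aaaa), the one printed
class expectation the single default rule does not generate.

Phenotypes follow complete dominance (white iff zero A copies), expected
ratios are reduced to least integer terms, and goodness of fit uses
Pearson's $\chi^2$ with expected counts scaled to the observed total,
df = 1, and **no Yates continuity correction** — the uncorrected statistic
is what reproduces the published per-class values (1.81, 3.27, 2.00,
0.07, 0.04, …); the corrected variant does not. A class with expected
probability zero contributes nothing when unobserved and flags the test
as degenerate (infinite $\chi^2$) when observed. Pooled `Total` rows use
class-size-weighted sums of per-class expected counts; published pooled
ratios were derived some other, unstated way and differ slightly, so they
are reported from the model, not copied.

One published triploid cell (27 red : 19 white against 1:1) prints 1.44
where the uncorrected Pearson value is 1.39; the package reproduces 1.39
and treats the printed figure as a source discrepancy. Progeny-ploidy
percentages are rounded half-even to 2 dp; the source table mixes
rounding and truncation in its last digit (e.g. 83.63 for 46/55), so
agreement is to one unit in the final printed digit.

## Numerical and design choices

* $\theta$ in degrees, matching its 0–90° presentation.
* $b$ is defined as $a_1/(a_1+a_2)$ — the allele-A share — which is the
  only orientation consistent with homozygous-AA classes near 1.
* Efficiency defaults to 2.0 for all assays; the design validates that
  the two allele assays amplify with essentially equal efficiency, and a
  shared configurable $E$ is the corresponding contract.
* Clustering and calling are deterministic: clusters are relabeled by
  increasing mean $b$; nearest-class ties break toward lower dosage.
* Exact rational arithmetic in the gamete model keeps probability masses
  summing to one identically for all ploidies up to at least 8 (verified
  exhaustively against subset enumeration).
* Fixture generation is fully seeded; identical specs produce
  byte-identical files (provenance headers carry tool version, config
  hash and seed, never timestamps).

Test-suite problem sizes — a 101-point round-trip grid, 1,000-sample call
recovery, $10^5$ sampled gametes, 3 replicates at 5 dosage levels for the
clustering/ANOVA checks — were chosen as the smallest sizes at which each
property is convincingly exercised.

## Known limitations

* Single biallelic locus; no multi-locus or linked-marker support.
* No double-reduction or preferential-pairing parameters; segregation
  tests are against the polysomic random-segregation null only.
* No absolute quantification or standard-curve efficiency estimation;
  efficiency is supplied, not fitted.
* Copy-number variation (the suspected cause of over-unity $b$ on real
  plates) is flagged but not corrected.
* The plate simulator's noise is Gaussian in cycle space only.

## A worked example

```{r example}
library(polydose)

# simulate the 13-member mixture library noise-free and fit b ~ p
lib <- simulate_mixture_library(ct_sd = 0, seed = 1)
fit <- proportion_dosage_regression(library_dosages(lib))
fit

# genotype a synthetic polyploid roster
dir <- tempfile()
generate_fixture(fixture_spec(seed = 1), dir)
calls <- genotype_samples(read_plate(file.path(dir, "plate.csv")),
                          read_samples(file.path(dir, "samples.csv")))
head(calls[, c("sample_id", "ploidy", "b", "genotype", "residual")])

# segregation of a tetraploid x diploid cross
segregation_table(data.frame(
  cross = "AAaa x aa", female_genotype = "AAaa", male_genotype = "aa",
  progeny_ploidy = 3L, observed_red = 66L, observed_white = 14L))
```
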