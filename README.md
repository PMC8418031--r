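# polydose

Allele dosage genotyping of polyploid plants from quantitative PCR.

Most genotyping assays only tell you *whether* an allele is present. In a
polyploid that is not enough: a red-fleshed tetraploid loquat can be AAAa,
AAaa or Aaaa, and those heterozygotes behave differently in breeding
crosses. `polydose` turns ordinary qPCR of genomic DNA into a quantitative
genotype: it estimates how many copies of each allele an individual
carries, calls the full allelic configuration at any ploidy, and tests
whether cross progeny segregate as polysomic Mendelian inheritance
predicts. It is aimed at plant breeders and geneticists working with
autopolyploid crops who need dosage-resolved genotypes without sequencing.

## The method

Each sample is run with three assays: a reference amplicon with constant
copy number per haploid genome, an allele-A-specific amplicon, and an
amplicon shared by alleles A and a. Relative quantities come from the
2^−ΔΔCt method against a heterozygous diploid calibrator, scaled so the
calibrator reads a1 = 1 (allele A) and a3 = 2 (both alleles). With
a2 = a3 − a1, the dosage statistic

    b = a1 / (a1 + a2)

estimates the fraction of locus copies that are allele A: a configuration
with k dominant copies at ploidy m sits at b = k/m (at 4x: aaaa 0,
Aaaa 0.25, AAaa 0.5, AAAa 0.75, AAAA 1). Calling assigns each b to the
nearest class. The companion angle θ = tan⁻¹(a2/a1) maps pure-A to 0° and
pure-a to 90°.

The package also provides:

* a simulator for homozygote DNA-mixture libraries (9:1 … 1:9 plus pure
  pools) and synthetic qPCR plates with Gaussian Ct noise, with an exact
  noise-free round trip (b = p);
* separability diagnostics: complete-linkage clustering of b and one-way
  ANOVA across dosage classes;
* a polysomic inheritance module: hypergeometric gamete distributions
  from parental configurations, expected red:white ratios per
  progeny-ploidy class, and Pearson chi-square goodness-of-fit tests
  (no continuity correction), including progeny-ploidy tabulation.

## Worked example

```r
library(polydose)

# 13-member AA/aa mixture library, noise-free plates, b regressed on p
lib <- simulate_mixture_library(ct_sd = 0, seed = 1)
fit <- proportion_dosage_regression(library_dosages(lib))
fit
#> b ~ p:     slope 1.0000, intercept -0.0000, R^2 = 1.0000
#> theta ~ p: slope -96.62, intercept 93.31, R^2 = 0.9953
```

Noise-free simulated mixtures recover b = p exactly, so the b-vs-p fit is
the identity with R² = 1; the θ fit is curvilinear (arctan), so its
linear R² stays slightly below 1.

```r
# genotype a synthetic polyploid roster (seeded, with 0.05-cycle Ct noise)
dir <- tempfile()
generate_fixture(fixture_spec(seed = 1), dir)
calls <- genotype_samples(read_plate(file.path(dir, "plate.csv")),
                          read_samples(file.path(dir, "samples.csv")))
head(calls[, c("sample_id", "ploidy", "b", "genotype", "residual")])
#>   sample_id ploidy      b genotype residual
#> 1      B431      4 0.2543     Aaaa 0.004263
#> 2      B432      4 0.2599     Aaaa 0.009895
#> 3      B479      4 0.7703     AAAa 0.020258
#> 4      B433      4 0.7268     AAAa 0.023225
#> 5      B456      4 0.5057     AAaa 0.005728
#> 6      H424      4 0.9794     AAAA 0.020587
```

Each sample's noisy b lands near its class center and is called to the
configuration whose expected b is nearest; `residual` is the distance to
that center.

```r
# does a AAaa x aa cross segregate as polysomic inheritance predicts?
segregation_table(data.frame(
  cross = "AAaa x aa", female_genotype = "AAaa", male_genotype = "aa",
  progeny_ploidy = 3L, observed_red = 66L, observed_white = 14L))
#>       cross female male class red white observed_ratio expected_ratio chi2    p
#> 1 AAaa x aa   AAaa   aa    3x  66    14         4.71:1            5:1 0.04 0.84
#> 2 AAaa x aa   AAaa   aa Total  66    14         4.71:1            5:1 0.04 0.84
```

A duplex tetraploid crossed to a recessive diploid gives triploid progeny
through diploid gametes whose A count is hypergeometric: only 1/6 of
gametes carry no A, so the expected ratio is 5:1. The observed 66:14
(4.71:1) fits with χ² = 0.04 (df 1, p = 0.84).

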