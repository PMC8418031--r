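# Delta-delta-Ct quantification, allele signals, reference stability.

test_that("relative quantity follows the delta-delta-Ct arithmetic", {
  pan <- assay_panel()
  # calibrator against itself: ddCt = 0 -> 1
  cal <- hand_plate("CAL2", c(reference = 20, allele_A = 21, combined = 20),
                    c(reference = 20, allele_A = 21, combined = 20))
  expect_equal(relative_quantity(cal, cal, "allele_A", pan,
                                 sample_id = "CAL2", calibrator_id = "CAL"), 1)
  # one cycle earlier at identical reference: ddCt = -1 -> 2
  pl <- hand_plate("S", c(reference = 20, allele_A = 20, combined = 19),
                   c(reference = 20, allele_A = 21, combined = 20))
  expect_equal(relative_quantity(pl, pl, "allele_A", pan, "S", "CAL"), 2)
  # hand evaluation of 2^-(4 - 3) = 0.5
  pl2 <- hand_plate("S", c(reference = 20, allele_A = 24, combined = 21),
                    c(reference = 20, allele_A = 23, combined = 21))
  expect_equal(relative_quantity(pl2, pl2, "allele_A", pan, "S", "CAL"), 0.5)
  # replicate Cts are averaged before ddCt
  pl3 <- rbind(
    data.frame(sample_id = "S", assay = rep(c("reference", "allele_A"), each = 2),
               replicate = c(1:2, 1:2), ct = c(20, 20, 22, 24)),
    data.frame(sample_id = "CAL", assay = c("reference", "allele_A"),
               replicate = 1L, ct = c(20, 22)))
  expect_equal(relative_quantity(pl3, pl3, "allele_A", pan, "S", "CAL"),
               2^-(23 - 20 - 2))
})

test_that("missing wells raise an incomplete-plate error naming the gap", {
  pan <- assay_panel()
  pl <- hand_plate("S", c(reference = 20, allele_A = 21, combined = 20),
                   c(reference = 20, allele_A = 21, combined = 20))
  expect_error(relative_quantity(pl[pl$assay != "allele_A", ], pl,
                                 "allele_A", pan, "S", "CAL"),
               "incomplete plate.*allele_A.*'S'|'S'.*allele_A")
  expect_error(validate_plate(data.frame(sample_id = "S", assay = "q2A",
                                         replicate = 1L, ct = 20)),
               "unknown assay")
  expect_error(validate_plate(data.frame(sample_id = "S", assay = "reference",
                                         replicate = 1L, ct = NaN)),
               "finite")
})

test_that("allele signals recover the calibrator scaling convention", {
  # noise-free AA diploid vs Aa calibrator: a1 = 2, a2 = 0, b = 1, theta = 0
  sig <- signals_for(exact_plate(1))
  expect_equal(sig$a1, 2, tolerance = 1e-12)
  expect_equal(sig$a2, 0, tolerance = 1e-12)
  expect_equal(sig$b, 1, tolerance = 1e-12)
  expect_equal(sig$theta, 0)
  # heterozygous diploid: a1 = a2 = 1, b = 0.5, theta = 45
  sig <- signals_for(exact_plate(0.5))
  expect_equal(c(sig$a1, sig$a2, sig$b, sig$theta), c(1, 1, 0.5, 45),
               tolerance = 1e-12)
  # triploid AAa surrogate: b = 2/3
  sig <- signals_for(exact_plate(expected_b("AAa")))
  expect_equal(sig$b, 2 / 3, tolerance = 1e-12)
  # calibrator against itself: a1 = 1, a3 = 2
  pl <- exact_plate(0.5)
  cal_cts <- pl[pl$sample_id == "CAL", ]
  self <- allele_signals(cal_cts, calibrator_spec(), cal_cts, assay_panel())
  expect_equal(c(self$a1, self$a3), c(1, 2), tolerance = 1e-12)
})

test_that("noise-free b equals the template A-fraction (copy-count oracle)", {
  # oracle: direct copy arithmetic, bypassing Ct space entirely
  for (p in c(0, 0.1, 1 / 3, 0.5, 2 / 3, 0.75, 0.9, 1)) {
    sig <- signals_for(exact_plate(p))
    expect_equal(sig$b, p, tolerance = 1e-9)
    expect_false(is.na(sig$b))
  }
})

test_that("b is strictly increasing in the template A-fraction", {
  ps <- seq(0, 1, length.out = 21)
  bs <- vapply(ps, function(p) signals_for(exact_plate(p))$b, 1)
  expect_true(all(diff(bs) > 0))
})

test_that("theta is consistent with b and handles the limits", {
  for (p in c(0.2, 0.5, 0.8, 1)) {
    sig <- signals_for(exact_plate(p))
    expect_equal(sig$theta, theta_from_b(sig$b), tolerance = 1e-6)
  }
  # pure-a sample: a1 = 0 -> theta 90
  expect_equal(signals_for(exact_plate(0))$theta, 90)
  expect_equal(dosage_theta(0, 0), 0)     # a2 <= 0 limit wins
  expect_equal(dosage_theta(1, -0.2), 0)  # negative a2 clamps theta only
})

test_that("over-unity signals keep their computed a2 and are flagged", {
  # combined signal one cycle late relative to the A signal -> a3 < a1
  pl <- hand_plate("S", c(reference = 20, allele_A = 20, combined = 20.3),
                   c(reference = 20, allele_A = 21, combined = 20))
  sig <- allele_signals(pl, calibrator_spec(), pl[pl$sample_id == "CAL", ],
                        assay_panel(), sample_id = "S")
  expect_lt(sig$a2, 0)
  expect_identical(sig$flag, "negative_a2")
  expect_gt(sig$b, 1)
  expect_equal(sig$theta, 0)
})

test_that("reference stability computes per-group CV in percent", {
  rs <- reference_stability(c(20, 20, 20, 20, 22), c(2, 2, 2, 3, 3))
  expect_equal(rs$summary$cv[rs$summary$group == "2"], 0)
  expect_equal(rs$summary$cv[rs$summary$group == "3"],
               100 * sqrt(2) / 21, tolerance = 1e-12)  # ~6.73%
  expect_false(rs$all_below)
  expect_error(reference_stability(c(20, 21, 22), c(2, 2, 3)),
               "fewer than 2")
})

test_that("fixture plates at default noise keep reference CV under 3%", {
  spec <- fixture_spec(seed = 11L)
  plate <- simulate_roster_plate(spec)
  ref <- plate[plate$assay == "reference", ]
  ploidy <- setNames(spec$roster$ploidy, spec$roster$sample_id)
  rs <- reference_stability(ref$ct, ploidy[ref$sample_id])
  expect_true(rs$all_below)
  expect_true(all(rs$summary$cv < 3))
})
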