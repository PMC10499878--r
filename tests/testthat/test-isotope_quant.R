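test_that("ratio <-> fraction round-trips exactly under both conventions", {
  f <- seq(0, 0.99, by = 0.01)
  for (conv in c("CN_monomer", "C2_dimer")) {
    expect_equal(ratio_to_fraction(fraction_to_ratio(f, conv), conv), f,
                 tolerance = 1e-12)
  }
  # the dimer convention satisfies r = 2f/(1-f) pointwise
  set.seed(1)
  fr <- runif(1000, 0, 0.99)
  expect_equal(fraction_to_ratio(fr, "C2_dimer"), 2 * fr / (1 - fr),
               tolerance = 1e-12)
  # frozen hand values
  expect_equal(ratio_to_fraction(0, "CN_monomer"), 0)
  expect_equal(ratio_to_fraction(0, "C2_dimer"), 0)
  expect_equal(ratio_to_fraction(1, "CN_monomer"), 0.5)
  expect_equal(ratio_to_fraction(0.022475, "C2_dimer"), 0.011112,
               tolerance = 1e-4)
  expect_error(ratio_to_fraction(-0.1, "CN_monomer"), "non-negative")
  expect_error(fraction_to_ratio(1, "CN_monomer"), "\\[0, 1\\)")
})

test_that("effective substrate fraction mixes labeled and natural pools", {
  sp <- substrate_spec(f_s_C_labeled = 0.18, f_s_N_labeled = 0.45,
                       dilution_unlabeled = 0.5)
  # hand arithmetic: 0.5*0.18 + 0.5*0.011112
  expect_equal(effective_substrate_fraction(sp, "C"), 0.095556,
               tolerance = 1e-9)
  sp0 <- substrate_spec(dilution_unlabeled = 0)
  expect_equal(effective_substrate_fraction(sp0, "C"), 0.18)
  expect_equal(effective_substrate_fraction(sp0, "N"), 0.45)
  sp1 <- substrate_spec(dilution_unlabeled = 1)
  expect_equal(effective_substrate_fraction(sp1, "N"),
               natural_abundance()$f15N)
})

test_that("Xnet closed form, endpoints, and affine invariance", {
  expect_equal(compute_xnet(0.003663, 0.003663, 0.45), 0)
  expect_equal(compute_xnet(0.45, 0.003663, 0.45), 100)
  # worked example: inputs printed to 6 digits, so the exact hand value is
  # 100*(0.039371-0.003663)/(0.45-0.003663) = 8.000233...; 8.000% printed
  expect_equal(compute_xnet(0.039371, 0.003663, 0.45),
               100 * (0.039371 - 0.003663) / (0.45 - 0.003663),
               tolerance = 1e-9)
  expect_equal(compute_xnet(0.039371, 0.003663, 0.45), 8, tolerance = 1e-4)
  # noise below baseline is reported as-is
  expect_lt(compute_xnet(0.003, 0.003663, 0.45), 0)
  expect_error(compute_xnet(0.01, 0.2, 0.2 + 1e-8), "indistinguishable")
  # affine invariance: remap all three fractions by x -> a*x + b
  set.seed(3)
  for (i in 1:20) {
    fi <- runif(1, 0, 0.01); fs <- runif(1, 0.1, 0.5)
    ff <- runif(1, fi, fs)
    a <- runif(1, 0.5, 2); b <- runif(1, -0.01, 0.01)
    expect_equal(compute_xnet(ff, fi, fs),
                 compute_xnet(a * ff + b, a * fi + b, a * fs + b),
                 tolerance = 1e-9)
  }
})

test_that("daily rate divides by duration and rejects bad durations", {
  expect_equal(daily_rate(8, 1), 8)
  expect_equal(daily_rate(8, 2), 4)
  expect_equal(daily_rate(20.65, 2), 10.325)
  expect_error(daily_rate(5, 0), "> 0")
})

test_that("enrichment call is median + 3 SD with strict inequality", {
  killed <- c(0.0036, 0.0037, 0.0038)  # median .0037, sd 1e-4
  expect_true(enrichment_call(0.0041, killed))
  thr <- median(killed) + 3 * sd(killed)
  expect_false(enrichment_call(thr, killed))          # exactly at threshold
  expect_false(enrichment_call(0.0037, rep(0.0037, 5)))  # sd 0, at median
  expect_error(enrichment_call(0.004, c(0.0037, 0.0038)), "at least 3")
})

test_that("coefficient of dispersion: hand quantiles, scale invariance", {
  expect_equal(coefficient_of_dispersion(1:5), 1 / 3, tolerance = 1e-12)
  expect_equal(coefficient_of_dispersion(rep(7, 10)), 0)
  set.seed(4)
  v <- rlnorm(50)
  expect_equal(coefficient_of_dispersion(v),
               coefficient_of_dispersion(17.3 * v), tolerance = 1e-12)
  expect_error(coefficient_of_dispersion(c(1, 2, 3)), "at least 4")
  expect_error(coefficient_of_dispersion(c(-5, -4, -3, -2)),
               "non-positive scale")
})

test_that("per-cycle ROI ratios: hand mean/SEM and the drop rule", {
  # 3 cycles, 2x2 image, ROI = all 4 px; per-cycle ratios 0.01/0.02/0.03
  major <- array(100, dim = c(3, 2, 2))
  minor <- array(0, dim = c(3, 2, 2))
  minor[1, , ] <- 1; minor[2, , ] <- 2; minor[3, , ] <- 3
  stacks <- list("12C14N" = major, "12C15N" = minor)
  px <- as.matrix(expand.grid(1:2, 1:2))
  r <- roi_cycle_ratios(stacks, px, "N")
  expect_equal(r$mean, 0.02)
  expect_equal(r$sem, sd(c(0.01, 0.02, 0.03)) / sqrt(3), tolerance = 1e-9)
  expect_equal(r$sem, 0.005774, tolerance = 1e-4)
  # identical cycle ratios -> SEM 0
  minor2 <- array(2, dim = c(3, 2, 2))
  r2 <- roi_cycle_ratios(list("12C14N" = major, "12C15N" = minor2), px, "N")
  expect_equal(r2$sem, 0)
  # zero-denominator cycle dropped and counted
  major3 <- major; major3[2, , ] <- 0
  r3 <- roi_cycle_ratios(list("12C14N" = major3, "12C15N" = minor), px, "N")
  expect_equal(r3$n_cycles_dropped, 1)
  expect_equal(r3$n_cycles_used, 2)
  expect_equal(r3$mean, mean(c(0.01, 0.03)))
  # all dropped -> error
  major4 <- array(0, dim = c(3, 2, 2))
  expect_error(
    roi_cycle_ratios(list("12C14N" = major4, "12C15N" = minor), px, "N"),
    "no usable cycles")
})
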