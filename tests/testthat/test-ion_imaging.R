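test_that("dead-time correction: identity, hand value, monotonicity, saturation", {
  stack <- array(c(0, 10, 100, 1000), dim = c(1, 2, 2))
  expect_identical(correct_dead_time(stack, tau_ns = 0), stack)
  # 100 counts in 1 ms -> rate 1e5 cps; m*tau = 0.0044 at tau = 44 ns
  one <- array(100, dim = c(1, 1, 1))
  expect_equal(as.vector(correct_dead_time(one, 44, 1)), 100 / (1 - 0.0044),
               tolerance = 1e-12)
  expect_equal(as.vector(correct_dead_time(one, 44, 1)), 100.4419,
               tolerance = 1e-4)
  # output >= input, strictly increasing in rate
  corr <- correct_dead_time(stack, 44, 1)
  expect_true(all(corr >= stack))
  expect_true(all(diff(as.vector(corr)) > diff(as.vector(stack)) - 1e-12))
  # formula matches n = m/(1 - m tau) across a rate sweep
  counts <- seq(0, 5000, by = 250)
  sw <- correct_dead_time(array(counts, c(1, 1, length(counts))), 44, 1)
  m <- counts / 1e-3
  expect_equal(as.vector(sw), (m / (1 - m * 44e-9)) * 1e-3,
               tolerance = 1e-12)
  # pole: m*tau = 1 at counts = dwell/tau
  sat <- array(1e-3 / 44e-9, dim = c(1, 1, 1))
  expect_error(correct_dead_time(sat, 44, 1), "saturation")
})

test_that("registration recovers planted shifts exactly (exhaustive oracle)", {
  base <- textured_image(64)
  n_cyc <- 4
  planted <- rbind(c(0, 0), c(2, -3), c(-1, 2), c(3, 3))
  arr <- array(0, dim = c(n_cyc, 64, 64))
  for (k in 1:n_cyc) {
    arr[k, , ] <- nanosipr:::shift_matrix(base, planted[k, 1], planted[k, 2])
  }
  reg <- register_cycles(list("12C14N" = arr), max_shift_px = 4)
  expect_equal(reg$shifts, -planted, ignore_attr = TRUE)
  # agreement with an independent SSD-minimizing exhaustive search
  for (k in 2:n_cyc) {
    expect_equal(reg$shifts[k, ], ssd_oracle_shift(base, arr[k, , ], 4),
                 ignore_attr = TRUE)
  }
  # aligned stack matches the reference cycle away from the border
  core <- 10:54
  for (k in 2:n_cyc) {
    expect_equal(reg$stacks[["12C14N"]][k, core, core], base[core, core])
  }
})

test_that("registration ties break toward zero and preconditions hold", {
  flat <- array(5, dim = c(3, 32, 32))
  reg <- register_cycles(list("12C14N" = flat), max_shift_px = 3)
  expect_true(all(reg$shifts == 0L))
  ident <- array(rep(textured_image(32, seed = 7), each = 3),
                 dim = c(3, 32, 32))
  reg2 <- register_cycles(list("12C14N" = ident), max_shift_px = 3)
  expect_true(all(reg2$shifts == 0L))
  expect_error(register_cycles(list("12C14N" = flat), max_shift_px = 16),
               "half the image side")
  expect_error(register_cycles(list("12C2" = flat)), "not present")
})

test_that("accumulation sums cycles and conserves counts at zero shift", {
  one <- array(rpois(64, 9), dim = c(1, 8, 8))
  expect_equal(accumulate_cycles(one), one[1, , ])
  two <- array(1, dim = c(2, 4, 4))
  expect_equal(accumulate_cycles(two), matrix(2, 4, 4))
  set.seed(8)
  stack <- array(rpois(5 * 16 * 16, 3), dim = c(5, 16, 16))
  expect_equal(sum(accumulate_cycles(stack)), sum(stack))
})

test_that("planted drift + registration restores the accumulated peak", {
  base <- matrix(0, 48, 48); base[24, 24] <- 1000
  base <- base + 2
  n_cyc <- 5
  shifts <- rbind(c(0, 0), c(1, 1), c(-2, 0), c(0, -2), c(2, 2))
  arr <- array(0, dim = c(n_cyc, 48, 48))
  for (k in 1:n_cyc) {
    arr[k, , ] <- nanosipr:::shift_matrix(base, shifts[k, 1], shifts[k, 2],
                                          fill = 2)
  }
  reg <- register_cycles(list("12C14N" = arr), max_shift_px = 3)
  acc <- accumulate_cycles(reg$stacks[["12C14N"]])
  # peak height equals cycles x per-cycle peak once drift is undone
  expect_equal(acc[24, 24], n_cyc * base[24, 24])
})

test_that("ratio images respect the denominator threshold", {
  img <- matrix(1:16, 4, 4) * 25
  r <- ratio_image(img, img, min_denominator_counts = 1)
  expect_true(all(r$values == 1))
  expect_true(all(r$valid_mask))
  den <- matrix(c(50, 200, 99, 100), 2, 2)
  num <- matrix(1, 2, 2)
  r2 <- ratio_image(num, den, min_denominator_counts = 100)
  expect_equal(r2$valid_mask, den >= 100)
  expect_true(is.na(r2$values[1, 1]))
  expect_equal(r2$values[2, 1], 1 / 200)
  expect_error(ratio_image(num, den, 0), "> 0")
  expect_error(ratio_image(num, matrix(1, 3, 3)), "share shape")
  # noiseless natural-abundance CN field gives the exact constant ratio
  cfg <- small_config(seed = 61, cycles = 3, pixels = 48)
  cells <- place_cells(cfg, n_bacteria = 2, seed = 3)
  sim <- render_ion_stacks(cells, cfg, noiseless = TRUE)
  summed <- lapply(sim$stacks, accumulate_cycles)
  rr <- ratio_image(summed[["12C15N"]], summed[["12C14N"]], 1)
  exact <- fraction_to_ratio(natural_abundance()$f15N, "CN_monomer")
  expect_equal(max(abs(rr$values - exact)), 0, tolerance = 1e-12)
  expect_equal(mean(rr$values), 0.003676, tolerance = 1e-3)
})

test_that("HDF5 stacks round-trip with metadata", {
  cfg <- small_config(seed = 71, cycles = 3, pixels = 32)
  cells <- place_cells(cfg, n_bacteria = 2, seed = 4)
  sim <- render_ion_stacks(cells, cfg)
  path <- tempfile(fileext = ".h5")
  write_ion_h5(sim, path)
  back <- read_ion_h5(path)
  for (sp in names(sim$stacks)) {
    expect_equal(back$stacks[[sp]], sim$stacks[[sp]], ignore_attr = TRUE)
  }
  expect_equal(back$meta$raster_um, cfg$raster_um)
  expect_equal(back$meta$seed, cfg$seed)
  unlink(path)
  # label-map CSV round trip
  lab <- matrix(sample(0:3, 64, TRUE), 8, 8)
  lp <- tempfile(fileext = ".csv")
  write_label_csv(lab, lp)
  expect_equal(read_label_csv(lp), lab, ignore_attr = TRUE)
  unlink(lp)
})
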