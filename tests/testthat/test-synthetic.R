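test_that("strain population inverts Xnet through the substrate relation", {
  s <- substrate_spec(f_s_N_labeled = 0.45, dilution_unlabeled = 0)
  # cd = 0: all cells identical, at the hand-inverted fraction
  f <- generate_strain_population(0.08, 0, 1, s, 10, seed = 1)
  # hand inversion: 0.003663 + 0.08 * (0.45 - 0.003663)
  expect_equal(unique(f), 0.003663 + 0.08 * (0.45 - 0.003663),
               tolerance = 1e-12)
  expect_equal(unique(f), 0.039371, tolerance = 1e-4)
  expect_length(f, 10)
  # large-sample median and CD recover the targets
  f2 <- generate_strain_population(0.08, 0.30, 1, s, 1e4, seed = 2)
  x <- compute_xnet(f2, natural_abundance()$f15N, 0.45) / 100
  expect_equal(median(x), 0.08, tolerance = 0.01 * 0.08 / 0.02)  # ~2% rel
  expect_equal(coefficient_of_dispersion(x), 0.30, tolerance = 0.02)
  # invalid dispersion and degenerate configs error
  expect_error(generate_strain_population(0.08, 1, 1, s, 10, seed = 1),
               "cd_target")
  expect_error(generate_strain_population(0.6, 0, 2, s, 10, seed = 1),
               "< 1")
})

test_that("rendering is seed-deterministic and isotopically consistent", {
  cfg <- small_config(seed = 11, cycles = 4, pixels = 48)
  cells <- place_cells(cfg, n_bacteria = 3, seed = 2)
  a <- render_ion_stacks(cells, cfg)
  b <- render_ion_stacks(cells, cfg)
  expect_identical(a$stacks, b$stacks)
  cfg2 <- small_config(seed = 12, cycles = 4, pixels = 48)
  c2 <- render_ion_stacks(cells, cfg2)
  expect_false(identical(a$stacks, c2$stacks))
})

test_that("ROI-summed ratio of one rendered cell matches Poisson error propagation", {
  # one bacterial cell at natural 15N abundance, high CN yield
  cfg <- generator_config(pixels = 64, cycles = 24, seed = 3,
                          yield_cell = c("12C2" = 45, "12C14N" = 200),
                          yield_bg = c("12C2" = 0, "12C14N" = 0))
  cells <- data.frame(cell_id = 1L, kind = "bacterial", row = 32, col = 32,
                      rx_px = 10, ry_px = 10, f13C_true = 0.011112,
                      f15N_true = 0.003663, attached_to = NA_integer_)
  sim <- render_ion_stacks(cells, cfg)
  summed <- lapply(sim$stacks, accumulate_cycles)
  inside <- summed[["12C14N"]] > 0
  n14 <- sum(summed[["12C14N"]][inside])
  n15 <- sum(summed[["12C15N"]][inside])
  ratio <- n15 / n14
  true_ratio <- 0.003676
  # Poisson SE of the ratio ~ ratio * sqrt(1/N15 + 1/N14)
  se <- true_ratio * sqrt(1 / (true_ratio * n14) + 1 / n14)
  expect_lt(abs(ratio - true_ratio), 3 * se)
  expect_equal(ratio, true_ratio, tolerance = 0.05)
  # zero background yields -> all off-cell pixels empty
  expect_true(all(summed[["12C14N"]][!inside] == 0))
  expect_true(all(summed[["12C2"]][!inside] == 0))
})

test_that("expected counts are conserved within Poisson noise", {
  cfg <- small_config(seed = 21, cycles = 6, pixels = 48)
  cells <- place_cells(cfg, n_bacteria = 4, seed = 5)
  sim <- render_ion_stacks(cells, cfg)
  area <- sum(sim$truth$area_px)
  npx <- 48 * 48
  for (sp in c("12C2", "12C14N")) {
    mu_cell <- cfg$yield_cell[[sp]]; mu_bg <- cfg$yield_bg[[sp]]
    expected <- 6 * (area * mu_cell + (npx - area) * mu_bg)
    total <- sum(sim$stacks[[sp]])
    expect_lt(abs(total - expected), 5 * sqrt(expected))
  }
})

test_that("noiseless rendering round-trips planted fractions to 1e-9", {
  cfg <- small_config(seed = 31, cycles = 4, pixels = 48)
  f_planted <- 0.0412
  cells <- data.frame(cell_id = 1L, kind = "bacterial", row = 24, col = 24,
                      rx_px = 6, ry_px = 6, f13C_true = 0.02,
                      f15N_true = f_planted, attached_to = NA_integer_)
  sim <- render_ion_stacks(cells, cfg, noiseless = TRUE)
  summed <- lapply(sim$stacks, accumulate_cycles)
  inside <- summed[["12C14N"]] >= 4 * cfg$yield_cell[["12C14N"]]
  rN <- sum(summed[["12C15N"]][inside]) / sum(summed[["12C14N"]][inside])
  expect_equal(ratio_to_fraction(rN, "CN_monomer"), f_planted,
               tolerance = 1e-9)
  rC <- sum(summed[["13C12C"]][inside]) / sum(summed[["12C2"]][inside])
  expect_equal(ratio_to_fraction(rC, "C2_dimer"), 0.02, tolerance = 1e-9)
})

test_that("overlap detection and placement invariants hold", {
  cfg <- small_config(seed = 41, cycles = 2, pixels = 48)
  cells <- data.frame(cell_id = 1:2, kind = "bacterial",
                      row = c(24, 25), col = c(24, 25),
                      rx_px = 5, ry_px = 5,
                      f13C_true = 0.011112, f15N_true = 0.003663,
                      attached_to = NA_integer_)
  expect_error(render_ion_stacks(cells, cfg), "overlap")
  expect_silent(render_ion_stacks(cells, cfg, allow_overlap = TRUE))
  # attached placement: boundary within 2 px of host (Chebyshev, approx)
  cfg2 <- small_config(seed = 42, cycles = 2, pixels = 96)
  pc <- place_cells(cfg2, n_bacteria = 4, n_algal = 1,
                    attached_fraction = 0.5, seed = 7)
  att <- pc[!is.na(pc$attached_to), ]
  expect_equal(nrow(att), 2)
  host <- pc[pc$kind == "algal", ]
  for (i in seq_len(nrow(att))) {
    th <- atan2(att$row[i] - host$row, att$col[i] - host$col)
    d <- sqrt((att$row[i] - host$row)^2 + (att$col[i] - host$col)^2)
    gap <- d - nanosipr:::ellipse_radius(host$rx_px, host$ry_px, th) -
      att$rx_px[i]
    expect_lt(gap, 2.5)
    expect_gt(gap, -1)   # no deep overlap with the host
  }
})

test_that("killed control sits at natural abundance; axenic carries an enriched subset", {
  cfg <- small_config(seed = 51, cycles = 2, pixels = 96)
  k <- generate_killed_control(cfg, n_bacteria = 5, n_algal = 1)
  na <- natural_abundance()
  expect_true(all(k$truth$f13C_true == na$f13C))
  expect_true(all(k$truth$f15N_true == na$f15N))
  ax <- generate_axenic(cfg, n_algal = 10,
                        enriched_subpopulation_fraction = 0.18, seed = 52,
                        algal_radii_um = c(1.5, 0.8))
  expect_equal(sum(ax$truth$f13C_true > na$f13C), round(0.18 * 10))
  expect_true(all(ax$truth$kind == "algal"))
})

test_that("guild fixture has three separated archetypes plus one incomplete strain", {
  g <- synthetic_guild_medians(seed = 9)
  expect_equal(nrow(g), 14)
  expect_equal(sum(is.na(g$algal_C_daily)), 1)
  expect_equal(sort(unique(stats::na.omit(g$archetype))), 1:3)
  # separation >= 5x within-archetype SD on the N-incorporation axis
  centers <- tapply(g$bact_N_daily, g$archetype, mean)
  sds <- tapply(g$bact_N_daily, g$archetype, sd)
  expect_gt(min(dist(centers)), 5 * max(sds))
})
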