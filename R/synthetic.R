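#' Acquisition configuration for the synthetic nanoSIMS generator
#'
#' Describes one simulated analysis area the way the instrument acquires it:
#' a square raster (default 20 um imaged at 256 x 256 pixels), repeated
#' scan cycles (default 24, typical range 19-30), a per-pixel dwell time of
#' 1 ms, and expected secondary-ion yields. Yields are given for the major
#' species only (`12C2` and `12C14N`, counts per pixel per cycle, inside
#' cells and in the background); minor-species yields follow from each
#' cell's isotope composition via the ion-ratio conventions, so the
#' generated images are isotopically consistent by construction.
#'
#' @param raster_um Physical field width in micrometers.
#' @param pixels Image side in pixels (`>= 16`).
#' @param cycles Number of scan cycles (`>= 2`).
#' @param dwell_ms Per-pixel dwell time in milliseconds.
#' @param yield_cell Named numeric: expected major-ion counts/pixel/cycle
#'   inside cells, names `"12C2"` and `"12C14N"`.
#' @param yield_bg Same, for background pixels.
#' @param cycle_shifts Optional `cycles x 2` integer matrix of planted
#'   (drow, dcol) stage-drift offsets per cycle (first cycle usually 0,0);
#'   exercises registration.
#' @param seed Integer seed; the same config + seed renders bit-identical
#'   stacks.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(raster_um = 20, pixels = 256, cycles = 24,
                             dwell_ms = 1,
                             yield_cell = c("12C2" = 45, "12C14N" = 50),
                             yield_bg = c("12C2" = 0.5, "12C14N" = 0.5),
                             cycle_shifts = NULL, seed = 1L) {
  if (pixels < 16) stop("pixels must be >= 16", call. = FALSE)
  if (cycles < 2) stop("cycles must be >= 2", call. = FALSE)
  if (any(yield_cell < 0) || any(yield_bg < 0)) {
    stop("ion yields must be >= 0", call. = FALSE)
  }
  for (nm in c("12C2", "12C14N")) {
    if (!nm %in% names(yield_cell) || !nm %in% names(yield_bg)) {
      stop(sprintf("yields must be named for species '%s'", nm),
           call. = FALSE)
    }
  }
  if (!is.null(cycle_shifts)) {
    cycle_shifts <- matrix(as.integer(cycle_shifts), ncol = 2)
    if (nrow(cycle_shifts) != cycles) {
      stop("cycle_shifts must have one (drow, dcol) row per cycle",
           call. = FALSE)
    }
  }
  structure(
    list(raster_um = raster_um, pixels = as.integer(pixels),
         cycles = as.integer(cycles), dwell_ms = dwell_ms,
         yield_cell = yield_cell, yield_bg = yield_bg,
         cycle_shifts = cycle_shifts, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Draw a population of per-cell final isotope fractions for one strain
#'
#' Cell-to-cell variability in net incorporation is modeled as lognormal on
#' Xnet: \eqn{X = X_{med}\,e^{\sigma Z}} with \eqn{X_{med}} the target
#' median (daily median times incubation days) and \eqn{\sigma} chosen so
#' the population quartile coefficient of dispersion equals `cd_target`.
#' For a lognormal, \eqn{Q_3 = X_{med} e^{\sigma z_{.75}}} and
#' \eqn{Q_1 = X_{med} e^{-\sigma z_{.75}}}, so
#' \eqn{CD = \tanh(\sigma z_{.75})} and \eqn{\sigma =
#' \mathrm{atanh}(CD)/z_{.75}} in closed form. Each cell's Xnet is then
#' inverted through the net-incorporation relation to a final fraction
#' \eqn{f_f = f_i + X\,(f_s - f_i)}.
#'
#' @param median_xnet_daily Target population median daily Xnet, as a
#'   fraction per day (e.g. `0.08` for 8 %/d).
#' @param cd_target Target quartile coefficient of dispersion in `[0, 1)`;
#'   `0` gives identical cells.
#' @param days Incubation length in days; `median_xnet_daily * days` must
#'   be `< 1`.
#' @param substrate A [substrate_spec()].
#' @param n Number of cells.
#' @param seed Integer seed.
#' @param element `"C"` or `"N"`.
#' @param f_i Initial fraction; defaults to natural abundance.
#' @return Numeric vector of `n` final fractions in `(0, 1)`.
#' @examples
#' s <- substrate_spec(f_s_N_labeled = 0.45, dilution_unlabeled = 0)
#' f <- generate_strain_population(0.08, 0.3, 1, s, 1000, seed = 7)
#' median(f)  # ~ 0.0394
#' @export
generate_strain_population <- function(median_xnet_daily, cd_target, days,
                                       substrate, n, seed,
                                       element = c("N", "C"), f_i = NULL) {
  element <- match.arg(element)
  stopifnot(inherits(substrate, "substrate_spec"))
  if (cd_target < 0 || cd_target >= 1) {
    stop("cd_target must lie in [0, 1)", call. = FALSE)
  }
  na <- natural_abundance()
  if (is.null(f_i)) f_i <- if (element == "C") na$f13C else na$f15N
  f_s <- effective_substrate_fraction(substrate, element)
  if (f_s <= f_i) {
    stop("substrate fraction must exceed the initial (natural) fraction",
         call. = FALSE)
  }
  x_med <- median_xnet_daily * days
  if (x_med >= 1) stop("median_xnet_daily * days must be < 1", call. = FALSE)
  sigma <- atanh(cd_target) / stats::qnorm(0.75)
  x <- if (cd_target == 0) rep(x_med, n) else {
    with_seed(seed, x_med * exp(sigma * stats::rnorm(n)))
  }
  f_f <- f_i + x * (f_s - f_i)
  if (any(f_f <= 0) || any(f_f >= 1)) {
    stop("configuration error: inverted final fractions fall outside (0, 1)",
         call. = FALSE)
  }
  f_f
}

# radial extent of an axis-aligned ellipse (rx along cols, ry along rows)
# in direction theta, measured from the center
ellipse_radius <- function(rx, ry, theta) {
  rx * ry / sqrt((ry * cos(theta))^2 + (rx * sin(theta))^2)
}

#' Place synthetic cells in a raster
#'
#' Lays out non-overlapping algal (ellipse) and bacterial (disk) cells with
#' per-cell isotope fractions. A requested fraction of bacteria is placed
#' attached: their boundary is put within 2 px of a host algal boundary
#' (outside it), the rest free-living with at least 3 px clearance from any
#' other cell.
#'
#' @param config A [generator_config()].
#' @param n_bacteria,n_algal Cell counts.
#' @param f13C,f15N Per-kind fraction vectors recycled over cells; defaults
#'   natural abundance. Provide lists with elements `algal`, `bacterial` or
#'   single vectors applied to bacteria (algae then sit at natural
#'   abundance).
#' @param attached_fraction Fraction of bacteria attached to algal hosts
#'   (requires `n_algal >= 1`).
#' @param bact_radius_um Bacterial cell radius (disk), micrometers.
#' @param algal_radii_um Length-2 algal ellipse radii (long, short),
#'   micrometers.
#' @param seed Integer seed for placement.
#' @return A `data.frame` of truth cells: `cell_id`, `kind`, `row`, `col`,
#'   `rx_px`, `ry_px`, `f13C_true`, `f15N_true`, `attached_to`.
#' @export
place_cells <- function(config, n_bacteria, n_algal = 0,
                        f13C = NULL, f15N = NULL,
                        attached_fraction = 0,
                        bact_radius_um = 0.35,
                        algal_radii_um = c(3, 1.2),
                        seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  na <- natural_abundance()
  pick <- function(x, kind, n, default) {
    if (is.null(x)) return(rep(default, n))
    if (is.list(x)) x <- x[[kind]]
    if (is.null(x)) return(rep(default, n))
    rep_len(x, n)
  }
  f13C_b <- pick(f13C, "bacterial", n_bacteria, na$f13C)
  f15N_b <- pick(f15N, "bacterial", n_bacteria, na$f15N)
  f13C_a <- pick(if (is.list(f13C)) f13C else NULL, "algal", n_algal, na$f13C)
  f15N_a <- pick(if (is.list(f15N)) f15N else NULL, "algal", n_algal, na$f15N)
  if (attached_fraction > 0 && n_algal < 1) {
    stop("attached bacteria require at least one algal host", call. = FALSE)
  }

  px_per_um <- config$pixels / config$raster_um
  rb <- bact_radius_um * px_per_um
  ra <- algal_radii_um * px_per_um   # (rx, ry) in px
  side <- config$pixels

  with_seed(seed, {
    cells <- list()
    # conservative circle-overlap test against all placed cells
    ok_clearance <- function(row, col, rad, clearance) {
      for (cl in cells) {
        rmax <- max(cl$rx_px, cl$ry_px)
        d <- sqrt((row - cl$row)^2 + (col - cl$col)^2)
        if (d < rad + rmax + clearance) return(FALSE)
      }
      TRUE
    }
    place_one <- function(rad_max, clearance) {
      for (try in 1:2000) {
        row <- stats::runif(1, rad_max + 2, side - rad_max - 1)
        col <- stats::runif(1, rad_max + 2, side - rad_max - 1)
        if (ok_clearance(row, col, rad_max, clearance)) {
          return(c(row, col))
        }
      }
      stop("could not place cell: raster too crowded", call. = FALSE)
    }
    id <- 0L
    for (i in seq_len(n_algal)) {
      p <- place_one(max(ra), 3)
      id <- id + 1L
      cells[[id]] <- list(cell_id = id, kind = "algal", row = p[1],
                          col = p[2], rx_px = ra[1], ry_px = ra[2],
                          f13C_true = f13C_a[i], f15N_true = f15N_a[i],
                          attached_to = NA_integer_)
    }
    n_att <- round(attached_fraction * n_bacteria)
    hosts <- if (n_algal > 0) sample.int(n_algal, n_att, replace = TRUE)
             else integer(0)
    for (i in seq_len(n_bacteria)) {
      id <- id + 1L
      if (i <= n_att) {
        host <- cells[[hosts[i]]]
        placed <- FALSE
        for (try in 1:500) {
          th <- stats::runif(1, 0, 2 * pi)
          # boundary gap <= 2 px (attached); 1 px nominal gap
          d <- ellipse_radius(host$rx_px, host$ry_px, th) + rb + 1
          row <- host$row + d * sin(th); col <- host$col + d * cos(th)
          if (row < rb + 2 || row > side - rb - 1 ||
              col < rb + 2 || col > side - rb - 1) next
          other <- cells[-host$cell_id]
          ok <- TRUE
          for (cl in other) {
            rmax <- max(cl$rx_px, cl$ry_px)
            if (sqrt((row - cl$row)^2 + (col - cl$col)^2) < rb + rmax + 3) {
              ok <- FALSE; break
            }
          }
          if (ok) { placed <- TRUE; break }
        }
        if (!placed) stop("could not place attached bacterium", call. = FALSE)
        cells[[id]] <- list(cell_id = id, kind = "bacterial", row = row,
                            col = col, rx_px = rb, ry_px = rb,
                            f13C_true = f13C_b[i], f15N_true = f15N_b[i],
                            attached_to = host$cell_id)
      } else {
        p <- place_one(rb, 3)
        cells[[id]] <- list(cell_id = id, kind = "bacterial", row = p[1],
                            col = p[2], rx_px = rb, ry_px = rb,
                            f13C_true = f13C_b[i], f15N_true = f15N_b[i],
                            attached_to = NA_integer_)
      }
    }
    do.call(rbind, lapply(cells, as.data.frame))
  })
}

# rasterize one cell to a logical mask over the full image
cell_mask <- function(cell, side) {
  rows <- matrix(seq_len(side), side, side)
  cols <- matrix(seq_len(side), side, side, byrow = TRUE)
  ((rows - cell$row) / cell$ry_px)^2 + ((cols - cell$col) / cell$rx_px)^2 <= 1
}

# integer-shift a matrix by (drow, dcol), filling vacated pixels with `fill`
shift_matrix <- function(m, drow, dcol, fill = 0) {
  side_r <- nrow(m); side_c <- ncol(m)
  out <- matrix(fill, side_r, side_c)
  src_r <- seq_len(side_r) - drow
  src_c <- seq_len(side_c) - dcol
  ok_r <- src_r >= 1 & src_r <= side_r
  ok_c <- src_c >= 1 & src_c <= side_c
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Render multi-cycle ion-count stacks from placed cells
#'
#' Forward model of the acquisition: per-pixel expected counts are set from
#' the configured major-ion yields (cell interior vs background) and each
#' cell's isotope composition (minor/major mean ratio `2f/(1-f)` for the C2
#' dimer, `f/(1-f)` for the CN monomer; background at natural abundance).
#' Every pixel in every cycle is an independent Poisson draw. Optional
#' planted per-cycle stage drift shifts the expected scene before drawing
#' (drifted-in area is background). Identical config + seed gives
#' bit-identical stacks.
#'
#' @param cells Truth table from [place_cells()].
#' @param config A [generator_config()].
#' @param allow_overlap If `FALSE` (default), overlapping cells are an
#'   error (ambiguous truth).
#' @param noiseless If `TRUE`, emit the per-pixel expected values instead
#'   of Poisson draws (real-valued stacks; exact round-trip of planted
#'   fractions for testing).
#' @return List with `stacks` (named list of `cycles x rows x cols` integer
#'   arrays, one per ion species), `truth` (the input table plus
#'   `area_px`), and `config`.
#' @export
render_ion_stacks <- function(cells, config, allow_overlap = FALSE,
                              noiseless = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  side <- config$pixels
  na <- natural_abundance()
  yc <- config$yield_cell; yb <- config$yield_bg

  mean_img <- list(
    "12C2"   = matrix(yb[["12C2"]], side, side),
    "13C12C" = matrix(yb[["12C2"]] * fraction_to_ratio(na$f13C, "C2_dimer"),
                      side, side),
    "12C14N" = matrix(yb[["12C14N"]], side, side),
    "12C15N" = matrix(yb[["12C14N"]] * fraction_to_ratio(na$f15N, "CN_monomer"),
                      side, side)
  )
  bg_mean <- vapply(mean_img, function(m) m[1, 1], numeric(1))

  claimed <- matrix(FALSE, side, side)
  area_px <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    msk <- cell_mask(cells[i, ], side)
    if (!allow_overlap && any(claimed & msk)) {
      stop("overlapping cells produce ambiguous truth; set allow_overlap",
           call. = FALSE)
    }
    claimed <- claimed | msk
    area_px[i] <- sum(msk)
    fC <- cells$f13C_true[i]; fN <- cells$f15N_true[i]
    mean_img[["12C2"]][msk]   <- yc[["12C2"]]
    mean_img[["13C12C"]][msk] <- yc[["12C2"]] * fraction_to_ratio(fC, "C2_dimer")
    mean_img[["12C14N"]][msk] <- yc[["12C14N"]]
    mean_img[["12C15N"]][msk] <- yc[["12C14N"]] *
      fraction_to_ratio(fN, "CN_monomer")
  }

  stacks <- with_seed(config$seed, {
    out <- list()
    for (sp in ION_SPECIES) {
      arr <- array(if (noiseless) 0 else 0L,
                   dim = c(config$cycles, side, side))
      for (k in seq_len(config$cycles)) {
        mu <- mean_img[[sp]]
        if (!is.null(config$cycle_shifts)) {
          sh <- config$cycle_shifts[k, ]
          if (any(sh != 0L)) mu <- shift_matrix(mu, sh[1], sh[2],
                                                fill = bg_mean[[sp]])
        }
        arr[k, , ] <- if (noiseless) as.vector(mu) else
          stats::rpois(side * side, as.vector(mu))
      }
      out[[sp]] <- arr
    }
    out
  })
  truth <- cells
  truth$area_px <- area_px
  list(stacks = stacks, truth = truth, config = config)
}

#' Simulate a formalin-killed control field
#'
#' All cells at natural abundance; the downstream pipeline should recover a
#' median Xnet indistinguishable from zero on such a field, and its per-cell
#' fractions define the enrichment-call baseline.
#'
#' @inheritParams place_cells
#' @param config A [generator_config()].
#' @return As [render_ion_stacks()].
#' @export
generate_killed_control <- function(config, n_bacteria, n_algal = 0,
                                    attached_fraction = 0,
                                    seed = config$seed) {
  cells <- place_cells(config, n_bacteria, n_algal,
                       attached_fraction = attached_fraction, seed = seed)
  render_ion_stacks(cells, config)
}

#' Simulate an axenic (algae-only) field with an enriched subpopulation
#'
#' Mirrors the observation that in axenic incubations a minority of algal
#' cells (default 18%) shows carbon-13 enrichment while the population as a
#' whole sits at baseline.
#'
#' @param config A [generator_config()].
#' @param n_algal Number of algal cells.
#' @param enriched_subpopulation_fraction Fraction of algal cells carrying
#'   elevated carbon-13.
#' @param enriched_f13C The elevated fraction assigned to that
#'   subpopulation.
#' @param seed Integer placement seed.
#' @param ... Further arguments to [place_cells()] (e.g. cell geometry).
#' @return As [render_ion_stacks()].
#' @export
generate_axenic <- function(config, n_algal,
                            enriched_subpopulation_fraction = 0.18,
                            enriched_f13C = 0.02, seed = config$seed, ...) {
  na <- natural_abundance()
  n_enr <- round(enriched_subpopulation_fraction * n_algal)
  fC <- rep(na$f13C, n_algal)
  if (n_enr > 0) fC[seq_len(n_enr)] <- enriched_f13C
  cells <- place_cells(config, n_bacteria = 0, n_algal = n_algal,
                       f13C = list(algal = fC), seed = seed, ...)
  render_ion_stacks(cells, config)
}

#' Synthetic strain-level guild fixture
#'
#' Strain-summary medians generated from three functional-guild archetypes
#' (high incorporator/remineralizers, macromolecule users remineralizing C
#' only, and small-molecule users with little complex-N use), with
#' within-archetype scatter at least 5x smaller than the between-archetype
#' separation, plus one strain with missing remineralization data (to
#' exercise the drop rule). Units: percent per day.
#'
#' @param seed Integer seed.
#' @param n_per_archetype Strains per archetype (default `c(5, 5, 4)`,
#'   14 strains total; the last listed strain carries the missing data).
#' @return Data frame with `strain`, the four guild features, and a
#'   `archetype` column (ground truth; `NA` for the dropped strain).
#' @export
synthetic_guild_medians <- function(seed = 1L, n_per_archetype = c(5, 5, 4)) {
  # macromolecule remineralizers (high N use, N + C feedback), macromolecule
  # users (highest C use and C feedback, no N feedback), small-molecule
  # users (little complex-substrate use); roughly equidistant after
  # z-standardization so the inertia curve has a single clear elbow
  archetypes <- data.frame(
    bact_C_daily  = c(2.5, 5.4, 1.0),
    bact_N_daily  = c(12.0, 5.0, 0.5),
    algal_C_daily = c(0.20, 0.45, 0.05),
    algal_N_daily = c(0.45, 0.04, 0.02))
  noise_sd <- c(0.15, 0.30, 0.02, 0.004)  # per-feature, >= 5x separation
  with_seed(seed, {
    rows <- list()
    for (g in seq_len(3)) {
      for (j in seq_len(n_per_archetype[g])) {
        v <- as.numeric(archetypes[g, ]) + stats::rnorm(4, 0, noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          strain = sprintf("strain%02d", length(rows) + 1L),
          bact_C_daily = v[1], bact_N_daily = v[2],
          algal_C_daily = v[3], algal_N_daily = v[4],
          archetype = g)
      }
    }
    out <- do.call(rbind, rows)
    # one strain with missing remineralization data (dropped downstream)
    out$algal_C_daily[nrow(out)] <- NA_real_
    out$algal_N_daily[nrow(out)] <- NA_real_
    out$archetype[nrow(out)] <- NA_integer_
    out
  })
}
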