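#' Assemble and validate a pipeline configuration
#'
#' One object drives an end-to-end run: acquisition geometry and yields,
#' substrate labeling, correction and segmentation parameters, the strain
#' models to simulate, the killed control, statistics and clustering
#' settings. All randomness is funneled through `seed`.
#'
#' @param seed Master integer seed.
#' @param generator Named list of [generator_config()] arguments (without
#'   `seed`).
#' @param substrate A [substrate_spec()] or a named list of its arguments.
#' @param strains Data frame (or list of lists) with one row per strain:
#'   `name`, `bact_C_daily`, `bact_N_daily` (median daily Xnet as
#'   fractions/day), `cd_C`, `cd_N`, `algal_C_daily`, `algal_N_daily`
#'   (remineralization medians, `NA` = missing), `cd_algal`, `n_cells`,
#'   `cells_per_ml`, `attached_fraction`.
#' @param killed Named list: `n_bacteria`, `n_algal`.
#' @param tau_ns Detector dead time for [correct_dead_time()].
#' @param register Estimate and correct per-cycle shifts (default `TRUE`).
#' @param max_shift_px Registration search radius in the pipeline.
#' @param segmentation Named list: `min_area_px`, `algal_min_area_px`,
#'   `adjacency_px`, `min_denominator_counts`.
#' @param alpha Significance level for enrichment verdicts.
#' @param k_range Candidate cluster counts for guild assignment.
#' @param cells_per_field,algal_per_field Field packing for the simulator.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            generator = list(),
                            substrate = substrate_spec(),
                            strains,
                            killed = list(n_bacteria = 60, n_algal = 6),
                            tau_ns = 44,
                            register = TRUE,
                            max_shift_px = 2,
                            segmentation = list(),
                            alpha = 0.05,
                            k_range = 1:6,
                            cells_per_field = 25,
                            algal_per_field = 1) {
  if (is.list(substrate) && !inherits(substrate, "substrate_spec")) {
    substrate <- do.call(substrate_spec, substrate)
  }
  if (!is.data.frame(strains)) {
    strains <- do.call(rbind, lapply(strains, function(s)
      as.data.frame(s, stringsAsFactors = FALSE)))
  }
  need <- c("name", "bact_C_daily", "bact_N_daily", "cd_C", "cd_N",
            "n_cells", "cells_per_ml")
  missing_cols <- setdiff(need, names(strains))
  if (length(missing_cols)) {
    stop("strains table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (opt in c("algal_C_daily", "algal_N_daily")) {
    if (!opt %in% names(strains)) strains[[opt]] <- NA_real_
  }
  # YAML 1.1 reads exponents like 2.0e6 as strings; coerce numeric columns
  for (cl in setdiff(names(strains), "name")) {
    strains[[cl]] <- as.numeric(strains[[cl]])
  }
  if (!"cd_algal" %in% names(strains)) strains$cd_algal <- 0.3
  strains$cd_algal[is.na(strains$cd_algal)] <- 0.3
  if (!"attached_fraction" %in% names(strains)) strains$attached_fraction <- 0
  strains$attached_fraction[is.na(strains$attached_fraction)] <- 0
  seg <- utils::modifyList(
    list(min_area_px = 20, algal_min_area_px = 80, adjacency_px = 2,
         min_denominator_counts = 100),
    segmentation)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(
    list(seed = as.integer(seed), generator = generator,
         substrate = substrate, strains = strains, killed = killed,
         tau_ns = tau_ns, register = isTRUE(register),
         max_shift_px = max_shift_px, segmentation = seg, alpha = alpha,
         k_range = k_range, cells_per_field = cells_per_field,
         algal_per_field = algal_per_field),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$strains)) {
    all_cols <- unique(unlist(lapply(cfg$strains, names)))
    cfg$strains <- do.call(rbind, lapply(cfg$strains, function(s) {
      s[vapply(s, is.null, logical(1))] <- NA
      for (m in setdiff(all_cols, names(s))) s[[m]] <- NA
      as.data.frame(s[all_cols], stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(cfg$k_range) && length(cfg$k_range) == 2) {
    cfg$k_range <- seq(cfg$k_range[1], cfg$k_range[2])
  }
  do.call(pipeline_config, cfg)
}

# deterministic per-stream child seeds below 2^31
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 16807) %% 2147483647
}

# draw per-cell final fractions for one strain (both elements + algae)
strain_fraction_draws <- function(strain, cfg, strain_idx) {
  sub <- cfg$substrate
  days <- sub$duration_days
  n <- strain$n_cells
  s0 <- 100 * strain_idx
  fC <- generate_strain_population(strain$bact_C_daily, strain$cd_C, days,
                                   sub, n, derive_seed(cfg$seed, s0 + 11),
                                   element = "C")
  fN <- generate_strain_population(strain$bact_N_daily, strain$cd_N, days,
                                   sub, n, derive_seed(cfg$seed, s0 + 13),
                                   element = "N")
  na <- natural_abundance()
  n_alg <- ceiling(n / cfg$cells_per_field) * cfg$algal_per_field
  aC <- if (is.na(strain$algal_C_daily)) rep(na$f13C, n_alg) else
    generate_strain_population(strain$algal_C_daily, strain$cd_algal, days,
                               sub, n_alg, derive_seed(cfg$seed, s0 + 17),
                               element = "C")
  aN <- if (is.na(strain$algal_N_daily)) rep(na$f15N, n_alg) else
    generate_strain_population(strain$algal_N_daily, strain$cd_algal, days,
                               sub, n_alg, derive_seed(cfg$seed, s0 + 19),
                               element = "N")
  list(bact_C = fC, bact_N = fN, algal_C = aC, algal_N = aN)
}

#' Simulate a full multi-strain nanoSIP experiment
#'
#' Renders one set of analysis areas (fields) per strain co-culture plus
#' killed-control fields, packing `cells_per_field` bacteria and
#' `algal_per_field` algal cells into each 256 x 256 raster. Per-cell
#' isotope fractions come from the lognormal strain models; killed cells
#' sit at natural abundance.
#'
#' @param cfg A [pipeline_config()].
#' @return List with `fields` (each: `strain`, `field`, `sim` from
#'   [render_ion_stacks()]) and `killed_fields` (same shape).
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  make_fields <- function(strain_name, n_bact, n_algal_per, draws,
                          attached_fraction, stream0) {
    n_fields <- ceiling(n_bact / cfg$cells_per_field)
    fields <- vector("list", n_fields)
    taken <- 0L; taken_a <- 0L
    for (j in seq_len(n_fields)) {
      nb <- min(cfg$cells_per_field, n_bact - taken)
      idx <- taken + seq_len(nb)
      aidx <- taken_a + seq_len(n_algal_per)
      gen <- do.call(generator_config, c(
        cfg$generator,
        list(seed = as.integer(derive_seed(cfg$seed, stream0 + j)))))
      cells <- place_cells(
        gen, n_bacteria = nb, n_algal = n_algal_per,
        f13C = list(bacterial = draws$bact_C[idx],
                    algal = draws$algal_C[aidx]),
        f15N = list(bacterial = draws$bact_N[idx],
                    algal = draws$algal_N[aidx]),
        attached_fraction = attached_fraction)
      fields[[j]] <- list(strain = strain_name, field = j,
                          sim = render_ion_stacks(cells, gen))
      taken <- taken + nb; taken_a <- taken_a + n_algal_per
    }
    fields
  }

  fields <- list()
  for (i in seq_len(nrow(cfg$strains))) {
    st <- cfg$strains[i, ]
    draws <- strain_fraction_draws(st, cfg, i)
    fields <- c(fields, make_fields(st$name, st$n_cells,
                                    cfg$algal_per_field, draws,
                                    st$attached_fraction,
                                    stream0 = 1000 * i))
  }
  na <- natural_abundance()
  nk <- cfg$killed$n_bacteria
  nk_fields <- ceiling(nk / cfg$cells_per_field)
  nka_per <- max(1L, ceiling(cfg$killed$n_algal / nk_fields))
  n_alg_total <- nka_per * nk_fields
  killed_draws <- list(
    bact_C = rep(na$f13C, nk), bact_N = rep(na$f15N, nk),
    algal_C = rep(na$f13C, n_alg_total),
    algal_N = rep(na$f15N, n_alg_total))
  killed_fields <- make_fields("killed", nk, nka_per, killed_draws, 0,
                               stream0 = 900000)
  list(fields = fields, killed_fields = killed_fields)
}

#' Correct, align, accumulate and segment one field
#'
#' @param stacks Named list of raw count stacks (all four species).
#' @param cfg A [pipeline_config()].
#' @param killed_stats Optional `c(median, sd)` of killed-control N ratios
#'   enabling ratio-based bacterial detection.
#' @param raster_um Physical field width.
#' @param dwell_ms Dwell time for the dead-time correction.
#' @return List with `rois` (a `cell_roi_set`), `corrected` (aligned
#'   corrected stacks), `summed`, `shifts`.
#' @export
process_field <- function(stacks, cfg, killed_stats = NULL, raster_um = 20,
                          dwell_ms = 1) {
  corrected <- lapply(stacks, correct_dead_time, tau_ns = cfg$tau_ns,
                      dwell_ms = dwell_ms)
  shifts <- NULL
  if (cfg$register) {
    reg <- register_cycles(corrected, max_shift_px = cfg$max_shift_px)
    corrected <- reg$stacks
    shifts <- reg$shifts
  }
  summed <- lapply(corrected, accumulate_cycles)
  seg <- cfg$segmentation
  rois <- segment_field(summed, killed_stats = killed_stats,
                        min_area_px = seg$min_area_px,
                        min_denominator_counts = seg$min_denominator_counts,
                        raster_um = raster_um,
                        algal_min_area_px = seg$algal_min_area_px,
                        adjacency_px = seg$adjacency_px)
  list(rois = rois, corrected = corrected, summed = summed, shifts = shifts)
}

# quantify all fields of one group into a per-cell table
quantify_fields <- function(flds, cfg, killed_stats = NULL,
                            killed_f = NULL) {
  out <- list()
  for (fl in flds) {
    raster_um <- fl$sim$config$raster_um
    pf <- process_field(fl$sim$stacks, cfg, killed_stats,
                        raster_um = raster_um,
                        dwell_ms = fl$sim$config$dwell_ms)
    if (nrow(pf$rois$table) == 0) next
    q <- quantify_cells(pf$corrected, pf$rois, cfg$substrate, killed_f)
    q$strain <- fl$strain
    q$field <- fl$field
    # truth matching for the rejects ledger
    q$truth_cell_id <- NA_integer_
    truth <- fl$sim$truth
    for (t in seq_len(nrow(truth))) {
      same <- which(pf$rois$table$kind == truth$kind[t])
      if (!length(same)) next
      d <- sqrt((pf$rois$table$centroid_row[same] - truth$row[t])^2 +
                  (pf$rois$table$centroid_col[same] - truth$col[t])^2)
      j <- same[which.min(d)]
      tol <- max(3, max(truth$rx_px[t], truth$ry_px[t]))
      if (min(d) <= tol && is.na(q$truth_cell_id[j])) {
        q$truth_cell_id[j] <- truth$cell_id[t]
      }
    }
    out[[length(out) + 1]] <- q
  }
  do.call(rbind, out)
}

# truth cells never matched to an ROI, with a reason
collect_rejects <- function(flds, per_cell) {
  rej <- list()
  for (fl in flds) {
    truth <- fl$sim$truth
    got <- per_cell$truth_cell_id[per_cell$strain == fl$strain &
                                    per_cell$field == fl$field]
    miss <- truth[!truth$cell_id %in% got, , drop = FALSE]
    if (nrow(miss)) {
      rej[[length(rej) + 1]] <- data.frame(
        strain = fl$strain, field = fl$field, cell_id = miss$cell_id,
        kind = miss$kind, reason = "not_segmented")
    }
  }
  if (length(rej)) do.call(rbind, rej) else
    data.frame(strain = character(0), field = integer(0),
               cell_id = integer(0), kind = character(0),
               reason = character(0))
}

safe_cd <- function(x) {
  tryCatch(coefficient_of_dispersion(x), error = function(e) NA_real_)
}

#' Summarize per-cell records into a per-strain table
#'
#' Bacterial ROIs only: n, median / Q1 / Q3 of the daily Xnet rates for C
#' and N (percent per day), the quartile coefficient of dispersion (NA
#' when undefined, e.g. no detectable incorporation), the enriched-cell
#' fractions, and the median projected area. Algal ROIs provide the
#' co-culture remineralization medians.
#'
#' @param per_cell Per-cell table from [quantify_fields()].
#' @return Data frame, one row per strain.
#' @export
summarize_strains <- function(per_cell) {
  bact <- per_cell[per_cell$kind == "bacterial", ]
  alg <- per_cell[per_cell$kind == "algal", ]
  strains <- unique(per_cell$strain)
  rows <- lapply(strains, function(s) {
    b <- bact[bact$strain == s, ]
    a <- alg[alg$strain == s, ]
    qC <- stats::quantile(b$xnet_C_daily, c(0.25, 0.5, 0.75), names = FALSE)
    qN <- stats::quantile(b$xnet_N_daily, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(
      strain = s, n_cells = nrow(b),
      median_xnet_C_daily = qC[2], q1_xnet_C_daily = qC[1],
      q3_xnet_C_daily = qC[3], cd_C = safe_cd(b$xnet_C_daily),
      median_xnet_N_daily = qN[2], q1_xnet_N_daily = qN[1],
      q3_xnet_N_daily = qN[3], cd_N = safe_cd(b$xnet_N_daily),
      frac_enriched_C = mean(b$enriched_C), frac_enriched_N = mean(b$enriched_N),
      median_area_um2 = stats::median(b$area_um2),
      algal_median_xnet_C_daily =
        if (nrow(a)) stats::median(a$xnet_C_daily) else NA_real_,
      algal_median_xnet_N_daily =
        if (nrow(a)) stats::median(a$xnet_N_daily) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Run the complete nanoSIP analysis pipeline
#'
#' simulate -> dead-time correct -> register -> accumulate -> segment ->
#' quantify -> summarize -> test -> flux -> cluster, writing every stage
#' table plus a provenance manifest to `out_dir`. Identical config + seed
#' produce byte-identical tables and manifest hash.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with `per_cell`, `strain_summary`, `stats_C`,
#'   `stats_N`, `fluxes`, `guilds`, `rejects`, `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(cfg)

  # killed controls first: they define baselines for everything else
  killed_cells <- quantify_fields(sim$killed_fields, cfg)
  if (is.null(killed_cells) || !nrow(killed_cells)) {
    stop("pipeline stage 'killed-control quantification': no cells found",
         call. = FALSE)
  }
  kb <- killed_cells[killed_cells$kind == "bacterial", ]
  ka <- killed_cells[killed_cells$kind == "algal", ]
  killed_stats <- c(stats::median(kb$ratio_mean_N), stats::sd(kb$ratio_mean_N))
  killed_f <- list(
    bacterial = list(C = kb$f13C, N = kb$f15N),
    algal = if (nrow(ka) >= 3) list(C = ka$f13C, N = ka$f15N)
            else list(C = kb$f13C, N = kb$f15N)
  )

  per_cell <- quantify_fields(sim$fields, cfg, killed_stats, killed_f)
  if (is.null(per_cell) || !nrow(per_cell)) {
    stop("pipeline stage 'quantification': no cells found", call. = FALSE)
  }
  killed_cells2 <- quantify_fields(sim$killed_fields, cfg, killed_stats,
                                   killed_f)
  rejects <- rbind(collect_rejects(sim$fields, per_cell),
                   collect_rejects(sim$killed_fields, killed_cells2))

  strain_summary <- summarize_strains(per_cell)

  # rank tests vs killed, per element, bacterial cells pooled across fields
  pooled <- rbind(per_cell, killed_cells2)
  pooled <- pooled[pooled$kind == "bacterial", ]
  stats_out <- list()
  for (el in c("C", "N")) {
    v <- pooled[[paste0("xnet_", el, "_daily")]]
    g <- pooled$strain
    kw <- kruskal_wallis(v, g)
    dn <- dunns_test(v, g, control = "killed")
    dn$element <- el
    dn$H <- kw$H
    dn$kw_p <- kw$p
    dn$significant <- dn$p_adj < cfg$alpha
    stats_out[[el]] <- dn
  }

  ss_b <- strain_summary[strain_summary$strain != "killed", ]
  regression <- tryCatch(
    median_regression_summary(ss_b$median_xnet_C_daily,
                              ss_b$median_xnet_N_daily),
    error = function(e) NULL)

  abund <- data.frame(strain = cfg$strains$name,
                      cells_per_ml = cfg$strains$cells_per_ml)
  fx <- strain_fluxes(strain_summary[strain_summary$strain != "killed", ],
                      abund)

  guild_in <- data.frame(
    strain = strain_summary$strain,
    bact_C_daily = strain_summary$median_xnet_C_daily,
    bact_N_daily = strain_summary$median_xnet_N_daily,
    algal_C_daily = strain_summary$algal_median_xnet_C_daily,
    algal_N_daily = strain_summary$algal_median_xnet_N_daily)
  guilds <- tryCatch({
    ft <- build_feature_table(guild_in)
    assign_guilds(ft, k_range = cfg$k_range, seed = cfg$seed)
  }, error = function(e) NULL)

  write_atomic <- function(df, name) {
    path <- file.path(out_dir, name)
    tmp <- tempfile(tmpdir = out_dir, fileext = ".tmp")
    utils::write.csv(df, tmp, row.names = FALSE)
    file.rename(tmp, path)
    path
  }
  files <- c(
    write_atomic(per_cell, "per_cell.csv"),
    write_atomic(killed_cells2, "killed_cells.csv"),
    write_atomic(strain_summary, "strain_summary.csv"),
    write_atomic(stats_out$C, "stats_C.csv"),
    write_atomic(stats_out$N, "stats_N.csv"),
    write_atomic(fx, "fluxes.csv"),
    write_atomic(rejects, "rejects.csv")
  )
  if (!is.null(regression)) {
    files <- c(files, write_atomic(as.data.frame(regression),
                                   "regression.csv"))
  }
  if (!is.null(guilds)) {
    files <- c(files,
      write_atomic(data.frame(strain = names(guilds$labels),
                              guild = unname(guilds$labels)), "guilds.csv"),
      write_atomic(data.frame(k = as.integer(names(guilds$inertia)),
                              inertia = unname(guilds$inertia)),
                   "inertia.csv"))
  }
  hashes <- tools::md5sum(files)
  hash_of_lines <- function(lines) {
    tf <- tempfile()
    writeLines(lines, tf)
    on.exit(unlink(tf))
    unname(tools::md5sum(tf))
  }
  config_hash <- hash_of_lines(deparse(unclass(cfg)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("nanosipr")),
    seed = cfg$seed,
    config_hash = config_hash,
    files = as.list(stats::setNames(unname(hashes), basename(files))),
    manifest_hash = hash_of_lines(c(config_hash, unname(hashes))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(per_cell = per_cell, killed_cells = killed_cells2,
                 strain_summary = strain_summary, stats_C = stats_out$C,
                 stats_N = stats_out$N, regression = regression,
                 fluxes = fx, guilds = guilds,
                 rejects = rejects, manifest = manifest))
}

#' A small bundled example configuration
#'
#' Four strains spanning daily N incorporation medians from 0.5 to 15 %/d
#' with realistic dispersion, a killed control, and a compact field layout
#' sized for examples and tests.
#'
#' @param seed Master seed.
#' @param n_cells_per_strain Bacterial cells per strain.
#' @return A [pipeline_config()].
#' @export
example_pipeline_config <- function(seed = 1L, n_cells_per_strain = 25) {
  strains <- data.frame(
    name = c("strainA", "strainB", "strainC", "strainD"),
    bact_C_daily = c(0.010, 0.030, 0.054, 0.009),
    bact_N_daily = c(0.005, 0.080, 0.160, 0.004),
    cd_C = c(0.25, 0.30, 0.35, 0.20),
    cd_N = c(0.25, 0.30, 0.40, 0.20),
    algal_C_daily = c(0.002, 0.004, 0.005, NA),
    algal_N_daily = c(0.001, 0.003, 0.005, NA),
    cd_algal = 0.3,
    n_cells = n_cells_per_strain,
    cells_per_ml = c(2e6, 4e6, 2e7, 4e5),
    attached_fraction = c(0, 0.1, 0, 0))
  pipeline_config(seed = seed, strains = strains,
                  killed = list(n_bacteria = 25, n_algal = 3),
                  cells_per_field = 25, algal_per_field = 1)
}
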