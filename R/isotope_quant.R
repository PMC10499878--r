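#' Convert measured ion ratios to rare-isotope atom fractions
#'
#' nanoSIMS reports molecular secondary-ion ratios, not atom fractions. For
#' the monomer CN convention the measured ratio is
#' \eqn{r = {}^{12}C^{15}N^- / {}^{12}C^{14}N^- = {}^{15}N/{}^{14}N}, so
#' \eqn{f = r/(1+r)}. For the C2 dimer convention
#' \eqn{r = {}^{13}C^{12}C^- / {}^{12}C_2^- = 2\,{}^{13}C/{}^{12}C}, i.e.
#' \eqn{r = 2f/(1-f)}, so \eqn{f = r/(2+r)}.
#'
#' @param r Non-negative ion ratio(s).
#' @param convention `"CN_monomer"` or `"C2_dimer"`.
#' @return Atom fraction(s) in `[0, 1)`.
#' @seealso [fraction_to_ratio()]
#' @examples
#' ratio_to_fraction(0.003676, "CN_monomer")   # natural-abundance 15N
#' ratio_to_fraction(0.022475, "C2_dimer")     # natural-abundance 13C
#' @export
ratio_to_fraction <- function(r, convention = c("CN_monomer", "C2_dimer")) {
  convention <- match.arg(convention)
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("ion ratios must be finite and non-negative", call. = FALSE)
  }
  switch(convention,
    CN_monomer = r / (1 + r),
    C2_dimer   = r / (2 + r)
  )
}

#' Convert rare-isotope atom fractions to measured ion ratios
#'
#' Inverse of [ratio_to_fraction()]: `CN_monomer` gives \eqn{r = f/(1-f)},
#' `C2_dimer` gives \eqn{r = 2f/(1-f)}.
#'
#' @param f Atom fraction(s) in `[0, 1)`.
#' @inheritParams ratio_to_fraction
#' @return Ion ratio(s) `>= 0`.
#' @export
fraction_to_ratio <- function(f, convention = c("CN_monomer", "C2_dimer")) {
  convention <- match.arg(convention)
  if (any(!is.finite(f)) || any(f < 0) || any(f >= 1)) {
    stop("atom fractions must lie in [0, 1)", call. = FALSE)
  }
  switch(convention,
    CN_monomer = f / (1 - f),
    C2_dimer   = 2 * f / (1 - f)
  )
}

#' Describe the isotope composition of the added substrate
#'
#' Bookkeeping container for the labeling experiment: the measured
#' rare-isotope fractions of the added C and N substrates, the fraction of
#' the total substrate pool that is unlabeled (e.g. organic matter exuded
#' during the incubation itself), and the incubation length. Defaults match
#' an algal-exudate addition measured at 18% \eqn{^{13}C} / 45%
#' \eqn{^{15}N}, further diluted by 50% unlabeled exudate, incubated 24 h.
#'
#' @param f_s_C_labeled,f_s_N_labeled Rare-isotope fraction of the added C /
#'   N substrate, in `[0, 1]`.
#' @param dilution_unlabeled Fraction of the total substrate pool that is
#'   unlabeled (at natural abundance), in `[0, 1]`.
#' @param duration_days Incubation length in days, `> 0`.
#' @return An object of class `substrate_spec`.
#' @examples
#' substrate_spec()  # labeled algal exudate, 50% diluted, 24 h
#' substrate_spec(f_s_C_labeled = 0.99, f_s_N_labeled = 0.98,
#'                dilution_unlabeled = 0, duration_days = 2)  # glycolate/nitrate
#' @export
substrate_spec <- function(f_s_C_labeled = 0.18, f_s_N_labeled = 0.45,
                           dilution_unlabeled = 0.5, duration_days = 1) {
  fr <- c(f_s_C_labeled, f_s_N_labeled, dilution_unlabeled)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
    stop("substrate fractions must lie in [0, 1]", call. = FALSE)
  }
  stop_if_not_scalar_number(duration_days, "duration_days")
  if (duration_days <= 0) stop("duration_days must be > 0", call. = FALSE)
  structure(
    list(f_s_C_labeled = f_s_C_labeled, f_s_N_labeled = f_s_N_labeled,
         dilution_unlabeled = dilution_unlabeled,
         duration_days = duration_days),
    class = "substrate_spec"
  )
}

#' @export
print.substrate_spec <- function(x, ...) {
  cat(sprintf(
    "substrate_spec: %.3f 13C / %.3f 15N labeled, %.0f%% unlabeled dilution, %.3g d\n",
    x$f_s_C_labeled, x$f_s_N_labeled, 100 * x$dilution_unlabeled,
    x$duration_days))
  invisible(x)
}

#' Effective substrate isotope fraction after unlabeled dilution
#'
#' Mixing the labeled substrate with an unlabeled pool at natural abundance
#' gives \eqn{f_s = (1-d)\,f_{labeled} + d\,f_{nat}}, the value entering the
#' net-incorporation calculation.
#'
#' @param spec A [substrate_spec()].
#' @param element `"C"` or `"N"`.
#' @param natural_fraction Natural-abundance fraction of the element;
#'   defaults to the fixed constants.
#' @return Effective substrate fraction `f_s`.
#' @examples
#' effective_substrate_fraction(substrate_spec(), "C")  # 0.0955...
#' @export
effective_substrate_fraction <- function(spec, element = c("C", "N"),
                                         natural_fraction = NULL) {
  element <- match.arg(element)
  stopifnot(inherits(spec, "substrate_spec"))
  if (is.null(natural_fraction)) {
    natural_fraction <- if (element == "C") natural_abundance()$f13C
                        else natural_abundance()$f15N
  }
  f_lab <- if (element == "C") spec$f_s_C_labeled else spec$f_s_N_labeled
  d <- spec$dilution_unlabeled
  (1 - d) * f_lab + d * natural_fraction
}

#' Net isotope incorporation (Xnet)
#'
#' The fraction of a cell's final elemental biomass newly synthesized from
#' the labeled substrate, in percent:
#' \deqn{X_{net}\% = 100\,(f_f - f_i) / (f_s - f_i)}
#' where \eqn{f_i} is the initial (killed-control) fraction, \eqn{f_f} the
#' measured final fraction and \eqn{f_s} the effective substrate fraction.
#' Values slightly below zero arise from counting noise and are reported
#' as-is, not clipped.
#'
#' @param f_f Final measured fraction(s).
#' @param f_i Initial (killed-control) fraction.
#' @param f_s Effective substrate fraction; must differ from `f_i`.
#' @return Xnet in percent (vectorized over `f_f`).
#' @examples
#' compute_xnet(0.039371, 0.003663, 0.45)  # 8
#' @export
compute_xnet <- function(f_f, f_i, f_s) {
  stop_if_not_scalar_number(f_i, "f_i")
  stop_if_not_scalar_number(f_s, "f_s")
  if (abs(f_s - f_i) < 1e-6) {
    stop("substrate indistinguishable from background (|f_s - f_i| < 1e-6)",
         call. = FALSE)
  }
  100 * (f_f - f_i) / (f_s - f_i)
}

#' Daily net incorporation rate
#'
#' Divides total Xnet by the incubation length, under the assumption that
#' single-cell biomass accumulation is linear (not exponential) over the
#' incubation; rates are therefore conservative for growing cells.
#'
#' @param xnet_total Xnet percent over the whole incubation.
#' @param duration_days Incubation length in days, `> 0`.
#' @return Percent per day.
#' @export
daily_rate <- function(xnet_total, duration_days) {
  stop_if_not_scalar_number(duration_days, "duration_days")
  if (duration_days <= 0) stop("duration_days must be > 0", call. = FALSE)
  xnet_total / duration_days
}

#' Call single-cell isotope enrichment against killed controls
#'
#' A cell is enriched when its measured fraction exceeds the killed-control
#' median by more than three killed-control sample standard deviations
#' (strict inequality; a cell exactly at the threshold is not enriched).
#'
#' @param f_cell Measured fraction(s) to call.
#' @param killed_values Killed-control fractions; at least 3 required.
#' @return Logical vector, `TRUE` where enriched.
#' @examples
#' enrichment_call(0.0041, killed_values = c(0.0036, 0.0037, 0.0038))
#' @export
enrichment_call <- function(f_cell, killed_values) {
  if (length(killed_values) < 3L) {
    stop("at least 3 killed-control cells are required", call. = FALSE)
  }
  thr <- stats::median(killed_values) + 3 * stats::sd(killed_values)
  f_cell > thr
}

#' Quartile coefficient of dispersion
#'
#' Robust relative spread \eqn{(Q_3-Q_1)/(Q_3+Q_1)}, with quartiles by
#' linear interpolation between order statistics (R's default type-7
#' convention). Scale-invariant: multiplying all values by `c > 0` leaves
#' the CD unchanged.
#'
#' @param values Numeric vector, `n >= 4`, with `Q1 + Q3 > 0`.
#' @return CD as a fraction in `[0, 1)` for positive data.
#' @examples
#' coefficient_of_dispersion(1:5)  # (4-2)/(4+2) = 1/3
#' @export
coefficient_of_dispersion <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) {
    stop("coefficient of dispersion needs at least 4 values", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  if (sum(q) <= 0) {
    stop("CD undefined for non-positive scale (Q1 + Q3 <= 0)", call. = FALSE)
  }
  unname(diff(q) / sum(q))
}

#' Per-cycle ROI ion ratios with mean and SEM
#'
#' For one ROI and one element, sums the minor and major ion counts over the
#' ROI pixels separately in every cycle, forms the per-cycle ratio, and
#' summarizes as the arithmetic mean and the standard error of the mean
#' (sample SD over cycles / sqrt(number of usable cycles)). Cycles whose
#' ROI-summed major counts are zero carry no ratio information and are
#' dropped (the count of dropped cycles is reported).
#'
#' @param stacks Named list of ion stacks (`cycles x rows x cols` arrays)
#'   containing at least the element's minor and major species; see
#'   [ELEMENT_SPECIES] naming (`"12C2"`, `"13C12C"`, `"12C14N"`, `"12C15N"`).
#' @param pixels Two-column integer matrix of (row, col) ROI pixels.
#' @param element `"C"` or `"N"`.
#' @return List with `ratios` (per usable cycle), `mean`, `sem`,
#'   `n_cycles_used`, `n_cycles_dropped`.
#' @export
roi_cycle_ratios <- function(stacks, pixels, element = c("C", "N")) {
  element <- match.arg(element)
  sp <- ELEMENT_SPECIES[[element]]
  minor <- stacks[[sp[["minor"]]]]
  major <- stacks[[sp[["major"]]]]
  if (is.null(minor) || is.null(major)) {
    stop(sprintf("stacks must contain species %s and %s",
                 sp[["minor"]], sp[["major"]]), call. = FALSE)
  }
  pixels <- as.matrix(pixels)
  n_cyc <- dim(major)[1]
  dims <- dim(major)[2:3]
  if (any(pixels[, 1] < 1 | pixels[, 1] > dims[1] |
          pixels[, 2] < 1 | pixels[, 2] > dims[2])) {
    stop("ROI pixels fall outside the image", call. = FALSE)
  }
  # linear indices of (cycle k, row r, col c) for all cycles at once
  n_rows <- dims[1]
  base <- (pixels[, 2] - 1) * n_cyc * n_rows + (pixels[, 1] - 1) * n_cyc
  lin <- outer(seq_len(n_cyc), base, "+")   # cycles x pixels
  minor_sum <- rowSums(matrix(minor[lin], nrow = n_cyc))
  major_sum <- rowSums(matrix(major[lin], nrow = n_cyc))
  usable <- major_sum > 0
  if (!any(usable)) stop("no usable cycles (all major counts zero)",
                         call. = FALSE)
  ratios <- minor_sum[usable] / major_sum[usable]
  n_used <- sum(usable)
  sem <- if (n_used >= 2L) stats::sd(ratios) / sqrt(n_used) else NA_real_
  list(
    ratios = ratios,
    mean = mean(ratios),
    sem = sem,
    n_cycles_used = n_used,
    n_cycles_dropped = n_cyc - n_used
  )
}

#' Quantify per-cell isotope records for a segmented field
#'
#' Runs [roi_cycle_ratios()] for every ROI and both elements, converts the
#' mean-of-cycle-ratios to atom fractions under the correct ion convention,
#' computes Xnet against killed-control baselines, daily rates, and 3-SD
#' enrichment calls.
#'
#' @param stacks Named list of aligned, corrected ion stacks (all four
#'   species).
#' @param rois ROI set from [classify_and_flag()] (a `cell_roi_set`).
#' @param substrate A [substrate_spec()].
#' @param killed_f Killed-control per-cell fractions supplying both the
#'   initial fraction `f_i` (their median) and the enrichment-call
#'   baseline. Either a list with numeric vectors `C` and `N` (pooled
#'   controls applied to every ROI) or a list with elements `bacterial`
#'   and/or `algal`, each such a list, to baseline each ROI against killed
#'   cells of its own kind. If `NULL`, natural abundance is used for `f_i`
#'   and no enrichment call is made.
#' @return A data frame, one row per ROI: ratio means/SEMs, fractions,
#'   `xnet_C_total`, `xnet_N_total` (percent), `xnet_C_daily`,
#'   `xnet_N_daily` (percent per day), `enriched_C`, `enriched_N`.
#' @export
quantify_cells <- function(stacks, rois, substrate, killed_f = NULL) {
  stopifnot(inherits(substrate, "substrate_spec"))
  na <- natural_abundance()
  by_kind <- !is.null(killed_f) &&
    any(c("bacterial", "algal") %in% names(killed_f))
  baseline_for <- function(kind) {
    if (is.null(killed_f)) return(NULL)
    if (by_kind) killed_f[[kind]] else killed_f
  }
  f_s <- list(
    C = effective_substrate_fraction(substrate, "C"),
    N = effective_substrate_fraction(substrate, "N")
  )
  conv <- c(C = "C2_dimer", N = "CN_monomer")
  tab <- rois$table
  out <- tab[, c("roi_id", "kind", "attached", "area_px", "area_um2")]
  for (el in c("C", "N")) {
    rm_ <- sem_ <- f_ <- xt_ <- xd_ <- rep(NA_real_, nrow(tab))
    dropped_ <- rep(NA_integer_, nrow(tab))
    enr_ <- rep(NA, nrow(tab))
    for (i in seq_len(nrow(tab))) {
      px <- roi_pixels(rois, tab$roi_id[i])
      cyc <- roi_cycle_ratios(stacks, px, el)
      rm_[i] <- cyc$mean
      sem_[i] <- cyc$sem
      dropped_[i] <- cyc$n_cycles_dropped
      f_[i] <- ratio_to_fraction(cyc$mean, conv[[el]])
      base <- baseline_for(tab$kind[i])
      f_i <- if (is.null(base)) {
        if (el == "C") na$f13C else na$f15N
      } else stats::median(base[[el]])
      xt_[i] <- compute_xnet(f_[i], f_i, f_s[[el]])
      xd_[i] <- daily_rate(xt_[i], substrate$duration_days)
      if (!is.null(base)) enr_[i] <- enrichment_call(f_[i], base[[el]])
    }
    out[[paste0("ratio_mean_", el)]] <- rm_
    out[[paste0("ratio_sem_", el)]] <- sem_
    out[[paste0("cycles_dropped_", el)]] <- dropped_
    out[[paste0("f", if (el == "C") "13C" else "15N")]] <- f_
    out[[paste0("xnet_", el, "_total")]] <- xt_
    out[[paste0("xnet_", el, "_daily")]] <- xd_
    out[[paste0("enriched_", el)]] <- enr_
  }
  out
}
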