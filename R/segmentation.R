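#' Otsu threshold of an image
#'
#' Classic histogram threshold maximizing between-class variance, computed
#' on a 256-bin histogram spanning the image range. Returns the threshold
#' value; pixels strictly above it are foreground.
#'
#' @param img Numeric matrix.
#' @param n_bins Histogram resolution.
#' @return Threshold value, or `NA` for a constant image.
#' @export
otsu_threshold <- function(img, n_bins = 256) {
  v <- as.vector(img)
  rng <- range(v)
  if (diff(rng) == 0) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b2)]
}

#' Label 8-connected components of a binary mask
#'
#' Iterative vectorized minimum-label propagation over the 8-neighborhood
#' until a fixed point, then compact relabeling `1..n` (background 0) and
#' removal of components smaller than `min_area_px`.
#'
#' @param mask Logical matrix.
#' @param min_area_px Minimum surviving component area, in pixels.
#' @return Integer label matrix.
#' @export
label_components <- function(mask, min_area_px = 1) {
  side_r <- nrow(mask); side_c <- ncol(mask)
  lab <- matrix(0L, side_r, side_c)
  lab[mask] <- seq_len(sum(mask))
  if (sum(mask) == 0) return(lab)
  big <- sum(mask) + 1L
  work <- matrix(big, side_r, side_c)
  work[mask] <- lab[mask]
  offsets <- expand.grid(dr = -1:1, dc = -1:1)
  offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0), ]
  repeat {
    new <- work
    for (j in seq_len(nrow(offsets))) {
      shifted <- shift_matrix(work, offsets$dr[j], offsets$dc[j], fill = big)
      new <- pmin(new, shifted)
    }
    new[!mask] <- big
    if (identical(new, work)) break
    work <- new
  }
  lab <- matrix(0L, side_r, side_c)
  lab[mask] <- work[mask]
  # compact labels, apply size filter
  tab <- table(lab[mask])
  keep <- as.integer(names(tab))[tab >= min_area_px]
  out <- matrix(0L, side_r, side_c)
  if (length(keep)) {
    remap <- integer(max(keep))
    remap[sort(keep)] <- seq_along(keep)
    sel <- lab > 0 & lab %in% keep
    out[sel] <- remap[lab[sel]]
  }
  out
}

#' Segment cells from an accumulated CN image
#'
#' Foreground by Otsu threshold on the summed \eqn{^{12}C^{14}N^-} image
#' (the structural channel: all biomass is CN-bright), 8-connected
#' components, size filter. Used for algal cells and for bacteria of
#' strains whose enrichment is too weak for ratio-based detection. A
#' constant image yields zero ROIs with a warning.
#'
#' @param cn_image Summed CN image (`rows x cols`).
#' @param min_area_px Minimum component area.
#' @return Integer label matrix.
#' @export
segment_cn <- function(cn_image, min_area_px = 20) {
  thr <- otsu_threshold(cn_image)
  if (is.na(thr)) {
    warning("constant image: no cells segmented")
    return(matrix(0L, nrow(cn_image), ncol(cn_image)))
  }
  label_components(cn_image > thr, min_area_px)
}

#' Segment enriched bacteria from an isotope ratio image
#'
#' Foreground is every valid ratio pixel exceeding the killed-control
#' median by more than 3 killed-control standard deviations (the same
#' criterion as the per-cell enrichment call, applied pixel-wise), followed
#' by 8-connected components and the size filter.
#'
#' @param rimg A [ratio_image()].
#' @param killed_stats Numeric `c(median, sd)` of killed-control pixel (or
#'   cell) ratios; `sd` must be `>= 0`.
#' @param min_area_px Minimum component area.
#' @return Integer label matrix.
#' @export
segment_bacteria_by_ratio <- function(rimg, killed_stats, min_area_px = 20) {
  stopifnot(inherits(rimg, "ratio_image"))
  if (killed_stats[2] < 0) stop("killed-control sd must be >= 0",
                                call. = FALSE)
  fg <- rimg$valid_mask & !is.na(rimg$values) &
    rimg$values > killed_stats[1] + 3 * killed_stats[2]
  label_components(fg, min_area_px)
}

# Chebyshev (square) dilation of a mask by `r` pixels
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  out <- mask
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_matrix(mask, dr, dc, fill = FALSE)
  }
  out
}

#' Classify ROIs as algal or bacterial and flag attachment
#'
#' Area gate: components with `area >= algal_min_area_px` are algal
#' (inclusive), smaller ones bacterial. A bacterial ROI is flagged attached
#' when any of its pixels lies within `adjacency_px` (Chebyshev distance)
#' of an algal ROI pixel; algal ROIs are never flagged. Following the
#' practice of excluding attached bacteria from hand-drawn algal outlines,
#' bacterial pixels dilated by 1 px are subtracted from algal ROIs.
#'
#' @param labels Integer label matrix (e.g. from [segment_cn()], or the
#'   union of CN-based algal and ratio-based bacterial maps built by
#'   [segment_field()]).
#' @param raster_um,pixels Field geometry, for `area_um2`.
#' @param algal_min_area_px Inclusive algal area gate (default 80 px at the
#'   20 um / 256 px scale).
#' @param adjacency_px Attachment distance (default 2 px); `>= 0`.
#' @return An object of class `cell_roi_set`: list with `table` (data
#'   frame: `roi_id`, `kind`, `attached`, `area_px`, `area_um2`,
#'   `centroid_row`, `centroid_col`) and `labels` (the possibly edited
#'   label matrix).
#' @export
classify_and_flag <- function(labels, raster_um = 20, pixels = nrow(labels),
                              algal_min_area_px = 80, adjacency_px = 2) {
  if (adjacency_px < 0) stop("adjacency_px must be >= 0", call. = FALSE)
  ids <- sort(unique(labels[labels > 0]))
  um2_per_px <- (raster_um / pixels)^2
  if (length(ids) == 0) {
    return(structure(list(
      table = data.frame(roi_id = integer(0), kind = character(0),
                         attached = logical(0), area_px = integer(0),
                         area_um2 = numeric(0), centroid_row = numeric(0),
                         centroid_col = numeric(0)),
      labels = labels), class = "cell_roi_set"))
  }
  areas <- tabulate(labels[labels > 0], max(ids))[ids]
  kind <- ifelse(areas >= algal_min_area_px, "algal", "bacterial")

  algal_ids <- ids[kind == "algal"]
  bact_ids <- ids[kind == "bacterial"]
  algal_mask <- matrix(labels %in% algal_ids, nrow(labels))
  bact_mask <- matrix(labels %in% bact_ids, nrow(labels))

  # keep attached bacteria out of algal ROIs: subtract dilated bacterial px
  if (any(bact_mask) && any(algal_mask)) {
    overlap <- dilate_mask(bact_mask, 1) & algal_mask
    labels[overlap] <- 0L
    algal_mask <- algal_mask & !overlap
  }

  attached <- rep(FALSE, length(ids))
  if (any(algal_mask) && length(bact_ids)) {
    near_algal <- dilate_mask(algal_mask, adjacency_px)
    for (i in which(kind == "bacterial")) {
      attached[i] <- any(near_algal[labels == ids[i]])
    }
  }

  rows <- row(labels); cols <- col(labels)
  area_px <- cr <- cc <- numeric(length(ids))
  for (i in seq_along(ids)) {
    sel <- labels == ids[i]
    area_px[i] <- sum(sel)
    cr[i] <- mean(rows[sel]); cc[i] <- mean(cols[sel])
  }
  structure(list(
    table = data.frame(
      roi_id = ids, kind = kind, attached = attached,
      area_px = as.integer(area_px), area_um2 = area_px * um2_per_px,
      centroid_row = cr, centroid_col = cc
    ),
    labels = labels
  ), class = "cell_roi_set")
}

#' @export
print.cell_roi_set <- function(x, ...) {
  cat(sprintf("cell_roi_set: %d ROIs (%d algal, %d bacterial, %d attached)\n",
              nrow(x$table), sum(x$table$kind == "algal"),
              sum(x$table$kind == "bacterial"), sum(x$table$attached)))
  invisible(x)
}

#' Pixels of one ROI
#'
#' @param rois A `cell_roi_set`.
#' @param roi_id Label of the ROI.
#' @return Two-column integer matrix of (row, col) pixels.
#' @export
roi_pixels <- function(rois, roi_id) {
  which(rois$labels == roi_id, arr.ind = TRUE)
}

#' Segment one field with the dual strategy
#'
#' Mirrors the two-channel ROI strategy: algal cells (and, for
#' non-enriched strains, bacteria) from the accumulated CN image; bacteria
#' of enriched strains from the \eqn{^{15}N/^{14}N} ratio image against
#' killed-control statistics. When `killed_stats` is supplied, ratio-based
#' bacterial components overwrite overlapping CN-based small components so
#' each cell is counted once.
#'
#' @param summed Named list of accumulated images (needs `"12C14N"`, and
#'   `"12C15N"` when `killed_stats` is given).
#' @param killed_stats Optional `c(median, sd)` of killed-control N
#'   ratios for ratio-based bacterial detection; `NULL` for CN-only.
#' @param min_area_px Minimum component area.
#' @param min_denominator_counts Validity threshold for the ratio image.
#' @inheritParams classify_and_flag
#' @return A `cell_roi_set`.
#' @export
segment_field <- function(summed, killed_stats = NULL, min_area_px = 20,
                          min_denominator_counts = 100, raster_um = 20,
                          algal_min_area_px = 80, adjacency_px = 2) {
  labels <- segment_cn(summed[["12C14N"]], min_area_px)
  if (!is.null(killed_stats)) {
    rimg <- ratio_image(summed[["12C15N"]], summed[["12C14N"]],
                        min_denominator_counts)
    rlab <- segment_bacteria_by_ratio(rimg, killed_stats, min_area_px)
    # The CN (biomass) channel defines cell footprints; the ratio channel
    # only contributes cells the CN threshold missed. Ratio components
    # overlapping an existing CN component are discarded so weakly
    # enriched cells keep their full CN footprint (using the noise-
    # selected bright-pixel subset would bias their ratios upward).
    if (any(rlab > 0)) {
      overlap_ids <- unique(rlab[rlab > 0 & labels > 0])
      new_mask <- rlab > 0 & !rlab %in% overlap_ids
      if (any(new_mask)) {
        labels[new_mask] <- rlab[new_mask] + max(labels)
        labels <- label_components(labels > 0, min_area_px)
      }
    }
  }
  classify_and_flag(labels, raster_um = raster_um,
                    pixels = nrow(labels),
                    algal_min_area_px = algal_min_area_px,
                    adjacency_px = adjacency_px)
}
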