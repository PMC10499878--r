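#' Electron-multiplier dead-time correction
#'
#' After each registered ion the detector is blind for `tau_ns`
#' nanoseconds, so observed count rates under-report true rates. With
#' observed rate \eqn{m} (counts per second of dwell), the corrected rate
#' is \eqn{n = m/(1 - m\tau)}; counts are rescaled by the same factor. The
#' correction is the identity at \eqn{\tau = 0}, always `>=` the input, and
#' monotone increasing in the observed rate. Pixels at or beyond saturation
#' (\eqn{m\tau \ge 1}) are a hard error.
#'
#' @param stack A `cycles x rows x cols` count array (one ion species).
#' @param tau_ns Detector dead time in nanoseconds (default 44, a typical
#'   electron-multiplier value; configurable).
#' @param dwell_ms Per-pixel dwell time in milliseconds.
#' @return Real-valued corrected stack, same shape.
#' @examples
#' correct_dead_time(array(100, c(1, 1, 1)), tau_ns = 44, dwell_ms = 1)
#' # 100 / (1 - 1e5 * 44e-9) = 100.4419...
#' @export
correct_dead_time <- function(stack, tau_ns = 44, dwell_ms = 1) {
  stop_if_not_scalar_number(tau_ns, "tau_ns")
  if (tau_ns < 0) stop("tau_ns must be >= 0", call. = FALSE)
  if (tau_ns == 0) return(stack)
  # m * tau = counts/dwell_s * tau_s
  mtau <- stack * (tau_ns * 1e-9) / (dwell_ms * 1e-3)
  if (any(mtau >= 1)) {
    bad <- max(stack[mtau >= 1])
    stop(sprintf(
      "dead-time saturation: pixel count %g gives m*tau >= 1 at tau = %g ns",
      bad, tau_ns), call. = FALSE)
  }
  stack / (1 - mtau)
}

# normalized cross-correlation of the overlapping region of `ref` and
# `img` shifted by (drow, dcol); -Inf when either side is constant
ncc_at_shift <- function(ref, img, drow, dcol) {
  nr <- nrow(ref); nc <- ncol(ref)
  r1 <- max(1, 1 + drow); r2 <- min(nr, nr + drow)
  c1 <- max(1, 1 + dcol); c2 <- min(nc, nc + dcol)
  if (r1 > r2 || c1 > c2) return(-Inf)
  a <- ref[r1:r2, c1:c2]
  b <- img[(r1:r2) - drow, (c1:c2) - dcol]
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) return(-Inf)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Estimate and apply per-cycle integer image shifts
#'
#' Stage drift between scan cycles is estimated on one reference species by
#' maximizing the normalized cross-correlation of each cycle against cycle
#' 1 over all integer shifts within `+/-max_shift_px`, with ties broken
#' toward the zero shift (flat, featureless cycles therefore get shift
#' (0, 0)). The same correction is applied to all species; pixels shifted
#' out of the field are zero-filled, and a per-pixel cycle-coverage count
#' is attached so downstream code can flag border loss.
#'
#' @param stacks Named list of `cycles x rows x cols` arrays, all sharing
#'   one geometry.
#' @param reference_species Species used for estimation (default
#'   `"12C14N"`, the structural image).
#' @param max_shift_px Search radius; must be `< image side / 2`.
#' @return List with `shifts` (`cycles x 2` integer matrix of applied
#'   (drow, dcol) corrections; cycle 1 is (0, 0)) and `stacks` (aligned),
#'   the latter carrying a `coverage` attribute (matrix of cycle counts).
#' @export
register_cycles <- function(stacks, reference_species = "12C14N",
                            max_shift_px = 5) {
  ref_stack <- stacks[[reference_species]]
  if (is.null(ref_stack)) {
    stop(sprintf("reference species '%s' not present", reference_species),
         call. = FALSE)
  }
  n_cyc <- dim(ref_stack)[1]
  side <- dim(ref_stack)[2]
  if (n_cyc < 2) stop("registration needs at least 2 cycles", call. = FALSE)
  if (max_shift_px >= side / 2) {
    stop("max_shift_px must be smaller than half the image side",
         call. = FALSE)
  }
  ref <- ref_stack[1, , ]
  grid <- expand.grid(drow = -max_shift_px:max_shift_px,
                      dcol = -max_shift_px:max_shift_px)
  # tie-break toward zero: stable order by Chebyshev then L1 distance
  grid <- grid[order(pmax(abs(grid$drow), abs(grid$dcol)),
                     abs(grid$drow) + abs(grid$dcol)), ]
  shifts <- matrix(0L, n_cyc, 2)
  for (k in 2:n_cyc) {
    img <- ref_stack[k, , ]
    best <- -Inf; best_sh <- c(0L, 0L)
    for (j in seq_len(nrow(grid))) {
      s <- ncc_at_shift(ref, img, grid$drow[j], grid$dcol[j])
      if (s > best + 1e-12) {  # strict improvement keeps zero-ward ties
        best <- s; best_sh <- c(grid$drow[j], grid$dcol[j])
      }
    }
    shifts[k, ] <- as.integer(best_sh)
  }
  aligned <- apply_cycle_shifts(stacks, shifts)
  list(shifts = shifts, stacks = aligned)
}

#' Apply known per-cycle shifts to all species stacks
#'
#' @param stacks Named list of `cycles x rows x cols` arrays.
#' @param shifts `cycles x 2` integer matrix of (drow, dcol) corrections.
#' @return Aligned stacks with a `coverage` attribute (per-pixel count of
#'   cycles that actually observed the pixel after shifting).
#' @export
apply_cycle_shifts <- function(stacks, shifts) {
  n_cyc <- nrow(shifts)
  side_r <- dim(stacks[[1]])[2]; side_c <- dim(stacks[[1]])[3]
  coverage <- matrix(0L, side_r, side_c)
  for (k in seq_len(n_cyc)) {
    cov_k <- shift_matrix(matrix(1L, side_r, side_c),
                          shifts[k, 1], shifts[k, 2], fill = 0L)
    coverage <- coverage + cov_k
  }
  out <- lapply(stacks, function(arr) {
    for (k in seq_len(n_cyc)) {
      if (any(shifts[k, ] != 0L)) {
        arr[k, , ] <- shift_matrix(arr[k, , ], shifts[k, 1], shifts[k, 2],
                                   fill = 0)
      }
    }
    arr
  })
  attr(out, "coverage") <- coverage
  out
}

#' Accumulate a stack over cycles
#'
#' Per-pixel sum over all cycles of an (aligned) stack. For zero-shift
#' stacks total counts are conserved exactly; shifted-out border pixels
#' were zero-filled upstream and are identifiable via the `coverage`
#' attribute of [apply_cycle_shifts()].
#'
#' @param stack A `cycles x rows x cols` array.
#' @return A `rows x cols` summed image.
#' @export
accumulate_cycles <- function(stack) {
  colSums(stack)  # sums over the cycle (first) dimension
}

#' Ratio image from accumulated ion images
#'
#' Pixel-wise `numerator / denominator` wherever the accumulated
#' denominator reaches `min_denominator_counts`; other pixels are marked
#' invalid (NA values, `FALSE` in the validity mask).
#'
#' @param numerator,denominator Summed images of equal shape.
#' @param min_denominator_counts Positive counts threshold.
#' @return An object of class `ratio_image`: list with `values`,
#'   `valid_mask`, `min_denominator_counts`.
#' @export
ratio_image <- function(numerator, denominator, min_denominator_counts = 100) {
  if (!all(dim(numerator) == dim(denominator))) {
    stop("numerator and denominator must share shape", call. = FALSE)
  }
  if (min_denominator_counts <= 0) {
    stop("min_denominator_counts must be > 0", call. = FALSE)
  }
  valid <- denominator >= min_denominator_counts
  vals <- matrix(NA_real_, nrow(numerator), ncol(numerator))
  vals[valid] <- numerator[valid] / denominator[valid]
  structure(
    list(values = vals, valid_mask = valid,
         min_denominator_counts = min_denominator_counts),
    class = "ratio_image"
  )
}
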