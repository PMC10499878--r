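#' Projected area to biovolume
#'
#' Converts a cell's projected (image) area to volume. `sphere`: diameter
#' \eqn{d = 2\sqrt{A/\pi}}, \eqn{V = \pi d^3/6}. `rod`: cylinder of width
#' `w` with hemispherical caps at total-length-to-width `aspect_ratio`,
#' matched to the projected area \eqn{A = w^2(ar - 1) + \pi w^2/4}; an
#' aspect ratio of 1 degenerates exactly to the sphere.
#'
#' @param area_um2 Projected area in square micrometers (`> 0`).
#' @param shape `"sphere"` or `"rod"`.
#' @param aspect_ratio Rod length/width (`>= 1`); ignored for spheres.
#' @return Biovolume in cubic micrometers.
#' @examples
#' area_to_biovolume(pi, "sphere")  # d = 2 um -> 4.18879 um^3
#' @export
area_to_biovolume <- function(area_um2, shape = c("sphere", "rod"),
                              aspect_ratio = 2) {
  shape <- match.arg(shape)
  if (any(area_um2 <= 0)) stop("area must be > 0", call. = FALSE)
  if (shape == "sphere") {
    d <- 2 * sqrt(area_um2 / pi)
    return(pi / 6 * d^3)
  }
  if (aspect_ratio < 1) stop("aspect_ratio must be >= 1", call. = FALSE)
  w <- sqrt(area_um2 / (aspect_ratio - 1 + pi / 4))
  l <- aspect_ratio * w
  pi * w^2 / 4 * (l - w) + pi * w^3 / 6
}

#' Allometric biovolume to cellular C and N content
#'
#' Power-law carbon content \eqn{C = a V^b} (femtograms), nitrogen by a
#' fixed C:N mass ratio. Defaults `a = 120` fg um^-3b, `b = 0.72`,
#' `cn_ratio = 4` are common bacterioplankton values; all three are
#' configuration-exposed because the size-to-content literature varies.
#'
#' @param volume_um3 Biovolume(s), `>= 0`.
#' @param a Scale factor, fg per um^3b (`> 0`).
#' @param b Allometric exponent.
#' @param cn_ratio C:N mass ratio (`> 0`).
#' @return List with `C_fg` and `N_fg`.
#' @export
biovolume_to_content <- function(volume_um3, a = 120, b = 0.72,
                                 cn_ratio = 4) {
  if (any(volume_um3 < 0)) stop("volume must be >= 0", call. = FALSE)
  if (a <= 0) stop("a must be > 0", call. = FALSE)
  if (cn_ratio <= 0) stop("cn_ratio must be > 0", call. = FALSE)
  C <- a * volume_um3^b
  list(C_fg = C, N_fg = C / cn_ratio)
}

#' Population-level volumetric element flux
#'
#' Standing stock times specific rate:
#' \deqn{flux = (cells\,mL^{-1} \cdot 10^3)\;(content_{fg} \cdot 10^{-9})\;
#'   (X_{net,daily}/100)}
#' in micrograms of element per liter per day. Negative daily rates (noise
#' below baseline) are floored at zero: a negative flux is meaningless.
#'
#' @param cells_per_ml Cell abundance (`>= 0`).
#' @param content_fg Per-cell element content in femtograms (`>= 0`).
#' @param xnet_daily Median daily Xnet in percent per day.
#' @return Flux in ug element L^-1 d^-1.
#' @examples
#' population_flux(1e6, 100, 5)  # 5 ug L^-1 d^-1
#' @export
population_flux <- function(cells_per_ml, content_fg, xnet_daily) {
  if (any(cells_per_ml < 0) || any(content_fg < 0)) {
    stop("abundance and content must be >= 0", call. = FALSE)
  }
  xnet_daily <- pmax(xnet_daily, 0)
  (cells_per_ml * 1e3) * (content_fg * 1e-9) * (xnet_daily / 100)
}

#' Cell density from microscopy field-of-view counts
#'
#' \deqn{density = \bar n_{FOV} \cdot (A_{filter}/A_{FOV}) / V_{mL}
#'   \cdot dilution}
#'
#' @param mean_per_fov Mean cells counted per field of view.
#' @param filter_area Total filter area (any unit shared with `fov_area`).
#' @param fov_area Field-of-view area (`> 0`).
#' @param volume_ml Volume filtered in mL (`> 0`).
#' @param dilution_factor Dilution applied before filtering.
#' @return Cells per mL.
#' @examples
#' microscopy_cell_density(50, 1.98e8, 1e4, 1, 10)  # 9.9e6
#' @export
microscopy_cell_density <- function(mean_per_fov, filter_area, fov_area,
                                    volume_ml, dilution_factor = 1) {
  if (fov_area <= 0) stop("fov_area must be > 0", call. = FALSE)
  if (volume_ml <= 0) stop("volume must be > 0", call. = FALSE)
  mean_per_fov * (filter_area / fov_area) / volume_ml * dilution_factor
}

#' Per-strain volumetric fluxes from per-cell records and abundances
#'
#' For each strain: per-cell C and N content from the median bacterial ROI
#' area (projected area -> biovolume -> allometric content), combined with
#' the strain's median daily Xnet and its abundance into volumetric C and N
#' fluxes.
#'
#' @param strain_summary Data frame with columns `strain`,
#'   `median_xnet_C_daily`, `median_xnet_N_daily`, `median_area_um2`.
#' @param abundances Data frame with columns `strain`, `cells_per_ml`.
#' @param shape,aspect_ratio Passed to [area_to_biovolume()].
#' @param a,b,cn_ratio Passed to [biovolume_to_content()].
#' @return Data frame: strain, content, and `flux_C_ug_per_l_per_day`,
#'   `flux_N_ug_per_l_per_day`.
#' @export
strain_fluxes <- function(strain_summary, abundances, shape = "sphere",
                          aspect_ratio = 2, a = 120, b = 0.72,
                          cn_ratio = 4) {
  df <- merge(strain_summary, abundances, by = "strain")
  vol <- area_to_biovolume(df$median_area_um2, shape, aspect_ratio)
  cont <- biovolume_to_content(vol, a, b, cn_ratio)
  df$content_C_fg <- cont$C_fg
  df$content_N_fg <- cont$N_fg
  df$flux_C_ug_per_l_per_day <-
    population_flux(df$cells_per_ml, cont$C_fg, df$median_xnet_C_daily)
  df$flux_N_ug_per_l_per_day <-
    population_flux(df$cells_per_ml, cont$N_fg, df$median_xnet_N_daily)
  df
}
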