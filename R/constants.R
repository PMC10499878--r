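#' Natural-abundance isotope constants
#'
#' Fixed reference values for the rare-isotope content of unlabeled biomass:
#' the \eqn{^{13}C/^{12}C} ratio 0.011237 (atom fraction 0.011112) and the
#' \eqn{^{15}N/^{14}N} ratio 0.003676 (atom fraction 0.003663). Killed
#' (formalin-fixed) controls sit at these values; enrichment is measured as
#' departure from them.
#'
#' @return A named list with elements `f13C`, `f15N` (atom fractions) and
#'   `r13C`, `r15N` (isotope ratios).
#' @examples
#' natural_abundance()$f15N
#' @export
natural_abundance <- function() {
  list(
    f13C = 0.011112, r13C = 0.011237,
    f15N = 0.003663, r15N = 0.003676
  )
}

# ion species dataset names used throughout (HDF5 dataset names included)
ION_SPECIES <- c("12C2", "13C12C", "12C14N", "12C15N")

# major (denominator) and minor (numerator) species per element
ELEMENT_SPECIES <- list(
  C = c(minor = "13C12C", major = "12C2"),
  N = c(minor = "12C15N", major = "12C14N")
)

# run `expr`-free reproducible draws without clobbering the caller's RNG
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
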