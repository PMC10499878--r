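#' Write a simulated (or corrected) ion-stack set to HDF5
#'
#' One dataset per ion species, named `"12C2"`, `"13C12C"`, `"12C14N"`,
#' `"12C15N"`, each `cycles x rows x cols`; `raster_um`, `dwell_ms` and
#' `seed` stored as root attributes. Raw counts are written as integers,
#' dead-time-corrected stacks as doubles.
#'
#' @param sim A list with `stacks` and `config` as returned by
#'   [render_ion_stacks()] (a `truth` element, if present, is not written;
#'   see [write_truth_csv()]).
#' @param path Output `.h5` path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_ion_h5 <- function(sim, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (sp in names(sim$stacks)) {
    suppressMessages(rhdf5::h5write(sim$stacks[[sp]], path, sp))
  }
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(sim$config$raster_um, fid, "raster_um")
  rhdf5::h5writeAttribute(sim$config$dwell_ms, fid, "dwell_ms")
  rhdf5::h5writeAttribute(sim$config$seed, fid, "seed")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read an ion-stack set from HDF5
#'
#' @param path Path written by [write_ion_h5()].
#' @return List with `stacks` (named list of arrays) and `meta`
#'   (`raster_um`, `dwell_ms`, `seed`).
#' @export
read_ion_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  stacks <- list()
  for (sp in intersect(ION_SPECIES, contents$name)) {
    stacks[[sp]] <- rhdf5::h5read(path, sp)
  }
  fid <- rhdf5::H5Fopen(path)
  meta <- list(
    raster_um = as.numeric(rhdf5::h5readAttributes(fid, "/")$raster_um),
    dwell_ms  = as.numeric(rhdf5::h5readAttributes(fid, "/")$dwell_ms),
    seed      = as.integer(rhdf5::h5readAttributes(fid, "/")$seed)
  )
  rhdf5::H5Fclose(fid)
  list(stacks = stacks, meta = meta)
}

#' Write / read a ground-truth cell table as CSV
#'
#' Columns: `cell_id`, `kind`, `row`, `col`, `f13C_true`, `f15N_true`,
#' `area_px`, `attached_to`.
#'
#' @param truth Truth table from [render_ion_stacks()].
#' @param path CSV path.
#' @return `path` (write) or a data frame (read).
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a label map as a CSV matrix
#'
#' Plain-text stand-in for a 16-bit label TIFF: a headerless CSV of
#' integers, background 0, one row per image row.
#'
#' @param labels Integer label matrix.
#' @param path CSV path.
#' @return `path` (write) or an integer matrix (read).
#' @export
write_label_csv <- function(labels, path) {
  utils::write.table(labels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_label_csv
#' @export
read_label_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}
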