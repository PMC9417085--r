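#' Read a single protein sequence from a FASTA file
#'
#' @param path FASTA file with one record of one-letter amino-acid
#'   codes.
#' @return A single uppercase sequence string (attribute `name` holds
#'   the record header).
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  if (length(recs) < 1) abort(sprintf("%s: no FASTA records.", path))
  if (length(recs) > 1) {
    warn(sprintf("%s: %d records; using the first.", path, length(recs)))
  }
  seq <- toupper(as.character(recs[[1]]))
  attr(seq, "name") <- attr(recs[[1]], "name")
  seq
}

#' Read a two-column spectrum CSV
#'
#' Expects columns `wavelength` and a value column (`intensity` for
#' emission spectra, `theta` for CD); extra columns are kept.
#'
#' @param path CSV path.
#' @return A tibble sorted by wavelength.
#' @export
read_spectrum_csv <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE)
  if (!"wavelength" %in% names(dat)) {
    abort(sprintf("%s: no `wavelength` column.", path))
  }
  dplyr::arrange(dat, .data$wavelength)
}

#' Read an ITC injection table and build an enthalpogram
#'
#' Expects columns `injection`, `volume_uL` and `heat_kcal_per_mol`;
#' the cumulative cell concentration is computed with the displacement
#' dilution model of [itc_cell_concentration()].
#'
#' @param path CSV path.
#' @param syringe_mM Titrant concentration in the syringe (mM).
#' @param cell_uL Cell volume (uL).
#' @param protein_uM Protein concentration in the cell (uM).
#' @return An [enthalpogram].
#' @export
read_itc_csv <- function(path, syringe_mM, cell_uL = 1400,
                         protein_uM = NA_real_) {
  dat <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("injection", "volume_uL", "heat_kcal_per_mol")
  if (!all(needed %in% names(dat))) {
    abort(sprintf(
      "%s: need columns %s.", path, paste(needed, collapse = ", ")
    ))
  }
  dat <- dplyr::arrange(dat, .data$injection)
  conc <- itc_cell_concentration(dat$volume_uL, syringe_mM, cell_uL)
  enthalpogram(dat$injection, conc, dat$heat_kcal_per_mol,
    protein_uM = protein_uM
  )
}

#' Read a YAML run configuration
#'
#' A light container for reproducible runs: input curve files with
#' contrast labels, model start values and free-parameter mask,
#' overridable constants (water SLDs, surfactant volume, exchange
#' fraction) and seeds. Referenced curve files are checked to exist.
#'
#' @param path YAML file.
#' @return The configuration list, with defaults filled in
#'   (`constants$exchange_fraction = 0.9`, `constants$v_sds = 412`,
#'   `seed = 1`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  cfg$constants <- utils::modifyList(
    list(exchange_fraction = 0.9, v_sds = 412),
    cfg$constants %||% list()
  )
  cfg$seed <- cfg$seed %||% 1L
  if (!is.null(cfg$curves)) {
    for (cv in cfg$curves) {
      if (!is.null(cv$path) && !file.exists(cv$path)) {
        abort(sprintf("configured curve file not found: %s", cv$path))
      }
    }
  }
  cfg
}
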