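#' Coherent neutron scattering lengths of the elements used for proteins
#'
#' Bound coherent scattering lengths in fm for H, D, C, N, O and S
#' (Sears compilation, as used throughout biomolecular SLD work).
#'
#' @return Named numeric vector (fm).
#' @export
#' @examples
#' atomic_scattering_lengths()[["H"]]
atomic_scattering_lengths <- function() {
  c(H = -3.7406, D = 6.671, C = 6.6511, N = 9.37, O = 5.803, S = 2.847)
}

#' Residue scattering table for the 20 standard amino acids
#'
#' Per-residue atomic compositions (residue = amino acid minus one water,
#' i.e. the peptide-bond condensation convention), the number of labile
#' (solvent-exchangeable) hydrogens, and residue volumes. Side chains are
#' taken in their neutral protonation state: Asp/Glu carry the carboxylic
#' proton, Lys the neutral amine, Arg the neutral guanidine, His the
#' neutral imidazole; labile hydrogens are the backbone amide H plus all
#' side-chain O-H, N-H and S-H. Volumes are the Zamyatnin consensus
#' residue volumes (A^3). The coherent scattering length of the fully
#' protonated residue is computed from the composition with
#' [atomic_scattering_lengths()].
#'
#' Users may override any entry by supplying their own table of the same
#' shape to the functions that accept a `residue_table` argument (e.g. a
#' table read from CSV with [readr::read_csv()]).
#'
#' @return A tibble with columns `residue` (one-letter code), `C`, `H`,
#'   `N`, `O`, `S` (atom counts), `n_exchangeable` (labile H among `H`),
#'   `volume` (A^3) and `b_protonated` (fm).
#' @export
#' @examples
#' residue_scattering_table()
residue_scattering_table <- function() {
  tab <- tibble::tribble(
    ~residue, ~C, ~H, ~N, ~O, ~S, ~n_exchangeable, ~volume,
    "G", 2L,  3L, 1L, 1L, 0L, 1L,  60.1,
    "A", 3L,  5L, 1L, 1L, 0L, 1L,  88.6,
    "S", 3L,  5L, 1L, 2L, 0L, 2L,  89.0,
    "C", 3L,  5L, 1L, 1L, 1L, 2L, 108.5,
    "D", 4L,  5L, 1L, 3L, 0L, 2L, 111.1,
    "P", 5L,  7L, 1L, 1L, 0L, 0L, 112.7,
    "N", 4L,  6L, 2L, 2L, 0L, 3L, 114.1,
    "T", 4L,  7L, 1L, 2L, 0L, 2L, 116.1,
    "E", 5L,  7L, 1L, 3L, 0L, 2L, 138.4,
    "V", 5L,  9L, 1L, 1L, 0L, 1L, 140.0,
    "Q", 5L,  8L, 2L, 2L, 0L, 3L, 143.8,
    "H", 6L,  7L, 3L, 1L, 0L, 2L, 153.2,
    "M", 5L,  9L, 1L, 1L, 1L, 1L, 162.9,
    "I", 6L, 11L, 1L, 1L, 0L, 1L, 166.7,
    "L", 6L, 11L, 1L, 1L, 0L, 1L, 166.7,
    "K", 6L, 12L, 2L, 1L, 0L, 3L, 168.6,
    "R", 6L, 12L, 4L, 1L, 0L, 5L, 173.4,
    "F", 9L,  9L, 1L, 1L, 0L, 1L, 189.9,
    "Y", 9L,  9L, 1L, 2L, 0L, 2L, 193.6,
    "W", 11L, 10L, 2L, 1L, 0L, 2L, 227.8
  )
  b <- atomic_scattering_lengths()
  tab$b_protonated <- tab$C * b[["C"]] + tab$H * b[["H"]] +
    tab$N * b[["N"]] + tab$O * b[["O"]] + tab$S * b[["S"]]
  tab
}

validate_residue_table <- function(tab) {
  needed <- c("residue", "n_exchangeable", "volume", "b_protonated")
  if (!all(needed %in% names(tab))) {
    abort(paste0(
      "residue table must have columns: ",
      paste(needed, collapse = ", ")
    ))
  }
  if (any(tab$volume <= 0)) abort("residue volumes must all be > 0.")
  if (any(tab$n_exchangeable < 0)) {
    abort("exchangeable-H counts must be >= 0.")
  }
  invisible(tab)
}
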