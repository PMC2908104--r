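# Physicochemical constants: residue alphabet, masses, hydropathy, pKa sets.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Monoisotopic residue masses (Da), standard IUPAC atomic masses.
MASS_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
WATER_MONO <- 18.0105646863

# Average residue masses (Da).
MASS_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_AVG <- 18.01528

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values used by [gravy()]. Positive values are
#' hydrophobic. Exported so users can inspect or substitute the scale.
#'
#' @format A named numeric vector over the 20 standard residues.
#' @export
kyte_doolittle <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

#' Default acid-dissociation constant table
#'
#' Builds the pKa table used by the charge model: free alpha-amino and
#' alpha-carboxyl termini plus the seven ionizable side chains
#' (D, E, C, Y acidic; H, K, R basic). The default values are the EMBOSS
#' free-amino-acid set. The same values ship as an editable TSV in
#' `system.file("extdata", "pka_default.tsv", package = "pepfrac")`;
#' see [read_pka_config()].
#'
#' @param ionize_cys If `FALSE`, cysteine is removed from the acidic
#'   groups — appropriate for alkylated (e.g. carbamidomethylated) samples
#'   where the thiol can no longer titrate.
#' @return A list with elements `nterm`, `cterm` (pH units), `side`
#'   (named numeric, residue pKa), `acidic` and `basic` (character vectors
#'   classifying the side chains).
#' @export
#' @examples
#' default_pka()$side
default_pka <- function(ionize_cys = TRUE) {
  side <- c(C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
  acidic <- c("C", "D", "E", "Y")
  if (!ionize_cys) {
    side <- side[names(side) != "C"]
    acidic <- setdiff(acidic, "C")
  }
  validate_pka(list(nterm = 8.6, cterm = 3.6, side = side,
                    acidic = acidic, basic = c("H", "K", "R")))
}

validate_pka <- function(pka) {
  vals <- c(pka$nterm, pka$cterm, pka$side)
  if (any(!is.finite(vals)) || any(vals <= 0) || any(vals >= 14)) {
    abort("All pKa values must lie in (0, 14).")
  }
  cls <- sort(c(pka$acidic, pka$basic))
  if (!identical(cls, sort(names(pka$side)))) {
    abort("Every side-chain pKa must be classified as exactly one of acidic/basic.")
  }
  pka
}

#' Read a pKa table from a key-value TSV config
#'
#' The file has two tab-separated columns `group` and `pka`. Groups are
#' `nterm`, `cterm`, or a one-letter residue code among D, E, C, Y, H, K, R.
#' Residues D/E/C/Y are classified acidic, H/K/R basic; omitting a residue
#' row removes that group from the model (e.g. drop the C row for
#' alkylated cysteines).
#'
#' @param path Path to the TSV file.
#' @return A pKa table as returned by [default_pka()].
#' @export
read_pka_config <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    group = readr::col_character(), pka = readr::col_double()))
  if (!all(c("group", "pka") %in% names(tab))) {
    abort("pKa config must have columns 'group' and 'pka'.")
  }
  known <- c("nterm", "cterm", "D", "E", "C", "Y", "H", "K", "R")
  bad <- setdiff(tab$group, known)
  if (length(bad) > 0) {
    abort(paste0("Unknown pKa group(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(tab$group)) abort("Duplicate group in pKa config.")
  if (!all(c("nterm", "cterm") %in% tab$group)) {
    abort("pKa config must include 'nterm' and 'cterm' rows.")
  }
  vals <- setNames(tab$pka, tab$group)
  res <- setdiff(tab$group, c("nterm", "cterm"))
  validate_pka(list(
    nterm = unname(vals[["nterm"]]), cterm = unname(vals[["cterm"]]),
    side = vals[res],
    acidic = intersect(c("C", "D", "E", "Y"), res),
    basic = intersect(c("H", "K", "R"), res)
  ))
}

check_sequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    abort("Peptide sequence must be a single non-empty string.")
  }
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(res, AA_ALPHABET)
  if (length(bad) > 0) {
    abort(paste0("Illegal residue(s) in sequence '", sequence, "': ",
                 paste(unique(bad), collapse = ", ")))
  }
  res
}
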