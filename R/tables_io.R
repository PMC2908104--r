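# Reading/writing the tab-delimited peptide and fraction-range tables.

#' Column-mapping dialect for peptide tables
#'
#' Names the columns of a tab-delimited peptide identification table.
#' Only `sequence` and `fraction` are mandatory in the file; the others
#' are optional (missing column or empty cell both mean "absent").
#' Unknown extra columns in the file are ignored, so exports from any
#' search engine can be read by remapping names.
#'
#' @param sequence,fraction,pI,mw,score Column names in the file.
#' @return A named list of column names.
#' @export
peptide_dialect <- function(sequence = "sequence", fraction = "fraction",
                            pI = "pI", mw = "mw", score = "score") {
  list(sequence = sequence, fraction = fraction,
       pI = pI, mw = mw, score = score)
}

ensure_optional_cols <- function(obs) {
  for (col in c("pI", "mw", "score")) {
    if (!col %in% names(obs)) obs[[col]] <- NA_real_
  }
  obs
}

parse_num_col <- function(x, lines, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & nzchar(trimws(x)) & is.na(out))
  if (length(bad) > 0) {
    abort(paste0("Non-numeric ", what, " value '", x[bad[1]],
                 "' at line ", lines[bad[1]], "."))
  }
  out[!nzchar(trimws(ifelse(is.na(x), "", x)))] <- NA_real_
  out
}

#' Read a tab-delimited peptide identification table
#'
#' One row per (peptide, fraction) observation: sequence, fraction index
#' and optional estimated pI, molecular weight and search-engine (e.g.
#' MASCOT ion) score. Empty cells mean missing; missing pI/mw can later be
#' completed locally with [fill_missing()]. Duplicate (sequence, fraction)
#' rows are collapsed to one observation keeping the maximum score.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @param dialect Column mapping from [peptide_dialect()].
#' @return A tibble of validated observations with columns `sequence`
#'   (uppercase one-letter residues), `fraction` (integer >= 1), `pI`,
#'   `mw`, `score` (NA when absent), one row per distinct
#'   (sequence, fraction) pair.
#' @export
read_peptide_table <- function(path, dialect = peptide_dialect()) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    na = character())
  for (col in c("sequence", "fraction")) {
    if (!dialect[[col]] %in% names(raw)) {
      abort(paste0("Missing mandatory column '", dialect[[col]],
                   "' in ", path))
    }
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(sequence = character(), fraction = integer(),
                          pI = double(), mw = double(), score = double()))
  }
  lines <- seq_len(nrow(raw)) + 1L  # file line numbers (after header)
  seqs <- toupper(trimws(raw[[dialect$sequence]]))
  frac_raw <- raw[[dialect$fraction]]
  frac_num <- suppressWarnings(as.numeric(frac_raw))
  bad <- which(is.na(frac_num) | frac_num != round(frac_num) | frac_num < 1)
  if (length(bad) > 0) {
    abort(paste0("Invalid fraction value '", frac_raw[bad[1]],
                 "' at line ", lines[bad[1]],
                 " (must be an integer >= 1)."))
  }
  for (i in seq_along(seqs)) {
    ok <- tryCatch({check_sequence(seqs[i]); TRUE},
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) abort(paste0("Line ", lines[i], ": ", ok))
  }
  opt <- function(col) {
    if (dialect[[col]] %in% names(raw)) {
      parse_num_col(raw[[dialect[[col]]]], lines, col)
    } else rep(NA_real_, nrow(raw))
  }
  pI <- opt("pI"); mw <- opt("mw"); score <- opt("score")
  bad_pi <- which(!is.na(pI) & (pI <= 0 | pI >= 14))
  if (length(bad_pi) > 0) {
    abort(paste0("pI out of (0, 14) at line ", lines[bad_pi[1]], "."))
  }
  bad_mw <- which(!is.na(mw) & mw <= 0)
  if (length(bad_mw) > 0) {
    abort(paste0("Non-positive mw at line ", lines[bad_mw[1]], "."))
  }
  tibble::tibble(sequence = seqs, fraction = as.integer(frac_num),
                 pI = pI, mw = mw, score = score) |>
    collapse_duplicates()
}

collapse_duplicates <- function(obs) {
  obs |>
    dplyr::group_by(.data$sequence, .data$fraction) |>
    dplyr::arrange(dplyr::desc(!is.na(.data$score)),
                   dplyr::desc(.data$score), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sequence, .data$fraction)
}

#' Read expected pH ranges per fraction
#'
#' Three tab-separated columns: `fraction`, `ph_low`, `ph_high`. Rows are
#' returned sorted by fraction index.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `fraction` (integer), `ph_low`, `ph_high`.
#' @export
read_fraction_ranges <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    fraction = readr::col_integer(),
    ph_low = readr::col_double(),
    ph_high = readr::col_double()), progress = FALSE)
  if (!all(c("fraction", "ph_low", "ph_high") %in% names(tab))) {
    abort("Fraction-range table needs columns fraction, ph_low, ph_high.")
  }
  validate_ranges(tab)
}

validate_ranges <- function(tab) {
  if (any(is.na(tab$fraction)) || any(tab$fraction < 1)) {
    abort("Fraction indices must be integers >= 1.")
  }
  if (anyDuplicated(tab$fraction)) {
    abort("Duplicate fraction index in range table.")
  }
  bad <- which(!(tab$ph_low < tab$ph_high))
  if (length(bad) > 0) {
    abort(paste0("ph_low >= ph_high for fraction ", tab$fraction[bad[1]], "."))
  }
  out <- dplyr::arrange(tab, .data$fraction)
  if (is.unsorted(out$ph_low)) {
    abort("ph_low must be non-decreasing with fraction index.")
  }
  out[c("fraction", "ph_low", "ph_high")]
}

#' Complete missing pI and molecular-weight values by local computation
#'
#' Every observation lacking an estimated pI or molecular weight gets a
#' value computed from its sequence (charge-model pI via
#' [isoelectric_point()], mass via [molecular_weight()]). User-supplied
#' values are never overwritten; all observations of one sequence receive
#' identical computed values, so the operation is idempotent. When a
#' user-supplied pI differs from the computed one by more than 1 pH unit a
#' message flags the discrepancy.
#'
#' @param observations Observation tibble, e.g. from [read_peptide_table()].
#' @param pka pKa table, see [default_pka()].
#' @param mass_mode `"monoisotopic"` or `"average"`.
#' @return The observations with `pI` and `mw` fully populated.
#' @export
fill_missing <- function(observations, pka = default_pka(),
                         mass_mode = c("monoisotopic", "average")) {
  mass_mode <- match.arg(mass_mode)
  obs <- ensure_optional_cols(observations)
  if (nrow(obs) == 0) return(obs)
  need <- unique(obs$sequence[is.na(obs$pI) | is.na(obs$mw)])
  supplied <- unique(obs$sequence[!is.na(obs$pI)])
  check <- unique(c(need, supplied))
  if (length(check) == 0) return(obs)
  lut <- tibble::tibble(
    sequence = check,
    pI_calc = purrr::map_dbl(check, isoelectric_point, pka = pka),
    mw_calc = purrr::map_dbl(check, molecular_weight, mode = mass_mode)
  )
  out <- obs |>
    dplyr::left_join(lut, by = "sequence")
  flag <- !is.na(out$pI) & !is.na(out$pI_calc) &
    abs(out$pI - out$pI_calc) > 1
  if (any(flag)) {
    n <- length(unique(out$sequence[flag]))
    message(n, " peptide(s) have a supplied pI differing from the computed",
            " value by more than 1 pH unit; supplied values kept.")
  }
  out |>
    dplyr::mutate(pI = dplyr::coalesce(.data$pI, .data$pI_calc),
                  mw = dplyr::coalesce(.data$mw, .data$mw_calc)) |>
    dplyr::select(-"pI_calc", -"mw_calc")
}

#' Write per-peptide summaries to a TSV
#'
#' One row per distinct peptide: sequence, comma-separated fraction list,
#' n-span, pI, mw, best score, flat-charge range and GRAVY. Numbers are
#' written at full precision so [read_summary_table()] round-trips exactly.
#'
#' @param summaries Tibble from [summarise_peptides()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_summary_table <- function(summaries, path) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0) {
    abort("`summaries` must be a non-empty data frame.")
  }
  flat <- summaries |>
    dplyr::mutate(
      fractions = purrr::map_chr(.data$fractions,
                                 \(f) paste(f, collapse = ","))) |>
    dplyr::select("sequence", "fractions", "n_span", "pI", "mw",
                  "score", "flat_range", "gravy")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' Read back a summary TSV written by [write_summary_table()]
#'
#' @param path Path to the summary TSV.
#' @return A tibble in the layout of [summarise_peptides()] (including the
#'   reconstructed `runs` list-column).
#' @export
read_summary_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    sequence = readr::col_character(),
    fractions = readr::col_character(),
    n_span = readr::col_integer(),
    .default = readr::col_double()), progress = FALSE)
  tab |>
    dplyr::mutate(
      fractions = purrr::map(strsplit(.data$fractions, ",", fixed = TRUE),
                             as.integer),
      runs = purrr::map(.data$fractions, run_lengths)) |>
    dplyr::select("sequence", "fractions", "n_span", "runs",
                  "pI", "mw", "score", "flat_range", "gravy")
}
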