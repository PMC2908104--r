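# Per-peptide physicochemistry: net charge vs pH, pI, flat-charge range,
# molecular weight and GRAVY hydropathy.

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch net charge: the free N-terminus and each basic side
#' chain (H, K, R) contribute `1 / (1 + 10^(pH - pKa))`; the free C-terminus
#' and each acidic side chain (D, E, C, Y) contribute
#' `-1 / (1 + 10^(pKa - pH))`. Side-chain contributions are summed once per
#' occurrence of the residue.
#'
#' @param sequence Uppercase one-letter amino-acid string.
#' @param ph pH value(s); vectorised.
#' @param pka pKa table, see [default_pka()].
#' @return Net charge in elementary-charge units, one value per element of
#'   `ph`. Always lies in `(-n_acidic, +n_basic)` and is non-increasing in pH.
#' @export
#' @examples
#' net_charge("PEPTIDE", 7)
#' net_charge("KKKKR", c(3, 7, 11))
net_charge <- function(sequence, ph, pka = default_pka()) {
  res <- check_sequence(sequence)
  stopifnot(is.numeric(ph), all(is.finite(ph)))
  counts <- table(factor(res, levels = names(pka$side)))
  pos_pka <- c(pka$nterm, rep(pka$side[pka$basic], counts[pka$basic]))
  neg_pka <- c(pka$cterm, rep(pka$side[pka$acidic], counts[pka$acidic]))
  vapply(ph, function(p) {
    sum(1 / (1 + 10^(p - pos_pka))) - sum(1 / (1 + 10^(neg_pka - p)))
  }, numeric(1))
}

#' Net-charge titration curve on the fixed pH grid
#'
#' Evaluates [net_charge()] on the fixed grid pH 1.0, 1.1, ..., 14.0
#' (131 points).
#'
#' @inheritParams net_charge
#' @return A tibble with columns `ph` (131 grid values) and `charge`
#'   (non-increasing).
#' @export
titration_curve <- function(sequence, pka = default_pka()) {
  grid <- seq(1, 14, by = 0.1)
  tibble::tibble(ph = grid, charge = net_charge(sequence, grid, pka))
}

#' Isoelectric point of a peptide
#'
#' Solves `net_charge(sequence, pH) = 0` on the continuous charge function
#' (not the 0.1 titration grid) by root bisection over (0, 14). The free
#' termini guarantee at least one acidic and one basic group, so a unique
#' root exists.
#'
#' @inheritParams net_charge
#' @param tol Bisection tolerance in pH units.
#' @return The pI in pH units; `abs(net_charge(sequence, pI))` is below 1e-6.
#' @export
#' @examples
#' isoelectric_point("DDDDD") < isoelectric_point("KKKKK")
isoelectric_point <- function(sequence, pka = default_pka(), tol = 1e-4) {
  f <- function(p) net_charge(sequence, p, pka)
  uniroot(f, lower = 1e-6, upper = 14 - 1e-6, tol = min(tol, 1e-10))$root
}

#' Flat-charge-range focussing parameter
#'
#' Length of the pH range over which the absolute net charge stays within a
#' threshold of zero, measured on the fixed 0.1-step titration grid:
#' `0.1 * number of grid points with |charge| <= threshold`. Wide values
#' indicate a flat titration curve around the pI and hence poor focussing
#' potential. Because the grid has 131 points the saturated value is 13.1.
#'
#' @param curve Titration curve tibble from [titration_curve()].
#' @param threshold Charge threshold in elementary-charge units
#'   (inclusive); must be positive. Default 0.01.
#' @return Flat range in pH units, in `[0, 13.1]`.
#' @export
flat_range <- function(curve, threshold = 0.01) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    abort("`threshold` must be a single positive number.")
  }
  stopifnot(is.data.frame(curve), all(c("ph", "charge") %in% names(curve)))
  0.1 * sum(abs(curve$charge) <= threshold)
}

#' Peptide molecular weight
#'
#' Sum of residue masses plus one water, with monoisotopic (default) or
#' average residue masses.
#'
#' @inheritParams net_charge
#' @param mode `"monoisotopic"` or `"average"`.
#' @return Mass in daltons.
#' @export
#' @examples
#' molecular_weight("G")  # glycine, C2H5NO2
molecular_weight <- function(sequence, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  res <- check_sequence(sequence)
  if (mode == "monoisotopic") sum(MASS_MONO[res]) + WATER_MONO
  else sum(MASS_AVG[res]) + WATER_AVG
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean per-residue hydropathy under the given scale (default
#' [kyte_doolittle]).
#'
#' @inheritParams net_charge
#' @param scale Named numeric vector of per-residue hydropathy values.
#' @return Dimensionless mean hydropathy.
#' @export
gravy <- function(sequence, scale = kyte_doolittle) {
  res <- check_sequence(sequence)
  missing_scale <- setdiff(res, names(scale))
  if (length(missing_scale) > 0) {
    abort(paste0("Hydropathy scale lacks residue(s): ",
                 paste(unique(missing_scale), collapse = ", ")))
  }
  mean(scale[res])
}

run_lengths <- function(fractions) {
  # lengths of maximal runs of consecutive integers in a sorted fraction set
  if (length(fractions) == 0) return(integer(0))
  breaks <- c(0L, which(diff(fractions) > 1L), length(fractions))
  as.integer(diff(breaks))
}

#' Summarise observations into one row per distinct peptide
#'
#' Collapses a per-(sequence, fraction) observation table into per-peptide
#' summaries carrying the fraction set, the n-span (number of distinct
#' fractions; a 1-span peptide is called "unique"), the lengths of maximal
#' contiguous fraction runs, the best search-engine score, and the computed
#' physicochemistry (pI, molecular weight, flat-charge range, GRAVY).
#' User-supplied pI/mw values (e.g. after [fill_missing()]) are kept;
#' missing ones are computed.
#'
#' @param observations Tibble with columns `sequence`, `fraction` and
#'   optionally `pI`, `mw`, `score`.
#' @param pka pKa table, see [default_pka()].
#' @param threshold Charge threshold for [flat_range()].
#' @param mass_mode Mass mode for [molecular_weight()].
#' @return A tibble with one row per distinct sequence and columns
#'   `sequence`, `fractions` (list of sorted integer vectors), `n_span`,
#'   `runs` (list of run lengths), `pI`, `mw`, `score`, `flat_range`,
#'   `gravy`.
#' @export
summarise_peptides <- function(observations, pka = default_pka(),
                               threshold = 0.01,
                               mass_mode = c("monoisotopic", "average")) {
  mass_mode <- match.arg(mass_mode)
  if (!is.data.frame(observations) || nrow(observations) == 0) {
    abort("`observations` must be a non-empty data frame.")
  }
  obs <- ensure_optional_cols(observations)
  need_pi <- unique(obs$sequence[is.na(obs$pI)])
  need_mw <- unique(obs$sequence[is.na(obs$mw)])
  phys <- obs |>
    dplyr::distinct(.data$sequence) |>
    dplyr::mutate(
      flat_range = purrr::map_dbl(
        .data$sequence,
        \(s) flat_range(titration_curve(s, pka), threshold)),
      gravy = purrr::map_dbl(.data$sequence, gravy),
      pI_calc = ifelse(.data$sequence %in% need_pi,
                       purrr::map_dbl(.data$sequence, \(s)
                         if (s %in% need_pi) isoelectric_point(s, pka)
                         else NA_real_),
                       NA_real_),
      mw_calc = ifelse(.data$sequence %in% need_mw,
                       purrr::map_dbl(.data$sequence, \(s)
                         if (s %in% need_mw) molecular_weight(s, mass_mode)
                         else NA_real_),
                       NA_real_)
    )
  obs |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(
      fractions = list(sort(unique(.data$fraction))),
      pI = if (all(is.na(.data$pI))) NA_real_ else max(.data$pI, na.rm = TRUE),
      mw = if (all(is.na(.data$mw))) NA_real_ else max(.data$mw, na.rm = TRUE),
      score = if (all(is.na(.data$score))) NA_real_
              else max(.data$score, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::left_join(phys, by = "sequence") |>
    dplyr::mutate(
      n_span = lengths(.data$fractions),
      runs = purrr::map(.data$fractions, run_lengths),
      pI = dplyr::coalesce(.data$pI, .data$pI_calc),
      mw = dplyr::coalesce(.data$mw, .data$mw_calc)
    ) |>
    dplyr::select("sequence", "fractions", "n_span", "runs",
                  "pI", "mw", "score", "flat_range", "gravy") |>
    dplyr::arrange(.data$sequence)
}
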