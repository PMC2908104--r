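# Dataset-level fractionation statistics.

infer_n_fractions <- function(summaries, n_fractions = NULL) {
  if (is.null(n_fractions)) max(unlist(summaries$fractions)) else
    as.integer(n_fractions)
}

#' Per-fraction statistics
#'
#' For each fraction 1..n_fractions: the number of distinct peptides
#' observed, how many of them are unique (1-span), the unique percentage,
#' and the pI values of all peptides seen in the fraction (for the box
#' plot). Fractions with no peptides are retained with zero counts so
#' outputs align with the physical well layout.
#'
#' @param summaries Per-peptide summaries from [summarise_peptides()].
#' @param ranges Optional expected pH-range tibble
#'   (see [read_fraction_ranges()]).
#' @param n_fractions Total number of fractions; defaults to the largest
#'   fraction index observed.
#' @return A tibble with columns `fraction`, `n_peptides`, `n_unique`,
#'   `pct_unique` (NA for empty fractions), `pI_values` (list-column) and,
#'   when `ranges` is given, `ph_low`/`ph_high`.
#' @export
fraction_stats <- function(summaries, ranges = NULL, n_fractions = NULL) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0)
  n_fractions <- infer_n_fractions(summaries, n_fractions)
  long <- summaries |>
    dplyr::select("sequence", "fractions", "n_span", "pI") |>
    tidyr::unnest_longer("fractions", values_to = "fraction")
  per <- long |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(
      n_peptides = dplyr::n_distinct(.data$sequence),
      n_unique = dplyr::n_distinct(.data$sequence[.data$n_span == 1L]),
      pI_values = list(.data$pI),
      .groups = "drop")
  out <- tibble::tibble(fraction = seq_len(n_fractions)) |>
    dplyr::left_join(per, by = "fraction") |>
    dplyr::mutate(
      n_peptides = dplyr::coalesce(.data$n_peptides, 0L),
      n_unique = dplyr::coalesce(.data$n_unique, 0L),
      pct_unique = ifelse(.data$n_peptides > 0,
                          100 * .data$n_unique / .data$n_peptides, NA_real_),
      pI_values = purrr::map(.data$pI_values, \(v) v %||% numeric(0)))
  if (!is.null(ranges)) {
    out <- dplyr::left_join(out, validate_ranges(ranges), by = "fraction")
  }
  out
}

#' Distribution of peptide spans
#'
#' Tallies distinct peptides by n-span (a peptide identified in n distinct
#' fractions is n-spanned; 1-span peptides are "unique") and derives
#' dataset-level percentages: unique vs non-unique, and the share of
#' non-unique peptides whose spread stays within adjacent fractions only
#' (their fraction set forms one contiguous run).
#'
#' @param summaries Per-peptide summaries from [summarise_peptides()].
#' @return An object of class `span_distribution`: a list with `counts`
#'   (tibble n_span/n_peptides), `n_peptides`, `pct_unique_overall`,
#'   `pct_nonunique_overall`, `pct_contiguous_spreads` (NA when no peptide
#'   is non-unique) and `max_span`. Has [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
span_distribution <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0)
  counts <- summaries |>
    dplyr::count(.data$n_span, name = "n_peptides") |>
    dplyr::arrange(.data$n_span)
  n <- nrow(summaries)
  n_unique <- sum(summaries$n_span == 1L)
  nonuni <- summaries[summaries$n_span > 1L, ]
  pct_contig <- if (nrow(nonuni) == 0) NA_real_ else
    100 * mean(lengths(nonuni$runs) == 1L)
  structure(list(
    counts = counts,
    n_peptides = n,
    pct_unique_overall = 100 * n_unique / n,
    pct_nonunique_overall = 100 * (n - n_unique) / n,
    pct_contiguous_spreads = pct_contig,
    max_span = max(summaries$n_span)
  ), class = "span_distribution")
}

#' @export
print.span_distribution <- function(x, ...) {
  cat(sprintf(
    "Span distribution: %d distinct peptides, %.1f%% unique, %.1f%% non-unique\n",
    x$n_peptides, x$pct_unique_overall, x$pct_nonunique_overall))
  if (!is.na(x$pct_contiguous_spreads)) {
    cat(sprintf("  %.1f%% of non-unique spreads are across adjacent fractions only\n",
                x$pct_contiguous_spreads))
  }
  cat(sprintf("  widest span: %d fractions\n", x$max_span))
  print(x$counts, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a span distribution into its per-category counts
#'
#' @param x A `span_distribution` object.
#' @param ... Unused.
#' @return A tibble with columns `n_span`, `n_peptides`, `pct`.
#' @method tidy span_distribution
#' @export
tidy.span_distribution <- function(x, ...) {
  dplyr::mutate(x$counts, pct = 100 * .data$n_peptides / x$n_peptides)
}

#' One-row summary of a span distribution
#'
#' @param x A `span_distribution` object.
#' @param ... Unused.
#' @return A one-row tibble with the dataset-level percentages.
#' @method glance span_distribution
#' @export
glance.span_distribution <- function(x, ...) {
  tibble::tibble(
    n_peptides = x$n_peptides,
    pct_unique_overall = x$pct_unique_overall,
    pct_nonunique_overall = x$pct_nonunique_overall,
    pct_contiguous_spreads = x$pct_contiguous_spreads,
    max_span = x$max_span)
}

#' Shared peptides between adjacent fractions
#'
#' For each pair of neighbouring fractions (i, i+1) counts the distinct
#' peptides present in both, together with the fraction sizes — the inputs
#' of the area-proportional overlap diagram.
#'
#' @param summaries Per-peptide summaries from [summarise_peptides()].
#' @param n_fractions Total number of fractions (>= 2); defaults to the
#'   largest fraction index observed.
#' @return A tibble with `n_fractions - 1` rows and columns `left`,
#'   `right`, `shared`, `size_left`, `size_right`.
#' @export
adjacent_overlaps <- function(summaries, n_fractions = NULL) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0)
  n_fractions <- infer_n_fractions(summaries, n_fractions)
  if (n_fractions < 2) abort("Need at least 2 fractions for overlaps.")
  sets <- purrr::map(seq_len(n_fractions), function(i) {
    summaries$sequence[purrr::map_lgl(summaries$fractions, \(f) i %in% f)]
  })
  tibble::tibble(
    left = seq_len(n_fractions - 1L),
    right = .data$left + 1L,
    shared = purrr::map2_int(.data$left, .data$right,
                             \(i, j) length(intersect(sets[[i]], sets[[j]]))),
    size_left = lengths(sets)[.data$left],
    size_right = lengths(sets)[.data$right])
}

#' Assign deterministic plot identifiers to peptides
#'
#' Every peptide gets a positive integer identifier ordered by span width:
#' peptides are sorted by (n_span, first fraction, pI, sequence) and
#' numbered consecutively, so peptides of equal n-span occupy a contiguous
#' identifier block and the assignment is reproducible for a given dataset.
#'
#' @param summaries Per-peptide summaries from [summarise_peptides()].
#' @return A tibble with columns `sequence`, `identifier`, `n_span`.
#' @export
assign_identifiers <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0)
  summaries |>
    dplyr::mutate(first_fraction = purrr::map_int(.data$fractions,
                                                  \(f) as.integer(f[1]))) |>
    dplyr::arrange(.data$n_span, .data$first_fraction, .data$pI,
                   .data$sequence) |>
    dplyr::mutate(identifier = dplyr::row_number()) |>
    dplyr::select("sequence", "identifier", "n_span")
}

#' Sort peptide summaries by pI, mass or score
#'
#' Stable ascending sort by the chosen key with lexicographic sequence
#' order as the tie-break.
#'
#' @param summaries Per-peptide summaries from [summarise_peptides()].
#' @param key One of `"pI"`, `"mass"`, `"score"`.
#' @return The reordered summaries tibble.
#' @export
sort_peptides <- function(summaries, key = c("pI", "mass", "score")) {
  key <- match.arg(key)
  col <- c(pI = "pI", mass = "mw", score = "score")[[key]]
  vals <- summaries[[col]]
  if (is.null(vals) || any(is.na(vals))) {
    abort(paste0("Sort key '", key, "' is missing for some peptides."))
  }
  summaries[order(vals, summaries$sequence), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
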