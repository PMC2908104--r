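# The five-panel diagnostic figure. Each panel_* function returns its
# plot-ready data layer alongside the ggplot, so all numeric checks can run
# without rasterisation.

new_panel <- function(data, plot, labels = character(0)) {
  structure(list(data = data, plot = plot, labels = labels),
            class = "pepfrac_panel")
}

#' @export
print.pepfrac_panel <- function(x, ...) {
  print(x$plot, ...)
  invisible(x)
}

#' Report configuration
#'
#' Collects the rendering options of [render_report()].
#'
#' @param format Output format: `"png"`, `"pdf"` or `"svg"`.
#' @param dpi Raster resolution (png only).
#' @param sort_key Panel-E sort key: `"pI"`, `"mass"` or `"score"`.
#' @param charge_threshold Flat-charge-range threshold
#'   (elementary charges).
#' @param grey_bounds Optional fixed `c(min, max)` flat-range bounds for
#'   the panel-E grey gradient; default uses the dataset's range.
#' @param max_radius Largest circle radius in the overlap chain.
#' @param width,height Page size in inches.
#' @return A list of class `report_spec`.
#' @export
report_spec <- function(format = c("png", "pdf", "svg"), dpi = 150,
                        sort_key = c("pI", "mass", "score"),
                        charge_threshold = 0.01, grey_bounds = NULL,
                        max_radius = 1, width = 10, height = 14) {
  structure(list(format = match.arg(format), dpi = dpi,
                 sort_key = match.arg(sort_key),
                 charge_threshold = charge_threshold,
                 grey_bounds = grey_bounds, max_radius = max_radius,
                 width = width, height = height),
            class = "report_spec")
}

# Shared colour maps: injective, reused across panels C, D and E.
span_colour_map <- function(n_spans) {
  lev <- sort(unique(n_spans))
  setNames(grDevices::hcl.colors(max(length(lev), 2), "Viridis")[
    seq_along(lev)], lev)
}

fraction_colour_map <- function(fractions) {
  lev <- sort(unique(fractions))
  setNames(grDevices::hcl.colors(max(length(lev), 2), "Zissou 1")[
    seq_along(lev)], lev)
}

#' Panel A: per-fraction pI box plot
#'
#' One box (median, quartiles, 1.5 IQR whiskers) per non-empty fraction
#' over the pI values of the peptides seen in it; expected pH ranges, when
#' provided, are overlaid as dotted step lines. In a well-behaved
#' separation the boxes track the expected gradient.
#'
#' @param stats Per-fraction statistics from [fraction_stats()].
#' @param ranges Optional expected-range tibble.
#' @return A `pepfrac_panel`: `$data` holds the long (fraction, pI) tibble,
#'   `$plot` the ggplot.
#' @export
panel_boxplot <- function(stats, ranges = NULL) {
  long <- stats |>
    dplyr::select("fraction", "pI_values") |>
    tidyr::unnest_longer("pI_values", values_to = "pI") |>
    dplyr::filter(!is.na(.data$pI))
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$fraction, y = .data$pI,
                                    group = .data$fraction)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.3,
                          fill = "grey90") +
    ggplot2::scale_x_continuous(breaks = stats$fraction) +
    ggplot2::labs(x = "Fraction", y = "Peptide pI",
                  title = "A  pI distribution per fraction") +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(ranges)) {
    p <- p +
      ggplot2::geom_step(data = ranges,
                         ggplot2::aes(x = .data$fraction - 0.5,
                                      y = .data$ph_low, group = 1),
                         linetype = "dotted", colour = "red") +
      ggplot2::geom_step(data = ranges,
                         ggplot2::aes(x = .data$fraction - 0.5,
                                      y = .data$ph_high, group = 1),
                         linetype = "dotted", colour = "red")
  }
  new_panel(long, p)
}

#' Panel B: percentage of unique peptides per fraction
#'
#' One bar per fraction at its unique (1-span) percentage; high bars mean
#' good focussing in that pH region. Empty fractions show no bar.
#'
#' @param stats Per-fraction statistics from [fraction_stats()].
#' @return A `pepfrac_panel` whose `$data` is the stats tibble.
#' @export
panel_unique_histogram <- function(stats) {
  p <- ggplot2::ggplot(dplyr::filter(stats, .data$n_peptides > 0),
                       ggplot2::aes(x = .data$fraction,
                                    y = .data$pct_unique)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.8) +
    ggplot2::scale_x_continuous(breaks = stats$fraction,
                                limits = range(stats$fraction) + c(-0.5, 0.5)) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "Fraction", y = "% unique peptides",
                  title = "B  Unique peptides per fraction") +
    ggplot2::theme_minimal(base_size = 9)
  new_panel(stats, p)
}

#' Panel C: overall fractionation pattern bitmap
#'
#' Every peptide is one horizontal row (its identifier, grouped into
#' n-span bands); a cell is filled at (fraction, row) wherever the peptide
#' was observed, so repetition across adjacent fractions draws continuous
#' horizontal segments. Cell colour encodes the n-span category and is
#' shared with the other panels.
#'
#' @param summaries Per-peptide summaries from [summarise_peptides()].
#' @param identifiers Identifier map from [assign_identifiers()].
#' @param colour_map Optional named colour vector over n-span levels.
#' @return A `pepfrac_panel`; `$data` has one row per filled cell
#'   (`fraction`, `identifier`, `n_span`).
#' @export
panel_span_bitmap <- function(summaries, identifiers = NULL,
                              colour_map = NULL) {
  if (is.null(identifiers)) identifiers <- assign_identifiers(summaries)
  cells <- summaries |>
    dplyr::select("sequence", "fractions") |>
    dplyr::inner_join(identifiers, by = "sequence") |>
    tidyr::unnest_longer("fractions", values_to = "fraction") |>
    dplyr::select("fraction", "identifier", "n_span", "sequence")
  if (is.null(colour_map)) colour_map <- span_colour_map(cells$n_span)
  p <- ggplot2::ggplot(cells,
                       ggplot2::aes(x = .data$fraction, y = .data$identifier,
                                    fill = factor(.data$n_span))) +
    ggplot2::geom_tile(width = 0.92, height = 1) +
    ggplot2::scale_fill_manual(values = colour_map, name = "n-span") +
    ggplot2::scale_x_continuous(breaks = sort(unique(cells$fraction))) +
    ggplot2::labs(x = "Fraction", y = "Peptide identifier",
                  title = "C  Fractionation pattern by n-span") +
    ggplot2::theme_minimal(base_size = 9)
  new_panel(cells, p)
}

circle_points <- function(cx, cy, r, n = 240) {
  t <- seq(0, 2 * pi, length.out = n)
  tibble::tibble(x = cx + r * cos(t), y = cy + r * sin(t))
}

lens_polygon <- function(cx1, cx2, r1, r2, gx, gy, n = 80) {
  # lens outline from the two arcs between the intersection points
  a <- atan2(gy, gx - cx1)           # half-angle on the left circle
  t1 <- seq(-a, a, length.out = n)   # arc bulging right
  b <- atan2(gy, gx - cx2)           # on the right circle (obtuse)
  t2 <- seq(b, 2 * pi - b, length.out = n)  # arc bulging left
  tibble::tibble(
    x = c(cx1 + r1 * cos(t1), cx2 + r2 * cos(t2)),
    y = c(r1 * sin(t1), r2 * sin(t2)))
}

#' Panel D: area-proportional adjacent-fraction overlap chain
#'
#' Circle areas are proportional to the number of peptides identified in
#' each fraction and each lens area to the peptides shared by the adjacent
#' pair; the lens is drawn from the two circle arcs between the computed
#' intersection points and labelled with the shared count.
#'
#' @param layout Solved layout from [layout_chain()].
#' @param colour_map Optional named colour vector over fraction indices.
#' @return A `pepfrac_panel`; `$data` is the layout (circles + lenses).
#' @export
panel_venn_chain <- function(layout, colour_map = NULL) {
  circles <- layout$circles
  lenses <- layout$lenses
  if (is.null(colour_map)) colour_map <- fraction_colour_map(circles$fraction)
  outlines <- circles |>
    dplyr::filter(.data$radius > 0) |>
    purrr::pmap(function(fraction, n_peptides, radius, cx, cy) {
      dplyr::mutate(circle_points(cx, cy, radius), fraction = fraction)
    }) |>
    purrr::list_rbind()
  lens_polys <- lenses |>
    dplyr::filter(.data$regime == "overlapping") |>
    purrr::pmap(function(left, right, gx, gy, ...) {
      dplyr::mutate(
        lens_polygon(circles$cx[left], circles$cx[right],
                     circles$radius[left], circles$radius[right], gx, gy),
        left = left)
    }) |>
    purrr::list_rbind()
  if (nrow(lens_polys) == 0) {
    lens_polys <- tibble::tibble(x = numeric(0), y = numeric(0),
                                 left = integer(0))
  }
  lab <- dplyr::filter(lenses, .data$shared > 0)
  rmax <- max(circles$radius)
  p <- ggplot2::ggplot() +
    ggplot2::geom_polygon(data = lens_polys,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       group = .data$left),
                          fill = "grey70", alpha = 0.6) +
    ggplot2::geom_path(data = outlines,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$fraction,
                                    colour = factor(.data$fraction)),
                       linewidth = 0.4) +
    ggplot2::geom_point(data = dplyr::filter(circles, .data$radius == 0),
                        ggplot2::aes(x = .data$cx, y = .data$cy), shape = 4) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = .data$label_x, y = 0,
                                    label = .data$shared), size = 2.6) +
    ggplot2::geom_text(data = circles,
                       ggplot2::aes(x = .data$cx, y = -rmax * 1.15,
                                    label = paste0("F", .data$fraction,
                                                   "\n", .data$n_peptides)),
                       size = 2.2, vjust = 1) +
    ggplot2::scale_colour_manual(values = colour_map, guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "D  Peptides shared between adjacent fractions") +
    ggplot2::theme_void(base_size = 9) +
    ggplot2::theme(plot.title = ggplot2::element_text(size = 9))
  labels <- c(paste0("F", circles$fraction), as.character(lab$shared),
              as.character(circles$n_peptides))
  new_panel(list(circles = circles, lenses = lenses), p, labels)
}

#' Panel E: segment-stack view of the spread between adjacent fractions
#'
#' Within each fraction, peptides are sorted by the chosen key (default
#' estimated pI) and drawn as centred horizontal segments whose length is
#' proportional to that value; columns widen with the number of peptides
#' in the fraction. A peptide present in fractions i and i+1 has its two
#' segments connected by a line whose grey level encodes the
#' flat-charge-range parameter (darker = wider = intrinsically poor
#' focussing). Horizontal lines between identical fractions, positive
#' slopes for an ideal continuous separation.
#'
#' @param summaries Per-peptide summaries from [summarise_peptides()].
#' @param sort_key `"pI"`, `"mass"` or `"score"`.
#' @param grey_bounds Optional fixed `c(min, max)` flat-range bounds for
#'   the grey gradient; defaults to the dataset's range.
#' @param n_fractions Total number of fractions.
#' @return A `pepfrac_panel`; `$data` holds `segments` (one per
#'   (peptide, fraction) with `x`, `y`, `half_len`) and `links` (one per
#'   adjacent co-occurrence with `grey` in [0, 1], 1 = darkest).
#' @export
panel_segment_stack <- function(summaries, sort_key = c("pI", "mass", "score"),
                                grey_bounds = NULL, n_fractions = NULL) {
  sort_key <- match.arg(sort_key)
  col <- c(pI = "pI", mass = "mw", score = "score")[[sort_key]]
  n_fractions <- infer_n_fractions(summaries, n_fractions)
  long <- summaries |>
    dplyr::mutate(value = .data[[col]]) |>
    dplyr::select("sequence", "fractions", "value", "flat_range") |>
    tidyr::unnest_longer("fractions", values_to = "fraction")
  if (any(is.na(long$value))) {
    abort(paste0("Sort key '", sort_key, "' is missing for some peptides."))
  }
  vr <- range(long$value)
  span_v <- if (diff(vr) > 0) diff(vr) else 1
  max_n <- max(table(long$fraction))
  segments <- long |>
    dplyr::group_by(.data$fraction) |>
    dplyr::arrange(.data$value, .data$sequence, .by_group = TRUE) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      y = -.data$rank,
      # column width grows with fraction size; value maps to [0.2, 1] of it
      col_width = 0.9 * dplyr::n() / max_n,
      half_len = .data$col_width *
        (0.2 + 0.8 * (.data$value - vr[1]) / span_v) / 2,
      x = .data$fraction) |>
    dplyr::ungroup()
  links <- dplyr::inner_join(
    segments, segments,
    by = "sequence", suffix = c("_l", "_r"),
    relationship = "many-to-many") |>
    dplyr::filter(.data$fraction_r == .data$fraction_l + 1L) |>
    dplyr::transmute(
      sequence = .data$sequence,
      left = .data$fraction_l, right = .data$fraction_r,
      x0 = .data$x_l + .data$half_len_l, y0 = .data$y_l,
      x1 = .data$x_r - .data$half_len_r, y1 = .data$y_r,
      flat_range = .data$flat_range_l)
  gb <- grey_bounds %||% range(summaries$flat_range)
  gspan <- if (diff(gb) > 0) diff(gb) else 1
  links$grey <- pmin(pmax((links$flat_range - gb[1]) / gspan, 0), 1)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = links,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       colour = .data$grey),
                          linewidth = 0.25) +
    ggplot2::scale_colour_gradient(low = "grey85", high = "grey5",
                                   limits = c(0, 1),
                                   name = "flat range\n(scaled)") +
    ggplot2::geom_segment(data = segments,
                          ggplot2::aes(x = .data$x - .data$half_len,
                                       xend = .data$x + .data$half_len,
                                       y = .data$y, yend = .data$y),
                          linewidth = 0.35, colour = "black") +
    ggplot2::scale_x_continuous(breaks = seq_len(n_fractions)) +
    ggplot2::labs(x = "Fraction", y = NULL,
                  title = "E  Spread between adjacent fractions") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  new_panel(list(segments = segments, links = links), p)
}
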