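# One-page report assembly and device output.

#' Render the one-page five-panel diagnostic report
#'
#' Runs the full analysis on an observation table and writes a single page
#' containing: (A) the per-fraction pI box plot against expected pH
#' ranges, (B) the per-fraction unique-peptide histogram, (C) the n-span
#' fractionation-pattern bitmap, (D) the area-proportional
#' adjacent-fraction overlap chain and (E) the segment-stack spread view.
#' Output is deterministic for a fixed input and spec. With fewer than two
#' fractions panels D and E are omitted with a notice.
#'
#' For SVG output the graphics device in use may outline text as glyph
#' paths; the fraction labels and shared counts are therefore also
#' embedded as an SVG `<desc>` metadata element so the file remains
#' text-searchable.
#'
#' @param observations Observation tibble (see [read_peptide_table()]);
#'   missing pI/mw values are completed with [fill_missing()].
#' @param path Output file path; the extension does not need to match the
#'   format. Written atomically (no partial file on error).
#' @param ranges Optional expected pH-range tibble.
#' @param spec Rendering options from [report_spec()].
#' @param pka,mass_mode Charge/mass model configuration.
#' @return Invisibly, a list with the computed `summaries`, `stats`,
#'   `spans`, `overlaps`, `layout` and the `panels`.
#' @export
render_report <- function(observations, path, ranges = NULL,
                          spec = report_spec(), pka = default_pka(),
                          mass_mode = c("monoisotopic", "average")) {
  mass_mode <- match.arg(mass_mode)
  obs <- fill_missing(observations, pka, mass_mode)
  summaries <- summarise_peptides(obs, pka, spec$charge_threshold, mass_mode)
  n_fractions <- max(obs$fraction)
  stats <- fraction_stats(summaries, ranges, n_fractions)
  spans <- span_distribution(summaries)
  ids <- assign_identifiers(summaries)
  span_cols <- span_colour_map(summaries$n_span)
  frac_cols <- fraction_colour_map(seq_len(n_fractions))

  pA <- panel_boxplot(stats, ranges)
  pB <- panel_unique_histogram(stats)
  pC <- panel_span_bitmap(summaries, ids, span_cols)
  panels <- list(A = pA, B = pB, C = pC)
  overlaps <- NULL; layout <- NULL
  if (n_fractions >= 2) {
    overlaps <- adjacent_overlaps(summaries, n_fractions)
    layout <- layout_chain(overlaps, spec$max_radius)
    panels$D <- panel_venn_chain(layout, frac_cols)
    panels$E <- panel_segment_stack(summaries, spec$sort_key,
                                    spec$grey_bounds, n_fractions)
    page <- patchwork::wrap_plots(
      patchwork::wrap_plots(pA$plot, pB$plot, ncol = 2),
      pC$plot, panels$D$plot, panels$E$plot,
      ncol = 1, heights = c(1, 1.3, 0.9, 1.3))
  } else {
    message("Fewer than 2 fractions: omitting overlap and spread panels.")
    page <- patchwork::wrap_plots(
      patchwork::wrap_plots(pA$plot, pB$plot, ncol = 2),
      pC$plot, ncol = 1)
  }

  tmp <- tempfile(fileext = paste0(".", spec$format))
  dev <- switch(spec$format,
                png = function(f) grDevices::png(f, spec$width, spec$height,
                                                 units = "in",
                                                 res = spec$dpi),
                pdf = function(f) grDevices::pdf(f, spec$width, spec$height),
                svg = function(f) grDevices::svg(f, spec$width, spec$height))
  dev(tmp)
  ok <- tryCatch({print(page); TRUE},
                 finally = grDevices::dev.off())
  if (!isTRUE(ok) || !file.exists(tmp)) {
    abort("Report rendering failed; no output written.")
  }
  if (spec$format == "svg") {
    labels <- unique(unlist(lapply(panels, function(p) p$labels)))
    embed_svg_desc(tmp, labels)
  }
  if (!dir.exists(dirname(path)) || file.access(dirname(path), 2) != 0) {
    unlink(tmp)
    abort(paste0("Cannot write to ", path))
  }
  file.copy(tmp, path, overwrite = TRUE)
  unlink(tmp)
  invisible(list(summaries = summaries, stats = stats, spans = spans,
                 overlaps = overlaps, layout = layout, panels = panels,
                 path = path))
}

embed_svg_desc <- function(path, labels) {
  if (length(labels) == 0) return(invisible(path))
  lines <- readLines(path, warn = FALSE)
  open_tag <- grep("<svg\\b", lines)[1]
  if (is.na(open_tag)) return(invisible(path))
  # the <svg ...> tag may span several lines; insert after it closes
  while (open_tag <= length(lines) && !grepl(">", lines[open_tag])) {
    open_tag <- open_tag + 1L
  }
  esc <- gsub("&", "&amp;", labels, fixed = TRUE)
  esc <- gsub("<", "&lt;", esc, fixed = TRUE)
  desc <- paste0("<desc>", paste(esc, collapse = " "), "</desc>")
  out <- append(lines, desc, after = open_tag)
  writeLines(out, path)
  invisible(path)
}
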