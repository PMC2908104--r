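fixture_summaries <- function() {
  obs <- tibble::tibble(
    sequence = c("ACDK", "ACDK", "ELVISK", "PEPTIDER", "PEPTIDER",
                 "GWGK", "AAAK"),
    fraction = c(1L, 2L, 1L, 2L, 3L, 3L, 3L),
    pI = NA_real_, mw = NA_real_,
    score = c(40, 55, 70, 20, 25, 90, 33))
  summarise_peptides(fill_missing(obs))
}

test_that("box plot panel carries one pI value per membership and tracks ranges", {
  summ <- fixture_summaries()
  st <- fraction_stats(summ, n_fractions = 3)
  rng <- tibble::tibble(fraction = 1:3, ph_low = c(3, 5, 7),
                        ph_high = c(5, 7, 9))
  pA <- panel_boxplot(st, rng)
  expect_s3_class(pA$plot, "ggplot")
  expect_equal(nrow(pA$data), sum(lengths(summ$fractions)))
  # zero-spread ordered fixture: medians non-decreasing with fraction
  peps <- c("DDDDDK", "ACDEFGHIK", "GGKGG", "KKKKR")
  sim <- simulate_fractionation(peps, spread_alpha = 0, noise_sigma = 0,
                                seed = 2)
  s2 <- summarise_peptides(fill_missing(sim$observations))
  med <- panel_boxplot(fraction_stats(s2))$data |>
    dplyr::group_by(fraction) |>
    dplyr::summarise(m = median(pI)) |>
    dplyr::arrange(fraction)
  expect_true(all(diff(med$m) >= 0))
})

test_that("unique histogram passes fraction stats through unchanged", {
  st <- fraction_stats(fixture_summaries(), n_fractions = 4)
  pB <- panel_unique_histogram(st)
  expect_identical(pB$data, st)
  all_uni <- summarise_peptides(fill_missing(tibble::tibble(
    sequence = c("GGK", "AAR", "ELVISK"), fraction = 1:3,
    pI = NA_real_, mw = NA_real_, score = NA_real_)))
  stu <- fraction_stats(all_uni)
  expect_equal(panel_unique_histogram(stu)$data$pct_unique, rep(100, 3))
})

test_that("span bitmap fills one cell per (peptide, fraction) pair in span bands", {
  summ <- fixture_summaries()
  ids <- assign_identifiers(summ)
  pC <- panel_span_bitmap(summ, ids)
  expect_equal(nrow(pC$data), sum(summ$n_span))
  # a 2-span peptide occupies two adjacent cells on one row
  row_acdk <- pC$data[pC$data$sequence == "ACDK", ]
  expect_equal(sort(row_acdk$fraction), c(1L, 2L))
  expect_equal(length(unique(row_acdk$identifier)), 1L)
  # identifiers group the y-axis into n-span bands
  band_order <- pC$data |>
    dplyr::distinct(identifier, n_span) |>
    dplyr::arrange(identifier)
  expect_true(all(diff(band_order$n_span) >= 0))
})

test_that("venn chain panel preserves the solved layout and labels shared counts", {
  summ <- fixture_summaries()
  ov <- adjacent_overlaps(summ, 3)
  lay <- layout_chain(ov)
  pD <- panel_venn_chain(lay)
  expect_identical(pD$data$circles, lay$circles)
  expect_identical(pD$data$lenses, lay$lenses)
  lab_counts <- lay$lenses$shared[lay$lenses$shared > 0]
  expect_true(all(as.character(lab_counts) %in% pD$labels))
  # zero-sharing chain: no lens labels
  dis <- summarise_peptides(fill_missing(tibble::tibble(
    sequence = c("GGK", "AAR"), fraction = 1:2,
    pI = NA_real_, mw = NA_real_, score = NA_real_)))
  lay0 <- layout_chain(adjacent_overlaps(dis, 2))
  pD0 <- panel_venn_chain(lay0)
  expect_false(any(grepl("^[0-9]+$", setdiff(pD0$labels,
                                             as.character(lay0$circles$n_peptides)))))
})

test_that("segment stack links adjacent co-occurrences with flat-range greys", {
  # two identical fractions: equal bar lengths, horizontal links
  obs <- tibble::tibble(
    sequence = rep(c("ACDK", "ELVISK", "GWGKGG"), each = 2),
    fraction = rep(1:2, 3), pI = NA_real_, mw = NA_real_, score = NA_real_)
  summ <- summarise_peptides(fill_missing(obs))
  pE <- panel_segment_stack(summ)
  expect_equal(nrow(pE$data$links), 3L)
  expect_equal(pE$data$links$y0, pE$data$links$y1)
  seg <- pE$data$segments
  len_by_frac <- split(seg$half_len[order(seg$sequence)],
                       seg$fraction[order(seg$sequence)])
  expect_equal(len_by_frac[[1]], len_by_frac[[2]])

  # adjacency-only: presence in i and i+2 draws no line
  gap <- summarise_peptides(fill_missing(tibble::tibble(
    sequence = c("ACDK", "ACDK", "GGK"), fraction = c(1L, 3L, 2L),
    pI = NA_real_, mw = NA_real_, score = NA_real_)))
  expect_equal(nrow(panel_segment_stack(gap)$data$links), 0L)

  # total links = sum over peptides of adjacent consecutive pairs
  summ2 <- fixture_summaries()
  pE2 <- panel_segment_stack(summ2)
  expected_links <- sum(vapply(summ2$fractions,
                               \(f) sum(diff(f) == 1L), integer(1)))
  expect_equal(nrow(pE2$data$links), expected_links)
  # grey levels map flat range linearly onto [0, 1] over the dataset bounds
  gb <- range(summ2$flat_range)
  expect_equal(pE2$data$links$grey,
               (pE2$data$links$flat_range - gb[1]) / diff(gb))

  # a dataset-maximal flat-range peptide that is linked gets the darkest grey
  widest <- summ2$sequence[which.max(summ2$flat_range)]
  obs3 <- tibble::tibble(
    sequence = c(widest, widest, summ2$sequence[-which.max(summ2$flat_range)]),
    fraction = c(1L, 2L, seq_along(summ2$sequence[-1]) + 2L),
    pI = NA_real_, mw = NA_real_, score = NA_real_)
  pE3 <- panel_segment_stack(summarise_peptides(fill_missing(obs3)))
  expect_equal(max(pE3$data$links$grey), 1)
})

test_that("report renders a deterministic one-page figure in each format", {
  obs <- fixture_summaries() |>
    dplyr::select(sequence, fractions, pI, mw, score) |>
    tidyr::unnest_longer(fractions, values_to = "fraction")
  dir <- withr::local_tempdir()
  png_path <- file.path(dir, "r.png")
  res <- render_report(obs, png_path)
  expect_true(file.exists(png_path))
  expect_gt(file.size(png_path), 1000)
  expect_identical(readBin(png_path, "raw", 8),
                   as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))
  expect_named(res$panels, c("A", "B", "C", "D", "E"))

  res2 <- render_report(obs, file.path(dir, "r2.png"))
  expect_identical(res$summaries, res2$summaries)
  expect_identical(res$layout, res2$layout)
  expect_identical(lapply(res$panels, `[[`, "data"),
                   lapply(res2$panels, `[[`, "data"))

  svg_path <- file.path(dir, "r.svg")
  resv <- render_report(obs, svg_path, spec = report_spec(format = "svg"))
  svg_txt <- paste(readLines(svg_path, warn = FALSE), collapse = "\n")
  shared <- resv$layout$lenses$shared
  for (lab in c("F1", "F2", "F3", as.character(shared[shared > 0]))) {
    expect_match(svg_txt, lab, fixed = TRUE)
  }
  expect_error(render_report(obs, "/nonexistent-dir/x/r.png"), "write|render")
})

test_that("single-fraction input degrades to the three fraction-level panels", {
  obs <- tibble::tibble(sequence = c("GGK", "ELVISK"), fraction = 1L,
                        pI = NA_real_, mw = NA_real_, score = NA_real_)
  dir <- withr::local_tempdir()
  expect_message(
    res <- render_report(obs, file.path(dir, "one.png")),
    "Fewer than 2 fractions")
  expect_named(res$panels, c("A", "B", "C"))
  expect_true(file.exists(file.path(dir, "one.png")))
})

test_that("panel colour maps are injective and shared across panels", {
  summ <- fixture_summaries()
  scol <- pepfrac:::span_colour_map(summ$n_span)
  fcol <- pepfrac:::fraction_colour_map(1:3)
  expect_false(anyDuplicated(scol) > 0)
  expect_false(anyDuplicated(fcol) > 0)
  pC <- panel_span_bitmap(summ, colour_map = scol)
  built <- ggplot2::ggplot_build(pC$plot)
  expect_true(all(unique(built$data[[1]]$fill) %in% scol))
})
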