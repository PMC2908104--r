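test_that("peptide tables load with duplicate collapse keeping the best score", {
  df <- tibble::tibble(
    sequence = c("PEPTIDE", "PEPTIDE", "ACDK", "ACDK"),
    fraction = c(1L, 2L, 1L, 1L),
    pI = c(NA, NA, NA, NA), mw = NA_real_,
    score = c(50, 60, 80, 30))
  path <- write_peptide_tsv(df)
  obs <- read_peptide_table(path)
  expect_equal(nrow(obs), 3L)
  expect_equal(max(obs$fraction), 2L)
  expect_equal(obs$score[obs$sequence == "ACDK"], 80)
})

test_that("empty optional columns and header-only files are handled", {
  df <- tibble::tibble(sequence = c("GGK", "AAR"), fraction = c(1L, 2L),
                       pI = c("", ""), mw = c("", ""), score = c("", ""))
  obs <- read_peptide_table(write_peptide_tsv(df))
  expect_true(all(is.na(obs$pI)))
  expect_true(all(is.na(obs$mw)))

  empty <- read_peptide_table(write_peptide_tsv(df[0, ]))
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("sequence", "fraction", "pI", "mw", "score"))
})

test_that("format errors name the column or line", {
  df <- tibble::tibble(seq = "GGK", fraction = 1L)
  expect_error(read_peptide_table(write_peptide_tsv(df)),
               "mandatory column 'sequence'")
  df2 <- tibble::tibble(sequence = c("GGK", "AAR"),
                        fraction = c("1", "banana"))
  expect_error(read_peptide_table(write_peptide_tsv(df2)),
               "line 3")
  df3 <- tibble::tibble(sequence = c("GGK", "AB1"), fraction = c(1L, 2L))
  expect_error(read_peptide_table(write_peptide_tsv(df3)), "Line 3")
})

test_that("column remapping reads foreign dialects", {
  df <- tibble::tibble(pep_seq = "ELVISK", well = 3L, ionscore = 42)
  obs <- read_peptide_table(
    write_peptide_tsv(df),
    peptide_dialect(sequence = "pep_seq", fraction = "well",
                    score = "ionscore"))
  expect_equal(obs$sequence, "ELVISK")
  expect_equal(obs$fraction, 3L)
  expect_equal(obs$score, 42)
})

test_that("fraction ranges validate, sort, and partition evenly", {
  rng <- tibble::tibble(fraction = 1:24,
                        ph_low = seq(3, 10, length.out = 25)[1:24],
                        ph_high = seq(3, 10, length.out = 25)[2:25])
  path <- write_peptide_tsv(rng)
  got <- read_fraction_ranges(path)
  expect_equal(nrow(got), 24L)
  expect_equal(got$ph_high - got$ph_low, rep(7 / 24, 24))

  shuffled <- rng[sample(24), ]
  got2 <- read_fraction_ranges(write_peptide_tsv(shuffled))
  expect_equal(got2$fraction, 1:24)

  bad <- tibble::tibble(fraction = 5L, ph_low = 7.0, ph_high = 6.5)
  expect_error(read_fraction_ranges(write_peptide_tsv(bad)), "ph_low")
  dup <- rng[c(1, 1, 2), ]
  expect_error(read_fraction_ranges(write_peptide_tsv(dup)), "Duplicate")
})

test_that("fill_missing completes locally, never overwrites, and is idempotent", {
  obs <- tibble::tibble(
    sequence = c("GGK", "GGK", "AAR"), fraction = c(1L, 2L, 1L),
    pI = c(NA, NA, 5.2), mw = c(NA, 123.4, NA), score = NA_real_)
  filled <- suppressMessages(fill_missing(obs))
  expect_false(anyNA(filled$pI))
  expect_false(anyNA(filled$mw))
  # user values kept
  expect_equal(filled$pI[filled$sequence == "AAR"], 5.2)
  expect_equal(filled$mw[filled$sequence == "GGK" & filled$fraction == 2], 123.4)
  # same sequence gets identical computed values
  expect_equal(length(unique(filled$pI[filled$sequence == "GGK"])), 1L)
  expect_equal(filled$pI[filled$sequence == "GGK"][1],
               isoelectric_point("GGK"))
  # idempotent; fully-specified input passes through unchanged
  expect_identical(suppressMessages(fill_missing(filled)), filled)
  # a supplied pI far from the computed one is flagged but kept
  expect_message(fill_missing(obs), "differing")
})

test_that("summary tables round-trip exactly", {
  obs <- tibble::tibble(
    sequence = c(rep("VADIGLAAWGR", 12), "ELVISK", "GGK"),
    fraction = c(6:15, 23L, 24L, 5L, 1L),
    pI = NA_real_, mw = NA_real_, score = c(rep(31.5, 12), 60, 70))
  summ <- summarise_peptides(fill_missing(obs))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(summ, path)
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           fractions = readr::col_character()))
  expect_equal(raw$fractions[raw$sequence == "VADIGLAAWGR"],
               "6,7,8,9,10,11,12,13,14,15,23,24")
  back <- read_summary_table(path)
  expect_equal(back$sequence, summ$sequence)
  expect_equal(back$fractions, summ$fractions)
  expect_equal(back$runs, summ$runs)
  for (col in c("n_span", "pI", "mw", "score", "flat_range", "gravy")) {
    expect_equal(back[[col]], summ[[col]], tolerance = 1e-12)
  }
  expect_error(write_summary_table(summ[0, ], path), "non-empty")
})

test_that("peptide table write/read round-trips distinct pairs", {
  withr::local_seed(21)
  df <- tibble::tibble(
    sequence = replicate(30, random_peptide()),
    fraction = sample(1:6, 30, replace = TRUE),
    pI = round(runif(30, 3, 10), 3), mw = round(runif(30, 600, 3000), 4),
    score = round(runif(30, 10, 100), 1))
  obs <- read_peptide_table(write_peptide_tsv(df))
  expect_equal(nrow(obs), nrow(dplyr::distinct(df, sequence, fraction)))
  again <- read_peptide_table(write_peptide_tsv(obs))
  expect_equal(again, obs)
})
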