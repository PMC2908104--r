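# Reproducible synthetic fractionation datasets: random proteins, in-silico
# tryptic digestion, and a pI-window carry-over model of IEF separation.

#' Generate random protein sequences
#'
#' Uniform-residue random sequences over the 20 standard amino acids,
#' reproducible under a seed.
#'
#' @param n Number of proteins, >= 1.
#' @param length_range Integer range `c(min, max)` of protein lengths.
#' @param seed Optional RNG seed; when given, the global RNG state is left
#'   untouched.
#' @return A character vector of `n` sequences.
#' @export
random_proteins <- function(n, length_range = c(200, 500), seed = NULL) {
  stopifnot(n >= 1, length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2])
  gen <- function() {
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    }, character(1))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P (the
#' standard trypsin rule). With `missed_cleavages = m`, every join of up to
#' `m + 1` consecutive fully-cleaved fragments is also produced. Peptides
#' shorter than `min_length` are dropped from the returned set (set
#' `min_length = 1` to keep everything; the zero-missed-cleavage fragments
#' then concatenate back to the protein).
#'
#' @param protein Protein sequence (uppercase one-letter string).
#' @param missed_cleavages Maximum number of missed cleavages, >= 0.
#' @param min_length Minimum reported peptide length (default 6, a typical
#'   lower bound for confident MS/MS identification).
#' @return Character vector of peptides, in N-to-C order of their start
#'   positions.
#' @export
#' @examples
#' tryptic_digest("AAKAAR", min_length = 1)  # "AAK" "AAR"
#' tryptic_digest("AAKPAA", min_length = 1)  # no cleavage before P
tryptic_digest <- function(protein, missed_cleavages = 0, min_length = 6) {
  res <- check_sequence(protein)
  stopifnot(missed_cleavages >= 0, min_length >= 1)
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[cut_after + 1] != "P" |
                           cut_after == n]
  bounds <- c(0, cut_after, if (length(cut_after) == 0 ||
                                max(cut_after) < n) n)
  starts <- head(bounds, -1) + 1
  ends <- tail(bounds, -1)
  frags <- substring(protein, starts, ends)
  out <- character(0)
  for (m in 0:missed_cleavages) {
    if (m + 1 > length(frags)) break
    idx <- seq_len(length(frags) - m)
    out <- c(out, vapply(idx, function(i) {
      paste(frags[i:(i + m)], collapse = "")
    }, character(1)))
  }
  out[nchar(out) >= min_length]
}

even_ranges <- function(n_fractions, ph_low, ph_high) {
  edges <- seq(ph_low, ph_high, length.out = n_fractions + 1)
  tibble::tibble(fraction = seq_len(n_fractions),
                 ph_low = head(edges, -1), ph_high = tail(edges, -1))
}

#' Simulate IEF fractionation of a peptide set
#'
#' A generative carry-over model encoding the qualitative mechanism that
#' peptides with flat net-charge titration curves around their pI focus
#' poorly: each peptide's apparent pI is its charge-model pI plus Gaussian
#' noise, and the peptide is observed in every fraction whose pH interval
#' intersects the window `apparent_pI +/- w` with
#' `w = spread_alpha * flat_range / 2`. Fraction pH intervals partition
#' `[ph_low, ph_high]` evenly (or follow a supplied range table). Peptides
#' whose window misses the gradient entirely are clamped to the nearest
#' boundary fraction, as the physical device accumulates out-of-gradient
#' analytes in the end wells. This is a test harness emulating the
#' statistical structure of such experiments, not a transport model of the
#' electrophoresis.
#'
#' @param peptides Character vector of peptide sequences (deduplicated
#'   internally).
#' @param n_fractions Number of fractions (default 24).
#' @param ph_low,ph_high Gradient bounds (defaults 3 and 10).
#' @param spread_alpha Dimensionless coupling of the flat-charge range to
#'   carry-over (default 0.5); 0 disables spreading.
#' @param noise_sigma Gaussian error on the apparent pI, pH units
#'   (default 0.1); 0 disables noise.
#' @param score_range Uniform range for simulated identification scores.
#' @param ranges Optional fraction range tibble overriding the even
#'   partition.
#' @param seed Optional RNG seed (global RNG state untouched when given).
#' @param pka,threshold Charge model configuration.
#' @return A list with `observations` (tibble sequence/fraction/pI/mw/
#'   score, the dialect read by [read_peptide_table()]), `ranges`, and
#'   `truth` (per peptide: true pI, apparent pI, flat range, window
#'   half-width and intended fraction set) for recovery tests.
#' @export
simulate_fractionation <- function(peptides, n_fractions = 24,
                                   ph_low = 3, ph_high = 10,
                                   spread_alpha = 0.5, noise_sigma = 0.1,
                                   score_range = c(20, 100), ranges = NULL,
                                   seed = NULL, pka = default_pka(),
                                   threshold = 0.01) {
  stopifnot(length(peptides) >= 1, n_fractions >= 2,
            spread_alpha >= 0, noise_sigma >= 0, ph_low < ph_high)
  peptides <- unique(peptides)
  if (is.null(ranges)) ranges <- even_ranges(n_fractions, ph_low, ph_high)
  ranges <- validate_ranges(ranges)
  n_fractions <- max(ranges$fraction)

  phys <- tibble::tibble(
    sequence = peptides,
    pI_true = purrr::map_dbl(peptides, isoelectric_point, pka = pka),
    flat = purrr::map_dbl(peptides,
                          \(s) flat_range(titration_curve(s, pka), threshold)),
    mw = purrr::map_dbl(peptides, molecular_weight))

  run <- function() {
    apparent <- phys$pI_true + rnorm(nrow(phys), 0, noise_sigma)
    w <- spread_alpha * phys$flat / 2
    wlo <- apparent - w
    whi <- apparent + w
    fracs <- purrr::map2(wlo, whi, function(lo, hi) {
      hit <- which(hi >= ranges$ph_low & lo < ranges$ph_high)
      if (length(hit) == 0) {
        # window misses the gradient: clamp to the nearest boundary well
        hit <- if (hi < ranges$ph_low[1]) 1L else n_fractions
      }
      as.integer(ranges$fraction[hit])
    })
    obs <- tibble::tibble(sequence = phys$sequence, pI = phys$pI_true,
                          mw = phys$mw, fraction = fracs) |>
      tidyr::unnest_longer("fraction")
    obs$score <- round(runif(nrow(obs), score_range[1], score_range[2]), 1)
    truth <- tibble::tibble(
      sequence = phys$sequence, pI_true = phys$pI_true,
      apparent_pI = apparent, flat_range = phys$flat, half_width = w,
      fractions = fracs)
    list(observations = obs[c("sequence", "fraction", "pI", "mw", "score")],
         ranges = ranges, truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a full IEF experiment from random proteins
#'
#' Convenience wrapper: [random_proteins()] -> [tryptic_digest()] ->
#' [simulate_fractionation()]. The defaults emulate a 24-fraction pH 3-10
#' peptide-level separation of a tryptic digest yielding on the order of
#' 2000 distinct peptides.
#'
#' @param n_proteins Number of random parent proteins.
#' @param length_range Protein length range.
#' @param missed_cleavages,min_length Digestion parameters,
#'   see [tryptic_digest()].
#' @param seed RNG seed driving both sequence generation and
#'   fractionation noise.
#' @param ... Passed to [simulate_fractionation()].
#' @return As [simulate_fractionation()], plus element `proteins`.
#' @export
simulate_ief_experiment <- function(n_proteins = 100,
                                    length_range = c(200, 500),
                                    missed_cleavages = 0, min_length = 6,
                                    seed = NULL, ...) {
  proteins <- random_proteins(n_proteins, length_range, seed = seed)
  peptides <- unique(unlist(lapply(proteins, tryptic_digest,
                                   missed_cleavages = missed_cleavages,
                                   min_length = min_length)))
  sim_seed <- if (is.null(seed)) NULL else seed + 1L
  out <- simulate_fractionation(peptides, seed = sim_seed, ...)
  out$proteins <- proteins
  out
}
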