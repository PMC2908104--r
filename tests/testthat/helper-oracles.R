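# Independent oracles and fixture builders shared across tests.
# Oracle code deliberately takes different computational routes than the
# package (matrix algebra on explicit group lists, Monte-Carlo sampling,
# brute-force set operations).

# Net charge of a peptide on a pH vector, via explicit group-pKa lists and
# matrix evaluation (independent of pepfrac::net_charge's accumulation).
oracle_charge <- function(sequence, ph, pka = default_pka()) {
  res <- strsplit(sequence, "")[[1]]
  pos <- c(pka$nterm, unname(pka$side[res[res %in% pka$basic]]))
  neg <- c(pka$cterm, unname(pka$side[res[res %in% pka$acidic]]))
  pos_m <- 1 / (1 + 10^outer(ph, pos, `-`))
  neg_m <- 1 / (1 + 10^(-outer(ph, neg, `-`)))
  rowSums(pos_m) - rowSums(neg_m)
}

# Brute-force pI: argmin of |charge| on a 0.001-step grid.
oracle_pi_grid <- function(sequence, pka = default_pka(), step = 0.001) {
  grid <- seq(step, 14 - step, by = step)
  grid[which.min(abs(oracle_charge(sequence, grid, pka)))]
}

# Monte-Carlo lens area: sample uniformly in the smaller circle (polar),
# count the fraction also inside the larger circle at distance d.
# Returns the estimate and its standard error.
oracle_mc_lens <- function(r1, r2, d, n = 1e6) {
  rmin <- min(r1, r2); rmax <- max(r1, r2)
  th <- runif(n, 0, 2 * pi)
  rr <- rmin * sqrt(runif(n))
  x <- rr * cos(th); y <- rr * sin(th)
  inside <- (x - d)^2 + y^2 <= rmax^2
  p <- mean(inside)
  disk <- pi * rmin^2
  list(area = disk * p, se = disk * sqrt(p * (1 - p) / n))
}

random_peptide <- function(min_len = 6, max_len = 30) {
  paste(sample(pepfrac:::AA_ALPHABET, sample(min_len:max_len, 1),
               replace = TRUE), collapse = "")
}

# A tiny hand-checkable summaries table (built through the package API).
toy_observations <- function() {
  tibble::tibble(
    sequence = c("ACDK", "ACDK", "ACDK", "ELVISK", "PEPTIDER",
                 "PEPTIDER", "GWGK"),
    fraction = c(1L, 2L, 3L, 1L, 2L, 4L, 4L),
    pI = NA_real_, mw = NA_real_,
    score = c(40, 55, 40, 70, 20, 25, 90))
}

write_peptide_tsv <- function(df, path = withr::local_tempfile(
                                fileext = ".tsv",
                                .local_envir = parent.frame())) {
  readr::write_tsv(df, path, progress = FALSE, na = "")
  path
}
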