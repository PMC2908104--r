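---
title: "Methods: peptide IEF fractionation QC in pepfrac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide IEF fractionation QC in pepfrac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepfrac)
```

## The problem

Liquid-phase isoelectric focussing (e.g. OFFGEL devices) separates a
peptide mixture into discrete wells along an immobilised pH gradient;
each well ("fraction") is then analysed by LC-MS/MS. Ideally every
peptide is recovered in the one fraction whose pH interval contains its
isoelectric point. Real separations leak: peptides appear in several
fractions, mostly adjacent ones, and the leakage concentrates where
focussing is physically hard. `pepfrac` quantifies that leakage from a
plain table of identifications and visualises it.

## Charge model

The net charge of a peptide at a given pH is the Henderson–Hasselbalch
sum over its ionizable groups: the free N-terminus and the H, K, R side
chains contribute $1/(1 + 10^{\mathrm{pH} - pK})$ each; the free
C-terminus and the D, E, C, Y side chains contribute
$-1/(1 + 10^{pK - \mathrm{pH}})$ each, one term per residue occurrence.
The model assumes independent titration of groups with fixed pKa values —
no electrostatic coupling, no temperature or ionic-strength correction,
and no post-translational modifications (sequences must be plain
one-letter strings).

**pKa values.** The package defaults to the EMBOSS free-amino-acid set
(N-terminus 8.6, C-terminus 3.6; side chains C 8.5, D 3.9, E 4.1, H 6.5,
K 10.8, R 12.5, Y 10.1), shipped as an editable TSV
(`inst/extdata/pka_default.tsv`) and loadable with `read_pka_config()`.
Published pKa sets differ by a few tenths of a pH unit; every computed
pI and flat-range value depends on this choice, so the default is pinned
by the test suite and documented rather than silently assumed.

**Cysteine.** Most proteomics workflows alkylate cysteines, which
abolishes the thiol's titration. `default_pka(ionize_cys = FALSE)`
removes C from the acidic groups; the default keeps it ionizable, which
is correct for underivatised peptides.

**Titration curve and flat-charge range.** The curve is evaluated on the
fixed grid pH 1.0–14.0 in 0.1 steps (131 points). The flat-charge range
is the grid measure of the low-charge region: $0.1 \times$ the number of
grid points with $|Q| \le \tau$, default threshold $\tau = 0.01$
elementary charges, inclusive (inclusivity is immaterial off the exact
boundary; we fix it for determinism). This grid-count convention means
the saturated value is 13.1 — all 131 points — not 13.0; we accept that
quirk rather than switch to interpolated interval lengths, because the
grid count is the literal, reproducible definition on the stated grid.
Peptides with a wide flat range feel almost no restoring force near
their pI and are the ones expected to focus poorly.

**pI.** Solved on the *continuous* charge function (not the 0.1 grid) by
`uniroot()` bisection over (0, 14) with a tight tolerance, so
$|Q(\mathrm{pI})| < 10^{-6}$. The free termini guarantee at least one
acidic and one basic group, so a root always exists and the monotone
charge function makes it unique. Tests verify agreement within 0.01 pH
against a brute-force 0.001-step grid argmin.

**Mass and hydropathy.** Molecular weight is the sum of residue masses
plus one water, monoisotopic by default (IUPAC atomic masses), average
optionally. GRAVY is the mean Kyte–Doolittle hydropathy; the scale is a
replaceable named vector.

## Span accounting

A peptide identified in $n$ distinct fractions is *n-spanned*; 1-span
peptides are *unique*. Per peptide we also decompose the fraction set
into maximal runs of consecutive indices, e.g. {6..15, 23, 24} has
spans 12 and runs (10, 2). Two definitions were genuinely open:

- **"Spread across adjacent fractions only."** We count a non-unique
  peptide as adjacent-only when its fraction set forms a single
  contiguous run (run count = 1). Alternatives (counting pairwise
  co-occurrences, or spans) exist; the per-peptide contiguity reading is
  the most direct and is what `span_distribution()` reports as
  `pct_contiguous_spreads`.
- **Plot identifiers.** Identifiers are "arbitrary, based on span
  width"; to make figures reproducible we fix the total order
  (n_span, first fraction, pI, sequence) and number consecutively, so
  equal-span peptides occupy contiguous identifier blocks.

Empty fractions are retained in all outputs with zero counts so that
panels align with the physical well layout (e.g. a 24-well device).

## Overlap geometry

For each adjacent pair, circle areas encode fraction sizes and the lens
(two-circle intersection) area encodes the shared-peptide count, with a
single global area constant $k$ chosen so the largest fraction has a
fixed maximum radius. The lens area has the closed form

$$A(d) = r_1^2 \cos^{-1}\!\frac{d^2 + r_1^2 - r_2^2}{2 d r_1}
       + r_2^2 \cos^{-1}\!\frac{d^2 + r_2^2 - r_1^2}{2 d r_2}
       - \tfrac{1}{2}\sqrt{(-d + r_1 + r_2)(d + r_1 - r_2)(d - r_1 + r_2)(d + r_1 + r_2)}$$

which is continuous and strictly decreasing in the centre distance $d$
on $(|r_1 - r_2|,\, r_1 + r_2)$. `solve_distance()` inverts it by
bisection (up to 200 halvings, relative area tolerance $10^{-12}$ — far
inside the $10^{-7}$ the tests require). Degenerate targets are clamped
exactly: zero sharing places the pair tangent ($d = r_1 + r_2$; compact
chains rather than arbitrary gaps), and a shared count equal to the
smaller fraction clamps to containment ($d = |r_1 - r_2|$). The
intersection points $\bigl((d^2 + r_1^2 - r_2^2)/2d,\ \pm\sqrt{r_1^2 -
x^2}\bigr)$ feed the arc rendering and are verified to lie on both
circles within $10^{-9}$. A shared count exceeding the smaller fraction
is an infeasibility error — it cannot arise from `adjacent_overlaps()`,
whose counts are set intersections.

The chain layout places each pair's solved distance sequentially on a
common baseline. Because only adjacent pairs carry meaning, non-adjacent
circles may incidentally overlap visually; this is accepted and
documented rather than corrected by force-directed adjustment. Empty
fractions are drawn as zero-radius markers with a small fixed gap.
Monte-Carlo validation in the tests samples uniformly inside the
smaller circle and accepts the solved layout when the estimate is
within 1% of the target or within 4 Monte-Carlo standard errors —
for small shared counts the 1% band is below the sampling noise floor
of $10^6$ points, so the standard-error criterion is the binding one
there.

## The report

`render_report()` assembles five panels with aligned fraction axes:

- **A** box plot of peptide pI per fraction, with expected pH ranges
  overlaid as dotted step lines when provided;
- **B** percentage of unique peptides per fraction (0–100);
- **C** the fractionation-pattern bitmap: one row per peptide
  (identifier), one fixed-width cell per fraction membership, coloured
  by n-span category — contiguous memberships read as horizontal
  segments;
- **D** the area-proportional overlap chain, lens arcs drawn from the
  computed intersection points, shared counts printed in the lenses;
- **E** the segment stack: per fraction, peptides sorted by the chosen
  key (default pI) as centred horizontal segments, column width
  proportional to fraction size, segment length mapping the sort value
  linearly onto [0.2, 1] of the column width (so minimal values stay
  visible), and adjacent co-occurrences joined by lines grey-graded by
  flat-charge range (darker = wider). Grey normalisation uses the
  dataset's flat-range min/max by default; fixed bounds can be supplied
  to compare reports.

Every panel function returns its plot-ready data structure alongside the
ggplot, so all numeric assertions in the test suite run on the data
layer without rasterisation. Colour maps (fraction → colour, n-span →
colour) are built once per report and shared across panels. Output
formats are PNG, PDF and SVG; with the cairo SVG device text is outlined
into glyph paths, so the fraction labels and shared counts are
additionally embedded as an SVG `<desc>` element, keeping the file
text-searchable. Rendering writes to a temporary file first, so a
failure leaves no partial output.

## Synthetic data

The generator emulates the statistical structure the tool assumes, so
that every stage is testable without experimental data:

1. uniform-residue random proteins (default 100 proteins of 200–500
   residues);
2. in-silico tryptic digestion (cleave after K/R, not before P;
   optional missed cleavages; reported peptides ≥ 6 residues) — with the
   defaults this yields on the order of 2000 distinct peptides;
3. fraction assignment: 24 fractions evenly partitioning pH 3–10 by
   default; each peptide's apparent pI is its computed pI plus Gaussian
   noise (σ = 0.1 pH), and it is observed in every fraction whose
   interval intersects the window apparent pI ± *w*, where
   *w* = `spread_alpha` · flat_range / 2 (default `spread_alpha` 0.5).
   Out-of-gradient peptides clamp to the boundary wells, as the physical
   device accumulates them in the end reservoirs. Scores are uniform on
   [20, 100].

The window model is a *test harness*, built to embody one qualitative
mechanism — flat titration curves cause spreading — not a transport
simulation of electrophoresis. Its spread couples monotonically to
`spread_alpha` and to the flat-charge range, which the acceptance suite
verifies (including a permutation test of the flat-range/n-span rank
correlation). What it does **not** reproduce about real data: gapped
(non-contiguous) spreads — the window always produces runs, so real
datasets' occasional gaps never occur here with zero noise; realistic
amino-acid composition (residues are uniform, so the pI distribution is
more bimodal than a real proteome digest); MS detectability, intensity
and identification-error (FDR) structure; and manufacturer-calibrated,
non-even pH ranges (a real range table can be supplied instead of the
even partition). Passing tests therefore demonstrate correctness of the
accounting, geometry and rendering, not a validated physical model of a
particular device.

## Numerical and interface choices

- Duplicate (sequence, fraction) rows collapse keeping the maximum
  score — the usual convention for repeated spectrum matches.
- `fill_missing()` never overwrites user-supplied pI/MW; a supplied pI
  more than 1 pH unit from the computed value triggers a message, since
  silent disagreement between external and internal charge models is a
  common source of confusing box plots.
- Sorting ties (equal pI/mass/score) break by sequence lexicographic
  order, making every ordering deterministic.
- Test and acceptance problem sizes: 500 random peptides for the
  charge/pI and flat-range sweeps, 500 random radius/count triples (each
  Monte-Carlo-checked with $10^6$ samples) for the geometry, 30 proteins
  (≈600 peptides) per generator-regime simulation, and one full-scale
  end-to-end run with ~2000 peptides — sizes at which each property is
  sharply testable while the whole suite stays quick on one CPU.

## Known limitations

- No PTM support: modified-residue annotations in sequence strings are
  rejected, not parsed.
- The charge model's accuracy is bounded by the chosen pKa set; pI
  values for short, unusual peptides can deviate substantially from
  experiment regardless of the set.
- Three-way (and wider) overlaps are not counted or drawn; the diagram
  is pairwise-adjacent by design.
- Panel E's column-width and segment-length rules are declared
  conventions ("proportional" admits many mappings), chosen for
  legibility and documented above.
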