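# Area-proportional two-circle overlap geometry for the Venn-like chain.

#' Circle radius for a peptide count
#'
#' Area-proportional encoding: the circle for a fraction of `n` peptides
#' has area `k * n`, hence radius `sqrt(k * n / pi)`. Empty fractions get
#' radius zero.
#'
#' @param n Peptide count(s), >= 0; vectorised.
#' @param k Area per peptide (layout units squared), > 0.
#' @return Radius in layout units.
#' @export
radius_for_count <- function(n, k) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    abort("`k` must be a single positive number.")
  }
  stopifnot(all(n >= 0))
  sqrt(k * n / pi)
}

#' Area of the lens (intersection) of two circles
#'
#' Closed-form circular-segment area for circles of radii `r1`, `r2` with
#' centre separation `d`: zero when the circles are disjoint or tangent
#' (`d >= r1 + r2`), the full smaller circle when one contains the other
#' (`d <= |r1 - r2|`), and strictly decreasing in `d` in between.
#'
#' @param r1,r2 Circle radii, > 0.
#' @param d Centre separation, >= 0. Vectorised.
#' @return Lens area in layout units squared.
#' @export
lens_area <- function(r1, r2, d) {
  if (any(c(r1, r2) <= 0) || any(d < 0)) {
    abort("Radii must be positive and distance non-negative.")
  }
  vapply(d, function(dd) {
    if (dd >= r1 + r2) return(0)
    if (dd <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
    a1 <- (dd^2 + r1^2 - r2^2) / (2 * dd * r1)
    a2 <- (dd^2 + r2^2 - r1^2) / (2 * dd * r2)
    tri <- (-dd + r1 + r2) * (dd + r1 - r2) * (dd - r1 + r2) * (dd + r1 + r2)
    r1^2 * acos(pmin(pmax(a1, -1), 1)) +
      r2^2 * acos(pmin(pmax(a2, -1), 1)) -
      0.5 * sqrt(max(tri, 0))
  }, numeric(1))
}

#' Solve the centre distance realising a target lens area
#'
#' Inverts [lens_area()] by bisection on the monotone open interval
#' `(|r1 - r2|, r1 + r2)`. A zero target places the circles tangent
#' (`d = r1 + r2`, regime "disjoint"); a target equal to the smaller
#' circle's area clamps to containment (`d = |r1 - r2|`); otherwise the
#' two circle-intersection points are reported in the left circle's frame
#' (left centre at the origin, right centre at `(d, 0)`).
#'
#' @param r1,r2 Circle radii, > 0.
#' @param target_area Desired lens area in `[0, pi * min(r1, r2)^2]`.
#' @param tol Relative tolerance on the achieved area.
#' @return A one-row tibble with columns `distance`, `lens_area`, `regime`
#'   (`"disjoint"`, `"overlapping"` or `"contained"`), and `px`, `py`: the
#'   intersection points are `(px, +py)` and `(px, -py)` (NA outside the
#'   overlapping regime).
#' @export
solve_distance <- function(r1, r2, target_area, tol = 1e-12) {
  if (any(c(r1, r2) <= 0)) abort("Radii must be positive.")
  amax <- pi * min(r1, r2)^2
  if (target_area < 0 || target_area > amax * (1 + 1e-9)) {
    abort(paste0("Infeasible target area ", format(target_area),
                 ": shared count would exceed the smaller fraction",
                 " (max ", format(amax), ")."))
  }
  out <- function(d, regime) {
    if (regime == "overlapping") {
      px <- (d^2 + r1^2 - r2^2) / (2 * d)
      py <- sqrt(max(r1^2 - px^2, 0))
    } else {
      px <- NA_real_; py <- NA_real_
    }
    tibble::tibble(distance = d, lens_area = lens_area(r1, r2, d),
                   regime = regime, px = px, py = py)
  }
  if (target_area <= 0) return(out(r1 + r2, "disjoint"))
  if (target_area >= amax) return(out(abs(r1 - r2), "contained"))
  lo <- abs(r1 - r2); hi <- r1 + r2
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    a <- lens_area(r1, r2, mid)
    if (abs(a - target_area) <= tol * max(1, target_area)) break
    if (a > target_area) lo <- mid else hi <- mid
  }
  out(mid, "overlapping")
}

#' Lay out the chain of area-proportional fraction circles
#'
#' Chooses the area constant `k` so the largest fraction's circle has
#' radius `max_radius`, places all fraction circles left-to-right on a
#' common horizontal baseline, and sets each consecutive centre distance
#' by solving the pairwise overlap for the shared-peptide count
#' (`target area = k * shared`). Pairs are solved independently, matching
#' the pairwise-only semantics of the diagram: non-adjacent circles may
#' incidentally overlap without meaning. Pairs with zero sharing are
#' placed tangent; empty fractions become zero-radius markers advanced by
#' a small gap so the axis stays continuous.
#'
#' @param overlaps Adjacent-overlap tibble from [adjacent_overlaps()].
#' @param max_radius Radius of the largest fraction's circle (layout
#'   units).
#' @return A list with `circles` (tibble fraction/n_peptides/radius/cx/cy),
#'   `lenses` (the per-pair [solve_distance()] solutions with global
#'   intersection coordinates `gx`, `gy` and label position `label_x`) and
#'   the constant `k`.
#' @export
layout_chain <- function(overlaps, max_radius = 1) {
  stopifnot(is.data.frame(overlaps), nrow(overlaps) >= 1)
  sizes <- c(overlaps$size_left, overlaps$size_right[nrow(overlaps)])
  fractions <- c(overlaps$left, overlaps$right[nrow(overlaps)])
  if (max(sizes) == 0) abort("All fractions are empty; nothing to lay out.")
  k <- pi * max_radius^2 / max(sizes)
  radii <- radius_for_count(sizes, k)
  gap <- max_radius * 0.05  # spacing next to zero-radius markers
  lenses <- purrr::pmap(overlaps, function(left, right, shared,
                                           size_left, size_right, ...) {
    r1 <- radii[left]; r2 <- radii[right]
    if (r1 == 0 || r2 == 0) {
      tibble::tibble(distance = r1 + r2 + gap, lens_area = 0,
                     regime = "disjoint", px = NA_real_, py = NA_real_)
    } else {
      solve_distance(r1, r2, k * shared)
    }
  }) |> purrr::list_rbind()
  cx <- cumsum(c(0, lenses$distance))
  circles <- tibble::tibble(fraction = fractions, n_peptides = sizes,
                            radius = radii, cx = cx, cy = 0)
  lenses <- dplyr::bind_cols(overlaps, lenses) |>
    dplyr::mutate(
      gx = cx[.data$left] + .data$px,
      gy = .data$py,
      label_x = ifelse(is.na(.data$px),
                       (cx[.data$left] + cx[.data$right]) / 2,
                       cx[.data$left] + .data$px))
  list(circles = circles, lenses = lenses, k = k)
}
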