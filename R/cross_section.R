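#' Create a measured cross-section
#'
#' A cross-section is one measured transverse profile of the body. Its
#' "identity segment" `d` is the portion of the slicing line truncated by the
#' body outline — the maximum section height in a side view (or maximum width
#' in a dorsal/ventral view) — and is the shared measurement linking the
#' silhouette and the cross-sectional profile. At slab boundaries the enclosed
#' area `S` and perimeter `C` must also be measured; at interior (subslab)
#' stations only `d` is needed.
#'
#' @param station Axial distance from the anterior end (length units).
#' @param d Identity-segment length (same length units, `>= 0`).
#' @param S Enclosed section area (length^2); `NA` at interior stations.
#' @param C Section perimeter (length); `NA` at interior stations.
#' @param label Optional free-text label.
#'
#' @return An object of class `cross_section`.
#' @examples
#' cs <- cross_section(station = 0.2, d = 0.5, S = pi * 0.25^2, C = pi * 0.5)
#' shape_phi(cs$S, cs$d)  # pi/4 for a circle
#' @export
cross_section <- function(station, d, S = NA_real_, C = NA_real_, label = "") {
  stopifnot(is.numeric(station), length(station) == 1L, is.finite(station))
  stopifnot(is.numeric(d), length(d) == 1L, is.finite(d), d >= 0)
  if (!is.na(S) && d > 0 && S <= 0)
    stop("section area S must be positive when measured on a non-degenerate section")
  if (!is.na(C) && d > 0 && C <= 0)
    stop("section perimeter C must be positive when measured on a non-degenerate section")
  x <- list(station = station, d = d, S = as.numeric(S), C = as.numeric(C),
            label = as.character(label))
  class(x) <- "cross_section"
  validate_cross_section(x)
  x
}

#' Validate geometric sanity of a cross-section
#'
#' Checks two necessary conditions for any closed plane curve:
#' the identity segment is a chord, so `C >= 2 d`; and the isoperimetric
#' inequality `C^2 >= 4 pi S` (equality only for a circle). Violations are
#' reported as warnings because they typically indicate measurement error
#' (e.g. mismatched scales between views), not fatal input.
#'
#' @param x A `cross_section`.
#' @param slack Relative slack allowed on both inequalities, to absorb
#'   rasterisation error when measurements come from pixel masks. Default 0.005.
#' @return `x`, invisibly.
#' @export
validate_cross_section <- function(x, slack = 0.005) {
  if (!is.na(x$C) && x$d > 0 && x$C < 2 * x$d * (1 - slack))
    warning(sprintf("section at station %g: perimeter C = %g < 2 d = %g (chord bound violated)",
                    x$station, x$C, 2 * x$d))
  if (!is.na(x$C) && !is.na(x$S) && x$C^2 < 4 * pi * x$S * (1 - slack))
    warning(sprintf("section at station %g: C^2 = %g < 4 pi S = %g (isoperimetric inequality violated)",
                    x$station, x$C^2, 4 * pi * x$S))
  invisible(x)
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> station %.6g  d %.6g  S %.6g  C %.6g%s\n",
              x$station, x$d, x$S, x$C,
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' Area shape ratio of a cross-section
#'
#' The dimensionless ratio `phi = S / d^2` of section area to squared identity
#' segment. It is `pi/4` for a circle, 1 for a square, and is assumed to vary
#' linearly along a slab between measured bases.
#'
#' @param S Section area (> 0).
#' @param d Identity-segment length (> 0).
#' @return The shape ratio `S / d^2`.
#' @seealso [shape_psi()] for the perimeter analogue.
#' @export
shape_phi <- function(S, d) {
  if (any(d <= 0)) stop("degenerate section: d must be > 0 to form phi = S/d^2 (use cone mode at an apex)")
  if (any(S <= 0)) stop("section area S must be > 0")
  S / d^2
}

#' Perimeter shape ratio of a cross-section
#'
#' The dimensionless ratio `psi = C / d` of section perimeter to identity
#' segment: `pi` for a circle, 4 for a square. Any closed section satisfies
#' `psi >= 2` because the identity segment is a chord.
#'
#' @param C Section perimeter (> 0).
#' @param d Identity-segment length (> 0).
#' @return The shape ratio `C / d`.
#' @export
shape_psi <- function(C, d) {
  if (any(d <= 0)) stop("degenerate section: d must be > 0 to form psi = C/d (use cone mode at an apex)")
  if (any(C <= 0)) stop("section perimeter C must be > 0")
  C / d
}

#' Linearly interpolate a shape ratio across a slab
#'
#' Shape ratios are assumed to change linearly from one measured base of a
#' slab to the other; this returns the interpolated value at the k-th of n
#' equally spaced subslab boundaries.
#'
#' @param k Boundary index, `0 <= k <= n` (0 = anterior base, n = posterior).
#' @param n Number of subslabs (>= 1).
#' @param r0,rn Ratio at the anterior and posterior base.
#' @return `k * (rn - r0) / n + r0`.
#' @export
interpolate_ratio <- function(k, n, r0, rn) {
  stopifnot(n >= 1)
  if (any(k < 0) || any(k > n)) stop("subslab boundary index k must lie in [0, n]")
  k * (rn - r0) / n + r0
}
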