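#' Create a slab between two measured cross-sections
#'
#' A slab is the body segment between two measured parallel cross-sections.
#' Mid-body slabs are treated as frusta with two measured bases ("frustum"
#' mode); the terminal slabs of a body may instead be treated as cones whose
#' apex carries `d = 0` ("cone" mode). In cone mode the shape ratios `phi` and
#' `psi` are held constant at the measured base's values, because `S/d^2` and
#' `C/d` are undefined at the apex.
#'
#' The slab is partitioned into `n` equal subslabs. At the `n - 1` interior
#' boundaries only the identity segment is measured (typically read off the
#' silhouette); the shape ratios there are linearly interpolated between the
#' bases (frustum) or held constant (cone).
#'
#' @param anterior,posterior [cross_section()] objects for the two bases,
#'   `posterior$station > anterior$station`. In frustum mode both need `S` and
#'   `C`; in cone mode the apex end has `d = 0` and its `S`, `C` are ignored.
#' @param interior_d Numeric vector of the `n - 1` interior identity segments,
#'   ordered anterior to posterior. `n` is inferred as `length(interior_d) + 1`.
#' @param mode `"frustum"` or `"cone"`. Default `"frustum"` unless one base
#'   has `d = 0`, in which case `"cone"` is chosen automatically.
#' @return An object of class `slab` with fields `anterior`, `posterior`,
#'   `L`, `n`, `interior_d`, `mode`.
#' @examples
#' a <- cross_section(0, d = 2, S = pi, C = 2 * pi)           # circle r = 1
#' apex <- cross_section(3, d = 0)
#' s <- slab(a, apex, interior_d = 2 * (1 - (1:9) / 10), mode = "cone")
#' slab_volume(s)   # exactly pi = (1/3) * (pi/4) * 2^2 * 3
#' @export
slab <- function(anterior, posterior, interior_d = numeric(0), mode = NULL) {
  stopifnot(inherits(anterior, "cross_section"), inherits(posterior, "cross_section"))
  L <- posterior$station - anterior$station
  if (L <= 0) stop("posterior station must exceed anterior station")
  if (any(interior_d < 0)) stop("interior identity segments must be >= 0")
  if (is.null(mode))
    mode <- if (anterior$d == 0 || posterior$d == 0) "cone" else "frustum"
  mode <- match.arg(mode, c("frustum", "cone"))
  if (mode == "frustum") {
    for (b in list(anterior, posterior))
      if (b$d <= 0 || is.na(b$S) || is.na(b$C))
        stop("frustum mode needs d > 0 and measured S, C at both bases")
  } else {
    n_apex <- (anterior$d == 0) + (posterior$d == 0)
    if (n_apex != 1L)
      stop("cone mode needs exactly one base with d = 0 (the apex)")
    base <- if (anterior$d == 0) posterior else anterior
    if (is.na(base$S) || is.na(base$C))
      stop("cone mode needs measured S and C at the non-apex base")
  }
  x <- list(anterior = anterior, posterior = posterior, L = L,
            n = length(interior_d) + 1L, interior_d = as.numeric(interior_d),
            mode = mode)
  class(x) <- "slab"
  x
}

#' @export
print.slab <- function(x, ...) {
  cat(sprintf("<slab %s> [%.6g, %.6g]  L = %.6g, n = %d subslabs\n",
              x$mode, x$anterior$station, x$posterior$station, x$L, x$n))
  invisible(x)
}

# phi, psi and d at all n + 1 subslab boundaries of a slab. Cone mode holds
# the measured base's ratios constant; frustum mode interpolates linearly.
slab_boundary_values <- function(slab) {
  n <- slab$n
  d <- c(slab$anterior$d, slab$interior_d, slab$posterior$d)
  if (slab$mode == "cone") {
    base <- if (slab$anterior$d == 0) slab$posterior else slab$anterior
    phi <- rep(shape_phi(base$S, base$d), n + 1L)
    psi <- rep(shape_psi(base$C, base$d), n + 1L)
  } else {
    k <- 0:n
    phi <- interpolate_ratio(k, n, shape_phi(slab$anterior$S, slab$anterior$d),
                             shape_phi(slab$posterior$S, slab$posterior$d))
    psi <- interpolate_ratio(k, n, shape_psi(slab$anterior$C, slab$anterior$d),
                             shape_psi(slab$posterior$C, slab$posterior$d))
  }
  list(d = d, phi = phi, psi = psi, Ln = slab$L / n)
}

# Subslab coefficient list for a slab, anterior to posterior.
slab_coefficients <- function(slab) {
  bv <- slab_boundary_values(slab)
  lapply(seq_len(slab$n), function(k)
    subslab_coefficients(bv$phi[k], bv$phi[k + 1L], bv$psi[k], bv$psi[k + 1L],
                         bv$d[k], bv$d[k + 1L], bv$Ln))
}

#' Slab volume
#'
#' Sum of the closed-form subslab volumes. Exact for any body whose section
#' area is piecewise-cubic in the axial coordinate under the slab's
#' interpolation scheme (in particular exact for cylinders, circular cones and
#' circular frusta at any subslab count).
#'
#' @param slab A [slab()] object.
#' @return Slab volume.
#' @export
slab_volume <- function(slab) {
  sum(vapply(slab_coefficients(slab), subslab_volume, numeric(1)))
}

#' Slab lateral surface area
#'
#' Sum of the closed-form subslab lateral areas: the integral of section
#' circumference along the axis. See [subslab_lateral_area()] for the
#' distinction from true slant area.
#'
#' @param slab A [slab()] object.
#' @return Slab lateral area.
#' @export
slab_area <- function(slab) {
  sum(vapply(slab_coefficients(slab), subslab_lateral_area, numeric(1)))
}

#' Per-subslab breakdown of a slab
#'
#' Volume, lateral area, local centroid and global centroid station for each
#' subslab; the raw material for mass and centre-of-mass computations.
#'
#' @param slab A [slab()] object.
#' @return A data.frame with one row per subslab: `k`, `start`, `Ln`,
#'   `volume`, `area`, `lbar` (local centroid offset, `NA` for a zero-volume
#'   subslab), `centroid_station`.
#' @export
slab_subslabs <- function(slab) {
  co <- slab_coefficients(slab)
  Ln <- slab$L / slab$n
  vol <- vapply(co, subslab_volume, numeric(1))
  area <- vapply(co, subslab_lateral_area, numeric(1))
  mom <- vapply(co, subslab_first_moment, numeric(1))
  lbar <- ifelse(vol > 0, mom / vol, NA_real_)
  start <- slab$anterior$station + (seq_len(slab$n) - 1L) * Ln
  data.frame(k = seq_len(slab$n), start = start, Ln = Ln,
             volume = vol, area = area, lbar = lbar,
             centroid_station = start + lbar)
}
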