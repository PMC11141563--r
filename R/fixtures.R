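#' Synthetic solids with exact reference values
#'
#' Builds a solid of known geometry for validating the estimators without any
#' external model. Every solid carries its exact volume, its exact lateral
#' (slant) surface area, and its "method area" — the axial integral of section
#' circumference, which is the quantity the cross-sectional method and GDI
#' actually estimate and which understates true slant area on tapering solids.
#' A section sampler returns the analytic `d`, `S`, `C` and the two semi-axes
#' at any station.
#'
#' Kinds and their parameters:
#' \describe{
#'   \item{cylinder}{`r` (radius), `L`. Circular sections.}
#'   \item{cone}{`r` (base radius), `L`. Radius tapers linearly to 0 at the
#'     posterior end.}
#'   \item{frustum}{`r0`, `r1`, `L`. Radius linear from `r0` to `r1`.}
#'   \item{superellipse_loft}{`a`, `b`, `k`, `L`. Constant superellipse
#'     section extruded along the axis.}
#'   \item{revolution_body}{`profile` (function of station returning the
#'     radius, default `0.5 + 0.1 sin(2 pi l)`), `L` (default 1). Circular
#'     sections; exact values by adaptive quadrature of the profile.}
#' }
#'
#' @param shape One of `"cylinder"`, `"cone"`, `"frustum"`,
#'   `"superellipse_loft"`, `"revolution_body"`.
#' @param ... Parameters for the chosen kind (see Details).
#' @return An object of class `synthetic_solid`: a list with `kind`, `length`,
#'   `exact_volume`, `exact_lateral_area`, `method_area`, and `section(l)`
#'   returning a list `d, S, C, a, b` (semi-width `a`, semi-height `b`).
#' @examples
#' s <- make_solid("cone", r = 1, L = 3)
#' c(s$exact_volume, s$method_area, s$exact_lateral_area)  # pi, 3 pi, pi sqrt(10)
#' @export
make_solid <- function(shape = c("cylinder", "cone", "frustum",
                                "superellipse_loft", "revolution_body"), ...) {
  shape <- match.arg(shape)
  p <- list(...)
  solid <- switch(shape,
    cylinder = {
      stopifnot(p$r > 0, p$L > 0)
      r <- p$r; L <- p$L
      list(length = L,
           radius_at = function(l) rep_len(r, length(l)),
           section = function(l) circle_section(rep_len(r, length(l))),
           exact_volume = pi * r^2 * L,
           method_area = 2 * pi * r * L,
           exact_lateral_area = 2 * pi * r * L)
    },
    cone = {
      stopifnot(p$r > 0, p$L > 0)
      r <- p$r; L <- p$L
      list(length = L,
           radius_at = function(l) r * (1 - l / L),
           section = function(l) circle_section(r * (1 - l / L)),
           exact_volume = pi * r^2 * L / 3,
           method_area = pi * r * L,
           exact_lateral_area = pi * r * sqrt(r^2 + L^2))
    },
    frustum = {
      stopifnot(p$r0 > 0, p$r1 >= 0, p$L > 0)
      r0 <- p$r0; r1 <- p$r1; L <- p$L
      list(length = L,
           radius_at = function(l) r0 + (r1 - r0) * l / L,
           section = function(l) circle_section(r0 + (r1 - r0) * l / L),
           exact_volume = pi * L * (r0^2 + r0 * r1 + r1^2) / 3,
           method_area = pi * (r0 + r1) * L,
           exact_lateral_area = pi * (r0 + r1) * sqrt(L^2 + (r1 - r0)^2))
    },
    superellipse_loft = {
      stopifnot(p$a > 0, p$b > 0, p$k > 0, p$L > 0)
      a <- p$a; b <- p$b; k <- p$k; L <- p$L
      A <- superellipse_area(a, b, k)
      P <- superellipse_perimeter(a, b, k)
      list(length = L,
           radius_at = function(l) rep_len(b, length(l)),
           section = function(l) {
             n <- length(l)
             list(d = rep_len(2 * b, n), S = rep_len(A, n), C = rep_len(P, n),
                  a = rep_len(a, n), b = rep_len(b, n), k = k)
           },
           exact_volume = A * L,
           method_area = P * L,
           exact_lateral_area = P * L)
    },
    revolution_body = {
      profile <- if (is.null(p$profile))
        function(l) 0.5 + 0.1 * sin(2 * pi * l) else p$profile
      L <- if (is.null(p$L)) 1 else p$L
      stopifnot(L > 0, all(profile(seq(0, L, length.out = 257)) > 0))
      q <- function(f) stats::integrate(f, 0, L, rel.tol = 1e-12,
                                        subdivisions = 1000L)$value
      eps <- 1e-6 * L
      dprof <- function(l) (profile(pmin(l + eps, L)) - profile(pmax(l - eps, 0))) /
        (pmin(l + eps, L) - pmax(l - eps, 0))
      list(length = L,
           radius_at = profile,
           section = function(l) circle_section(profile(l)),
           exact_volume = pi * q(function(l) profile(l)^2),
           method_area = 2 * pi * q(profile),
           exact_lateral_area = 2 * pi * q(function(l)
             profile(l) * sqrt(1 + dprof(l)^2)))
    })
  solid$kind <- shape
  solid$parameters <- p
  class(solid) <- "synthetic_solid"
  solid
}

circle_section <- function(r) {
  list(d = 2 * r, S = pi * r^2, C = 2 * pi * r, a = r, b = r)
}

#' @export
print.synthetic_solid <- function(x, ...) {
  cat(sprintf("<synthetic_solid %s> L = %g, V = %.8g, method area = %.8g, lateral area = %.8g\n",
              x$kind, x$length, x$exact_volume, x$method_area, x$exact_lateral_area))
  invisible(x)
}

#' Sample CSM measurements from a synthetic solid
#'
#' Emulates the data-collection workflow on a solid of known geometry:
#' identity segments at every subslab station, plus section area and perimeter
#' at slab boundaries, all analytic, with optional multiplicative Gaussian
#' measurement noise. Slabs whose posterior (or anterior) boundary has `d = 0`
#' become cone-mode slabs automatically.
#'
#' @param solid A [make_solid()] object.
#' @param slab_bounds Strictly increasing boundary stations within
#'   `[0, solid$length]`. Default: 12 equal slabs.
#' @param n_subslabs Subslabs per slab (default 10).
#' @param noise_sd Relative standard deviation of multiplicative Gaussian
#'   noise applied independently to every `d`, `S`, `C` (default 0, exact).
#' @param seed Optional integer seed used only when `noise_sd > 0`.
#' @return A [body_measurement()] object.
#' @export
sample_measurements <- function(solid, slab_bounds = NULL, n_subslabs = 10,
                                noise_sd = 0, seed = NULL) {
  stopifnot(inherits(solid, "synthetic_solid"))
  if (is.null(slab_bounds)) slab_bounds <- seq(0, solid$length, length.out = 13L)
  stopifnot(min(slab_bounds) >= 0, max(slab_bounds) <= solid$length)
  st <- slice_stations(slab_bounds, n_subslabs)
  sec <- solid$section(st$station)
  d <- sec$d; S <- sec$S; C <- sec$C
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    jitter <- function(v) v * (1 + stats::rnorm(length(v), sd = noise_sd))
    d <- pmax(jitter(d), 0); S <- pmax(jitter(S), 0); C <- pmax(jitter(C), 0)
  }
  S[!st$is_boundary] <- NA_real_
  C[!st$is_boundary] <- NA_real_
  measurements_to_body(data.frame(station = st$station, d = d, S = S, C = C,
                                  label = ifelse(st$is_boundary, "boundary", "")),
                       boundary_stations = slab_bounds)
}

#' Build a body from a measurement table
#'
#' Converts a `station, d, S, C` table — the CSM's canonical input — into a
#' [body_measurement()]. Slab boundaries are the rows at `boundary_stations`
#' (by default every row with a finite `S`); rows strictly between two
#' boundaries supply the interior identity segments and must be equally
#' spaced. A boundary with `d = 0` makes its slab a cone.
#'
#' @param tab Data.frame with columns `station`, `d`, `S`, `C` (and optional
#'   `label`), sorted by station.
#' @param boundary_stations Optional explicit boundary stations; default is
#'   every station with non-`NA` `S`.
#' @param boundary_tol Passed to [body_measurement()].
#' @return A `body_measurement` (no appendages).
#' @export
measurements_to_body <- function(tab, boundary_stations = NULL,
                                 boundary_tol = 0.01) {
  stopifnot(all(c("station", "d", "S", "C") %in% names(tab)))
  tab <- tab[order(tab$station), , drop = FALSE]
  if (is.null(boundary_stations))
    boundary_stations <- tab$station[!is.na(tab$S)]
  bidx <- match(boundary_stations, tab$station)
  if (anyNA(bidx)) stop("boundary stations missing from the measurement table")
  if (length(bidx) < 2L) stop("need at least two slab boundaries")
  mk_cs <- function(i) {
    dd <- tab$d[i]
    if (dd == 0)
      cross_section(tab$station[i], 0)
    else
      cross_section(tab$station[i], dd, tab$S[i], tab$C[i],
                    if ("label" %in% names(tab)) tab$label[i] else "")
  }
  slabs <- vector("list", length(bidx) - 1L)
  for (s in seq_len(length(bidx) - 1L)) {
    i0 <- bidx[s]; i1 <- bidx[s + 1L]
    interior <- if (i1 > i0 + 1L) tab$d[(i0 + 1L):(i1 - 1L)] else numeric(0)
    if (i1 > i0 + 1L) {
      gaps <- diff(tab$station[i0:i1])
      if (max(gaps) - min(gaps) > 1e-6 * mean(gaps))
        stop(sprintf("interior stations of slab %d are not equally spaced", s))
    }
    slabs[[s]] <- slab(mk_cs(i0), mk_cs(i1), interior)
  }
  body_measurement(slabs, boundary_tol = boundary_tol)
}

#' Extract the two-view profile of a synthetic solid
#'
#' Samples the analytic semi-axes at `n` equally spaced stations, as the
#' comparator methods would read them off the two orthogonal views.
#'
#' @param solid A [make_solid()] object.
#' @param n Number of stations (default 121).
#' @return A [two_view_profile()].
#' @export
solid_profile <- function(solid, n = 121) {
  st <- seq(0, solid$length, length.out = n)
  sec <- solid$section(st)
  two_view_profile(st, half_height = sec$b, half_width = sec$a)
}

#' Render silhouette and section masks of a synthetic solid
#'
#' Rasterises the side-view silhouette (axis along columns, body centred
#' vertically) and one cross-section mask per requested station. Circular
#' sections produce disks, superellipse lofts produce superellipse masks. The
#' default resolution matches the convention of 6000 x 4000 px working
#' images; any resolution large enough to resolve the solid may be used.
#'
#' @param solid A [make_solid()] object.
#' @param stations Stations for section masks (default: none).
#' @param width,height Silhouette raster size in pixels (default 6000 x 4000).
#' @param section_px Section mask raster size (square, default `height`).
#' @return A list with `silhouette` (a [mask_image()]), `scale` (units per
#'   pixel) and `sections` (list of `mask_image`, same order as `stations`).
#' @export
render_masks <- function(solid, stations = numeric(0),
                         width = 6000, height = 4000, section_px = height) {
  stopifnot(inherits(solid, "synthetic_solid"), width >= 50, height >= 50)
  scale <- solid$length / width
  sec_all <- solid$section(seq(0, solid$length, length.out = 513L))
  dmax <- max(sec_all$d, 2 * max(sec_all$a))
  if (dmax / scale > height - 4)
    stop("resolution too small: the body's height does not fit the silhouette raster")
  xc <- (seq_len(width) - 0.5) * scale
  r_of_x <- solid$radius_at(pmin(pmax(xc, 0), solid$length))
  yc <- (seq_len(height) - 0.5 - height / 2) * scale
  sil <- outer(yc, r_of_x, function(y, r) abs(y) <= r) * 1L
  masks <- lapply(stations, function(s0) {
    sec <- solid$section(s0)
    if (sec$d == 0) return(NULL)   # apex: no section to rasterise
    if (max(sec$a, sec$b) / scale > section_px / 2 - 2)
      stop("resolution too small for the section mask")
    u <- (seq_len(section_px) - 0.5 - section_px / 2) * scale
    k <- if (!is.null(sec$k)) sec$k else 2
    m <- outer(u, u, function(y, x)
      (abs(x) / sec$a)^k + (abs(y) / sec$b)^k <= 1) * 1L
    mask_image(m, scale)
  })
  list(silhouette = mask_image(sil, scale), scale = scale, sections = masks)
}
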