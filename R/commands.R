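#' Measure CSM inputs from mask images
#'
#' High-level measurement command: reads a silhouette PNG and one section PNG
#' per slab boundary, measures identity segments, areas and perimeters, and
#' writes the `station, d, S, C` table.
#'
#' @param silhouette_png Path to the side-view mask PNG.
#' @param section_pngs Character vector of section mask PNG paths, one per
#'   slab boundary, anterior to posterior (`NA` entries allowed for apex
#'   boundaries where `d = 0`).
#' @param scale Length units per pixel (required).
#' @param slab_bounds,n_subslabs Partition of the axis; see [slice_stations()].
#' @param out Optional output CSV path.
#' @return The measurement data.frame, invisibly if `out` is given.
#' @export
csm_measure <- function(silhouette_png, section_pngs, scale,
                        slab_bounds, n_subslabs, out = NULL) {
  if (missing(scale) || is.null(scale) || !is.finite(scale))
    stop("a physical scale (length units per pixel) is required")
  sil <- read_mask_png(silhouette_png, scale)
  secs <- lapply(section_pngs, function(p)
    if (is.na(p)) NULL else read_mask_png(p, scale))
  tab <- measure_body(sil, secs, slab_bounds, n_subslabs)
  if (!is.null(out)) {
    write_measurements(tab, out)
    return(invisible(tab))
  }
  tab
}

#' Estimate volume, area and mass from measurements
#'
#' Runs one of the three estimators on a measurement table.
#'
#' * `"csm"`: the cross-sectional method. Needs the full `station, d, S, C`
#'   table; returns volume, lateral area and — when `density` is supplied —
#'   mass and the CM-plane station, plus a per-slab table.
#' * `"gdi"`: Graphic Double Integration on a two-view profile.
#' * `"superellipse"`: superellipse bracketing on a two-view profile; returns
#'   low/mean/high for volume and area.
#'
#' @param measurements For `"csm"`: a measurement data.frame (or CSV path).
#'   For the comparators: a [two_view_profile()] or a data.frame/CSV with
#'   columns `station, half_height, half_width`.
#' @param method `"csm"`, `"gdi"` or `"superellipse"`.
#' @param density Optional [density_model()] (CSM only).
#' @param boundary_stations Optional explicit slab boundaries (CSM only).
#' @param gdi_slabs GDI slab count (default 120).
#' @param k_range Length-2 bracketing exponents (default `c(1.6, 2.4)`).
#' @return A report list; fields depend on the method.
#' @export
csm_estimate <- function(measurements, method = c("csm", "gdi", "superellipse"),
                         density = NULL, boundary_stations = NULL,
                         gdi_slabs = 120, k_range = c(1.6, 2.4)) {
  method <- match.arg(method)
  if (is.character(measurements) && method == "csm")
    measurements <- read_measurements(measurements)
  if (method == "csm") {
    body <- if (inherits(measurements, "body_measurement")) measurements
            else measurements_to_body(measurements, boundary_stations)
    if (is.null(density)) {
      list(method = "csm", volume = body_volume(body), area = body_area(body))
    } else {
      mp <- apply_density(body, density)
      list(method = "csm", volume = mp$volume, area = mp$area,
           mass = mp$mass, cm_station = mp$cm_station,
           slab_table = mp$slab_table)
    }
  } else {
    prof <- as_two_view_profile(measurements)
    if (method == "gdi") {
      g <- gdi_body(prof, n_slabs = gdi_slabs)
      list(method = "gdi", volume = g$volume, area = g$area,
           n_slabs = gdi_slabs)
    } else {
      b <- superellipse_body(prof, k_range[1], k_range[2])
      c(list(method = "superellipse", k_range = k_range), b)
    }
  }
}

as_two_view_profile <- function(x) {
  if (inherits(x, "two_view_profile")) return(x)
  if (is.character(x)) x <- utils::read.csv(x)
  if (!all(c("station", "half_height", "half_width") %in% names(x)))
    stop("comparator methods need a two-view profile: station, half_height, half_width")
  two_view_profile(x$station, x$half_height, x$half_width)
}

#' Validate all three estimators against synthetic solids
#'
#' Runs the cross-sectional method, GDI and superellipse bracketing on a set
#' of synthetic solids with exact reference values and tabulates signed error
#' rates (percent) for volume and area, plus a mean-absolute-error row. Volume
#' errors are against exact volume; area errors are against the method area
#' (axial circumference integral) — except the superellipse column is also
#' against method area for comparability.
#'
#' @param solids Named list of [make_solid()] objects. Default: the standard
#'   fixture suite (cylinder, cone, frustum, two superellipse lofts, sinusoidal
#'   body of revolution).
#' @param n_slabs,n_subslabs CSM partition (defaults 12 and 10).
#' @param gdi_slabs GDI slab count (default 120).
#' @param k_range Superellipse bracket (default `c(1.6, 2.4)`).
#' @param digits Rounding applied to the printed percent columns (default 2);
#'   the `Mean` row is computed from unrounded values and then rounded.
#' @return A data.frame: one row per solid plus a `Mean` row; columns
#'   `model, volume_csm, volume_gdi, volume_se, area_csm, area_gdi, area_se`
#'   (signed percent errors).
#' @export
csm_validate <- function(solids = standard_fixture_suite(),
                         n_slabs = 12, n_subslabs = 10,
                         gdi_slabs = 120, k_range = c(1.6, 2.4),
                         digits = 2) {
  stopifnot(length(solids) >= 1L)
  if (is.null(names(solids)) || any(!nzchar(names(solids))))
    names(solids) <- paste0("solid_", seq_along(solids))
  rows <- lapply(names(solids), function(nm) {
    s <- solids[[nm]]
    bounds <- seq(0, s$length, length.out = n_slabs + 1L)
    body <- sample_measurements(s, bounds, n_subslabs)
    prof <- solid_profile(s, n = gdi_slabs + 1L)
    g <- gdi_body(prof, n_slabs = gdi_slabs)
    se <- superellipse_body(prof, k_range[1], k_range[2])
    data.frame(
      model = nm,
      volume_csm = error_rate(body_volume(body), s$exact_volume),
      volume_gdi = error_rate(g$volume, s$exact_volume),
      volume_se = error_rate(se$volume_mean, s$exact_volume),
      area_csm = error_rate(body_area(body), s$method_area),
      area_gdi = error_rate(g$area, s$method_area),
      area_se = error_rate(se$area_mean, s$method_area))
  })
  tab <- do.call(rbind, rows)
  num <- names(tab)[-1]
  mean_row <- c(model = "Mean", as.list(vapply(tab[num], mean_error, numeric(1))))
  tab <- rbind(tab, as.data.frame(mean_row))
  tab[num] <- lapply(tab[num], round, digits = digits)
  tab
}

#' The standard synthetic fixture suite
#'
#' Cylinder, cone, circular frustum, two constant-section superellipse lofts
#' (k = 1.6 and k = 2.2) and the sinusoidal body of revolution — a set that
#' spans elliptical, sub-elliptical and fluctuating profiles.
#'
#' @return Named list of [make_solid()] objects.
#' @export
standard_fixture_suite <- function() {
  list(
    cylinder = make_solid("cylinder", r = 0.3, L = 1),
    cone = make_solid("cone", r = 0.4, L = 1),
    frustum = make_solid("frustum", r0 = 0.4, r1 = 0.15, L = 1),
    loft_k16 = make_solid("superellipse_loft", a = 0.5, b = 0.5, k = 1.6, L = 1),
    loft_k22 = make_solid("superellipse_loft", a = 0.35, b = 0.25, k = 2.2, L = 1),
    revolution = make_solid("revolution_body"))
}
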