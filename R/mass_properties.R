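#' Define a density model
#'
#' A density model assigns a uniform default density, optional per-slab
#' overrides, and optional zero-density ellipsoidal voids (e.g. a lung
#' simplified to an ellipsoid). A void is axisymmetric about the body axis
#' only in the sense used here: its axial semi-axis is `p` and its transverse
#' semi-axes are `q` and `r`, so its cross-sectional area at axial offset `u`
#' from its centre is `pi q r (1 - u^2 / p^2)`.
#'
#' @param default Default density (mass / length^3, >= 0).
#' @param per_slab Optional named or indexed numeric vector / list mapping
#'   main-body slab index to a density override.
#' @param voids Optional list of voids, each a list with fields `center`
#'   (axial station of the void centre), `p` (axial semi-axis), `q`, `r`
#'   (transverse semi-axes).
#' @return An object of class `density_model`.
#' @examples
#' density_model(1027)                      # seawater-adjusted whole-body mean
#' density_model(1000, voids = list(list(center = 0.4, p = 0.1, q = 0.05, r = 0.04)))
#' @export
density_model <- function(default, per_slab = NULL, voids = list()) {
  stopifnot(is.numeric(default), default >= 0)
  if (!is.null(per_slab)) stopifnot(all(unlist(per_slab) >= 0))
  for (v in voids) {
    stopifnot(all(c("center", "p", "q", "r") %in% names(v)))
    stopifnot(v$p > 0, v$q > 0, v$r > 0)
  }
  x <- list(default = default, per_slab = per_slab, voids = voids)
  class(x) <- "density_model"
  x
}

#' Convert volume to mass
#'
#' @param V Volume (>= 0).
#' @param rho Density (>= 0).
#' @return `V * rho`.
#' @examples
#' volume_to_mass(0.3098, 1027)  # ~318 kg
#' @export
volume_to_mass <- function(V, rho) {
  stopifnot(all(V >= 0), all(rho >= 0))
  V * rho
}

# Volume of an ellipsoid (axial semi-axis p, transverse q, r) between two
# axial planes at offsets u1 <= u2 from its centre, clipped to [-p, p]:
# integral of pi q r (1 - u^2/p^2) = pi q r [u - u^3/(3 p^2)].
ellipsoid_segment_volume <- function(u1, u2, p, q, r) {
  u1 <- pmin(pmax(u1, -p), p); u2 <- pmin(pmax(u2, -p), p)
  if (u2 <= u1) return(0)
  F <- function(u) u - u^3 / (3 * p^2)
  pi * q * r * (F(u2) - F(u1))
}

# First moment of the same segment about the ellipsoid centre:
# integral of pi q r (1 - u^2/p^2) u = pi q r [u^2/2 - u^4/(4 p^2)].
ellipsoid_segment_moment <- function(u1, u2, p, q, r) {
  u1 <- pmin(pmax(u1, -p), p); u2 <- pmin(pmax(u2, -p), p)
  if (u2 <= u1) return(0)
  G <- function(u) u^2 / 2 - u^4 / (4 * p^2)
  pi * q * r * (G(u2) - G(u1))
}

#' Centre-of-mass plane from centroid records
#'
#' The mass-weighted mean axial station: `sum(m x) / sum(m)`. Because the
#' method carries no transverse coordinate system, only the vertical plane
#' containing the centre of mass is determined, reported as its axial station.
#'
#' @param mass Subslab (or slab) masses.
#' @param station Axial station of each centroid.
#' @return Axial station of the CM plane.
#' @export
cm_plane <- function(mass, station) {
  stopifnot(length(mass) == length(station), length(mass) >= 1L)
  total <- sum(mass)
  if (total <= 0) stop("centre of mass undefined: total mass is not positive")
  sum(mass * station) / total
}

#' Apply a density model to a body
#'
#' Converts the body's per-subslab volumes to masses, subtracts zero-density
#' ellipsoidal voids analytically per subslab interval, and locates the
#' vertical plane containing the centre of mass of the main body. Appendage
#' volume, area and mass (at the default density) are included in the totals
#' but excluded from the CM plane, whose axial placement they do not carry.
#'
#' @param body A [body_measurement()] object.
#' @param model A [density_model()] object.
#' @return An object of class `mass_properties`: a list with `volume`, `area`,
#'   `mass`, `cm_station`, and `slab_table` (per-slab volume, area, mass,
#'   centroid station for the main body).
#' @export
apply_density <- function(body, model) {
  stopifnot(inherits(body, "body_measurement"), inherits(model, "density_model"))
  rng <- body_range(body)
  for (v in model$voids)
    if (v$center - v$p < rng[1] - 1e-9 || v$center + v$p > rng[2] + 1e-9)
      stop(sprintf("void [%g, %g] extends outside the main body's axial range [%g, %g]",
                   v$center - v$p, v$center + v$p, rng[1], rng[2]))

  slab_rho <- function(i) {
    ov <- model$per_slab
    if (!is.null(ov)) {
      key <- as.character(i)
      if (!is.null(names(ov)) && key %in% names(ov)) return(as.numeric(ov[[key]]))
      if (is.null(names(ov)) && i <= length(ov) && !is.na(ov[[i]])) return(as.numeric(ov[[i]]))
    }
    model$default
  }

  rows <- list()
  for (i in seq_along(body$slabs)) {
    tb <- slab_subslabs(body$slabs[[i]])
    rho <- slab_rho(i)
    mass <- rho * tb$volume
    # moment about station 0: rho * (integral of l S dl + start * V) per subslab
    moment <- rho * (tb$volume * ifelse(is.na(tb$lbar), 0, tb$lbar) + tb$start * tb$volume)
    void_vol <- numeric(nrow(tb))
    void_mom <- numeric(nrow(tb))
    for (v in model$voids) {
      x0 <- tb$start; x1 <- tb$start + tb$Ln
      for (j in seq_len(nrow(tb))) {
        u1 <- x0[j] - v$center; u2 <- x1[j] - v$center
        dv <- ellipsoid_segment_volume(u1, u2, v$p, v$q, v$r)
        if (dv > 0) {
          void_vol[j] <- void_vol[j] + dv
          void_mom[j] <- void_mom[j] +
            dv * v$center + ellipsoid_segment_moment(u1, u2, v$p, v$q, v$r)
        }
      }
    }
    if (any(void_vol > tb$volume + 1e-9))
      warning(sprintf("slab %d: void volume exceeds subslab volume; body thinner than the void there", i))
    rows[[i]] <- data.frame(
      slab = i, volume = sum(tb$volume), area = sum(tb$area),
      mass = sum(mass - rho * void_vol),
      moment = sum(moment - rho * void_mom))
  }
  st <- do.call(rbind, rows)
  st$centroid_station <- ifelse(st$mass > 0, st$moment / st$mass, NA_real_)
  st$moment <- NULL

  main_mass <- sum(st$mass)
  app_vol <- sum(vapply(body$appendages, body_volume, numeric(1)))
  app_area <- sum(vapply(body$appendages, body_area, numeric(1)))
  out <- list(
    volume = body_volume(body),
    area = body_area(body),
    mass = main_mass + model$default * app_vol,
    cm_station = {
      total_moment <- sum(vapply(seq_len(nrow(st)), function(i)
        st$mass[i] * st$centroid_station[i], numeric(1)), na.rm = TRUE)
      if (main_mass > 0) total_moment / main_mass else NA_real_
    },
    slab_table = st,
    appendage_volume = app_vol,
    appendage_area = app_area)
  class(out) <- "mass_properties"
  out
}

#' @export
print.mass_properties <- function(x, ...) {
  cat("<mass_properties>\n")
  cat(sprintf("  volume      %.6g\n  area        %.6g\n  mass        %.6g\n  cm_station  %.6g\n",
              x$volume, x$area, x$mass, x$cm_station))
  cat(sprintf("  main body: %d slab(s); appendages: volume %.6g, area %.6g\n",
              nrow(x$slab_table), x$appendage_volume, x$appendage_area))
  invisible(x)
}

#' Signed error rate of an estimate, in percent
#'
#' `(calculated - observed) / observed * 100`: positive when the method
#' overestimates, negative when it underestimates.
#'
#' @param calculated Estimated value(s).
#' @param observed True / observed value(s), > 0.
#' @return Signed percent error.
#' @examples
#' error_rate(318, 304.8)  # +4.33
#' @export
error_rate <- function(calculated, observed) {
  if (any(observed <= 0)) stop("observed value must be > 0")
  (calculated - observed) / observed * 100
}

#' Mean absolute error rate, in percent
#'
#' The mean of the absolute error rates — the "Mean" row of a validation
#' table. Invariant under sign flips and reordering.
#'
#' @param rates Vector of signed percent error rates.
#' @return Mean of `abs(rates)`.
#' @export
mean_error <- function(rates) {
  if (length(rates) == 0L) stop("mean error of an empty set is undefined")
  mean(abs(rates))
}
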