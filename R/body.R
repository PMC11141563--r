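#' Assemble a body from ordered slabs and separated appendages
#'
#' A body measurement is an ordered chain of slabs along the sagittal axis
#' (the main body) plus zero or more appendages — protruding structures such
#' as fins, limbs or flukes that were separated from the main body before
#' slicing and are measured independently with the same method. Adjacent
#' slabs must share their boundary section: stations must coincide and the
#' measured `d`, `S`, `C` may differ only within a small relative tolerance
#' (allowance for repeated measurement of the same physical section).
#'
#' @param slabs List of [slab()] objects, ordered anterior to posterior.
#' @param appendages Optional list of `body_measurement` objects (or single
#'   slabs, which are wrapped), one per separated structure.
#' @param boundary_tol Relative tolerance for shared-boundary agreement on
#'   `d`, `S`, `C` (default 0.01).
#' @return An object of class `body_measurement`.
#' @export
body_measurement <- function(slabs, appendages = list(), boundary_tol = 0.01) {
  stopifnot(length(slabs) >= 1L, all(vapply(slabs, inherits, logical(1), "slab")))
  if (length(slabs) > 1L) {
    for (i in seq_len(length(slabs) - 1L)) {
      a <- slabs[[i]]$posterior; b <- slabs[[i + 1L]]$anterior
      if (abs(a$station - b$station) > boundary_tol * max(1e-12, abs(a$station)))
        stop(sprintf("slabs %d and %d do not share a boundary station (%g vs %g)",
                     i, i + 1L, a$station, b$station))
      for (f in c("d", "S", "C")) {
        va <- a[[f]]; vb <- b[[f]]
        if (!is.na(va) && !is.na(vb) && va > 0 &&
            abs(va - vb) > boundary_tol * va)
          stop(sprintf("slabs %d and %d disagree on boundary %s beyond %.1f%% (%g vs %g)",
                       i, i + 1L, f, 100 * boundary_tol, va, vb))
      }
    }
  }
  appendages <- lapply(appendages, function(a) {
    if (inherits(a, "slab")) a <- list(a)
    if (is.list(a) && !inherits(a, "body_measurement"))
      a <- body_measurement(a, boundary_tol = boundary_tol)
    stopifnot(inherits(a, "body_measurement"))
    a
  })
  x <- list(slabs = slabs, appendages = appendages)
  class(x) <- "body_measurement"
  x
}

#' @export
print.body_measurement <- function(x, ...) {
  cat(sprintf("<body_measurement> %d slab(s) over [%.6g, %.6g], %d appendage(s)\n",
              length(x$slabs), x$slabs[[1]]$anterior$station,
              x$slabs[[length(x$slabs)]]$posterior$station, length(x$appendages)))
  invisible(x)
}

#' Total body volume
#'
#' Sum of the slab volumes of the main body plus the volumes of all
#' appendages (additive by construction).
#'
#' @param body A [body_measurement()] object.
#' @return Total volume.
#' @export
body_volume <- function(body) {
  sum(vapply(body$slabs, slab_volume, numeric(1))) +
    sum(vapply(body$appendages, body_volume, numeric(1)))
}

#' Total body lateral surface area
#'
#' Sum of the slab lateral areas of the main body plus all appendages. This
#' is the axial circumference integral, not the true slant area; the two
#' coincide for cylinders.
#'
#' @param body A [body_measurement()] object.
#' @return Total lateral area.
#' @export
body_area <- function(body) {
  sum(vapply(body$slabs, slab_area, numeric(1))) +
    sum(vapply(body$appendages, body_area, numeric(1)))
}

#' Axial extent of the main body
#'
#' @param body A [body_measurement()] object.
#' @return Numeric length-2 vector: anterior and posterior station of the
#'   main body.
#' @export
body_range <- function(body) {
  c(body$slabs[[1]]$anterior$station,
    body$slabs[[length(body$slabs)]]$posterior$station)
}

#' Rescale a body to a target total length
#'
#' Multiplies all stations and identity segments by `target / current length`,
#' areas by its square. Useful for comparing bodies normalised to unit length.
#'
#' @param body A [body_measurement()] object.
#' @param target Target total length of the main body (default 1).
#' @return A rescaled `body_measurement`.
#' @export
body_rescale <- function(body, target = 1) {
  rng <- body_range(body)
  f <- target / (rng[2] - rng[1])
  scale_cs <- function(cs)
    cross_section(cs$station * f, cs$d * f, cs$S * f^2, cs$C * f, cs$label)
  scale_slab <- function(s)
    slab(scale_cs(s$anterior), scale_cs(s$posterior), s$interior_d * f, s$mode)
  body_measurement(lapply(body$slabs, scale_slab),
                   lapply(body$appendages, function(a)
                     body_rescale(a, target = f * diff(body_range(a)))))
}
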