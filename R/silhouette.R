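#' Create a mask image
#'
#' Binary silhouette or cross-section mask with a physical scale. Foreground
#' is any nonzero pixel. The sagittal axis runs along grid columns by default
#' (anterior at column 0); pixel indices are 0-based and a station in length
#' units maps to the nearest pixel-centre column, pixel `j` having its centre
#' at `(j + 0.5) * scale`.
#'
#' @param pixels Numeric/integer/logical matrix, rows x columns; nonzero =
#'   foreground.
#' @param scale Length units per pixel (> 0).
#' @param axis `"cols"` (default) if the sagittal axis runs along columns,
#'   `"rows"` if along rows (the matrix is transposed internally).
#' @return An object of class `mask_image`.
#' @export
mask_image <- function(pixels, scale, axis = c("cols", "rows")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(pixels), is.numeric(scale), scale > 0)
  m <- (pixels != 0) * 1L
  if (axis == "rows") m <- t(m)
  if (!any(m > 0)) stop("mask has no foreground pixels")
  x <- list(pixels = m, scale = scale)
  class(x) <- "mask_image"
  x
}

#' Read a PNG mask
#'
#' Reads an 8-bit grayscale (or any) PNG and thresholds at 0.5 of full scale.
#' Multi-channel images are reduced to their first channel.
#'
#' @param path PNG file path.
#' @param scale Length units per pixel.
#' @param axis See [mask_image()].
#' @return A `mask_image`.
#' @export
read_mask_png <- function(path, scale, axis = "cols") {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  mask_image(img > 0.5, scale, axis)
}

# Nearest pixel-centre column (1-based) for an axial station.
station_to_col <- function(mask, station) {
  extent <- ncol(mask$pixels) * mask$scale
  if (any(station < -1e-9 * extent) || any(station > extent * (1 + 1e-9)))
    stop("station outside the image extent")
  j <- round(station / mask$scale - 0.5) + 1L
  as.integer(pmin(pmax(j, 1L), ncol(mask$pixels)))
}

#' Identity segments along the axis of a silhouette mask
#'
#' At each station, the identity segment is the vertical extent of the
#' foreground in the nearest pixel column, measured as an inclusive pixel span
#' `(max row - min row + 1) * scale` to avoid systematic half-pixel shrinkage.
#' Columns with no foreground return 0.
#'
#' @param mask A [mask_image()].
#' @param stations Axial positions (length units), all within the image.
#' @return Numeric vector of identity-segment lengths.
#' @export
identity_segment_profile <- function(mask, stations) {
  cols <- station_to_col(mask, stations)
  vapply(cols, function(j) {
    rows <- which(mask$pixels[, j] > 0)
    if (length(rows) == 0L) return(0)
    (max(rows) - min(rows) + 1L) * mask$scale
  }, numeric(1))
}

#' Foreground area of a mask
#'
#' Pixel count times `scale^2`, after filling interior holes (the method's
#' section area refers to the outer profile).
#'
#' @param mask A [mask_image()].
#' @return Area in length units squared.
#' @export
region_area <- function(mask) {
  filled <- EBImage::fillHull(mask$pixels)
  sum(filled > 0) * mask$scale^2
}

#' Sub-pixel perimeter of a mask's foreground region
#'
#' Interior holes are filled, the mask is checked to contain exactly one
#' connected foreground component, and the boundary is extracted as a
#' marching-squares contour at level 0.5 of a Gaussian-smoothed copy of the
#' mask (smoothing makes the level crossings sub-pixel; contouring the raw
#' binary mask would overestimate smooth boundaries by several percent). If
#' the region is too small to survive smoothing, the raw contour is used.
#'
#' @param mask A [mask_image()].
#' @param sigma Smoothing standard deviation in pixels (default 1.5).
#' @return Boundary length in length units.
#' @export
region_perimeter <- function(mask, sigma = 1.5) {
  filled <- EBImage::fillHull(mask$pixels)
  lab <- EBImage::bwlabel(filled)
  ncomp <- max(lab)
  if (ncomp != 1L)
    stop(sprintf("mask must contain exactly one connected region, found %d", ncomp))
  # zero border guarantees closed contours
  pad <- 2L + ceiling(3 * sigma)
  z <- matrix(0, nrow(filled) + 2L * pad, ncol(filled) + 2L * pad)
  z[pad + seq_len(nrow(filled)), pad + seq_len(ncol(filled))] <- filled
  g <- EBImage::gblur(z, sigma = sigma)
  if (max(g) <= 0.5) g <- z   # tiny region: fall back to the raw mask
  cl <- grDevices::contourLines(seq_len(nrow(z)), seq_len(ncol(z)), g, levels = 0.5)
  total <- 0
  for (cc in cl) {
    xs <- c(cc$x, cc$x[1]); ys <- c(cc$y, cc$y[1])
    total <- total + sum(sqrt(diff(xs)^2 + diff(ys)^2))
  }
  total * mask$scale
}

#' Subslab station table for a slab partition
#'
#' Given ordered slab boundaries along the axis and a per-slab subslab count,
#' returns every station at which the identity segment must be read: the slab
#' boundaries plus the equally spaced interior subslab boundaries.
#'
#' @param slab_bounds Strictly increasing numeric vector of slab boundary
#'   stations (length >= 2).
#' @param n_subslabs Integer: subslabs per slab; recycled to
#'   `length(slab_bounds) - 1`.
#' @return A data.frame with columns `station`, `slab` (slab index; boundary
#'   stations belong to the slab they start, the final boundary to the last
#'   slab) and `is_boundary`.
#' @export
slice_stations <- function(slab_bounds, n_subslabs) {
  if (is.unsorted(slab_bounds, strictly = TRUE))
    stop("slab bounds must be strictly increasing")
  nslab <- length(slab_bounds) - 1L
  stopifnot(nslab >= 1L, all(n_subslabs >= 1))
  n_subslabs <- rep_len(as.integer(n_subslabs), nslab)
  out <- list()
  for (i in seq_len(nslab)) {
    s <- seq(slab_bounds[i], slab_bounds[i + 1L], length.out = n_subslabs[i] + 1L)
    keep <- if (i < nslab) utils::head(s, -1) else s   # half-open [start, end)
    out[[i]] <- data.frame(station = keep, slab = i,
                           is_boundary = keep %in% slab_bounds[c(i, i + 1L)])
  }
  do.call(rbind, out)
}

#' Cross-check the identity segment between two views
#'
#' The identity segment appears both on the silhouette and on the measured
#' cross-section; a discrepancy beyond tolerance indicates inconsistent
#' scaling or a mis-positioned section.
#'
#' @param d_silhouette Identity segment read from the silhouette (> 0).
#' @param d_section Identity segment read from the cross-section mask (> 0).
#' @param tol Relative tolerance (default 0.01).
#' @return A list with `ok` (logical), `relative_difference` and a `message`.
#' @export
consistency_check <- function(d_silhouette, d_section, tol = 0.01) {
  stopifnot(all(d_silhouette > 0), all(d_section > 0))
  rel <- abs(d_silhouette - d_section) / d_section
  ok <- rel <= tol
  list(ok = ok, relative_difference = rel,
       message = ifelse(ok, "identity segments agree",
                        sprintf("identity segment mismatch: %.2f%% > %.2f%% tolerance",
                                100 * rel, 100 * tol)))
}

#' Measure a full CSM input table from masks
#'
#' Runs the measurement workflow: identity segments at every subslab station
#' from the side-view silhouette, plus area and perimeter of each
#' slab-boundary cross-section mask.
#'
#' @param silhouette A [mask_image()] of the side (or dorsal/ventral) view.
#' @param sections Named or ordered list of [mask_image()]s, one per slab
#'   boundary, anterior to posterior (`length(slab_bounds)` of them).
#' @param slab_bounds,n_subslabs Passed to [slice_stations()].
#' @param check_tol If not `NULL`, tolerance for [consistency_check()] between
#'   the silhouette identity segment and each section mask's own maximum
#'   vertical extent; failures raise warnings.
#' @return A data.frame `station, d, S, C, label` with `S`, `C` populated at
#'   slab boundaries only.
#' @export
measure_body <- function(silhouette, sections, slab_bounds, n_subslabs,
                         check_tol = 0.01) {
  st <- slice_stations(slab_bounds, n_subslabs)
  d <- identity_segment_profile(silhouette, st$station)
  S <- rep(NA_real_, nrow(st)); C <- rep(NA_real_, nrow(st))
  bidx <- which(st$is_boundary)
  if (length(sections) != length(bidx))
    stop(sprintf("need %d section masks (one per slab boundary), got %d",
                 length(bidx), length(sections)))
  for (i in seq_along(bidx)) {
    row <- bidx[i]
    if (d[row] > 0) {
      sec <- sections[[i]]
      if (is.null(sec))
        stop(sprintf("no section mask supplied for slab boundary at station %g", st$station[row]))
      S[row] <- region_area(sec)
      C[row] <- region_perimeter(sec)
      if (!is.null(check_tol)) {
        d_sec <- max(apply(sec$pixels, 2, function(col) {
          r <- which(col > 0)
          if (length(r) == 0L) 0L else max(r) - min(r) + 1L
        })) * sec$scale
        chk <- consistency_check(d[row], d_sec, check_tol)
        if (!chk$ok)
          warning(sprintf("station %g: %s", st$station[row], chk$message))
      }
    } else {
      S[row] <- 0; C[row] <- 0
    }
  }
  data.frame(station = st$station, d = d, S = S, C = C,
             label = ifelse(st$is_boundary, "boundary", ""))
}
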