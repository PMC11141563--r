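# Independent quadrature oracles and randomized-slab generators.
# The oracles integrate the piecewise section-area / circumference functions
# numerically and never touch the closed-form antiderivatives they check.

quad_subslab <- function(coeff, f, moment = FALSE) {
  g <- if (moment) function(l) f(l, coeff) * l else function(l) f(l, coeff)
  stats::integrate(g, 0, coeff$Ln, rel.tol = 1e-12, abs.tol = 0)$value
}

quad_slab_volume <- function(s)
  sum(vapply(crossvol:::slab_coefficients(s), quad_subslab, numeric(1),
             f = section_area_at))

quad_slab_area <- function(s)
  sum(vapply(crossvol:::slab_coefficients(s), quad_subslab, numeric(1),
             f = section_circumference_at))

# Random well-formed slab: shape ratios respect psi >= 2 and the
# isoperimetric bound phi <= psi^2 / (4 pi); d fluctuates irregularly.
random_slab <- function(n = sample(2:8, 1), cone = FALSE) {
  L <- stats::runif(1, 0.5, 3)
  mk_base <- function(station, d) {
    psi <- stats::runif(1, 2.8, 4.5)
    phi <- stats::runif(1, 0.5, 0.95) * psi^2 / (4 * pi)
    cross_section(station, d, S = phi * d^2, C = psi * d)
  }
  d0 <- stats::runif(1, 0.5, 2)
  interior <- pmax(d0 * (1 + cumsum(stats::rnorm(n - 1, 0, 0.08))), 0.05)
  if (cone) {
    interior <- d0 * sort(stats::runif(n - 1, 0.05, 0.95), decreasing = TRUE)
    slab(mk_base(0, d0), cross_section(L, 0), interior_d = interior, mode = "cone")
  } else {
    dn <- stats::runif(1, 0.5, 2)
    slab(mk_base(0, d0), mk_base(L, dn), interior_d = interior)
  }
}

# Slab representing a circular frustum r0 -> r1 over length L with n subslabs.
circular_frustum_slab <- function(r0, r1, L, n) {
  r_at <- function(l) r0 + (r1 - r0) * l / L
  mk <- function(st, r) cross_section(st, 2 * r, pi * r^2, 2 * pi * r)
  interior <- 2 * r_at(L * seq_len(n - 1) / n)
  slab(mk(0, r0), mk(L, r1), interior_d = interior)
}

# Slab representing a circular cone, base radius r, length L, n subslabs.
circular_cone_slab <- function(r, L, n) {
  interior <- 2 * r * (1 - seq_len(n - 1) / n)
  slab(cross_section(0, 2 * r, pi * r^2, 2 * pi * r), cross_section(L, 0),
       interior_d = interior, mode = "cone")
}

# Rasterised disk mask of radius r_px inside an (2m+1)^2 image.
disk_mask <- function(r_px, pad = 25, scale = 1) {
  n <- 2 * (r_px + pad) + 1
  cx <- r_px + pad + 1
  ii <- matrix(seq_len(n), n, n)
  jj <- t(ii)
  mask_image(((ii - cx)^2 + (jj - cx)^2 <= r_px^2) * 1L, scale)
}
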