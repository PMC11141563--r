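test_that("volume-to-mass conversion reproduces the worked example", {
  expect_equal(volume_to_mass(0.3098, 1027), 318.1646)
  expect_equal(round(volume_to_mass(0.3098, 1027)), 318)
  expect_equal(volume_to_mass(0, 1027), 0)
  expect_equal(volume_to_mass(1, 1000), 1000)
})

test_that("error rate follows the over/underestimate sign convention", {
  expect_equal(round(error_rate(318, 304.8), 2), 4.33)
  expect_equal(error_rate(100, 100), 0)
  expect_equal(error_rate(90, 100), -10)
  expect_gt(error_rate(110, 100), 0)
  expect_error(error_rate(1, 0), "observed")
})

test_that("mean error is the mean of absolute rates", {
  rates <- c(0.04, -0.17, -0.28, 0.03, 0.10, -0.35, -0.14, 0.89, 0.09)
  expect_equal(round(mean_error(rates), 2), 0.23)
  expect_equal(mean_error(rates), mean_error(-rates))
  expect_equal(mean_error(sample(rates)), mean_error(rates))
  expect_equal(mean_error(c(0, 0, 0)), 0)
  expect_error(mean_error(numeric(0)), "empty")
})

test_that("cm_plane is the mass-weighted mean station", {
  expect_equal(cm_plane(c(1, 1), c(0.25, 0.75)), 0.5)
  expect_equal(cm_plane(5, 0.42), 0.42)
  expect_equal(cm_plane(c(1, 3), c(0, 1)), 0.75)
  expect_error(cm_plane(c(0, 0), c(0, 1)), "total mass")
})

test_that("uniform density without voids gives mass = rho * V", {
  set.seed(5)
  s <- random_slab(n = 5)
  body <- body_measurement(list(s))
  mp <- apply_density(body, density_model(1027))
  expect_equal(mp$mass, 1027 * body_volume(body), tolerance = 1e-12)
  expect_equal(mp$volume, body_volume(body))
  expect_equal(mp$area, body_area(body))
})

test_that("per-slab density overrides apply to the right slabs", {
  r <- 0.5
  mk <- function(st) cross_section(st, 2 * r, pi * r^2, 2 * pi * r)
  s1 <- slab(mk(0), mk(1), interior_d = rep(2 * r, 4))
  s2 <- slab(mk(1), mk(2), interior_d = rep(2 * r, 4))
  body <- body_measurement(list(s1, s2))
  mp <- apply_density(body, density_model(1000, per_slab = list(`2` = 500)))
  V1 <- slab_volume(s1)
  expect_equal(mp$mass, 1000 * V1 + 500 * slab_volume(s2), tolerance = 1e-12)
  # heavier anterior slab pulls the CM forward of the midpoint
  expect_lt(mp$cm_station, 1)
})

test_that("ellipsoid void segments integrate exactly", {
  # full ellipsoid p = q = r = 1 -> 4 pi / 3; half -> 2 pi / 3
  expect_equal(crossvol:::ellipsoid_segment_volume(-1, 1, 1, 1, 1), 4 * pi / 3)
  expect_equal(crossvol:::ellipsoid_segment_volume(0, 1, 1, 1, 1), 2 * pi / 3)
  expect_equal(crossvol:::ellipsoid_segment_volume(-2, 2, 1, 1, 1), 4 * pi / 3)
  expect_equal(crossvol:::ellipsoid_segment_volume(0.5, 0.2, 1, 1, 1), 0)
  # moments: full ellipsoid balanced, half-ellipsoid centroid at 3p/8
  expect_equal(crossvol:::ellipsoid_segment_moment(-1, 1, 1, 1, 1), 0)
  m_half <- crossvol:::ellipsoid_segment_moment(0, 1, 1, 1, 1)
  expect_equal(m_half / (2 * pi / 3), 3 / 8)
  # against quadrature for a clipped segment of a scalene ellipsoid
  p <- 0.8; q <- 0.3; r <- 0.2
  quad <- stats::integrate(function(u) pi * q * r * (1 - u^2 / p^2),
                           -0.3, 0.6, rel.tol = 1e-12)$value
  expect_equal(crossvol:::ellipsoid_segment_volume(-0.3, 0.6, p, q, r), quad,
               tolerance = 1e-12)
})

test_that("an interior void removes exactly rho * void volume", {
  r <- 0.5
  mk <- function(st) cross_section(st, 2 * r, pi * r^2, 2 * pi * r)
  slabs <- lapply(1:4, function(i)
    slab(mk(i - 1), mk(i), interior_d = rep(2 * r, 9)))
  body <- body_measurement(slabs)
  v <- list(center = 1.7, p = 0.4, q = 0.15, r = 0.1)
  mp0 <- apply_density(body, density_model(1000))
  mp1 <- apply_density(body, density_model(1000, voids = list(v)))
  expect_equal(mp0$mass - mp1$mass, 1000 * 4 / 3 * pi * v$p * v$q * v$r,
               tolerance = 1e-12)
  # the void straddles slab boundary 2: the removed mass must not depend on
  # how the subslab grid cuts it
  slabs2 <- lapply(1:4, function(i)
    slab(mk(i - 1), mk(i), interior_d = rep(2 * r, 6)))
  mp2 <- apply_density(body_measurement(slabs2), density_model(1000, voids = list(v)))
  expect_equal(mp1$mass, mp2$mass, tolerance = 1e-12)
  # a void centred forward of the midpoint (1.7 < 2) pushes the CM aft
  expect_gt(mp1$cm_station, mp0$cm_station)
  expect_error(apply_density(body, density_model(1000, voids = list(
    list(center = 0.1, p = 0.4, q = 0.1, r = 0.1)))), "outside")
})

test_that("CM of a symmetric uniform body sits at the axial midpoint", {
  profile <- function(l) 0.3 + 0.1 * sin(pi * l)   # symmetric about l = 0.5
  sol <- make_solid("revolution_body", profile = profile, L = 1)
  body <- sample_measurements(sol, seq(0, 1, length.out = 13), 10)
  mp <- apply_density(body, density_model(1000))
  expect_equal(mp$cm_station, 0.5, tolerance = 1e-10)
})

test_that("cone slab centroid lies at L/4 from the base", {
  s <- circular_cone_slab(r = 1, L = 2, n = 1)
  tb <- slab_subslabs(s)
  expect_equal(tb$lbar, 0.5)  # 2 / 4 measured from the base
  # refined partitions agree through the mass-weighted combination
  s10 <- circular_cone_slab(r = 1, L = 2, n = 10)
  tb10 <- slab_subslabs(s10)
  expect_equal(cm_plane(tb10$volume, tb10$centroid_station), 0.5,
               tolerance = 1e-12)
})

test_that("appendages add mass but do not shift the CM plane", {
  r <- 0.5
  mk <- function(st) cross_section(st, 2 * r, pi * r^2, 2 * pi * r)
  main <- body_measurement(list(slab(mk(0), mk(2), interior_d = rep(2 * r, 9))))
  fin <- circular_cone_slab(0.1, 0.5, 5)
  with_fin <- body_measurement(main$slabs, appendages = list(fin))
  mp0 <- apply_density(main, density_model(1000))
  mp1 <- apply_density(with_fin, density_model(1000))
  expect_equal(mp1$mass - mp0$mass, 1000 * slab_volume(fin), tolerance = 1e-12)
  expect_equal(mp1$cm_station, mp0$cm_station)
})
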