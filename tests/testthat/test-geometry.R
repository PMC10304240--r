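test_that("model construction enforces physical invariants", {
  m <- build_mitochondrion()
  expect_s3_class(m, "mitochondrion_model")
  expect_equal(2 * m$radius / m$lattice$a, 5)   # 2 um over a 400 nm lattice
  expect_equal(sum(m$wall$d), 131.6)
  expect_equal(length(m$wall$n), 23)
  expect_silent(build_mitochondrion(n_B = 1.38))
  expect_error(build_mitochondrion(n_B = 0.9), "refractive")
  expect_error(build_mitochondrion(radius = -5), "radius")
  expect_error(gyroid_lattice(a = 0), "positive")
  expect_error(gyroid_lattice(orientation = diag(3) * 2), "rotation")
})

test_that("point classification is periodic, symmetric and bisects space", {
  m <- build_mitochondrion()
  # lattice periodicity (points kept inside the sphere)
  p <- matrix(c(100, 50, -80, -120, 210, 40), 2, 3, byrow = TRUE)
  expect_equal(classify_point(m, p),
               classify_point(m, sweep(p, 2, c(m$lattice$a, 0, 0), "+")))
  expect_equal(as.character(classify_point(m, c(2 * m$radius, 0, 0))), "exterior")
  # 90-degree rotation about a lattice axis applied to both model and points
  rot <- rotation_about(c(0, 0, 1), 90)
  m_rot <- build_mitochondrion(lattice = gyroid_lattice(400, rot))
  set.seed(7)
  q <- matrix(runif(300, -900, 900), ncol = 3)
  q <- q[sqrt(rowSums(q^2)) < m$radius, , drop = FALSE]
  expect_equal(classify_point(m_rot, t(rot %*% t(q))), classify_point(m, q))
  # the gyroid zero set bisects space: volume fraction of A ~ 1/2
  set.seed(11)
  s <- matrix(runif(3e6, -1000, 1000), ncol = 3)
  s <- s[rowSums(s^2) <= 1000^2, , drop = FALSE]
  fA <- mean(classify_point(m, s) == "compartment_A")
  expect_lt(abs(fA - 0.5), 0.005)
})

test_that("ray intersection lands on the sphere or the mid-surface", {
  m <- build_mitochondrion()
  # pointing away: no intersection
  expect_null(intersect_ray(m, c(0, 0, 3000), c(0, 0, 1)))
  expect_null(intersect_ray(m, c(0, 5000, 0), c(1, 0, 0)))
  # membranes disabled: central chord is 2R
  mb <- make_fixture("ball_lens")
  h_in <- intersect_ray(mb, c(-2000, 0, 0), c(1, 0, 0))
  expect_equal(h_in$path_length, 1000)
  h_out <- intersect_ray(mb, h_in$position + c(0.5, 0, 0), c(1, 0, 0))
  expect_equal(h_out$path_length, 2000 - 0.5, tolerance = 1e-6)
  expect_equal(h_in$from_region, "exterior")
  # residual oracle on random rays
  set.seed(3)
  for (i in 1:40) {
    o <- runif(3, -300, 300)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    h <- intersect_ray(m, o, d)
    expect_false(is.null(h))
    on_sphere <- abs(sqrt(sum(h$position^2)) - m$radius) < 0.1
    resid <- abs(gyroid_value(m, h$position))
    # |g| residual bounded by bisection tolerance (0.1 nm) times the maximum
    # gradient scale (~2 * 2pi/a per nm), with margin
    expect_true(on_sphere || resid < 0.1 * 2 * (2 * pi / m$lattice$a) * 3)
    if (h$type == "membrane") {
      expect_lt(abs(sqrt(sum(h$normal^2)) - 1), 1e-9)
      expect_gte(h$theta_incidence, 0)
      expect_lte(h$theta_incidence, pi / 2 + 1e-9)
    }
  }
})

test_that("unit-cell count matches the closed-form volume ratio", {
  expect_identical(count_unit_cells(5)$interior_estimate, 65L)
  expect_identical(count_unit_cells(2)$interior_estimate, 4L)
  expect_identical(count_unit_cells(1e-4)$interior_estimate, 0L)
  for (d in c(0.7, 1.9, 3.3, 6.4, 10)) {
    expect_identical(count_unit_cells(d)$interior_estimate,
                     as.integer(round(4 / 3 * pi * (d / 2)^3)))
  }
  expect_gt(count_unit_cells(5)$boundary_note, 0)
})

test_that("volume fractions are conserved and symmetric without a wall", {
  m0 <- build_mitochondrion(wall = list(n = 1.4, d = 0))
  vf0 <- volume_fractions(m0, n_samples = 2e4, seed = 5)
  expect_equal(sum(vf0), 1, tolerance = 1e-9)
  expect_equal(unname(vf0["wall"]), 0)
  expect_equal(unname(vf0["compartment_A"]), 0.5, tolerance = 0.02)
  vf <- volume_fractions(build_mitochondrion(), n_samples = 2e4, seed = 5)
  expect_equal(sum(vf), 1, tolerance = 1e-9)
  expect_true(all(vf >= 0))
})
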