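# hand-built trace results let the integrators be probed record by record
synthetic_trace <- function(records, model, wavelength = 550, spacing = 10) {
  structure(list(records = records, wavelength = wavelength, spacing = spacing,
                 model = model,
                 ledger = list(input = sum(records$energy),
                               exited_forward = sum(records$energy))),
            class = "trace_result")
}

one_record <- function(y = 0, z = 0, As = complex(real = 1), phase = 0) {
  data.frame(x = 1000, y = y, z = z, dx = 1, dy = 0, dz = 0,
             bx = 0, by = 1, bz = 0,
             amplitude_s = As, amplitude_p = complex(real = 0),
             phase = phase, energy = Mod(As)^2, depth = 1, forward = TRUE)
}

test_that("coherent addition and cancellation behave on the image plane", {
  m0 <- make_fixture("null_sphere")
  single <- accumulate_first_order(synthetic_trace(one_record(), m0), 1000)
  pair <- accumulate_first_order(
    synthetic_trace(rbind(one_record(), one_record()), m0), 1000)
  expect_equal(max(pair$intensity), 4 * max(single$intensity), tolerance = 1e-9)
  anti <- accumulate_first_order(
    synthetic_trace(rbind(one_record(), one_record(phase = pi)), m0), 1000)
  expect_lt(max(anti$intensity), 1e-4 * max(pair$intensity))
})

test_that("a null model produces a flat, wavelength-independent flux spectrum", {
  m0 <- make_fixture("null_sphere")
  fs <- flux_ratio_spectrum(m0, wavelengths = c(400, 550, 700),
                            planes = c(1000, 3000, 5000), spacing = 30, seed = 1)
  expect_true(all(abs(fs$ratio$ratio - 1) < 0.02))
})

test_that("plane power never exceeds the forward exited energy", {
  m0 <- make_fixture("null_sphere")
  # pixel size an exact multiple of the ray spacing: no binning moire
  tr <- trace(m0, make_source(source_grid(spacing = 25), m0), seed = 1)
  for (pl in c(500, 2000)) {
    fm <- accumulate_first_order(tr, pl, pixel_size = 150, half_extent = 2500)
    expect_lte(fm$total_power, tr$ledger$exited_forward * 1.02)
    expect_gte(fm$total_power, tr$ledger$exited_forward * 0.85) # rim pixels
  }
  m <- default_model_cached()
  trm <- trace(m, small_source(m, 500), seed = 1)
  fm <- accumulate_first_order(trm, 1000)
  expect_lte(fm$total_power, trm$ledger$exited_forward * 1.02)
})

test_that("the surface-patch integrator reconstructs a plane wave", {
  m0 <- make_fixture("null_sphere")
  tr <- trace(m0, small_source(m0, 2500), seed = 1)
  fmA <- accumulate_first_order(tr, 1000, pixel_size = 150, half_extent = 1200)
  fmB <- patch_integrate(tr, 1000, pixel_size = 150, half_extent = 1200)
  # the shadow interior stays illuminated at the unit level, with the
  # Fresnel edge ringing of a sharply truncated wavefront on top (the
  # physical near-field ripple of a large circular aperture)
  rr <- sqrt(outer(fmB$y^2, fmB$z^2, "+"))
  core <- fmB$intensity[rr < 500]
  expect_lt(stats::sd(core) / mean(core), 0.6)
  # the two integration models carry comparable power near the sphere
  powA <- disk_power(fmA, 900, c(0, 0))
  powB <- disk_power(fmB, 900, c(0, 0))
  expect_lt(abs(powB - powA) / powA, 0.2)
  # patch count at the default 100 nm tiling is of order 1e3 for R = 1 um
  expect_gt(fmB$n_patches, 300)
  expect_lt(fmB$n_patches, 3000)
})

test_that("a single patch radiates an inverse-square wavelet", {
  m0 <- make_fixture("null_sphere")
  tr <- synthetic_trace(one_record(), m0)
  near <- patch_integrate(tr, 2000, pixel_size = 100, half_extent = 300)
  far <- patch_integrate(tr, 4000, pixel_size = 100, half_extent = 300)
  mid <- length(near$y) %/% 2
  # on-axis intensity from a single emitter falls as 1/L^2 (L from the patch)
  L1 <- 2000; L2 <- 4000
  expect_equal(near$intensity[mid, mid] / far$intensity[mid, mid],
               (L2 / L1)^2, tolerance = 0.05)
})

test_that("a homogeneous ball lens focuses near the paraxial prediction", {
  mb <- make_fixture("ball_lens")
  # paraxial rays only: aperture limited to 0.35 R
  spacing <- 18
  src <- source_grid(spacing = spacing, radius = mb$radius, wavelength = 550)
  ms <- make_source(src, mb)
  b <- sqrt(ms$origins[, 2]^2 + ms$origins[, 3]^2)
  ms$origins <- ms$origins[b < 0.35 * mb$radius, , drop = FALSE]
  ms$n_rays <- nrow(ms$origins)
  tr <- trace(mb, ms, seed = 1)
  n_rel <- mb$n_A
  efl <- n_rel * mb$radius / (2 * (n_rel - 1.33) / 1.33) / 1.33
  bfd <- efl - mb$radius
  fr <- find_focus(mb, 550, plane_range = c(1000, round(1.5 * bfd, -2)),
                   step = 100, tr = tr)
  expect_false(fr$no_focus)
  expect_lt(abs(fr$focus_nm - bfd) / bfd, 0.15)
  expect_true(fr$centered)
})

test_that("rotation sweeps report null variation for a single angle", {
  m <- default_model_cached()
  sw <- rotation_sweep(m, angles_deg = 45, wavelength = 550, spacing = 45,
                       seed = 1, focus_plane = 3000)
  expect_equal(sw$energy_variation, 0)
  expect_equal(sw$central_variation, 0)
  expect_equal(nrow(sw$table), 1)
})

test_that("waveguide diagnostics reduce to area fractions without contrast", {
  meq <- build_mitochondrion(n_A = 1.40, n_B = 1.40)
  wg <- waveguide_diagnostics(meq, wavelengths = 550, spacing = 40, seed = 2)
  expect_true(wg$no_waveguide)
  # binomial 3 sigma on the energy-weighted exit fraction
  expect_lt(abs(wg$table$channel_fraction[1] - wg$area_fraction), 0.05)
})

test_that("waveguide diagnostics are well-formed on the contrasted model", {
  m <- default_model_cached()
  wg <- waveguide_diagnostics(m, wavelengths = c(450, 700), spacing = 40, seed = 2)
  expect_false(wg$no_waveguide)
  expect_true(all(wg$table$channel_fraction >= 0 & wg$table$channel_fraction <= 1))
  expect_true(all(is.finite(wg$table$enhancement)))
  # index contrast moves the exit split away from the pure area fraction
  expect_gt(max(abs(wg$table$channel_fraction - wg$area_fraction)), 0.01)
})
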