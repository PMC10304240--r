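test_that("the source grid tiles the illumination disc", {
  m <- default_model_cached()
  src <- make_source(source_grid(spacing = 10, radius = 1000), m)
  expect_lt(abs(src$n_rays - pi * 100^2) / (pi * 100^2), 0.02)
  # every ray's line meets the sphere: closest approach <= R
  b <- sqrt((src$origins[, 2] - m$center[2])^2 + (src$origins[, 3] - m$center[3])^2)
  expect_true(all(b <= m$radius))
  expect_error(source_grid(spacing = 1), "spacing")
  expect_error(source_grid(polarization = c(0, 0)), "polarization")
})

test_that("single-event scattering conserves energy and detects TIR", {
  m <- default_model_cached()
  mk_packet <- function(dir, lam = 550) {
    dir <- dir / sqrt(sum(dir^2))
    ref <- if (abs(dir[2]) < 0.9) c(0, 1, 0) else c(0, 0, 1)
    b1 <- ref - sum(ref * dir) * dir
    b1 <- b1 / sqrt(sum(b1^2))
    list(position = NULL, direction = dir, basis_s = b1,
         amplitude_s = complex(real = 0.6), amplitude_p = complex(real = 0.8),
         phase = 0, energy = 1, wavelength = lam)
  }
  # normal incidence on an index-matched wall: transmission only
  m_null <- build_mitochondrion(n_A = 1.33, n_B = 1.33,
                                wall = list(n = rep(1.33, 3), d = c(5, 10, 5)))
  p0 <- mk_packet(c(1, 0, 0))
  h0 <- intersect_ray(m_null, c(-2000, 1, 2), c(1, 0, 0))
  h0m <- intersect_ray(m_null, h0$position + 0.5 * c(1, 0, 0), c(1, 0, 0))
  sc0 <- scatter(p0, h0m, m_null)
  expect_null(sc0$reflected)
  expect_equal(sc0$transmitted$energy, 1, tolerance = 1e-12)
  expect_equal(sc0$transmitted$direction, c(1, 0, 0))
  # random membrane hits: children sum to the parent energy below TIR
  set.seed(5)
  n_checked <- 0
  for (i in 1:30) {
    o <- runif(3, -400, 400)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    h <- intersect_ray(m, o, d)
    if (is.null(h) || h$type != "membrane") next
    p <- mk_packet(d)
    sc <- scatter(p, h, m)
    et <- if (is.null(sc$transmitted)) 0 else sc$transmitted$energy
    er <- if (is.null(sc$reflected)) 0 else sc$reflected$energy
    expect_equal(et + er, 1, tolerance = 1e-10)
    if (sc$tir) {
      expect_null(sc$transmitted)
      expect_equal(er, 1, tolerance = 1e-10)
    } else {
      # Snell invariant across the crossing
      nfrom <- if (h$from_region == "compartment_A") m$n_A else m$n_B
      nto <- if (h$to_region == "compartment_A") m$n_A else m$n_B
      sin_out <- sqrt(max(0, 1 - sum(sc$transmitted$direction *
                                     (-sign(sum(d * h$normal)) * h$normal))^2))
      expect_equal(nto * sin_out, nfrom * sin(h$theta_incidence), tolerance = 1e-6)
    }
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 10)
})

test_that("TIR geometry reflects the full energy", {
  # flat-wall surrogate: bare 1.48 -> 1.33 interface beyond the critical angle
  st <- stratified_stack(1.48, list(), 1.33)
  rt <- stack_rt(st, 80 * pi / 180, 550, "s")
  expect_true(rt$tir)
  expect_equal(rt$R, 1, tolerance = 1e-10)
  expect_equal(rt$T, 0)
})

test_that("the null model transmits everything undeviated", {
  m0 <- make_fixture("null_sphere")
  tr <- trace(m0, small_source(m0, 300), seed = 1)
  l <- tr$ledger
  expect_equal(l$exited_forward / l$input, 1, tolerance = 1e-9)
  expect_equal(l$discarded, 0, tolerance = 1e-12 * l$input)
  expect_true(all(abs(tr$records$dx - 1) < 1e-12))
  expect_equal(abs(l$balance) / l$input, 0, tolerance = 1e-9)
})

test_that("the energy ledger closes and splitting is deterministic", {
  m <- default_model_cached()
  src <- small_source(m, 250)
  tr1 <- trace(m, src, strategy = "ii", seed = 1)
  tr2 <- trace(m, src, strategy = "ii", seed = 99)   # seed must not matter
  expect_identical(tr1$records, tr2$records)
  l <- tr1$ledger
  expect_lt(abs(l$balance), 1e-9 * l$input)
  expect_lt(l$discarded / l$input, 0.01)
  expect_true(all(tr1$records$energy >= 0))
  # per-packet energy identity |As|^2 + |Ap|^2 = energy
  en <- Mod(tr1$records$amplitude_s)^2 + Mod(tr1$records$amplitude_p)^2
  expect_equal(en, tr1$records$energy, tolerance = 1e-9)
})

test_that("Russian roulette (strategy i) is an unbiased estimator of strategy ii", {
  m <- default_model_cached()
  src <- small_source(m, 1600)
  t2 <- trace(m, src, strategy = "ii", seed = 1)
  t1 <- trace(m, src, strategy = "i", seed = 7)
  f2 <- t2$ledger$exited_forward / t2$ledger$input
  f1 <- t1$ledger$exited_forward / t1$ledger$input
  # per-ray forward energy has sd < 0.3; 3 sigma over n rays
  tol3 <- 3 * 0.3 / sqrt(t1$ledger$input)
  expect_lt(abs(f1 - f2), tol3)
})

test_that("depth exhaustion is ledgered and warned about", {
  m <- default_model_cached()
  src <- small_source(m, 120)
  expect_warning(tr <- trace(m, src, max_depth = 4), "max_depth")
  expect_gt(tr$ledger$discarded_depth, 0)
  expect_lt(abs(tr$ledger$balance), 1e-9 * tr$ledger$input)
})

test_that("polarization state is carried into the records", {
  # the per-record s/p basis rotates with each plane of incidence, so the
  # polarization check is on the reconstructed global transverse field
  m0 <- make_fixture("null_sphere")
  grid <- source_grid(spacing = 45, polarization = c(1, 0), wavelength = 550)
  tr <- trace(m0, make_source(grid, m0), seed = 1)
  fy <- mitolens:::record_fields(tr)
  expect_true(all(Mod(fy$Ez) < 1e-9))
  expect_equal(Mod(fy$Ey)^2, fy$energy, tolerance = 1e-9)
  griz <- source_grid(spacing = 45, polarization = c(0, 1i), wavelength = 550)
  trz <- trace(m0, make_source(griz, m0), seed = 1)
  fz <- mitolens:::record_fields(trz)
  expect_true(all(Mod(fz$Ey) < 1e-9))
  expect_equal(sum(trz$records$energy), trz$ledger$input, tolerance = 1e-9)
})
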