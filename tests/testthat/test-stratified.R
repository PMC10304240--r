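test_that("Snell chain propagates the invariant and flags evanescence", {
  st <- stratified_stack(1.4, list(n = c(1.4, 1.4), d = c(10, 20)), 1.4)
  ch <- refraction_chain(st, 0.6, 550)
  expect_equal(Re(acos(ch$cos_theta)), c(0.6, 0.6))
  expect_false(ch$tir)
  # dense-to-rare: 1.48 sin 80 / 1.33 = 1.096 > 1 -> substrate evanescent
  st2 <- stratified_stack(1.48, list(), 1.33)
  ch2 <- refraction_chain(st2, 80 * pi / 180, 550)
  expect_true(ch2$tir)
  expect_equal(Re(ch2$cos_theta_s), 0)
  expect_equal(Im(ch2$cos_theta_s), sqrt((1.48 * sin(80 * pi / 180) / 1.33)^2 - 1))
  ch0 <- refraction_chain(st, 0, 550)
  expect_equal(ch0$cos_theta, c(1 + 0i, 1 + 0i))
})

test_that("layer matrices are unimodular with the closed quarter-wave form", {
  ch <- refraction_chain(stratified_stack(1.0, list(n = 1.5, d = 100), 1.0), 0.3, 600)
  M <- layer_matrix(layer(1.5, 100), ch, "s")
  expect_equal(M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1], 1 + 0i,
               tolerance = 1e-10)
  expect_equal(layer_matrix(layer(1.5, 0), ch, "p"), diag(2) + 0i)
  # quarter-wave at normal incidence: k0 * n * d = pi/2
  lam <- 600
  d_qw <- lam / (4 * 1.5)
  ch0 <- refraction_chain(stratified_stack(1, list(n = 1.5, d = d_qw), 1), 0, lam)
  Mq <- layer_matrix(layer(1.5, d_qw), ch0, "s")
  expect_equal(Mq[1, 1], 0 + 0i, tolerance = 1e-12)
  expect_equal(Mq[2, 2], 0 + 0i, tolerance = 1e-12)
  expect_equal(Mq[1, 2], 1i / 1.5, tolerance = 1e-12)
  expect_equal(Mq[2, 1], 1i * 1.5, tolerance = 1e-12)
})

test_that("bare-interface amplitudes match Fresnel with the fixed sign", {
  st <- stratified_stack(1.0, list(), 1.5)
  rt <- stack_rt(st, 0, 550, "s")
  expect_equal(rt$r, -0.2 + 0i, tolerance = 1e-12)
  expect_equal(rt$R, 0.04, tolerance = 1e-12)
  expect_equal(rt$R + rt$T, 1, tolerance = 1e-12)
  # Brewster null for p
  thB <- atan(1.5 / 1.0)
  expect_lt(stack_rt(st, thB, 550, "p")$R, 1e-10)
  # s and p coincide at normal incidence for any stack
  set.seed(1)
  st3 <- random_stack()
  expect_equal(stack_rt(st3, 0, 480, "s")$R, stack_rt(st3, 0, 480, "p")$R,
               tolerance = 1e-12)
})

test_that("multilayer transmission conserves energy and composes correctly", {
  rw <- reference_wall()
  wall <- stratified_stack(1.33, list(n = rw$n, d = rw$d), 1.48)
  rt <- stack_rt(wall, 0, 587.56, "s")
  expect_equal(rt$R + rt$T, 1, tolerance = 1e-9)
  # two adjacent equal-index layers merge into one of summed thickness
  stA <- stratified_stack(1.2, list(n = c(1.6, 1.6, 1.4), d = c(30, 45, 80)), 1.1)
  stB <- stratified_stack(1.2, list(n = c(1.6, 1.4), d = c(75, 80)), 1.1)
  for (pol in c("s", "p")) {
    a <- stack_rt(stA, 0.4, 500, pol)
    b <- stack_rt(stB, 0.4, 500, pol)
    expect_equal(a$r, b$r, tolerance = 1e-12)
    expect_equal(a$t, b$t, tolerance = 1e-12)
  }
  # reciprocity: reversed stack with swapped bounding media, same T
  stR <- stratified_stack(1.1, list(n = rev(c(1.6, 1.4)), d = rev(c(75, 80))), 1.2)
  for (pol in c("s", "p"))
    expect_equal(stack_rt(stB, 0.35, 500, pol)$T,
                 stack_rt(stR, asin(1.2 * sin(0.35) / 1.1), 500, pol)$T,
                 tolerance = 1e-9)
})

test_that("energy is conserved on random lossless stacks below TIR", {
  set.seed(42)
  for (i in 1:300) {
    st <- random_stack(sample(0:4, 1))
    th_max <- if (st$ns < st$n0) asin(st$ns / st$n0) * 0.98 else pi / 2 - 0.02
    th <- runif(1, 0, th_max)
    lam <- runif(1, 350, 900)
    for (pol in c("s", "p")) {
      rt <- stack_rt(st, th, lam, pol)
      expect_lt(abs(rt$R + rt$T - 1), 1e-9)
      expect_true(rt$R >= 0 && rt$R <= 1 + 1e-12)
    }
  }
})

test_that("the matrix solution agrees with an independent Fresnel recursion", {
  set.seed(9)
  for (i in 1:60) {
    st <- random_stack(3)
    th <- runif(1, 0, 0.9 * pi / 2)
    lam <- runif(1, 380, 850)
    for (pol in c("s", "p")) {
      mine <- stack_rt(st, th, lam, pol)
      oracle <- fresnel_recursion_rt(st, th, lam, pol)
      # reflectance and amplitude modulus; the absolute phase of r is
      # convention-dependent (time-harmonic sign, phase reference plane)
      expect_equal(mine$R, oracle$R, tolerance = 1e-8)
      expect_equal(Mod(mine$r), Mod(oracle$r), tolerance = 1e-8)
    }
  }
})

test_that("compiled and R optics kernels agree", {
  set.seed(21)
  for (i in 1:25) {
    st <- random_stack(sample(1:5, 1))
    th <- runif(1, 0, 0.95 * pi / 2)
    lam <- runif(1, 350, 900)
    cpp <- mitolens:::cpp_stack_rt(st$n0, st$ns, st$n, st$d, th, lam)
    s <- stack_rt(st, th, lam, "s")
    p <- stack_rt(st, th, lam, "p")
    expect_equal(cpp$rs, s$r, tolerance = 1e-10)
    expect_equal(cpp$rp, p$r, tolerance = 1e-10)
    expect_equal(cpp$Rs, s$R, tolerance = 1e-10)
    expect_equal(cpp$Tp, p$T, tolerance = 1e-10)
    expect_equal(cpp$tir, s$tir)
  }
})

test_that("reflectance grids have the documented shape and Fresnel limit", {
  st <- stratified_stack(1.33, list(), 1.48)
  g <- reflectance_grid(st)
  expect_equal(nrow(g), 81 * 91)
  expect_equal(length(unique(g$wavelength_nm)), 81)
  expect_equal(length(unique(g$angle_deg)), 91)
  g1 <- reflectance_grid(st, 550, 37)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$Rs, stack_rt(st, 37 * pi / 180, 550, "s")$R, tolerance = 1e-12)
  expect_equal(g1$Rp, stack_rt(st, 37 * pi / 180, 550, "p")$R, tolerance = 1e-12)
  # closed-form Fresnel across the grid for the bare interface
  sub <- g[g$angle_deg %in% c(0, 25, 60, 89), ]
  th <- sub$angle_deg * pi / 180
  ct <- cos(th); stn <- 1.33 * sin(th) / 1.48
  ctt <- sqrt(1 - stn^2)
  rs <- (1.33 * ct - 1.48 * ctt) / (1.33 * ct + 1.48 * ctt)
  rp <- (1.48 * ct - 1.33 * ctt) / (1.48 * ct + 1.33 * ctt)
  expect_equal(sub$Rs, rs^2, tolerance = 1e-9)
  expect_equal(sub$Rp, rp^2, tolerance = 1e-9)
  # 90 degrees evaluated as the one-sided limit: R -> 1
  expect_gt(min(g$Rs[g$angle_deg == 90]), 0.999)
})
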