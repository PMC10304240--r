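#' A homogeneous dielectric layer
#'
#' @param n real refractive index (>= 1, lossless).
#' @param d thickness in nm (>= 0).
#' @return object of class `layer`.
#' @export
layer <- function(n, d) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1,
            is.numeric(d), length(d) == 1, d >= 0)
  structure(list(n = n, d = d), class = "layer")
}

#' A stratified medium (plane-parallel stack)
#'
#' Ordered finite layers between two semi-infinite bounding media. An empty
#' layer list describes a bare interface.
#'
#' @param n_incident refractive index of the incidence medium (n0).
#' @param layers list of [layer()] objects (possibly empty), or a list with
#'   numeric vectors `n` and `d`.
#' @param n_substrate refractive index of the substrate (ns).
#' @return object of class `stratified_stack`.
#' @export
stratified_stack <- function(n_incident, layers = list(), n_substrate) {
  stopifnot(is.numeric(n_incident), n_incident >= 1,
            is.numeric(n_substrate), n_substrate >= 1)
  if (is.list(layers) && !is.null(layers$n)) {
    nv <- as.numeric(layers$n); dv <- as.numeric(layers$d)
  } else {
    nv <- vapply(layers, function(l) l$n, numeric(1))
    dv <- vapply(layers, function(l) l$d, numeric(1))
  }
  stopifnot(length(nv) == length(dv), all(nv >= 1), all(dv >= 0))
  structure(list(n0 = n_incident, n = nv, d = dv, ns = n_substrate),
            class = "stratified_stack")
}

#' @export
print.stratified_stack <- function(x, ...) {
  cat(sprintf("<stratified_stack> n0 = %g | %d layers (%.1f nm) | ns = %g\n",
              x$n0, length(x$n), sum(x$d), x$ns))
  invisible(x)
}

#' Snell angle chain through a stack
#'
#' Propagates the Snell invariant \eqn{n_0 \sin\theta_0} through every layer
#' and the substrate. Where \eqn{n_0 \sin\theta_0 / n_j > 1} the layer is
#' evanescent and \eqn{\cos\theta_j = i\sqrt{\sin^2\theta_j - 1}}; total
#' internal reflection is declared only when the substrate is evanescent.
#'
#' @param stack a [stratified_stack()].
#' @param theta0 incidence angle in the incidence medium, rad, in \[0, pi/2\].
#' @param wavelength vacuum wavelength, nm.
#' @return list with `snell` (the invariant), per-layer complex `cos_theta`,
#'   substrate `cos_theta_s`, `k0` and `tir`.
#' @export
refraction_chain <- function(stack, theta0, wavelength) {
  stopifnot(inherits(stack, "stratified_stack"), theta0 >= 0, theta0 <= pi / 2)
  snell <- stack$n0 * sin(theta0)
  costh <- function(n) {
    s <- snell / n
    complex(real = sqrt(pmax(0, 1 - s^2)), imaginary = sqrt(pmax(0, s^2 - 1)))
  }
  list(snell = snell, k0 = 2 * pi / wavelength,
       cos_theta0 = cos(theta0),
       cos_theta = costh(stack$n), cos_theta_s = costh(stack$ns),
       tir = snell / stack$ns > 1)
}

#' Characteristic matrix of a single layer
#'
#' \deqn{M = \begin{pmatrix}\cos(k_0 h) & i\sin(k_0 h)/\gamma \\
#'   i\gamma\sin(k_0 h) & \cos(k_0 h)\end{pmatrix}}
#' with apparent thickness \eqn{h = n d \cos\theta} and characteristic
#' admittance \eqn{\gamma_s = n\cos\theta}, \eqn{\gamma_p = n/\cos\theta}
#' (the vacuum admittance \eqn{\sqrt{\epsilon_0/\mu_0}} is normalised to 1:
#' it cancels in every amplitude ratio).
#'
#' @param lay a [layer()].
#' @param chain output of [refraction_chain()] for the containing stack.
#' @param polarization `"s"` or `"p"`.
#' @return 2x2 complex matrix with unit determinant.
#' @export
layer_matrix <- function(lay, chain, polarization = c("s", "p")) {
  polarization <- match.arg(polarization)
  s <- chain$snell / lay$n
  ct <- if (s <= 1) complex(real = sqrt(1 - s^2)) else complex(imaginary = sqrt(s^2 - 1))
  g <- if (polarization == "s") lay$n * ct else lay$n / ct
  ph <- chain$k0 * lay$n * lay$d * ct
  matrix(c(cos(ph), 1i * g * sin(ph), 1i * sin(ph) / g, cos(ph)), 2, 2)
}

#' Reflection and transmission of a stratified stack
#'
#' Multiplies the per-layer characteristic matrices in propagation order and
#' applies the boundary conditions for the bounding media:
#' \deqn{r = \frac{\gamma_0 m_{11} + \gamma_0\gamma_s m_{12} - m_{21} -
#'   \gamma_s m_{22}}{\gamma_0 m_{11} + \gamma_0\gamma_s m_{12} + m_{21} +
#'   \gamma_s m_{22}}, \quad t = \frac{2\gamma_0}{\cdots}}
#' For p polarization the reflection amplitude carries the opposite sign
#' (right-handed s,p,k triads for every ray, so s and p reflection agree at
#' normal incidence) and the transmission amplitude carries the
#' \eqn{\cos\theta_0/\cos\theta_s} field-conversion factor. Reflectance is
#' \eqn{R = |r|^2}; transmittance \eqn{T = \mathrm{Re}(\gamma_s)/\gamma_0
#' \,|t_{tang}|^2}, which guarantees \eqn{R + T = 1} for lossless stacks and
#' \eqn{T = 0} under total internal reflection.
#'
#' @inheritParams refraction_chain
#' @param polarization `"s"` or `"p"`.
#' @return list of class `rt_result`: complex `r`, `t`, energy fractions `R`,
#'   `T`, and logical `tir`.
#' @export
stack_rt <- function(stack, theta0, wavelength, polarization = c("s", "p")) {
  polarization <- match.arg(polarization)
  ch <- refraction_chain(stack, theta0, wavelength)
  m <- diag(2) + 0i
  nl <- length(stack$n)
  for (j in seq_len(nl))
    m <- m %*% layer_matrix(layer(stack$n[j], stack$d[j]), ch, polarization)
  c0 <- ch$cos_theta0
  cs <- ch$cos_theta_s
  if (polarization == "s") {
    g0 <- stack$n0 * c0; gs <- stack$ns * cs
  } else {
    g0 <- stack$n0 / c0; gs <- stack$ns / cs
  }
  D <- g0 * m[1, 1] + g0 * gs * m[1, 2] + m[2, 1] + gs * m[2, 2]
  r <- (g0 * m[1, 1] + g0 * gs * m[1, 2] - m[2, 1] - gs * m[2, 2]) / D
  t_tang <- 2 * g0 / D
  if (polarization == "p") {
    r <- -r
    t <- t_tang * c0 / cs
  } else {
    t <- t_tang
  }
  R <- Mod(r)^2
  T <- if (ch$tir) 0 else Re(gs) / Re(g0) * Mod(t_tang)^2
  structure(list(r = r, t = t, R = R, T = T, tir = ch$tir), class = "rt_result")
}

#' Polarized reflectance over a wavelength x angle grid
#'
#' Vectorised characteristic-matrix evaluation of both polarizations on the
#' full grid. An angle of exactly 90 degrees is evaluated as the one-sided
#' limit (90 deg - 1e-6 rad) to avoid the \eqn{1/\cos\theta} singularity.
#'
#' @param stack a [stratified_stack()].
#' @param wavelengths numeric vector, nm (default 400-800 in 5 nm steps).
#' @param angles numeric vector of incidence angles in degrees
#'   (default 0-90 in 1 degree steps).
#' @return data.frame with columns `wavelength_nm`, `angle_deg`, `Rs`, `Rp`,
#'   `Ts`, `Tp`.
#' @export
reflectance_grid <- function(stack, wavelengths = seq(400, 800, by = 5),
                             angles = seq(0, 90, by = 1)) {
  stopifnot(length(wavelengths) > 0, length(angles) > 0)
  th <- pmin(angles * pi / 180, pi / 2 - 1e-6)
  grid <- expand.grid(wavelength_nm = wavelengths, angle_deg = angles,
                      KEEP.OUT.ATTRS = FALSE)
  thv <- pmin(grid$angle_deg * pi / 180, pi / 2 - 1e-6)
  rt <- grid_rt(stack, grid$wavelength_nm, thv)
  data.frame(grid, Rs = rt$Rs, Rp = rt$Rp, Ts = rt$Ts, Tp = rt$Tp)
}

# vectorised core over paired (wavelength, theta) vectors
grid_rt <- function(stack, lam, th) {
  k0 <- 2 * pi / lam
  snell <- stack$n0 * sin(th)
  c0 <- cos(th)
  costh <- function(n) {
    s <- snell / n
    ev <- s > 1
    out <- complex(real = sqrt(pmax(0, 1 - s^2)))
    out[ev] <- complex(imaginary = sqrt(s[ev]^2 - 1))
    out
  }
  one <- rep(1 + 0i, length(lam))
  zero <- rep(0 + 0i, length(lam))
  ms <- list(one, zero, zero, one)  # m11, m12, m21, m22
  mp <- list(one, zero, zero, one)
  for (j in seq_along(stack$n)) {
    n <- stack$n[j]; d <- stack$d[j]
    cj <- costh(n)
    ph <- k0 * n * d * cj
    cph <- cos(ph); sph <- sin(ph)
    for (pol in 1:2) {
      g <- if (pol == 1) n * cj else n / cj
      a12 <- 1i * sph / g; a21 <- 1i * g * sph
      m <- if (pol == 1) ms else mp
      t11 <- m[[1]] * cph + m[[2]] * a21
      t12 <- m[[1]] * a12 + m[[2]] * cph
      t21 <- m[[3]] * cph + m[[4]] * a21
      t22 <- m[[3]] * a12 + m[[4]] * cph
      if (pol == 1) ms <- list(t11, t12, t21, t22) else mp <- list(t11, t12, t21, t22)
    }
  }
  cs <- costh(stack$ns)
  tir <- snell / stack$ns > 1
  res <- list()
  for (pol in 1:2) {
    if (pol == 1) {
      g0 <- stack$n0 * c0; gs <- stack$ns * cs; m <- ms
    } else {
      g0 <- stack$n0 / c0; gs <- stack$ns / cs; m <- mp
    }
    D <- g0 * m[[1]] + g0 * gs * m[[2]] + m[[3]] + gs * m[[4]]
    r <- (g0 * m[[1]] + g0 * gs * m[[2]] - m[[3]] - gs * m[[4]]) / D
    t <- 2 * g0 / D
    R <- Mod(r)^2
    T <- Re(gs) / Re(g0) * Mod(t)^2
    T[tir] <- 0
    if (pol == 1) { res$Rs <- R; res$Ts <- T } else { res$Rp <- R; res$Tp <- T }
  }
  res
}

#' Write a reflectance grid as TSV
#'
#' Wide export: one header row of wavelengths, one column per angle, two
#' blocks (s then p) stacked long-form for portability.
#'
#' @param grid output of [reflectance_grid()].
#' @param path output file path.
#' @export
write_reflectance_tsv <- function(grid, path) {
  utils::write.table(grid, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
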