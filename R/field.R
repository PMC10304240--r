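#' Transverse complex field components of exit records
#'
#' Converts each record's Jones amplitudes (s/p in its own transverse basis)
#' into global transverse components \eqn{(E_y, E_z)} including the
#' accumulated propagation phase.
#'
#' @param tr a `trace_result` from [trace()].
#' @param forward_only keep only forward-going records (direction x > 0).
#' @return data.frame with positions, directions, complex `Ey`, `Ez`, energy.
#' @keywords internal
record_fields <- function(tr, forward_only = TRUE) {
  r <- tr$records
  if (forward_only) r <- r[r$forward, , drop = FALSE]
  # b2 = d x b1
  b2x <- r$dy * r$bz - r$dz * r$by
  b2y <- r$dz * r$bx - r$dx * r$bz
  b2z <- r$dx * r$by - r$dy * r$bx
  ph <- exp(1i * r$phase)
  Ey <- (r$amplitude_s * r$by + r$amplitude_p * b2y) * ph
  Ez <- (r$amplitude_s * r$bz + r$amplitude_p * b2z) * ph
  data.frame(x = r$x, y = r$y, z = r$z, dx = r$dx, dy = r$dy, dz = r$dz,
             Ey = Ey, Ez = Ez, energy = r$energy)
}

new_field_map <- function(plane, pixel, half_extent, center_yz) {
  np <- 2L * as.integer(ceiling(half_extent / pixel))
  coord <- (seq_len(np) - (np + 1) / 2) * pixel
  list(plane = plane, pixel = pixel,
       y = coord + center_yz[1], z = coord + center_yz[2],
       Ey = matrix(0 + 0i, np, np), Ez = matrix(0 + 0i, np, np),
       skipped = 0)
}

#' First-order near-field integration (accumulator-map model)
#'
#' Each forward exit record is propagated geometrically to the image plane,
#' its complex transverse amplitudes added at the landing pixel with the
#' phase advanced by \eqn{2\pi n_{ext} \ell / \lambda}; the complex map is
#' then convolved with an Airy point-spread function.
#'
#' The map stores the sampled transverse field density times the pixel size:
#' each record of amplitude \eqn{a} represents a beamlet of area
#' \eqn{s^2} (the source-grid spacing squared), so its pixel contribution is
#' scaled by \eqn{s/\mathrm{px}}. With this convention pixel intensity is
#' power per pixel for extended coherent fields, the map total equals the
#' forward exited power wherever the field is adequately sampled, and the
#' PSF (normalised to unit DC gain) leaves extended-field power unchanged.
#'
#' Where the membrane stack makes the exit rays chaotic below the sampling
#' scale (the gyroid's local curvature radius is ~a/2pi, smaller than any
#' practical ray spacing), the coherent pixel sums underestimate the absolute
#' power while preserving the interference structure; `renormalize = TRUE`
#' rescales the map so its total equals the geometric energy landing on it,
#' which is exact for smooth fields and restores the energy scale for
#' speckled ones.
#'
#' @param tr a `trace_result`.
#' @param plane image-plane position in nm measured from the sphere's rear
#'   pole (positive = downstream).
#' @param pixel_size pixel size in nm (default wavelength / 4).
#' @param half_extent map half-width in nm (default 2 x radius).
#' @param psf apply the Airy point-spread function (default TRUE).
#' @param psf_na `"medium"` (default): the wave-resolution floor
#'   \eqn{NA = n_{ext}}, appropriate because the coherent ray sum already
#'   carries the aperture geometry; `"aperture"`: the aperture-limited
#'   \eqn{NA = n_{ext}\min(1, R/\sqrt{R^2+x^2})}.
#' @param renormalize rescale total map power to the geometric landing
#'   energy (default FALSE).
#' @param fields optional precomputed [record_fields()] table (reused across
#'   planes by [find_focus()]).
#' @return object of class `field_map`: complex `Ey`, `Ez` matrices, pixel
#'   `intensity` (power per pixel), `total_power`, `landed_energy` (geometric
#'   energy landing inside the map), coordinates, and the plane position.
#' @export
accumulate_first_order <- function(tr, plane, pixel_size = NULL,
                                   half_extent = NULL, psf = TRUE,
                                   psf_na = c("medium", "aperture"),
                                   renormalize = FALSE, fields = NULL) {
  psf_na <- match.arg(psf_na)
  model <- tr$model
  lam <- tr$wavelength
  if (is.null(pixel_size)) pixel_size <- lam / 4
  if (is.null(half_extent)) half_extent <- 2 * model$radius
  k0 <- 2 * pi / lam
  n_ext <- model$n_exterior
  fm <- new_field_map(plane, pixel_size, half_extent, model$center[2:3])
  f <- if (is.null(fields)) record_fields(tr, forward_only = TRUE) else fields
  fm$skipped <- nrow(tr$records) - nrow(f)
  X <- model$center[1] + model$radius + plane
  s <- (X - f$x) / f$dx
  yl <- f$y + s * f$dy
  zl <- f$z + s * f$dz
  scale <- tr$spacing / pixel_size      # record amplitude -> field density * px
  adv <- scale * exp(1i * k0 * n_ext * s)
  Ey <- f$Ey * adv
  Ez <- f$Ez * adv
  np <- length(fm$y)
  iy <- floor((yl - fm$y[1]) / pixel_size + 0.5) + 1
  iz <- floor((zl - fm$z[1]) / pixel_size + 0.5) + 1
  ok <- iy >= 1 & iy <= np & iz >= 1 & iz <= np & s > 0
  fm$outside <- sum(!ok)
  fm$landed_energy <- sum(f$energy[ok])
  idx <- iy[ok] + (iz[ok] - 1) * np
  acc <- rowsum(cbind(Re(Ey[ok]), Im(Ey[ok]), Re(Ez[ok]), Im(Ez[ok])), idx)
  ii <- as.integer(rownames(acc))
  fm$Ey[ii] <- complex(real = acc[, 1], imaginary = acc[, 2])
  fm$Ez[ii] <- complex(real = acc[, 3], imaginary = acc[, 4])
  if (psf) {
    na <- if (psf_na == "medium") n_ext
          else n_ext * min(1, model$radius / sqrt(model$radius^2 + plane^2))
    kern <- airy_kernel(k0, na, pixel_size, max_halfwidth = half_extent)
    fm$Ey <- conv2_fft(fm$Ey, kern)
    fm$Ez <- conv2_fft(fm$Ez, kern)
  }
  fm$intensity <- Mod(fm$Ey)^2 + Mod(fm$Ez)^2
  fm$total_power <- sum(fm$intensity)
  if (renormalize && fm$total_power > 0) {
    fac <- fm$landed_energy / fm$total_power
    fm$Ey <- fm$Ey * sqrt(fac)
    fm$Ez <- fm$Ez * sqrt(fac)
    fm$intensity <- fm$intensity * fac
    fm$total_power <- fm$landed_energy
    fm$renormalization <- fac
  }
  class(fm) <- "field_map"
  fm
}

# Airy amplitude kernel 2 J1(v)/v, v = k0 NA r, normalised to unit DC gain
# so extended in-band fields pass with their power unchanged
airy_kernel <- function(k0, na, pixel, max_halfwidth = Inf) {
  r1 <- 3.8317 / (k0 * na)            # first dark ring
  m <- max(1L, as.integer(ceiling(min(3 * r1, max_halfwidth) / pixel)))
  coord <- (-m:m) * pixel
  r <- sqrt(outer(coord^2, coord^2, "+"))
  v <- k0 * na * r
  h <- ifelse(v < 1e-9, 1, 2 * besselJ(v, 1) / pmax(v, 1e-12))
  h / sum(h)
}

# zero-padded FFT convolution, 'same' size
conv2_fft <- function(x, k) {
  nx <- nrow(x); nk <- nrow(k)
  n <- nx + nk - 1
  X <- stats::fft(rbind(cbind(x, matrix(0, nx, n - nx)), matrix(0, n - nx, n)))
  K <- stats::fft(rbind(cbind(k, matrix(0, nk, n - nk)), matrix(0, n - nk, n)))
  full <- stats::fft(X * K, inverse = TRUE) / n^2
  off <- (nk - 1) %/% 2
  full[(off + 1):(off + nx), (off + 1):(off + nx)]
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field_map> plane %+g nm | %d x %d px (%.1f nm) | power %.4g\n",
              x$plane, length(x$y), length(x$z), x$pixel, x$total_power))
  invisible(x)
}

#' Surface-patch (Huygens) near-field integration
#'
#' Exit records are first binned onto spherical surface patches (~`patch_nm`
#' across, on an angular tiling of the exit hemisphere); each patch then
#' re-emits its summed complex amplitude toward the image plane as a
#' spherical wavelet (Rayleigh-Sommerfeld kernel
#' \eqn{dS/(i\lambda)\, e^{ik\ell}/\ell} with obliquity
#' \eqn{\max(0, \cos\chi)} about the patch's energy-weighted mean direction).
#'
#' @inheritParams accumulate_first_order
#' @param patch_nm nominal patch diameter in nm (default 100).
#' @return a `field_map` (no separate PSF is applied; the wavelet sum is
#'   already diffraction-limited by the patch sampling).
#' @export
patch_integrate <- function(tr, plane, pixel_size = NULL, half_extent = NULL,
                            patch_nm = 100) {
  model <- tr$model
  lam <- tr$wavelength
  if (is.null(pixel_size)) pixel_size <- lam / 4
  if (is.null(half_extent)) half_extent <- 2 * model$radius
  k <- 2 * pi / lam * model$n_exterior
  R <- model$radius
  f <- record_fields(tr, forward_only = TRUE)
  # angular tiling of the forward hemisphere about +x
  p_rel <- cbind(f$x - model$center[1], f$y - model$center[2], f$z - model$center[3])
  th <- acos(pmax(-1, pmin(1, p_rel[, 1] / R)))      # polar angle from +x
  ph <- atan2(p_rel[, 3], p_rel[, 2])
  dth <- patch_nm / R
  ith <- pmin(floor(th / dth), floor(pi / dth))
  nphi <- pmax(1, round(2 * pi * R * sin((ith + 0.5) * dth) / patch_nm))
  iph <- floor((ph + pi) / (2 * pi) * nphi)
  iph <- pmin(iph, nphi - 1)
  key <- paste(ith, iph)
  geo <- rowsum(cbind(p_rel[, 1], p_rel[, 2], p_rel[, 3], 1,
                      f$energy * f$dx, f$energy * f$dy, f$energy * f$dz,
                      f$energy), key)
  cnt <- geo[, 4]
  pos <- geo[, 1:3, drop = FALSE] / cnt
  # project mean positions back to the sphere
  pos <- pos / pmax(sqrt(rowSums(pos^2)), 1e-12) * R
  mdir <- geo[, 5:7, drop = FALSE] / pmax(geo[, 8], 1e-300)
  mdir <- mdir / pmax(sqrt(rowSums(mdir^2)), 1e-12)
  # phase-reference every record to its patch center along its own
  # direction (plane-wavelet extrapolation); without this the ~lambda/4
  # patch size injects up to +-pi/2 of binning phase error
  row_of <- match(key, rownames(geo))
  dpos <- pos[row_of, , drop = FALSE] - p_rel
  dph <- exp(1i * k * (f$dx * dpos[, 1] + f$dy * dpos[, 2] + f$dz * dpos[, 3]))
  Eya <- f$Ey * dph
  Eza <- f$Ez * dph
  agg <- rowsum(cbind(Re(Eya), Im(Eya), Re(Eza), Im(Eza)), key)
  Ey <- complex(real = agg[, 1], imaginary = agg[, 2])
  Ez <- complex(real = agg[, 3], imaginary = agg[, 4])
  pos <- sweep(pos, 2, model$center, "+")
  fm <- new_field_map(plane, pixel_size, half_extent, model$center[2:3])
  X <- model$center[1] + R + plane
  np <- length(fm$y)
  yy <- matrix(fm$y, np, np)
  zz <- matrix(fm$z, np, np, byrow = TRUE)
  accEy <- matrix(0 + 0i, np, np)
  accEz <- matrix(0 + 0i, np, np)
  # each record is a beamlet of area spacing^2; the Rayleigh-Sommerfeld sum
  # over patch-binned amplitudes then carries spacing * pixel / (i lambda_med)
  pref <- tr$spacing * pixel_size / (1i * lam / model$n_exterior)
  for (i in seq_along(Ey)) {
    dxp <- X - pos[i, 1]
    dyp <- yy - pos[i, 2]
    dzp <- zz - pos[i, 3]
    ell <- sqrt(dxp^2 + dyp^2 + dzp^2)
    cchi <- (dxp * mdir[i, 1] + dyp * mdir[i, 2] + dzp * mdir[i, 3]) / ell
    cchi[cchi < 0] <- 0
    kern <- pref * exp(1i * k * ell) / ell * cchi
    accEy <- accEy + Ey[i] * kern
    accEz <- accEz + Ez[i] * kern
  }
  fm$Ey <- accEy
  fm$Ez <- accEz
  fm$intensity <- Mod(fm$Ey)^2 + Mod(fm$Ez)^2
  fm$total_power <- sum(fm$intensity)
  fm$n_patches <- length(Ey)
  class(fm) <- "field_map"
  fm
}

#' Power through an on-axis disk of a field map
#'
#' @param fm a `field_map`.
#' @param radius disk radius in nm.
#' @param center_yz disk center (defaults to the map center).
#' @return scalar power.
#' @export
disk_power <- function(fm, radius, center_yz = NULL) {
  if (is.null(center_yz)) center_yz <- c(mean(fm$y), mean(fm$z))
  np <- length(fm$y)
  yy <- matrix(fm$y, np, np) - center_yz[1]
  zz <- matrix(fm$z, np, np, byrow = TRUE) - center_yz[2]
  r <- sqrt(yy^2 + zz^2)
  # linear anti-aliasing of the rim pixels
  w <- pmin(1, pmax(0, (radius - r) / fm$pixel + 0.5))
  sum(fm$intensity * w)
}

#' Locate the plane of best geometric focus
#'
#' Traces the model once, integrates the exit field onto each candidate
#' image plane with [accumulate_first_order()], and reports the plane with
#' the highest peak intensity. When no plane's peak exceeds 1.05x the
#' free-propagation background level the result is flagged as having no
#' definitive focus.
#'
#' @param model a `mitochondrion_model`.
#' @param wavelength nm.
#' @param plane_range numeric length-2, nm behind the rear pole
#'   (default 500-6000).
#' @param step plane spacing in nm (default 100).
#' @param spacing source-grid ray spacing in nm.
#' @param strategy,epsilon,seed passed to [trace()].
#' @param pixel_size,half_extent map geometry passed to
#'   [accumulate_first_order()].
#' @param tr optional pre-computed `trace_result` to reuse.
#' @return object of class `focus_result`: `focus_nm` (plane of maximum peak
#'   intensity behind the rear pole; still reported when `no_focus` is set,
#'   as the location of the global intensity maximum), `peak_intensity` and
#'   `lateral_offset_nm` (from the diffraction-limited map at that plane),
#'   `centered` (offset < 2 pixels), `no_focus` flag, and the per-plane
#'   profile table.
#' @export
find_focus <- function(model, wavelength, plane_range = c(500, 6000),
                       step = 100, spacing = 15, strategy = "ii",
                       epsilon = 1e-9, seed = 1, pixel_size = NULL,
                       half_extent = NULL, tr = NULL) {
  if (is.null(tr)) {
    src <- source_grid(spacing = spacing, radius = model$radius,
                       wavelength = wavelength)
    tr <- trace(model, src, strategy = strategy, epsilon = epsilon, seed = seed,
                record_floor = 1e-10)
  }
  # lambda/8 pixels: arrival angles span most of the hemisphere, so the
  # transverse field needs finer-than-Nyquist sampling for stable peaks
  if (is.null(pixel_size)) pixel_size <- wavelength / 8
  if (is.null(half_extent)) half_extent <- 1.5 * model$radius
  planes <- seq(plane_range[1], plane_range[2], by = step)
  fields <- record_fields(tr, forward_only = TRUE)
  prof <- data.frame(plane = planes, raw_peak = NA_real_, offset = NA_real_,
                     power = NA_real_)
  for (i in seq_along(planes)) {
    raw <- accumulate_first_order(tr, planes[i], pixel_size, half_extent,
                                  psf = FALSE, fields = fields)
    pk <- which.max(raw$intensity)
    iy <- (pk - 1) %% length(raw$y) + 1
    iz <- (pk - 1) %/% length(raw$y) + 1
    prof$raw_peak[i] <- raw$intensity[pk]
    prof$offset[i] <- sqrt((raw$y[iy] - model$center[2])^2 +
                           (raw$z[iz] - model$center[3])^2)
    prof$power[i] <- raw$total_power
  }
  # plane selection on a 3-plane rolling mean of the interference peaks:
  # single-plane argmax jitters with the speckle realisation
  sm <- prof$raw_peak
  n <- length(sm)
  if (n >= 3)
    sm <- c(sm[1], (prof$raw_peak[-c(n - 1, n)] + prof$raw_peak[-c(1, n)] +
                    prof$raw_peak[-c(1, 2)]) / 3, sm[n])
  prof$peak_smooth <- sm
  best <- which.max(sm)
  # significance of the focus: pre-PSF peaks against the analytic
  # free-propagation level (raw maps preserve smooth coherent fields exactly)
  background <- tr$ledger$input * pixel_size^2 / (pi * model$radius^2)
  no_focus <- max(prof$raw_peak) <= 1.05 * background
  # diffraction-limited map at the selected plane for the reported shape
  fm <- accumulate_first_order(tr, planes[best], pixel_size, half_extent,
                               psf = TRUE, fields = fields)
  pk <- which.max(fm$intensity)
  iy <- (pk - 1) %% length(fm$y) + 1
  iz <- (pk - 1) %/% length(fm$y) + 1
  offset <- sqrt((fm$y[iy] - model$center[2])^2 +
                 (fm$z[iz] - model$center[3])^2)
  structure(list(focus_nm = prof$plane[best],
                 peak_intensity = fm$intensity[pk],
                 raw_peak_intensity = prof$raw_peak[best],
                 lateral_offset_nm = offset,
                 centered = offset < 2 * pixel_size,
                 no_focus = no_focus, profile = prof,
                 background = background, wavelength = wavelength,
                 trace = tr),
            class = "focus_result")
}

#' @export
print.focus_result <- function(x, ...) {
  cat(sprintf("<focus_result> %g nm: %s %.2f um behind rear pole, peak %.3g, offset %.0f nm (%s)\n",
              x$wavelength,
              if (x$no_focus) "no definitive focus; intensity maximum"
              else "focus", x$focus_nm / 1000, x$peak_intensity,
              x$lateral_offset_nm, if (x$centered) "centered" else "off-center"))
  invisible(x)
}

#' Flux-ratio spectrum through the mitochondrion-diameter disk
#'
#' For each wavelength, the total power through an on-axis disk of the
#' sphere's diameter at each image plane, as a ratio to the free-propagation
#' flux of the same source. The denominator is computed analytically: the
#' full source disc passes through the reference disk under free propagation,
#' so it equals the input energy. The numerator is the geometric energy
#' transport: the summed energy of forward exit records whose straight-line
#' propagation crosses the plane inside the disk. Disk-scale flux is an
#' energy integral over many speckle grains and is therefore robust to the
#' sub-sampling-scale phase chaos of the membrane exit field (see the
#' methods vignette); sub-disk interference structure does not move the
#' disk total.
#'
#' @param model a `mitochondrion_model`.
#' @param wavelengths numeric vector, nm.
#' @param planes numeric vector, nm behind the rear pole.
#' @param spacing source-grid spacing in nm.
#' @param strategy,epsilon,seed passed to [trace()].
#' @return object of class `flux_spectrum`: long data.frame `ratio` with
#'   columns wavelength, plane, ratio; plus the source description.
#' @export
flux_ratio_spectrum <- function(model, wavelengths = seq(350, 900, by = 50),
                                planes = seq(1000, 6000, by = 500),
                                spacing = 15, strategy = "ii", epsilon = 1e-9,
                                seed = 1) {
  out <- vector("list", length(wavelengths))
  for (iw in seq_along(wavelengths)) {
    lam <- wavelengths[iw]
    src <- source_grid(spacing = spacing, radius = model$radius, wavelength = lam)
    tr <- trace(model, src, strategy = strategy, epsilon = epsilon, seed = seed,
                record_floor = 1e-10)
    f <- record_fields(tr, forward_only = TRUE)
    ratios <- vapply(planes, function(pl) {
      X <- model$center[1] + model$radius + pl
      s <- (X - f$x) / f$dx
      r2 <- (f$y + s * f$dy - model$center[2])^2 +
            (f$z + s * f$dz - model$center[3])^2
      sum(f$energy[s > 0 & r2 <= model$radius^2]) / tr$ledger$input
    }, numeric(1))
    out[[iw]] <- data.frame(wavelength = lam, plane = planes, ratio = ratios)
  }
  structure(list(ratio = do.call(rbind, out), spacing = spacing),
            class = "flux_spectrum")
}

#' Rotation-robustness sweep
#'
#' Rotates the lattice about `axis` by each angle, traces, and reports the
#' total forward-transmitted energy and the intensity within the central
#' beam (on-axis disk of radius R/4) at the zero-angle focus plane. The
#' relative variation reported for each quantity is (max - min) / mean.
#'
#' @param model a `mitochondrion_model`.
#' @param axis rotation axis (default z, perpendicular to propagation).
#' @param angles_deg numeric vector of rotation angles in degrees.
#' @param wavelength nm.
#' @param spacing source-grid spacing in nm.
#' @param strategy,epsilon,seed passed to [trace()].
#' @param focus_plane central-beam evaluation plane in nm behind the rear
#'   pole; `NULL` locates the zero-angle focus first.
#' @return object of class `rotation_sweep`: per-angle table, the two
#'   relative variations, and the focus plane used.
#' @export
rotation_sweep <- function(model, axis = c(0, 0, 1),
                           angles_deg = seq(0, 80, by = 10),
                           wavelength = 550, spacing = 15,
                           strategy = "ii", epsilon = 1e-9, seed = 1,
                           focus_plane = NULL) {
  rotate_model <- function(ang) {
    lat <- model$lattice
    lat$orientation <- rotation_about(axis, ang) %*% lat$orientation
    m <- model
    m$lattice <- gyroid_lattice(lat$a, lat$orientation, lat$phase_offset)
    m
  }
  tab <- data.frame(angle = angles_deg, transmitted = NA_real_,
                    central = NA_real_)
  traces <- vector("list", length(angles_deg))
  for (i in seq_along(angles_deg)) {
    m <- rotate_model(angles_deg[i])
    src <- source_grid(spacing = spacing, radius = m$radius,
                       wavelength = wavelength)
    traces[[i]] <- trace(m, src, strategy = strategy, epsilon = epsilon,
                         seed = seed, record_floor = 1e-10)
    tab$transmitted[i] <- traces[[i]]$ledger$exited_forward /
      traces[[i]]$ledger$input
  }
  if (is.null(focus_plane)) {
    i0 <- which.min(abs(angles_deg))
    f0 <- find_focus(model, wavelength, tr = traces[[i0]])
    focus_plane <- if (f0$no_focus) 3000 else f0$focus_nm
  }
  for (i in seq_along(angles_deg)) {
    # diffraction-limited, energy-renormalised map: the R/4 disk spans only a
    # few speckle grains, so the raw coherent map is too noisy across angles
    fm <- accumulate_first_order(traces[[i]], focus_plane, psf = TRUE,
                                 renormalize = TRUE)
    tab$central[i] <- disk_power(fm, model$radius / 4, model$center[2:3])
  }
  relvar <- function(x) (max(x) - min(x)) / mean(x)
  structure(list(table = tab,
                 energy_variation = relvar(tab$transmitted),
                 central_variation = relvar(tab$central),
                 focus_plane = focus_plane, wavelength = wavelength),
            class = "rotation_sweep")
}

#' @export
print.rotation_sweep <- function(x, ...) {
  cat(sprintf("<rotation_sweep> %g nm, %d angles | energy variation %.1f%%, central-beam variation %.1f%%\n",
              x$wavelength, nrow(x$table), 100 * x$energy_variation,
              100 * x$central_variation))
  invisible(x)
}

#' Waveguide transport diagnostics
#'
#' Reports the fraction of forward-exited energy whose exit points lie in the
#' mouths of the higher-index compartment's channels (compartment B), against
#' the geometric area fraction of those channels on the exit hemisphere. An
#' excess over the area fraction indicates preferential guiding.
#'
#' @param model a `mitochondrion_model`.
#' @param wavelengths numeric vector, nm.
#' @param spacing source-grid spacing in nm.
#' @param strategy,epsilon,seed passed to [trace()].
#' @return object of class `waveguide_report`: per-wavelength table with
#'   `channel_fraction`, constant `area_fraction`, `enhancement`, a
#'   `monotone_increasing` flag over wavelength, and `no_waveguide` when the
#'   compartment indices are equal.
#' @export
waveguide_diagnostics <- function(model, wavelengths = c(450, 550, 650, 750),
                                  spacing = 15, strategy = "ii",
                                  epsilon = 1e-9, seed = 1) {
  # area fraction of compartment-B mouths on the exit hemisphere
  nseed <- 20000
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u <- stats::runif(nseed); v <- stats::runif(nseed)
  cth <- u                       # x/R in (0, 1): forward hemisphere
  sth <- sqrt(1 - cth^2)
  phi <- 2 * pi * v
  pts <- cbind(cth, sth * cos(phi), sth * sin(phi)) * (model$radius - 1)
  pts <- sweep(pts, 2, model$center, "+")
  area_fraction <- mean(classify_point(model, pts) == "compartment_B")
  tab <- data.frame(wavelength = wavelengths, channel_fraction = NA_real_,
                    forward = NA_real_)
  for (i in seq_along(wavelengths)) {
    src <- source_grid(spacing = spacing, radius = model$radius,
                       wavelength = wavelengths[i])
    tr <- trace(model, src, strategy = strategy, epsilon = epsilon, seed = seed,
                record_floor = 1e-10)
    r <- tr$records[tr$records$forward, , drop = FALSE]
    inside <- cbind(r$x - r$dx, r$y - r$dy, r$z - r$dz)   # 1 nm back inside
    reg <- classify_point(model, inside)
    w <- r$energy
    tab$channel_fraction[i] <- sum(w[reg == "compartment_B"]) / sum(w)
    tab$forward[i] <- tr$ledger$exited_forward / tr$ledger$input
  }
  tab$enhancement <- tab$channel_fraction / area_fraction
  structure(list(table = tab, area_fraction = area_fraction,
                 monotone_increasing = all(diff(tab$channel_fraction) >= -0.02),
                 no_waveguide = isTRUE(all.equal(model$n_A, model$n_B))),
            class = "waveguide_report")
}

#' @export
print.waveguide_report <- function(x, ...) {
  cat(sprintf("<waveguide_report> area fraction %.3f%s\n", x$area_fraction,
              if (x$no_waveguide) " [equal indices: no waveguide expected]" else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}
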