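#' Plane-wave source grid
#'
#' Rays are fired parallel to +x from a square grid in the y-z plane whose
#' points are offset by half a spacing and kept only where they fall inside
#' the circle of radius `radius`, so every ray's line intersects the sphere.
#' All rays share wavelength, phase (zero) and a common Jones polarization
#' expressed in the global (y, z) transverse basis.
#'
#' @param spacing grid spacing in nm, in \[2, 50\].
#' @param radius extent radius in nm (the mitochondrion radius).
#' @param polarization length-2 (possibly complex) Jones vector `(Ey, Ez)`;
#'   normalised so each ray carries unit energy.
#' @param wavelength vacuum wavelength in nm.
#' @return object of class `source_grid`.
#' @export
source_grid <- function(spacing = 10, radius = 1000,
                        polarization = c(1, 0), wavelength = 550) {
  stopifnot(spacing >= 2, spacing <= 50, radius > 0, wavelength > 0,
            length(polarization) == 2)
  if (sum(Mod(polarization)^2) <= 0) stop("polarization must be non-zero")
  structure(list(spacing = spacing, radius = radius,
                 polarization = as.complex(polarization),
                 wavelength = wavelength),
            class = "source_grid")
}

#' Generate the light packets of a source grid
#'
#' @param grid a [source_grid()].
#' @param model a `mitochondrion_model` (sets the launch plane and center).
#' @return list with `origins` (n x 3 matrix, nm), `direction` (+x),
#'   `polarization`, `wavelength`, and `n_rays`.
#' @export
make_source <- function(grid, model) {
  stopifnot(inherits(grid, "source_grid"))
  s <- grid$spacing
  R <- grid$radius
  m <- ceiling(R / s)
  off <- (seq(-m, m) + 0.5) * s
  yz <- expand.grid(y = off, z = off)
  keep <- yz$y^2 + yz$z^2 < R^2
  yz <- yz[keep, , drop = FALSE]
  x0 <- model$center[1] - model$radius - 10
  origins <- cbind(x0, yz$y + model$center[2], yz$z + model$center[3])
  colnames(origins) <- c("x", "y", "z")
  list(origins = origins, direction = c(1, 0, 0),
       polarization = grid$polarization, wavelength = grid$wavelength,
       n_rays = nrow(origins), spacing = s)
}

#' Scatter a packet at a surface hit (single-event reference path)
#'
#' Re-expresses the packet's Jones amplitudes in the s/p basis of the plane
#' of incidence, evaluates the wall stack (or bare interface) at the local
#' angle, and returns the transmitted and reflected child packets. This is
#' the R reference implementation of the event kernel used (in compiled form)
#' inside [trace()]; the two are cross-checked in the test suite.
#'
#' @param packet list with `position`, `direction`, `basis_s` (unit vector,
#'   the s axis of the current transverse basis), complex `amplitude_s`,
#'   `amplitude_p`, `phase`, `energy`, `wavelength`.
#' @param hit a `surface_hit` from [intersect_ray()].
#' @param model a `mitochondrion_model`.
#' @return list `transmitted`, `reflected` (either may be `NULL`), plus
#'   `tir` flag. Child energies sum to the parent energy below TIR.
#' @export
scatter <- function(packet, hit, model) {
  d <- packet$direction
  idx <- function(region) switch(region, exterior = model$n_exterior,
                                 compartment_A = model$n_A,
                                 compartment_B = model$n_B)
  n_from <- idx(hit$from_region)
  n_to <- idx(hit$to_region)
  nrm <- hit$normal
  nu <- if (sum(d * nrm) > 0) -nrm else nrm
  ct <- max(min(-sum(d * nu), 1), 1e-9)
  st <- sqrt(max(0, 1 - ct^2))
  normal_inc <- st < 1e-6
  shat <- if (normal_inc) packet$basis_s else {
    v <- cross3(d, nu); v / sqrt(sum(v^2))
  }
  b2 <- cross3(d, packet$basis_s)
  phat <- cross3(d, shat)
  As <- packet$amplitude_s * sum(packet$basis_s * shat) + packet$amplitude_p * sum(b2 * shat)
  Ap <- packet$amplitude_s * sum(packet$basis_s * phat) + packet$amplitude_p * sum(b2 * phat)
  wall <- hit$type == "membrane" && model$membranes && length(model$wall$n) > 0
  wn <- if (wall) model$wall$n else numeric(0)
  wd <- if (wall) model$wall$d else numeric(0)
  if (wall && hit$from_region == "compartment_B") {
    wn <- rev(wn); wd <- rev(wd)
  }
  # reference path built on the R-level stratified optics (the compiled
  # tracer carries its own copy; the two are cross-checked in the tests)
  stk <- stratified_stack(n_from, list(n = wn, d = wd), n_to)
  rts <- stack_rt(stk, acos(ct), packet$wavelength, "s")
  rtp <- stack_rt(stk, acos(ct), packet$wavelength, "p")
  flux <- if (rts$tir) 0 else sqrt(Re(stk$ns * refraction_chain(stk, acos(ct),
            packet$wavelength)$cos_theta_s) / (n_from * ct))
  rt <- list(rs = rts$r, rp = rtp$r,
             tsf = rts$t * flux, tpf = rtp$t * flux, tir = rts$tir)
  mk <- function(dir, b1, As, Ap) {
    e <- Mod(As)^2 + Mod(Ap)^2
    list(position = hit$position, direction = dir, basis_s = b1,
         amplitude_s = As, amplitude_p = Ap, phase = packet$phase,
         energy = e, wavelength = packet$wavelength)
  }
  d_r <- d + 2 * ct * nu
  reflected <- mk(d_r / sqrt(sum(d_r^2)), if (normal_inc) packet$basis_s else shat,
                  As * rt$rs, Ap * rt$rp)
  transmitted <- NULL
  if (!rt$tir) {
    mu <- n_from / n_to
    ctt <- sqrt(max(0, 1 - mu^2 * st^2))
    d_t <- mu * d + (mu * ct - ctt) * nu
    transmitted <- mk(d_t / sqrt(sum(d_t^2)),
                      if (normal_inc) packet$basis_s else shat,
                      As * rt$tsf, Ap * rt$tpf)
  }
  if (!is.null(reflected) && reflected$energy < 1e-24) reflected <- NULL
  list(transmitted = transmitted, reflected = reflected, tir = rt$tir)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Trace a source through the model with photon splitting
#'
#' Iterates intersection and scattering until every packet either exits the
#' sphere, falls below the discard threshold, or reaches the depth cap.
#' Splitting strategies: `"i"` Russian roulette (one unbiased survivor per
#' event, seeded counter-based RNG per ray); `"ii"` both branches pursued,
#' weaker first, branches below `epsilon` of the per-ray input energy
#' discarded into the ledger (fully deterministic); `"iii"` as `"ii"` with
#' the transmitted branch of each membrane crossing fanned into a symmetric
#' 3-ray angular kernel emulating small-scale diffraction.
#'
#' @param model a `mitochondrion_model`.
#' @param source output of [make_source()] (or a [source_grid()], which is
#'   expanded against `model`).
#' @param strategy `"i"`, `"ii"` (default) or `"iii"`.
#' @param epsilon discard threshold as a fraction of per-ray input energy.
#' @param max_depth split-generation cap.
#' @param seed integer seed (used by strategy `"i"` only).
#' @param record_floor drop exit records below this energy from the returned
#'   table (they still enter the energy ledger exactly).
#' @return object of class `trace_result`: `records` (data.frame of exit
#'   records), `ledger` (energy bookkeeping), plus run metadata.
#' @export
trace <- function(model, source, strategy = c("ii", "i", "iii"),
                  epsilon = 1e-9, max_depth = 60, seed = 1,
                  record_floor = 0) {
  strategy <- match.arg(strategy)
  if (inherits(source, "source_grid")) source <- make_source(source, model)
  res <- cpp_trace(model_plist(model), source$origins, source$direction,
                   source$polarization, source$wavelength,
                   match(strategy, c("i", "ii", "iii")), epsilon, max_depth,
                   as.double(seed), source$spacing %||% 10, record_floor, 5e7)
  led <- res$ledger
  led$discarded <- led$discarded_eps + led$discarded_depth
  led$balance <- led$input - led$exited_forward - led$exited_backward - led$discarded
  if (led$discarded_depth > 1e-3 * led$input)
    warning(sprintf("max_depth exhausted on %.2f%% of input energy",
                    100 * led$discarded_depth / led$input))
  records <- data.frame(
    x = res$position[, 1], y = res$position[, 2], z = res$position[, 3],
    dx = res$direction[, 1], dy = res$direction[, 2], dz = res$direction[, 3],
    bx = res$basis_s[, 1], by = res$basis_s[, 2], bz = res$basis_s[, 3],
    amplitude_s = res$amplitude_s, amplitude_p = res$amplitude_p,
    phase = res$phase, energy = res$energy,
    depth = res$depth, forward = res$forward == 1L)
  structure(list(records = records, ledger = led,
                 wavelength = source$wavelength, n_rays = source$n_rays,
                 spacing = source$spacing %||% 10,
                 strategy = strategy, epsilon = epsilon, seed = seed,
                 model = model),
            class = "trace_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trace_result <- function(x, ...) {
  l <- x$ledger
  cat("<trace_result>\n")
  cat(sprintf("  %d rays at %g nm, strategy %s | %d exit records\n",
              x$n_rays, x$wavelength, x$strategy, nrow(x$records)))
  cat(sprintf("  energy: input %.4g, forward %.4g (%.2f%%), backward %.4g (%.2f%%), discarded %.4g (%.3f%%)\n",
              l$input, l$exited_forward, 100 * l$exited_forward / l$input,
              l$exited_backward, 100 * l$exited_backward / l$input,
              l$discarded, 100 * l$discarded / l$input))
  invisible(x)
}
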