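#' Gyroid lattice description
#'
#' The cubic-membrane scaffold is modelled as the standard gyroid level-set
#' approximant \eqn{g(u,v,w) = \sin u \cos v + \sin v \cos w + \sin w \cos u}
#' evaluated in rotated, phase-shifted lattice coordinates
#' \eqn{u = 2\pi x / a} etc. The zero level set is the membrane mid-surface
#' onto which the full multilayer wall is collapsed (center approximation).
#'
#' @param a lattice constant in nm (default 400).
#' @param orientation 3x3 rotation matrix (world = orientation %*% lattice),
#'   or a length-3 numeric of ZYX Euler angles in degrees.
#' @param phase_offset length-3 numeric phase offset in lattice units.
#' @return object of class `gyroid_lattice`.
#' @export
gyroid_lattice <- function(a = 400, orientation = diag(3), phase_offset = c(0, 0, 0)) {
  if (!is.numeric(a) || length(a) != 1 || a <= 0)
    stop("lattice constant `a` must be a positive scalar (nm)")
  if (is.numeric(orientation) && is.null(dim(orientation)) && length(orientation) == 3)
    orientation <- rotation_zyx(orientation[1], orientation[2], orientation[3])
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3, 3)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-8 ||
      abs(det(orientation) - 1) > 1e-8)
    stop("`orientation` must be a proper rotation (orthonormal, det +1)")
  stopifnot(length(phase_offset) == 3)
  structure(list(a = a, orientation = orientation,
                 phase_offset = as.numeric(phase_offset)),
            class = "gyroid_lattice")
}

#' Rotation matrix from ZYX Euler angles (degrees)
#'
#' @param z,y,x rotation angles in degrees, applied in Z, then Y, then X
#'   (intrinsic ZYX order): `R = Rz(z) %*% Ry(y) %*% Rx(x)`.
#' @return 3x3 rotation matrix.
#' @export
rotation_zyx <- function(z = 0, y = 0, x = 0) {
  d <- pi / 180
  cz <- cos(z * d); sz <- sin(z * d)
  cy <- cos(y * d); sy <- sin(y * d)
  cx <- cos(x * d); sx <- sin(x * d)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Rotation matrix about an arbitrary axis
#' @param axis length-3 axis (normalised internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Build a sphere-confined lens-mitochondrion model
#'
#' A sphere of radius `radius` clipped against the gyroid mid-surface divides
#' the interior into two interpenetrating labyrinths: compartment A
#' (\eqn{g > 0}, cytosol-like by default) and compartment B (\eqn{g < 0},
#' the dense, higher-index compartment). The membrane wall separating them is
#' carried as a stratified stack applied at each mid-surface crossing; it has
#' no geometric thickness in the ray tracer (center approximation).
#'
#' @param radius sphere radius in nm (default 1000, i.e. 1 um).
#' @param center sphere center in nm.
#' @param lattice a [gyroid_lattice()].
#' @param n_A,n_B refractive indices of the two compartments.
#' @param n_exterior refractive index outside the sphere.
#' @param wall wall stack: a list with numeric `n` and `d` (nm) vectors, the
#'   finite layers met when crossing from the A side; `NULL` for the default
#'   12-bilayer wall ([reference_wall()] layers).
#' @param membranes logical: when `FALSE` the gyroid mid-surface is ignored
#'   entirely and only the spherical envelope refracts (homogeneous ball).
#' @return object of class `mitochondrion_model`.
#' @export
build_mitochondrion <- function(radius = 1000, center = c(0, 0, 0),
                                lattice = gyroid_lattice(),
                                n_A = 1.33, n_B = 1.48, n_exterior = 1.33,
                                wall = NULL, membranes = TRUE) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("`radius` must be a positive scalar (nm)")
  stopifnot(inherits(lattice, "gyroid_lattice"))
  for (nm in c(n_A, n_B, n_exterior))
    if (!is.numeric(nm) || length(nm) != 1 || nm < 1)
      stop("refractive indices must be scalars >= 1")
  if (is.null(wall)) {
    rw <- reference_wall()
    wall <- list(n = rw$n, d = rw$d)
  }
  stopifnot(length(wall$n) == length(wall$d), all(wall$n >= 1), all(wall$d >= 0))
  if (sum(wall$d) >= lattice$a)
    stop("wall stack total thickness must be smaller than the lattice constant")
  structure(list(radius = radius, center = as.numeric(center), lattice = lattice,
                 n_A = n_A, n_B = n_B, n_exterior = n_exterior,
                 wall = wall, membranes = isTRUE(membranes)),
            class = "mitochondrion_model")
}

#' @export
print.mitochondrion_model <- function(x, ...) {
  cat("<mitochondrion_model>\n")
  cat(sprintf("  radius: %g nm  lattice a: %g nm  (diameter = %.2f cells)\n",
              x$radius, x$lattice$a, 2 * x$radius / x$lattice$a))
  cat(sprintf("  n_A = %g, n_B = %g, n_exterior = %g\n", x$n_A, x$n_B, x$n_exterior))
  cat(sprintf("  wall: %d layers, %.1f nm total%s\n", length(x$wall$n), sum(x$wall$d),
              if (x$membranes) "" else "  [membranes disabled]"))
  invisible(x)
}

# flat list passed to the C++ core
model_plist <- function(model) {
  list(radius = model$radius, center = model$center,
       lattice_a = model$lattice$a, orientation = model$lattice$orientation,
       phase_offset = model$lattice$phase_offset,
       n_A = model$n_A, n_B = model$n_B, n_exterior = model$n_exterior,
       wall_n = as.numeric(model$wall$n), wall_d = as.numeric(model$wall$d),
       membranes = model$membranes)
}

#' Evaluate the gyroid level-set function
#'
#' @param model a `mitochondrion_model`.
#' @param p n x 3 matrix (or length-3 vector) of points in nm.
#' @return numeric vector of `g` values.
#' @export
gyroid_value <- function(model, p) {
  p <- rbind_points(p)
  cpp_gyroid_g(model_plist(model), p)
}

#' Classify points into exterior / compartment A / compartment B
#'
#' Points outside the sphere are `exterior`; inside, the sign of the gyroid
#' level function decides: `compartment_A` for \eqn{g \ge 0} (ties resolved to
#' A), `compartment_B` for \eqn{g < 0}.
#'
#' @inheritParams gyroid_value
#' @return factor with levels `exterior`, `compartment_A`, `compartment_B`.
#' @export
classify_point <- function(model, p) {
  p <- rbind_points(p)
  idx <- cpp_classify(model_plist(model), p) + 1L
  factor(c("exterior", "compartment_A", "compartment_B")[idx],
         levels = c("exterior", "compartment_A", "compartment_B"))
}

rbind_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = TRUE)
  storage.mode(p) <- "double"
  p
}

#' Intersect a ray with the model
#'
#' Finds the nearest forward intersection of the ray `origin + s * direction`
#' with either the spherical envelope or the gyroid mid-surface inside it.
#' The mid-surface root is located by sampling `g` along the ray at steps of
#' `a/50` and bisecting the bracketed sign change to 0.1 nm.
#'
#' @param model a `mitochondrion_model`.
#' @param origin length-3 numeric, nm.
#' @param direction length-3 unit vector.
#' @return `NULL` if the ray line misses the sphere, otherwise a `surface_hit`
#'   list: `position`, `normal` (unit, oriented from compartment A toward B
#'   for membrane hits, outward for sphere hits), `theta_incidence` (rad),
#'   `from_region`, `to_region`, `path_length` (nm), `type`.
#' @export
intersect_ray <- function(model, origin, direction) {
  stopifnot(length(origin) == 3, length(direction) == 3)
  nd <- sqrt(sum(direction^2))
  if (abs(nd - 1) > 1e-8) stop("`direction` must be a unit vector")
  h <- cpp_intersect(model_plist(model), as.numeric(origin), as.numeric(direction), 0)
  if (h$type == 0) return(NULL)
  regions <- c("exterior", "compartment_A", "compartment_B")
  normal <- h$normal
  if (h$type == 2) normal <- -normal  # grad g points toward A; report A -> B
  structure(list(position = h$position, normal = normal,
                 theta_incidence = h$theta,
                 from_region = regions[h$from_region + 1L],
                 to_region = regions[h$to_region + 1L],
                 path_length = h$s,
                 type = if (h$type == 1) "sphere" else "membrane"),
            class = "surface_hit")
}

#' Closed-form unit-cell count for a sphere-confined lattice
#'
#' @param diameter_in_cells sphere diameter expressed in lattice constants.
#' @return list with `interior_estimate` (nearest integer to the sphere/cell
#'   volume ratio \eqn{\frac{4}{3}\pi (d/2)^3}) and `boundary_note` (number of
#'   whole lattice cubes intersected by the spherical surface for a sphere
#'   centered on a lattice corner).
#' @export
count_unit_cells <- function(diameter_in_cells) {
  stopifnot(is.numeric(diameter_in_cells), length(diameter_in_cells) == 1,
            diameter_in_cells > 0)
  r <- diameter_in_cells / 2
  interior <- round(4 / 3 * pi * r^3)
  # cubes [i,i+1]^3 whose closest corner-distance straddles the radius
  m <- ceiling(r)
  idx <- seq.int(-m - 1, m)
  grid <- expand.grid(i = idx, j = idx, k = idx)
  lo <- cbind(grid$i, grid$j, grid$k)
  hi <- lo + 1
  nearest <- sqrt(rowSums(pmax(lo, pmin(hi, 0))^2))
  corner_max <- sqrt(rowSums(pmax(abs(lo), abs(hi))^2))
  boundary <- sum(nearest < r & corner_max > r)
  list(interior_estimate = as.integer(interior), boundary_note = as.integer(boundary))
}

#' Volume fractions of the structural roles inside the sphere
#'
#' Monte Carlo estimate over the sphere volume. The wall is assigned the
#' first-order distance band \eqn{|g|/|\nabla g| < t/2} around the
#' mid-surface, where `t` is the total wall-stack thickness; the residual
#' volume is split by the sign of `g` into the two compartments.
#'
#' @param model a `mitochondrion_model`.
#' @param n_samples number of sample points (>= 1e4).
#' @param seed RNG seed.
#' @return named numeric: `wall`, `compartment_A`, `compartment_B` (sums to 1).
#' @export
volume_fractions <- function(model, n_samples = 1e5, seed = 1) {
  stopifnot(n_samples >= 1e4)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  R <- model$radius
  n <- 0L; pts <- NULL
  while (n < n_samples) {
    cand <- matrix(stats::runif(3 * ceiling(1.95 * (n_samples - n)), -R, R), ncol = 3)
    cand <- cand[rowSums(cand^2) <= R^2, , drop = FALSE]
    pts <- rbind(pts, cand)
    n <- nrow(pts)
  }
  pts <- pts[seq_len(n_samples), , drop = FALSE]
  pts <- sweep(pts, 2, model$center, "+")
  g <- gyroid_value(model, pts)
  # |grad g| in lattice units times 2*pi/a gives the spatial gradient scale;
  # evaluate by finite differences for robustness to orientation
  h <- 1e-2 * model$lattice$a
  gx <- (gyroid_value(model, sweep(pts, 2, c(h, 0, 0), "+")) -
         gyroid_value(model, sweep(pts, 2, c(h, 0, 0), "-"))) / (2 * h)
  gy <- (gyroid_value(model, sweep(pts, 2, c(0, h, 0), "+")) -
         gyroid_value(model, sweep(pts, 2, c(0, h, 0), "-"))) / (2 * h)
  gz <- (gyroid_value(model, sweep(pts, 2, c(0, 0, h), "+")) -
         gyroid_value(model, sweep(pts, 2, c(0, 0, h), "-"))) / (2 * h)
  grad <- sqrt(gx^2 + gy^2 + gz^2)
  dist <- abs(g) / pmax(grad, 1e-12)
  t2 <- sum(model$wall$d) / 2
  wall <- mean(dist < t2)
  fa <- mean(dist >= t2 & g >= 0)
  fb <- 1 - wall - fa
  c(wall = wall, compartment_A = fa, compartment_B = fb)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
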