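#' The 25-medium reference membrane wall
#'
#' The wall separating the two gyroid compartments: 12 lipid bilayers
#' (n = 1.70, 1.8 nm each) alternating with 11 cytosolic gap layers
#' (n = 1.38, 10 nm each), bounded on both sides by cytosol-index media
#' (n = 1.33) -- 25 media in total, 131.6 nm of finite layers. Indices are
#' referenced at the Fraunhofer D line (587.56 nm); no dispersion is modelled.
#'
#' @param n_bound bounding medium index (both sides), default 1.33.
#' @return a [stratified_stack()] with attribute `layers` giving the finite
#'   layer table.
#' @export
reference_wall <- function(n_bound = 1.33) {
  n <- rep(c(1.70, 1.38), length.out = 23)
  d <- rep(c(1.8, 10.0), length.out = 23)
  s <- stratified_stack(n_bound, list(n = n, d = d), n_bound)
  s
}

#' Equivalent-bilayer parameter set
#'
#' @param na outer refractive index, in \[1, 2\].
#' @param nb core refractive index, in \[1, 2\].
#' @param da outer thickness, nm, in (0, 500).
#' @param db core thickness, nm, in (0, 500).
#' @return object of class `bilayer_params`.
#' @export
bilayer_params <- function(na, nb, da, db) {
  x <- c(na = na, nb = nb, da = da, db = db)
  if (na < 1 || na > 2 || nb < 1 || nb > 2)
    stop("refractive indices must lie in [1, 2]")
  if (da <= 0 || da >= 500 || db <= 0 || db >= 500)
    stop("thicknesses must lie in (0, 500) nm")
  structure(as.list(x), class = "bilayer_params")
}

#' Build the closed-bilayer stack for a parameter set
#'
#' Two variants are supported. `"two_layer"` is the minimal reading of the
#' four parameters: the asymmetric stack \[na, da\]\[nb, db\] between the
#' bounding media. `"sandwich"` mirrors a closed membrane with two outer
#' leaflets: \[na, da\]\[nb, db\]\[na, da\]. The default is `"sandwich"`,
#' which reproduces the reference-wall equivalence fit; the variant used is
#' recorded in run manifests.
#'
#' @param x a [bilayer_params()].
#' @param n_bound bounding medium index.
#' @param variant `"sandwich"` or `"two_layer"`.
#' @return a [stratified_stack()].
#' @export
bilayer_stack <- function(x, n_bound = 1.33, variant = c("sandwich", "two_layer")) {
  variant <- match.arg(variant)
  if (variant == "two_layer")
    stratified_stack(n_bound, list(n = c(x$na, x$nb), d = c(x$da, x$db)), n_bound)
  else
    stratified_stack(n_bound, list(n = c(x$na, x$nb, x$na), d = c(x$da, x$db, x$da)),
                     n_bound)
}

#' Reflectance-difference objective between a wall and a closed bilayer
#'
#' \deqn{\sum_{i,j} |R_\perp(\lambda_i,\theta_j) - \hat R_\perp| +
#'       |R_\parallel(\lambda_i,\theta_j) - \hat R_\parallel|}
#' over the sampling grid (default: 400-800 nm in 5 nm steps, 0-90 degrees in
#' 1 degree steps).
#'
#' @param x a [bilayer_params()] (or named list/vector na, nb, da, db).
#' @param reference a [stratified_stack()] (default [reference_wall()]), or a
#'   precomputed reference grid from [reflectance_grid()].
#' @param wavelengths,angles sampling grids (nm, degrees).
#' @param variant bilayer topology, see [bilayer_stack()].
#' @return non-negative scalar.
#' @export
bilayer_objective <- function(x, reference = reference_wall(),
                              wavelengths = seq(400, 800, by = 5),
                              angles = seq(0, 90, by = 1),
                              variant = c("sandwich", "two_layer")) {
  variant <- match.arg(variant)
  if (!inherits(x, "bilayer_params")) x <- bilayer_params(x[["na"]], x[["nb"]], x[["da"]], x[["db"]])
  ref_grid <- if (is.data.frame(reference)) reference
              else reflectance_grid(reference, wavelengths, angles)
  bg <- reflectance_grid(bilayer_stack(x, variant = variant), wavelengths, angles)
  sum(abs(ref_grid$Rs - bg$Rs)) + sum(abs(ref_grid$Rp - bg$Rp))
}

#' Fit the equivalent closed bilayer to a reference wall
#'
#' Bound-constrained quasi-Newton minimisation (PORT routines via
#' [stats::nlminb()]) of [bilayer_objective()], multi-started from a fixed
#' set of quasi-random initial points plus any user-supplied start; the best
#' local minimiser is returned.
#'
#' @param reference a [stratified_stack()], default [reference_wall()].
#' @param init optional [bilayer_params()] start added to the multi-start set.
#' @param lower,upper named bounds for `na`, `nb`, `da`, `db`.
#' @param n_starts number of quasi-random starts (>= 8 recommended).
#' @param wavelengths,angles objective sampling grids.
#' @param variant bilayer topology, see [bilayer_stack()].
#' @return list with `params` ([bilayer_params()]), `objective`, `variant`,
#'   `starts` (per-start results), `mean_index` and `total_thickness` of the
#'   fitted bilayer.
#' @export
fit_bilayer <- function(reference = reference_wall(), init = NULL,
                        lower = c(na = 1.33, nb = 1.33, da = 1, db = 1),
                        upper = c(na = 2.0, nb = 2.0, da = 200, db = 200),
                        n_starts = 8,
                        wavelengths = seq(400, 800, by = 5),
                        angles = seq(0, 90, by = 1),
                        variant = c("sandwich", "two_layer")) {
  variant <- match.arg(variant)
  ref_grid <- reflectance_grid(reference, wavelengths, angles)
  obj <- function(p) {
    p <- pmin(pmax(p, lower), upper)
    x <- list(na = p[1], nb = p[2], da = p[3], db = p[4])
    bg <- grid_rt_stack(bilayer_stack_raw(x, variant), ref_grid)
    sum(abs(ref_grid$Rs - bg$Rs)) + sum(abs(ref_grid$Rp - bg$Rp))
  }
  # fixed quasi-random (Halton) starts spanning the box
  starts <- halton_box(n_starts, lower, upper)
  if (!is.null(init)) {
    stopifnot(inherits(init, "bilayer_params"))
    starts <- rbind(unlist(init)[c("na", "nb", "da", "db")], starts)
  }
  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    p0 <- as.numeric(starts[i, ])
    fit <- stats::nlminb(p0, obj, lower = lower, upper = upper,
                         control = list(eval.max = 2000, iter.max = 500))
    runs[[i]] <- list(start = p0, par = fit$par, objective = fit$objective,
                      convergence = fit$convergence, objective_at_start = obj(p0))
  }
  objs <- vapply(runs, function(r) r$objective, numeric(1))
  if (all(!is.finite(objs)))
    stop("bilayer fit failed to converge from any start")
  best <- runs[[which.min(objs)]]
  p <- best$par
  params <- bilayer_params(p[1], p[2], p[3], p[4])
  weights <- if (variant == "sandwich") c(2 * p[3], p[4]) else c(p[3], p[4])
  list(params = params, objective = best$objective, variant = variant,
       starts = runs,
       mean_index = sum(c(p[1], p[2]) * weights) / sum(weights),
       total_thickness = sum(weights))
}

# minimal stack constructor used inside the optimizer hot loop
bilayer_stack_raw <- function(x, variant) {
  if (variant == "two_layer")
    list(n0 = 1.33, n = c(x$na, x$nb), d = c(x$da, x$db), ns = 1.33)
  else
    list(n0 = 1.33, n = c(x$na, x$nb, x$na), d = c(x$da, x$db, x$da), ns = 1.33)
}

grid_rt_stack <- function(stack_list, ref_grid) {
  class(stack_list) <- "stratified_stack"
  thv <- pmin(ref_grid$angle_deg * pi / 180, pi / 2 - 1e-6)
  grid_rt(stack_list, ref_grid$wavelength_nm, thv)
}

# deterministic Halton sequence mapped into the bound box
halton_box <- function(n, lower, upper) {
  halton1 <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  bases <- c(2, 3, 5, 7)
  pts <- t(vapply(seq_len(n), function(i)
    vapply(bases, function(b) halton1(i, b), numeric(1)), numeric(4)))
  sweep(sweep(pts, 2, upper - lower, "*"), 2, lower, "+")
}

#' Thickness-weighted mean refractive index of a stack
#'
#' @param stack a [stratified_stack()].
#' @return scalar mean index over the finite layers.
#' @export
mean_index <- function(stack) {
  sum(stack$n * stack$d) / sum(stack$d)
}
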