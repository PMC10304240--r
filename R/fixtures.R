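#' Deterministic test fixtures
#'
#' Named model/stack generators used throughout the test suite and available
#' to users for calibration runs:
#' \describe{
#'   \item{`flat_wall`}{the 25-medium reference wall as an infinite slab
#'     (a [stratified_stack()]) for spectral checks.}
#'   \item{`null_sphere`}{a `mitochondrion_model` with every index 1.33 and
#'     an index-matched wall: optically empty, rays pass undeviated.}
#'   \item{`ball_lens`}{a homogeneous sphere at the thickness-weighted mean
#'     index of the wall layers (~1.43) with membranes disabled: a classical
#'     ball lens for focal-distance oracles.}
#'   \item{`reference_wall`}{the canonical 12-bilayer wall stack, identical to
#'     [reference_wall()].}
#' }
#'
#' @param name fixture name.
#' @param ... overrides forwarded to the underlying constructor.
#' @return a `mitochondrion_model` or `stratified_stack`.
#' @export
make_fixture <- function(name = c("flat_wall", "null_sphere", "ball_lens",
                                  "reference_wall"), ...) {
  name <- tryCatch(match.arg(name),
                   error = function(e)
                     stop("unknown fixture; choose one of: flat_wall, ",
                          "null_sphere, ball_lens, reference_wall"))
  switch(name,
    flat_wall = reference_wall(),
    reference_wall = reference_wall(),
    null_sphere = build_mitochondrion(n_A = 1.33, n_B = 1.33,
                                      n_exterior = 1.33, membranes = FALSE,
                                      ...),
    ball_lens = {
      nbar <- mean_index(reference_wall())
      build_mitochondrion(n_A = round(nbar, 2), n_B = round(nbar, 2),
                          n_exterior = 1.33, membranes = FALSE, ...)
    })
}

#' List available fixtures
#' @return character vector of fixture names.
#' @export
list_fixtures <- function() c("flat_wall", "null_sphere", "ball_lens", "reference_wall")
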