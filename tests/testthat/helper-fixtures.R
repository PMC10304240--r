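# shared helpers: small deterministic sources and an independent Fresnel
# recursion oracle for the characteristic-matrix optics

# a reduced source: full grid thinned to roughly n rays (deterministic)
small_source <- function(model, n = 400, wavelength = 550,
                         polarization = c(1, 0)) {
  spacing <- max(2, min(50, sqrt(pi * model$radius^2 / n)))
  src <- source_grid(spacing = spacing, radius = model$radius,
                     polarization = polarization, wavelength = wavelength)
  make_source(src, model)
}

# independent multilayer oracle: Airy summation via recursive Fresnel
# interface coefficients (no characteristic matrices anywhere)
fresnel_recursion_rt <- function(stack, theta0, wavelength, polarization) {
  n <- c(stack$n0, stack$n, stack$ns)
  d <- c(0, stack$d, 0)
  k0 <- 2 * pi / wavelength
  snell <- n[1] * sin(theta0)
  cth <- function(nj) {
    s <- snell / nj
    if (s <= 1) complex(real = sqrt(1 - s^2)) else complex(imaginary = sqrt(s^2 - 1))
  }
  m <- length(n)
  cos_j <- vapply(n, cth, complex(1))
  r_if <- t_if <- vector("complex", m - 1)
  for (j in seq_len(m - 1)) {
    n1 <- n[j]; n2 <- n[j + 1]
    c1 <- cos_j[j]; c2 <- cos_j[j + 1]
    if (polarization == "s") {
      r_if[j] <- (n1 * c1 - n2 * c2) / (n1 * c1 + n2 * c2)
      t_if[j] <- 2 * n1 * c1 / (n1 * c1 + n2 * c2)
    } else {
      # sign convention: r_p = +r_s at normal incidence is NOT used here;
      # the recursion below only needs internal consistency, and R = |r|^2
      r_if[j] <- (n2 * c1 - n1 * c2) / (n2 * c1 + n1 * c2)
      t_if[j] <- 2 * n1 * c1 / (n2 * c1 + n1 * c2)
    }
  }
  # recursive composition from the substrate upwards
  r <- r_if[m - 1]; t <- t_if[m - 1]
  for (j in seq(m - 2, 1)) {
    beta <- k0 * n[j + 1] * d[j + 1] * cos_j[j + 1]
    ph <- exp(2i * beta)
    denom <- 1 + r_if[j] * r * ph
    t <- t_if[j] * t * exp(1i * beta) / denom
    r <- (r_if[j] + r * ph) / denom
  }
  # reflectance is convention-independent; that is what the oracle certifies
  list(r = r, R = Mod(r)^2)
}

# random lossless stacks for property tests
random_stack <- function(rng_n = 3) {
  stratified_stack(runif(1, 1, 2),
                   list(n = runif(rng_n, 1, 2), d = runif(rng_n, 0, 200)),
                   runif(1, 1, 2))
}

default_model_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_mitochondrion()
    m
  }
})
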