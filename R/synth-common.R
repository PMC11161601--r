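# Synthetic-image generators.
#
# These emulate the inputs the analysis modules consume — multichannel
# organoid planes, collagen-like fiber fields, bead time-lapses and tumor
# border masks — with exact ground truth attached, so recovery of known
# quantities can be tested end to end. Rendering is deliberately schematic
# (flat-intensity cells, stamped straight fibers, Gaussian bead spots):
# only the statistics the analysis measures are matched, not confocal
# appearance.

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler for the circular normal distribution;
#' used to draw fiber axes on the doubled angle. At \code{kappa = 0} it
#' reduces to the uniform distribution on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return numeric vector of angles in radians (unwrapped around mu).
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(mu + runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(16L, ceiling((n - got) * 1.5))
    z <- cos(pi * runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(m)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    f <- f[acc]
    if (length(f) == 0) next
    take <- min(length(f), n - got)
    sgn <- sign(runif(take) - 0.5)
    out[(got + 1):(got + take)] <- mu + sgn * acos(pmax(-1, pmin(1, f[seq_len(take)])))
    got <- got + take
  }
  out
}

#' Sample axial fiber angles from the doubled-angle von Mises model
#'
#' Draws fiber axes whose doubled angles are von Mises distributed around
#' \code{2 * mu_deg} with concentration \code{kappa}; the expected nematic
#' order parameter of the sample is \eqn{I_1(\kappa)/I_0(\kappa)}.
#'
#' @param n number of fibers.
#' @param mu_deg mean axis in degrees.
#' @param kappa concentration (>= 0).
#' @return angles in degrees, wrapped to [-90, 90).
#' @export
rfiber_angles <- function(n, mu_deg = 0, kappa = 1) {
  wrap_axial(rvonmises(n, 2 * mu_deg * pi / 180, kappa) / 2 * 180 / pi)
}

# stamp additive Gaussian noise, clipped at zero
add_noise <- function(m, sd) {
  if (sd <= 0) return(m)
  pmax(m + matrix(rnorm(length(m), 0, sd), nrow(m), ncol(m)), 0)
}

#' Synthetic oriented grating
#'
#' A sinusoidal grating whose stripes run along \code{angle_deg} (degrees
#' counterclockwise from the x-axis, y up) — a minimal fixture for
#' orientation estimators.
#'
#' @param dims image size, c(rows, cols).
#' @param angle_deg stripe axis.
#' @param wavelength_px spatial period in pixels.
#' @return numeric matrix in [0, 1].
#' @export
gen_grating <- function(dims = c(128, 128), angle_deg = 0,
                        wavelength_px = 8) {
  g <- expand.grid(row = seq_len(dims[1]), col = seq_len(dims[2]))
  x <- g$col - 1
  y <- -(g$row - 1)
  a <- angle_deg * pi / 180
  # intensity varies along the normal (-sin a, cos a) of the stripe axis
  phase <- (-x * sin(a) + y * cos(a)) * 2 * pi / wavelength_px
  matrix((1 + cos(phase)) / 2, dims[1], dims[2])
}
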