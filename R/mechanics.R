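#' Physical parameters of the uptake-propensity model
#'
#' Bundles the constants of the membrane-wrapping thermodynamics and the two
#' saturating (tanh) laws that tie cell state to substrate rigidity. Units are
#' kPa for moduli and rigidities, micrometres for lengths, so the work of
#' adhesion is kPa*um and the bending modulus kPa*um^3.
#'
#' @param delta_gamma Work of adhesion per unit cell-particle contact area,
#'   kPa*um. Default 0.002.
#' @param kappa Membrane bending modulus, kPa*um^3. Default 1.9e-5.
#' @param E_max Saturating cell Young's modulus, kPa: the prefactor of the
#'   rigidity-to-cell-modulus law `E(xi) = E_max * tanh(alpha_E * xi)`. The
#'   underlying law is stated only up to proportionality, so the scale is a
#'   calibration choice; the default 0.0075 kPa places the wrapping transition
#'   (the uptake peak) of an 0.8 um bead at 8 kPa, mid-panel, so the model
#'   rises and falls across the experimental rigidity window. On the scale of
#'   the adhesion and bending constants used here this prefactor absorbs all
#'   unstated proportionality constants; it is not a literal cell modulus.
#' @param alpha_A Rate of the spreading-area law `A(xi) = tanh(alpha_A * xi)`,
#'   1/kPa. Default 0.2.
#' @param alpha_E Rate of the cell-modulus law, 1/kPa. Default 0.05.
#' @param beta_func Amplitude of the (optional) cell-functionality correction,
#'   dimensionless, >= 0. Default 0 (pure physics).
#' @param xi_half Half-saturation rigidity of the functionality correction,
#'   kPa. Default 16.
#'
#' @return An object of class `mechanics_params` (a validated named list).
#' @examples
#' p <- mechanics_params()
#' spreading_area(8, p)
#' @export
mechanics_params <- function(delta_gamma = 0.002, kappa = 1.9e-5,
                             E_max = 0.0075,
                             alpha_A = 0.2, alpha_E = 0.05,
                             beta_func = 0, xi_half = 16) {
  p <- list(delta_gamma = delta_gamma, kappa = kappa, E_max = E_max,
            alpha_A = alpha_A, alpha_E = alpha_E,
            beta_func = beta_func, xi_half = xi_half)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (p$beta_func < 0) stop("'beta_func' must be >= 0", call. = FALSE)
  strict <- setdiff(names(p), "beta_func")
  bad <- strict[vapply(p[strict], function(v) v <= 0, logical(1))]
  if (length(bad))
    stop("parameter(s) ", paste(sQuote(bad), collapse = ", "),
         " must be > 0", call. = FALSE)
  structure(p, class = "mechanics_params")
}

#' @export
print.mechanics_params <- function(x, ...) {
  cat("Uptake mechanics parameters:\n")
  cat(sprintf("  delta_gamma = %g kPa*um   kappa = %g kPa*um^3\n",
              x$delta_gamma, x$kappa))
  cat(sprintf("  E_max = %g kPa   alpha_A = %g /kPa   alpha_E = %g /kPa\n",
              x$E_max, x$alpha_A, x$alpha_E))
  cat(sprintf("  functionality: beta = %g, xi_half = %g kPa\n",
              x$beta_func, x$xi_half))
  invisible(x)
}

as_mechanics_params <- function(params) {
  if (inherits(params, "mechanics_params")) return(params)
  do.call(mechanics_params, as.list(params))
}

check_xi <- function(xi) {
  if (!is.numeric(xi) || any(!is.finite(xi)))
    stop("rigidity 'xi' must be finite numeric", call. = FALSE)
  if (any(xi < 0))
    stop("rigidity 'xi' must be >= 0 kPa", call. = FALSE)
  invisible(xi)
}

check_radius <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("particle 'radius' must be a single positive number (um)",
         call. = FALSE)
  invisible(radius)
}

#' Relative cell spreading area on a substrate of given rigidity
#'
#' Saturating law `A(xi) = tanh(alpha_A * xi)`: cells spread more on stiffer
#' substrates until the area saturates. Dimensionless, in `[0, 1)`; the
#' absolute area scale is absorbed into the uptake calibration constant.
#'
#' @param xi Substrate rigidity (Young's modulus), kPa; vectorised, >= 0.
#' @param params A [mechanics_params()] object.
#' @return Relative spreading area in `[0, 1)`.
#' @export
spreading_area <- function(xi, params = mechanics_params()) {
  params <- as_mechanics_params(params)
  check_xi(xi)
  tanh(params$alpha_A * xi)
}

#' Cell Young's modulus as a function of substrate rigidity
#'
#' Cells stiffen on stiffer substrates: `E(xi) = E_max * tanh(alpha_E * xi)`,
#' bounded by `E_max`.
#'
#' @inheritParams spreading_area
#' @return Cell modulus in kPa, in `[0, E_max)`.
#' @export
cell_modulus <- function(xi, params = mechanics_params()) {
  params <- as_mechanics_params(params)
  check_xi(xi)
  params$E_max * tanh(params$alpha_E * xi)
}

#' Equilibrium particle-wrapping contact angle
#'
#' Balance of adhesion gain against membrane bending and cell deformation:
#' `theta = 0.75 * pi * (delta_gamma - 4 * kappa / R^2) / (E * R)`, clamped to
#' `[0, pi]`. A negative pre-clamp value means adhesion cannot pay the bending
#' cost (no stable wrapping, theta = 0); values above pi mean full wrapping.
#' The expression is dimensionless: consistent unit changes leave it intact.
#'
#' @param E Cell Young's modulus, kPa; vectorised, must be > 0 (an infinitely
#'   compliant cell is outside model validity).
#' @param radius Particle radius R, um.
#' @inheritParams spreading_area
#' @return Wrapping angle in radians, in `[0, pi]`.
#' @seealso [critical_radius()] for the radius below which theta is exactly 0.
#' @export
contact_angle <- function(E, radius, params = mechanics_params()) {
  params <- as_mechanics_params(params)
  check_radius(radius)
  if (!is.numeric(E) || any(!is.finite(E)))
    stop("'E' must be finite numeric", call. = FALSE)
  if (any(E <= 0))
    stop("'E' must be > 0 kPa: zero modulus is a singular input",
         call. = FALSE)
  theta <- 0.75 * pi * (params$delta_gamma - 4 * params$kappa / radius^2) /
    (E * radius)
  pmin(pmax(theta, 0), pi)
}

#' Critical particle radius for stable membrane wrapping
#'
#' Below `R = sqrt(4 * kappa / delta_gamma)` the bending penalty exceeds the
#' adhesion gain at any contact angle and the wrapping angle is exactly zero.
#'
#' @inheritParams spreading_area
#' @return Critical radius in um (about 0.195 um at the default constants).
#' @export
critical_radius <- function(params = mechanics_params()) {
  params <- as_mechanics_params(params)
  sqrt(4 * params$kappa / params$delta_gamma)
}

#' Cell-particle contact area of a spherical cap
#'
#' `a = 2 * pi * R^2 * (1 - cos(theta))`: the membrane area wrapped around a
#' particle of radius R at wrapping angle theta.
#'
#' @param theta Wrapping angle, radians, in `[0, pi]`; vectorised.
#' @param radius Particle radius, um.
#' @return Contact area in um^2.
#' @export
contact_area <- function(theta, radius) {
  check_radius(radius)
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("'theta' must be finite numeric", call. = FALSE)
  if (any(theta < 0 | theta > pi))
    stop("'theta' must lie in [0, pi]", call. = FALSE)
  2 * pi * radius^2 * (1 - cos(theta))
}

#' Cell-functionality correction factor
#'
#' Saturating (Michaelis-type) multiplier
#' `g(xi) = 1 + beta_func * xi / (xi + xi_half)` standing in for the elevated
#' biological activity of cells on stiffer substrates, on top of the purely
#' physical wrapping model. `g(0) = 1` and `g` tends to `1 + beta_func`.
#'
#' @inheritParams spreading_area
#' @return Multiplier >= 1.
#' @export
functionality_factor <- function(xi, params = mechanics_params()) {
  params <- as_mechanics_params(params)
  check_xi(xi)
  1 + params$beta_func * xi / (xi + params$xi_half)
}

#' Uptake propensity at one substrate rigidity
#'
#' The composite model: propensity proportional to spreading area times
#' cell-particle contact area, `P(xi) = A(xi) * a(theta(E(xi), R), R)`,
#' optionally multiplied by the functionality factor `g(xi)`. The two factors
#' oppose each other: spreading grows with rigidity while the contact area
#' shrinks as the cell stiffens, producing a rise-then-fall in propensity.
#'
#' @inheritParams spreading_area
#' @param radius Particle radius, um (0.4 and 1.2 um are the canonical bead
#'   radii for 0.8 and 2.4 um beads).
#' @param include_functionality If `TRUE`, multiply by
#'   [functionality_factor()].
#' @return Dimensionless propensity >= 0 (area units um^2 absorbed in the
#'   downstream calibration constant).
#' @export
uptake_propensity <- function(xi, radius, params = mechanics_params(),
                              include_functionality = FALSE) {
  params <- as_mechanics_params(params)
  check_xi(xi)
  check_radius(radius)
  A <- spreading_area(xi, params)
  # E(0) = 0 is singular for the contact angle but A(0) = 0 forces P(0) = 0
  p <- numeric(length(xi))
  pos <- xi > 0
  if (any(pos)) {
    E <- cell_modulus(xi[pos], params)
    a <- contact_area(contact_angle(E, radius, params), radius)
    p[pos] <- A[pos] * a
  }
  if (include_functionality) p <- p * functionality_factor(xi, params)
  p
}

#' Predicted uptake curve over a substrate panel
#'
#' Evaluates [uptake_propensity()] element-wise on a panel of rigidities and
#' locates the propensity peak on a dense log-spaced grid spanning the panel
#' range (ties broken toward the softest rigidity).
#'
#' @param rigidities Strictly increasing vector of substrate rigidities, kPa,
#'   all > 0. The canonical commercial panel is `c(0.5, 2, 8, 16, 32, 64)`.
#' @inheritParams uptake_propensity
#' @param grid_points Number of log-spaced grid points used for the peak scan
#'   (>= 500 when the panel spans a range). Default 512.
#' @return An `uptake_curve`: a data.frame with columns `rigidity_kpa`,
#'   `value`, `value_kind` (`"propensity"`), `radius_um`, carrying attributes
#'   `peak_rigidity` (argmax on the dense grid, kPa) and `grid` (the scan
#'   grid and its values).
#' @export
predict_uptake_curve <- function(rigidities, radius,
                                 params = mechanics_params(),
                                 include_functionality = FALSE,
                                 grid_points = 512) {
  params <- as_mechanics_params(params)
  if (length(rigidities) == 0L)
    stop("empty substrate panel", call. = FALSE)
  check_xi(rigidities)
  if (any(rigidities <= 0) || is.unsorted(rigidities, strictly = TRUE))
    stop("'rigidities' must be strictly increasing and > 0", call. = FALSE)
  vals <- uptake_propensity(rigidities, radius, params, include_functionality)
  if (length(rigidities) > 1L) {
    grid <- exp(seq(log(min(rigidities)), log(max(rigidities)),
                    length.out = grid_points))
  } else {
    grid <- rigidities
  }
  gv <- uptake_propensity(grid, radius, params, include_functionality)
  peak <- grid[which.max(gv)]  # which.max returns the first (softest) tie
  structure(
    data.frame(rigidity_kpa = rigidities, value = vals,
               value_kind = "propensity", radius_um = radius),
    peak_rigidity = peak,
    grid = list(rigidity_kpa = grid, value = gv),
    class = c("uptake_curve", "data.frame")
  )
}

#' Construct an uptake curve from measured or simulated values
#'
#' @param rigidities Rigidities, kPa.
#' @param values Propensities, probabilities or measured uptake fractions.
#' @param value_kind One of `"propensity"`, `"probability"`,
#'   `"measured_fraction"`.
#' @param radius Particle radius, um.
#' @return An `uptake_curve` data.frame.
#' @export
uptake_curve <- function(rigidities, values,
                         value_kind = c("measured_fraction", "probability",
                                        "propensity"),
                         radius) {
  value_kind <- match.arg(value_kind)
  check_radius(radius)
  if (length(rigidities) != length(values))
    stop("'rigidities' and 'values' must have the same length", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("'values' must be finite and >= 0", call. = FALSE)
  if (value_kind != "propensity" && any(values > 1))
    stop("'values' must be <= 1 for kind ", sQuote(value_kind), call. = FALSE)
  structure(
    data.frame(rigidity_kpa = rigidities, value = values,
               value_kind = value_kind, radius_um = radius),
    class = c("uptake_curve", "data.frame")
  )
}
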