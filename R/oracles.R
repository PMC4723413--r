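# Closed-form references used by the test suite and validation scripts.
# These are implemented independently of the solvers and the Rayleigh
# kernel: plane-interface coefficients, the on-axis piston field and the
# free-space monopole.

#' Analytic plane-wave interface coefficients
#'
#' Pressure transmission and reflection at a flat interface.  At normal
#' incidence `T = 2 Z2 / (Z1 + Z2)` and `R = (Z2 - Z1)/(Z2 + Z1)` with
#' `Z = rho c`.  For a fluid-solid interface at oblique incidence the
#' mode-matched coefficients use the effective solid impedance
#' `Z_eff = Zp cos^2(2 theta_s) + Zs sin^2(2 theta_s)`.
#'
#' @param spec list with `c1`, `rho1` (incidence fluid), `c2`, `rho2`
#'   (transmission medium; compressional), optional `cs2` (solid shear
#'   speed) and `angle` (incidence angle, rad).
#' @return list with `transmission`, `reflection`, and for the oblique
#'   solid case also `T_shear` (shear-stress amplitude coefficient) and the
#'   refraction angles.
#' @export
analytic_transmission <- function(spec) {
  a <- spec$angle %||% 0
  if (a < 0 || a >= pi / 2 - 1e-9) stop("grazing incidence not supported")
  Z1 <- spec$rho1 * spec$c1
  if (is.null(spec$cs2) || spec$cs2 == 0) {
    if (a == 0) {
      Z2 <- spec$rho2 * spec$c2
      return(list(transmission = 2 * Z2 / (Z1 + Z2),
                  reflection = (Z2 - Z1) / (Z2 + Z1)))
    }
    s2 <- spec$c2 / spec$c1 * sin(a)
    if (s2 >= 1) stop("beyond the critical angle for fluid-fluid")
    t2 <- asin(s2)
    Z1a <- Z1 / cos(a); Z2a <- spec$rho2 * spec$c2 / cos(t2)
    return(list(transmission = 2 * Z2a / (Z1a + Z2a),
                reflection = (Z2a - Z1a) / (Z2a + Z1a)))
  }
  # fluid -> solid, oblique (Brekhovskikh mode matching)
  sp <- spec$c2 / spec$c1 * sin(a)
  ss <- spec$cs2 / spec$c1 * sin(a)
  if (sp >= 1) stop("beyond the longitudinal critical angle")
  tp <- asin(sp); ts <- asin(ss)
  Z1a <- Z1 / cos(a)
  Zp <- spec$rho2 * spec$c2 / cos(tp)
  Zs <- spec$rho2 * spec$cs2 / cos(ts)
  Zeff <- Zp * cos(2 * ts)^2 + Zs * sin(2 * ts)^2
  R <- (Zeff - Z1a) / (Zeff + Z1a)
  Tp <- 2 * Zp * cos(2 * ts) / (Zeff + Z1a)
  Ts <- -2 * Zs * sin(2 * ts) / (Zeff + Z1a)
  list(transmission = Tp, reflection = R, T_shear = Ts,
       theta_p = tp, theta_s = ts)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' On-axis pressure of a baffled circular piston
#'
#' `|p| = 2 rho c u0 |sin((k/2)(sqrt(z^2 + a^2) - z))|`.
#'
#' @param a piston radius (m).
#' @param z axial distance (m), > 0.
#' @param c,rho medium properties.
#' @param f0 frequency (Hz).
#' @param u0 normal velocity amplitude (m/s).
#' @return pressure magnitude (Pa).
#' @export
on_axis_piston <- function(a, z, c = 1480, rho = 1000, f0 = 220e3, u0 = 1) {
  stopifnot(all(z > 0))
  k <- 2 * pi * f0 / c
  2 * rho * c * abs(u0) * abs(sin(k / 2 * (sqrt(z^2 + a^2) - z)))
}

#' Free-space monopole field
#'
#' `p(r) = S exp(i k r) / (4 pi r)` for monopole strength `S`.
#'
#' @param r distance (m), > 0.
#' @param c sound speed (m/s).
#' @param f0 frequency (Hz).
#' @param strength complex monopole strength `S` (Pa m).
#' @return complex pressure.
#' @export
monopole_field <- function(r, c = 1480, f0 = 220e3, strength = 1) {
  stopifnot(all(r > 0))
  k <- 2 * pi * f0 / c
  strength * exp(1i * k * r) / (4 * pi * r)
}
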