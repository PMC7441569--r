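#' Model parameters for paravascular flow simulations
#'
#' Collects the physical and geometric parameters of the axisymmetric
#' arteriole/PVS/brain model. Lengths are accepted in micrometres and the
#' brain shear modulus in kilopascals (the units used throughout the
#' experimental literature); everything is converted to SI once, on
#' construction, and stored in SI.
#'
#' @param R1 Arteriolar radius, um.
#' @param wd PVS width (gap between arteriolar wall and brain), um.
#' @param La PVS length, um.
#' @param R3 Outer radius of the simulated brain-tissue section, um.
#' @param mu_f CSF dynamic viscosity, Pa s.
#' @param rho_f CSF density, kg/m^3.
#' @param zeta PVS porosity (fluid volume fraction), dimensionless.
#' @param k_s PVS permeability, m^2. `Inf` selects the Navier-Stokes limit
#'   (the Brinkman drag is dropped).
#' @param mu_s Brain tissue shear modulus, kPa.
#' @param nu Poisson's ratio of the brain tissue (compressible
#'   Saint Venant-Kirchhoff model), must be < 0.5.
#' @param rho_s Brain tissue density, kg/m^3.
#' @param b1 Heartbeat pulsation amplitude, percent of arteriolar radius,
#'   peak-to-peak (so the peak radial excursion is `(b1/2)% * R1`).
#' @param f Pulsation frequency, Hz.
#' @param c Pulse wave propagation speed along the arteriolar wall, m/s.
#' @param D Solute diffusion coefficient (amyloid-beta), cm^2/s; used only
#'   for Peclet numbers.
#' @param r_sas Ratio of the subarachnoid-space outlet resistance to the PVS
#'   reference resistance (pial end).
#' @param r_par Ratio of the parenchymal outlet resistance to the PVS
#'   reference resistance (deep end).
#' @param validate If `TRUE` (default), reject values outside the ranges
#'   supported by the experimental literature (see Details). Set to `FALSE`
#'   for deliberately non-physiological studies such as the
#'   wavelength-long-arteriole pumping case.
#'
#' @details
#' Accepted ranges with `validate = TRUE`: R1 5-20 um, wd 2-10 um,
#' La 250-500 um, R3 100-200 um, zeta 0.5-0.9, k_s 2e-15 to 7e-13 m^2 (or
#' infinite), mu_s 1-8 kPa, b1 0.5-2 %, f 7-14 Hz, c 0.5-10 m/s.
#'
#' Derived quantities stored on the object: the pulse wavelength
#' `lambda_wave = c/f` (m), the first Lame parameter `lambda_s` (Pa), the
#' PVS annular cross-section area `A_pvs` (m^2), the geometric PVS volume
#' `V_pvs` (m^3) and the PVS fluid volume `zeta * V_pvs`.
#'
#' @return An object of class `pvs_parameters`: a list of SI quantities.
#' @seealso [default_parameters()], [pvs_reference_resistance()],
#'   [lame_lambda()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$lambda_wave        # 0.1 m
#' p$V_pvs * 1e18       # geometric PVS volume in um^3
pvs_parameters <- function(R1 = 12, wd = 3, La = 250, R3 = 150,
                           mu_f = 1e-3, rho_f = 1000,
                           zeta = 0.8, k_s = 2e-14,
                           mu_s = 4, nu = 0.45, rho_s = 1000,
                           b1 = 1, f = 10, c = 1,
                           D = 1.4e-6,
                           r_sas = 0.01, r_par = 10,
                           validate = TRUE) {
  um <- 1e-6
  if (wd <= 0) stop("degenerate geometry: PVS width 'wd' must be positive")
  if (R1 <= 0 || La <= 0) stop("R1 and La must be positive")
  if (R3 <= R1 + wd) stop("brain outer radius R3 must exceed R1 + wd")
  if (zeta <= 0 || zeta >= 1) stop("porosity 'zeta' must lie in (0, 1)")
  if (!is.infinite(k_s) && k_s <= 0) stop("permeability 'k_s' must be positive or infinite")
  if (nu < 0 || nu >= 0.5) {
    stop("Poisson's ratio 'nu' must lie in [0, 0.5): the compressible model is inapplicable")
  }
  if (r_sas <= 0 || r_par <= 0) stop("resistance ratios 'r_sas', 'r_par' must be positive")
  if (f <= 0 || c <= 0) stop("'f' and 'c' must be positive")

  if (validate) {
    chk <- function(x, lo, hi, name, unit) {
      if (x < lo || x > hi) {
        stop(sprintf("%s = %g %s is outside the supported range [%g, %g] %s; use validate = FALSE to override",
                     name, x, unit, lo, hi, unit))
      }
    }
    chk(R1, 5, 20, "R1", "um")
    chk(wd, 2, 10, "wd", "um")
    chk(La, 250, 500, "La", "um")
    chk(R3, 100, 200, "R3", "um")
    chk(zeta, 0.5, 0.9, "zeta", "")
    if (!is.infinite(k_s)) chk(k_s, 2e-15, 7e-13, "k_s", "m^2")
    chk(mu_s, 1, 8, "mu_s", "kPa")
    chk(b1, 0.5, 2, "b1", "%")
    chk(f, 7, 14, "f", "Hz")
    chk(c, 0.5, 10, "c", "m/s")
  }

  R1_m <- R1 * um; wd_m <- wd * um; La_m <- La * um; R3_m <- R3 * um
  A_pvs <- pi * ((R1_m + wd_m)^2 - R1_m^2)
  V_pvs <- A_pvs * La_m
  p <- structure(list(
    R1 = R1_m, wd = wd_m, La = La_m, R3 = R3_m,
    mu_f = mu_f, rho_f = rho_f, zeta = zeta, k_s = k_s,
    mu_s = mu_s * 1e3, nu = nu, rho_s = rho_s,
    lambda_s = lame_lambda(mu_s * 1e3, nu),
    b1 = b1, f = f, c = c, lambda_wave = c / f,
    D = D * 1e-4,                       # cm^2/s -> m^2/s
    r_sas = r_sas, r_par = r_par,
    A_pvs = A_pvs, V_pvs = V_pvs, V_fluid = zeta * V_pvs
  ), class = "pvs_parameters")
  p
}

#' Default simulation parameters
#'
#' The default parameter set of the model: a 12 um arteriole with a 3 um
#' wide, 250 um long PVS of porosity 0.8 and permeability 2e-14 m^2, a brain
#' section of outer radius 150 um with shear modulus 4 kPa (Poisson 0.45),
#' heartbeat pulsations of 1% peak-to-peak at 10 Hz traveling at 1 m/s, and
#' outlet resistance ratios 0.01 (subarachnoid space) and 10 (parenchyma).
#'
#' @param ... Overrides passed on to [pvs_parameters()].
#' @return A `pvs_parameters` object.
#' @export
default_parameters <- function(...) pvs_parameters(...)

#' First Lame parameter of a compressible solid
#'
#' `lambda_s = 2 nu mu_s / (1 - 2 nu)`, in the same units as `mu_s`.
#'
#' @param mu_s Shear modulus.
#' @param nu Poisson's ratio, in `[0, 0.5)`.
#' @return The first Lame parameter.
#' @export
#' @examples
#' lame_lambda(4, 0.45)  # 36 (kPa in, kPa out)
lame_lambda <- function(mu_s, nu) {
  if (any(nu < 0) || any(nu >= 0.5)) {
    stop("Poisson's ratio must lie in [0, 0.5): the compressible model is inapplicable")
  }
  2 * nu * mu_s / (1 - 2 * nu)
}

#' Reference hydraulic resistance of the PVS
#'
#' Steady-state axial flow resistance of the PVS annulus, used to scale the
#' lumped Robin outlet resistances (`r_sas` and `r_par` multiples of this
#' value). For finite permeability this is the Darcy resistance
#' `mu_f zeta La / (k_s A)` with `A = pi((R1+wd)^2 - R1^2)`; in the
#' Navier-Stokes limit (`k_s = Inf`) it is the classical concentric-annulus
#' Poiseuille resistance.
#'
#' @param params A [pvs_parameters] object.
#' @return Hydraulic resistance, Pa s / m^3.
#' @export
#' @examples
#' pvs_reference_resistance(default_parameters())  # ~3.93e16 Pa s/m^3
pvs_reference_resistance <- function(params) {
  stopifnot(inherits(params, "pvs_parameters"))
  if (params$wd <= 0) stop("degenerate geometry: wd must be positive")
  if (is.infinite(params$k_s)) {
    annular_poiseuille_resistance(params$R1, params$R1 + params$wd,
                                  params$mu_f, params$La)
  } else {
    params$mu_f * params$zeta * params$La / (params$k_s * params$A_pvs)
  }
}

#' @rdname pvs_reference_resistance
#' @param R1,R2 Inner and outer radii of the annulus, m.
#' @param mu Dynamic viscosity, Pa s.
#' @param L Channel length, m.
#' @export
annular_poiseuille_resistance <- function(R1, R2, mu, L) {
  geom <- R2^4 - R1^4 - (R2^2 - R1^2)^2 / log(R2 / R1)
  8 * mu * L / (pi * geom)
}

#' Outlet resistances of the two PVS ends
#'
#' @param params A [pvs_parameters] object.
#' @return A list with elements `pvs` (the reference resistance), `sas`
#'   (pial end) and `par` (parenchymal end), Pa s / m^3.
#' @export
outlet_resistances <- function(params) {
  R <- pvs_reference_resistance(params)
  list(pvs = R, sas = params$r_sas * R, par = params$r_par * R)
}

#' Read model parameters from a JSON configuration file
#'
#' The file holds a flat object whose names mirror the parameter table
#' (`R1`, `wd`, `La`, `R3`, `mu_f`, `rho_f`, `zeta`, `k_s`, `mu_s`, `nu`,
#' `rho_s`, `b1`, `f`, `c`, `D`, `r_sas`, `r_par`), with lengths in um and
#' `mu_s` in kPa. `"inf"` (any case) or `"Inf"` for `k_s` selects the
#' Navier-Stokes limit. Missing fields take their defaults; `overrides`
#' (a named list) wins over the file.
#'
#' @param path Path to the JSON file.
#' @param overrides Named list of per-field overrides.
#' @param validate Passed to [pvs_parameters()].
#' @return A `pvs_parameters` object.
#' @export
#' @examples
#' cfg <- system.file("extdata", "params-default.json", package = "pvsflow")
#' read_parameters(cfg, overrides = list(k_s = "inf"))
read_parameters <- function(path, overrides = list(), validate = TRUE) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg[names(overrides)] <- overrides
  if (!is.null(cfg$k_s) && is.character(cfg$k_s)) {
    if (tolower(cfg$k_s) %in% c("inf", "infinite")) cfg$k_s <- Inf
    else cfg$k_s <- as.numeric(cfg$k_s)
  }
  allowed <- setdiff(names(formals(pvs_parameters)), c("...", "validate"))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown parameter field(s) in config: ", paste(unknown, collapse = ", "))
  }
  do.call(pvs_parameters, c(cfg, list(validate = validate)))
}

#' @export
print.pvs_parameters <- function(x, ...) {
  um <- 1e6
  cat("Paravascular flow model parameters\n")
  cat(sprintf("  geometry : R1 = %g um, wd = %g um, La = %g um, R3 = %g um\n",
              x$R1 * um, x$wd * um, x$La * um, x$R3 * um))
  cat(sprintf("  fluid    : mu_f = %g Pa s, rho_f = %g kg/m^3, zeta = %g, k_s = %s\n",
              x$mu_f, x$rho_f, x$zeta,
              if (is.infinite(x$k_s)) "Inf (Navier-Stokes)" else format(x$k_s)))
  cat(sprintf("  solid    : mu_s = %g kPa, nu = %g, rho_s = %g kg/m^3\n",
              x$mu_s / 1e3, x$nu, x$rho_s))
  cat(sprintf("  driving  : b1 = %g%% p-p, f = %g Hz, c = %g m/s (lambda = %g m)\n",
              x$b1, x$f, x$c, x$lambda_wave))
  cat(sprintf("  outlets  : r_sas = %g, r_par = %g (R_PVS = %.3g Pa s/m^3)\n",
              x$r_sas, x$r_par, pvs_reference_resistance(x)))
  invisible(x)
}
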