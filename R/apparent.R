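#' Apparent molar volume from solution and solvent densities
#'
#' `V_phi = M/rho - (rho - rho0) / (m_A * rho * rho0)`, the volume a mole
#' of solute apparently occupies in a solution of molality `m_A`:
#' algebraically identical to `((1 + m_A*M)/rho - 1/rho0) / m_A`, the
#' volume of solution containing 1 kg of solvent minus the solvent volume,
#' per mole of solute.
#'
#' @param m_A solute molality, mol kg^-1 (> 0; the property is undefined at
#'   infinite dilution -- use [fit_limiting()] to extrapolate instead).
#' @param rho solution density, kg m^-3.
#' @param rho0 solvent (baseline) density at the same `(m_B, T)`, kg m^-3.
#' @param M solute molar mass, kg mol^-1.
#' @return apparent molar volume, m^3 mol^-1.
#' @examples
#' # when rho == rho0 the solute displaces exactly its ideal volume M/rho0
#' apparent_molar_volume(0.1, 997.047, 997.047, 0.11912)
#' @export
apparent_molar_volume <- function(m_A, rho, rho0, M) {
  if (any(m_A <= 0)) {
    stop("apparent molar volume is undefined at m_A = 0 (infinite dilution); ",
      "extrapolate with fit_limiting() instead",
      call. = FALSE
    )
  }
  if (any(rho <= 0) || any(rho0 <= 0)) stop("densities must be positive", call. = FALSE)
  M / rho - (rho - rho0) / (m_A * rho * rho0)
}

#' Isentropic compressibility from the Newton--Laplace relation
#'
#' `K_s = 1 / (u^2 * rho)`: the adiabatic compressibility of a fluid from
#' its speed of sound and density.
#'
#' @param u speed of sound, m s^-1 (> 0).
#' @param rho density, kg m^-3 (> 0).
#' @return isentropic compressibility, Pa^-1.
#' @examples
#' isentropic_compressibility(1496.7, 997.047) # water near 298 K, ~4.48e-10
#' @export
isentropic_compressibility <- function(u, rho) {
  if (any(u <= 0) || any(rho <= 0)) {
    stop("u and rho must be positive", call. = FALSE)
  }
  1 / (u^2 * rho)
}

#' Apparent molar isentropic compressibility
#'
#' `K_phi_s = M*Ks/rho + (Ks*rho0 - Ks0*rho) / (m_A * rho * rho0)`, the
#' solute's contribution to the solution's isentropic compressibility per
#' mole; equivalently `((1 + m_A*M)*Ks/rho - Ks0/rho0) / m_A`. Negative
#' values are physically meaningful: the hydration shell is less
#' compressible than bulk solvent.
#'
#' @inheritParams apparent_molar_volume
#' @param Ks solution isentropic compressibility, Pa^-1.
#' @param Ks0 solvent (baseline) isentropic compressibility, Pa^-1.
#' @return apparent molar isentropic compressibility, m^3 mol^-1 Pa^-1.
#' @export
apparent_molar_compressibility <- function(m_A, rho, rho0, Ks, Ks0, M) {
  if (any(m_A <= 0)) {
    stop("apparent molar compressibility is undefined at m_A = 0", call. = FALSE)
  }
  if (any(rho <= 0) || any(rho0 <= 0) || any(Ks <= 0) || any(Ks0 <= 0)) {
    stop("densities and compressibilities must be positive", call. = FALSE)
  }
  M * Ks / rho + (Ks * rho0 - Ks0 * rho) / (m_A * rho * rho0)
}

#' First-order uncertainty propagation for the apparent properties
#'
#' Delta-method propagation of independent measurement uncertainties in
#' `(rho, rho0, u, u0)` through the apparent molar volume and
#' compressibility. Returns both the total standard uncertainties and the
#' split into the independent (per-measurement) part and the gradients with
#' respect to the shared baseline quantities; the latter feed the
#' generalized-least-squares option of [fit_limiting()], where the baseline
#' error is common to all points of a dilution series.
#'
#' @inheritParams apparent_molar_compressibility
#' @param u,u0 solution and baseline speed of sound, m s^-1 (may be `NA`
#'   for volume-only data).
#' @param sigma_rho,sigma_rho0 standard uncertainties of `rho`, `rho0`
#'   (kg m^-3).
#' @param sigma_u,sigma_u0 standard uncertainties of `u`, `u0` (m s^-1).
#' @return data.frame with columns `sigma_V_phi`, `sigma_K_phi_s` (total),
#'   `sigma_V_indep`, `sigma_K_indep` (excluding baseline terms) and the
#'   baseline gradients `dV_drho0`, `dK_drho0`, `dK_du0`.
#' @export
propagate_uncertainty <- function(m_A, rho, rho0, u = NA, u0 = NA, M,
                                  sigma_rho = 0.05, sigma_rho0 = sigma_rho,
                                  sigma_u = 0.4, sigma_u0 = sigma_u) {
  stopifnot(all(m_A > 0))
  if (any(c(sigma_rho, sigma_rho0, sigma_u, sigma_u0) < 0, na.rm = TRUE)) {
    stop("uncertainties must be non-negative", call. = FALSE)
  }
  # V = ((1 + m M)/rho - 1/rho0)/m
  dV_drho <- -(1 + m_A * M) / (m_A * rho^2)
  dV_drho0 <- 1 / (m_A * rho0^2)
  var_V_indep <- (dV_drho * sigma_rho)^2
  sigma_V <- sqrt(var_V_indep + (dV_drho0 * sigma_rho0)^2)

  # K = ((1 + m M)/(u^2 rho^2) - 1/(u0^2 rho0^2))/m
  dK_du <- -2 * (1 + m_A * M) / (m_A * u^3 * rho^2)
  dK_drho <- -2 * (1 + m_A * M) / (m_A * u^2 * rho^3)
  dK_du0 <- 2 / (m_A * u0^3 * rho0^2)
  dK_drho0 <- 2 / (m_A * u0^2 * rho0^3)
  var_K_indep <- (dK_du * sigma_u)^2 + (dK_drho * sigma_rho)^2
  sigma_K <- sqrt(var_K_indep + (dK_du0 * sigma_u0)^2 + (dK_drho0 * sigma_rho0)^2)

  data.frame(
    sigma_V_phi = sigma_V,
    sigma_K_phi_s = sigma_K,
    sigma_V_indep = sqrt(var_V_indep),
    sigma_K_indep = sqrt(var_K_indep),
    dV_drho0 = dV_drho0,
    dK_drho0 = dK_drho0,
    dK_du0 = dK_du0
  )
}

#' Per-measurement apparent properties for a whole measurement table
#'
#' For every solute row of a validated [measurement table][as_measurement_table],
#' looks up the `m_A = 0` baseline of its `(m_B, T)` group and computes the
#' apparent molar volume, the isentropic compressibilities of solution and
#' solvent and, when speed-of-sound data are present, the apparent molar
#' isentropic compressibility -- each with propagated uncertainty.
#'
#' @param measurements a `measurement_table` (see [read_measurements()]).
#' @param solutes solute registry data.frame (`name`, `molar_mass`);
#'   defaults to [default_solutes()].
#' @return data.frame of apparent records keyed by `(solute, m_B, T, m_A)`
#'   with columns `V_phi`, `Ks`, `Ks0`, `K_phi_s`, `sigma_V_phi`,
#'   `sigma_K_phi_s`, baseline values/uncertainties and the baseline
#'   gradients from [propagate_uncertainty()]. Compressibility columns are
#'   `NA` for volume-only input.
#' @export
apparent_properties <- function(measurements, solutes = default_solutes()) {
  stopifnot(inherits(measurements, "measurement_table"))
  sol <- measurements[!measurements$baseline, , drop = FALSE]
  if (nrow(sol) == 0L) stop("no solute rows in measurement table", call. = FALSE)
  base <- measurements[measurements$baseline, , drop = FALSE]
  bkey <- paste(base$m_B, base$T, sep = "\r")
  idx <- match(paste(sol$m_B, sol$T, sep = "\r"), bkey)
  stopifnot(!anyNA(idx)) # guaranteed by table validation

  M <- .solute_mass(sol$solute, solutes)
  rho0 <- base$rho[idx]
  u0 <- base$u[idx]
  sigma_rho0 <- base$sigma_rho[idx]
  sigma_u0 <- base$sigma_u[idx]

  have_u <- !is.na(sol$u) & !is.na(u0)
  V_phi <- apparent_molar_volume(sol$m_A, sol$rho, rho0, M)
  Ks <- ifelse(have_u, 1 / (sol$u^2 * sol$rho), NA_real_)
  Ks0 <- ifelse(have_u, 1 / (u0^2 * rho0), NA_real_)
  K_phi_s <- ifelse(
    have_u,
    M * Ks / sol$rho + (Ks * rho0 - Ks0 * sol$rho) / (sol$m_A * sol$rho * rho0),
    NA_real_
  )
  unc <- propagate_uncertainty(
    m_A = sol$m_A, rho = sol$rho, rho0 = rho0,
    u = sol$u, u0 = u0, M = M,
    sigma_rho = sol$sigma_rho, sigma_rho0 = sigma_rho0,
    sigma_u = sol$sigma_u, sigma_u0 = sigma_u0
  )

  out <- data.frame(
    solute = sol$solute, m_B = sol$m_B, T = sol$T, m_A = sol$m_A,
    rho = sol$rho, u = sol$u, rho0 = rho0, u0 = u0,
    V_phi = V_phi, Ks = Ks, Ks0 = Ks0, K_phi_s = K_phi_s,
    sigma_rho0 = sigma_rho0, sigma_u0 = sigma_u0,
    stringsAsFactors = FALSE
  )
  cbind(out, unc)
}
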