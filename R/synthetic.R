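#' Ground truth for the synthetic densimetry generator
#'
#' Bundles everything [generate_dataset()] needs to emulate a dilution
#' study: the experimental design (solutes, co-solvent molalities,
#' temperatures, solute-molality grid), the true limiting properties and
#' slopes, solvent baselines, and the instrument noise.
#'
#' The defaults reproduce the design of a vibrating-tube densimeter study
#' of l-threonine and glycyl-l-threonine in aqueous
#' 1-octyl-3-methylimidazolium bromide: four temperatures
#' (288.15--318.15 K), five co-solvent molalities (0.00--0.40 mol kg^-1),
#' eight solute molalities in 0.05--0.40 mol kg^-1, and noise standard
#' deviations of 0.05 kg m^-3 (density) and 0.4 m s^-1 (sound speed) --
#' half the instrument's expanded uncertainties at coverage factor 2.
#' True limiting volumes follow a per-solute quadratic in temperature
#' plus a pair/triplet co-solvent dependence
#' `V0(m_B, T) = V0_water(T) + 2*v_pair*m_B + 3*v_triplet*m_B^2`, so the
#' downstream transfer functions obey the interaction-coefficient model
#' exactly and end-to-end recovery is well-defined. Limiting compressions
#' are tabulated per temperature with the analogous pair/triplet term.
#' Solvent baselines are fixed water-like constants with mild linear
#' temperature and co-solvent trends (no equation of state is embedded).
#'
#' @param solutes solute registry (`name`, `molar_mass`).
#' @param m_B co-solvent molalities (the `m_B = 0` level must be included
#'   if transfer functions are to be recovered).
#' @param temperatures study temperatures, K.
#' @param m_A solute-molality grid, mol kg^-1 (all > 0).
#' @param T_ref reference temperature of the quadratic volume model, K.
#' @param volume_model named list (per solute) of `c(a, b, c)` in SI:
#'   limiting-volume quadratic in water.
#' @param v_pair,v_triplet named numeric (per solute): volume interaction
#'   coefficients, m^3 mol^-2 kg and m^3 mol^-3 kg^2.
#' @param s_v named numeric (per solute): experimental slope of `V_phi`
#'   vs `m_A`, m^3 mol^-1 (mol kg^-1)^-1.
#' @param k0_water named list (per solute) of limiting compressions in
#'   water at each temperature (same order as `temperatures`), Pa^-1-based
#'   SI (m^3 mol^-1 Pa^-1).
#' @param k_pair,k_triplet,s_k named numeric (per solute): compression
#'   analogues of `v_pair`, `v_triplet`, `s_v`.
#' @param rho0_fun,u0_fun functions `(m_B, T) ->` baseline density
#'   (kg m^-3) / sound speed (m s^-1); evaluated once at construction into
#'   a baseline table.
#' @param sigma_rho,sigma_u instrument noise standard deviations.
#' @return list of class `ground_truth`; element `baselines` tabulates
#'   `rho0`, `u0` per `(m_B, T)`.
#' @export
ground_truth <- function(
    solutes = default_solutes(),
    m_B = c(0, 0.1, 0.2, 0.3, 0.4),
    temperatures = c(288.15, 298.15, 308.15, 318.15),
    m_A = seq(0.05, 0.40, length.out = 8),
    T_ref = 298.15,
    volume_model = list(
      "l-threonine" = c(a = 77.70e-6, b = 0.00915e-6, c = 0.00016e-6),
      "glycyl-l-threonine" = c(a = 108.78e-6, b = 0.05113e-6, c = -0.00056e-6)
    ),
    v_pair = c("l-threonine" = 1.65e-6, "glycyl-l-threonine" = 0.62e-6),
    v_triplet = c("l-threonine" = -0.05e-6, "glycyl-l-threonine" = -0.05e-6),
    s_v = c("l-threonine" = 0.5e-6, "glycyl-l-threonine" = 0.5e-6),
    k0_water = list(
      "l-threonine" = c(-37.8995, -29.6277, -26.5794, -26.4624) * 1e-15,
      "glycyl-l-threonine" = c(-55.0303, -44.7933, -38.5984, -33.0062) * 1e-15
    ),
    k_pair = c("l-threonine" = 12.6e-15, "glycyl-l-threonine" = 10.5e-15),
    k_triplet = c("l-threonine" = -6.5e-15, "glycyl-l-threonine" = -1.0e-15),
    s_k = c("l-threonine" = -0.2e-15, "glycyl-l-threonine" = -0.5e-15),
    rho0_fun = function(m_B, T) 997.047 - 0.40 * (T - 298.15) + 45 * m_B,
    u0_fun = function(m_B, T) 1496.7 + 2.4 * (T - 298.15) + 60 * m_B,
    sigma_rho = 0.05, sigma_u = 0.4) {
  stopifnot(all(m_A > 0), all(temperatures > 0), all(m_B >= 0))
  stopifnot(sigma_rho >= 0, sigma_u >= 0)
  for (s in solutes$name) {
    if (is.null(volume_model[[s]]) || is.null(k0_water[[s]])) {
      stop("ground truth lacks volume_model/k0_water for solute ", s, call. = FALSE)
    }
    if (length(k0_water[[s]]) != length(temperatures)) {
      stop("k0_water for ", s, " must have one value per temperature", call. = FALSE)
    }
  }
  baselines <- expand.grid(m_B = m_B, T = temperatures, KEEP.OUT.ATTRS = FALSE)
  baselines$rho0 <- rho0_fun(baselines$m_B, baselines$T)
  baselines$u0 <- u0_fun(baselines$m_B, baselines$T)
  if (any(baselines$rho0 <= 0) || any(baselines$u0 <= 0)) {
    stop("baseline functions produced non-positive rho0/u0", call. = FALSE)
  }
  structure(
    list(
      solutes = solutes, m_B = m_B, temperatures = temperatures, m_A = m_A,
      T_ref = T_ref, volume_model = volume_model,
      v_pair = v_pair, v_triplet = v_triplet, s_v = s_v,
      k0_water = k0_water, k_pair = k_pair, k_triplet = k_triplet, s_k = s_k,
      baselines = baselines, sigma_rho = sigma_rho, sigma_u = sigma_u
    ),
    class = "ground_truth"
  )
}

#' True limiting properties implied by a ground truth
#'
#' Expands a [ground_truth()] into the per-`(solute, m_B, T)` limiting
#' values the analysis pipeline should recover: `V0_phi`, `S_v`,
#' `K0_phi_s`, `S_k` (all SI).
#'
#' @param truth a `ground_truth`.
#' @return data.frame keyed by `(solute, m_B, T)`.
#' @export
true_limits <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  grid <- expand.grid(
    solute = truth$solutes$name, m_B = truth$m_B, T = truth$temperatures,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  vm <- truth$volume_model
  x <- grid$T - truth$T_ref
  V0w <- mapply(function(s, xi) {
    p <- vm[[s]]
    p[["a"]] + p[["b"]] * xi + p[["c"]] * xi^2
  }, grid$solute, x)
  grid$V0_phi <- V0w + 2 * truth$v_pair[grid$solute] * grid$m_B +
    3 * truth$v_triplet[grid$solute] * grid$m_B^2
  grid$S_v <- unname(truth$s_v[grid$solute])
  ti <- match(grid$T, truth$temperatures)
  K0w <- mapply(function(s, i) truth$k0_water[[s]][i], grid$solute, ti)
  grid$K0_phi_s <- K0w + 2 * truth$k_pair[grid$solute] * grid$m_B +
    3 * truth$k_triplet[grid$solute] * grid$m_B^2
  grid$S_k <- unname(truth$s_k[grid$solute])
  rownames(grid) <- NULL
  grid
}

#' Solution density implying a target apparent molar volume
#'
#' Exact algebraic inverse of the apparent-molar-volume definition:
#' `rho = (1 + m_A*M) / (1/rho0 + m_A*V_phi_target)`, so that
#' [apparent_molar_volume()] applied to the result returns
#' `V_phi_target` to machine precision.
#'
#' @inheritParams apparent_molar_volume
#' @param V_phi_target desired apparent molar volume, m^3 mol^-1.
#' @return solution density, kg m^-3.
#' @export
invert_density <- function(m_A, V_phi_target, rho0, M) {
  stopifnot(all(m_A > 0), all(rho0 > 0))
  denom <- 1 / rho0 + m_A * V_phi_target
  if (any(denom <= 0)) {
    stop("target apparent volume implies non-positive solution volume", call. = FALSE)
  }
  (1 + m_A * M) / denom
}

#' Speed of sound implying a target apparent molar compressibility
#'
#' Inverts the apparent-molar-compressibility definition for the solution
#' compressibility, `Ks = (K_phi_s*m_A*rho*rho0 + Ks0*rho) / (rho0*(1 +
#' m_A*M))`, then the Newton--Laplace relation for the sound speed,
#' `u = 1/sqrt(Ks*rho)`.
#'
#' @inheritParams apparent_molar_compressibility
#' @param K_phi_s_target desired apparent molar isentropic
#'   compressibility, m^3 mol^-1 Pa^-1.
#' @return speed of sound, m s^-1.
#' @export
invert_sound_speed <- function(m_A, K_phi_s_target, rho, rho0, Ks0, M) {
  stopifnot(all(m_A > 0), all(rho > 0), all(rho0 > 0), all(Ks0 > 0))
  Ks <- (K_phi_s_target * m_A * rho * rho0 + Ks0 * rho) / (rho0 * (1 + m_A * M))
  if (any(Ks <= 0)) {
    stop("target apparent compressibility implies non-positive Ks", call. = FALSE)
  }
  1 / sqrt(Ks * rho)
}

# Deterministic per-row noise: each row draws from its own substream,
# seeded by (seed, key-hash), so the generated table is independent of
# iteration order and two tables from the same seed are identical.
.row_hash <- function(key) {
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  h
}

.row_noise <- function(seed, key, n = 2L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.numeric(seed) + .row_hash(key)) %% 2147483647)
  stats::rnorm(n)
}

#' Generate a synthetic measurement table
#'
#' Emulates the instrument: for each `(solute, m_B, T, m_A)` cell the true
#' apparent properties `V_phi = V0 + S_v*m_A` and `K_phi_s = K0 + S_k*m_A`
#' are inverted to a noiseless `(rho, u)` pair via [invert_density()] and
#' [invert_sound_speed()], then independent Gaussian noise of standard
#' deviation `sigma_rho` / `sigma_u` is added. Baseline rows (`m_A = 0`)
#' receive noise too. Noise is drawn from per-row substreams keyed by the
#' measurement identity, so the same seed always yields the same table
#' regardless of row order, and `seed` fully determines the output.
#'
#' @param truth a [ground_truth()].
#' @param seed integer seed; `NULL` generates a noiseless table only if
#'   the truth's sigmas are zero, otherwise an error.
#' @return a `measurement_table` ready for [apparent_properties()].
#' @export
generate_dataset <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  noisy <- truth$sigma_rho > 0 || truth$sigma_u > 0
  if (noisy && is.null(seed)) {
    stop("a seed is required when noise is non-zero", call. = FALSE)
  }
  limits <- true_limits(truth)
  base <- truth$baselines
  rows <- vector("list", nrow(base) * (1 + nrow(truth$solutes) * length(truth$m_A)))
  k <- 0L
  for (i in seq_len(nrow(base))) {
    mB <- base$m_B[i]
    Tk <- base$T[i]
    rho0_true <- base$rho0[i]
    u0_true <- base$u0[i]
    Ks0_true <- 1 / (u0_true^2 * rho0_true)
    bnoise <- if (noisy) {
      .row_noise(seed, paste("baseline", mB, Tk, sep = "|"))
    } else {
      c(0, 0)
    }
    k <- k + 1L
    rows[[k]] <- data.frame(
      solute = "none", m_B = mB, m_A = 0, T = Tk, p = 0.1,
      rho = rho0_true + truth$sigma_rho * bnoise[1],
      u = u0_true + truth$sigma_u * bnoise[2],
      sigma_rho = truth$sigma_rho, sigma_u = truth$sigma_u,
      stringsAsFactors = FALSE
    )
    for (s in seq_len(nrow(truth$solutes))) {
      sname <- truth$solutes$name[s]
      M <- truth$solutes$molar_mass[s]
      lim <- limits[limits$solute == sname & limits$m_B == mB & limits$T == Tk, ]
      for (mA in truth$m_A) {
        V_t <- lim$V0_phi + lim$S_v * mA
        K_t <- lim$K0_phi_s + lim$S_k * mA
        rho_t <- invert_density(mA, V_t, rho0_true, M)
        u_t <- invert_sound_speed(mA, K_t, rho_t, rho0_true, Ks0_true, M)
        nz <- if (noisy) {
          .row_noise(seed, paste(sname, mB, Tk, mA, sep = "|"))
        } else {
          c(0, 0)
        }
        rho_obs <- rho_t + truth$sigma_rho * nz[1]
        u_obs <- u_t + truth$sigma_u * nz[2]
        if (rho_obs <= 0 || u_obs <= 0) {
          stop("noise configuration produced non-physical rho/u", call. = FALSE)
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          solute = sname, m_B = mB, m_A = mA, T = Tk, p = 0.1,
          rho = rho_obs, u = u_obs,
          sigma_rho = truth$sigma_rho, sigma_u = truth$sigma_u,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  as_measurement_table(do.call(rbind, rows[seq_len(k)]))
}
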