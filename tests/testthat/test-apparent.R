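test_that("apparent molar volume matches the total-volume oracle and its limits", {
  M <- 0.11912
  # density-match limit: V_phi = M/rho0 for any m_A
  expect_equal(apparent_molar_volume(0.3, 997.047, 997.047, M), M / 997.047)
  # frozen example against the oracle
  v <- apparent_molar_volume(0.1, 998.000, 997.047, M)
  expect_equal(v, V_phi_oracle(0.1, 998.000, 997.047, M), tolerance = 1e-12)
  expect_equal(v, 1.0978e-4, tolerance = 1e-4)
  # linearity in (rho - rho0) of the deficit term
  m <- 0.2; rho0 <- 997.0
  v1 <- apparent_molar_volume(m, rho0 + 1, rho0, M)
  d1 <- v1 - M / (rho0 + 1)
  expect_equal(d1, -1 / (m * (rho0 + 1) * rho0), tolerance = 1e-12)
  expect_error(apparent_molar_volume(0, 998, 997, M), "infinite dilution")
})

test_that("Newton-Laplace compressibility evaluates and is scale-invariant", {
  expect_equal(isentropic_compressibility(1000, 1000), 1e-9)
  expect_equal(isentropic_compressibility(1496.7, 997.047), 4.477e-10, tolerance = 1e-3)
  k <- 1.7
  expect_equal(
    isentropic_compressibility(1496.7 * k, 997.047 / k^2),
    isentropic_compressibility(1496.7, 997.047),
    tolerance = 1e-14
  )
  expect_error(isentropic_compressibility(-1, 1000), "positive")
})

test_that("apparent molar compressibility matches its oracle on random inputs", {
  M <- 0.17617
  # baseline-match limit
  Ks0 <- 4.48e-10
  expect_equal(
    apparent_molar_compressibility(0.2, 997.0, 997.0, Ks0, Ks0, M),
    M * Ks0 / 997.0
  )
  # forced-negative sign case
  expect_lt(
    apparent_molar_compressibility(0.1, 998, 997, 4.40e-10, 4.48e-10, M), 0
  )
  set.seed(101)
  for (i in 1:1000) {
    m <- runif(1, 0.01, 0.5)
    rho0 <- runif(1, 900, 1100)
    rho <- rho0 + runif(1, -5, 5)
    Ks0 <- runif(1, 3e-10, 6e-10)
    Ks <- Ks0 * runif(1, 0.9, 1.1)
    Mi <- runif(1, 0.05, 0.3)
    # equality to 1e-12 relative to the property's natural scale (M/rho,
    # M*Ks/rho), which stays meaningful when the property crosses zero
    ko <- K_phi_oracle(m, rho, rho0, Ks, Ks0, Mi)
    expect_lt(
      abs(apparent_molar_compressibility(m, rho, rho0, Ks, Ks0, Mi) - ko),
      1e-12 * max(abs(ko), Mi * Ks0 / rho0)
    )
    vo <- V_phi_oracle(m, rho, rho0, Mi)
    expect_lt(
      abs(apparent_molar_volume(m, rho, rho0, Mi) - vo),
      1e-12 * max(abs(vo), Mi / rho0)
    )
  }
})

test_that("propagated uncertainties agree with a finite-difference Jacobian", {
  M <- 0.11912
  m <- 0.15; rho <- 998.2; rho0 <- 997.0; u <- 1500.1; u0 <- 1496.7
  s_rho <- 0.05; s_u <- 0.4
  unc <- propagate_uncertainty(m, rho, rho0, u, u0, M,
    sigma_rho = s_rho, sigma_rho0 = s_rho, sigma_u = s_u, sigma_u0 = s_u
  )
  # numerical Jacobian oracle
  h <- 1e-4
  fV <- function(r, r0) V_phi_oracle(m, r, r0, M)
  gV <- c(
    (fV(rho + h, rho0) - fV(rho - h, rho0)) / (2 * h),
    (fV(rho, rho0 + h) - fV(rho, rho0 - h)) / (2 * h)
  )
  sV_num <- sqrt(sum((gV * s_rho)^2))
  expect_equal(unc$sigma_V_phi, sV_num, tolerance = 0.01)

  fK <- function(r, r0, uu, uu0) {
    K_phi_oracle(m, r, r0, 1 / (uu^2 * r), 1 / (uu0^2 * r0), M)
  }
  gK <- c(
    (fK(rho + h, rho0, u, u0) - fK(rho - h, rho0, u, u0)) / (2 * h) * s_rho,
    (fK(rho, rho0 + h, u, u0) - fK(rho, rho0 - h, u, u0)) / (2 * h) * s_rho,
    (fK(rho, rho0, u + h, u0) - fK(rho, rho0, u - h, u0)) / (2 * h) * s_u,
    (fK(rho, rho0, u, u0 + h) - fK(rho, rho0, u, u0 - h)) / (2 * h) * s_u
  )
  expect_equal(unc$sigma_K_phi_s, sqrt(sum(gK^2)), tolerance = 0.01)

  # zero in, zero out
  z <- propagate_uncertainty(m, rho, rho0, u, u0, M,
    sigma_rho = 0, sigma_rho0 = 0, sigma_u = 0, sigma_u0 = 0
  )
  expect_equal(z$sigma_V_phi, 0)
  expect_equal(z$sigma_K_phi_s, 0)

  # dominant-term asymptotics: sigma ~ 1/m_A at small m_A
  s1 <- propagate_uncertainty(0.01, rho, rho0, u, u0, M)$sigma_V_phi
  s2 <- propagate_uncertainty(0.02, rho, rho0, u, u0, M)$sigma_V_phi
  expect_equal(s1 / s2, 2, tolerance = 0.01)
})

test_that("apparent_properties pairs each solute row with its group baseline", {
  tab <- as_measurement_table(
    make_raw_table(m_B = c(0, 0.1), T = c(298.15, 298.15), m_A = c(0.1, 0.2, 0.3))
  )
  rec <- apparent_properties(tab)
  expect_equal(nrow(rec), 6L)
  expect_true(all(rec$m_A > 0))
  base <- tab[tab$baseline & tab$m_B == 0.1, ]
  expect_true(all(rec$rho0[rec$m_B == 0.1] == base$rho))
  # volume-only input leaves compressibility columns NA
  df <- make_raw_table()
  df$u <- NULL
  rec2 <- apparent_properties(as_measurement_table(df))
  expect_true(all(is.na(rec2$K_phi_s)))
  expect_true(all(is.finite(rec2$V_phi)))
})
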