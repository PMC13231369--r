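test_that("density inversion is the exact inverse of the apparent volume", {
  M <- 0.11912
  rho0 <- 997.047
  # density-match limit
  expect_equal(invert_density(0.2, M / rho0, rho0, M), rho0, tolerance = 1e-14)
  # continuity towards infinite dilution
  expect_equal(invert_density(1e-9, 1.1e-4, rho0, M), rho0, tolerance = 1e-6)
  set.seed(606)
  for (i in 1:1000) {
    m <- runif(1, 0.01, 0.5)
    r0 <- runif(1, 900, 1100)
    Mi <- runif(1, 0.05, 0.3)
    Vt <- runif(1, 0.5e-4, 2e-4)
    rho <- invert_density(m, Vt, r0, Mi)
    expect_equal(apparent_molar_volume(m, rho, r0, Mi), Vt, tolerance = 1e-12)
  }
  expect_error(invert_density(0.5, -3e-3, 997, M), "non-positive")
})

test_that("sound-speed inversion is the exact inverse of the compressibility chain", {
  M <- 0.17617
  rho0 <- 997.047; u0 <- 1496.7
  Ks0 <- isentropic_compressibility(u0, rho0)
  # baseline-match inverse
  expect_equal(
    invert_sound_speed(0.1, M * Ks0 / rho0, rho0, rho0, Ks0, M), u0,
    tolerance = 1e-12
  )
  # strongly negative target at small m_A: sound speed rises above u0
  rho <- invert_density(0.02, 1.1e-4, rho0, M)
  u <- invert_sound_speed(0.02, -45e-15, rho, rho0, Ks0, M)
  expect_gt(u, u0)
  set.seed(707)
  for (i in 1:1000) {
    m <- runif(1, 0.02, 0.5)
    r0 <- runif(1, 950, 1050)
    uu0 <- runif(1, 1400, 1600)
    K0 <- isentropic_compressibility(uu0, r0)
    Mi <- runif(1, 0.05, 0.3)
    rho <- invert_density(m, runif(1, 0.5e-4, 2e-4), r0, Mi)
    Kt <- runif(1, -60e-15, 10e-15)
    u <- invert_sound_speed(m, Kt, rho, r0, K0, Mi)
    Ks <- isentropic_compressibility(u, rho)
    expect_equal(
      apparent_molar_compressibility(m, rho, r0, Ks, K0, Mi), Kt,
      tolerance = 1e-10
    )
  }
})

test_that("the same seed reproduces the same table, independent of design order", {
  tr <- ground_truth()
  d1 <- generate_dataset(tr, seed = 99)
  d2 <- generate_dataset(tr, seed = 99)
  expect_identical(d1, d2)
  p1 <- tempfile(); p2 <- tempfile()
  write_results(d1, p1); write_results(d2, p2)
  expect_identical(readLines(p1), readLines(p2))
  d3 <- generate_dataset(tr, seed = 100)
  expect_false(identical(d1$rho, d3$rho))
  # per-row substreams: reversing the molality grid leaves shared rows identical
  tr_rev <- ground_truth(m_A = rev(tr$m_A))
  d4 <- generate_dataset(tr_rev, seed = 99)
  expect_identical(d1, d4) # canonical sort + keyed noise
  # noise requires a seed
  expect_error(generate_dataset(tr), "seed")
})

test_that("the generator does not perturb the global RNG stream", {
  set.seed(31415)
  before <- .Random.seed
  invisible(generate_dataset(ground_truth(), seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("zero-noise generation followed by the pipeline is the identity on ground truth", {
  tr <- ground_truth(sigma_rho = 0, sigma_u = 0)
  res <- analyze(generate_dataset(tr))
  tl <- true_limits(tr)
  f <- res$limiting$fits
  key <- paste(tl$solute, tl$m_B, tl$T)
  fv <- f[f$property == "volume", ]
  iv <- match(paste(fv$solute, fv$m_B, fv$T), key)
  expect_lt(max(abs(fv$intercept - tl$V0_phi[iv]) / abs(tl$V0_phi[iv])), 1e-9)
  expect_lt(max(abs(fv$slope - tl$S_v[iv]) / abs(tl$S_v[iv])), 1e-9)
  fk <- f[f$property == "compression", ]
  ik <- match(paste(fk$solute, fk$m_B, fk$T), key)
  expect_lt(max(abs(fk$intercept - tl$K0_phi_s[ik]) / abs(tl$K0_phi_s[ik])), 1e-9)
  expect_lt(max(abs(fk$slope - tl$S_k[ik]) / abs(tl$S_k[ik])), 1e-9)
  # temperature-model coefficients
  tm <- res$temperature$models
  for (s in tr$solutes$name) {
    row <- tm[tm$solute == s & tm$m_B == 0, ]
    p <- tr$volume_model[[s]]
    expect_equal(row$a, unname(p[["a"]]), tolerance = 1e-9)
    expect_equal(row$b, unname(p[["b"]]), tolerance = 1e-9)
    expect_equal(row$c, unname(p[["c"]]), tolerance = 1e-6)
  }
})

test_that("predicted standard errors match the Monte-Carlo spread of recovered intercepts", {
  tr0 <- ground_truth(
    solutes = default_solutes()[1, ],
    m_B = 0, temperatures = 298.15,
    volume_model = list("l-threonine" = c(a = 77.70e-6, b = 0.00915e-6, c = 0.00016e-6)),
    s_v = c("l-threonine" = 0.5e-6),
    k0_water = list("l-threonine" = -29.6277e-15),
    sigma_rho = 0.05, sigma_u = 0.4
  )
  est <- matrix(NA_real_, 200, 2)
  for (r in 1:200) {
    rec <- apparent_properties(generate_dataset(tr0, seed = 7000 + r))
    f <- fit_all_groups(rec, method = "gls")$fits
    fv <- f[f$property == "volume", ]
    est[r, ] <- c(fv$intercept, fv$se_intercept)
  }
  ratio <- sd(est[, 1]) / mean(est[, 2])
  expect_lt(ratio, 1.25)
  expect_gt(ratio, 1 / 1.25)
})
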