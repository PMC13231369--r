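study_T <- c(288.15, 298.15, 308.15, 318.15)

test_that("quadratic temperature model recovers generating coefficients exactly", {
  a <- 77.70e-6; b <- 0.00915e-6; c <- 0.00016e-6
  V0 <- a + b * (study_T - 298.15) + c * (study_T - 298.15)^2
  m <- fit_temperature_model(study_T, V0)
  expect_equal(m$a, a, tolerance = 1e-10)
  expect_equal(m$b, b, tolerance = 1e-10)
  expect_equal(m$c, c, tolerance = 1e-10)
  # constant data: pure intercept
  mc <- fit_temperature_model(study_T, rep(5e-5, 4))
  expect_equal(mc$b, 0, tolerance = 1e-15)
  expect_equal(mc$c, 0, tolerance = 1e-15)
  expect_equal(mc$a, 5e-5)
  expect_error(fit_temperature_model(study_T[1:2], c(1, 2)), "at least 3")
  expect_error(fit_temperature_model(c(288, 288, 298), c(1, 2, 3)), "duplicate")
})

test_that("coefficients match a Vandermonde solve on random 3- and 4-point sets", {
  set.seed(303)
  for (i in 1:200) {
    n <- sample(3:4, 1)
    Tk <- sort(sample(seq(280, 330, by = 2.5), n))
    y <- rnorm(n, 1e-4, 1e-6)
    m <- fit_temperature_model(Tk, y, T_ref = 300)
    x <- Tk - 300
    if (n == 3) {
      cf <- solve(cbind(1, x, x^2), y) # exact interpolation
    } else {
      X <- cbind(1, x, x^2)
      cf <- solve(t(X) %*% X, t(X) %*% y) # normal equations
    }
    expect_equal(c(m$a, m$b, m$c), as.numeric(cf), tolerance = 1e-10)
  }
})

test_that("fit-quality metrics behave as residual summaries", {
  a <- 1e-4; b <- 1e-8; c <- 1e-10
  V0 <- a + b * (study_T - 298.15) + c * (study_T - 298.15)^2
  m <- fit_temperature_model(study_T, V0)
  q <- fit_quality(study_T, V0, m)
  expect_equal(q$residual_sd, 0, tolerance = 1e-15)
  expect_equal(q$ard, 0, tolerance = 1e-12)
  # one perturbed point on a 4-point fit: residual_sd equals |delta * r|
  # with r from the hat matrix, cross-checked by direct refit
  delta <- 3e-7
  V0p <- V0; V0p[2] <- V0p[2] + delta
  mp <- fit_temperature_model(study_T, V0p)
  qp <- fit_quality(study_T, V0p, mp)
  x <- study_T - 298.15
  X <- cbind(1, x, x^2)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  # RSS = delta^2 * (I - H)[2,2] for a single perturbed point
  expect_equal(qp$residual_sd, abs(delta) * sqrt(1 - H[2, 2]), tolerance = 1e-8)
  # homogeneity: ard is scale-invariant, residual_sd scales linearly
  mk <- fit_temperature_model(study_T, 10 * V0p)
  qk <- fit_quality(study_T, 10 * V0p, mk)
  expect_equal(qk$ard, qp$ard, tolerance = 1e-10)
  expect_equal(qk$residual_sd, 10 * qp$residual_sd, tolerance = 1e-10)
  # 3-point fit has no residual degrees of freedom: flagged as NA
  m3 <- fit_temperature_model(study_T[1:3], V0[1:3])
  expect_true(is.na(m3$residual_sd))
})

test_that("expansibility follows E0 = b + 2c(T - T_ref) and matches finite differences", {
  m <- temp_model(a = 78.03e-6, b = 0.01177e-6, c = 0.00015e-6)
  e <- expansibility(m, c(288.15, 298.15, 318.15))
  expect_equal(e$E0_phi[2], 0.01177e-6) # b at T_ref, exactly
  expect_equal(e$dE0_dT, rep(2 * 0.00015e-6, 3))
  # central finite differences of the fitted V0(T)
  h <- 1e-3
  num <- (predict_temp_model(m, 308.15 + h) - predict_temp_model(m, 308.15 - h)) / (2 * h)
  expect_equal(expansibility(m, 308.15)$E0_phi, num, tolerance = 1e-8)
  # c = 0: constant expansibility
  e0 <- expansibility(temp_model(1, 2e-9, 0), c(280, 300, 320))
  expect_true(all(e0$E0_phi == 2e-9))
  # published sign-resolved example: glycyl dipeptide in water, c < 0
  mg <- temp_model(a = 108.78e-6, b = 0.05113e-6, c = -0.00056e-6)
  expect_equal(expansibility(mg, 318.15)$E0_phi, 0.02873e-6, tolerance = 1e-11)
  # within rounding of the 2-significant-figure printed c, matches 0.02869
  expect_lt(abs(expansibility(mg, 318.15)$E0_phi - 0.02869e-6), 2.05e-10)
})

test_that("the derivative of the fitted model equals the slope of its own E0 values", {
  m <- temp_model(a = 1e-4, b = 3.1e-10, c = -5.6e-10)
  e <- expansibility(m, study_T)
  expect_equal(
    expansibility_slope_from_values(study_T, e$E0_phi),
    2 * m$c,
    tolerance = 1e-12
  )
  expect_equal(expansibility_slope_from_values(c(280, 320), c(4, 4)), 0)
  expect_error(expansibility_slope_from_values(300, 1), "at least 2")
})

test_that("published expansibility rows give the published derivative magnitudes", {
  expect_equal(
    expansibility_slope_from_values(study_T, c(0.00602, 0.00915, 0.01227, 0.01539)),
    0.00031,
    tolerance = 0.02
  )
  expect_equal(
    abs(expansibility_slope_from_values(study_T, c(0.06235, 0.05113, 0.03991, 0.02869))),
    0.00112,
    tolerance = 0.01
  )
})

test_that("Hepler classification responds only to the sign of dE0/dT", {
  expect_equal(hepler_classification(0.00031e-6), "structure_maker")
  expect_equal(hepler_classification(-0.00031e-6), "structure_breaker")
  expect_equal(hepler_classification(0), "indeterminate")
  expect_equal(hepler_classification(5e-12, tol = 1e-11), "indeterminate")
  expect_error(hepler_classification(1, tol = -1), "non-negative")
  # invariance to T_ref: same data, shifted reference, same classification
  V0 <- 77.7e-6 + 0.009e-6 * (study_T - 298.15) + 0.0002e-6 * (study_T - 298.15)^2
  m1 <- fit_temperature_model(study_T, V0, T_ref = 298.15)
  m2 <- fit_temperature_model(study_T, V0, T_ref = 288.15)
  expect_equal(2 * m1$c, 2 * m2$c, tolerance = 1e-12)
  expect_identical(
    hepler_classification(2 * m1$c),
    hepler_classification(2 * m2$c)
  )
})
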