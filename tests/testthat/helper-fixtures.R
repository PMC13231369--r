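# Shared fixtures: all inputs are built in code at test time.

# Minimal well-formed measurement data.frame: one baseline + two solute rows
# per (m_B, T) group requested.
make_raw_table <- function(m_B = 0, T = 298.15,
                           solute = "l-threonine",
                           m_A = c(0.1, 0.2),
                           rho0 = 997.047, drho_per_m = 9.5) {
  rows <- lapply(seq_along(m_B), function(i) {
    base <- data.frame(
      solute = "none", m_B = m_B[i], m_A = 0, T = T[i],
      rho = rho0, u = 1496.7, stringsAsFactors = FALSE
    )
    sol <- data.frame(
      solute = solute, m_B = m_B[i], m_A = m_A, T = T[i],
      rho = rho0 + drho_per_m * m_A, u = 1496.7 + 5 * m_A,
      stringsAsFactors = FALSE
    )
    rbind(base, sol)
  })
  do.call(rbind, rows)
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Closed-form simple-linear-regression oracle (normal equations),
# independent of lm().
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  d <- n * sxx - sx^2
  slope <- (n * sxy - sx * sy) / d
  intercept <- (sy - slope * sx) / n
  r <- y - intercept - slope * x
  s2 <- sum(r^2) / (n - 2)
  list(
    intercept = intercept, slope = slope,
    se_intercept = sqrt(s2 * sxx / d), se_slope = sqrt(s2 * n / d)
  )
}

# Total-volume / total-compressibility definitions used as independent
# oracles for the apparent properties.
V_phi_oracle <- function(m, rho, rho0, M) ((1 + m * M) / rho - 1 / rho0) / m
K_phi_oracle <- function(m, rho, rho0, Ks, Ks0, M) {
  ((1 + m * M) * Ks / rho - Ks0 / rho0) / m
}
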