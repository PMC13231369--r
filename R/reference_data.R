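# Published derived-property reference tables for l-threonine and
# glycyl-l-threonine in aqueous 1-octyl-3-methylimidazolium bromide
# ([OMIm][Br]), 288.15-318.15 K. Values are stored on the journal
# reporting scales (volumes x 1e6 m^3 mol^-1; compressions in the 1e-6
# m^3 mol^-1 GPa^-1 convention); set `si = TRUE` to convert.

.ref_csv <- function(name) {
  path <- system.file("extdata", name, package = "solvatherm", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Reference temperature-model coefficients
#'
#' Quadratic temperature-model coefficients `(a, b, c)` with `T_ref =
#' 298.15 K`, and the published fit-quality column `ard`, for l-threonine
#' and glycyl-l-threonine at five [OMIm][Br] molalities. The published
#' table prints `|c|`; here `c` carries the sign implied by the
#' temperature trend of the corresponding expansibility row (negative for
#' the glycyl-l-threonine rows at `m_B <= 0.2` whose expansibility falls
#' with temperature).
#'
#' @param si convert values to SI units (default: reporting scale,
#'   `a x 1e6` etc.).
#' @return data.frame: `solute`, `m_B`, `a`, `b`, `c`, `ard`.
#' @export
ref_temp_coefficients <- function(si = FALSE) {
  df <- .ref_csv("thr_glythr_omimbr_temp_coefficients.csv")
  if (si) {
    df$a <- report_to_si(df$a, "volume")
    df$b <- report_to_si(df$b, "expansibility")
    df$c <- report_to_si(df$c, "expansibility_slope")
  }
  df
}

#' Reference limiting apparent molar expansibilities
#'
#' Limiting apparent molar expansibility `E0_phi` at the four study
#' temperatures and its temperature derivative (published as a magnitude),
#' per `(solute, m_B)`.
#'
#' @param si convert to SI units.
#' @param long return one row per `(solute, m_B, T)` instead of the
#'   published wide layout.
#' @return data.frame; wide: `solute`, `m_B`, `E_288.15` ... `E_318.15`,
#'   `dE0_dT`; long: `solute`, `m_B`, `T`, `E0_phi`, `dE0_dT`.
#' @export
ref_expansibilities <- function(si = FALSE, long = FALSE) {
  df <- .ref_csv("thr_glythr_omimbr_expansibility.csv")
  if (si) {
    for (col in grep("^E_", names(df), value = TRUE)) {
      df[[col]] <- report_to_si(df[[col]], "expansibility")
    }
    df$dE0_dT <- report_to_si(df$dE0_dT, "expansibility_slope")
  }
  if (!long) {
    return(df)
  }
  ecols <- grep("^E_", names(df), value = TRUE)
  temps <- as.numeric(sub("^E_", "", ecols))
  out <- do.call(rbind, lapply(seq_along(ecols), function(i) {
    data.frame(
      solute = df$solute, m_B = df$m_B, T = temps[i],
      E0_phi = df[[ecols[i]]], dE0_dT = df$dE0_dT,
      stringsAsFactors = FALSE
    )
  }))
  out[order(out$solute, out$m_B, out$T), , drop = FALSE]
}

#' Reference limiting apparent molar isentropic compressions
#'
#' Limiting compressions `K0_phi_s` and experimental slopes `S_k` with
#' their published standard errors, per `(solute, m_B, T)`.
#'
#' @param si convert to SI units.
#' @return data.frame: `solute`, `m_B`, `T`, `K0`, `se_K0`, `S_k`,
#'   `se_S_k`.
#' @export
ref_limiting_compressions <- function(si = FALSE) {
  df <- .ref_csv("thr_glythr_omimbr_limiting_compression.csv")
  if (si) {
    for (col in c("K0", "se_K0", "S_k", "se_S_k")) {
      df[[col]] <- report_to_si(df[[col]], "compression")
    }
  }
  df
}

#' Reference transfer compressions
#'
#' Water-to-mixed-solvent transfer of the limiting compression,
#' per `(solute, m_B > 0, T)`.
#'
#' @param si convert to SI units.
#' @return data.frame: `solute`, `m_B`, `T`, `dK0`.
#' @export
ref_transfer_compressions <- function(si = FALSE) {
  df <- .ref_csv("thr_glythr_omimbr_transfer_compression.csv")
  if (si) df$dK0 <- report_to_si(df$dK0, "compression")
  df
}
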