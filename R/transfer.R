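#' Transfer of a limiting property from water to the mixed solvent
#'
#' `delta = value_mix - value_water`: the change of a limiting apparent
#' molar property when the solute moves from infinite dilution in water
#' (`m_B = 0`) to infinite dilution in the water + co-solvent medium at
#' the same temperature. Standard errors combine in quadrature
#' (`se = sqrt(se_mix^2 + se_water^2)`), the two fits being independent.
#'
#' @param value_mix limiting value in the mixed solvent.
#' @param value_water limiting value in pure water at the same `(solute, T)`.
#' @param se_mix,se_water standard errors of the two limiting values.
#' @return list with `delta` and `se_delta`.
#' @export
transfer_value <- function(value_mix, value_water, se_mix = 0, se_water = 0) {
  list(
    delta = value_mix - value_water,
    se_delta = sqrt(se_mix^2 + se_water^2)
  )
}

#' Transfer functions for a whole table of limiting fits
#'
#' For each `(solute, T, property)` group, subtracts the `m_B = 0` (water)
#' limiting value from every `m_B > 0` limiting value. Transfer is defined
#' between limiting fits, never between raw apparent values, because the
#' property is a statement about infinite dilution.
#'
#' @param fits data.frame of limiting fits (the `fits` element of
#'   [fit_all_groups()], or any table with columns `solute`, `m_B`, `T`,
#'   `property`, `intercept`, `se_intercept`).
#' @return data.frame with columns `solute`, `m_B`, `T`, `property`,
#'   `delta`, `se_delta`.
#' @export
transfer_all <- function(fits) {
  stopifnot(is.data.frame(fits))
  needed <- c("solute", "m_B", "T", "property", "intercept")
  if (!all(needed %in% names(fits))) {
    stop("fits table must have columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!"se_intercept" %in% names(fits)) fits$se_intercept <- 0
  mix <- fits[fits$m_B > 0, , drop = FALSE]
  water <- fits[fits$m_B == 0, , drop = FALSE]
  if (nrow(mix) == 0L) stop("no m_B > 0 fits to transfer", call. = FALSE)
  wkey <- paste(water$solute, water$T, water$property, sep = "\r")
  idx <- match(paste(mix$solute, mix$T, mix$property, sep = "\r"), wkey)
  if (anyNA(idx)) {
    miss <- unique(mix[is.na(idx), c("solute", "T", "property")])
    stop(
      "missing water (m_B = 0) reference for: ",
      paste(sprintf(
        "(%s, T=%s, %s)", miss$solute, miss$T, miss$property
      ), collapse = "; "),
      call. = FALSE
    )
  }
  se_mix <- mix$se_intercept
  se_wat <- water$se_intercept[idx]
  se_mix[is.na(se_mix)] <- 0
  se_wat[is.na(se_wat)] <- 0
  out <- data.frame(
    solute = mix$solute, m_B = mix$m_B, T = mix$T, property = mix$property,
    delta = mix$intercept - water$intercept[idx],
    se_delta = sqrt(se_mix^2 + se_wat^2),
    stringsAsFactors = FALSE
  )
  out[order(out$solute, out$property, out$T, out$m_B), , drop = FALSE]
}
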