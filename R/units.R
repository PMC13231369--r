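#' Convert SI quantities to the conventional reporting scales
#'
#' Journal tables in this field report molar volumes as `V x 1e6 / (m^3
#' mol^-1)`, molar compressions as `K / (m^3 mol^-1 GPa^-1)` on a 1e-6
#' scale (i.e. `K x 1e15` of the SI `m^3 mol^-1 Pa^-1` value), and
#' expansibilities as `E x 1e6 / (m^3 mol^-1 K^-1)`. Internally everything
#' is strict SI; this helper applies the outbound scale factor.
#'
#' @param x numeric vector in SI units.
#' @param quantity one of `"volume"` (m^3 mol^-1 -> 1e6 scale),
#'   `"compression"` (m^3 mol^-1 Pa^-1 -> 1e-6 m^3 mol^-1 GPa^-1 scale,
#'   factor 1e15), `"expansibility"` (m^3 mol^-1 K^-1, factor 1e6),
#'   `"expansibility_slope"` (m^3 mol^-1 K^-2, factor 1e6),
#'   `"volume_pair"`/`"volume_triplet"` (factor 1e6),
#'   `"compression_pair"`/`"compression_triplet"` (factor 1e15).
#' @return rescaled numeric vector.
#' @seealso [report_to_si()] for the inbound direction.
#' @export
si_to_report <- function(x, quantity) {
  x * .report_factor(quantity)
}

#' Convert reported values back to SI
#'
#' Inverse of [si_to_report()]; used when loading published derived-property
#' tables whose values are printed on the conventional scales.
#'
#' @inheritParams si_to_report
#' @return numeric vector in SI units.
#' @export
report_to_si <- function(x, quantity) {
  x / .report_factor(quantity)
}

.report_factor <- function(quantity) {
  switch(match.arg(quantity, c(
    "volume", "compression", "expansibility", "expansibility_slope",
    "volume_pair", "volume_triplet", "compression_pair", "compression_triplet"
  )),
  volume = 1e6,
  expansibility = 1e6,
  expansibility_slope = 1e6,
  volume_pair = 1e6,
  volume_triplet = 1e6,
  compression = 1e15,
  compression_pair = 1e15,
  compression_triplet = 1e15
  )
}

#' Default solute registry
#'
#' Molar masses used when converting between mass-based densities and
#' mole-based apparent properties. The two default entries are the solutes
#' of the reference study: l-threonine (C4H9NO3) and its dipeptide
#' glycyl-l-threonine (C6H12N2O4).
#'
#' @return data.frame with columns `name`, `molar_mass` (kg mol^-1) and
#'   `kind` (one of `"amino_acid"`, `"dipeptide"`, `"other"`).
#' @examples
#' default_solutes()
#' @export
default_solutes <- function() {
  data.frame(
    name = c("l-threonine", "glycyl-l-threonine"),
    molar_mass = c(0.11912, 0.17617),
    kind = c("amino_acid", "dipeptide"),
    stringsAsFactors = FALSE
  )
}

.solute_mass <- function(solute, solutes) {
  stopifnot(is.data.frame(solutes), all(c("name", "molar_mass") %in% names(solutes)))
  if (anyDuplicated(solutes$name)) {
    stop("solute registry has duplicated names", call. = FALSE)
  }
  if (any(solutes$molar_mass <= 0)) {
    stop("solute molar masses must be positive", call. = FALSE)
  }
  idx <- match(solute, solutes$name)
  if (anyNA(idx)) {
    stop(
      "unknown solute(s): ",
      paste(unique(solute[is.na(idx)]), collapse = ", "),
      call. = FALSE
    )
  }
  solutes$molar_mass[idx]
}
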