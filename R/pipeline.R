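#' Run the full volumetric/acoustic analysis pipeline
#'
#' Orchestrates the analysis chain on a validated measurement table:
#' per-measurement apparent properties, limiting fits per
#' `(solute, m_B, T)`, transfer functions versus the `m_B = 0` reference,
#' quadratic temperature models with expansibilities and Hepler
#' classification, and pair/triplet interaction coefficients. Input
#' lacking speed-of-sound data degrades gracefully to a volume-only run
#' (recorded in `notes`). Skipped groups are reported, never silently
#' dropped.
#'
#' @param measurements a `measurement_table` (from [read_measurements()],
#'   [as_measurement_table()] or [generate_dataset()]).
#' @param solutes solute registry; defaults to [default_solutes()].
#' @param T_ref reference temperature of the quadratic volume model, K.
#' @param method limiting-fit estimator (see [fit_limiting()]).
#' @param output_dir optional directory; when given, result tables are
#'   written as CSV (SI units, deterministic formatting) together with a
#'   JSON run manifest.
#' @param seed seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return list with elements `records`, `limiting` (`$fits`, `$skipped`),
#'   `transfers`, `temperature` (`$models`, `$expansibilities`,
#'   `$skipped`), `interactions` (`$fits`, `$skipped`) and `notes`
#'   (character).
#' @export
analyze <- function(measurements, solutes = default_solutes(),
                    T_ref = 298.15, method = c("ols", "wls", "gls"),
                    output_dir = NULL, seed = NA) {
  method <- match.arg(method)
  notes <- character()

  records <- apparent_properties(measurements, solutes = solutes)
  if (all(is.na(records$K_phi_s))) {
    notes <- c(notes, "no speed-of-sound data: volume-only run, compressibility stages skipped")
  }

  limiting <- fit_all_groups(records, method = method)
  if (nrow(limiting$skipped)) {
    notes <- c(notes, sprintf(
      "%d limiting-fit group(s) skipped (see $limiting$skipped)",
      nrow(limiting$skipped)
    ))
  }

  transfers <- if (any(limiting$fits$m_B > 0) && any(limiting$fits$m_B == 0)) {
    transfer_all(limiting$fits)
  } else {
    notes <- c(notes, "no (m_B = 0, m_B > 0) pairing: transfer stage skipped")
    data.frame()
  }

  temperature <- fit_temperature_tables(limiting$fits, T_ref = T_ref)
  if (nrow(temperature$skipped)) {
    notes <- c(notes, sprintf(
      "%d temperature-model group(s) skipped (see $temperature$skipped)",
      nrow(temperature$skipped)
    ))
  }

  interactions <- if (nrow(transfers)) {
    fit_interaction_tables(transfers)
  } else {
    list(fits = data.frame(), skipped = data.frame())
  }

  result <- list(
    records = records, limiting = limiting, transfers = transfers,
    temperature = temperature, interactions = interactions, notes = notes
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(records, file.path(output_dir, "apparent_records.csv"))
    write_results(limiting$fits, file.path(output_dir, "limiting_fits.csv"))
    if (nrow(transfers)) {
      write_results(transfers, file.path(output_dir, "transfer_values.csv"))
    }
    if (nrow(temperature$models)) {
      write_results(temperature$models, file.path(output_dir, "temperature_models.csv"))
      write_results(
        temperature$expansibilities,
        file.path(output_dir, "expansibilities.csv")
      )
    }
    if (nrow(interactions$fits)) {
      write_results(interactions$fits, file.path(output_dir, "interaction_fits.csv"))
    }
    write_manifest(
      file.path(output_dir, "manifest.json"),
      inputs = character(),
      config = list(T_ref = T_ref, method = method, solutes = solutes$name),
      seed = seed
    )
  }
  result
}

#' Consistency checks between published derived-property tables
#'
#' Re-derives one published table from another and reports per-row
#' verdicts:
#' \itemize{
#'   \item coefficients -> expansibilities: `E0 = b + 2c(T - T_ref)`
#'     evaluated at each tabulated temperature, and the OLS slope of each
#'     expansibility row compared against the printed derivative column
#'     (magnitudes, since the printed derivative is unsigned);
#'   \item limiting -> transfer compressions: `delta = K0(mix) - K0(water)`
#'     per cell.
#' }
#' Tolerances follow print precision: half a unit in the last printed
#' decimal of each input, propagated through the arithmetic.
#'
#' @param coefficients coefficient table shaped like
#'   [ref_temp_coefficients()] (reporting scale).
#' @param expansibilities expansibility table shaped like
#'   [ref_expansibilities()] (wide, reporting scale).
#' @param limiting limiting-compression table shaped like
#'   [ref_limiting_compressions()].
#' @param transfers transfer table shaped like
#'   [ref_transfer_compressions()].
#' @param T_ref reference temperature, K.
#' @return data.frame: `check`, `solute`, `m_B`, `T`, `computed`,
#'   `printed`, `tolerance`, `pass`.
#' @export
validate_consistency <- function(coefficients = NULL, expansibilities = NULL,
                                 limiting = NULL, transfers = NULL,
                                 T_ref = 298.15) {
  out <- list()
  if (!is.null(coefficients) && !is.null(expansibilities)) {
    ecols <- grep("^E_", names(expansibilities), value = TRUE)
    temps <- as.numeric(sub("^E_", "", ecols))
    for (i in seq_len(nrow(expansibilities))) {
      row <- expansibilities[i, ]
      co <- coefficients[
        coefficients$solute == row$solute & coefficients$m_B == row$m_B, ,
        drop = FALSE
      ]
      if (nrow(co) != 1L) {
        stop(
          "no unique coefficient row for (", row$solute, ", m_B=", row$m_B, ")",
          call. = FALSE
        )
      }
      model <- temp_model(co$a, co$b, co$c, T_ref = T_ref)
      E <- expansibility(model, temps)$E0_phi
      # half-ulp of b (5 printed decimals) plus half-ulp of c through 2c*dT
      tol_E <- 0.5e-5 + 2 * 0.5e-5 * abs(temps - T_ref)
      for (j in seq_along(temps)) {
        out[[length(out) + 1L]] <- data.frame(
          check = "coefficients_to_expansibility",
          solute = row$solute, m_B = row$m_B, T = temps[j],
          computed = E[j], printed = row[[ecols[j]]],
          tolerance = tol_E[j],
          pass = abs(E[j] - row[[ecols[j]]]) <= tol_E[j],
          stringsAsFactors = FALSE
        )
      }
      slope <- expansibility_slope_from_values(
        temps,
        as.numeric(row[ecols])
      )
      out[[length(out) + 1L]] <- data.frame(
        check = "expansibility_row_to_derivative",
        solute = row$solute, m_B = row$m_B, T = NA_real_,
        computed = abs(slope), printed = row$dE0_dT,
        tolerance = 5.000001e-6,
        pass = abs(abs(slope) - row$dE0_dT) <= 5.000001e-6,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(limiting) && !is.null(transfers)) {
    water <- limiting[limiting$m_B == 0, , drop = FALSE]
    wkey <- paste(water$solute, water$T, sep = "\r")
    for (i in seq_len(nrow(transfers))) {
      tr <- transfers[i, ]
      mixrow <- limiting[
        limiting$solute == tr$solute & limiting$m_B == tr$m_B &
          limiting$T == tr$T, ,
        drop = FALSE
      ]
      wrow <- water[match(paste(tr$solute, tr$T, sep = "\r"), wkey), , drop = FALSE]
      if (nrow(mixrow) != 1L || anyNA(wrow$K0)) {
        stop(
          "limiting table lacks the cells needed for (", tr$solute,
          ", m_B=", tr$m_B, ", T=", tr$T, ")",
          call. = FALSE
        )
      }
      comp <- mixrow$K0 - wrow$K0
      out[[length(out) + 1L]] <- data.frame(
        check = "limiting_to_transfer",
        solute = tr$solute, m_B = tr$m_B, T = tr$T,
        computed = comp, printed = tr$dK0,
        tolerance = 2e-4,
        pass = abs(comp - tr$dK0) <= 2e-4,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    stop("supply at least one supported table pair", call. = FALSE)
  }
  do.call(rbind, out)
}
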