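#' Read and validate a measurement table
#'
#' Loads a tidy CSV of densimetry/velocimetry measurements into the
#' internal SI representation. Each row is one measurement of a solution:
#' solute identity (or `"none"` for a solvent baseline), co-solvent
#' molality `m_B`, solute molality `m_A`, temperature `T`, pressure `p`,
#' density `rho` and (optionally) speed of sound `u`. Rows with
#' `m_A = 0` supply the solvent baseline (`rho0`, `u0`) for their
#' `(m_B, T)` group; every group that contains solute rows must contain
#' exactly one such baseline.
#'
#' @param path CSV file (RFC-4180, UTF-8, `.` decimal separator).
#' @param config optional configuration: a YAML file path or a list with
#'   elements `columns` (named list mapping internal names `solute`,
#'   `m_B`, `m_A`, `T`, `p`, `rho`, `u`, `sigma_rho`, `sigma_u` to the
#'   file's column names) and `units` (named list; supported:
#'   `rho = "kg/m^3"` or `"g/cm^3"`, `u = "m/s"`, `p = "MPa"`).
#' @param sigma_rho,sigma_u default per-measurement standard uncertainties
#'   (kg m^-3, m s^-1) used where the file supplies none. The defaults are
#'   half the expanded instrument uncertainties of a DSA 5000 M class
#'   densimeter (coverage factor 2).
#' @return a `measurement_table`: a validated data.frame in SI units with
#'   columns `solute`, `m_B`, `m_A`, `T`, `p`, `rho`, `u`, `sigma_rho`,
#'   `sigma_u` and logical `baseline`, sorted canonically so validation is
#'   independent of input row order.
#' @export
read_measurements <- function(path, config = NULL,
                              sigma_rho = 0.05, sigma_u = 0.4) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- .load_config(config)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(cfg$columns)) {
    for (internal in names(cfg$columns)) {
      ext <- cfg$columns[[internal]]
      if (!ext %in% names(raw)) {
        stop("configured column '", ext, "' not present in ", path, call. = FALSE)
      }
      names(raw)[names(raw) == ext] <- internal
    }
  }
  as_measurement_table(raw,
    units = cfg$units,
    sigma_rho = sigma_rho, sigma_u = sigma_u
  )
}

.load_config <- function(config) {
  if (is.null(config)) {
    return(list(columns = NULL, units = NULL))
  }
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

#' Validate a raw measurement data.frame
#'
#' Applies the same validation and unit normalisation as
#' [read_measurements()] to an in-memory data.frame. Enforces: positive
#' densities and sound speeds, non-negative molalities, positive absolute
#' temperatures, uniqueness of the `(solute, m_B, m_A, T)` key, and the
#' presence of exactly one `m_A = 0` baseline row per `(m_B, T)` group
#' that contains solute rows.
#'
#' @param df data.frame with at least `solute`, `m_B`, `m_A`, `T`, `rho`.
#' @param units optional named list of declared input units (see
#'   [read_measurements()]).
#' @inheritParams read_measurements
#' @return a `measurement_table` (SI units, canonical row order).
#' @export
as_measurement_table <- function(df, units = NULL,
                                 sigma_rho = 0.05, sigma_u = 0.4) {
  required <- c("solute", "m_B", "m_A", "T", "rho")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  df$solute <- as.character(df$solute)
  df$solute[is.na(df$solute) | df$solute == ""] <- "none"
  for (col in intersect(c("m_B", "m_A", "T", "p", "rho", "u", "sigma_rho", "sigma_u"), names(df))) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "")
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at row ", bad[1], call. = FALSE)
    }
    df[[col]] <- num
  }
  if (!"p" %in% names(df)) df$p <- 0.1
  if (!"u" %in% names(df)) df$u <- NA_real_
  if (!"sigma_rho" %in% names(df)) df$sigma_rho <- NA_real_
  if (!"sigma_u" %in% names(df)) df$sigma_u <- NA_real_
  df$sigma_rho[is.na(df$sigma_rho)] <- sigma_rho
  df$sigma_u[is.na(df$sigma_u)] <- sigma_u

  if (!is.null(units$rho)) {
    df$rho <- switch(units$rho,
      "kg/m^3" = df$rho,
      "g/cm^3" = df$rho * 1000,
      stop("unsupported density unit: ", units$rho, call. = FALSE)
    )
  }
  if (!is.null(units$u) && !identical(units$u, "m/s")) {
    stop("unsupported speed-of-sound unit: ", units$u, call. = FALSE)
  }

  with_na <- function(x, chk) !is.na(x) & chk
  if (any(with_na(df$rho, df$rho <= 0))) stop("rho must be positive", call. = FALSE)
  if (any(with_na(df$u, df$u <= 0))) stop("u must be positive", call. = FALSE)
  if (any(df$m_A < 0, na.rm = TRUE)) stop("m_A must be non-negative", call. = FALSE)
  if (any(df$m_B < 0, na.rm = TRUE)) stop("m_B must be non-negative", call. = FALSE)
  if (any(df$T <= 0, na.rm = TRUE)) stop("T must be positive (kelvin)", call. = FALSE)
  if (anyNA(df$m_A) || anyNA(df$m_B) || anyNA(df$T) || anyNA(df$rho)) {
    stop("m_B, m_A, T and rho must be present in every row", call. = FALSE)
  }

  df$baseline <- df$m_A == 0
  key <- paste(df$solute, df$m_B, df$m_A, df$T, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(
      "duplicate measurement key (solute=", d$solute, ", m_B=", d$m_B,
      ", m_A=", d$m_A, ", T=", d$T, ")",
      call. = FALSE
    )
  }

  grp <- paste(df$m_B, df$T, sep = "\r")
  for (g in unique(grp[!df$baseline])) {
    nb <- sum(df$baseline & grp == g)
    if (nb != 1L) {
      parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
      stop(
        if (nb == 0L) "missing" else "multiple", " baseline row(s) (m_A = 0) for group (m_B=",
        parts[1], ", T=", parts[2], ")",
        call. = FALSE
      )
    }
  }

  df <- df[order(df$solute, df$m_B, df$T, df$m_A), , drop = FALSE]
  rownames(df) <- NULL
  df <- df[, c(
    "solute", "m_B", "m_A", "T", "p", "rho", "u",
    "sigma_rho", "sigma_u", "baseline"
  )]
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Write a result table to CSV with stable formatting
#'
#' Writes a derived table with fixed column order and deterministic numeric
#' formatting, so repeated writes of the same table are byte-identical.
#' Numeric columns are rendered with full `%.15g` precision; callers that
#' want journal-scale values apply [si_to_report()] first.
#'
#' @param table nonempty data.frame.
#' @param path output CSV path.
#' @return invisibly, the path written.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("refusing to write an empty table", call. = FALSE)
  }
  out <- table
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- sprintf("%.15g", out[[col]])
  }
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con))
  lines <- c(
    paste(names(out), collapse = ","),
    do.call(paste, c(unname(as.list(out)), sep = ","))
  )
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write a run manifest
#'
#' Records inputs, configuration hash and seed alongside a set of result
#' tables, for reproducibility audits. The hash is the MD5 of the
#' canonical JSON serialization of `config`. No timestamps are recorded,
#' so reruns with identical inputs produce identical manifests.
#'
#' @param path output JSON path.
#' @param inputs character vector of input file paths (may be empty).
#' @param config list of run options.
#' @param seed integer seed used for any stochastic step (or `NA`).
#' @return invisibly, the manifest list.
#' @export
write_manifest <- function(path, inputs = character(), config = list(), seed = NA) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  manifest <- list(
    package = "solvatherm",
    version = as.character(utils::packageVersion("solvatherm")),
    inputs = as.character(inputs),
    config = config,
    config_md5 = unname(tools::md5sum(tmp)),
    seed = seed
  )
  unlink(tmp)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
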