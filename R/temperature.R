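#' Quadratic temperature model of the limiting volume
#'
#' Fits `V0(T) = a + b*(T - T_ref) + c*(T - T_ref)^2` by least squares.
#' With the customary four study temperatures the fit retains one residual
#' degree of freedom. `T_ref = 298.15 K` is the convention under which `b`
#' equals the limiting apparent molar expansibility at 298.15 K.
#'
#' @param T temperatures, K (>= 3 distinct values; duplicates rejected).
#' @param V0 limiting apparent molar volumes at each `T` (SI, m^3 mol^-1,
#'   or any consistent unit).
#' @param T_ref reference temperature, K.
#' @return list of class `temp_model`: coefficients `a`, `b`, `c` (signed),
#'   `T_ref`, `n_T`, and the two fit-quality metrics `residual_sd`
#'   (`sqrt(RSS/(n-3))`, `NA` when `n = 3`) and `ard`
#'   (mean absolute relative deviation).
#' @export
fit_temperature_model <- function(T, V0, T_ref = 298.15) {
  stopifnot(length(T) == length(V0))
  if (length(T) < 3L) stop("need at least 3 temperatures", call. = FALSE)
  if (anyDuplicated(T)) stop("duplicate temperatures in fit", call. = FALSE)
  x <- T - T_ref
  lmfit <- stats::lm(V0 ~ x + I(x^2))
  cf <- unname(stats::coef(lmfit))
  model <- list(
    a = cf[1], b = cf[2], c = cf[3], T_ref = T_ref,
    n_T = length(T)
  )
  q <- fit_quality(T, V0, model)
  model$residual_sd <- q$residual_sd
  model$ard <- q$ard
  class(model) <- "temp_model"
  model
}

#' Construct a temperature model from known coefficients
#'
#' Builds a `temp_model` object directly, e.g. from a published
#' coefficient table, for use with [expansibility()].
#'
#' @param a,b,c model coefficients (`a` in m^3 mol^-1, `b` in
#'   m^3 mol^-1 K^-1, `c` -- signed -- in m^3 mol^-1 K^-2).
#' @param T_ref reference temperature, K.
#' @return a `temp_model` object.
#' @export
temp_model <- function(a, b, c, T_ref = 298.15) {
  structure(
    list(
      a = a, b = b, c = c, T_ref = T_ref, n_T = NA_integer_,
      residual_sd = NA_real_, ard = NA_real_
    ),
    class = "temp_model"
  )
}

#' Evaluate a temperature model
#'
#' @param model a `temp_model`.
#' @param T temperatures, K.
#' @return predicted limiting volumes.
#' @export
predict_temp_model <- function(model, T) {
  x <- T - model$T_ref
  model$a + model$b * x + model$c * x^2
}

#' Fit-quality metrics for a temperature model
#'
#' Two candidate summaries of agreement between observed and
#' model-calculated limiting volumes: the residual standard deviation
#' `sqrt(sum((obs - calc)^2) / (n - 3))` and the mean absolute relative
#' deviation `mean(|obs - calc| / |obs|)`. Both are reported; which one a
#' table labels "sigma" is a reporting convention, not a property of the
#' fit.
#'
#' @inheritParams fit_temperature_model
#' @param model a `temp_model`.
#' @return list with `residual_sd` (`NA` with a zero-degree-of-freedom fit,
#'   i.e. `n = 3`) and `ard` (dimensionless).
#' @export
fit_quality <- function(T, V0, model) {
  calc <- predict_temp_model(model, T)
  r <- V0 - calc
  n <- length(T)
  list(
    residual_sd = if (n > 3L) sqrt(sum(r^2) / (n - 3)) else NA_real_,
    ard = mean(abs(r) / abs(V0))
  )
}

#' Limiting apparent molar expansibility and Hepler classification
#'
#' From the quadratic temperature model, `E0_phi = dV0/dT = b + 2c*(T -
#' T_ref)` and its temperature derivative `dE0/dT = 2c`, constant in `T`.
#' Hepler's criterion classifies a solute from the sign of `dE0/dT`
#' (equivalently of `d2V0/dT2`): positive for structure-makers
#' (kosmotropes), negative for structure-breakers.
#'
#' @param model a `temp_model`.
#' @param T temperatures at which to evaluate, K.
#' @param tol dead-band for the classification (same units as `dE0/dT`);
#'   magnitudes not exceeding `tol` are `"indeterminate"`.
#' @return data.frame with columns `T`, `E0_phi`, `dE0_dT`,
#'   `classification`.
#' @export
expansibility <- function(model, T, tol = 0) {
  E0 <- model$b + 2 * model$c * (T - model$T_ref)
  d <- rep(2 * model$c, length(T))
  data.frame(
    T = T, E0_phi = E0, dE0_dT = d,
    classification = hepler_classification(d, tol = tol),
    stringsAsFactors = FALSE
  )
}

#' OLS slope of expansibility values against temperature
#'
#' Consistency route for a published expansibility table: regressing the
#' tabulated `E0_phi` values on `T` recovers `dE0/dT` (equal to `2c` when
#' the values come from a quadratic volume model).
#'
#' @param T temperatures, K (>= 2).
#' @param E0_phi expansibility values at each `T`.
#' @return the fitted slope, in `E0_phi` units per kelvin.
#' @export
expansibility_slope_from_values <- function(T, E0_phi) {
  if (length(T) < 2L) stop("need at least 2 points", call. = FALSE)
  unname(stats::coef(stats::lm(E0_phi ~ T))[2])
}

#' Hepler structure-maker / structure-breaker classification
#'
#' @param dE0_dT temperature derivative of the limiting apparent molar
#'   expansibility (`2c` of the quadratic model), m^3 mol^-1 K^-2.
#' @param tol non-negative dead-band; `|dE0_dT| <= tol` is
#'   `"indeterminate"`.
#' @return character vector: `"structure_maker"`, `"structure_breaker"` or
#'   `"indeterminate"`.
#' @export
hepler_classification <- function(dE0_dT, tol = 0) {
  if (any(tol < 0)) stop("tol must be non-negative", call. = FALSE)
  ifelse(dE0_dT > tol, "structure_maker",
    ifelse(dE0_dT < -tol, "structure_breaker", "indeterminate")
  )
}

#' Temperature models for every (solute, m_B) group of limiting volume fits
#'
#' @param fits data.frame of limiting fits (volume rows are used).
#' @param T_ref reference temperature, K.
#' @param tol Hepler dead-band passed to [expansibility()]; the default
#'   `NULL` uses the propagated standard error of `2c` from each fit, so
#'   classifications are not over-claimed from noise.
#' @return list with `models` (data.frame: `solute`, `m_B`, `a`, `b`, `c`,
#'   `T_ref`, `n_T`, `residual_sd`, `ard`), `expansibilities` (one row per
#'   `(solute, m_B, T)`) and `skipped`.
#' @export
fit_temperature_tables <- function(fits, T_ref = 298.15, tol = NULL) {
  vol <- fits[fits$property == "volume", , drop = FALSE]
  if (nrow(vol) == 0L) stop("no volume fits supplied", call. = FALSE)
  keys <- unique(vol[, c("solute", "m_B")])
  keys <- keys[order(keys$solute, keys$m_B), , drop = FALSE]
  models <- list()
  expans <- list()
  skipped <- list()
  for (i in seq_len(nrow(keys))) {
    g <- vol[vol$solute == keys$solute[i] & vol$m_B == keys$m_B[i], , drop = FALSE]
    if (nrow(g) < 3L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        solute = keys$solute[i], m_B = keys$m_B[i],
        reason = "fewer than 3 temperatures", stringsAsFactors = FALSE
      )
      next
    }
    m <- fit_temperature_model(g$T, g$intercept, T_ref = T_ref)
    models[[length(models) + 1L]] <- data.frame(
      solute = keys$solute[i], m_B = keys$m_B[i],
      a = m$a, b = m$b, c = m$c, T_ref = T_ref, n_T = m$n_T,
      residual_sd = m$residual_sd, ard = m$ard, stringsAsFactors = FALSE
    )
    # se(2c) from the quadratic refit, for the classification dead-band
    band <- if (is.null(tol)) {
      x <- g$T - T_ref
      lmfit <- stats::lm(g$intercept ~ x + I(x^2))
      se_c <- sqrt(diag(suppressWarnings(stats::vcov(lmfit))))[3]
      if (is.finite(se_c)) 2 * se_c else 0
    } else {
      tol
    }
    e <- expansibility(m, sort(g$T), tol = band)
    expans[[length(expans) + 1L]] <- cbind(
      data.frame(
        solute = keys$solute[i], m_B = keys$m_B[i],
        stringsAsFactors = FALSE
      ),
      e
    )
  }
  list(
    models = if (length(models)) do.call(rbind, models) else data.frame(),
    expansibilities = if (length(expans)) do.call(rbind, expans) else data.frame(),
    skipped = if (length(skipped)) do.call(rbind, skipped) else data.frame()
  )
}
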