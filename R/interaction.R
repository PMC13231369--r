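#' Pair and triplet interaction coefficients from transfer functions
#'
#' Fits the McMillan--Mayer / Friedman--Krishnan expansion
#' `delta(m_B) = 2*pair*m_B + 3*triplet*m_B^2`
#' to a transfer function versus co-solvent molality by zero-intercept
#' least squares (the transfer is identically zero at `m_B = 0`, so the
#' model has no constant term). Both coefficients are fitted jointly.
#'
#' @param m_B co-solvent molalities, mol kg^-1 (>= 2 distinct positive
#'   values).
#' @param delta transfer-function values at each `m_B` (volume:
#'   m^3 mol^-1; compression: m^3 mol^-1 Pa^-1).
#' @return list of class `interaction_fit`: `pair`, `triplet` (units
#'   `delta`-unit mol^-1 kg and `delta`-unit mol^-2 kg^2), `se_pair`,
#'   `se_triplet` (`NA` with fewer than 3 points), `n_points`.
#' @examples
#' m <- c(0.1, 0.2, 0.3, 0.4)
#' fit_pair_triplet(m, 2 * 5 * m + 3 * (-2) * m^2) # recovers (5, -2)
#' @export
fit_pair_triplet <- function(m_B, delta) {
  ok <- is.finite(m_B) & is.finite(delta)
  m_B <- m_B[ok]
  delta <- delta[ok]
  n <- length(m_B)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (length(unique(m_B)) < 2L) {
    stop("singular design: all m_B identical", call. = FALSE)
  }
  x1 <- 2 * m_B
  x2 <- 3 * m_B^2
  lmfit <- stats::lm(delta ~ x1 + x2 - 1)
  cf <- unname(stats::coef(lmfit))
  se <- if (n >= 3L) {
    unname(sqrt(diag(suppressWarnings(stats::vcov(lmfit)))))
  } else {
    c(NA_real_, NA_real_)
  }
  structure(
    list(
      pair = cf[1], triplet = cf[2],
      se_pair = se[1], se_triplet = se[2],
      n_points = n
    ),
    class = "interaction_fit"
  )
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf(
    "interaction fit (n = %d): pair %.6g (se %.3g), triplet %.6g (se %.3g)\n",
    x$n_points, x$pair, x$se_pair, x$triplet, x$se_triplet
  ))
  invisible(x)
}

#' Interaction coefficients for every (solute, T, property) group
#'
#' @param transfers transfer-value table from [transfer_all()] (columns
#'   `solute`, `m_B`, `T`, `property`, `delta`).
#' @return list with `fits` (data.frame: `solute`, `T`, `property`, `pair`,
#'   `triplet`, `se_pair`, `se_triplet`, `n_points`) and `skipped`.
#' @export
fit_interaction_tables <- function(transfers) {
  stopifnot(is.data.frame(transfers))
  if (nrow(transfers) == 0L) stop("empty transfer table", call. = FALSE)
  keys <- unique(transfers[, c("solute", "T", "property")])
  keys <- keys[order(keys$solute, keys$property, keys$T), , drop = FALSE]
  fits <- list()
  skipped <- list()
  for (i in seq_len(nrow(keys))) {
    g <- transfers[
      transfers$solute == keys$solute[i] &
        transfers$T == keys$T[i] &
        transfers$property == keys$property[i], ,
      drop = FALSE
    ]
    res <- tryCatch(fit_pair_triplet(g$m_B, g$delta), error = function(e) e)
    key <- data.frame(
      solute = keys$solute[i], T = keys$T[i],
      property = keys$property[i], stringsAsFactors = FALSE
    )
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <- cbind(key, reason = conditionMessage(res))
    } else {
      fits[[length(fits) + 1L]] <- cbind(key, data.frame(
        pair = res$pair, triplet = res$triplet,
        se_pair = res$se_pair, se_triplet = res$se_triplet,
        n_points = res$n_points
      ))
    }
  }
  list(
    fits = if (length(fits)) do.call(rbind, fits) else data.frame(),
    skipped = if (length(skipped)) do.call(rbind, skipped) else data.frame()
  )
}
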