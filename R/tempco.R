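#' Amide-proton temperature coefficients
#'
#' Fits, per residue, an ordinary-least-squares line to the HN chemical
#' shift versus temperature series and reports the gradient in ppb/K with
#' its standard error.  Classification follows the conventional -4.6 ppb/K
#' boundary: slopes less negative than -4.6 (and non-positive) indicate an
#' intramolecular hydrogen-bond-protected amide, slopes at or below -4.6
#' indicate a solvent-exposed amide (the boundary value itself classifies as
#' solvent-exposed), and positive slopes indicate conformational exchange or
#' aromatic ring-current effects.
#'
#' @param series data.frame with columns \code{residue_index},
#'   \code{temperature_K}, \code{shift_ppm} (see [readTempSeries()]).
#' @param boundary class boundary in ppb/K (default -4.6).
#' @return data.frame with \code{residue_index}, \code{slope_ppb_per_K},
#'   \code{se_ppb_per_K}, \code{class}.
#' @examples
#' s <- data.frame(residue_index = 1, temperature_K = seq(298, 310, 2),
#'                 shift_ppm = 8.0 - 5e-3 * (seq(298, 310, 2) - 298))
#' fitTempCoefficient(s)  # slope -5 ppb/K, solvent_exposed
#' @export
fitTempCoefficient <- function(series, boundary = -4.6) {
  req <- c("residue_index", "temperature_K", "shift_ppm")
  if (!all(req %in% names(series)))
    stop("series must have columns: ", paste(req, collapse = ", "))
  idx <- sort(unique(series$residue_index))
  rows <- lapply(idx, function(i) {
    s <- series[series$residue_index == i, ]
    if (nrow(s) < 3L)
      stop("residue ", i, ": at least 3 observations are required for a fit")
    if (length(unique(s$temperature_K)) < 2L)
      stop("residue ", i, ": all observations at a single temperature")
    fit <- lm(shift_ppm ~ temperature_K, data = s)
    # summary.lm warns on noiseless collinear input; that case is legitimate here
    sm <- withCallingHandlers(summary(fit)$coefficients,
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    slope <- sm["temperature_K", "Estimate"] * 1000      # ppm/K -> ppb/K
    se <- sm["temperature_K", "Std. Error"] * 1000
    # boundary applied with <= (tiny tolerance so an exactly-boundary line
    # is not misclassified by floating-point noise in the fit)
    eps <- 1e-9
    cls <- if (slope <= boundary + eps) "solvent_exposed"
           else if (slope <= eps) "hbond_protected"
           else "exchange_or_aromatic"
    data.frame(residue_index = i, slope_ppb_per_K = slope,
               se_ppb_per_K = se, class = cls)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a temperature-series CSV
#'
#' Dialect: header \code{residue_index,temperature_K,shift_ppm}, one row per
#' (residue, temperature) observation.
#'
#' @param path file path.
#' @return data.frame suitable for [fitTempCoefficient()].
#' @export
readTempSeries <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("residue_index", "temperature_K", "shift_ppm")
  if (!all(req %in% names(d)))
    stop("temperature-series CSV must have header: ", paste(req, collapse = ","))
  d
}
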