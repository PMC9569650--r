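#' Per-residue Ca root-mean-square fluctuation
#'
#' Models are superposed onto their mean structure (two passes: fit to the
#' first model, average, refit to the average) over the CA atoms of
#' \code{alignRange} (default: all residues), and the RMSF of each CA is
#' the root-mean over models of its squared displacement from the mean
#' position.  Invariant under rigid rotation/translation of any model.
#'
#' @param ensemble a [ConformerEnsemble-class] with >= 2 models.
#' @param alignRange optional residue indices used for the superposition.
#' @return data.frame with \code{residue_index}, \code{residue_name},
#'   \code{rmsf} (Angstrom).
#' @export
rmsfProfile <- function(ensemble, alignRange = NULL) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  if (nModels(ensemble) < 2L) stop("RMSF requires at least 2 models")
  a <- ensemble@atoms
  caSel <- a$atom_name == "CA"
  resTab <- .residueTable(ensemble)
  missing <- setdiff(resTab$residue_index, a$residue_index[caSel])
  if (length(missing))
    warning("residues without CA reported missing: ",
            paste(missing, collapse = ", "))
  fitSel <- caSel & (if (is.null(alignRange)) TRUE
                     else a$residue_index %in% alignRange)
  if (!any(fitSel)) stop("alignment range selects no CA atoms")
  fitIdx <- .xyzIndex(fitSel)
  xyz <- ensemble@xyz
  for (pass in 1:2) {
    ref <- if (pass == 1L) xyz[1, ] else colMeans(xyz)
    xyz <- bio3d::fit.xyz(ref, xyz, fixed.inds = fitIdx, mobile.inds = fitIdx)
  }
  mu <- colMeans(xyz)
  caIdx <- which(caSel)
  rmsf <- vapply(caIdx, function(i) {
    cols <- (3 * i - 2):(3 * i)
    disp2 <- rowSums((xyz[, cols, drop = FALSE] -
                      matrix(mu[cols], nrow(xyz), 3, byrow = TRUE))^2)
    sqrt(mean(disp2))
  }, 0)
  out <- merge(resTab,
               data.frame(residue_index = a$residue_index[caIdx], rmsf = rmsf),
               by = "residue_index", all.x = TRUE)
  out[order(out$residue_index), c("residue_index", "residue_name", "rmsf")]
}

#' Mean and SD of a per-residue profile over a residue range
#'
#' @param profile data.frame with \code{residue_index} and the value column,
#'   or a plain named numeric vector (names = residue indices).
#' @param range inclusive residue indices to average over.
#' @param column value column name when \code{profile} is a data.frame.
#' @return list with \code{mean}, \code{sd} (sample SD), \code{n}.
#' @examples
#' regionAverage(c(`1` = 6, `2` = 8), 1:2)  # 7 +/- 1.414
#' @export
regionAverage <- function(profile, range, column = "rmsf") {
  if (is.data.frame(profile)) {
    v <- setNames(profile[[column]], profile$residue_index)
  } else v <- profile
  v <- v[names(v) %in% as.character(range)]
  v <- v[!is.na(v)]
  if (!length(v)) stop("residue range has no values to average")
  list(mean = mean(v), sd = if (length(v) > 1L) sd(v) else 0, n = length(v))
}

#' Named preset for the shift-based order-parameter map
#'
#' Coefficients of the random-coil-index-style mapping used by
#' [predictS2()]: per-nucleus weights (protons are up-weighted so that
#' their ppm-scale deviations are commensurate with carbon/nitrogen),
#' the secondary-shift floor below which a residue is maximally flexible,
#' the saturation constant of the monotone map, and the S2 floor.
#'
#' @return named list of coefficients with an \code{id} stamped into outputs.
#' @export
s2Preset <- function() {
  list(id = "rci-lite-1",
       weights = c(CA = 1, CB = 1, N = 0.4, HA = 7, H = 7),
       shiftFloor = 0.1,   # ppm; |secondary shift| at/below this is noise
       tau = 0.3,          # ppm; saturation scale of the monotone map
       s2Floor = 0.3)      # minimum (maximally flexible) order parameter
}

#' Chemical-shift-predicted order parameters
#'
#' Random-coil-index-style S2 prediction: per residue, the weighted mean of
#' absolute secondary shifts over the available backbone (+ CB) nuclei is
#' floored at \code{shiftFloor} and transformed by the monotone saturating
#' map \eqn{S^2 = f + (1-f)(1 - e^{-(s - s_0)/\tau})} onto
#' [\code{s2Floor}, 1].  Larger secondary shifts never yield a lower S2.
#' Residues with fewer than 2 usable nuclei are reported missing.  The
#' preset id is recorded in the \code{"s2_preset"} attribute.
#'
#' @param sec a [SecondaryShiftTable-class].
#' @param coeffs coefficient block, see [s2Preset()].
#' @return data.frame with \code{residue_index}, \code{residue_name},
#'   \code{s2}.
#' @export
predictS2 <- function(sec, coeffs = s2Preset()) {
  stopifnot(is(sec, "SecondaryShiftTable"))
  d <- secondaryDeltas(sec)
  d <- d[d$atom_name %in% names(coeffs$weights), ]
  resn <- unique(d[c("residue_index", "residue_name")])
  s2 <- vapply(resn$residue_index, function(i) {
    g <- d[d$residue_index == i, ]
    if (nrow(g) < 2L) return(NA_real_)
    w <- coeffs$weights[g$atom_name]
    s <- sum(w * abs(g$delta_ppm)) / sum(w)
    s <- max(s, coeffs$shiftFloor)
    coeffs$s2Floor + (1 - coeffs$s2Floor) *
      (1 - exp(-(s - coeffs$shiftFloor) / coeffs$tau))
  }, 0)
  out <- data.frame(residue_index = resn$residue_index,
                    residue_name = resn$residue_name, s2 = s2)
  out <- out[order(out$residue_index), ]
  rownames(out) <- NULL
  attr(out, "s2_preset") <- coeffs$id
  out
}

#' T2-filter intensity-ratio model
#'
#' During a CPMG filter of duration T, transverse relaxation attenuates a
#' residue's cross-peak to \eqn{I/I_0 = e^{-R_2 T}}; a residue is
#' detectable when the ratio exceeds the noise floor.  Residues relaxing
#' faster than the nominal filter rate \eqn{1/T} are the ones lost from the
#' filtered spectrum.
#'
#' @param r2 per-residue transverse relaxation rates, as a named numeric
#'   vector (names = residue indices) or a data.frame with
#'   \code{residue_index}, \code{r2_hz}.
#' @param filterTime filter duration T in seconds (e.g. 0.125 or 0.250).
#' @param noiseFloor detectability threshold as a fraction of the reference
#'   intensity (default 0.1).
#' @return data.frame with \code{residue_index}, \code{r2_hz},
#'   \code{ratio}, \code{detectable}; filter metadata in attributes.
#' @examples
#' t2Filter(c(`1` = 4), 0.250)  # ratio exp(-1)
#' @export
t2Filter <- function(r2, filterTime, noiseFloor = 0.1) {
  stopifnot(filterTime > 0)
  if (is.data.frame(r2)) r2 <- setNames(r2$r2_hz, r2$residue_index)
  if (any(r2 < 0)) stop("R2 rates must be non-negative")
  ratio <- exp(-r2 * filterTime)
  out <- data.frame(residue_index = as.integer(names(r2)), r2_hz = unname(r2),
                    ratio = unname(ratio),
                    detectable = unname(ratio > noiseFloor))
  attr(out, "filter_time_s") <- filterTime
  attr(out, "nominal_rate_hz") <- 1 / filterTime
  attr(out, "noise_floor") <- noiseFloor
  out
}
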