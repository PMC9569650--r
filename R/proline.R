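#' Proline cis/trans classification from the Cb-Cg shift difference
#'
#' The Xaa-Pro peptide bond configuration is read from
#' \eqn{\Delta\beta\gamma = \delta C\beta - \delta C\gamma}: trans prolines
#' cluster near 5 ppm (Cb ~ 32, Cg ~ 27 ppm), cis prolines near 10 ppm
#' (Cb ~ 35, Cg ~ 25 ppm).  A configurable gap between the two bands yields
#' an explicit \code{ambiguous} call instead of a knife-edge decision.
#'
#' @param cb,cg proline Cb and Cg chemical shifts (ppm); vectorized.
#' @param residueIndex optional residue number(s) carried into the result.
#' @param residueName 3-letter code(s); anything other than PRO is rejected.
#' @param transMax upper \eqn{\Delta\beta\gamma} bound for a trans call (ppm).
#' @param cisMin lower bound for a cis call (ppm).
#' @return data.frame with \code{residue_index}, \code{cb_ppm},
#'   \code{cg_ppm}, \code{delta_bg_ppm}, \code{configuration}.
#' @examples
#' classifyProline(32, 27)   # trans, delta = 5
#' classifyProline(35, 25)   # cis,   delta = 10
#' @export
classifyProline <- function(cb, cg, residueIndex = NA_integer_,
                            residueName = "PRO", transMax = 6, cisMin = 8) {
  if (any(toupper(residueName) != "PRO"))
    stop("classifyProline applies to proline residues only, got: ",
         paste(setdiff(toupper(residueName), "PRO"), collapse = ", "))
  if (transMax >= cisMin)
    stop("transMax must be below cisMin (an empty ambiguous band is allowed, ",
         "an inverted one is not)")
  stopifnot(length(cb) == length(cg), all(is.finite(cb)), all(is.finite(cg)))
  dbg <- cb - cg
  conf <- ifelse(dbg <= transMax, "trans", ifelse(dbg >= cisMin, "cis", "ambiguous"))
  data.frame(residue_index = rep_len(as.integer(residueIndex), length(dbg)),
             cb_ppm = cb, cg_ppm = cg, delta_bg_ppm = dbg, configuration = conf)
}

#' @rdname classifyProline
#' @param obs a [ShiftTable-class]; every proline with both CB and CG
#'   assigned is classified.
#' @param ... passed to [classifyProline()].
#' @export
prolineRecords <- function(obs, ...) {
  stopifnot(is(obs, "ShiftTable"))
  s <- shifts(obs)
  pro <- s[s$residue_name == "PRO" & s$atom_name %in% c("CB", "CG"), ]
  idx <- sort(unique(pro$residue_index))
  rows <- lapply(idx, function(i) {
    cb <- pro$shift_ppm[pro$residue_index == i & pro$atom_name == "CB"]
    cg <- pro$shift_ppm[pro$residue_index == i & pro$atom_name == "CG"]
    if (length(cb) != 1L || length(cg) != 1L) return(NULL)
    classifyProline(cb, cg, residueIndex = i, ...)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- classifyProline(numeric(0), numeric(0))
  out
}

#' Cis population from cis/trans peak intensities
#'
#' The minor cis population of an Xaa-Pro bond is estimated from the
#' intensities of the resolved cis and trans signals as
#' \eqn{I_{cis} / (I_{cis} + I_{trans})}; the complementary trans fraction
#' is \code{1 - cisPopulation(...)} exactly.
#'
#' @param iCis,iTrans non-negative peak intensities.
#' @return fraction in [0, 1]; NA (with a warning) when both intensities are
#'   zero, since the ratio is then undefined.
#' @examples
#' cisPopulation(1, 9)  # 0.10
#' @export
cisPopulation <- function(iCis, iTrans) {
  if (any(iCis < 0) || any(iTrans < 0))
    stop("peak intensities must be non-negative")
  tot <- iCis + iTrans
  out <- ifelse(tot == 0, NA_real_, iCis / tot)
  if (anyNA(out))
    warning("cis population undefined where both intensities are zero; reported as NA")
  out
}
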