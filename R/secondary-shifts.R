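#' Secondary chemical shifts
#'
#' Computes \eqn{\Delta\delta = \delta_{obs} - \delta_{rc}} for every
#' observed cell whose nucleus has a random-coil reference (H, HA, N, CA,
#' CB), together with the per-residue \eqn{\Delta\delta C\alpha -
#' \Delta\delta C\beta} difference.  Cells without a reference (e.g. side
#' chains beyond CB) are dropped, and missing observations propagate as
#' missing, never as zero.  Non-standard residues are resolved through the
#' alias map of the random-coil model; an unmapped residue type is an error
#' naming the residue.
#'
#' @param obs a [ShiftTable-class] of observed shifts.
#' @param rc a [RandomCoilModel-class]; default packaged table.
#' @return a [SecondaryShiftTable-class].
#' @examples
#' obs <- ShiftTable("toy", data.frame(
#'   residue_index = 1:2, residue_name = c("GLU", "GLU"),
#'   atom_name = c("HA", "CA"), shift_ppm = c(4.10, 57.1)))
#' secondaryShifts(obs)
#' @export
secondaryShifts <- function(obs, rc = randomCoilModel()) {
  stopifnot(is(obs, "ShiftTable"), is(rc, "RandomCoilModel"))
  s <- shifts(obs)
  .resolveResidue(rc, unique(s$residue_name))  # fail loudly on unknown types
  ref <- randomCoilShift(rc, s$residue_name, s$atom_name)
  keep <- !is.na(ref)
  d <- s[keep, c("residue_index", "residue_name", "atom_name")]
  d$delta_ppm <- s$shift_ppm[keep] - ref[keep]
  rownames(d) <- NULL

  resn <- unique(s[c("residue_index", "residue_name")])
  grab <- function(atom) {
    m <- d[d$atom_name == atom, c("residue_index", "delta_ppm")]
    setNames(m$delta_ppm, m$residue_index)[as.character(resn$residue_index)]
  }
  caCb <- data.frame(residue_index = resn$residue_index,
                     residue_name = resn$residue_name,
                     delta_ca_cb = unname(grab("CA") - grab("CB")))
  caCb <- caCb[order(caCb$residue_index), , drop = FALSE]
  rownames(caCb) <- NULL
  new("SecondaryShiftTable", peptideId = peptideId(obs), deltas = d, caCb = caCb)
}

#' @rdname SecondaryShiftTable-class
#' @param object a SecondaryShiftTable.
#' @export
setMethod("peptideId", "SecondaryShiftTable", function(object) object@peptideId)

#' Secondary-shift cells of a SecondaryShiftTable
#' @param x a [SecondaryShiftTable-class].
#' @return data.frame of per-cell \code{delta_ppm} values.
#' @export
secondaryDeltas <- function(x) { stopifnot(is(x, "SecondaryShiftTable")); x@deltas }

#' @rdname secondaryDeltas
#' @return [caCbDifference()] returns the per-residue
#'   \eqn{\Delta\delta C\alpha - \Delta\delta C\beta} data.frame.
#' @export
caCbDifference <- function(x) { stopifnot(is(x, "SecondaryShiftTable")); x@caCb }

setMethod("show", "SecondaryShiftTable", function(object) {
  cat("SecondaryShiftTable for", sQuote(object@peptideId), "-",
      nrow(object@deltas), "cells,",
      sum(!is.na(object@caCb$delta_ca_cb)), "CA-CB differences\n")
})

#' Call secondary structure from consecutive CA-CB secondary shifts
#'
#' A residue is called helix when it belongs to a run of at least
#' \code{window} consecutive residues with \eqn{\Delta\delta C\alpha -
#' \Delta\delta C\beta > } \code{threshold} ppm, strand for a run below
#' \code{-threshold}, and coil otherwise; values within the band (the
#' \eqn{\pm 2} ppm range conventionally taken to indicate the absence of
#' stable secondary structure) always yield coil.  Missing values break runs.
#'
#' @param sec a [SecondaryShiftTable-class].
#' @param window minimum run length (consecutive residues); must be >= 2.
#' @param threshold band half-width in ppm (default 2).
#' @return data.frame with \code{residue_index}, \code{delta_ca_cb},
#'   \code{call} in \code{helix}/\code{strand}/\code{coil}.
#' @export
callSecondaryStructure <- function(sec, window = 3L, threshold = 2) {
  stopifnot(is(sec, "SecondaryShiftTable"))
  if (window < 2) stop("window must be >= 2: a single residue cannot be 'consecutive'")
  cc <- sec@caCb[order(sec@caCb$residue_index), , drop = FALSE]
  v <- cc$delta_ca_cb
  sign3 <- ifelse(is.na(v), 0L, ifelse(v > threshold, 1L, ifelse(v < -threshold, -1L, 0L)))
  # gaps in residue numbering also break runs
  run <- cumsum(c(1L, diff(cc$residue_index) != 1L | diff(sign3) != 0L))
  call <- rep("coil", length(v))
  for (r in unique(run)) {
    idx <- which(run == r)
    if (length(idx) >= window && sign3[idx[1]] == 1L) call[idx] <- "helix"
    if (length(idx) >= window && sign3[idx[1]] == -1L) call[idx] <- "strand"
  }
  data.frame(residue_index = cc$residue_index, residue_name = cc$residue_name,
             delta_ca_cb = v, call = call)
}
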