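#' Nucleus class of an atom label
#'
#' Maps nucleus labels onto the six classes entering the global CS-RMSD:
#' \code{Ca} (CA), \code{Cb} (CB), \code{HN} (H), \code{Ha} (HA, HA2, HA3),
#' \code{N} (backbone N) and \code{Hside} (all other protons).  Labels
#' outside these classes (e.g. aliphatic carbons beyond CB) return NA and
#' are excluded from the score.
#'
#' @param atomName nucleus label(s).
#' @return character class or NA.
#' @export
nucleusClass <- function(atomName) {
  a <- toupper(atomName)
  out <- rep(NA_character_, length(a))
  out[a == "CA"] <- "Ca"
  out[a == "CB"] <- "Cb"
  out[a == "H"] <- "HN"
  out[a %in% c("HA", "HA2", "HA3")] <- "Ha"
  out[a == "N"] <- "N"
  out[is.na(out) & startsWith(a, "H")] <- "Hside"
  out
}

.csClasses <- c("Ca", "Cb", "HN", "Ha", "N", "Hside")

#' Global chemical-shift RMSD between observed and predicted tables
#'
#' The deviation between observation and back-calculation is summarized per
#' nucleus class (Ca, Cb, HN, Ha, N, side-chain H) as the root-mean-square
#' difference over the cells shared by both tables, and globally as the
#' unweighted sum of the class RMSDs - the ranking score of the
#' chemical-shift-driven conformer selection.  Classes absent from the
#' observations are skipped (and listed in the result); zero shared cells
#' overall is an error.
#'
#' @param obs,pred [ShiftTable-class] objects.
#' @return list with \code{perClass} (named numeric), \code{global} (ppm),
#'   \code{nShared}, \code{skippedClasses}.
#' @examples
#' a <- ShiftTable("x", data.frame(residue_index = 1, residue_name = "ALA",
#'                                 atom_name = "CA", shift_ppm = 52.5))
#' b <- ShiftTable("x", data.frame(residue_index = 1, residue_name = "ALA",
#'                                 atom_name = "CA", shift_ppm = 53.0))
#' globalCsRmsd(a, b)$global  # 0.5
#' @export
globalCsRmsd <- function(obs, pred) {
  stopifnot(is(obs, "ShiftTable"), is(pred, "ShiftTable"))
  m <- merge(shifts(obs), shifts(pred), by = c("residue_index", "atom_name"),
             suffixes = c("_obs", "_pred"))
  m$class <- nucleusClass(m$atom_name)
  m <- m[!is.na(m$class), ]
  if (nrow(m) == 0L)
    stop("no shared (residue, nucleus) cells between observed and predicted tables")
  perClass <- vapply(split(m, m$class), function(g)
    sqrt(mean((g$shift_ppm_obs - g$shift_ppm_pred)^2)), 0)
  skipped <- setdiff(.csClasses, names(perClass))
  list(perClass = perClass, global = sum(perClass), nShared = nrow(m),
       skippedClasses = skipped)
}

.rms <- function(x) sqrt(mean(x^2))

#' Chemical-shift Q factor
#'
#' Normalized disagreement between observed and predicted secondary shifts:
#' \deqn{Q = \mathrm{rms}(\Delta\delta_{obs} - \Delta\delta_{pred}) /
#'       \mathrm{rms}(\Delta\delta_{obs})}
#' Q = 0 at perfect agreement and Q = 1 when the prediction carries no
#' secondary-shift information at all.  Given two [SecondaryShiftTable-class]
#' objects the cells are paired on (residue, nucleus) and both a pooled and
#' per-nucleus-class Q are reported; plain numeric vectors give the pooled
#' value only.
#'
#' @param obs observed secondary shifts (numeric vector or
#'   [SecondaryShiftTable-class]).
#' @param pred predicted secondary shifts, matching \code{obs}.
#' @return list with \code{pooled} and (for tables) \code{perClass}.
#' @export
qFactor <- function(obs, pred) {
  if (is.numeric(obs) && is.numeric(pred)) {
    stopifnot(length(obs) == length(pred))
    ok <- !is.na(obs) & !is.na(pred)
    return(list(pooled = .qOf(obs[ok], pred[ok]), perClass = NULL))
  }
  stopifnot(is(obs, "SecondaryShiftTable"), is(pred, "SecondaryShiftTable"))
  m <- merge(secondaryDeltas(obs), secondaryDeltas(pred),
             by = c("residue_index", "atom_name"), suffixes = c("_obs", "_pred"))
  if (nrow(m) == 0L) stop("no shared secondary-shift cells")
  m$class <- nucleusClass(m$atom_name)
  perClass <- vapply(split(m, m$class), function(g)
    .qOf(g$delta_ppm_obs, g$delta_ppm_pred), 0)
  list(pooled = .qOf(m$delta_ppm_obs, m$delta_ppm_pred), perClass = perClass)
}

.qOf <- function(o, p) {
  if (!length(o) || .rms(o) == 0) {
    warning("rms of observed secondary shifts is zero; Q undefined")
    return(NA_real_)
  }
  .rms(o - p) / .rms(o)
}
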