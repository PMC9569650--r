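#' Karplus parameters for the HN-Ha three-bond coupling
#'
#' Named presets of the Karplus coefficients relating the backbone phi
#' dihedral to \eqn{^{3}J_{HNH\alpha}}; the active preset id is carried in
#' the object and stamped into downstream outputs.  Available presets are
#' \code{"bax1997"} (A=7.09, B=-1.42, C=1.55 Hz) and \code{"bax1993"}
#' (A=6.51, B=-1.76, C=1.60 Hz); custom coefficients can be supplied
#' directly.
#'
#' @param preset preset id, ignored when A/B/C are all given.
#' @param A,B,C coefficients in Hz.
#' @param theta0 phase offset in degrees; the default -60 reproduces the
#'   conventional \eqn{J(\phi) = A\cos^2(\phi - 60^\circ) + \ldots} relation.
#' @return a [KarplusParams-class].
#' @export
karplusParams <- function(preset = "bax1997", A = NULL, B = NULL, C = NULL,
                          theta0 = -60) {
  if (is.null(A) && is.null(B) && is.null(C)) {
    t <- read.csv(.extdata("karplus_presets.csv"), stringsAsFactors = FALSE)
    row <- t[t$id == preset, ]
    if (nrow(row) != 1L)
      stop("unknown Karplus preset ", sQuote(preset), "; available: ",
           paste(t$id, collapse = ", "))
    A <- row$A_hz; B <- row$B_hz; C <- row$C_hz
    theta0 <- row$theta0_deg
  } else preset <- "custom"
  # slots assigned one by one: an argument named C would partially match
  # new()'s Class argument
  p <- new("KarplusParams")
  p@A <- A; p@B <- B; p@C <- C; p@theta0 <- theta0; p@id <- preset
  validObject(p)
  p
}

setMethod("show", "KarplusParams", function(object) {
  cat(sprintf("KarplusParams '%s': J(phi) = %.2f cos^2(phi%+g) %+.2f cos(phi%+g) %+.2f Hz\n",
              object@id, object@A, object@theta0, object@B, object@theta0, object@C))
})

#' Evaluate the Karplus relation
#'
#' \deqn{^{3}J(\phi) = A\cos^2(\phi + \theta_0) + B\cos(\phi + \theta_0) + C}
#' with angles in degrees; periodic in 360 degrees by construction.
#'
#' @param phi backbone phi dihedral(s) in degrees.
#' @param params a [KarplusParams-class].
#' @return coupling(s) in Hz.
#' @examples
#' karplusJ(-60, karplusParams())
#' @export
karplusJ <- function(phi, params = karplusParams()) {
  stopifnot(is(params, "KarplusParams"))
  ct <- cos((phi + params@theta0) * pi / 180)
  params@A * ct^2 + params@B * ct + params@C
}

#' Circular mean of angles in degrees
#'
#' Mean direction of the unit vectors \eqn{(\cos\theta, \sin\theta)};
#' well-behaved across the +/-180 degree wrap where an arithmetic mean is
#' not.  NA values are removed; an empty input yields NA.
#'
#' @param thetaDeg angles in degrees.
#' @return mean angle in (-180, 180], degrees.
#' @export
circularMeanDeg <- function(thetaDeg) {
  thetaDeg <- thetaDeg[!is.na(thetaDeg)]
  if (!length(thetaDeg)) return(NA_real_)
  r <- thetaDeg * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

#' Ensemble-averaged 3JHNHa back-calculation
#'
#' For every residue with a defined phi dihedral in all models (the first
#' residue has none, and prolines carry no amide proton), the coupling is
#' the Karplus relation evaluated at the circular mean of phi over the
#' ensemble - the fast-exchange average the measured coupling reports.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param params a [KarplusParams-class]; its preset id is recorded in the
#'   \code{"karplus_preset"} attribute of the result.
#' @return data.frame with \code{residue_index}, \code{residue_name},
#'   \code{phi_mean_deg}, \code{j_pred_hz} (NA rows mark excluded residues).
#' @export
ensembleJ <- function(ensemble, params = karplusParams()) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  dh <- phiPsi(ensemble)
  resn <- .residueTable(ensemble)
  phiMean <- apply(dh$phi, 2, function(col) {
    if (anyNA(col)) NA_real_ else circularMeanDeg(col)
  })
  usable <- !is.na(phiMean) & resn$residue_name != "PRO"
  out <- data.frame(residue_index = resn$residue_index,
                    residue_name = resn$residue_name,
                    phi_mean_deg = ifelse(usable, phiMean, NA_real_),
                    j_pred_hz = NA_real_)
  out$j_pred_hz[usable] <- karplusJ(phiMean[usable], params)
  attr(out, "karplus_preset") <- params@id
  out
}

#' Validate predicted couplings against measurements
#'
#' Pearson correlation and RMS deviation between observed and
#' back-calculated \eqn{^{3}J_{HNH\alpha}} values over paired residues.
#' Couplings outside the physical 0-15 Hz range trigger a warning (not an
#' error).  With fewer than 3 pairs, or zero variance in either vector, the
#' correlation is undefined and reported as NA.
#'
#' @param observed,predicted paired coupling values in Hz (NA pairs dropped).
#' @return list with \code{r}, \code{rmsd_hz}, \code{n}.
#' @export
validateJ <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- !is.na(observed) & !is.na(predicted)
  o <- observed[ok]; p <- predicted[ok]
  if (any(o <= 0 | o >= 15) || any(p <= 0 | p >= 15))
    warning("coupling value(s) outside the physical 0-15 Hz range")
  if (length(o) < 3L) {
    warning("fewer than 3 paired couplings; correlation undefined")
    return(list(r = NA_real_, rmsd_hz = if (length(o)) sqrt(mean((o - p)^2)) else NA_real_,
                n = length(o)))
  }
  r <- if (sd(o) == 0 || sd(p) == 0) {
    warning("zero variance in observed or predicted couplings; correlation undefined")
    NA_real_
  } else cor(o, p)
  list(r = r, rmsd_hz = sqrt(mean((o - p)^2)), n = length(o))
}
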