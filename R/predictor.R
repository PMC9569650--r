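#' Dihedral basin parameters and shift offsets
#'
#' The versioned basin table defines the (phi, psi) centers and widths of
#' the helix, strand and coil basins; the offset table defines the fixed
#' per-basin, per-nucleus secondary-shift offsets of the toy predictor
#' (helix lowers HA and raises CA; strand the reverse; coil is offset-free).
#' The two files share one version so the synthetic generator and the toy
#' predictor are mutually consistent by construction.
#'
#' @param version data-file version tag.
#' @return data.frame of basin parameters / offsets.
#' @export
basinTable <- function(version = "v1") {
  read.csv(.extdata(paste0("basin_params_", version, ".csv")),
           stringsAsFactors = FALSE)
}

#' @rdname basinTable
#' @export
basinOffsets <- function(version = "v1") {
  read.csv(.extdata(paste0("basin_offsets_", version, ".csv")),
           stringsAsFactors = FALSE)
}

# smallest absolute angular difference in degrees
.angDiff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Assign a (phi, psi) pair to the nearest dihedral basin
#'
#' Nearest basin center by Euclidean distance in wrapped (phi, psi) space.
#' When one angle is undefined (chain termini) the distance uses the
#' remaining angle only; with neither defined the residue is coil.
#'
#' @param phi,psi dihedrals in degrees (NA allowed).
#' @param basins basin parameter table from [basinTable()].
#' @return basin name: \code{"helix"}, \code{"strand"} or \code{"coil"}.
#' @export
classifyBasin <- function(phi, psi, basins = basinTable()) {
  vapply(seq_along(phi), function(i) {
    p <- phi[i]; q <- psi[i]
    if (is.na(p) && is.na(q)) return("coil")
    d2 <- vapply(seq_len(nrow(basins)), function(b) {
      dp <- if (is.na(p)) 0 else .angDiff(p, basins$phi_center_deg[b])^2
      dq <- if (is.na(q)) 0 else .angDiff(q, basins$psi_center_deg[b])^2
      dp + dq
    }, 0)
    basins$basin[which.min(d2)]
  }, "")
}

#' Built-in toy chemical-shift predictor
#'
#' @param randomCoil a [RandomCoilModel-class] providing baseline shifts.
#' @param version version tag of the basin/offset data files.
#' @return a [ToyShiftPredictor-class].
#' @seealso [predictShifts()]
#' @export
toyShiftPredictor <- function(randomCoil = randomCoilModel(), version = "v1") {
  new("ToyShiftPredictor", randomCoil = randomCoil,
      offsets = basinOffsets(version), basins = basinTable(version),
      id = paste0("toy-basin-", version))
}

setMethod("show", "ToyShiftPredictor", function(object) {
  cat("ToyShiftPredictor", sQuote(object@id), "on random-coil table",
      sQuote(object@randomCoil@id), "\n")
})

#' @rdname predictShifts
setMethod("predictShifts", "ToyShiftPredictor",
  function(predictor, ensemble, model) {
    stopifnot(is(ensemble, "ConformerEnsemble"),
              model >= 1L, model <= nModels(ensemble))
    dh <- phiPsi(ensemble)
    .toyPredictOne(predictor, ensemble, model, dh)
  })

.toyPredictOne <- function(predictor, ensemble, model, dh) {
  resTab <- .residueTable(ensemble)
  basin <- classifyBasin(dh$phi[model, ], dh$psi[model, ], predictor@basins)
  rc <- predictor@randomCoil
  nuclei <- unique(predictor@offsets$atom_name)
  rows <- do.call(rbind, lapply(seq_len(nrow(resTab)), function(r) {
    rn <- resTab$residue_name[r]
    base <- randomCoilShift(rc, rep(rn, length(nuclei)), nuclei)
    off <- predictor@offsets[[basin[r]]][match(nuclei, predictor@offsets$atom_name)]
    ok <- !is.na(base)  # e.g. GLY CB, PRO H have no reference shift
    data.frame(residue_index = resTab$residue_index[r], residue_name = rn,
               atom_name = nuclei[ok], shift_ppm = base[ok] + off[ok])
  }))
  ShiftTable(peptideId(ensemble), rows)
}

# batch prediction: dihedrals computed once for the whole ensemble
.predictAll <- function(predictor, ensemble) {
  M <- nModels(ensemble)
  if (is(predictor, "ToyShiftPredictor")) {
    dh <- phiPsi(ensemble)
    lapply(seq_len(M), function(m)
      tryCatch(.toyPredictOne(predictor, ensemble, m, dh),
               error = function(e) e))
  } else {
    lapply(seq_len(M), function(m)
      tryCatch(predictShifts(predictor, ensemble, m), error = function(e) e))
  }
}

#' @rdname predictShifts
setMethod("predictShifts", "function",
  function(predictor, ensemble, model) {
    out <- predictor(ensemble, model)
    if (!is(out, "ShiftTable"))
      stop("a predictor function must return a ShiftTable")
    out
  })

#' Average shift tables cell-wise
#'
#' Population-weighted (uniform) average over a list of shift tables: the
#' fast-exchange observable of an ensemble.  Cells are averaged over the
#' tables in which they appear.
#'
#' @param tables list of [ShiftTable-class] objects.
#' @param id identifier for the averaged table (default: first table's id).
#' @return a [ShiftTable-class].
#' @export
meanShiftTable <- function(tables, id = NULL) {
  stopifnot(length(tables) >= 1L, all(vapply(tables, is, TRUE, "ShiftTable")))
  all <- do.call(rbind, lapply(tables, shifts))
  agg <- aggregate(shift_ppm ~ residue_index + residue_name + atom_name,
                   data = all, FUN = mean)
  ShiftTable(id %||% peptideId(tables[[1]]), agg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
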