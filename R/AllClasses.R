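#' ShiftTable: per-residue, per-nucleus chemical shifts
#'
#' Container for an assigned chemical-shift list of one peptide.  Rows are
#' (residue index, residue name, nucleus label, shift in ppm); missing
#' assignments are absent rows, never sentinel values.
#'
#' @slot peptideId single identifier string.
#' @slot shifts data.frame with columns \code{residue_index},
#'   \code{residue_name}, \code{atom_name}, \code{shift_ppm}.
#' @seealso [ShiftTable()], [readShiftTable()], [secondaryShifts()]
#' @exportClass ShiftTable
setClass("ShiftTable",
  representation(peptideId = "character", shifts = "data.frame"))

setValidity("ShiftTable", function(object) {
  s <- object@shifts
  req <- c("residue_index", "residue_name", "atom_name", "shift_ppm")
  if (!all(req %in% names(s)))
    return(paste("shifts must have columns:", paste(req, collapse = ", ")))
  if (length(object@peptideId) != 1L || is.na(object@peptideId))
    return("peptideId must be a single non-NA string")
  if (nrow(s) == 0L) return(TRUE)
  if (any(!is.finite(s$shift_ppm))) return("shift_ppm must be finite")
  if (any(s$residue_index < 1L | s$residue_index != round(s$residue_index)))
    return("residue_index must be positive integers")
  bad <- setdiff(unique(s$atom_name), .shiftAtomVocabulary)
  if (length(bad))
    return(paste("atom_name outside the controlled vocabulary:",
                 paste(bad, collapse = ", ")))
  key <- paste(s$residue_index, s$atom_name)
  if (anyDuplicated(key))
    return(paste("duplicated (residue_index, atom_name) cells:",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  TRUE
})

#' RandomCoilModel: residue-type random-coil reference shifts
#'
#' Statistical-coil reference shifts per residue type and nucleus, with an
#' alias map for non-standard residues (e.g. \code{DGLU -> GLU},
#' \code{HCIT -> LYS}) and acquisition metadata.  Neighbor corrections are
#' not modelled and default to zero.
#'
#' @slot id version identifier of the packaged table.
#' @slot table data.frame with \code{residue_name}, \code{atom_name},
#'   \code{shift_ppm}.
#' @slot aliases named character vector mapping non-standard residue names to
#'   standard ones.
#' @slot temperatureK,pH acquisition metadata of the reference table.
#' @seealso [randomCoilModel()]
#' @exportClass RandomCoilModel
setClass("RandomCoilModel",
  representation(id = "character", table = "data.frame",
                 aliases = "character", temperatureK = "numeric",
                 pH = "numeric"))

setValidity("RandomCoilModel", function(object) {
  t <- object@table
  if (!all(c("residue_name", "atom_name", "shift_ppm") %in% names(t)))
    return("table must have residue_name, atom_name, shift_ppm")
  missing <- setdiff(.standardResidues, unique(t$residue_name))
  if (length(missing))
    return(paste("reference table lacks standard residues:",
                 paste(missing, collapse = ", ")))
  TRUE
})

#' SecondaryShiftTable: random-coil-referenced secondary shifts
#'
#' Per-cell secondary shifts \eqn{\Delta\delta = \delta_{obs} -
#' \delta_{rc}} together with the per-residue
#' \eqn{\Delta\delta C\alpha - \Delta\delta C\beta} difference used for
#' secondary-structure calling.
#'
#' @slot peptideId identifier of the underlying peptide.
#' @slot deltas data.frame with \code{residue_index}, \code{residue_name},
#'   \code{atom_name}, \code{delta_ppm}.
#' @slot caCb data.frame with \code{residue_index}, \code{residue_name},
#'   \code{delta_ca_cb} (NA where either nucleus is unassigned).
#' @seealso [secondaryShifts()], [callSecondaryStructure()], [qFactor()]
#' @exportClass SecondaryShiftTable
setClass("SecondaryShiftTable",
  representation(peptideId = "character", deltas = "data.frame",
                 caCb = "data.frame"))

#' CSPProfile: combined chemical-shift perturbation profile
#'
#' Per-residue combined \eqn{^{1}H/^{15}N/^{13}C} chemical-shift perturbation
#' between two peptide variants, with profile mean/SD and per-residue
#' significance flags.
#'
#' @slot profile data.frame with \code{residue_index}, \code{csp_ppm},
#'   \code{n_nuclei}, \code{flag} (\code{below_avg}, \code{above_avg},
#'   \code{above_avg_plus_sd}).
#' @slot mean,sd profile mean and sample SD over residues.
#' @slot weights the per-nucleus-type weights used.
#' @seealso [combinedCSP()]
#' @exportClass CSPProfile
setClass("CSPProfile",
  representation(profile = "data.frame", mean = "numeric", sd = "numeric",
                 weights = "numeric"))

#' ConformerEnsemble: multi-model peptide backbone ensemble
#'
#' M conformers of one peptide sharing atom order; coordinates are stored as
#' an M x 3N matrix (bio3d xyz convention).  Backbone dihedrals are derived
#' from coordinates on demand via [phiPsi()].
#'
#' @slot peptideId identifier string.
#' @slot atoms data.frame with \code{residue_index}, \code{residue_name},
#'   \code{atom_name}, one row per atom in coordinate order.
#' @slot xyz numeric matrix, one row per model, columns x1,y1,z1,x2,...
#' @slot cyclicHead TRUE when residues 1-5 form the cyclic RGD head.
#' @seealso [readPdbEnsemble()], [generateEnsemble()], [pairwiseRmsd()]
#' @exportClass ConformerEnsemble
setClass("ConformerEnsemble",
  representation(peptideId = "character", atoms = "data.frame",
                 xyz = "matrix", cyclicHead = "logical"))

setValidity("ConformerEnsemble", function(object) {
  a <- object@atoms
  if (!all(c("residue_index", "residue_name", "atom_name") %in% names(a)))
    return("atoms must have residue_index, residue_name, atom_name")
  if (ncol(object@xyz) != 3L * nrow(a))
    return("xyz must have 3 columns per atom")
  if (nrow(object@xyz) < 1L) return("ensemble must contain at least one model")
  if (any(!is.finite(object@xyz))) return("coordinates must be finite")
  if (any(a$residue_index < 1L)) return("residue_index must be positive")
  TRUE
})

#' ClusterResult: Kelley-penalty hierarchical clustering of an ensemble
#'
#' @slot labels integer cluster assignment per model at the chosen cut.
#' @slot medoids integer model indices of the per-cluster representatives.
#' @slot levels data.frame of every candidate cut: \code{n_clusters},
#'   \code{avg_spread}, \code{norm_spread}, \code{penalty}.
#' @slot chosenK number of clusters minimizing the Kelley penalty.
#' @slot linkage agglomeration method used for the tree.
#' @slot tree the underlying \code{hclust} object (NULL for degenerate input).
#' @seealso [kelleyCluster()]
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(labels = "integer", medoids = "integer",
                 levels = "data.frame", chosenK = "integer",
                 linkage = "character", tree = "ANY"))

setValidity("ClusterResult", function(object) {
  if (length(object@labels) == 0L) return("empty assignment")
  k <- length(unique(object@labels))
  if (length(object@medoids) != k)
    return("one medoid required per cluster")
  for (cl in seq_along(object@medoids)) {
    if (object@labels[object@medoids[[cl]]] != as.integer(names(object@medoids)[cl]))
      return("medoid must belong to its cluster")
  }
  TRUE
})

#' SelectionResult: chemical-shift-RMSD ranked conformer selection
#'
#' @slot peptideId identifier of the scored ensemble.
#' @slot ranking data.frame of all scored conformers: \code{conformer},
#'   per-nucleus-class RMSD columns, \code{global_cs_rmsd}; sorted
#'   non-decreasing in score (ties broken by conformer id).
#' @slot selected integer ids of the selected conformers.
#' @slot mode one of \code{lowest}, \code{highest}, \code{random}.
#' @slot n requested ensemble size.
#' @slot seed seed used for random mode (NA otherwise).
#' @slot ensembleScore global CS-RMSD of the population-averaged predicted
#'   shifts of the selected ensemble against the observations.
#' @slot ensemblePerClass per-nucleus-class RMSDs of the averaged prediction.
#' @slot meanConformerScore mean of the selected conformers' individual
#'   global CS-RMSDs (transparency alternative to \code{ensembleScore}).
#' @seealso [selectEnsemble()], [globalCsRmsd()]
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(peptideId = "character", ranking = "data.frame",
                 selected = "integer", mode = "character", n = "integer",
                 seed = "numeric", ensembleScore = "numeric",
                 ensemblePerClass = "numeric", meanConformerScore = "numeric"))

#' KarplusParams: coefficients of the three-bond coupling relation
#'
#' Parameterizes \eqn{^{3}J(\phi) = A\cos^2(\phi+\theta_0) +
#' B\cos(\phi+\theta_0) + C} with \eqn{\theta_0 = -60^\circ} by convention
#' for the HN-Ha coupling.
#'
#' @slot A,B,C coefficients in Hz.
#' @slot theta0 phase offset in degrees.
#' @slot id preset identifier recorded in outputs.
#' @seealso [karplusParams()], [karplusJ()]
#' @exportClass KarplusParams
setClass("KarplusParams",
  representation(A = "numeric", B = "numeric", C = "numeric",
                 theta0 = "numeric", id = "character"),
  prototype(A = 0, B = 0, C = 0, theta0 = -60, id = "custom"))

setValidity("KarplusParams", function(object) {
  v <- c(object@A, object@B, object@C, object@theta0)
  if (length(v) != 4L || any(!is.finite(v)))
    return("A, B, C, theta0 must be single finite numbers")
  TRUE
})

#' ToyShiftPredictor: dihedral-basin chemical-shift back-calculator
#'
#' Built-in predictor satisfying the predictor contract: a total,
#' deterministic map from conformer geometry to a [ShiftTable].  Each residue
#' is assigned to the nearest (phi, psi) basin (helix / strand / coil) and
#' its shifts are the random-coil reference plus a fixed per-basin,
#' per-nucleus offset from a versioned table shared with the synthetic
#' generator.
#'
#' @slot randomCoil the [RandomCoilModel] providing baseline shifts.
#' @slot offsets data.frame of per-basin offsets keyed by \code{atom_name}.
#' @slot basins data.frame of basin centers/widths (degrees).
#' @slot id predictor version identifier stamped into outputs.
#' @seealso [toyShiftPredictor()], [predictShifts()]
#' @exportClass ToyShiftPredictor
setClass("ToyShiftPredictor",
  representation(randomCoil = "RandomCoilModel", offsets = "data.frame",
                 basins = "data.frame", id = "character"))

#' SyntheticSpec: study conditions for the synthetic-data generator
#'
#' @slot sequence character vector of 3-letter residue names (non-standard
#'   DGLU/HCIT allowed).
#' @slot nConformers number of conformers M to generate.
#' @slot nTrue size of the hidden true sub-ensemble.
#' @slot truePopulations,decoyPopulations basin populations
#'   (helix/strand/coil, summing to 1) for true and decoy conformers.
#' @slot shiftSigma Gaussian noise SD (ppm) on simulated observed shifts.
#' @slot cyclicHead enforce the cyclic-head closure on residues 1-5.
#' @slot closureMaxDist CA1-CA5 acceptance distance (Angstrom).
#' @slot seed base seed; all stochastic output is a pure function of it.
#' @seealso [syntheticSpec()], [generateEnsemble()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(sequence = "character", nConformers = "integer",
                 nTrue = "integer", truePopulations = "numeric",
                 decoyPopulations = "numeric", shiftSigma = "numeric",
                 cyclicHead = "logical", closureMaxDist = "numeric",
                 seed = "numeric"))

setValidity("SyntheticSpec", function(object) {
  for (p in list(object@truePopulations, object@decoyPopulations)) {
    if (!setequal(names(p), c("helix", "strand", "coil")))
      return("populations must be named helix/strand/coil")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      return("populations must be non-negative and sum to 1")
  }
  if (object@shiftSigma < 0) return("shiftSigma must be >= 0")
  if (object@nTrue > object@nConformers)
    return("nTrue cannot exceed nConformers")
  if (length(object@sequence) < 2L) return("sequence too short")
  TRUE
})
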