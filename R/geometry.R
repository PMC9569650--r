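#' @rdname ConformerEnsemble-class
#' @param peptideId identifier string.
#' @param atoms atom table (\code{residue_index}, \code{residue_name},
#'   \code{atom_name}).
#' @param xyz numeric M x 3N coordinate matrix (bio3d xyz convention).
#' @param cyclicHead whether residues 1-5 form the cyclic RGD head.
#' @export
ConformerEnsemble <- function(peptideId, atoms, xyz, cyclicHead = FALSE) {
  atoms <- as.data.frame(atoms)
  atoms$residue_index <- as.integer(atoms$residue_index)
  atoms$residue_name <- toupper(as.character(atoms$residue_name))
  atoms$atom_name <- toupper(as.character(atoms$atom_name))
  xyz <- as.matrix(xyz)
  if (is.null(dim(xyz)) || nrow(xyz) == 0) stop("xyz must be a non-empty matrix")
  new("ConformerEnsemble", peptideId = as.character(peptideId), atoms = atoms,
      xyz = xyz, cyclicHead = isTRUE(cyclicHead))
}

#' @rdname ConformerEnsemble-class
#' @export
setMethod("peptideId", "ConformerEnsemble", function(object) object@peptideId)

#' @rdname ConformerEnsemble-class
#' @export
setMethod("nModels", "ConformerEnsemble", function(object) nrow(object@xyz))

#' @rdname ConformerEnsemble-class
#' @export
setMethod("nResidues", "ConformerEnsemble",
          function(object) length(unique(object@atoms$residue_index)))

setMethod("show", "ConformerEnsemble", function(object) {
  cat("ConformerEnsemble", sQuote(object@peptideId), "-",
      nModels(object), "models,", nResidues(object), "residues,",
      nrow(object@atoms), "atoms/model",
      if (object@cyclicHead) "(cyclic head)" else "", "\n")
})

#' Atom table of an ensemble
#' @param ensemble a [ConformerEnsemble-class].
#' @return data.frame with one row per atom in coordinate order.
#' @export
ensembleAtoms <- function(ensemble) {
  stopifnot(is(ensemble, "ConformerEnsemble")); ensemble@atoms
}

#' @rdname ensembleAtoms
#' @return [ensembleXyz()] returns the M x 3N coordinate matrix.
#' @export
ensembleXyz <- function(ensemble) {
  stopifnot(is(ensemble, "ConformerEnsemble")); ensemble@xyz
}

# residue_index/residue_name lookup in residue order
.residueTable <- function(ensemble) {
  a <- ensemble@atoms
  r <- unique(a[c("residue_index", "residue_name")])
  r <- r[order(r$residue_index), , drop = FALSE]
  rownames(r) <- NULL
  r
}

# N x 3 coordinates of one model
.modelCoords <- function(ensemble, model) {
  matrix(ensemble@xyz[model, ], ncol = 3, byrow = TRUE)
}

# xyz column indices of the atoms selected by a logical/integer atom index
.xyzIndex <- function(atomIdx) {
  if (is.logical(atomIdx)) atomIdx <- which(atomIdx)
  as.vector(rbind(3 * atomIdx - 2, 3 * atomIdx - 1, 3 * atomIdx))
}

#' Dihedral angle defined by four points
#'
#' Signed torsion (IUPAC convention) in degrees, in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric xyz triples.
#' @return angle in degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi dihedrals of every model
#'
#' Angles are computed from the stored N/CA/C coordinates; phi of the first
#' residue and psi of the last are undefined (NA).
#'
#' @param ensemble a [ConformerEnsemble-class] with complete N, CA, C
#'   backbone atoms.
#' @return list of two M x nResidues matrices \code{phi} and \code{psi}
#'   (degrees), columns named by residue index.
#' @export
phiPsi <- function(ensemble) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  a <- ensemble@atoms
  resTab <- .residueTable(ensemble)
  nres <- nrow(resTab)
  idxOf <- function(res, name) {
    i <- which(a$residue_index == res & a$atom_name == name)
    if (length(i) != 1L) NA_integer_ else i
  }
  iN <- vapply(resTab$residue_index, idxOf, 0L, name = "N")
  iCA <- vapply(resTab$residue_index, idxOf, 0L, name = "CA")
  iC <- vapply(resTab$residue_index, idxOf, 0L, name = "C")
  if (anyNA(c(iN, iCA, iC)))
    stop("phiPsi requires N, CA and C atoms for every residue")
  M <- nModels(ensemble)
  phi <- matrix(NA_real_, M, nres, dimnames = list(NULL, resTab$residue_index))
  psi <- phi
  for (m in seq_len(M)) {
    co <- .modelCoords(ensemble, m)
    for (r in seq_len(nres)) {
      if (r > 1L)
        phi[m, r] <- dihedralAngle(co[iC[r - 1L], ], co[iN[r], ],
                                   co[iCA[r], ], co[iC[r], ])
      if (r < nres)
        psi[m, r] <- dihedralAngle(co[iN[r], ], co[iCA[r], ],
                                   co[iC[r], ], co[iN[r + 1L], ])
    }
  }
  list(phi = phi, psi = psi)
}

# --- idealized backbone construction (NeRF) ---------------------------------

# place a new atom D given A, B, C and internal coordinates of D w.r.t. them
.placeAtom <- function(a, b, c, bond, angleDeg, torsionDeg) {
  ang <- angleDeg * pi / 180
  tor <- torsionDeg * pi / 180
  d2 <- c(bond * cos(pi - ang),
          bond * sin(pi - ang) * cos(tor),
          bond * sin(pi - ang) * sin(tor))
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  nxbc <- c(n[2] * bc[3] - n[3] * bc[2],
            n[3] * bc[1] - n[1] * bc[3],
            n[1] * bc[2] - n[2] * bc[1])
  rot <- cbind(bc, nxbc, n)
  c + as.vector(rot %*% d2)
}

# idealized bond lengths (A) and angles (deg) of the peptide backbone
.idealGeometry <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231,
  a_NCAC = 111.2, a_CACN = 116.2, a_CNCA = 121.7, a_CACO = 120.5)

#' Build an idealized backbone from phi/psi dihedrals
#'
#' Constructs N, CA, C, O coordinates for one conformer from backbone
#' dihedrals using fixed bond lengths and angles and a planar trans peptide
#' bond (omega = 180 degrees).  phi of residue 1 is immaterial.
#'
#' @param phi,psi dihedral vectors in degrees, one value per residue.
#' @return numeric (4 * nres) x 3 coordinate matrix in atom order
#'   N, CA, C, O per residue.
#' @export
buildBackboneXyz <- function(phi, psi) {
  stopifnot(length(phi) == length(psi), length(phi) >= 2L)
  g <- .idealGeometry
  nres <- length(phi)
  co <- matrix(NA_real_, 4L * nres, 3L)
  rowOf <- function(res, atom) (res - 1L) * 4L + match(atom, c("N", "CA", "C", "O"))
  # residue 1: N at origin, CA on x, C in the xy-plane
  co[rowOf(1, "N"), ] <- c(0, 0, 0)
  co[rowOf(1, "CA"), ] <- c(g$b_NCA, 0, 0)
  ang <- g$a_NCAC * pi / 180
  co[rowOf(1, "C"), ] <- co[rowOf(1, "CA"), ] +
    g$b_CAC * c(cos(pi - ang), sin(pi - ang), 0)
  for (r in seq_len(nres)) {
    if (r > 1L) {
      co[rowOf(r, "N"), ] <- .placeAtom(
        co[rowOf(r - 1L, "N"), ], co[rowOf(r - 1L, "CA"), ], co[rowOf(r - 1L, "C"), ],
        g$b_CN, g$a_CACN, psi[r - 1L])
      co[rowOf(r, "CA"), ] <- .placeAtom(
        co[rowOf(r - 1L, "CA"), ], co[rowOf(r - 1L, "C"), ], co[rowOf(r, "N"), ],
        g$b_NCA, g$a_CNCA, 180)  # trans peptide bond
      co[rowOf(r, "C"), ] <- .placeAtom(
        co[rowOf(r - 1L, "C"), ], co[rowOf(r, "N"), ], co[rowOf(r, "CA"), ],
        g$b_CAC, g$a_NCAC, phi[r])
    }
    # carbonyl oxygen from psi (anti-periplanar to the next N)
    nxt <- if (r < nres) psi[r] + 180 else 0
    co[rowOf(r, "O"), ] <- .placeAtom(
      co[rowOf(r, "N"), ], co[rowOf(r, "CA"), ], co[rowOf(r, "C"), ],
      g$b_CO, g$a_CACO, nxt)
  }
  co
}
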