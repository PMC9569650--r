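#' Read / write multi-model PDB ensembles
#'
#' Ensembles travel as multi-model PDB (MODEL/ENDMDL records, 1-based
#' residue numbering preserved).  Reading goes through bio3d and accepts
#' the 4-character non-standard residue names (DGLU, HCIT) without alias
#' loss; writing emits fixed-width records that round-trip coordinates to
#' the 3-decimal PDB precision.
#'
#' @param path PDB file path.
#' @param peptideId identifier for the ensemble (default: file name).
#' @param cyclicHead whether residues 1-5 form the cyclic head.
#' @return [readPdbEnsemble()] returns a [ConformerEnsemble-class].
#' @export
readPdbEnsemble <- function(path, peptideId = NULL, cyclicHead = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  if (anyNA(at$resno))
    stop("malformed PDB: residue numbers could not be parsed in ", path)
  atoms <- data.frame(residue_index = at$resno,
                      residue_name = toupper(at$resid),
                      atom_name = toupper(at$elety))
  xyz <- unclass(pdb$xyz)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("malformed PDB: inconsistent atom count across MODEL records in ", path)
  ConformerEnsemble(peptideId %||% sub("\\.pdb$", "", basename(path)),
                    atoms, xyz, cyclicHead = cyclicHead)
}

#' @rdname readPdbEnsemble
#' @param ensemble a [ConformerEnsemble-class].
#' @export
writePdbEnsemble <- function(ensemble, path) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  a <- ensemble@atoms
  lines <- character(0)
  pad <- function(n) if (nchar(n) < 4L) sprintf(" %-3s", n) else n
  for (m in seq_len(nModels(ensemble))) {
    co <- .modelCoords(ensemble, m)
    lines <- c(lines, sprintf("MODEL     %4d", m),
      sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
              seq_len(nrow(a)), vapply(a$atom_name, pad, ""),
              a$residue_name, "A", a$residue_index,
              co[, 1], co[, 2], co[, 3], 1, 0),
      "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read auxiliary per-residue CSV inputs
#'
#' J-coupling dialect: \code{residue_index,j_obs_hz,j_err_hz}.
#' R2 dialect: \code{residue_index,r2_hz}.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readJCoupling <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("residue_index", "j_obs_hz") %in% names(d)))
    stop("J-coupling CSV must have header residue_index,j_obs_hz[,j_err_hz]")
  d
}

#' @rdname readJCoupling
#' @export
readR2 <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("residue_index", "r2_hz") %in% names(d)))
    stop("R2 CSV must have header residue_index,r2_hz")
  d
}
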