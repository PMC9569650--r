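#' Construct a ShiftTable
#'
#' @param peptideId identifier string for the peptide.
#' @param shifts data.frame with columns \code{residue_index},
#'   \code{residue_name}, \code{atom_name}, \code{shift_ppm}.
#' @return a validated [ShiftTable-class] object.
#' @examples
#' st <- ShiftTable("toy", data.frame(
#'   residue_index = 1L, residue_name = "ALA",
#'   atom_name = "CA", shift_ppm = 52.5))
#' shifts(st)
#' @export
ShiftTable <- function(peptideId, shifts) {
  shifts <- as.data.frame(shifts)
  shifts$residue_index <- as.integer(shifts$residue_index)
  shifts$residue_name <- toupper(as.character(shifts$residue_name))
  shifts$atom_name <- toupper(as.character(shifts$atom_name))
  shifts <- shifts[order(shifts$residue_index, shifts$atom_name), , drop = FALSE]
  rownames(shifts) <- NULL
  new("ShiftTable", peptideId = as.character(peptideId), shifts = shifts)
}

#' @rdname ShiftTable-class
#' @export
setMethod("peptideId", "ShiftTable", function(object) object@peptideId)

#' @rdname ShiftTable-class
#' @export
setMethod("shifts", "ShiftTable", function(object) object@shifts)

setMethod("show", "ShiftTable", function(object) {
  s <- object@shifts
  cat("ShiftTable for peptide", sQuote(object@peptideId), "\n")
  cat(" ", nrow(s), "assigned cells over",
      length(unique(s$residue_index)), "residues;",
      "nuclei:", paste(sort(unique(s$atom_name)), collapse = " "), "\n")
})

#' Read / write chemical-shift tables
#'
#' CSV dialect with header
#' \code{peptide_id,residue_index,residue_name,atom_name,shift_ppm}.
#' Missing assignments are absent rows; a duplicated (residue, atom) cell is
#' rejected with the offending line numbers.
#'
#' @param path file path.
#' @return [readShiftTable()] returns a [ShiftTable-class];
#'   [writeShiftTable()] returns \code{path} invisibly.
#' @export
readShiftTable <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("peptide_id", "residue_index", "residue_name", "atom_name", "shift_ppm")
  if (!all(req %in% names(d)))
    stop("shift CSV must have header: ", paste(req, collapse = ","))
  key <- paste(d$residue_index, toupper(d$atom_name))
  if (anyDuplicated(key)) {
    dupkey <- unique(key[duplicated(key)])
    lines <- which(key %in% dupkey) + 1L  # +1 for the header line
    stop("duplicated (residue_index, atom_name) cells in ", path,
         " at lines ", paste(lines, collapse = ", "))
  }
  pid <- unique(d$peptide_id)
  if (length(pid) != 1L)
    stop("shift CSV must describe exactly one peptide, found: ",
         paste(pid, collapse = ", "))
  ShiftTable(pid, d[c("residue_index", "residue_name", "atom_name", "shift_ppm")])
}

#' @rdname readShiftTable
#' @param x a [ShiftTable-class] object.
#' @export
writeShiftTable <- function(x, path) {
  stopifnot(is(x, "ShiftTable"))
  d <- cbind(peptide_id = x@peptideId, x@shifts)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
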