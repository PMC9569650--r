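#' Random-coil (statistical coil) reference shifts
#'
#' Loads a versioned residue-type reference table of random-coil chemical
#' shifts (H, HA, N, CA, CB for the 20 standard residues, plus the proline
#' CG needed for cis/trans analysis).  The packaged default
#' (\code{"wishart1995"}) holds statistical-coil values compiled from the
#' standard literature tables; it can be swapped for any CSV with the same
#' layout.  Non-standard residues are handled through an explicit alias map
#' (by default the D-glutamate of the cyclic RGD head is referenced as
#' glutamate and homocitrulline as lysine); an unmapped residue type fails
#' loudly rather than silently falling back.
#'
#' @param id identifier of a packaged table, or ignored when \code{path}
#'   is given.
#' @param path optional CSV with columns \code{residue_name},
#'   \code{atom_name}, \code{shift_ppm} replacing the packaged table.
#' @param aliases named character vector mapping non-standard 3-letter codes
#'   to standard ones.
#' @param temperatureK,pH metadata describing the reference conditions.
#' @return a [RandomCoilModel-class].
#' @examples
#' rc <- randomCoilModel()
#' randomCoilShift(rc, "DGLU", "CA")  # referenced via the GLU alias
#' @export
randomCoilModel <- function(id = "wishart1995", path = NULL,
                            aliases = c(DGLU = "GLU", HCIT = "LYS"),
                            temperatureK = 298, pH = 5.0) {
  if (is.null(path)) path <- .extdata(paste0("random_coil_", id, ".csv"))
  t <- read.csv(path, stringsAsFactors = FALSE)
  t$residue_name <- toupper(t$residue_name)
  t$atom_name <- toupper(t$atom_name)
  al <- if (length(aliases)) setNames(toupper(aliases), toupper(names(aliases)))
        else character(0)
  new("RandomCoilModel", id = id, table = t, aliases = al,
      temperatureK = temperatureK, pH = pH)
}

# resolve a residue name through the alias map; error when unknown
.resolveResidue <- function(rc, residueName) {
  rn <- toupper(residueName)
  mapped <- ifelse(rn %in% names(rc@aliases), rc@aliases[rn], rn)
  known <- unique(rc@table$residue_name)
  bad <- setdiff(unique(mapped), known)
  if (length(bad))
    stop("residue type(s) with no random-coil reference and no alias: ",
         paste(bad, collapse = ", "))
  unname(mapped)
}

#' @rdname randomCoilModel
#' @param rc a [RandomCoilModel-class].
#' @param residueName 3-letter residue code(s); aliases are applied.
#' @param atomName nucleus label(s).
#' @return [randomCoilShift()] returns the reference shift(s) in ppm
#'   (NA where the table has no entry for that nucleus).
#' @export
randomCoilShift <- function(rc, residueName, atomName) {
  stopifnot(is(rc, "RandomCoilModel"))
  mapped <- .resolveResidue(rc, residueName)
  key <- paste(mapped, toupper(atomName))
  ref <- setNames(rc@table$shift_ppm, paste(rc@table$residue_name, rc@table$atom_name))
  unname(ref[key])
}

setMethod("show", "RandomCoilModel", function(object) {
  cat("RandomCoilModel", sQuote(object@id), "-",
      length(unique(object@table$residue_name)), "residue types,",
      nrow(object@table), "reference shifts\n")
  if (length(object@aliases))
    cat("  aliases:", paste(names(object@aliases), "->", object@aliases,
                            collapse = ", "), "\n")
})
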