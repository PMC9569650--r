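#' Score every conformer of an ensemble against observed shifts
#'
#' Back-calculates a shift table per model and evaluates its
#' [globalCsRmsd()] against the observations.  A predictor failure on a
#' conformer excludes that conformer with a logged warning, never a silent
#' score.  The ranking is a total order: non-decreasing global CS-RMSD with
#' ties broken by ascending conformer id.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param obs observed [ShiftTable-class].
#' @param predictor a predictor accepted by [predictShifts()].
#' @return data.frame with \code{conformer}, one RMSD column per nucleus
#'   class, and \code{global_cs_rmsd}, sorted by score; the predicted
#'   tables are attached as attribute \code{"predicted"} (indexed by
#'   conformer id).
#' @export
scoreConformers <- function(ensemble, obs, predictor = toyShiftPredictor()) {
  stopifnot(is(ensemble, "ConformerEnsemble"), is(obs, "ShiftTable"))
  M <- nModels(ensemble)
  preds <- .predictAll(predictor, ensemble)
  rows <- vector("list", M)
  for (m in seq_len(M)) {
    tab <- preds[[m]]
    if (inherits(tab, "error")) {
      preds[m] <- list(NULL)
      warning("conformer ", m, " excluded: predictor failed (",
              conditionMessage(tab), ")")
      next
    }
    sc <- globalCsRmsd(obs, tab)
    cls <- setNames(rep(NA_real_, length(.csClasses)), .csClasses)
    cls[names(sc$perClass)] <- sc$perClass
    rows[[m]] <- data.frame(conformer = m, t(cls), global_cs_rmsd = sc$global)
  }
  rank <- do.call(rbind, rows)
  if (is.null(rank)) stop("no conformer could be scored")
  rank <- rank[order(rank$global_cs_rmsd, rank$conformer), , drop = FALSE]
  rownames(rank) <- NULL
  attr(rank, "predicted") <- preds
  rank
}

#' Select a representative sub-ensemble by global CS-RMSD
#'
#' Ranks all conformers by [globalCsRmsd()] against the observed shifts and
#' selects N of them: the N best scores (\code{"lowest"}, the selection
#' protocol proper), the N worst (\code{"highest"}, negative control), or a
#' seeded uniform sample (\code{"random"}, baseline control).  The
#' ensemble-level score is the global CS-RMSD of the population-averaged
#' predicted table of the selected conformers (fast-exchange average); the
#' mean of the selected conformers' individual scores is also reported for
#' transparency.
#'
#' @param ensemble a [ConformerEnsemble-class] of candidate conformers
#'   (e.g. cluster representatives).
#' @param obs observed [ShiftTable-class].
#' @param n number of conformers to select (if it exceeds the number of
#'   candidates, all are selected with a warning).
#' @param mode \code{"lowest"}, \code{"highest"} or \code{"random"}.
#' @param seed RNG seed used by random mode.
#' @param predictor a predictor accepted by [predictShifts()].
#' @param ranking optional precomputed result of [scoreConformers()] to
#'   avoid re-prediction when selecting repeatedly from one ensemble.
#' @return a [SelectionResult-class].
#' @export
selectEnsemble <- function(ensemble, obs, n = 50L,
                           mode = c("lowest", "highest", "random"),
                           seed = 1L, predictor = toyShiftPredictor(),
                           ranking = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 1L)
  if (is.null(ranking))
    ranking <- scoreConformers(ensemble, obs, predictor)
  preds <- attr(ranking, "predicted")
  if (is.null(preds))  # ranking supplied without its prediction cache
    preds <- .predictAll(predictor, ensemble)
  M <- nrow(ranking)
  if (n > M) {
    warning("requested ", n, " conformers but only ", M,
            " candidates; selecting all")
    n <- M
  }
  selected <- switch(mode,
    lowest = ranking$conformer[seq_len(n)],
    highest = ranking$conformer[seq.int(M, M - n + 1L)],
    random = { set.seed(seed); sort(sample(ranking$conformer, n)) })
  ensTab <- meanShiftTable(preds[selected])
  ensScore <- globalCsRmsd(obs, ensTab)
  selScores <- ranking$global_cs_rmsd[match(selected, ranking$conformer)]
  new("SelectionResult", peptideId = peptideId(ensemble),
      ranking = as.data.frame(ranking), selected = as.integer(selected),
      mode = mode, n = as.integer(n),
      seed = if (mode == "random") as.numeric(seed) else NA_real_,
      ensembleScore = ensScore$global, ensemblePerClass = ensScore$perClass,
      meanConformerScore = mean(selScores))
}

#' @rdname selectEnsemble
#' @param x a [SelectionResult-class].
#' @export
selectedConformers <- function(x) { stopifnot(is(x, "SelectionResult")); x@selected }

#' @rdname selectEnsemble
#' @export
selectionRanking <- function(x) { stopifnot(is(x, "SelectionResult")); x@ranking }

#' @rdname selectEnsemble
#' @export
ensembleScore <- function(x) { stopifnot(is(x, "SelectionResult")); x@ensembleScore }

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult (", object@mode, " mode): ", length(object@selected),
      " of ", nrow(object@ranking), " conformers of ",
      sQuote(object@peptideId), "\n", sep = "")
  cat(sprintf("  ensemble global CS-RMSD %.4f ppm (mean of selected conformer scores %.4f ppm)\n",
              object@ensembleScore, object@meanConformerScore))
})
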