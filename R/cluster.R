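#' Pairwise superposition RMSD matrix of an ensemble
#'
#' Optimal-superposition (Kabsch) RMSD for every model pair.  By default
#' models are both fitted and measured on the selected atoms; when
#' \code{alignRange} is given, the superposition uses only the CA atoms of
#' those residues and the RMSD is then measured over \code{atomSelection}
#' without refitting.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param atomSelection atom names entering the RMSD (default \code{"CA"}).
#' @param alignRange optional residue indices used for the superposition.
#' @return symmetric M x M matrix in Angstrom with zero diagonal.
#' @export
pairwiseRmsd <- function(ensemble, atomSelection = "CA", alignRange = NULL) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  a <- ensemble@atoms
  sel <- a$atom_name %in% atomSelection
  if (!any(sel)) stop("atom selection is empty")
  selXyz <- .xyzIndex(sel)
  M <- nModels(ensemble)
  d <- matrix(0, M, M)
  rmsOf <- function(a, b) sqrt(mean(colSums(matrix((a - b)^2, nrow = 3))))
  if (is.null(alignRange)) {
    fitXyz <- selXyz
  } else {
    fitSel <- a$atom_name == "CA" & a$residue_index %in% alignRange
    if (!any(fitSel)) stop("alignment range selects no CA atoms")
    fitXyz <- .xyzIndex(fitSel)
  }
  for (i in seq_len(M - 1L)) {
    fitted <- bio3d::fit.xyz(ensemble@xyz[i, ],
                             ensemble@xyz[(i + 1L):M, , drop = FALSE],
                             fixed.inds = fitXyz, mobile.inds = fitXyz)
    for (j in (i + 1L):M)
      d[i, j] <- d[j, i] <- rmsOf(ensemble@xyz[i, selXyz],
                                  fitted[j - i, selXyz])
  }
  d
}

#' Kelley-penalty hierarchical clustering
#'
#' Builds an average-linkage hierarchical tree over a pairwise distance
#' matrix and selects the cut level by the Kelley penalty: at every level
#' the average spread (mean pairwise distance within clusters of two or more
#' members) is normalized across levels to the range [1, M-1] and added to
#' the number of clusters; the level minimizing this sum balances cluster
#' tightness against cluster count.  Each cluster is represented by its
#' medoid (the member minimizing total distance to the rest of the cluster).
#'
#' @param d symmetric distance matrix (e.g. from [pairwiseRmsd()]).
#' @param linkage agglomeration method for \code{hclust} (default
#'   \code{"average"}).
#' @return a [ClusterResult-class].
#' @export
kelleyCluster <- function(d, linkage = "average") {
  d <- as.matrix(d)
  M <- nrow(d)
  if (M < 3L) {
    warning("fewer than 3 models: returning a single trivial cluster")
    labels <- rep(1L, M)
    return(new("ClusterResult", labels = labels,
               medoids = setNames(.medoids(d, labels), "1"),
               levels = data.frame(n_clusters = 1L, avg_spread = NA_real_,
                                   norm_spread = NA_real_, penalty = NA_real_),
               chosenK = 1L, linkage = linkage, tree = NULL))
  }
  tree <- hclust(as.dist(d), method = linkage)
  ks <- seq_len(M - 1L)  # candidate levels: 1 .. M-1 clusters
  avg <- vapply(ks, function(k) .averageSpread(d, cutree(tree, k = k)), 0)
  rng <- range(avg, na.rm = TRUE)
  norm <- if (diff(rng) == 0) rep(1, length(avg))
          else (M - 2) * (avg - rng[1]) / diff(rng) + 1
  penalty <- norm + ks
  chosenK <- ks[which.min(penalty)]  # ties resolve to the smaller k
  labels <- cutree(tree, k = chosenK)
  med <- .medoids(d, labels)
  new("ClusterResult", labels = as.integer(labels),
      medoids = setNames(med, as.character(seq_along(med))),
      levels = data.frame(n_clusters = ks, avg_spread = avg,
                          norm_spread = norm, penalty = penalty),
      chosenK = as.integer(chosenK), linkage = linkage, tree = tree)
}

# mean within-cluster pairwise distance, averaged over multi-member clusters
.averageSpread <- function(d, labels) {
  sp <- vapply(unique(labels), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) return(NA_real_)
    mean(d[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))])
  }, 0)
  if (all(is.na(sp))) 0 else mean(sp, na.rm = TRUE)
}

.medoids <- function(d, labels) {
  vapply(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    idx[which.min(rowSums(d[idx, idx, drop = FALSE]))]
  }, 0L)
}

#' @rdname kelleyCluster
#' @param x a [ClusterResult-class].
#' @export
clusterLabels <- function(x) { stopifnot(is(x, "ClusterResult")); x@labels }

#' @rdname kelleyCluster
#' @export
clusterMedoids <- function(x) { stopifnot(is(x, "ClusterResult")); x@medoids }

#' @rdname kelleyCluster
#' @export
clusterLevels <- function(x) { stopifnot(is(x, "ClusterResult")); x@levels }

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", object@chosenK, "clusters over",
      length(object@labels), "models (", object@linkage, "linkage,",
      "Kelley penalty minimum )\n")
  print(table(cluster = object@labels))
})
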