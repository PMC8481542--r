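#' Select the best-scoring decoys of an ensemble
#'
#' Returns the `topN` lowest-score decoys in stable order by
#' (score, id); lower scores are better. Mirrors the usual pre-filter of
#' an ab initio run, where only the few thousand best-scored decoys of a
#' much larger set are analysed further.
#'
#' @param ensemble a [DecoyEnsemble-class].
#' @param topN number of decoys to keep (>= 1). When larger than the
#'   ensemble the whole ensemble is returned with a message.
#' @return a [DecoyEnsemble-class] subset.
#' @export
rankByScore <- function(ensemble, topN) {
  .stopIfNot(topN >= 1, "'topN' must be >= 1")
  n <- length(ensemble)
  if (topN > n) {
    message("topN (", topN, ") exceeds ensemble size (", n,
            "); returning the full ensemble")
    topN <- n
  }
  ord <- order(ensemble@scores, ensemble@ids)
  ensemble[ord[seq_len(topN)]]
}

#' Filter decoys on cross-link restraint satisfaction
#'
#' Keeps, in input order, every decoy that satisfies at least
#' `minSatisfied` of the resolvable cross-link restraints.
#'
#' @param ensemble a [DecoyEnsemble-class].
#' @param links cross-link table (see [parseCrossLinks()]).
#' @param linkers linker dictionary.
#' @param params [restraintParams()].
#' @param minSatisfied minimum satisfied-link count; `NULL` (default)
#'   requires every link resolvable on the first decoy.
#' @return filtered [DecoyEnsemble-class] (possibly empty, with a message).
#' @export
filterByRestraints <- function(ensemble, links, linkers = defaultLinkers(),
                               params = restraintParams(),
                               minSatisfied = NULL) {
  if (length(ensemble) == 0L || nrow(links) == 0L) return(ensemble)
  if (is.null(minSatisfied)) {
    ev1 <- evaluateSet(ensemble@decoys[[1]], links, linkers, params)
    minSatisfied <- nrow(ev1$table)
  }
  nSat <- vapply(ensemble@decoys, function(s)
    evaluateSet(s, links, linkers, params)$nSatisfied, numeric(1))
  keep <- nSat >= minSatisfied
  if (!any(keep))
    message("no decoy satisfies >= ", minSatisfied, " restraints")
  ensemble[which(keep)]
}

#' Pairwise-nearest-neighbour clustering with a distance ceiling
#'
#' Agglomerative clustering of decoys on an all-versus-all RMSD matrix:
#' the globally nearest pair of clusters (complete-linkage distance,
#' i.e. the maximum cross-pair RMSD) is merged repeatedly while that
#' distance does not exceed the threshold, so every intra-cluster
#' pairwise RMSD is guaranteed to stay within the threshold. Ties are
#' broken deterministically towards the pair containing the smallest
#' decoy index. Clusters are numbered by decreasing size (ties by
#' smallest member index).
#'
#' @param mat symmetric pairwise RMSD matrix (see [pairwiseRmsd()]).
#' @param threshold distance ceiling, Angstrom (> 0).
#' @return a [ClusterAssignment-class] with per-cluster sizes and
#'   spreads (maximum intra-cluster pairwise RMSD).
#' @export
pnnCluster <- function(mat, threshold) {
  mat <- as.matrix(mat)
  .stopIfNot(threshold > 0, "'threshold' must be > 0")
  n <- nrow(mat)
  .stopIfNot(n == ncol(mat) && max(abs(mat - t(mat))) <= 1e-9,
             "'mat' must be a symmetric square matrix")
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  members <- as.list(seq_len(n))     # cluster -> decoy indices
  D <- mat                           # complete-linkage cluster distances
  diag(D) <- Inf
  alive <- rep(TRUE, n)
  while (sum(alive) > 1L) {
    Dv <- D
    Dv[!alive, ] <- Inf; Dv[, !alive] <- Inf
    dmin <- min(Dv)
    if (dmin > threshold) break
    # candidate merges at the minimum distance; tie-break on smallest index
    idx <- which(Dv == dmin, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(idx)), function(k)
      min(c(members[[idx[k, 1]]], members[[idx[k, 2]]])), numeric(1))
    pick <- idx[order(key, idx[, 1], idx[, 2])[1], ]
    i <- pick[1]; j <- pick[2]
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    alive[j] <- FALSE
    D[i, ] <- D[, i] <- pmax(D[i, ], D[j, ])
    diag(D) <- Inf
  }
  members <- members[alive]
  sizes <- vapply(members, length, integer(1))
  firsts <- vapply(members, min, numeric(1))
  ord <- order(-sizes, firsts)
  members <- members[ord]
  labels <- integer(n)
  for (k in seq_along(members)) labels[members[[k]]] <- k
  spread <- vapply(members, function(m)
    if (length(m) < 2L) 0 else max(mat[m, m]), numeric(1))
  new("ClusterAssignment", threshold = threshold, ids = ids,
      labels = labels, sizes = sizes[ord], spread = spread)
}

#' Select the final model from a scored, restrained decoy ensemble
#'
#' The full decoy-selection protocol: rank by score, keep the `topN`
#' best, drop decoys failing the cross-link restraints, cluster the
#' survivors by pairwise CA RMSD with [pnnCluster()], take the cluster
#' with the most members — the cluster comprising the largest number of
#' best-scoring decoys; size ties go to the cluster containing the
#' single best-scoring decoy — and return its lowest-score member. The
#' audit trail records the decoy count entering and leaving each stage.
#'
#' @param ensemble a [DecoyEnsemble-class] (non-empty).
#' @param links cross-link table; an empty table skips restraint
#'   filtering.
#' @param linkers linker dictionary.
#' @param params [restraintParams()].
#' @param topN score pre-filter size.
#' @param threshold clustering ceiling, Angstrom.
#' @param minSatisfied passed to [filterByRestraints()].
#' @param elety RMSD atom selection (default CA).
#' @param superposed superpose before RMSD (default TRUE).
#' @return a [SelectionResult-class].
#' @export
selectFinalModel <- function(ensemble, links, linkers = defaultLinkers(),
                             params = restraintParams(), topN = 5000,
                             threshold = 0.55, minSatisfied = NULL,
                             elety = "CA", superposed = TRUE) {
  .stopIfNot(length(ensemble) >= 1L, "'ensemble' must be non-empty")
  audit <- data.frame(stage = character(0), n_in = integer(0),
                      n_out = integer(0), stringsAsFactors = FALSE)
  note <- function(stage, nin, nout)
    rbind(audit, data.frame(stage = stage, n_in = nin, n_out = nout))

  ranked <- suppressMessages(rankByScore(ensemble, topN))
  audit <- note("rank_by_score", length(ensemble), length(ranked))

  filtered <- filterByRestraints(ranked, links, linkers, params, minSatisfied)
  audit <- note("filter_by_restraints", length(ranked), length(filtered))
  if (length(filtered) == 0L)
    stop("empty selection: every decoy was removed by restraint filtering")

  m <- pairwiseRmsd(filtered, elety = elety, superposed = superposed)
  cl <- pnnCluster(m, threshold)
  audit <- note("pnn_cluster", length(filtered), length(filtered))

  top <- which(cl@sizes == max(cl@sizes))
  winner <- if (length(top) == 1L) top else {
    # tie: the cluster holding the single best-scoring decoy
    ordScore <- order(filtered@scores, filtered@ids)
    lab <- cl@labels[ordScore]
    lab[lab %in% top][1]
  }
  memb <- which(cl@labels == winner)
  pickOrd <- order(filtered@scores[memb], filtered@ids[memb])
  finalId <- filtered@ids[memb[pickOrd[1]]]
  audit <- note("select_cluster", length(filtered), length(memb))
  audit <- note("select_final", length(memb), 1L)

  new("SelectionResult", finalId = finalId, clusterId = as.integer(winner),
      clusters = cl, audit = audit)
}

#' Pose-convergence counts against the best-scoring decoy
#'
#' For docking-style convergence analysis: the RMSD of each decoy to the
#' best-scoring (target) decoy is computed without superposition, and
#' for each cutoff the number of decoys closer than that cutoff is
#' reported. Counts are non-decreasing in the cutoff.
#'
#' @param ensemble a [DecoyEnsemble-class] (e.g. the top-k by score).
#' @param cutoffs numeric vector of RMSD cutoffs, Angstrom (non-empty).
#' @param targetId decoy to measure against; default the lowest-score
#'   decoy (ties by id).
#' @param elety atom selection (default CA).
#' @return named integer vector of counts, one per cutoff; the RMSD
#'   vector is attached as attribute `"rmsd"`.
#' @export
convergenceCounts <- function(ensemble, cutoffs, targetId = NULL,
                              elety = "CA") {
  .stopIfNot(length(cutoffs) >= 1L, "'cutoffs' must be non-empty")
  if (is.null(targetId))
    targetId <- ensemble@ids[order(ensemble@scores, ensemble@ids)[1]]
  .stopIfNot(targetId %in% ensemble@ids,
             "target '", targetId, "' not in ensemble")
  tgt <- atomCoords(getDecoy(ensemble, targetId), elety = elety)
  r <- vapply(ensemble@decoys, function(s)
    rmsdNoSuperposition(atomCoords(s, elety = elety), tgt), numeric(1))
  counts <- vapply(cutoffs, function(ct) sum(r < ct), integer(1))
  names(counts) <- as.character(cutoffs)
  attr(counts, "rmsd") <- stats::setNames(r, ensemble@ids)
  counts
}
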