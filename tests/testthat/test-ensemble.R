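makeScoredEnsemble <- function(scores, ids = NULL) {
  n <- length(scores)
  if (is.null(ids)) ids <- sprintf("d%02d", seq_len(n))
  decoys <- lapply(seq_len(n), function(i)
    randomStructure(5, seed = i, id = ids[i]))
  DecoyEnsemble(decoys, scores, ids)
}

test_that("rank by score keeps the lowest scores with stable ties", {
  e <- makeScoredEnsemble(c(3, 1, 2))
  top <- rankByScore(e, 2)
  expect_equal(sort(decoyScores(top)), sort(c(d02 = 1, d03 = 2)))
  # ties broken by id, lexicographically
  et <- makeScoredEnsemble(c(1, 1, 5), ids = c("zz", "aa", "mm"))
  expect_equal(decoyIds(rankByScore(et, 1)), "aa")
  # topN above ensemble size returns everything (sorted), with a message
  expect_message(full <- rankByScore(e, 10), "exceeds")
  expect_equal(length(full), 3L)
  expect_equal(decoyScores(full), c(d02 = 1, d03 = 2, d01 = 3))
})

test_that("restraint filtering matches per-decoy brute-force counts", {
  tr <- makeTruth(2, 15, c("helix", "coil"), seed = 4)
  links <- simulateCrossLinks(tr, "DSS", nTrue = 5, falseRate = 0.4, seed = 4)
  e <- perturbEnsemble(tr, nDecoys = 25, fractionNear = 0.4, seed = 4)
  # identity filter
  expect_equal(length(filterByRestraints(e, links, minSatisfied = 0)),
               length(e))
  kept <- filterByRestraints(e, links, minSatisfied = 5)
  ref <- decoyIds(e)[vapply(decoyIds(e), function(id)
    evaluateSet(getDecoy(e, id), links)$nSatisfied >= 5, logical(1))]
  expect_identical(decoyIds(kept), ref)
})

test_that("PNN clustering handles degenerate and threshold-edge cases", {
  # three identical decoys: one cluster, zero spread
  m0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  cl0 <- pnnCluster(m0, 0.5)
  expect_equal(nClusters(cl0), 1L)
  expect_equal(unname(clusterSpread(cl0)), 0)
  # all pairs beyond the ceiling: all singletons
  mFar <- matrix(5, 4, 4); diag(mFar) <- 0
  dimnames(mFar) <- list(letters[1:4], letters[1:4])
  clF <- pnnCluster(mFar, 1)
  expect_equal(nClusters(clF), 4L)
  expect_true(all(clusterSizes(clF) == 1))
  expect_error(pnnCluster(matrix(c(0, 1, 2, 0), 2), 1), "symmetric")
})

test_that("PNN equals complete-linkage hclust cut at the ceiling", {
  # complete linkage is monotone, so stopping the merge at the ceiling is
  # the same partition as cutting the full dendrogram at that height
  for (s in 1:25) {
    set.seed(s)
    n <- sample(4:8, 1)
    pts <- matrix(rnorm(2 * n), ncol = 2)
    m <- as.matrix(dist(pts))
    dimnames(m) <- list(as.character(1:n), as.character(1:n))
    thr <- runif(1, 0.3, 2.5)
    cl <- pnnCluster(m, thr)
    ref <- cutree(hclust(as.dist(m), method = "complete"), h = thr)
    # same partition up to label renaming
    expect_equal(length(unique(ref)), nClusters(cl), info = paste("seed", s))
    tab <- table(clusterLabels(cl), ref)
    expect_true(all(rowSums(tab > 0) == 1), info = paste("seed", s))
  }
})

test_that("every intra-cluster RMSD stays within the reported spread", {
  for (s in 1:10) {
    set.seed(s)
    n <- 8
    m <- as.matrix(dist(matrix(rnorm(3 * n), ncol = 3)))
    dimnames(m) <- list(as.character(1:n), as.character(1:n))
    cl <- pnnCluster(m, 1.5)
    lab <- clusterLabels(cl)
    for (k in seq_len(nClusters(cl))) {
      idx <- which(lab == k)
      if (length(idx) >= 2) {
        expect_lte(max(m[idx, idx]), clusterSpread(cl)[k] + 1e-12)
        expect_lte(clusterSpread(cl)[k], 1.5)
      }
    }
    expect_equal(sum(clusterSizes(cl)), n)
  }
})

test_that("cluster count is non-increasing in the threshold", {
  set.seed(11)
  m <- as.matrix(dist(matrix(rnorm(20), ncol = 2)))
  dimnames(m) <- list(as.character(1:10), as.character(1:10))
  ks <- vapply(c(0.1, 0.3, 0.6, 1, 2, 4, 8),
               function(h) nClusters(pnnCluster(m, h)), integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("final-model selection follows the documented pipeline", {
  tr <- makeTruth(2, 20, c("helix", "coil"), seed = 8)
  links <- simulateCrossLinks(tr, "DSS", nTrue = 6, falseRate = 0, seed = 8)
  e <- perturbEnsemble(tr, nDecoys = 40, fractionNear = 0.4, seed = 8)
  res <- selectFinalModel(e, links, topN = 20, threshold = 2,
                          minSatisfied = 6)
  audit <- selectionAudit(res)
  expect_equal(audit$stage[1], "rank_by_score")
  expect_true(all(diff(audit$n_out) <= 0))
  # the selected decoy is the lowest-score member of the winning cluster
  lab <- clusterLabels(res@clusters)
  memb <- names(lab)[lab == res@clusterId]
  sc <- decoyScores(e)[memb]
  expect_equal(selectedId(res), names(sc)[order(sc, names(sc))][1])
  # determinism: identical rerun
  res2 <- selectFinalModel(e, links, topN = 20, threshold = 2,
                           minSatisfied = 6)
  expect_identical(selectedId(res2), selectedId(res))
  expect_identical(selectionAudit(res2), selectionAudit(res))
  # single-decoy ensemble trivially selects itself
  one <- e[decoyIds(e)[1]]
  r1 <- selectFinalModel(one, links[0, ], topN = 1, threshold = 1)
  expect_equal(selectedId(r1), decoyIds(one))
  # empty selection errors
  expect_error(
    selectFinalModel(e, links, topN = 20, threshold = 2,
                     minSatisfied = nrow(links) + 5), "empty selection")
})

test_that("size ties go to the cluster holding the best-scoring decoy", {
  # construct two 2-decoy clusters far apart; best score sits in cluster B
  base <- buildIdealHelix(10)
  shift <- function(s, dx, id) {
    a <- atomTable(s); a$x <- a$x + dx
    XLStructure(id, a)
  }
  decoys <- list(shift(base, 0, "a1"), shift(base, 0.1, "a2"),
                 shift(base, 50, "b1"), shift(base, 50.1, "b2"))
  e <- DecoyEnsemble(decoys, scores = c(2, 3, 1, 4))
  res <- selectFinalModel(e, linkRow("A", 1, "A", 2)[0, ], topN = 4,
                          threshold = 2)
  expect_equal(selectedId(res), "b1")
})

test_that("convergence counts match direct recomputation and monotonicity", {
  tr <- makeTruth(1, 12, "helix", seed = 3)
  e <- perturbEnsemble(tr, nDecoys = 15, fractionNear = 0.5, seed = 3)
  cuts <- c(0.25, 1, 5, 50)
  counts <- convergenceCounts(e, cuts)
  expect_true(all(diff(counts) >= 0))
  # the target itself is counted at every cutoff
  expect_gte(counts[[1]], 1L)
  # direct recomputation
  target <- decoyIds(e)[order(decoyScores(e), decoyIds(e))[1]]
  tc <- atomCoords(getDecoy(e, target))
  r <- vapply(decoyIds(e), function(id)
    rmsdNoSuperposition(atomCoords(getDecoy(e, id)), tc), numeric(1))
  expect_equal(as.integer(counts), vapply(cuts, function(ct) sum(r < ct),
                                          integer(1)))
  # identical decoys count fully at any positive cutoff
  same <- DecoyEnsemble(rep(list(getDecoy(e, target)), 4), scores = 1:4,
                        ids = paste0("s", 1:4))
  expect_equal(as.integer(convergenceCounts(same, 0.1)), 4L)
  expect_error(convergenceCounts(e, numeric(0)), "non-empty")
})
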