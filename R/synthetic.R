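#' Generate a ground-truth multi-chain assembly
#'
#' Builds a synthetic CA/CB backbone assembly to serve as ground truth
#' for pipeline validation: each chain is either an ideal alpha helix or
#' a self-avoiding random coil (3.8 A CA steps), CB atoms sit 1.5 A from
#' their CA (glycines carry no CB), and chains are placed in mutual
#' contact without CA clashes below 4 A. The first residue of every
#' chain is a methionine so that N-terminal amine chemistry is
#' exercised; side-chain identities are sampled so lysines, aspartates
#' and glutamates (cross-linkable residues) are frequent. Fully
#' determined by `seed`.
#'
#' @param nChains number of chains (>= 1, chains named A, B, C, ...).
#' @param residuesPerChain residues per chain (recycled).
#' @param topology "helix" or "coil" per chain (recycled).
#' @param seed integer seed.
#' @param id structure id.
#' @return an [XLStructure-class].
#' @export
makeTruth <- function(nChains = 2, residuesPerChain = 30,
                      topology = c("helix", "coil"), seed = 1,
                      id = "truth") {
  .stopIfNot(nChains >= 1, "'nChains' must be >= 1")
  nres <- rep_len(residuesPerChain, nChains)
  topo <- rep_len(topology, nChains)
  chains <- LETTERS[seq_len(nChains)]
  aaPool <- c("LYS", "LYS", "ASP", "GLU", "ALA", "LEU", "SER", "GLY",
              "VAL", "THR")

  .withSeed(seed, {
    buildChain <- function(ch, n, top) {
      if (top == "helix") {
        ca <- atomCoords(buildIdealHelix(n), elety = "CA")
        # CB radially outward from the helix axis (z)
        dirs <- cbind(ca[, 1], ca[, 2], 0)
        nrm <- sqrt(rowSums(dirs^2)); nrm[nrm == 0] <- 1
        cb <- ca + 1.5 * dirs / nrm
      } else {
        ca <- matrix(0, n, 3)
        for (i in seq_len(n)[-1]) {
          for (try in seq_len(500)) {
            st <- stats::rnorm(3)
            cand <- ca[i - 1, ] + 3.8 * st / sqrt(sum(st^2))
            if (i == 2 || min(sqrt(rowSums(
                  sweep(ca[seq_len(i - 2), , drop = FALSE], 2, cand)^2))) >
                3.5) { ca[i, ] <- cand; break }
            if (try == 500) stop("self-avoiding walk failed")
          }
        }
        dirs <- matrix(stats::rnorm(3 * n), n, 3)
        cb <- ca + 1.5 * dirs / sqrt(rowSums(dirs^2))
      }
      resid <- c("MET", sample(aaPool, n - 1, replace = TRUE))
      hasCB <- resid != "GLY"
      data.frame(
        chain = ch,
        resno = c(seq_len(n), seq_len(n)[hasCB]),
        resid = c(resid, resid[hasCB]),
        elety = c(rep("CA", n), rep("CB", sum(hasCB))),
        x = c(ca[, 1], cb[hasCB, 1]),
        y = c(ca[, 2], cb[hasCB, 2]),
        z = c(ca[, 3], cb[hasCB, 3]),
        stringsAsFactors = FALSE)
    }
    orderChain <- function(df) df[order(df$resno, df$elety), ]

    placed <- orderChain(buildChain(chains[1], nres[1], topo[1]))
    if (nChains > 1) {
      for (k in 2:nChains) {
        raw <- buildChain(chains[k], nres[k], topo[k])
        ok <- FALSE
        for (try in seq_len(1000)) {
          R <- .randomRotation()
          xyz <- as.matrix(raw[, c("x", "y", "z")]) %*% t(R)
          target <- .centroid(as.matrix(placed[, c("x", "y", "z")])) +
            stats::rnorm(3, 0, 12)
          xyz2 <- sweep(xyz, 2, .centroid(xyz)) +
            matrix(target, nrow(xyz), 3, byrow = TRUE)
          nc <- xyz2[raw$elety == "CA", , drop = FALSE]
          # contact (but no clash) with EVERY placed chain, so that an
          # n-chain truth forms a mutually-touching junction
          dmin <- vapply(unique(placed$chain), function(ch) {
            pc <- as.matrix(placed[placed$elety == "CA" &
                                     placed$chain == ch, c("x", "y", "z")])
            d2 <- outer(rowSums(pc^2), rowSums(nc^2), "+") - 2 * pc %*% t(nc)
            sqrt(max(0, min(d2)))
          }, numeric(1))
          if (min(dmin) >= 4 && max(dmin) <= 8) {
            raw[, c("x", "y", "z")] <- xyz2
            placed <- rbind(placed, orderChain(raw))
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("failed to place chain ", chains[k],
                      " without clashes after bounded retries")
      }
    }
    XLStructure(id, placed)
  })
}

#' Simulate a noisy cross-link list from a ground-truth assembly
#'
#' Samples `nTrue` residue pairs uniformly from pairs that satisfy the
#' linker's restraints in the truth structure, plus
#' `ceiling(falseRate * nTrue)` false-positive links sampled from
#' violated pairs; row order is shuffled deterministically by the seed.
#' With `falseRate = 0` the returned list is satisfied in full by the
#' truth, by construction.
#'
#' @param truth an [XLStructure-class] (see [makeTruth()]).
#' @param linkerName linker to simulate (default "DSS").
#' @param nTrue number of true (satisfied-in-truth) links.
#' @param falseRate false-positive fraction relative to `nTrue`.
#' @param seed integer seed.
#' @param interChainOnly restrict to inter-chain pairs (default TRUE).
#' @param chainPairs optional list of length-2 chain-id vectors; when
#'   given, only residue pairs between those chain pairs are sampled
#'   (e.g. `list(c("A","C"), c("B","C"))` for links to chain C only).
#' @param linkers,params restraint dictionary and parameters used to
#'   decide satisfaction.
#' @param condition,approach tags copied into every row.
#' @return cross-link data.frame (see [parseCrossLinks()]) with a
#'   logical attribute `"isTrue"` marking the satisfied-in-truth rows.
#' @export
simulateCrossLinks <- function(truth, linkerName = "DSS", nTrue = 6,
                               falseRate = 0, seed = 1,
                               interChainOnly = TRUE, chainPairs = NULL,
                               linkers = defaultLinkers(),
                               params = restraintParams(),
                               condition = "both", approach = 1L) {
  spec <- linkers[match(linkerName, linkers$name), , drop = FALSE]
  .stopIfNot(!is.na(spec$name[1]), "unknown linker '", linkerName, "'")
  a <- truth@atoms
  res <- unique(a[a$elety == "CA", c("chain", "resno")])
  idx <- utils::combn(nrow(res), 2)
  pa <- res[idx[1, ], ]; pb <- res[idx[2, ], ]
  if (interChainOnly) {
    keep <- pa$chain != pb$chain
    pa <- pa[keep, , drop = FALSE]; pb <- pb[keep, , drop = FALSE]
  }
  if (!is.null(chainPairs)) {
    key <- paste(pmin(pa$chain, pb$chain), pmax(pa$chain, pb$chain))
    want <- vapply(chainPairs, function(p) paste(min(p), max(p)),
                   character(1))
    keep <- key %in% want
    pa <- pa[keep, , drop = FALSE]; pb <- pb[keep, , drop = FALSE]
  }
  cand <- data.frame(protein_a = pa$chain, res_a = pa$resno,
                     protein_b = pb$chain, res_b = pb$resno,
                     linker = linkerName, condition = condition,
                     approach = as.integer(approach),
                     stringsAsFactors = FALSE)
  sat <- vapply(seq_len(nrow(cand)), function(i)
    evaluateLink(truth, cand[i, ], spec, params)$satisfied, logical(1))
  nFalse <- as.integer(ceiling(falseRate * nTrue))
  if (sum(sat) < nTrue)
    stop("only ", sum(sat), " satisfiable pair(s) available (", nTrue,
         " requested)")
  if (sum(!sat) < nFalse)
    stop("only ", sum(!sat), " violated pair(s) available (", nFalse,
         " requested)")
  .withSeed(.childSeed(seed, 101L), {
    iT <- sample(which(sat), nTrue)
    iF <- if (nFalse > 0) sample(which(!sat), nFalse) else integer(0)
    out <- cand[c(iT, iF), , drop = FALSE]
    isTrue <- c(rep(TRUE, nTrue), rep(FALSE, nFalse))
    ord <- sample(nrow(out))
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "isTrue") <- isTrue[ord]
    out
  })
}

#' Generate a score-ranked perturbed decoy ensemble
#'
#' Emulates, at desk scale, the output of a large sampling run: a
#' fraction of decoys are near-truth (truth plus isotropic Gaussian
#' coordinate noise of `nearSd`), the remainder are far decoys
#' (coordinate noise `farSd` plus an independent random rigid kick per
#' chain: uniform SO(3) rotation and a translation of up to 20 A). Each
#' decoy's score is its superposed CA RMSD to the truth plus Gaussian
#' noise, so near-truth decoys are enriched among the low scores — the
#' minimal score model under which lowest-energy-cluster selection is
#' meaningful. Fully determined by `seed`.
#'
#' @param truth an [XLStructure-class].
#' @param nDecoys ensemble size (>= 2).
#' @param fractionNear fraction of near-truth decoys (default 0.3).
#' @param nearSd,farSd per-coordinate noise, Angstrom (defaults 0.5, 8).
#' @param scoreNoiseSd score noise s.d. (default 0.5).
#' @param seed integer seed.
#' @return a [DecoyEnsemble-class] with attributes `"isNear"` (logical
#'   per decoy) and `"rmsdToTruth"` (superposed CA RMSD per decoy).
#' @export
perturbEnsemble <- function(truth, nDecoys = 200, fractionNear = 0.3,
                            nearSd = 0.5, farSd = 8, scoreNoiseSd = 0.5,
                            seed = 1) {
  .stopIfNot(nDecoys >= 2, "'nDecoys' must be >= 2")
  nNear <- round(fractionNear * nDecoys)
  truthCA <- atomCoords(truth, elety = "CA")
  a0 <- truth@atoms
  .withSeed(.childSeed(seed, 202L), {
    isNear <- c(rep(TRUE, nNear), rep(FALSE, nDecoys - nNear))
    decoys <- vector("list", nDecoys)
    rmsdT <- numeric(nDecoys)
    width <- max(2L, nchar(as.character(nDecoys)))
    for (i in seq_len(nDecoys)) {
      a <- a0
      xyz <- as.matrix(a[, c("x", "y", "z")])
      if (isNear[i]) {
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, nearSd),
                            nrow(xyz), 3)
      } else {
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, farSd),
                            nrow(xyz), 3)
        for (ch in unique(a$chain)) {        # independent rigid kick per chain
          rows <- which(a$chain == ch)
          sub <- xyz[rows, , drop = FALSE]
          cen <- .centroid(sub)
          R <- .randomRotation()
          kick <- stats::runif(3, -20, 20)
          xyz[rows, ] <- sweep(sweep(sub, 2, cen) %*% t(R), 2, cen + kick, "+")
        }
      }
      a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
      idc <- sprintf(paste0("d%0", width, "d"), i)
      decoys[[i]] <- XLStructure(idc, a)
      rmsdT[i] <- kabschSuperpose(truthCA,
                                  atomCoords(decoys[[i]], "CA"))$rmsd
    }
    scores <- rmsdT + stats::rnorm(nDecoys, 0, scoreNoiseSd)
    ord <- sample(nDecoys)                    # shuffle generation order
    e <- DecoyEnsemble(decoys[ord], scores[ord])
    attr(e, "isNear") <- isNear[ord]
    attr(e, "rmsdToTruth") <- stats::setNames(rmsdT[ord], decoyIds(e))
    e
  })
}
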