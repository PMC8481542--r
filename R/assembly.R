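#' Apply a rigid-body pose to a structure
#'
#' Maps every coordinate x to `R x + t`; atom metadata is unchanged.
#'
#' @param mobile an [XLStructure-class].
#' @param pose a [PoseTransform-class] (validity enforces a proper,
#'   orthonormal rotation).
#' @return the posed [XLStructure-class].
#' @export
applyPose <- function(mobile, pose) {
  validObject(pose)
  a <- mobile@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(pose@rotation)
  a$x <- xyz[, 1] + pose@translation[1]
  a$y <- xyz[, 2] + pose@translation[2]
  a$z <- xyz[, 3] + pose@translation[3]
  XLStructure(mobile@id, a)
}

#' Merge structures with disjoint chains
#'
#' @param ... [XLStructure-class] objects with pairwise-disjoint chain ids.
#' @param id id of the merged structure.
#' @return an [XLStructure-class].
#' @export
mergeStructures <- function(..., id = "assembly") {
  parts <- list(...)
  chains <- unlist(lapply(parts, function(s) unique(s@atoms$chain)))
  .stopIfNot(!anyDuplicated(chains),
             "structures to merge must have disjoint chain ids")
  XLStructure(id, do.call(rbind, lapply(parts, atomTable)))
}

# Precompute per-pair geometry of inter-component links: which atom sits
# on the fixed vs the mobile side, local coordinates, thresholds, and the
# link each pair belongs to. Errors on links not spanning fixed<->mobile.
.interLinkGeometry <- function(fixed, mobile, links, linkers, params) {
  fc <- unique(fixed@atoms$chain); mc <- unique(mobile@atoms$chain)
  merged0 <- mergeStructures(fixed, mobile, id = ".geom")
  F <- list(); M <- list(); thr <- c(); li <- c(); mode <- c()
  for (i in seq_len(nrow(links))) {
    link <- links[i, , drop = FALSE]
    aFixed <- link$protein_a %in% fc; aMob <- link$protein_a %in% mc
    bFixed <- link$protein_b %in% fc; bMob <- link$protein_b %in% mc
    if (!((aFixed && bMob) || (aMob && bFixed)))
      stop("link ", i, " (", link$protein_a, ":", link$res_a, "-",
           link$protein_b, ":", link$res_b,
           ") does not span the fixed and mobile components")
    spec <- linkers[match(link$linker, linkers$name), , drop = FALSE]
    .stopIfNot(!is.na(spec$name[1]), "unknown linker '", link$linker, "'")
    pairs <- mapLinkAtoms(merged0, link, spec, params)
    pick <- function(prot, res, a) {
      s <- if (prot %in% fc) fixed else mobile
      r <- s@atoms[s@atoms$chain == prot & s@atoms$resno == res &
                     s@atoms$elety == a, c("x", "y", "z")]
      .stopIfNot(nrow(r) >= 1, "unresolved site ", prot, ":", res, ":", a)
      as.numeric(r[1, ])
    }
    for (k in seq_len(nrow(pairs))) {
      pa <- pick(link$protein_a, link$res_a, pairs$atom_a[k])
      pb <- pick(link$protein_b, link$res_b, pairs$atom_b[k])
      if (aFixed) { F[[length(F) + 1L]] <- pa; M[[length(M) + 1L]] <- pb }
      else        { F[[length(F) + 1L]] <- pb; M[[length(M) + 1L]] <- pa }
      thr <- c(thr, pairs$threshold[k]); li <- c(li, i)
    }
  }
  list(F = do.call(rbind, F), M = do.call(rbind, M), thr = thr,
       linkIndex = li, nLinks = nrow(links),
       fixedCA = atomCoords(fixed, "CA"), mobileCA = atomCoords(mobile, "CA"))
}

# Fast evaluation of one pose against precomputed geometry.
# Returns energy, per-link satisfaction count, clash count, and the sum
# of pair distances (the compactness tie-break currency).
.poseScore <- function(geom, R, t, params, clashCutoff) {
  P <- geom$M %*% t(R)
  P <- sweep(P, 2, t, "+")
  d <- sqrt(rowSums((geom$F - P)^2))
  pen <- sum(flatHarmonic(d, geom$thr, params$sd))
  within <- d <= geom$thr
  satByLink <- tapply(within, geom$linkIndex,
                      if (params$mode == "all") all else any)
  clash <- 0L
  minCross <- NA_real_
  if (clashCutoff > 0) {
    PC <- geom$mobileCA %*% t(R)
    PC <- sweep(PC, 2, t, "+")
    FC <- geom$fixedCA
    d2 <- outer(rowSums(FC^2), rowSums(PC^2), "+") - 2 * FC %*% t(PC)
    clash <- sum(d2 < clashCutoff^2)
    minCross <- sqrt(max(0, min(d2)))
  }
  list(energy = pen, nSatisfied = sum(satByLink), clash = as.integer(clash),
       distSum = sum(d), minCross = minCross)
}

#' Restraint energy of a candidate component placement
#'
#' Scores one rigid-body pose of a mobile component against a fixed
#' partial assembly: the energy is the sum of flat-harmonic penalties
#' over the inter-component cross-links evaluated on the posed mobile,
#' and the clash count is the number of fixed/mobile CA pairs closer
#' than `clashCutoff`. Every link must span the two components.
#'
#' @param fixed,mobile [XLStructure-class] objects with disjoint chains.
#' @param pose [PoseTransform-class] applied to `mobile`.
#' @param interLinks cross-link table, each row spanning fixed and mobile.
#' @param linkers linker dictionary.
#' @param params [restraintParams()].
#' @param clashCutoff CA clash distance, Angstrom (default 3.0; 0
#'   disables clash counting).
#' @return an [AssemblyState-class].
#' @export
assemblyEnergy <- function(fixed, mobile, pose, interLinks,
                           linkers = defaultLinkers(),
                           params = restraintParams(), clashCutoff = 3.0) {
  geom <- .interLinkGeometry(fixed, mobile, interLinks, linkers, params)
  sc <- .poseScore(geom, pose@rotation, pose@translation, params, clashCutoff)
  new("AssemblyState", pose = pose, energy = sc$energy,
      nSatisfied = as.integer(sc$nSatisfied), clashCount = sc$clash)
}

#' Restraint-guided rigid-body placement search
#'
#' Places a mobile component against a fixed partial assembly, guided
#' purely by cross-link restraints plus a hard-sphere CA clash penalty
#' (one penalty unit per clashing pair); no force field is evaluated.
#' The placement criterion mirrors the modelling protocol: a pose is
#' better when it satisfies more inter-component restraints; clash count
#' and then flat-harmonic energy break ties, which keeps the search
#' robust to a minority of false-positive links (a grossly violated
#' false link cannot outvote satisfiable true links).
#'
#' From `nStarts` seeded random initial poses (rotation uniform over
#' SO(3) via quaternions; translation placing the mobile centroid
#' uniformly within the fixed component's bounding box inflated by the
#' largest link threshold) each pose is refined by iterative local moves
#' (rotation up to 5 degrees and translation up to 1 A per step),
#' accepting a move when the (satisfaction, clash, energy) objective
#' improves lexicographically.
#'
#' Because a flat restraint carries no information inside its threshold,
#' every pose within the mutually-satisfied region is equally supported
#' by the data. The search therefore does not stop at the first feasible
#' pose: from the refined starts that reach the best (satisfaction,
#' clash) tier it launches constrained random walks that wander through
#' the supported region without leaving the tier, time-averages the
#' posed CA coordinates of each walker, clusters the walker means
#' (pairwise no-superposition CA RMSD) to separate distinct binding
#' modes, and returns as top-ranked state the rigid pose fitted
#' (Kabsch) to the largest mode's mean coordinates — an estimate of the
#' centre of the supported region rather than an arbitrary corner of
#' it. When that consensus pose does not itself reach the tier's
#' quality, the tier medoid is returned instead. Deterministic for a
#' given seed.
#'
#' @inheritParams assemblyEnergy
#' @param nStarts number of random initial poses (>= 1).
#' @param nRefineSteps local refinement steps per start.
#' @param seed integer seed controlling all randomness.
#' @param maxRotStep,maxTransStep per-step move sizes (degrees, A).
#' @param nWalkers,nSampleSteps number of within-region walkers (taken
#'   from the best tier) and steps per walker for the consensus stage;
#'   `nWalkers = 0` disables consensus and returns the sorted refined
#'   starts only.
#' @param contactMax compactness prior, Angstrom: assembly components
#'   are taken to form an interface, so poses whose nearest
#'   fixed-mobile CA pair is farther than this are penalised during
#'   refinement and excluded from the consensus walk (default 8; `Inf`
#'   disables it). This operationalises the protocol's
#'   maximise-compactness criterion without pulling the component
#'   deeper into the interface than the restraints support.
#' @param consensusThreshold clustering ceiling (A, no-superposition CA
#'   RMSD between walker means) separating distinct binding modes
#'   before averaging; default 8.
#' @return list of [AssemblyState-class], best first: the consensus (or
#'   medoid) state, then the refined starts sorted by decreasing
#'   satisfaction, then clash count, then energy.
#' @export
rigidBodySearch <- function(fixed, mobile, interLinks,
                            linkers = defaultLinkers(),
                            params = restraintParams(),
                            nStarts = 32, nRefineSteps = 250, seed = 1,
                            clashCutoff = 3.0, maxRotStep = 5,
                            maxTransStep = 1, nWalkers = 8,
                            nSampleSteps = 400, contactMax = 8,
                            consensusThreshold = 8) {
  .stopIfNot(nrow(interLinks) >= 1, "at least one inter-component link required")
  .stopIfNot(nStarts >= 1, "'nStarts' must be >= 1")
  geom <- .interLinkGeometry(fixed, mobile, interLinks, linkers, params)
  box <- apply(geom$fixedCA, 2, range)
  pad <- max(geom$thr)
  cm <- .centroid(atomCoords(mobile, elety = NULL))
  # refinement objective adds the contact (compactness) term to the
  # restraint energy; clash count is the senior continuous tie-break
  eObj <- function(sc) sc$energy +
    if (is.finite(contactMax) && is.finite(sc$minCross))
      max(0, sc$minCross - contactMax)^2 else 0
  better <- function(a, b)   # lexicographic (-nSat, clash, objective)
    (a$nSatisfied > b$nSatisfied) ||
    (a$nSatisfied == b$nSatisfied && a$clash < b$clash) ||
    (a$nSatisfied == b$nSatisfied && a$clash == b$clash &&
       eObj(a) < eObj(b) - 1e-12)

  # data-driven initial pose: superpose the mobile link anchors onto
  # their fixed partners, which orients the component approximately as
  # the restraints demand (clashes are resolved by refinement)
  anchorCen <- .centroid(geom$F)
  anchorFit <- if (nrow(geom$M) >= 3 &&
                     !inherits(tryCatch(kabschSuperpose(geom$F, geom$M),
                                        error = identity), "error")) {
    kabschSuperpose(geom$F, geom$M)
  } else NULL
  states <- .withSeed(seed, {
    lapply(seq_len(nStarts), function(k) {
      # mix blind starts across the inflated bounding box with
      # perturbed anchor-superposition starts
      if (k %% 4 != 1 && !is.null(anchorFit)) {
        dR <- .smallRandomRotation(25)
        R <- dR %*% anchorFit$rotation
        cen <- as.numeric(anchorFit$rotation %*% cm) +
          anchorFit$translation
        t <- as.numeric(dR %*% (anchorFit$translation - cen)) + cen +
          stats::runif(3, -4, 4)
      } else {
        R <- .randomRotation()
        target <- stats::runif(3, box[1, ] - pad, box[2, ] + pad)
        t <- target - as.numeric(R %*% cm)
      }
      cur <- .poseScore(geom, R, t, params, clashCutoff)
      for (step in seq_len(nRefineSteps)) {
        dR <- .smallRandomRotation(maxRotStep)
        dt <- stats::runif(3, -maxTransStep, maxTransStep)
        cen <- as.numeric(R %*% cm) + t      # current posed centroid
        R2 <- dR %*% R
        t2 <- as.numeric(dR %*% (t - cen)) + cen + dt
        nw <- .poseScore(geom, R2, t2, params, clashCutoff)
        if (better(nw, cur)) { R <- R2; t <- t2; cur <- nw }
      }
      list(R = R, t = t, sc = cur)
    })
  })

  nSat <- vapply(states, function(s) s$sc$nSatisfied, numeric(1))
  clash <- vapply(states, function(s) s$sc$clash, integer(1))
  energy <- vapply(states, function(s) s$sc$energy, numeric(1))
  ord <- order(-nSat, clash, energy)
  states <- states[ord]
  nSat <- nSat[ord]; clash <- clash[ord]; energy <- energy[ord]

  asState <- function(s) new(
    "AssemblyState", pose = poseTransform(s$R, s$t), energy = s$sc$energy,
    nSatisfied = as.integer(s$sc$nSatisfied), clashCount = s$sc$clash)

  tier <- which(nSat == nSat[1] & clash == clash[1])
  out <- lapply(states, asState)
  if (nWalkers >= 1 && length(tier) >= 1) {
    mobCA <- atomCoords(mobile)
    tierSat <- nSat[1]; tierClash <- clash[1]
    tierE <- min(energy[tier])
    inRegion <- function(sc)
      sc$nSatisfied >= tierSat && sc$clash <= tierClash &&
        sc$energy <= tierE + 1 &&
        (!is.finite(contactMax) || !is.finite(sc$minCross) ||
           sc$minCross <= contactMax)
    # walkers from tier states spread across the tier, preferring starts
    # already inside the supported (restraints + contact) region
    ok <- tier[vapply(states[tier], function(s) inRegion(s$sc), logical(1))]
    if (length(ok) == 0) ok <- tier
    wi <- ok[unique(round(seq(1, length(ok),
                              length.out = min(nWalkers, length(ok)))))]
    walkerMeans <- .withSeed(.childSeed(seed, 5077L), {
      lapply(states[wi], function(s) {
        R <- s$R; t <- s$t
        acc <- sweep(mobCA %*% t(R), 2, t, "+")
        nAcc <- 1L
        for (step in seq_len(nSampleSteps)) {
          dR <- .smallRandomRotation(maxRotStep)
          dt <- stats::runif(3, -maxTransStep, maxTransStep)
          cen <- as.numeric(R %*% cm) + t
          R2 <- dR %*% R
          t2 <- as.numeric(dR %*% (t - cen)) + cen + dt
          nw <- .poseScore(geom, R2, t2, params, clashCutoff)
          # wander anywhere inside the supported region
          if (inRegion(nw)) { R <- R2; t <- t2 }
          acc <- acc + sweep(mobCA %*% t(R), 2, t, "+")
          nAcc <- nAcc + 1L
        }
        acc / nAcc
      })
    })
    n <- length(walkerMeans)
    m <- matrix(0, n, n, dimnames = list(as.character(seq_len(n)),
                                         as.character(seq_len(n))))
    if (n >= 2) {
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
        m[i, j] <- m[j, i] <- rmsdNoSuperposition(walkerMeans[[i]],
                                                  walkerMeans[[j]])
    }
    memb <- if (n >= 2) {
      cl <- pnnCluster(m, consensusThreshold)
      # among distinct binding modes prefer the most caged one (contacts
      # to the largest number of fixed chains within contactMax), then
      # the mode supported by most walkers
      fixedChainCA <- lapply(unique(fixed@atoms$chain), function(ch)
        atomCoords(fixed, "CA", chain = ch))
      nContact <- vapply(walkerMeans, function(P) {
        sum(vapply(fixedChainCA, function(FC) {
          d2 <- outer(rowSums(FC^2), rowSums(P^2), "+") - 2 * FC %*% t(P)
          sqrt(max(0, min(d2))) <=
            (if (is.finite(contactMax)) contactMax else Inf)
        }, logical(1)))
      }, numeric(1))
      lab <- clusterLabels(cl)
      perMode <- vapply(seq_len(nClusters(cl)), function(k)
        max(nContact[lab == k]), numeric(1))
      best <- order(-perMode, -clusterSizes(cl))[1]
      which(lab == best)
    } else 1L
    meanCoords <- Reduce(`+`, walkerMeans[memb]) / length(memb)
    fit <- kabschSuperpose(meanCoords, mobCA)
    sc <- .poseScore(geom, fit$rotation, fit$translation, params,
                     clashCutoff)
    if (sc$nSatisfied >= tierSat && sc$clash <= tierClash && inRegion(sc)) {
      # second pass: re-walk from the consensus itself, which explores
      # the supported region symmetrically around the current estimate
      means2 <- .withSeed(.childSeed(seed, 6121L), {
        lapply(seq_len(min(nWalkers, 8L)), function(w) {
          R <- fit$rotation; t <- fit$translation
          acc <- sweep(mobCA %*% t(R), 2, t, "+")
          nAcc <- 1L
          for (step in seq_len(nSampleSteps)) {
            dR <- .smallRandomRotation(maxRotStep)
            dt <- stats::runif(3, -maxTransStep, maxTransStep)
            cen <- as.numeric(R %*% cm) + t
            R2 <- dR %*% R
            t2 <- as.numeric(dR %*% (t - cen)) + cen + dt
            nw <- .poseScore(geom, R2, t2, params, clashCutoff)
            if (inRegion(nw)) { R <- R2; t <- t2 }
            acc <- acc + sweep(mobCA %*% t(R), 2, t, "+")
            nAcc <- nAcc + 1L
          }
          acc / nAcc
        })
      })
      mean2 <- Reduce(`+`, means2) / length(means2)
      fit2 <- kabschSuperpose(mean2, mobCA)
      sc2 <- .poseScore(geom, fit2$rotation, fit2$translation, params,
                        clashCutoff)
      if (sc2$nSatisfied >= tierSat && sc2$clash <= tierClash) {
        fit <- fit2; sc <- sc2
      }
    }
    if (sc$nSatisfied >= tierSat && sc$clash <= tierClash) {
      cons <- asState(list(R = fit$rotation, t = fit$translation, sc = sc))
      out <- c(list(cons), out)
    }
    # else: consensus fell outside the supported region; keep the sorted
    # refined starts, whose first element is the best tier member
  }
  out
}

#' Sequential restraint-guided assembly
#'
#' Docks an ordered series of mobile components: each component is
#' placed against the union of the fixed structure and all previously
#' placed components, so links to already-placed neighbours constrain
#' later stages. Links relevant to each stage are selected automatically
#' from the full table.
#'
#' @param fixed starting [XLStructure-class].
#' @param mobiles ordered list of mobile [XLStructure-class] components.
#' @param links full cross-link table; per stage, rows spanning the
#'   current assembly and the docked component are used.
#' @param ... passed to [rigidBodySearch()] (linkers, params, nStarts,
#'   nRefineSteps, seed, ...).
#' @param seed integer seed; stage k uses a child seed derived from it.
#' @return list with `assembly` (merged [XLStructure-class]), `states`
#'   (best [AssemblyState-class] per stage) and `audit` (data.frame:
#'   stage, mobile id, links used, energy, satisfied, clashes).
#' @export
sequentialAssemble <- function(fixed, mobiles, links, ..., seed = 1) {
  current <- fixed
  states <- list()
  audit <- NULL
  for (k in seq_along(mobiles)) {
    mob <- mobiles[[k]]
    mc <- unique(mob@atoms$chain)
    cc <- unique(current@atoms$chain)
    use <- (links$protein_a %in% cc & links$protein_b %in% mc) |
           (links$protein_a %in% mc & links$protein_b %in% cc)
    stageLinks <- links[use, , drop = FALSE]
    ranked <- rigidBodySearch(current, mob, stageLinks, ...,
                              seed = .childSeed(seed, k))
    best <- ranked[[1]]
    states[[k]] <- best
    current <- mergeStructures(current, applyPose(mob, best@pose),
                               id = "assembly")
    audit <- rbind(audit, data.frame(
      stage = k, mobile = mob@id, n_links = nrow(stageLinks),
      energy = best@energy, n_satisfied = best@nSatisfied,
      clashes = best@clashCount, stringsAsFactors = FALSE))
  }
  list(assembly = current, states = states, audit = audit)
}

#' Validate an assembly against a full cross-link set
#'
#' Evaluates every resolvable cross-link on the assembled model and
#' summarises the satisfied fraction overall, by linker and by
#' experimental condition — the validation step applied to an optimized
#' assembly when restraints were held out of the optimisation itself.
#'
#' @param assembly an [XLStructure-class].
#' @param links cross-link table.
#' @param linkers linker dictionary.
#' @param params [restraintParams()].
#' @return list with `table` (per-link rows from [evaluateSet()]),
#'   `summary` (overall n, n_satisfied, fraction), `byLinker` and
#'   `byCondition` (data.frames of per-group fractions), and
#'   `unresolved`.
#' @export
validateAssembly <- function(assembly, links, linkers = defaultLinkers(),
                             params = restraintParams()) {
  ev <- evaluateSet(assembly, links, linkers, params)
  tab <- ev$table
  frac <- function(g) {
    agg <- stats::aggregate(tab$satisfied, by = list(group = g),
                            FUN = function(v) c(n = length(v), sat = sum(v)))
    data.frame(group = agg$group, n = agg$x[, "n"],
               n_satisfied = agg$x[, "sat"],
               fraction = agg$x[, "sat"] / agg$x[, "n"],
               stringsAsFactors = FALSE)
  }
  list(
    table = tab,
    summary = data.frame(n = nrow(tab), n_satisfied = ev$nSatisfied,
                         fraction = if (nrow(tab)) ev$nSatisfied / nrow(tab)
                                    else NA_real_),
    byLinker = if (nrow(tab)) frac(tab$linker) else NULL,
    byCondition = if (nrow(tab)) frac(tab$condition) else NULL,
    unresolved = ev$unresolved)
}
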