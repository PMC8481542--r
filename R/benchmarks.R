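#' Seeded parameter-recovery benchmarks
#'
#' The package validates its two stochastic stages by parameter
#' recovery on synthetic ground truth.
#'
#' `selectionRecoveryTrial()` builds a two-chain truth (a 30-residue
#' helix against a 30-residue coil), simulates a DSS cross-link list of
#' 8 true links plus one false positive (12.5% false rate), generates a
#' 200-decoy ensemble with 30% near-truth decoys under the default
#' noise model, and runs the full selection pipeline (top 50 by score,
#' restraint filter at 8 satisfied links, clustering at 2 A). It
#' reports the superposed CA RMSD between the selected decoy and the
#' truth.
#'
#' `assemblyRecoveryTrial()` builds a four-chain junction truth in
#' which a 14-residue helical fragment (chain D) is caged by three
#' 30-residue chains, simulates a validated (false-free, as placement
#' restraints are curated) link set of 12 EDC plus 8 DSS links from the
#' fragment to its cage, and runs the restraint-guided rigid-body
#' search from scratch. It reports the no-superposition CA RMSD between
#' the recovered and the true fragment pose.
#'
#' @param seed integer seed; every trial is fully determined by it.
#' @return a list: `rmsd` (A, the recovery error), plus trial details
#'   (`selectedId`/`nSatisfied`, link and ensemble sizes).
#' @seealso [selectFinalModel()], [rigidBodySearch()]
#' @export
selectionRecoveryTrial <- function(seed) {
  tr <- makeTruth(2, 30, c("helix", "coil"), seed = seed)
  links <- simulateCrossLinks(tr, "DSS", nTrue = 8, falseRate = 0.125,
                              seed = seed)
  ens <- perturbEnsemble(tr, nDecoys = 200, fractionNear = 0.3,
                         seed = seed)
  res <- selectFinalModel(ens, links, topN = 50, threshold = 2,
                          minSatisfied = 8)
  sel <- getDecoy(ens, selectedId(res))
  rmsd <- kabschSuperpose(atomCoords(tr), atomCoords(sel))$rmsd
  list(rmsd = rmsd, selectedId = selectedId(res),
       nDecoys = length(ens), nLinks = nrow(links))
}

#' @rdname selectionRecoveryTrial
#' @export
assemblyRecoveryTrial <- function(seed) {
  tr <- makeTruth(4, c(30, 30, 30, 14),
                  c("coil", "helix", "coil", "helix"), seed = seed)
  ta <- atomTable(tr)
  fixed <- XLStructure("fixed", ta[ta$chain != "D", ])
  mobile <- XLStructure("mobile", ta[ta$chain == "D", ])
  cage <- list(c("A", "D"), c("B", "D"), c("C", "D"))
  links <- rbind(
    simulateCrossLinks(tr, "EDC", nTrue = 12, falseRate = 0, seed = seed,
                       chainPairs = cage),
    simulateCrossLinks(tr, "DSS", nTrue = 8, falseRate = 0,
                       seed = .childSeed(seed, 37L), chainPairs = cage))
  ranked <- rigidBodySearch(fixed, mobile, links, nStarts = 48,
                            nRefineSteps = 250, nWalkers = 16,
                            nSampleSteps = 1200, seed = seed)
  top <- ranked[[1]]
  posed <- applyPose(mobile, top@pose)
  rmsd <- rmsdNoSuperposition(atomCoords(posed), atomCoords(mobile))
  list(rmsd = rmsd, nSatisfied = top@nSatisfied, nLinks = nrow(links))
}
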