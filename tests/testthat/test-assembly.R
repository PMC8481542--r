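# small fixed/mobile two-body problem shared across assembly tests
twoBodyFixture <- function(seed = 11, nres = c(30, 14),
                           topo = c("coil", "helix"), nTrue = 6,
                           falseRate = 0, linker = "DSS") {
  tr <- makeTruth(2, nres, topo, seed = seed)
  ta <- atomTable(tr)
  list(truth = tr,
       fixed = XLStructure("fixed", ta[ta$chain == "A", ]),
       mobile = XLStructure("mobile", ta[ta$chain == "B", ]),
       links = simulateCrossLinks(tr, linker, nTrue = nTrue,
                                  falseRate = falseRate, seed = seed))
}

test_that("poses apply rigidly and compose with their inverse", {
  s <- randomStructure(20, seed = 2)
  expect_equal(atomTable(applyPose(s, poseTransform())), atomTable(s))
  shifted <- applyPose(s, poseTransform(translation = c(1, 2, 3)))
  expect_equal(unname(colMeans(atomCoords(shifted, NULL)) -
                        colMeans(atomCoords(s, NULL))), c(1, 2, 3))
  R <- randomRotationFixture(5)
  t <- c(4, -2, 9)
  posed <- applyPose(s, poseTransform(R, t))
  Rinv <- t(R)
  back <- applyPose(posed, poseTransform(Rinv, -as.numeric(Rinv %*% t)))
  expect_equal(atomCoords(back, NULL), atomCoords(s, NULL),
               tolerance = 1e-9)
  # improper rotations are rejected
  expect_error(poseTransform(diag(c(1, 1, -1))), "proper")
})

test_that("assembly energy scores posed links and counts clashes", {
  fx <- twoBodyFixture()
  # true pose satisfies everything with no clashes
  st <- assemblyEnergy(fx$fixed, fx$mobile, poseTransform(), fx$links)
  expect_equal(st@energy, 0)
  expect_equal(st@nSatisfied, nrow(fx$links))
  expect_equal(st@clashCount, 0L)
  # moving the mobile 1000 A away violates everything; energy matches a
  # direct flat-harmonic recomputation on the displaced structure
  far <- poseTransform(translation = c(1000, 0, 0))
  stFar <- assemblyEnergy(fx$fixed, fx$mobile, far, fx$links)
  expect_equal(stFar@nSatisfied, 0L)
  expect_equal(stFar@clashCount, 0L)
  merged <- mergeStructures(fx$fixed, applyPose(fx$mobile, far))
  ref <- evaluateSet(merged, fx$links)
  expect_equal(stFar@energy, ref$totalPenalty, tolerance = 1e-9)
  # clashCutoff 0 disables clash counting
  st0 <- assemblyEnergy(fx$fixed, fx$mobile, poseTransform(), fx$links,
                        clashCutoff = 0)
  expect_equal(st0@clashCount, 0L)
  # links must span the two components
  intra <- linkRow("A", 1, "A", 5)
  expect_error(assemblyEnergy(fx$fixed, fx$mobile, poseTransform(), intra),
               "span")
})

test_that("assembly energy is isometry-invariant as a whole", {
  fx <- twoBodyFixture(seed = 13)
  pose <- poseTransform(randomRotationFixture(3), c(2, 5, -1))
  st <- assemblyEnergy(fx$fixed, fx$mobile, pose, fx$links)
  # transform fixed and the posed mobile by a common rigid map
  Rg <- randomRotationFixture(8)
  tg <- c(-20, 13, 7)
  fixed2 <- transformStructure(fx$fixed, Rg, tg)
  # composite pose: x -> Rg (R x + t) + tg
  pose2 <- poseTransform(Rg %*% pose@rotation,
                         as.numeric(Rg %*% pose@translation) + tg)
  st2 <- assemblyEnergy(fixed2, fx$mobile, pose2, fx$links)
  expect_equal(st2@energy, st@energy, tolerance = 1e-9)
  expect_equal(st2@nSatisfied, st@nSatisfied)
  expect_equal(st2@clashCount, st@clashCount)
})

test_that("rigid-body search is deterministic and reaches zero energy", {
  fx <- twoBodyFixture(seed = 21, nTrue = 4)
  rk <- rigidBodySearch(fx$fixed, fx$mobile, fx$links, nStarts = 8,
                        nRefineSteps = 120, nWalkers = 2,
                        nSampleSteps = 60, seed = 99)
  expect_true(length(rk) >= 8)
  top <- rk[[1]]
  expect_equal(top@energy, 0)
  expect_equal(top@nSatisfied, nrow(fx$links))
  # satisfaction never increases down the ranking
  nS <- vapply(rk, function(s) s@nSatisfied, integer(1))
  expect_true(all(diff(nS[-1]) <= 0))
  # byte-identical rerun under the same seed
  rk2 <- rigidBodySearch(fx$fixed, fx$mobile, fx$links, nStarts = 8,
                         nRefineSteps = 120, nWalkers = 2,
                         nSampleSteps = 60, seed = 99)
  expect_identical(lapply(rk, function(s) s@pose@rotation),
                   lapply(rk2, function(s) s@pose@rotation))
  expect_identical(vapply(rk, function(s) s@energy, numeric(1)),
                   vapply(rk2, function(s) s@energy, numeric(1)))
  expect_error(rigidBodySearch(fx$fixed, fx$mobile, fx$links[0, ]),
               "at least one")
})

test_that("more refinement steps never worsen the best pose found", {
  fx <- twoBodyFixture(seed = 23, nTrue = 5)
  quality <- function(steps, s) {
    rk <- rigidBodySearch(fx$fixed, fx$mobile, fx$links, nStarts = 6,
                          nRefineSteps = steps, nWalkers = 0, seed = s)
    c(sat = rk[[1]]@nSatisfied, e = rk[[1]]@energy + rk[[1]]@clashCount)
  }
  for (s in 1:3) {
    lo <- quality(15, s)
    hi <- quality(150, s)
    expect_gte(hi["sat"], lo["sat"])
    if (hi["sat"] == lo["sat"]) expect_lte(hi["e"], lo["e"] + 1e-9)
  }
})

test_that("a caged mobile fragment is recovered near its true pose", {
  trial <- assemblyRecoveryTrial(4)
  expect_equal(trial$nSatisfied, trial$nLinks)
  expect_lt(trial$rmsd, 5)
})

test_that("sequential assembly stages dock in order against the union", {
  tr <- makeTruth(3, c(30, 14, 14), c("coil", "helix", "helix"), seed = 31)
  ta <- atomTable(tr)
  fixed <- XLStructure("fixed", ta[ta$chain == "A", ])
  mobB <- XLStructure("mobB", ta[ta$chain == "B", ])
  mobC <- XLStructure("mobC", ta[ta$chain == "C", ])
  links <- simulateCrossLinks(tr, "DSS", nTrue = 12, falseRate = 0,
                              seed = 31)
  res <- sequentialAssemble(fixed, list(mobB, mobC), links,
                            nStarts = 8, nRefineSteps = 100,
                            nWalkers = 2, nSampleSteps = 50, seed = 31)
  expect_equal(res$audit$stage, c(1, 2))
  expect_equal(res$audit$mobile, c("mobB", "mobC"))
  expect_equal(sort(unique(atomTable(res$assembly)$chain)),
               c("A", "B", "C"))
  # single-mobile sequential assembly equals a direct search
  direct <- rigidBodySearch(fixed, mobB,
                            links[(links$protein_a %in% c("A", "B")) &
                                    (links$protein_b %in% c("A", "B")), ],
                            nStarts = 8, nRefineSteps = 100, nWalkers = 2,
                            nSampleSteps = 50,
                            seed = XLAssemble:::.childSeed(31, 1))
  solo <- sequentialAssemble(fixed, list(mobB), links, nStarts = 8,
                             nRefineSteps = 100, nWalkers = 2,
                             nSampleSteps = 50, seed = 31)
  expect_equal(solo$states[[1]]@pose@rotation, direct[[1]]@pose@rotation)
})

test_that("assembly validation reports exact per-group fractions", {
  tr <- makeTruth(2, 20, c("helix", "coil"), seed = 17)
  links <- rbind(
    simulateCrossLinks(tr, "DSS", nTrue = 6, falseRate = 0.5, seed = 17,
                       condition = "with_precursor"),
    simulateCrossLinks(tr, "EDC", nTrue = 4, falseRate = 0, seed = 18,
                       condition = "without_precursor"))
  rep <- validateAssembly(tr, links)
  expect_equal(nrow(rep$table), nrow(links))
  expect_equal(rep$summary$n_satisfied, sum(rep$table$satisfied))
  expect_equal(rep$summary$fraction,
               sum(rep$table$satisfied) / nrow(rep$table))
  # group fractions recompute from the table
  for (g in seq_len(nrow(rep$byLinker))) {
    rows <- rep$table$linker == rep$byLinker$group[g]
    expect_equal(rep$byLinker$fraction[g],
                 mean(rep$table$satisfied[rows]))
  }
  byc <- rep$byCondition
  expect_equal(sort(byc$group), c("with_precursor", "without_precursor"))
  # a fully satisfied assembly reports 100%
  clean <- simulateCrossLinks(tr, "DSS", nTrue = 5, falseRate = 0,
                              seed = 19)
  expect_equal(validateAssembly(tr, clean)$summary$fraction, 1)
})
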