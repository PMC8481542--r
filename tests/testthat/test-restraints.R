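test_that("the default linker dictionary carries the published values", {
  d <- defaultLinkers()
  dss <- d[d$name == "DSS", ]
  expect_equal(dss$spacer, 11.4)
  expect_equal(dss$ca_ca, 30)
  expect_equal(dss$cb_cb, 22)
  expect_equal(d$spacer[d$name == "DSSO"], 10.1)
  expect_equal(d$spacer[d$name == "SDA"], 3.9)
  expect_equal(d$spacer[d$name == "EDC"], 0)
  edc <- d[d$name == "EDC", ]
  expect_equal(edc$edc_n, 10)
  expect_equal(edc$edc_side, 14)
  # internal consistency: CB threshold never exceeds CA threshold
  amine <- d[!is.na(d$ca_ca), ]
  expect_true(all(amine$cb_cb <= amine$ca_ca))
})

test_that("flat harmonic is zero inside, quadratic outside, continuous", {
  expect_equal(flatHarmonic(25, 30, 1), 0)
  expect_equal(flatHarmonic(30, 30, 1), 0)
  expect_equal(flatHarmonic(34, 30, 1), 16)
  expect_equal(flatHarmonic(31, 30, 2), 0.25)
  # continuity at the threshold
  eps <- 1e-8
  expect_lt(flatHarmonic(30 + eps, 30, 1), 1e-12)
  # monotone non-decreasing in distance
  d <- seq(0, 50, by = 0.5)
  expect_true(all(diff(flatHarmonic(d, 30, 1)) >= 0))
  expect_error(flatHarmonic(10, 30, 0), "sd")
})

test_that("amine linkers map to CA/CB pairs with glycine fallback", {
  s <- twoResidueStructure(10)
  dss <- defaultLinkers()[defaultLinkers()$name == "DSS", ]
  p <- mapLinkAtoms(s, linkRow("A", 1, "B", 1), dss)
  expect_equal(p$atom_a, c("CA", "CB"))
  expect_equal(p$threshold, c(30, 22))
  # drop the CB of chain B (glycine-like residue)
  a <- atomTable(s)
  sG <- XLStructure("g", a[!(a$chain == "B" & a$elety == "CB"), ])
  pG <- mapLinkAtoms(sG, linkRow("A", 1, "B", 1), dss)
  expect_equal(pG$atom_a, "CA")
  expect_error(
    mapLinkAtoms(sG, linkRow("A", 1, "B", 1), dss,
                 restraintParams(caFallback = FALSE)), "unresolved")
  expect_error(mapLinkAtoms(s, linkRow("A", 9, "B", 1), dss), "A:9")
})

test_that("EDC selects site anchors and the 10/14 A thresholds", {
  # chain A: MET 1 (backbone N) + ASP 12; chain B mirrors with LYS 27
  atoms <- data.frame(
    chain = c("A", "A", "A", "A", "B", "B", "B", "B"),
    resno = c(1L, 1L, 12L, 12L, 22L, 22L, 27L, 27L),
    resid = c("MET", "MET", "ASP", "ASP", "ASP", "ASP", "LYS", "LYS"),
    elety = c("N", "CA", "CA", "CG", "CA", "CG", "CA", "NZ"),
    x = c(0, 1, 5, 6, 10, 11, 15, 16), y = 0, z = 0,
    stringsAsFactors = FALSE)
  s <- XLStructure("edc", atoms)
  edc <- defaultLinkers()[defaultLinkers()$name == "EDC", ]
  # N-terminal amine to aspartate side chain: backbone N pair, 10 A
  p1 <- mapLinkAtoms(s, linkRow("A", 1, "A", 12, "EDC"), edc)
  expect_equal(p1$atom_a, "N")
  expect_equal(p1$atom_b, "CG")
  expect_equal(p1$threshold, 10)
  # side chain to side chain: CG vs NZ, 14 A
  p2 <- mapLinkAtoms(s, linkRow("B", 22, "B", 27, "EDC"), edc)
  expect_equal(p2$atom_a, "CG")
  expect_equal(p2$atom_b, "NZ")
  expect_equal(p2$threshold, 14)
})

test_that("evaluateLink applies mode semantics and sums pair penalties", {
  # CA-CA 31, CB-CB 21 under DSS: violated under all, satisfied under any
  s <- twoResidueStructure(dCA = 31, dCB = 21)
  dss <- defaultLinkers()[defaultLinkers()$name == "DSS", ]
  link <- linkRow("A", 1, "B", 1)
  evAll <- evaluateLink(s, link, dss, restraintParams(sd = 1, mode = "all"))
  expect_false(evAll$satisfied)
  expect_equal(evAll$penalty, 1.0)   # ((31-30)/1)^2 + 0
  evAny <- evaluateLink(s, link, dss, restraintParams(sd = 1, mode = "any"))
  expect_true(evAny$satisfied)
  expect_equal(evAny$penalty, evAll$penalty)
  # fully satisfied pair
  ev0 <- evaluateLink(twoResidueStructure(10), link, dss, restraintParams())
  expect_true(ev0$satisfied)
  expect_equal(ev0$penalty, 0)
  # penalty zero iff satisfied under mode=all
  expect_equal(evAll$penalty == 0, FALSE)
  expect_equal(ev0$penalty == 0, TRUE)
})

test_that("evaluateSet matches per-link brute force and handles edge cases", {
  empty <- evaluateSet(twoResidueStructure(10),
                       linkRow("A", 1, "B", 1)[0, ])
  expect_equal(empty$nSatisfied, 0)
  expect_equal(empty$totalPenalty, 0)
  expect_equal(nrow(empty$table), 0L)

  tr <- makeTruth(2, 20, c("helix", "coil"), seed = 5)
  links <- simulateCrossLinks(tr, "DSS", nTrue = 12, falseRate = 0.5,
                              seed = 5)
  got <- evaluateSet(tr, links)
  # brute force: evaluate each link independently and aggregate
  dss <- defaultLinkers()[defaultLinkers()$name == "DSS", ]
  ref <- lapply(seq_len(nrow(links)), function(i)
    evaluateLink(tr, links[i, ], dss, restraintParams()))
  expect_equal(got$nSatisfied, sum(vapply(ref, `[[`, logical(1), "satisfied")))
  expect_equal(got$totalPenalty, sum(vapply(ref, `[[`, numeric(1), "penalty")))
  expect_equal(got$table$penalty,
               vapply(ref, `[[`, numeric(1), "penalty"))
  # permutation invariance of the aggregate
  perm <- sample(nrow(links))
  got2 <- evaluateSet(tr, links[perm, ])
  expect_equal(got2$nSatisfied, got$nSatisfied)
  expect_equal(got2$totalPenalty, got$totalPenalty)
  # unresolved links are reported, not counted
  bad <- rbind(links, linkRow("Z", 1, "A", 1))
  got3 <- evaluateSet(tr, bad)
  expect_equal(nrow(got3$unresolved), 1L)
  expect_equal(got3$nSatisfied, got$nSatisfied)
})

test_that("restraint evaluation is invariant under rigid transforms", {
  tr <- makeTruth(2, 15, "coil", seed = 9)
  links <- simulateCrossLinks(tr, "DSS", nTrue = 6, falseRate = 0.5,
                              seed = 9)
  ev0 <- evaluateSet(tr, links)
  for (k in 1:5) {
    R <- randomRotationFixture(k)
    tv <- c(10 * k, -5, 3)
    evk <- evaluateSet(transformStructure(tr, R, tv), links)
    expect_equal(evk$totalPenalty, ev0$totalPenalty, tolerance = 1e-9)
    expect_identical(evk$table$satisfied, ev0$table$satisfied)
  }
})
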