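# helper: donor N + hydrogen + acceptor O at controlled geometry
hbTriple <- function(dNA, devDeg) {
  a <- devDeg * pi / 180
  topo <- mkTopo(c("N", "HN", "O"), c("N", "H", "O"), c(1L, 1L, 2L),
                 c("A", "A", "B"))
  tr <- mkTraj(topo, list(rbind(c(0, 0, 0), c(cos(a), sin(a), 0), c(dNA, 0, 0))))
  list(tr = tr, sA = selOf(topo, 1:2, "a"), sB = selOf(topo, 3L, "b"))
}

test_that("hydrogen-bond geometry criteria gate on distance and angle", {
  x <- hbTriple(2.9, 10)
  rec <- detectHbondsFrame(x$tr, 1, x$sA, x$sB)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$donorAtom, "N")
  expect_equal(rec$acceptorAtom, "O")
  expect_equal(nrow(detectHbondsFrame(hbTriple(3.8, 10)$tr, 1, x$sA, x$sB)), 0L)
  expect_equal(nrow(detectHbondsFrame(hbTriple(2.9, 40)$tr, 1, x$sA, x$sB)), 0L)
  # invalid criteria rejected
  expect_error(hbondCriteria(distanceCutoff = -1))
  expect_error(hbondCriteria(angleCutoff = 95))
})

test_that("missing hydrogens require the heavy-atom fallback", {
  topo <- mkTopo(c("N", "O"), c("N", "O"), 1:2, c("A", "B"))
  tr <- mkTraj(topo, list(rbind(c(0, 0, 0), c(3.0, 0, 0))))
  sA <- selOf(topo, 1L); sB <- selOf(topo, 2L)
  expect_error(detectHbondsFrame(tr, 1, sA, sB), "topology error")
  rec <- detectHbondsFrame(tr, 1, sA, sB, hbondCriteria(heavyAtomOnly = TRUE))
  expect_equal(nrow(rec), 1L)
  expect_true(is.na(rec$hydrogenAtom))
})

test_that("scheduled contacts give the planted counts, symmetry, and step structure", {
  dom <- data.frame(name = c("d1", "d2"), chain = c("A", "B"),
                    startRes = c(1L, 1L), endRes = c(10L, 10L),
                    cx = c(0, 40), cy = 0, cz = 0, sigma = 0.2,
                    stringsAsFactors = FALSE)
  contacts <- rbind(
    contactSchedule("c1", "d1", 2L, "GLY", "d2", 2L, "GLY", "hbond", c(1L, 100L)),
    contactSchedule("c2", "d1", 5L, "GLY", "d2", 5L, "GLY", "hbond", c(1L, 100L)),
    contactSchedule("c3", "d1", 8L, "GLY", "d2", 8L, "GLY", "hbond", c(1L, 100L)))
  sys <- generateTrajectory(syntheticSpec(dom, contacts = contacts,
                                          nframes = 100L, seed = 3L))
  map <- domainMap(d1 = "A:1-10", d2 = "B:1-10")
  sA <- selectDomain(sys$topology, map, "d1", "all")
  sB <- selectDomain(sys$topology, map, "d2", "all")
  cnt <- interdomainHbondCount(sys$trajectory, sA, sB)
  expect_equal(cnt$value, rep(3, 100))   # three always-formed contacts
  # symmetry: count(A, B) == count(B, A) frame by frame
  expect_equal(interdomainHbondCount(sys$trajectory, sB, sA)$value, cnt$value)

  # 4 -> 2 drop at the scheduled frame
  contacts2 <- rbind(
    contactSchedule("c1", "d1", 1L, "GLY", "d2", 1L, "GLY", "hbond", c(1L, 50L)),
    contactSchedule("c2", "d1", 3L, "GLY", "d2", 3L, "GLY", "hbond", c(1L, 50L)),
    contactSchedule("c3", "d1", 6L, "GLY", "d2", 6L, "GLY", "hbond", c(1L, 100L)),
    contactSchedule("c4", "d1", 9L, "GLY", "d2", 9L, "GLY", "hbond", c(1L, 100L)))
  sys2 <- generateTrajectory(syntheticSpec(dom, contacts = contacts2,
                                           nframes = 100L, seed = 4L))
  sA2 <- selectDomain(sys2$topology, map, "d1", "all")
  sB2 <- selectDomain(sys2$topology, map, "d2", "all")
  cnt2 <- interdomainHbondCount(sys2$trajectory, sA2, sB2)
  expect_equal(cnt2$value, c(rep(4, 50), rep(2, 50)))
})

test_that("windowed occupancancy matches the schedule exactly, including boundaries", {
  dom <- data.frame(name = c("d1", "d2"), chain = c("A", "B"),
                    startRes = c(1L, 1L), endRes = c(6L, 6L),
                    cx = c(0, 40), cy = 0, cz = 0, sigma = 0.2,
                    stringsAsFactors = FALSE)
  contacts <- rbind(
    # on frames 1-500, off 501-1000: with 250-frame windows -> 1, 1, 0, 0
    contactSchedule("p1", "d1", 2L, "GLY", "d2", 2L, "GLY", "hbond", c(1L, 500L)),
    # always formed -> 1.0 in all windows
    contactSchedule("p2", "d1", 4L, "GLY", "d2", 4L, "GLY", "hbond", c(1L, 1000L)),
    # on for exactly half of every window -> 0.50, not flagged (strict < 0.5)
    contactSchedule("p3", "d1", 6L, "GLY", "d2", 6L, "GLY", "hbond",
                    rbind(c(1L, 125L), c(251L, 375L), c(501L, 625L), c(751L, 875L))))
  sys <- generateTrajectory(syntheticSpec(dom, contacts = contacts,
                                          nframes = 1000L, dtNs = 1, seed = 5L))
  map <- domainMap(d1 = "A:1-6", d2 = "B:1-6")
  sA <- selectDomain(sys$topology, map, "d1", "all")
  sB <- selectDomain(sys$topology, map, "d2", "all")
  occ <- pairOccupancy(sys$trajectory, sA, sB, windowNs = 250)
  m <- occupancy(occ)
  expect_equal(dim(m), c(3L, 4L))
  p1 <- grep("A:GLY2", rownames(m)); p2 <- grep("A:GLY4", rownames(m))
  p3 <- grep("A:GLY6", rownames(m))
  expect_equal(unname(m[p1, ]), c(1, 1, 0, 0))
  expect_equal(unname(m[p2, ]), c(1, 1, 1, 1))
  expect_equal(unname(m[p3, ]), c(0.5, 0.5, 0.5, 0.5))
  fl <- occupancyFlags(occ)
  expect_equal(unname(fl[p3, ]), rep(FALSE, 4))   # 0.50 is not flagged
  expect_equal(unname(fl[p1, ]), c(FALSE, FALSE, TRUE, TRUE))

  # conservation: window occupancies, weighted by frames per window, equal the
  # whole-trajectory occupancy
  widx <- trajnet:::.windowIndex(frameTimes(sys$trajectory), occ@windows)
  wts <- tabulate(widx, nbins = nrow(occ@windows))
  whole <- as.numeric(occ@occupancy %*% wts) / sum(wts)
  expect_equal(whole, c(0.5, 1, 0.5), tolerance = 1e-12)

  # window shorter than the frame spacing is a resolution error
  expect_error(pairOccupancy(sys$trajectory, sA, sB, windowNs = 0.5),
               "resolution error")
})

test_that("loosening cutoffs never decreases per-frame counts", {
  pf <- presetFixture()
  map <- specDomainMap(pf$spec)
  sA <- selectDomain(pf$topology, map, "nSH2", "all")
  sB <- selectDomain(pf$topology, map, "helical", "all")
  frames <- seq(1L, nFrames(pf$trajectory), by = 100L)
  tight <- interdomainHbondCount(pf$trajectory, sA, sB,
                                 hbondCriteria(3.0, 15), frames = frames)
  mid <- interdomainHbondCount(pf$trajectory, sA, sB,
                               hbondCriteria(3.5, 30), frames = frames)
  loose <- interdomainHbondCount(pf$trajectory, sA, sB,
                                 hbondCriteria(4.5, 45), frames = frames)
  expect_true(all(mid$value >= tight$value))
  expect_true(all(loose$value >= mid$value))
})

test_that("salt bridges gate on the N(+)...O(-) cutoff and follow schedules", {
  topo <- mkTopo(c("CA", "NZ", "CA", "OE1"), c("C", "N", "C", "O"),
                 c(1L, 1L, 2L, 2L), c("A", "A", "B", "B"),
                 resnames = c("LYS", "LYS", "GLU", "GLU"))
  near <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(8, 0, 0), c(5.0, 0, 0))  # 3.5 A
  far <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(8, 0, 0), c(6.0, 0, 0))   # 4.5 A
  sA <- selOf(topo, 1:2); sB <- selOf(topo, 3:4)
  occNear <- detectSaltBridges(mkTraj(topo, list(near)), sA, sB, windowNs = 1)
  expect_equal(nrow(occNear@pairs), 1L)
  expect_equal(as.numeric(occupancy(occNear)), 1)
  occFar <- detectSaltBridges(mkTraj(topo, list(far)), sA, sB, windowNs = 1)
  expect_equal(nrow(occFar@pairs), 0L)

  # planted K-E bridge broken at the scheduled frame: occupancy drops there
  pf <- presetFixture()
  map <- specDomainMap(pf$spec)
  sN <- selectDomain(pf$topology, map, "nSH2", "all")
  sH <- selectDomain(pf$topology, map, "helical", "all")
  occ <- detectSaltBridges(pf$trajectory, sN, sH, windowNs = 100)
  m <- occupancy(occ)
  r340 <- grep("ARG340", rownames(m))
  tf <- pf$truth
  dtNs <- frameTimes(pf$trajectory)[2] - frameTimes(pf$trajectory)[1]
  breakNs <- (tf@detachFrame - 1) * dtNs
  before <- which(occ@windows$end_ns <= breakNs + 1e-9)
  after <- which(occ@windows$start_ns >= breakNs - 1e-9 &
                 occ@windows$end_ns <= tf@transientFrames[1] * dtNs)
  expect_true(all(m[r340, before] == 1))
  expect_true(all(m[r340, after] == 0))
})
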