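# Contact maps, persistence filtering, consensus and classification.

## two C-alphas at an exact separation, third chain far away
fixedSeparationTraj <- function(sep, nFrames = 3) {
  atoms <- data.frame(eleno = 1:3, elety = "CA", resid = "ALA",
                      chain = c("C", "A", "B"), resno = 1L)
  cc <- array(0, dim = c(3, 3, nFrames))
  cc[2, 1, ] <- sep
  cc[3, 1, ] <- -100
  new("TrajectoryWindow", topology = complexTopology(atoms), coords = cc,
      times = seq_len(nFrames) - 1, groundTruth = list())
}

mkMap <- function(pers, level = "all_atom", cutoff = 3) {
  new("ContactMap", persistence = pers, chainPair = c("C", "A"),
      level = level, cutoff = cutoff, window = c(1L, 10L), nFrames = 10L)
}

test_that("the contact test is inclusive at the cutoff neighborhood", {
  expect_equal(unname(persistence(contactMap(fixedSeparationTraj(10.9),
                                             c("C", "A"), "c_alpha")))[1, 1], 1)
  expect_equal(unname(persistence(contactMap(fixedSeparationTraj(11.1),
                                             c("C", "A"), "c_alpha")))[1, 1], 0)
})

test_that("contact persistence equals the brute-force oracle on random fixtures", {
  for (seed in 1:3) {
    traj <- makeRandomTrajectory(seed, nRes = 5, nFrames = 8)
    for (level in c("c_alpha", "all_atom")) {
      cutoff <- if (level == "c_alpha") 11 else 3
      got <- persistence(contactMap(traj, c("C", "A"), level, cutoff))
      expect_equal(got, oracleContactPersistence(traj, c("C", "A"),
                                                 level, cutoff),
                   tolerance = 1e-12)
    }
  }
})

test_that("persistence filtering is strict at the threshold", {
  pers <- matrix(c(0.6, 0.5, 0.4, 0), 2, 2,
                 dimnames = list(c("1", "2"), c("1", "2")))
  filt <- persistence(persistenceFilter(mkMap(pers), 0.5))
  expect_equal(filt[1, 1], 0.6)   # > 0.5 retained
  expect_equal(filt[2, 1], 0)     # exactly 0.5 dropped
  expect_equal(filt[1, 2], 0)
  zero <- mkMap(matrix(0, 2, 2, dimnames = list(c("1", "2"), c("1", "2"))))
  expect_true(all(persistence(persistenceFilter(zero)) == 0))
})

test_that("consensus counts match exhaustive enumeration and the >=3 rule", {
  dn <- list(as.character(1:3), as.character(1:3))
  set.seed(9)
  maps <- lapply(1:6, function(i)
    mkMap(matrix(sample(c(0, 0.8), 9, replace = TRUE), 3, 3,
                 dimnames = dn)))
  cs <- consensusMerge(maps, threshold = 3)
  # ten-line enumeration oracle
  expected <- matrix(0L, 3, 3)
  for (m in maps) expected <- expected + (persistence(m) > 0)
  expect_equal(unname(presenceCounts(cs)), unname(expected))
  expect_equal(unname(cs@retained), unname(expected >= 3))

  one <- mkMap(matrix(c(rep(0.9, 3), rep(0, 6)), 3, 3, dimnames = dn))
  two <- consensusMerge(rep(list(one), 6), threshold = 3)
  expect_true(all(presenceCounts(two) %in% c(0L, 6L)))

  # a pair in 3 of 6 maps is retained; in 2 of 6 dropped
  hit <- mkMap(matrix(c(0.9, rep(0, 8)), 3, 3, dimnames = dn))
  miss <- mkMap(matrix(0, 3, 3, dimnames = dn))
  expect_true(retainedPairs(consensusMerge(c(rep(list(hit), 3),
                                             rep(list(miss), 3))))[1, "count"] == 3)
  expect_equal(nrow(retainedPairs(consensusMerge(c(rep(list(hit), 2),
                                                   rep(list(miss), 4))))), 0)
})

test_that("stricter consensus thresholds retain a subset", {
  set.seed(10)
  dn <- list(as.character(1:4), as.character(1:4))
  maps <- lapply(1:6, function(i)
    mkMap(matrix(sample(c(0, 1), 16, replace = TRUE), 4, 4, dimnames = dn)))
  r3 <- consensusMerge(maps, 3)@retained
  r6 <- consensusMerge(maps, 6)@retained
  expect_true(all(!r6 | r3))
})

test_that("mismatched residue ranges are an alignment error", {
  a <- mkMap(matrix(0.6, 2, 2, dimnames = list(c("1", "2"), c("1", "2"))))
  b <- mkMap(matrix(0.6, 2, 2, dimnames = list(c("1", "2"), c("2", "3"))))
  expect_error(consensusMerge(list(a, b)), "alignment error")
})

test_that("interaction classes follow residue chemistry and occupancy evidence", {
  topo <- trimerAssembly()$topology
  counts <- matrix(0L, 30, 28,
                   dimnames = list(14:43, 6:33))
  counts["26", "16"] <- 5L  # K26/D16
  counts["19", "12"] <- 4L  # L19/I12
  counts["34", "23"] <- 3L  # W34/I23
  counts["20", "24"] <- 3L  # A20/A24
  cs <- new("ConsensusContactSet", counts = counts, retained = counts >= 3L,
            threshold = 3L, nMaps = 6L, mapKeys = as.character(1:6))
  cls <- classifyInteractions(cs, topo, referenceOccupancyTable(),
                              hydrophobicSet = c("LEU", "ILE", "TRP"))
  rowFor <- function(p) cls[cls$pair == p, ]
  expect_true(rowFor("K26/D16")$saltBridge)
  expect_true(rowFor("K26/D16")$hydrogenBond)
  expect_false(rowFor("K26/D16")$hydrophobic)
  expect_true(rowFor("L19/I12")$hydrophobic)
  expect_false(rowFor("L19/I12")$saltBridge)
  expect_true(rowFor("W34/I23")$hydrophobic)
  # alanine pair with no registered donor/acceptor and (here) outside the
  # hydrophobic set falls through and is flagged
  expect_true(rowFor("A20/A24")$unclassified)
  # with the default hydrophobic set (alanine included) it classifies
  cls2 <- classifyInteractions(cs, topo, referenceOccupancyTable())
  expect_true(cls2[cls2$pair == "A20/A24", ]$hydrophobic)
})

test_that("atomistic pair maps match the oracle and the schedule geometry", {
  sched <- occupancySchedule("NZ-OD1", "K26/D16", 26, "NZ", "HZ1",
                             "A", 16, "OD1", target = 1)
  traj <- generateTrajectory(trimerAssembly(), nFrames = 10, noiseSigma = 0,
                             schedules = list(sched), seed = 2)
  pm <- atomisticPairMap(traj, list(chain = "C", resno = 26),
                         list(chain = "A", resno = 16))
  expect_equal(pm["NZ", "OD1"], 1)
  far <- atomisticPairMap(traj, list(chain = "C", resno = 40),
                          list(chain = "B", resno = 6))
  expect_true(all(far == 0))
  rnd <- makeRandomTrajectory(7, nRes = 4, nFrames = 6)
  atoms <- atomTable(rnd)
  i1 <- which(atoms$chain == "C" & atoms$resno == 2)
  i2 <- which(atoms$chain == "A" & atoms$resno == 3)
  expect_equal(atomisticPairMap(rnd, list(chain = "C", resno = 2),
                                list(chain = "A", resno = 3), cutoff = 6),
               oracleAtomPairPersistence(rnd, i1, i2, 6), tolerance = 1e-12)
})

test_that("all-atom contact sets grow monotonically with the cutoff", {
  traj <- makeRandomTrajectory(11, nRes = 5, nFrames = 6)
  cuts <- c(2, 3, 5, 8)
  prev <- NULL
  for (cutoff in cuts) {
    cur <- persistence(contactMap(traj, c("C", "A"), "all_atom", cutoff)) > 0
    if (!is.null(prev)) expect_true(all(!prev | cur))
    prev <- cur
  }
})

test_that("persistence is invariant under frame reordering", {
  traj <- makeRandomTrajectory(13, nRes = 4, nFrames = 10)
  set.seed(1)
  perm <- sample(10)
  shuffled <- new("TrajectoryWindow", topology = traj@topology,
                  coords = coords(traj)[, , perm],
                  times = frameTimes(traj), groundTruth = list())
  expect_equal(persistence(contactMap(traj, c("C", "A"), "all_atom")),
               persistence(contactMap(shuffled, c("C", "A"), "all_atom")),
               tolerance = 1e-12)
})

test_that("the kinked bundle engages adaptor A only over the middle region", {
  kinked <- generateTrajectory(trimerAssembly(kink = TRUE), nFrames = 30,
                               seed = 21)
  mapA <- contactMap(kinked, c("C", "A"), "c_alpha")
  mapB <- contactMap(kinked, c("C", "B"), "c_alpha")
  sumA <- middleRegionPersistence(mapA)
  sumB <- middleRegionPersistence(mapB)
  expect_gt(sumA, 0)
  expect_lt(sumB, 0.1 * sumA)

  straight <- generateTrajectory(trimerAssembly(), nFrames = 30, seed = 22)
  sA <- middleRegionPersistence(contactMap(straight, c("C", "A"), "c_alpha"))
  sB <- middleRegionPersistence(contactMap(straight, c("C", "B"), "c_alpha"))
  expect_gt(sB, 0.5 * sA)
  expect_gt(sA, 0.5 * sB)
})
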