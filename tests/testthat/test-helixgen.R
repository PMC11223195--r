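# Synthetic helix/trajectory generator.

test_that("radius-zero helix collapses onto the axis with spacing equal to the rise", {
  h <- buildIdealHelix(helixSpec(5, radius = 0))
  ca <- coords(h)[atomTable(h)$elety == "CA", ]
  d <- sqrt(rowSums(diff(ca)^2))
  expect_equal(d, rep(1.5, 4), tolerance = 1e-12)
  expect_true(all(abs(ca[, 1:2]) < 1e-12))
})

test_that("consecutive C-alpha spacing matches the chord-plus-rise identity", {
  h <- buildIdealHelix(helixSpec(40))
  ca <- coords(h)[atomTable(h)$elety == "CA", ]
  d <- sqrt(rowSums(diff(ca)^2))
  expected <- sqrt(1.5^2 + (2 * 2.3 * sin(50 * pi / 180))^2) # 3.8297777637502834
  expect_equal(d, rep(expected, 39), tolerance = 1e-9)
})

test_that("invalid helix parameters are rejected, naming the violated bound", {
  expect_error(helixSpec(4), "nResidues")
  expect_error(helixSpec(10, rise = 0), "rise")
  expect_error(helixSpec(10, twist = 360), "twist")
  expect_error(helixSpec(10, sequence = "AAA"), "sequence")
})

test_that("four-point angle on generated coordinates matches the dot-product oracle", {
  h <- buildIdealHelix(receptorHelixSpec(), chain = "C", startResno = 14)
  measured <- kinkAngle(h, kinkVectorSpec())
  v1 <- analyticReceptorCA(24) - analyticReceptorCA(20)
  v2 <- analyticReceptorCA(36) - analyticReceptorCA(32)
  expect_equal(measured, oracleAngleDeg(v1, v2), tolerance = 1e-9)
  # frozen oracle value for the straight default helix
  expect_equal(measured, 25.378035502267, tolerance = 1e-9)
})

test_that("zero kink is the identity and opposite kinks cancel", {
  h <- placeSidechainProbes(buildIdealHelix(receptorHelixSpec(),
                                            chain = "C", startResno = 14))
  expect_identical(coords(applyKink(h, kinkSpec(26, 0))), coords(h))
  bent <- applyKink(h, kinkSpec(26, 30, azimuth = 90))
  undone <- applyKink(bent, kinkSpec(26, 30, azimuth = 270))
  expect_equal(coords(undone), coords(h), tolerance = 1e-9)
})

test_that("kink moves only residues beyond the hinge and keeps segments rigid", {
  h <- buildIdealHelix(receptorHelixSpec(), chain = "C", startResno = 14)
  bent <- applyKink(h, kinkSpec(26, 60, azimuth = 135))
  atoms <- atomTable(h)
  lower <- atoms$resno <= 26
  expect_equal(coords(bent)[lower, ], coords(h)[lower, ], tolerance = 1e-12)
  upper <- which(!lower)
  d0 <- as.matrix(dist(coords(h)[upper, ]))
  d1 <- as.matrix(dist(coords(bent)[upper, ]))
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("a programmed 60-degree bend is recovered by the segment-axis fit", {
  h <- buildIdealHelix(receptorHelixSpec(), chain = "C", startResno = 14)
  bent <- applyKink(h, kinkSpec(26, 60, azimuth = 135))
  expect_equal(oracleSegmentAxisAngle(bent, "C", 26), 60, tolerance = 0.5)
})

test_that("hinge residues near the helix ends are rejected", {
  h <- buildIdealHelix(receptorHelixSpec(), chain = "C", startResno = 14)
  expect_error(applyKink(h, kinkSpec(16, 30)), "parameter error")
  expect_error(applyKink(h, kinkSpec(41, 30)), "parameter error")
  expect_error(applyKink(h, kinkSpec(99, 30)), "parameter error")
})

test_that("probe atoms exist at bonded offsets and can be oriented to a stated distance", {
  asm <- trimerAssembly()$assembly
  atoms <- atomTable(asm)
  nz <- coords(asm)[atoms$chain == "C" & atoms$resno == 26 &
                      atoms$elety == "NZ", ]
  caK <- coords(asm)[atoms$chain == "C" & atoms$resno == 26 &
                       atoms$elety == "CA", ]
  expect_equal(sqrt(sum((nz - caK)^2)), 3.4, tolerance = 1e-9)
  for (hz in c("HZ1", "HZ2", "HZ3")) {
    hpos <- coords(asm)[atoms$chain == "C" & atoms$resno == 26 &
                          atoms$elety == hz, ]
    expect_equal(sqrt(sum((hpos - nz)^2)), 1.0, tolerance = 1e-9)
  }
  oriented <- setAtomPairDistance(asm,
                                  a = list(chain = "C", resno = 26, elety = "NZ"),
                                  b = list(chain = "A", resno = 16, elety = "OD1"),
                                  distance = 2.8)
  od1 <- coords(oriented)[atoms$chain == "A" & atoms$resno == 16 &
                            atoms$elety == "OD1", ]
  expect_equal(sqrt(sum((od1 - nz)^2)), 2.8, tolerance = 0.01)
})

test_that("requesting a probe atom on the wrong residue type is a topology error", {
  h <- buildIdealHelix(receptorHelixSpec(), chain = "C", startResno = 14)
  expect_error(
    placeSidechainProbes(h, requests = data.frame(chain = "C", resno = 19,
                                                  elety = "OD1")),
    "topology error")
})

test_that("written structures round-trip through an independent PDB parser", {
  asm <- trimerAssembly()$assembly
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeAssemblyPDB(asm, tmp)
  back <- readTrajectoryPDB(tmp)
  expect_identical(atomTable(back)$elety, atomTable(asm)$elety)
  expect_identical(atomTable(back)$chain, atomTable(asm)$chain)
  expect_identical(atomTable(back)$resno, atomTable(asm)$resno)
  expect_identical(atomTable(back)$resid, atomTable(asm)$resid)
  expect_equal(coords(back)[, , 1], unname(coords(asm)), tolerance = 1e-3)
})

test_that("a quota schedule is satisfied on exactly the target count of frames", {
  sched <- occupancySchedule("NZ-OD1", "K26/D16", 26, "NZ", "HZ1",
                             "A", 16, "OD1", target = 0.6)
  traj <- generateTrajectory(trimerAssembly(), nFrames = 100,
                             noiseSigma = 0, schedules = list(sched),
                             seed = 3)
  mask <- groundTruth(traj)$schedules[[1]]$mask
  expect_identical(sum(mask), 60L)
  dists <- distanceTrace(traj, list(chain = "C", resno = 26, elety = "NZ"),
                         list(chain = "A", resno = 16, elety = "OD1"))
  expect_equal(sum(dists <= 3.0), 60)
  expect_true(all(dists[!mask] > 3.5))
  counts <- hbondCountSeries(traj)$total
  expect_identical(sum(counts), 60L)
})

test_that("zero noise with no schedules reproduces the assembly on every frame", {
  asm <- trimerAssembly()
  traj <- generateTrajectory(asm, nFrames = 5, noiseSigma = 0, seed = 1)
  for (f in 1:5)
    expect_equal(coords(traj)[, , f], unname(coords(asm$assembly)),
                 tolerance = 1e-12)
})

test_that("identical seeds give byte-identical trajectory files", {
  write1 <- function(path) {
    traj <- generateTrajectory(trimerAssembly(kink = TRUE), nFrames = 20,
                               schedules = defaultSchedules("6z0g_TD"),
                               seed = 11)
    writeTrajectoryPDB(traj, path)
  }
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write1(f1); write1(f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("two schedules claiming one acceptor atom are a schedule error", {
  s1 <- occupancySchedule("NZ-OD1", "K26/D16", 26, "NZ", "HZ1",
                          "A", 16, "OD1", target = 0.5)
  s2 <- occupancySchedule("NZ-OD1b", "K26/D16", 26, "NZ", "HZ2",
                          "A", 16, "OD1", target = 0.3)
  expect_error(
    generateTrajectory(trimerAssembly(), nFrames = 10,
                       schedules = list(s1, s2), seed = 1),
    "schedule error")
  expect_error(
    generateTrajectory(trimerAssembly(), nFrames = 10,
                       schedules = list(s1, s1), seed = 1),
    "schedule error")
})
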