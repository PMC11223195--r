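# Geometric hydrogen-bond detection, occupancy and salt bridges.

test_that("the distance and angle criteria gate detection as specified", {
  d <- c(0, 0, 0); h <- c(1, 0, 0)
  expect_true(detectHBond(d, h, c(2.8, 0, 0)))          # 2.8 A, 180 deg
  expect_false(detectHBond(d, h, c(3.2, 0, 0)))         # distance fails
  a120 <- h + 1.8 * c(cos(pi / 3), sin(pi / 3), 0)      # 2.46 A, 120 deg
  expect_false(detectHBond(d, h, a120))                 # angle fails
  # hydrogen-acceptor convention: D-A 3.2 but H-A 2.2 passes
  crit <- hBondCriteria(distanceDefinition = "hydrogen_acceptor")
  expect_true(detectHBond(d, h, c(3.2, 0, 0), crit))
})

test_that("quota schedules yield exact occupancies; absent bonds report zero", {
  sched <- occupancySchedule("NZ-OD1", "K26/D16", 26, "NZ", "HZ1",
                             "A", 16, "OD1", target = 0.6)
  traj <- generateTrajectory(trimerAssembly(), nFrames = 100,
                             schedules = list(sched), seed = 4)
  tab <- occupancy(occupancyTable(traj))
  expect_equal(tab$occupancy[tab$label == "NZ-OD1" & tab$chain == "A"], 60)
  # every unscheduled registry entry stays at zero
  expect_true(all(tab$occupancy[!(tab$label == "NZ-OD1" &
                                    tab$chain == "A")] == 0))
  # both distance conventions agree on schedule-built fixtures
  tab2 <- occupancy(occupancyTable(
    traj, criteria = hBondCriteria(distanceDefinition = "hydrogen_acceptor")))
  expect_equal(tab2$occupancy, tab$occupancy)
})

test_that("Bernoulli schedules are recovered within binomial error", {
  sched <- occupancySchedule("NZ-OD1", "K26/D16", 26, "NZ", "HZ1",
                             "A", 16, "OD1", target = 0.35,
                             mode = "bernoulli")
  traj <- generateTrajectory(trimerAssembly(), nFrames = 2000,
                             schedules = list(sched), seed = 12)
  reg <- defaultRegistry()
  reg <- reg[reg$label == "NZ-OD1" & reg$acceptorChain == "A", ]
  got <- occupancy(occupancyTable(traj, registry = reg))$occupancy
  expect_lt(abs(got - 35), 2 * sqrt(0.35 * 0.65 / 2000) * 100)
})

test_that("aggregate occupancy is the per-label sum with half-up reporting", {
  ref <- referenceOccupancyTable()
  agg <- aggregateOccupancy(ref, "K26/D16", "A", system = "6z0g_TD")
  expect_equal(agg$reported, 79.3)              # 34.74 + 44.57 = 79.31
  expect_equal(agg$raw, 79.31, tolerance = 1e-9)
  expect_false(agg$overcounted)
  expect_true(is.na(agg$union))                 # published table: no frames
  zero <- aggregateOccupancy(ref, "W34/T20", "B", system = "6z0g_TD")
  expect_equal(zero$reported, 0)
  expect_error(aggregateOccupancy(ref, "K99/D16", "A"), "key error")

  # measured tables: aggregate >= each component, union <= raw sum
  s1 <- occupancySchedule("NZ-OD1", "K26/D16", 26, "NZ", "HZ1",
                          "A", 16, "OD1", target = 0.5)
  s2 <- occupancySchedule("NZ-OD2", "K26/D16", 26, "NZ", "HZ2",
                          "A", 16, "OD2", target = 0.4, phase = 0.5)
  traj <- generateTrajectory(trimerAssembly(), nFrames = 200,
                             schedules = list(s1, s2), seed = 14)
  ot <- occupancyTable(traj)
  agg2 <- aggregateOccupancy(ot, "K26/D16", "A")
  comp <- occupancy(ot)
  comp <- comp$occupancy[comp$pair == "K26/D16" & comp$chain == "A"]
  expect_true(all(agg2$raw >= comp - 1e-9))
  expect_lte(agg2$union, agg2$raw + 1e-9)
})

test_that("distance traces match the direct Euclidean oracle", {
  traj <- makeRandomTrajectory(17, nRes = 3, nFrames = 12)
  atoms <- atomTable(traj)
  i <- which(atoms$chain == "C" & atoms$resno == 1 & atoms$elety == "CA")
  j <- which(atoms$chain == "A" & atoms$resno == 2 & atoms$elety == "O")
  expect_equal(distanceTrace(traj, list(chain = "C", resno = 1, elety = "CA"),
                             list(chain = "A", resno = 2, elety = "O")),
               oracleDistanceTrace(traj, i, j), tolerance = 1e-12)
  expect_error(distanceTrace(traj, list(chain = "C", resno = 1, elety = "XX"),
                             list(chain = "A", resno = 2, elety = "O")),
               "selection error")
})

test_that("per-frame bond counts follow the schedules and the oracle", {
  s1 <- occupancySchedule("NZ-OD1", "K26/D16", 26, "NZ", "HZ1",
                          "A", 16, "OD1", target = 1)
  s2 <- occupancySchedule("NZ-OD2", "K26/D16", 26, "NZ", "HZ2",
                          "B", 16, "OD2", target = 1)
  traj <- generateTrajectory(trimerAssembly(), nFrames = 25,
                             schedules = list(s1, s2), seed = 15)
  expect_identical(hbondCountSeries(traj)$total, rep(2L, 25))
  none <- generateTrajectory(trimerAssembly(), nFrames = 10, seed = 16)
  expect_identical(hbondCountSeries(none)$total, rep(0L, 10))

  rnd <- makeRandomTrajectory(19, nRes = 5, nFrames = 10)
  reg <- randomFixtureRegistry(5)
  expect_identical(hbondCountSeries(rnd, registry = reg)$total,
                   oracleHbondCounts(rnd, reg))
})

test_that("occupancies are invariant under frame reordering and rigid motion", {
  s1 <- occupancySchedule("NZ-OD1", "K26/D16", 26, "NZ", "HZ1",
                          "A", 16, "OD1", target = 0.4)
  traj <- generateTrajectory(trimerAssembly(), nFrames = 50,
                             schedules = list(s1), seed = 18)
  base <- occupancy(occupancyTable(traj))$occupancy
  set.seed(2)
  perm <- sample(50)
  shuffled <- new("TrajectoryWindow", topology = traj@topology,
                  coords = coords(traj)[, , perm],
                  times = frameTimes(traj), groundTruth = list())
  expect_equal(occupancy(occupancyTable(shuffled))$occupancy, base)
  moved <- applyRigidMotion(traj, randomRotation(3), c(8, -4, 12))
  expect_equal(occupancy(occupancyTable(moved))$occupancy, base,
               tolerance = 1e-9)
})

test_that("a negligible angle cutoff reduces detection to the distance test", {
  rnd <- makeRandomTrajectory(23, nRes = 4, nFrames = 20)
  crit <- hBondCriteria(distanceCutoff = 3, angleCutoff = 1e-9,
                        distanceDefinition = "hydrogen_acceptor")
  reg <- randomFixtureRegistry(4)[1, ]
  sat <- hbondCountSeries(rnd, registry = reg, criteria = crit)$total == 1
  dists <- distanceTrace(rnd, list(chain = "C", resno = 1, elety = "HB"),
                         list(chain = "A", resno = 1, elety = "O"))
  expect_identical(sat, dists <= 3)
})

test_that("salt-bridge occupancy brackets the hydrogen-bond occupancy", {
  s1 <- occupancySchedule("NZ-OD2", "K26/D16", 26, "NZ", "HZ2",
                          "A", 16, "OD2", target = 1)
  traj <- generateTrajectory(trimerAssembly(), nFrames = 20,
                             schedules = list(s1), seed = 24)
  basic <- data.frame(chain = "C", resno = 26, elety = "NZ")
  acidic <- data.frame(chain = "A", resno = 16, elety = c("OD1", "OD2"))
  expect_equal(saltBridgeOccupancy(traj, basic, acidic), 100)
  farAcidic <- data.frame(chain = "B", resno = 16, elety = c("OD1", "OD2"))
  expect_equal(saltBridgeOccupancy(traj, basic, farAcidic), 0)
  expect_error(saltBridgeOccupancy(traj, basic[0, ], acidic),
               "selection error")

  # partial schedule: hydrogen-bond frames are a subset of salt-bridge frames
  s2 <- occupancySchedule("NZ-OD2", "K26/D16", 26, "NZ", "HZ2",
                          "A", 16, "OD2", target = 0.45)
  traj2 <- generateTrajectory(trimerAssembly(), nFrames = 200,
                              schedules = list(s2), seed = 25)
  hb <- occupancy(occupancyTable(traj2))
  hb <- hb$occupancy[hb$label == "NZ-OD2" & hb$chain == "A"]
  expect_gte(saltBridgeOccupancy(traj2, basic, acidic), hb)
})
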