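# Independent brute-force oracles and fixture builders. These deliberately
# use naive loops and direct formulas, not the package's vectorized code
# paths.

oracleAngleDeg <- function(v1, v2) {
  acos(max(-1, min(1, sum(v1 * v2) /
                     (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
}

## analytic C-alpha position of the default receptor helix (chain C,
## residues 14-43, 2.3 A radius, 1.5 A rise, 100 deg twist)
analyticReceptorCA <- function(resno, start = 14, r = 2.3, rise = 1.5,
                               twist = 100) {
  i <- resno - start
  ph <- i * twist * pi / 180
  c(r * cos(ph), r * sin(ph), i * rise)
}

## principal-axis fit of each C-alpha segment flanking the hinge; axes
## oriented N-to-C so the angle between them is the bend
oracleSegmentAxisAngle <- function(assembly, chain, hinge) {
  atoms <- atomTable(assembly)
  xyz <- coords(assembly)
  sel <- which(atoms$chain == chain & atoms$elety == "CA")
  resno <- atoms$resno[sel]
  axisOf <- function(m) {
    v <- prcomp(m)$rotation[, 1]
    if (sum((m[nrow(m), ] - m[1, ]) * v) < 0) v <- -v
    v
  }
  a <- axisOf(xyz[sel[resno <= hinge], , drop = FALSE])
  b <- axisOf(xyz[sel[resno > hinge], , drop = FALSE])
  oracleAngleDeg(a, b)
}

## residue-level contact persistence by exhaustive double loop
oracleContactPersistence <- function(traj, chainPair, level, cutoff) {
  atoms <- atomTable(traj)
  cc <- coords(traj)
  nf <- dim(cc)[3]
  pick <- function(ch) {
    idx <- which(atoms$chain == ch)
    if (level == "c_alpha") idx <- idx[atoms$elety[idx] == "CA"]
    idx
  }
  i1 <- pick(chainPair[1]); i2 <- pick(chainPair[2])
  res1 <- sort(unique(atoms$resno[i1]))
  res2 <- sort(unique(atoms$resno[i2]))
  out <- matrix(0, length(res1), length(res2),
                dimnames = list(res1, res2))
  for (a in seq_along(res1)) for (b in seq_along(res2)) {
    ia <- i1[atoms$resno[i1] == res1[a]]
    ib <- i2[atoms$resno[i2] == res2[b]]
    hits <- 0
    for (f in seq_len(nf)) {
      mind <- Inf
      for (x in ia) for (y in ib) {
        d <- sqrt(sum((cc[x, , f] - cc[y, , f])^2))
        if (d < mind) mind <- d
      }
      if (mind <= cutoff) hits <- hits + 1
    }
    out[a, b] <- hits / nf
  }
  out
}

oracleAtomPairPersistence <- function(traj, i1, i2, cutoff) {
  atoms <- atomTable(traj)
  cc <- coords(traj)
  nf <- dim(cc)[3]
  out <- matrix(0, length(i1), length(i2),
                dimnames = list(atoms$elety[i1], atoms$elety[i2]))
  for (a in seq_along(i1)) for (b in seq_along(i2)) {
    hits <- 0
    for (f in seq_len(nf))
      if (sqrt(sum((cc[i1[a], , f] - cc[i2[b], , f])^2)) <= cutoff)
        hits <- hits + 1
    out[a, b] <- hits / nf
  }
  out
}

oracleDistanceTrace <- function(traj, i, j) {
  cc <- coords(traj)
  vapply(seq_len(dim(cc)[3]), function(f)
    sqrt(sum((cc[i, , f] - cc[j, , f])^2)), numeric(1))
}

## per-frame hydrogen-bond count by explicit enumeration over registry rows
oracleHbondCounts <- function(traj, registry, distCut = 3, angCut = 150,
                              definition = "donor_acceptor") {
  atoms <- atomTable(traj)
  cc <- coords(traj)
  nf <- dim(cc)[3]
  roles <- chainRoles(traj)
  dch <- names(roles)[roles == "receptor"]
  idx <- function(ch, rn, at) which(atoms$chain == ch & atoms$resno == rn &
                                      atoms$elety == at)
  counts <- integer(nf)
  for (f in seq_len(nf)) {
    n <- 0L
    for (k in seq_len(nrow(registry))) {
      r <- registry[k, ]
      di <- idx(dch, r$donorResno, r$donorAtom)
      ai <- idx(r$acceptorChain, r$acceptorResno, r$acceptorAtom)
      ok <- FALSE
      for (hh in strsplit(r$hydrogens, ",")[[1]]) {
        hi <- idx(dch, r$donorResno, hh)
        d <- cc[di, , f]; h <- cc[hi, , f]; a <- cc[ai, , f]
        dist <- if (definition == "donor_acceptor")
          sqrt(sum((d - a)^2)) else sqrt(sum((h - a)^2))
        ang <- oracleAngleDeg(d - h, a - h)
        if (dist <= distCut && ang >= angCut) { ok <- TRUE; break }
      }
      if (ok) n <- n + 1L
    }
    counts[f] <- n
  }
  counts
}

## random three-chain fixture with generic atoms (chain C carries a
## donor/hydrogen pair per residue, chains A/B an acceptor)
makeRandomTrajectory <- function(seed, nRes = 6, nFrames = 15, box = 12) {
  set.seed(seed)
  mk <- function(chain, names) {
    do.call(rbind, lapply(seq_len(nRes), function(r)
      data.frame(elety = names, resid = "ALA", chain = chain, resno = r,
                 stringsAsFactors = FALSE)))
  }
  atoms <- rbind(mk("C", c("CA", "CB", "HB")),
                 mk("A", c("CA", "O")), mk("B", c("CA", "O")))
  atoms$eleno <- seq_len(nrow(atoms))
  atoms <- atoms[, c("eleno", "elety", "resid", "chain", "resno")]
  cc <- array(runif(nrow(atoms) * 3 * nFrames, 0, box),
              dim = c(nrow(atoms), 3, nFrames))
  new("TrajectoryWindow", topology = complexTopology(atoms),
      coords = cc, times = seq_len(nFrames) - 1, groundTruth = list())
}

## registry matching makeRandomTrajectory's atom names
randomFixtureRegistry <- function(nRes = 6) {
  data.frame(pair = paste0("C", seq_len(nRes), "/A", seq_len(nRes)),
             label = "CB-O", donorResno = seq_len(nRes), donorAtom = "CB",
             hydrogens = "HB", acceptorResno = seq_len(nRes),
             acceptorAtom = "O", acceptorChain = "A",
             stringsAsFactors = FALSE)
}

randomRotation <- function(seed) {
  set.seed(seed)
  qr0 <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr0)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## apply a rigid motion to every frame of a trajectory
applyRigidMotion <- function(traj, R, shift) {
  cc <- coords(traj)
  for (f in seq_len(dim(cc)[3]))
    cc[, , f] <- cc[, , f] %*% t(R) +
      matrix(shift, dim(cc)[1], 3, byrow = TRUE)
  new("TrajectoryWindow", topology = traj@topology, coords = cc,
      times = frameTimes(traj), groundTruth = groundTruth(traj))
}

## small straight trimer trajectory cache for cheap tests
straightTrimerTraj <- local({
  cache <- NULL
  function(nFrames = 40, seed = 42, schedules = list(), noise = 0.15) {
    generateTrajectory(trimerAssembly(), nFrames = nFrames,
                       noiseSigma = noise, schedules = schedules,
                       seed = seed)
  }
})
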