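# independent two-test evaluation of a D-H...A geometry
bruteHBond <- function(D, H, A, maxD = 2.5, minA = 120) {
  ha <- sqrt(sum((H - A)^2))
  v1 <- D - H; v2 <- A - H
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  ha <= maxD && ang >= minA
}

test_that("hydrogen bonds follow the Baker-Hubbard two-test rule", {
  mkTriple <- function(dHA, angle) {
    th <- angle * pi / 180
    D <- c(0, 0, 0); H <- c(1, 0, 0)
    A <- H + dHA * c(-cos(th), sin(th), 0)
    at <- simpleAtoms(3, element = c("N", "H", "O"),
                      residue = c(1, 1, 5), name = c("N", "H", "O"))
    list(traj = makeTraj(at, list(rbind(D, H, A))), D = D, H = H, A = A)
  }
  g <- mkTriple(2.0, 180)
  ev <- detectHBonds(g$traj, triples = data.frame(d = 1, h = 2, a = 3))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$distance, 2.0, tolerance = 1e-9)
  expect_equal(ev$angle, 180, tolerance = 1e-6)

  far <- mkTriple(3.5, 180)
  expect_equal(nrow(detectHBonds(far$traj,
                                 triples = data.frame(d = 1, h = 2, a = 3))), 0)

  # randomized geometries agree with brute-force evaluation
  set.seed(7)
  for (k in 1:50) {
    dHA <- runif(1, 1.2, 4); ang <- runif(1, 60, 180)
    g <- mkTriple(dHA, ang)
    got <- nrow(detectHBonds(g$traj,
                             triples = data.frame(d = 1, h = 2, a = 3))) == 1
    expect_equal(got, bruteHBond(g$D, g$H, g$A))
  }

  # auto-resolved donor triples from a topology with hydrogens
  toy <- genToyComplex(F = 1, hbondGeometry = c(2, 180), seed = 1)
  evAuto <- detectHBonds(toy$trajectory)
  expect_equal(nrow(evAuto), 1)
  expect_error(detectHBonds(makeTraj(simpleAtoms(2),
                                     list(matrix(0, 2, 3)))),
               "triples")
})

test_that("pi-pi detection uses ring-COM distance and folded normal angle", {
  mk <- function(d, ang) genToyComplex(F = 1, ringGeometry = c(d, ang),
                                       seed = 1)
  ev <- detectPiPi(mk(4, 0)$trajectory, mk(4, 0)$rings)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$distance, 4, tolerance = 1e-9)
  expect_equal(ev$angle, 0, tolerance = 1e-6)
  # perpendicular rings fail the default 30-degree test
  expect_equal(nrow(detectPiPi(mk(4, 90)$trajectory, mk(4, 90)$rings)), 0)
  # near-parallel via the fold: 170 degrees between normals counts as 10
  ev2 <- detectPiPi(mk(4, 170)$trajectory, mk(4, 170)$rings)
  expect_equal(ev2$angle, 10, tolerance = 1e-6)
  # degenerate ring skipped with a warning
  at <- simpleAtoms(12, residue = c(rep(1, 6), rep(5, 6)),
                    name = paste0("C", 1:12))
  xyz <- rbind(cbind(seq(0, 5, length.out = 6), 0, 0),       # collinear
               cbind(1.39 * cos(0:5 * pi / 3) + 10,
                     1.39 * sin(0:5 * pi / 3), 0))
  tr <- makeTraj(at, list(xyz))
  rings <- list(ringDefinition(1, "A", 1:6), ringDefinition(5, "A", 7:12))
  expect_warning(ev3 <- detectPiPi(tr, rings), "degenerate")
  expect_equal(nrow(ev3), 0)
})

test_that("XH-ring detection applies the distance and angle tests by donor element", {
  toy <- genToyComplex(F = 1, xhGeometry = c(3.5, 170), seed = 1)
  ev <- detectXHRing(toy$trajectory, toy$rings, xhPairs = toy$xhPairs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "ch_ring")
  expect_equal(ev$distance, 3.5, tolerance = 1e-9)
  expect_equal(ev$angle, 170, tolerance = 1e-4)
  bad <- genToyComplex(F = 1, xhGeometry = c(3.5, 90), seed = 1)
  expect_equal(nrow(detectXHRing(bad$trajectory, bad$rings,
                                 xhPairs = bad$xhPairs)), 0)
})

test_that("every emitted event re-satisfies its own criteria", {
  crit <- geomCriteria()
  toy <- genToyComplex(F = 15, sigma = 0.25, ringGeometry = c(5.3, 25),
                       hbondGeometry = c(2.4, 125), xhGeometry = c(4.3, 125),
                       seed = 31)
  ev <- rbind(detectPiPi(toy$trajectory, toy$rings, crit),
              detectHBonds(toy$trajectory, crit, toy$hbondTriples),
              detectXHRing(toy$trajectory, toy$rings, crit,
                           xhPairs = toy$xhPairs))
  expect_gt(nrow(ev), 0)
  ok <- with(ev, ifelse(type == "pipi",
                        distance <= crit$pipi$maxDist & angle <= crit$pipi$maxAngle,
                 ifelse(type == "hbond",
                        distance <= crit$hbond$maxDist & angle >= crit$hbond$minAngle,
                        distance <= crit$xhRing$maxDist & angle >= crit$xhRing$minAngle)))
  expect_true(all(ok))
})

test_that("interaction counts equal a brute-force group-by", {
  ev <- data.frame(
    frame = c(7, 7, 7, 2, 2, 9),
    type = c("pipi", "pipi", "pipi", "hbond", "pipi", "hbond"),
    res_i = c(89, 89, 89, 89, 3, 12), chain_i = "L",
    res_j = c(30, 31, 32, 50, 4, 89), chain_j = "G",
    atoms = "x", distance = 3, angle = 150, stringsAsFactors = FALSE)
  ci <- countInteractions(ev, 89, nFrames = 10)
  expect_equal(ci$counts$pipi[7], 3)
  expect_equal(ci$counts$hbond[c(2, 9)], c(1, 1))
  expect_equal(sum(ci$counts$pipi), 3)
  none <- countInteractions(ev[0, ], 89, nFrames = 5)
  expect_equal(nrow(none$summary), 0)

  set.seed(41)
  rnd <- data.frame(frame = sample(20, 200, TRUE),
                    type = sample(c("pipi", "hbond", "ch_ring"), 200, TRUE),
                    res_i = sample(5, 200, TRUE), chain_i = "A",
                    res_j = sample(5, 200, TRUE), chain_j = "B",
                    atoms = "x", distance = 3, angle = 150,
                    stringsAsFactors = FALSE)
  ci2 <- countInteractions(rnd, 3, nFrames = 20)
  for (tp in unique(rnd$type)) {
    brute <- sapply(1:20, function(f)
      sum(rnd$frame == f & rnd$type == tp &
            (rnd$res_i == 3 | rnd$res_j == 3)))
    expect_equal(ci2$counts[[tp]], brute)
  }
})

test_that("network frequencies count frame presence, not event multiplicity", {
  ev <- data.frame(
    frame = c(1:50, 5, 5, 5, 1:5),
    type = c(rep("pipi", 50), rep("pipi", 3), rep("hbond", 5)),
    res_i = 10, chain_i = "H", res_j = 20, chain_j = "L",
    atoms = "x", distance = 3, angle = 150, stringsAsFactors = FALSE)
  net <- buildNetwork(ev, nFrames = 100)
  e <- edges(net)
  expect_equal(e$frequency[e$type == "pipi"], 0.5)  # duplicates ignored
  # 5/100 < 0.1 -> hbond edge dropped
  expect_false("hbond" %in% e$type)
  expect_true("hbond" %in% edges(buildNetwork(ev, 100, minFrequency = 0.01))$type)

  # random event set: frequencies equal a brute-force tally
  set.seed(13)
  rnd <- data.frame(frame = sample(40, 300, TRUE), type = "pipi",
                    res_i = sample(4, 300, TRUE), chain_i = "A",
                    res_j = sample(4, 300, TRUE), chain_j = "B",
                    atoms = "x", distance = 3, angle = 150,
                    stringsAsFactors = FALSE)
  net2 <- buildNetwork(rnd, 40, minFrequency = 0)
  e2 <- edges(net2)
  for (k in seq_len(nrow(e2))) {
    ri <- as.integer(sub("A:", "", e2$res_i[k]))
    rj <- as.integer(sub("B:", "", e2$res_j[k]))
    brute <- length(unique(rnd$frame[rnd$res_i == ri & rnd$res_j == rj]))
    expect_equal(e2$frequency[k], brute / 40)
  }
})

test_that("network differencing joins edge unions and flags perturbed residues", {
  ev <- function(res_j, frames) data.frame(
    frame = frames, type = "pipi", res_i = 1, chain_i = "H",
    res_j = res_j, chain_j = "L", atoms = "x", distance = 3, angle = 150,
    stringsAsFactors = FALSE)
  netA <- buildNetwork(ev(2, 1:80), 100)
  netB <- buildNetwork(ev(2, 1:50), 100)
  # identical networks -> all zero deltas, empty perturbed set
  d0 <- diffNetwork(netA, netA)
  expect_true(all(d0$edges$delta == 0))
  expect_length(d0$perturbedResidues, 0)
  # edge only in the reference at 0.8 -> delta -0.8, both endpoints perturbed
  dEmpty <- diffNetwork(netA, buildNetwork(ev(2, 1)[0, ], 100))
  expect_equal(dEmpty$edges$delta, -0.8)
  expect_setequal(dEmpty$perturbedResidues, c("H:1", "L:2"))
  # antisymmetric under argument swap
  dAB <- diffNetwork(netA, netB); dBA <- diffNetwork(netB, netA)
  expect_equal(dAB$edges$delta, -dBA$edges$delta)
  # topology mismatch is refused
  netT1 <- buildNetwork(ev(2, 1:10), 100, topologyId = "sysA")
  netT2 <- buildNetwork(ev(2, 1:10), 100, topologyId = "sysB")
  expect_error(diffNetwork(netT1, netT2), "different topologies")
})
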