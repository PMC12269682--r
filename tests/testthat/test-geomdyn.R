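test_that("center of mass matches weighted-mean oracles", {
  at <- simpleAtoms(2)
  tr <- makeTraj(at, list(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)))
  com <- centerOfMass(tr, comSelection("both", 1:2))
  expect_equal(unname(com[1, ]), c(1, 0, 0))

  at2 <- simpleAtoms(2)
  at2$mass <- c(1, 3)
  tr2 <- makeTraj(at2, list(matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE)))
  expect_equal(unname(centerOfMass(tr2, comSelection("w", 1:2))[1, 1]), 3)

  # 50 random atoms: equals sum(m r) / sum(m) within 1e-10
  set.seed(4)
  at3 <- simpleAtoms(50)
  at3$mass <- runif(50, 1, 30)
  xyz <- matrix(rnorm(150, sd = 10), 50, 3)
  tr3 <- makeTraj(at3, list(xyz))
  got <- centerOfMass(tr3, comSelection("all", 1:50))[1, ]
  expect_equal(unname(got), colSums(xyz * at3$mass) / sum(at3$mass),
               tolerance = 1e-10)
})

test_that("COM distances, angles and RMSD behave on constructed geometries", {
  at <- simpleAtoms(2)
  tr <- makeTraj(at, list(matrix(c(0, 0, 0, 3, 4, 0), 2, 3, byrow = TRUE)))
  d <- comDistanceSeries(tr, comSelection("a", 1L), comSelection("b", 2L))
  expect_equal(d$value, 5)
  expect_equal(comDistanceSeries(tr, comSelection("a", 1:2),
                                 comSelection("b", 1:2))$value, 0)

  at3 <- simpleAtoms(3)
  tr3 <- makeTraj(at3, list(matrix(c(1, 0, 0, 0, 0, 0, 0, 1, 0), 3, 3,
                                   byrow = TRUE)))
  a <- vhVlAngleSeries(tr3, comSelection("cdrl", 1L), comSelection("vl", 2L),
                       comSelection("vh", 3L))
  expect_equal(a$value, 90)
  trCol <- makeTraj(at3, list(matrix(c(-1, 0, 0, 0, 0, 0, 2, 0, 0), 3, 3,
                                     byrow = TRUE)))
  expect_equal(vhVlAngleSeries(trCol, comSelection("a", 1L),
                               comSelection("b", 2L),
                               comSelection("c", 3L))$value, 180)
})

test_that("COM descriptors are invariant to rigid motion of every frame", {
  toy <- genToyComplex(F = 10, sigma = 0.3, seed = 12)
  tr <- toy$trajectory
  sel <- toy$selections
  d0 <- comDistanceSeries(tr, sel$CDR, sel$antigen)$value
  a0 <- vhVlAngleSeries(tr, sel$CDRL, sel$VL, sel$VH)$value
  v0 <- vhVlDistanceSeries(tr, sel$VH, sel$VL)$value
  set.seed(33)
  for (k in 1:5) {
    tr2 <- applyRigid(tr, randomRotation(), rnorm(3, sd = 50))
    expect_equal(comDistanceSeries(tr2, sel$CDR, sel$antigen)$value, d0,
                 tolerance = 1e-9)
    expect_equal(vhVlAngleSeries(tr2, sel$CDRL, sel$VL, sel$VH)$value, a0,
                 tolerance = 1e-9)
    expect_equal(vhVlDistanceSeries(tr2, sel$VH, sel$VL)$value, v0,
                 tolerance = 1e-9)
  }
})

test_that("RMSD after superposition is zero on self and matches closed forms", {
  toy <- genToyComplex(F = 3, sigma = 0, seed = 6)
  sel <- comSelection("all", seq_len(nAtoms(toy$trajectory)))
  r <- rmsdSeries(toy$trajectory, toy$structure, sel)
  expect_equal(r$value, rep(0, 3), tolerance = 1e-6)

  # translated copy -> 0 after superposition
  tr2 <- applyRigid(toy$trajectory, diag(3), c(5, 5, 5))
  expect_equal(rmsdSeries(tr2, toy$structure, sel)$value, rep(0, 3),
               tolerance = 1e-6)

  # 4 atoms, one displaced by 2 A in a way that cannot be absorbed by any
  # rigid motion of the mirror-symmetric base: compare to bio3d as an
  # independent implementation
  at <- simpleAtoms(4)
  base <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0, 10, 10, 0), 4, 3,
                 byrow = TRUE)
  moved <- base
  moved[4, 3] <- moved[4, 3] + 2
  ref <- new("Structure", atoms = at, coords = base)
  tr4 <- makeTraj(at, list(moved))
  got <- rmsdSeries(tr4, ref, comSelection("all", 1:4))$value
  oracle <- bio3d::rmsd(as.vector(t(base)), as.vector(t(moved)),
                        fit = TRUE)  # bio3d rounds to 3 decimals
  expect_lt(abs(got - oracle), 5.1e-4)

  # symmetric under exchanging frame and reference
  ref2 <- new("Structure", atoms = at, coords = moved)
  tr5 <- makeTraj(at, list(base))
  expect_equal(rmsdSeries(tr5, ref2, comSelection("all", 1:4))$value, got,
               tolerance = 1e-9)
})

test_that("native contacts equal brute-force enumeration with the exclusion rule", {
  set.seed(14)
  n <- 30
  at <- simpleAtoms(n, residue = rep(1:10, each = 3),
                    name = paste0("C", 1:n))
  at$element[seq(3, n, 3)] <- "H"  # hydrogens must be ignored
  xyz <- matrix(runif(n * 3, 0, 12), n, 3)
  s <- new("Structure", atoms = at, coords = xyz)
  cs <- nativeContacts(s, cutoff = 4.5, exclusion = 3)
  # O(n^2) brute force
  brute <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (at$element[i] == "H" || at$element[j] == "H") next
    dres <- abs(at$residue_index[i] - at$residue_index[j])
    if (dres < 3) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 4.5) brute <- brute + 1
  }
  expect_equal(nrow(contactPairs(cs)), brute)
  expect_true(all(contactPairs(cs)$ref_dist <= 4.5))

  # inclusion/exclusion on constructed pairs
  at2 <- simpleAtoms(2, residue = c(1, 11), name = c("CA", "CA"))
  s2 <- new("Structure", atoms = at2,
            coords = matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(nrow(contactPairs(nativeContacts(s2))), 1)
  at3 <- simpleAtoms(2, residue = c(1, 2), name = c("CA", "CA"))
  s3 <- new("Structure", atoms = at3,
            coords = matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(nrow(contactPairs(nativeContacts(s3))), 0)
})

test_that("contact retention tracks constructed contact breaking", {
  toy <- genToyComplex(F = 4, sigma = 0, seed = 2)
  # the toy lattice spacing is 5 A, so a 5.5 A cutoff captures row contacts
  cs <- nativeContacts(toy$structure, cutoff = 5.5)
  ret <- contactRetention(toy$trajectory, cs)
  expect_true(all(ret$retained_fraction == 1))

  # exploded coordinates -> all fractions 0
  tr <- toy$trajectory
  co <- coords(tr)
  for (f in seq_len(dim(co)[1])) co[f, , ] <- co[f, , ] * 3
  boom <- new("Trajectory", topology = atoms(tr), coords = co,
              frameTimes = frameTimes(tr))
  expect_true(all(contactRetention(boom, cs)$retained_fraction == 0))

  # one residue with exactly half its contacts broken
  at <- simpleAtoms(5, residue = c(1, 5, 5, 9, 13),
                    name = c("CA", "CA", "CB", "CA", "CA"))
  xyz <- matrix(c(0, 0, 0,  3, 0, 0,  3, 1.4, 0,  6, 0, 0,  30, 0, 0),
                5, 3, byrow = TRUE)
  s <- new("Structure", atoms = at, coords = xyz)
  cs2 <- nativeContacts(s, cutoff = 4.5, exclusion = 3)
  # residue 5 (atoms 2,3) contacts residues 1 and 9
  moved <- xyz
  moved[1, 1] <- -20  # break contacts with residue 1 only
  tr2 <- makeTraj(at, list(moved))
  ret2 <- contactRetention(tr2, cs2)
  r5 <- ret2$retained_fraction[ret2$residue == 5]
  expect_equal(r5, 0.5)
})

test_that("unbinding detection flags sustained excursions only", {
  expect_false(detectUnbinding(rep(10, 200))$flag)

  step <- c(rep(10, 99), rep(30, 901))
  call <- detectUnbinding(step, baselineWindow = 50)
  expect_true(call$flag)
  expect_equal(call$onset_frame, 100L)

  spike <- rep(10, 500); spike[200:220] <- 40; spike[221:500] <- 9.9
  expect_false(detectUnbinding(spike, baselineWindow = 50)$flag)

  # monotone in factor: raising factor never turns a false call true
  set.seed(19)
  for (k in 1:20) {
    v <- 10 + cumsum(rnorm(300, sd = 0.3))
    v <- abs(v)
    flags <- sapply(c(1.2, 1.5, 2, 3), function(f)
      detectUnbinding(v, baselineWindow = 15, factor = f)$flag)
    expect_true(all(diff(as.integer(flags)) <= 0))
  }
  expect_error(detectUnbinding(c(1, NA, 3)), "non-finite")
})
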