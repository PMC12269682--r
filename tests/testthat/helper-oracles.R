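# Independent oracles and small fixture builders used across tests.

# wild-type rank by explicit sort-free counting (the documented convention)
bruteRank <- function(row, wtIdx) 1L + sum(row > row[wtIdx])

# plug-in MI by direct double loop over the joint table (bits)
bruteMI <- function(x, y) {
  xs <- unique(x); ys <- unique(y)
  n <- length(x)
  mi <- 0
  for (a in xs) for (b in ys) {
    pxy <- sum(x == a & y == b) / n
    if (pxy > 0) mi <- mi + pxy * log2(pxy / ((sum(x == a) / n) * (sum(y == b) / n)))
  }
  mi
}

# apply one rigid motion (rotation R, translation t) to every frame
applyRigid <- function(traj, R, t) {
  co <- coords(traj)
  for (f in seq_len(dim(co)[1]))
    co[f, , ] <- sweep(matrix(co[f, , ], ncol = 3) %*% t(R), 2, t, `+`)
  new("Trajectory", topology = atoms(traj), coords = co,
      frameTimes = frameTimes(traj))
}

randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# minimal single-frame trajectory from an atom table + coordinates
makeTraj <- function(at, xyzList) {
  F <- length(xyzList)
  co <- array(NA_real_, dim = c(F, nrow(at), 3))
  for (f in seq_len(F)) co[f, , ] <- xyzList[[f]]
  new("Trajectory", topology = at, coords = co,
      frameTimes = as.numeric(seq_len(F) - 1))
}

simpleAtoms <- function(n, element = "C", chain = "A",
                        residue = seq_len(n), name = NULL) {
  if (is.null(name)) name <- paste0("C", seq_len(n))
  data.frame(atom_id = seq_len(n), atom_name = name, element = element,
             residue_index = residue, residue_name = "ALA",
             chain_id = chain,
             mass = ifelse(element == "H", 1.008, 12.011),
             stringsAsFactors = FALSE)
}

# 2-fragment MIMatrix with a single pair value (for diffCoupling tests)
makeMIM <- function(v) {
  m <- matrix(c(NA, v, v, NA), 2, 2)
  new("MIMatrix", values = m, fragments = 1:2, nFramesUsed = 100L)
}

# exhaustive 3v3 replica-label permutation p on |mean difference|
brutePermP <- function(b, u) {
  pool <- c(b, u)
  combos <- combn(6, 3, simplify = FALSE)
  obs <- abs(mean(b) - mean(u))
  stats <- sapply(combos, function(a) abs(mean(pool[a]) - mean(pool[-a])))
  mean(stats >= obs - 1e-12)
}

regionMapVH <- function() {
  loadRegionMap(system.file("extdata", "region_map_vh.tsv",
                            package = "fwdyn"))
}
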