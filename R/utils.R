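# Internal helpers shared across modules.

# Standard atomic masses (Da) for elements seen in protein/ligand PDB files.
.ATOMIC_MASS <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  "NA" = 22.990, K = 39.098, MG = 24.305, CA = 40.078, MN = 54.938,
  FE = 55.845, CO = 58.933, NI = 58.693, CU = 63.546, ZN = 65.38,
  SE = 78.971
)

.elementMass <- function(element) {
  el <- toupper(trimws(element))
  m <- .ATOMIC_MASS[el]
  if (anyNA(m)) {
    bad <- unique(el[is.na(m)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            "; assigning carbon mass", call. = FALSE)
    m[is.na(m)] <- .ATOMIC_MASS[["C"]]
  }
  unname(m)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stable per-component offset so adding generator outputs never reshuffles
# existing ones: each component draws from seed + offset, both < 2^31.
.derivedSeed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Minimum RMSD between two n x 3 point sets after optimal rigid superposition
# (Kabsch, reflections disallowed), unweighted.
.kabschRMSD <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y))
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(crossprod(Yc, Xc))
  d <- sign(det(s$u %*% t(s$v)))
  # e2: residual sum of squares after rotation, guarded against tiny negatives
  e2 <- sum(Xc^2) + sum(Yc^2) - 2 * sum(s$d * c(1, 1, d))
  sqrt(max(e2, 0) / nrow(X))
}

# Rotation matrix superposing Y onto X (used where aligned coordinates are
# needed, not just the RMSD).
.kabschRotation <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(crossprod(Yc, Xc))
  d <- sign(det(s$u %*% t(s$v)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

# Uniformly random rotation matrix (QR of a Gaussian matrix, det +1).
.randomRotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

.angleDeg <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9) return(NA_real_)
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

.AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.AA321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

.aa321 <- function(resid3) {
  out <- .AA321[toupper(trimws(resid3))]
  out[is.na(out)] <- "X"
  unname(out)
}
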