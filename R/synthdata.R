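#' @include AllClasses.R
NULL

#' Analytic mutual information of the coupling channel (bits)
#'
#' For the generator's coupling channel — y equals x with probability s and
#' is otherwise uniform over M states, x uniform — the joint distribution is
#' p(x, y) = (1/M) (s 1[y = x] + (1 - s)/M), and this returns its exact MI.
#'
#' @param s coupling strength in [0, 1].
#' @param M number of states.
#' @return MI in bits.
#' @export
analyticChannelMI <- function(s, M) {
  stopifnot(s >= 0, s <= 1, M >= 2)
  pSame <- (s + (1 - s) / M) / M   # joint mass of each (x, x)
  pDiff <- (1 - s) / M^2           # joint mass of each (x, y != x)
  px <- 1 / M
  term <- function(p) if (p > 0) p * log2(p / (px * px)) else 0
  M * term(pSame) + M * (M - 1) * term(pDiff)
}

#' Generate bound/unbound structural-alphabet state sequences
#'
#' Uncoupled fragments are i.i.d. uniform over M states in every frame. A
#' coupled pair (i, j, condition, strength s) overwrites fragment j so that,
#' frame-wise, it copies fragment i with probability s and is uniform
#' otherwise — only in the designated condition ("bound", "unbound" or
#' "both"). The ground-truth record carries the exact channel MI of every
#' injected coupling. Bit-reproducible under a fixed seed.
#'
#' @param nFragments fragments per replica.
#' @param M alphabet cardinality.
#' @param F frames per replica.
#' @param replicas replicas per condition.
#' @param coupledPairs data.frame(i, j, condition, strength) or NULL.
#' @param seed RNG seed.
#' @return list(bound, unbound) of per-replica \linkS4class{StateEncoding}
#'   lists, plus \code{groundTruth} (analytic channel MI per injected pair
#'   and, for pairs coupled in both conditions, the analytic log2 MI ratio).
#' @export
genStateSequences <- function(nFragments, M, F, replicas,
                              coupledPairs = NULL, seed = 1) {
  if (!is.null(coupledPairs)) {
    stopifnot(all(c("i", "j", "condition", "strength") %in% names(coupledPairs)),
              all(coupledPairs$i != coupledPairs$j),
              all(c(coupledPairs$i, coupledPairs$j) >= 1),
              all(c(coupledPairs$i, coupledPairs$j) <= nFragments),
              all(coupledPairs$strength >= 0 & coupledPairs$strength <= 1),
              all(coupledPairs$condition %in% c("bound", "unbound", "both")))
  }
  gen <- function(cond, offset) .withSeed(.derivedSeed(seed, offset), {
    lapply(seq_len(replicas), function(r) {
      st <- matrix(sample.int(M, nFragments * F, replace = TRUE),
                   nFragments, F)
      if (!is.null(coupledPairs)) {
        rows <- which(coupledPairs$condition %in% c(cond, "both"))
        for (k in rows) {
          i <- coupledPairs$i[k]; j <- coupledPairs$j[k]
          s <- coupledPairs$strength[k]
          copy <- stats::runif(F) < s
          fresh <- sample.int(M, F, replace = TRUE)
          st[j, ] <- ifelse(copy, st[i, ], fresh)
        }
      }
      new("StateEncoding", states = st,
          fragments = seq_len(nFragments), M = as.integer(M))
    })
  })
  bound <- gen("bound", 211L)
  unbound <- gen("unbound", 223L)
  gt <- NULL
  if (!is.null(coupledPairs)) {
    gt <- coupledPairs
    gt$analytic_mi <- vapply(gt$strength, analyticChannelMI, 0, M = M)
    both <- unique(gt[, c("i", "j")])
    lfc <- vapply(seq_len(nrow(both)), function(k) {
      sb <- gt$strength[gt$i == both$i[k] & gt$j == both$j[k] &
                        gt$condition %in% c("bound", "both")]
      su <- gt$strength[gt$i == both$i[k] & gt$j == both$j[k] &
                        gt$condition %in% c("unbound", "both")]
      mb <- if (length(sb)) analyticChannelMI(sb[1], M) else 0
      mu <- if (length(su)) analyticChannelMI(su[1], M) else 0
      if (mu == 0) Inf else log2(mb / mu)
    }, 0)
    both$analytic_log2fc <- lfc
    gt <- list(pairs = gt, log2fc = both)
  }
  list(bound = bound, unbound = unbound, groundTruth = gt)
}

# ---- toy complex construction ------------------------------------------

.HEX_ANGLES <- (0:5) * pi / 3

# Planar 6-ring of carbons, radius 1.39 A, centered at `center`, normal along
# `normal` (unit); returns 6 x 3 coordinates.
.hexRing <- function(center, normal) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n; u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  t(vapply(.HEX_ANGLES, function(a)
    center + 1.39 * (cos(a) * u + sin(a) * v), numeric(3)))
}

.atomRow <- function(id, name, element, res, resname, chain) {
  data.frame(atom_id = id, atom_name = name, element = element,
             residue_index = res, residue_name = resname, chain_id = chain,
             mass = .elementMass(element), stringsAsFactors = FALSE)
}

#' Generate a rigid two-domain toy antibody-antigen complex
#'
#' Deterministic layout of three Calpha-plus-sidechain-bead clusters: two
#' antibody-like domains (chains H and L), with their last rows of residues
#' marking the CDR-like face, and an antigen blob (chain G) sitting above
#' the CDR face. The antigen optionally drifts away at a constant rate
#' (emulating unbinding); thermal jitter is i.i.d. Gaussian per atom and
#' frame (frame 1 is always jitter-free so placed motif geometries are
#' exact there). Optional placed motifs: an aromatic ring pair at an exact
#' COM distance/inter-normal angle, a donor-H...acceptor triple at an exact
#' H...A distance/D-H-A angle, and a C-H donor above a third ring at an
#' exact X-COM distance/X-H-COM angle.
#'
#' @param residuesPerDomain residues in each antibody-like domain
#'   (default 12, laid out 4 per row).
#' @param antigenResidues residues in the antigen blob (default 8).
#' @param drift antigen drift in Angstrom per frame along +y (0 = bound).
#' @param F number of frames.
#' @param sigma thermal jitter standard deviation in Angstrom.
#' @param ringGeometry NULL or c(dist, angle): ring-pair COM distance
#'   (Angstrom) and inter-normal angle (degrees).
#' @param hbondGeometry NULL or c(dist, angle): H...A distance and D-H-A
#'   angle.
#' @param xhGeometry NULL or c(dist, angle): X-COMring distance and
#'   X-H-COMring angle.
#' @param seed RNG seed.
#' @return list with \code{structure} (frame-1 \linkS4class{Structure}),
#'   \code{trajectory}, named \code{selections} (VH, VL, CDR, CDRL,
#'   antigen), \code{rings}, \code{hbondTriples}, \code{xhPairs}, and
#'   \code{groundTruth} (true CDR-antigen COM distance series at sigma = 0,
#'   motif geometries, layout constants).
#' @export
genToyComplex <- function(residuesPerDomain = 12, antigenResidues = 8,
                          drift = 0, F = 100, sigma = 0,
                          ringGeometry = NULL, hbondGeometry = NULL,
                          xhGeometry = NULL, seed = 1) {
  stopifnot(F >= 1, sigma >= 0)
  atoms <- NULL; xyz <- NULL
  addAtom <- function(name, element, res, resname, chain, pos) {
    id <- if (is.null(atoms)) 1L else nrow(atoms) + 1L
    atoms <<- rbind(atoms, .atomRow(id, name, element, res, resname, chain))
    xyz <<- rbind(xyz, pos)
    id
  }
  domain <- function(chain, center) {
    ids <- integer(0)
    for (k in seq_len(residuesPerDomain)) {
      row <- (k - 1) %/% 4; col <- (k - 1) %% 4
      ca <- center + c(col * 5 - 7.5, row * 5 - 5, 0)
      ids <- c(ids, addAtom("CA", "C", k, "ALA", chain, ca),
               addAtom("CB", "C", k, "ALA", chain, ca + c(0, 0, 1.5)))
    }
    ids
  }
  idH <- domain("H", c(0, 0, 0))
  idL <- domain("L", c(25, 0, 0))
  # CDR-like face: the residues in the top row of each domain
  topRow <- function(ids, chain) {
    res <- atoms$residue_index[ids]
    ids[res > residuesPerDomain - 4]
  }
  idCdrH <- topRow(idH); idCdrL <- topRow(idL)
  idG <- integer(0)
  antCenter <- c(12.5, 20, 0)
  antPos0 <- NULL
  for (k in seq_len(antigenResidues)) {
    row <- (k - 1) %/% 4; col <- (k - 1) %% 4
    ca <- antCenter + c(col * 5 - 7.5, row * 5 - 2.5, 0)
    idG <- c(idG, addAtom("CA", "C", k, "GLY", "G", ca))
    antPos0 <- rbind(antPos0, ca)
  }
  rings <- list(); hbondTriples <- NULL; xhPairs <- NULL
  motifGeom <- list()
  if (!is.null(ringGeometry)) {
    d <- ringGeometry[1]; th <- ringGeometry[2] * pi / 180
    c1 <- c(60, 0, 0)
    r1 <- .hexRing(c1, c(0, 0, 1))
    r2 <- .hexRing(c1 + c(0, 0, d), c(sin(th), 0, cos(th)))
    names6 <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
    ids1 <- vapply(1:6, function(a)
      addAtom(names6[a], "C", 901L, "PHE", "X", r1[a, ]), 0L)
    ids2 <- vapply(1:6, function(a)
      addAtom(names6[a], "C", 902L, "PHE", "X", r2[a, ]), 0L)
    rings <- c(rings, list(ringDefinition(901L, "X", ids1),
                           ringDefinition(902L, "X", ids2)))
    motifGeom$ring_pair <- c(dist = unname(ringGeometry[1]),
                             angle = unname(ringGeometry[2]))
  }
  if (!is.null(hbondGeometry)) {
    d <- hbondGeometry[1]; th <- hbondGeometry[2] * pi / 180
    D <- c(80, 0, 0); H <- D + c(1.0, 0, 0)
    A <- H + d * c(-cos(th), sin(th), 0)
    di <- addAtom("N", "N", 903L, "GLY", "Y", D)
    hi <- addAtom("H", "H", 903L, "GLY", "Y", H)
    ai <- addAtom("O", "O", 904L, "GLY", "Y", A)
    hbondTriples <- data.frame(d = di, h = hi, a = ai)
    motifGeom$hbond <- c(dist = unname(hbondGeometry[1]),
                         angle = unname(hbondGeometry[2]))
  }
  if (!is.null(xhGeometry)) {
    d <- xhGeometry[1]; eta <- xhGeometry[2]
    c3 <- c(100, 0, 0)
    r3 <- .hexRing(c3, c(0, 0, 1))
    names6 <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
    ids3 <- vapply(1:6, function(a)
      addAtom(names6[a], "C", 905L, "PHE", "X", r3[a, ]), 0L)
    X <- c3 + c(0, 0, d)
    # place H on the X-H bond (1.09 A) so that angle X-H-COM equals eta
    f <- function(alpha) {
      H <- X + 1.09 * c(sin(alpha), 0, -cos(alpha))
      .angleDeg(X - H, c3 - H) - eta
    }
    alpha <- if (abs(f(0)) < 1e-9) 0 else
      stats::uniroot(f, c(1e-6, pi - 1e-6), tol = 1e-12)$root
    H <- X + 1.09 * c(sin(alpha), 0, -cos(alpha))
    xi <- addAtom("CX", "C", 906L, "GLY", "Y", X)
    hi <- addAtom("HX", "H", 906L, "GLY", "Y", H)
    xhPairs <- data.frame(x = xi, h = hi)
    rings <- c(rings, list(ringDefinition(905L, "X", ids3)))
    motifGeom$xh_ring <- c(dist = unname(xhGeometry[1]),
                           angle = unname(xhGeometry[2]))
  }
  A <- nrow(atoms)
  co <- array(NA_real_, dim = c(F, A, 3))
  jitter <- if (sigma > 0)
    .withSeed(.derivedSeed(seed, 307L),
              array(stats::rnorm((F - 1) * A * 3, 0, sigma),
                    dim = c(F - 1, A, 3)))
  else NULL
  for (f in seq_len(F)) {
    frame <- xyz
    frame[idG, 2] <- frame[idG, 2] + drift * (f - 1)
    if (f > 1 && !is.null(jitter)) frame <- frame + jitter[f - 1, , ]
    co[f, , ] <- frame
  }
  rownames(atoms) <- NULL
  topo <- atoms
  struct <- new("Structure", atoms = topo,
                coords = matrix(co[1, , ], ncol = 3,
                                dimnames = list(NULL, c("x", "y", "z"))))
  traj <- new("Trajectory", topology = topo, coords = co,
              frameTimes = as.numeric(seq_len(F) - 1))
  selections <- list(
    VH = comSelection("VH", idH),
    VL = comSelection("VL", idL),
    CDR = comSelection("CDR", c(idCdrH, idCdrL)),
    CDRL = comSelection("CDRL", idCdrL),
    antigen = comSelection("antigen", idG))
  # analytic CDR-antigen COM distance at sigma = 0 (all atoms are carbon,
  # so the mass-weighted COM is the plain centroid of the construction)
  cdrCen <- colMeans(xyz[c(idCdrH, idCdrL), , drop = FALSE])
  antCen0 <- colMeans(antPos0)
  trueDist <- vapply(seq_len(F), function(f)
    sqrt(sum((antCen0 + c(0, drift * (f - 1), 0) - cdrCen)^2)), 0)
  list(structure = struct, trajectory = traj, selections = selections,
       rings = rings, hbondTriples = hbondTriples, xhPairs = xhPairs,
       groundTruth = list(trueDistance = trueDist, drift = drift,
                          sigma = sigma, motifs = motifGeom))
}

#' Analytic unbinding onset of a noiseless distance series
#'
#' Independent closed-form oracle for \code{\link{detectUnbinding}}: the
#' baseline is the mean of the first \code{baselineWindow} values of the
#' noiseless series and the onset is the first index exceeding factor x
#' baseline (for a monotone drift this is the sustained excursion's first
#' frame). Returns NA when the threshold is never crossed.
#'
#' @param values noiseless distance series (e.g. ground-truth trueDistance).
#' @param baselineWindow frames for the baseline (default: first 5%, >= 2).
#' @param factor threshold multiplier (default 1.5).
#' @return integer onset index or NA.
#' @export
analyticUnbindingOnset <- function(values, baselineWindow = NULL,
                                   factor = 1.5) {
  F <- length(values)
  if (is.null(baselineWindow)) baselineWindow <- max(2L, floor(0.05 * F))
  baseline <- mean(values[seq_len(baselineWindow)])
  hit <- which(values > factor * baseline)
  if (length(hit)) hit[1] else NA_integer_
}

#' Mock per-position scorer with a region-controlled wild-type bias
#'
#' Emits deterministic logits: i.i.d. standard normals per (position, amino
#' acid) drawn once under the seed, with the wild-type letter's logit raised
#' by the bias of the position's region (FW or CDR). At large bias the wild
#' type ranks first everywhere in that region; at bias 0 the wild-type rank
#' is uniform on 1..20.
#'
#' @param seq a \linkS4class{ChainSequence}.
#' @param map a \linkS4class{RegionMap} covering the chain.
#' @param fwBias logit bias added at FW positions (default 10).
#' @param cdrBias logit bias added at CDR positions (default 0).
#' @param seed RNG seed.
#' @return list(scorer, logits, sequence, map); the scorer carries
#'   \code{attr(scorer, "emits") == "logits"} and suits
#'   \code{\link{scanPositions}}.
#' @export
genMutationScores <- function(seq, map, fwBias = 10, cdrBias = 0, seed = 1) {
  stopifnot(fwBias >= 0, cdrBias >= 0)
  L <- length(seq@residues)
  logits <- .withSeed(.derivedSeed(seed, 401L),
                      matrix(stats::rnorm(L * 20), L, 20,
                             dimnames = list(NULL, .AA1)))
  region <- regionLookup(map, seq@chainId, seq@residueIndex)
  isFW <- grepl("^FW", region)
  for (p in seq_len(L)) {
    j <- match(seq@residues[p], .AA1)
    if (is.na(j) || is.na(region[p])) next
    logits[p, j] <- logits[p, j] + if (isFW[p]) fwBias else cdrBias
  }
  scorer <- function(residues, position) logits[position, ]
  attr(scorer, "emits") <- "logits"
  list(scorer = scorer, logits = logits, sequence = seq, map = map)
}

#' Generate a synthetic repertoire and its occurrence profile
#'
#' Sequences are drawn position-wise from per-position residue
#' distributions (by default a consensus residue at probability 0.8 with
#' the remaining mass uniform). The returned profile equals the empirical
#' fractions of the emitted sequences exactly.
#'
#' @param L sequence length.
#' @param nSequences repertoire size.
#' @param residueFreqs NULL, or a list of length L of named probability
#'   vectors over amino acids.
#' @param fastaPath optional path; when given the repertoire is written as
#'   FASTA.
#' @param seed RNG seed.
#' @return list(sequences, profile, residueFreqs).
#' @export
genRepertoire <- function(L, nSequences, residueFreqs = NULL,
                          fastaPath = NULL, seed = 1) {
  out <- .withSeed(.derivedSeed(seed, 503L), {
    if (is.null(residueFreqs)) {
      residueFreqs <- lapply(seq_len(L), function(p) {
        cons <- sample(.AA1, 1)
        pr <- stats::setNames(rep(0.2 / 19, 20), .AA1)
        pr[cons] <- 0.8
        pr
      })
    }
    stopifnot(length(residueFreqs) == L)
    seqs <- vapply(seq_len(nSequences), function(s)
      paste(vapply(seq_len(L), function(p) {
        pr <- residueFreqs[[p]]
        sample(names(pr), 1, prob = pr)
      }, ""), collapse = ""), "")
    list(seqs = seqs, freqs = residueFreqs)
  })
  names(out$seqs) <- sprintf("seq%05d", seq_len(nSequences))
  if (!is.null(fastaPath)) writeFasta(out$seqs, fastaPath)
  list(sequences = out$seqs, profile = buildRepertoireProfile(out$seqs),
       residueFreqs = out$freqs)
}
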