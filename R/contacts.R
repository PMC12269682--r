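#' @include AllClasses.R
NULL

#' Geometric criteria for non-covalent interaction classification
#'
#' Distance/angle cutoffs for the three detector families. Defaults follow
#' the standard literature conventions: Baker-Hubbard hydrogen bonds
#' (H...acceptor <= 2.5 Angstrom, donor-H-acceptor angle >= 120 degrees),
#' pi-pi stacking (ring-COM distance <= 5.5 Angstrom, inter-normal angle
#' <= 30 degrees after folding to [0, 90]), and XH-ring interactions with
#' X in {C, N} (X-COMring distance <= 4.5 Angstrom, X-H-COMring angle >=
#' 120 degrees). Every cutoff is configurable; boundary equality satisfies
#' a criterion.
#'
#' @param hbondMaxDist,hbondMinAngle hydrogen-bond cutoffs.
#' @param pipiMaxDist,pipiMaxAngle pi-pi cutoffs.
#' @param xhRingMaxDist,xhRingMinAngle XH-ring cutoffs.
#' @return a named list of class "GeomCriteria".
#' @export
geomCriteria <- function(hbondMaxDist = 2.5, hbondMinAngle = 120,
                         pipiMaxDist = 5.5, pipiMaxAngle = 30,
                         xhRingMaxDist = 4.5, xhRingMinAngle = 120) {
  cr <- list(
    hbond = list(maxDist = hbondMaxDist, minAngle = hbondMinAngle),
    pipi = list(maxDist = pipiMaxDist, maxAngle = pipiMaxAngle),
    xhRing = list(maxDist = xhRingMaxDist, minAngle = xhRingMinAngle))
  stopifnot(all(vapply(cr, function(b) all(unlist(b) > 0), TRUE)))
  class(cr) <- "GeomCriteria"
  cr
}

#' Load geometric criteria from a TSV or JSON config
#'
#' TSV schema mirrors a cutoff table: columns interaction (hbond | pipi |
#' xh_ring), parameter (max_dist | min_angle | max_angle), value, units.
#'
#' @param path config path (.tsv or .json).
#' @return a "GeomCriteria" list.
#' @export
loadCriteria <- function(path) {
  cr <- geomCriteria()
  if (grepl("\\.json$", path)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (nm in names(raw)) cr[[nm]] <- utils::modifyList(cr[[nm]], as.list(raw[[nm]]))
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    map <- c(hbond = "hbond", pipi = "pipi", xh_ring = "xhRing")
    pmap <- c(max_dist = "maxDist", min_angle = "minAngle",
              max_angle = "maxAngle")
    for (k in seq_len(nrow(tab)))
      cr[[map[[tab$interaction[k]]]]][[pmap[[tab$parameter[k]]]]] <-
        as.numeric(tab$value[k])
  }
  class(cr) <- "GeomCriteria"
  cr
}

.emptyEvents <- function() {
  data.frame(frame = integer(), type = character(),
             res_i = integer(), chain_i = character(),
             res_j = integer(), chain_j = character(),
             atoms = character(), distance = numeric(), angle = numeric(),
             stringsAsFactors = FALSE)
}

# H atoms covalently bonded to donor elements, resolved from the first frame
# (bond length <= 1.25 Angstrom, same residue).
.bondedHydrogens <- function(traj, donorElements) {
  at <- atoms(traj)
  xyz <- frameCoords(traj, 1)
  hIdx <- which(at$element == "H")
  dIdx <- which(at$element %in% donorElements)
  if (!length(hIdx) || !length(dIdx)) return(NULL)
  out <- NULL
  for (h in hIdx) {
    cand <- dIdx[at$residue_index[dIdx] == at$residue_index[h] &
                 at$chain_id[dIdx] == at$chain_id[h]]
    if (!length(cand)) next
    dd <- sqrt(rowSums((xyz[cand, , drop = FALSE] -
                        matrix(xyz[h, ], length(cand), 3, byrow = TRUE))^2))
    if (min(dd) <= 1.25)
      out <- rbind(out, data.frame(d = cand[which.min(dd)], h = h))
  }
  out
}

#' Detect hydrogen bonds by the Baker-Hubbard geometric criterion
#'
#' An event is emitted for a donor-H...acceptor triple in a frame iff the
#' H...acceptor distance is at most the cutoff and the donor-H-acceptor
#' angle is at least the minimum angle. Donor triples are resolved from the
#' topology (H bonded to N/O/S) unless given explicitly; acceptors are N, O
#' and S atoms outside the donor's residue.
#'
#' @param traj a \linkS4class{Trajectory} whose topology includes hydrogens,
#'   unless \code{triples} is supplied.
#' @param criteria a "GeomCriteria" list (see \code{\link{geomCriteria}}).
#' @param triples optional data.frame (d, h, a) of atom indices.
#' @return data.frame of interaction events (frame, type, residues, atoms,
#'   distance, angle).
#' @export
detectHBonds <- function(traj, criteria = geomCriteria(), triples = NULL) {
  at <- atoms(traj)
  if (is.null(triples)) {
    dh <- .bondedHydrogens(traj, c("N", "O", "S"))
    if (is.null(dh))
      stop("topology has no resolvable donor-H pairs; supply explicit ",
           "(d, h, a) triples", call. = FALSE)
    acc <- which(at$element %in% c("N", "O", "S"))
    triples <- do.call(rbind, lapply(seq_len(nrow(dh)), function(k) {
      a <- acc[!(at$residue_index[acc] == at$residue_index[dh$h[k]] &
                 at$chain_id[acc] == at$chain_id[dh$h[k]])]
      if (!length(a)) return(NULL)
      data.frame(d = dh$d[k], h = dh$h[k], a = a)
    }))
    if (is.null(triples) || !nrow(triples)) return(.emptyEvents())
  }
  maxD <- criteria$hbond$maxDist; minA <- criteria$hbond$minAngle
  out <- vector("list", nFrames(traj))
  for (f in seq_len(nFrames(traj))) {
    xyz <- frameCoords(traj, f)
    ha <- sqrt(rowSums((xyz[triples$h, , drop = FALSE] -
                        xyz[triples$a, , drop = FALSE])^2))
    cand <- which(ha <= maxD)
    if (!length(cand)) next
    ang <- vapply(cand, function(k)
      .angleDeg(xyz[triples$d[k], ] - xyz[triples$h[k], ],
                xyz[triples$a[k], ] - xyz[triples$h[k], ]), 0)
    hit <- cand[!is.na(ang) & ang >= minA]
    if (!length(hit)) next
    out[[f]] <- data.frame(
      frame = f, type = "hbond",
      res_i = at$residue_index[triples$d[hit]],
      chain_i = at$chain_id[triples$d[hit]],
      res_j = at$residue_index[triples$a[hit]],
      chain_j = at$chain_id[triples$a[hit]],
      atoms = paste0(at$atom_name[triples$d[hit]], "-",
                     at$atom_name[triples$h[hit]], "...",
                     at$atom_name[triples$a[hit]]),
      distance = ha[hit], angle = ang[!is.na(ang) & ang >= minA],
      stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, out)
  if (is.null(ev)) .emptyEvents() else ev
}

#' Define an aromatic ring for geometric detectors
#'
#' @param residueIndex residue carrying the ring.
#' @param chainId chain identifier.
#' @param atomIndices indices of the ring atoms (>= 5).
#' @return a list of class "RingDefinition".
#' @export
ringDefinition <- function(residueIndex, chainId, atomIndices) {
  stopifnot(length(atomIndices) >= 5)
  structure(list(residueIndex = as.integer(residueIndex),
                 chainId = as.character(chainId),
                 atomIndices = as.integer(atomIndices)),
            class = "RingDefinition")
}

#' Aromatic rings of standard residues in a topology
#'
#' Builds \code{\link{ringDefinition}}s for PHE/TYR (6-ring), TRP (both
#' rings as one 9-atom plane is avoided: the 6-membered ring is used) and
#' HIS (5-ring) side chains.
#'
#' @param x a \linkS4class{Structure} or \linkS4class{Trajectory}.
#' @return list of RingDefinition.
#' @export
aromaticRings <- function(x) {
  at <- atoms(x)
  defs <- list(
    PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))
  out <- list()
  key <- paste(at$chain_id, at$residue_index)
  for (k in unique(key)) {
    rows <- which(key == k)
    rn <- at$residue_name[rows[1]]
    if (!rn %in% names(defs)) next
    idx <- rows[match(defs[[rn]], at$atom_name[rows])]
    if (anyNA(idx)) next
    out[[length(out) + 1]] <- ringDefinition(at$residue_index[rows[1]],
                                             at$chain_id[rows[1]], idx)
  }
  out
}

# Ring COM (mass-weighted) and unit normal (smallest principal axis of the
# ring atoms); returns NULL for degenerate (collinear) rings.
.ringGeometry <- function(xyz, masses, ring) {
  idx <- ring$atomIndices
  com <- .comFrame(xyz, masses, idx, TRUE)
  centered <- sweep(xyz[idx, , drop = FALSE], 2, colMeans(xyz[idx, , drop = FALSE]))
  ev <- eigen(crossprod(centered), symmetric = TRUE)
  if (ev$values[2] < 1e-9) return(NULL)  # collinear: no defined plane
  normal <- ev$vectors[, 3]
  list(com = com, normal = normal / sqrt(sum(normal^2)))
}

#' Detect pi-pi stacking between aromatic rings
#'
#' An event is emitted for a ring pair in a frame iff the distance between
#' the ring centers of mass is at most the cutoff and the angle between the
#' ring normals, folded to [0, 90] degrees (normals are sign-ambiguous), is
#' at most the maximum angle. Degenerate (collinear) rings are skipped with
#' a warning.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param rings list of \code{\link{ringDefinition}} objects (>= 2).
#' @param criteria a "GeomCriteria" list.
#' @return data.frame of interaction events.
#' @export
detectPiPi <- function(traj, rings, criteria = geomCriteria()) {
  stopifnot(length(rings) >= 2)
  at <- atoms(traj)
  maxD <- criteria$pipi$maxDist; maxA <- criteria$pipi$maxAngle
  out <- vector("list", nFrames(traj))
  warned <- FALSE
  for (f in seq_len(nFrames(traj))) {
    xyz <- frameCoords(traj, f)
    geo <- lapply(rings, function(r) .ringGeometry(xyz, at$mass, r))
    bad <- vapply(geo, is.null, TRUE)
    if (any(bad) && !warned) {
      warning(sum(bad), " degenerate ring(s) skipped", call. = FALSE)
      warned <- TRUE
    }
    recs <- NULL
    for (a in seq_along(rings)) for (b in seq_along(rings)) {
      if (b <= a || bad[a] || bad[b]) next
      dd <- sqrt(sum((geo[[a]]$com - geo[[b]]$com)^2))
      if (dd > maxD) next
      th <- .angleDeg(geo[[a]]$normal, geo[[b]]$normal)
      th <- min(th, 180 - th)
      if (th > maxA) next
      recs <- rbind(recs, data.frame(
        frame = f, type = "pipi",
        res_i = rings[[a]]$residueIndex, chain_i = rings[[a]]$chainId,
        res_j = rings[[b]]$residueIndex, chain_j = rings[[b]]$chainId,
        atoms = paste0("ring", a, "-ring", b),
        distance = dd, angle = th, stringsAsFactors = FALSE))
    }
    out[[f]] <- recs
  }
  ev <- do.call(rbind, out)
  if (is.null(ev)) .emptyEvents() else ev
}

#' Detect CH-ring / NH-ring interactions
#'
#' For every X-H bonded pair (X = C or N, resolved from the topology unless
#' supplied) and every ring, an event is emitted in a frame iff the
#' X-COMring distance is at most the cutoff and the X-H-COMring angle is at
#' least the minimum angle. Pairs within the ring's own residue are skipped.
#' Event type is \code{ch_ring} or \code{nh_ring} according to X.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param rings list of \code{\link{ringDefinition}} objects.
#' @param criteria a "GeomCriteria" list.
#' @param X donor heavy element, "C" or "N".
#' @param xhPairs optional data.frame (x, h) of atom indices.
#' @return data.frame of interaction events.
#' @export
detectXHRing <- function(traj, rings, criteria = geomCriteria(),
                         X = c("C", "N"), xhPairs = NULL) {
  X <- match.arg(X)
  at <- atoms(traj)
  if (is.null(xhPairs)) {
    dh <- .bondedHydrogens(traj, X)
    if (is.null(dh)) return(.emptyEvents())
    xhPairs <- data.frame(x = dh$d, h = dh$h)
  }
  maxD <- criteria$xhRing$maxDist; minA <- criteria$xhRing$minAngle
  type <- if (X == "C") "ch_ring" else "nh_ring"
  out <- vector("list", nFrames(traj))
  for (f in seq_len(nFrames(traj))) {
    xyz <- frameCoords(traj, f)
    recs <- NULL
    for (r in seq_along(rings)) {
      ring <- rings[[r]]
      geo <- .ringGeometry(xyz, at$mass, ring)
      if (is.null(geo)) next
      keep <- which(!(at$residue_index[xhPairs$x] == ring$residueIndex &
                      at$chain_id[xhPairs$x] == ring$chainId))
      for (k in keep) {
        xi <- xhPairs$x[k]; hi <- xhPairs$h[k]
        dd <- sqrt(sum((xyz[xi, ] - geo$com)^2))
        if (dd > maxD) next
        ang <- .angleDeg(xyz[xi, ] - xyz[hi, ], geo$com - xyz[hi, ])
        if (is.na(ang) || ang < minA) next
        recs <- rbind(recs, data.frame(
          frame = f, type = type,
          res_i = at$residue_index[xi], chain_i = at$chain_id[xi],
          res_j = ring$residueIndex, chain_j = ring$chainId,
          atoms = paste0(at$atom_name[xi], "-", at$atom_name[hi],
                         "...ring", r),
          distance = dd, angle = ang, stringsAsFactors = FALSE))
      }
    }
    out[[f]] <- recs
  }
  ev <- do.call(rbind, out)
  if (is.null(ev)) .emptyEvents() else ev
}

#' Per-frame interaction counts for a focus residue
#'
#' Counts events involving the focus residue, per frame and interaction
#' type, with median and IQR summaries per type over frames (frames with no
#' event count 0).
#'
#' @param events event data.frame from the detectors (one trajectory).
#' @param focusResidue residue index of interest.
#' @param nFrames total frames of the source trajectory.
#' @param chainId optional chain of the focus residue.
#' @return list(counts = frame x type data.frame, summary = per-type median
#'   and IQR).
#' @export
countInteractions <- function(events, focusResidue, nFrames,
                              chainId = NULL) {
  sel <- events$res_i == focusResidue | events$res_j == focusResidue
  if (!is.null(chainId))
    sel <- (events$res_i == focusResidue & events$chain_i == chainId) |
           (events$res_j == focusResidue & events$chain_j == chainId)
  ev <- events[sel, , drop = FALSE]
  types <- sort(unique(events$type))
  if (!length(types)) types <- character(0)
  counts <- data.frame(frame = seq_len(nFrames))
  for (tp in types) {
    tab <- table(factor(ev$frame[ev$type == tp], levels = seq_len(nFrames)))
    counts[[tp]] <- as.integer(tab)
  }
  summ <- data.frame(
    type = types,
    median = vapply(types, function(tp) stats::median(counts[[tp]]), 0),
    iqr = vapply(types, function(tp)
      unname(stats::quantile(counts[[tp]], .75) -
             stats::quantile(counts[[tp]], .25)), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts, summary = summ)
}

.edgeKey <- function(ri, ci, rj, cj, type) {
  a <- paste(ci, ri, sep = ":"); b <- paste(cj, rj, sep = ":")
  lo <- ifelse(a <= b, a, b); hi <- ifelse(a <= b, b, a)
  paste(lo, hi, type, sep = "|")
}

#' Build a residue interaction network from events
#'
#' Edge identity is the unordered residue pair plus interaction type; a
#' frame contributes 0/1 per edge (presence, not event multiplicity), and
#' the edge frequency is the fraction of frames with at least one event.
#' Edges below \code{minFrequency} are dropped, as are self-edges.
#'
#' @param events event data.frame.
#' @param nFrames total frames F (>= 1).
#' @param minFrequency minimum retained frequency (default 0.1).
#' @param topologyId optional identifier of the source topology, checked by
#'   \code{\link{diffNetwork}}.
#' @return an \linkS4class{InteractionNetwork}.
#' @export
buildNetwork <- function(events, nFrames, minFrequency = 0.1,
                         topologyId = NA_character_) {
  stopifnot(nFrames >= 1)
  if (nrow(events)) {
    nodeI <- paste(events$chain_i, events$res_i, sep = ":")
    nodeJ <- paste(events$chain_j, events$res_j, sep = ":")
    keep <- nodeI != nodeJ
    ev <- events[keep, , drop = FALSE]
    nodeI <- nodeI[keep]; nodeJ <- nodeJ[keep]
    key <- .edgeKey(ev$res_i, ev$chain_i, ev$res_j, ev$chain_j, ev$type)
    uf <- !duplicated(paste(key, ev$frame))
    freq <- table(key[uf]) / nFrames
    parts <- strsplit(names(freq), "|", fixed = TRUE)
    edges <- data.frame(
      res_i = vapply(parts, `[`, "", 1),
      res_j = vapply(parts, `[`, "", 2),
      type = vapply(parts, `[`, "", 3),
      frequency = as.numeric(freq), stringsAsFactors = FALSE)
    edges <- edges[edges$frequency >= minFrequency, , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(res_i = character(), res_j = character(),
                        type = character(), frequency = numeric(),
                        stringsAsFactors = FALSE)
  }
  new("InteractionNetwork", edges = edges, nFrames = as.integer(nFrames),
      topologyId = topologyId)
}

#' Difference between two residue interaction networks
#'
#' Joins the union of edges of the two networks (absent edges count as
#' frequency 0) and reports the per-edge frequency change
#' \code{delta = freq_alt - freq_ref}. The perturbed-residue set is the
#' union of endpoints of edges with |delta| at or above the threshold.
#'
#' @param netRef,netAlt \linkS4class{InteractionNetwork} objects over the
#'   same topology.
#' @param perturbThreshold minimal |delta| marking an edge perturbed
#'   (default 0.25).
#' @return list(edges = union-join table with freq_ref, freq_alt, delta;
#'   perturbedResidues = character vector of "chain:residue" labels).
#' @export
diffNetwork <- function(netRef, netAlt, perturbThreshold = 0.25) {
  if (!is.na(netRef@topologyId) && !is.na(netAlt@topologyId) &&
      netRef@topologyId != netAlt@topologyId)
    stop("networks come from different topologies (",
         netRef@topologyId, " vs ", netAlt@topologyId, ")", call. = FALSE)
  er <- netRef@edges; ea <- netAlt@edges
  kr <- paste(er$res_i, er$res_j, er$type, sep = "|")
  ka <- paste(ea$res_i, ea$res_j, ea$type, sep = "|")
  keys <- union(kr, ka)
  fr <- er$frequency[match(keys, kr)]; fr[is.na(fr)] <- 0
  fa <- ea$frequency[match(keys, ka)]; fa[is.na(fa)] <- 0
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(
    res_i = vapply(parts, `[`, "", 1),
    res_j = vapply(parts, `[`, "", 2),
    type = vapply(parts, `[`, "", 3),
    freq_ref = fr, freq_alt = fa, delta = fa - fr,
    stringsAsFactors = FALSE)
  pert <- out[abs(out$delta) >= perturbThreshold, , drop = FALSE]
  list(edges = out,
       perturbedResidues = sort(unique(c(pert$res_i, pert$res_j))))
}
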