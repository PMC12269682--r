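#' @include AllClasses.R
NULL

.checkSelection <- function(traj, sel) {
  stopifnot(is(sel, "ComSelection"))
  if (any(sel@indices > nAtoms(traj)))
    stop("selection '", sel@name, "' references atoms beyond the topology",
         call. = FALSE)
}

.comFrame <- function(xyz, masses, idx, massWeighted) {
  w <- if (massWeighted) masses[idx] else rep(1, length(idx))
  colSums(xyz[idx, , drop = FALSE] * w) / sum(w)
}

#' Per-frame center of mass of an atom selection
#'
#' Mass-weighted (default) or plain mean of the selected atom coordinates in
#' every frame.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param sel a \linkS4class{ComSelection}.
#' @return numeric F x 3 matrix of COM coordinates (Angstrom).
#' @export
centerOfMass <- function(traj, sel) {
  .checkSelection(traj, sel)
  masses <- atoms(traj)$mass
  F <- nFrames(traj)
  out <- matrix(NA_real_, F, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (f in seq_len(F))
    out[f, ] <- .comFrame(frameCoords(traj, f), masses, sel@indices,
                          sel@massWeighted)
  out
}

.seriesResult <- function(values, traj, unit) {
  data.frame(frame = seq_len(nFrames(traj)), time_ps = frameTimes(traj),
             value = values, unit = unit, stringsAsFactors = FALSE)
}

#' Distance between the centers of mass of two selections, per frame
#'
#' The CDR-antigen engagement proxy: e.g. the distance between the COM of
#' the CDR loops and the COM of the antigen juxtamembrane region, monitored
#' along the trajectory.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param selA,selB \linkS4class{ComSelection} objects.
#' @return data.frame (frame, time_ps, value, unit) with values in Angstrom.
#' @export
comDistanceSeries <- function(traj, selA, selB) {
  a <- centerOfMass(traj, selA)
  b <- centerOfMass(traj, selB)
  .seriesResult(sqrt(rowSums((a - b)^2)), traj, "angstrom")
}

#' VH-VL packing angle series
#'
#' Planar angle defined on three centers of mass (light-chain CDR, VL and
#' VH). The vertex defaults to the VL COM, i.e. the angle between the
#' vectors VL->CDR-L and VL->VH, reported in degrees in [0, 180]. Frames
#' where two COMs coincide (separation < 1e-9 Angstrom) yield NA with a
#' warning.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param selCdrL,selVL,selVH \linkS4class{ComSelection} objects.
#' @param vertex which COM sits at the angle vertex: "VL" (default), "VH" or
#'   "CDRL".
#' @return data.frame (frame, time_ps, value, unit), degrees.
#' @export
vhVlAngleSeries <- function(traj, selCdrL, selVL, selVH,
                            vertex = c("VL", "VH", "CDRL")) {
  vertex <- match.arg(vertex)
  coms <- list(CDRL = centerOfMass(traj, selCdrL),
               VL = centerOfMass(traj, selVL),
               VH = centerOfMass(traj, selVH))
  arms <- setdiff(names(coms), vertex)
  v <- coms[[vertex]]
  ang <- vapply(seq_len(nFrames(traj)), function(f)
    .angleDeg(coms[[arms[1]]][f, ] - v[f, ], coms[[arms[2]]][f, ] - v[f, ]),
    0)
  if (anyNA(ang))
    warning(sum(is.na(ang)), " frame(s) with coincident COMs: angle ",
            "undefined, set to NA", call. = FALSE)
  .seriesResult(ang, traj, "degree")
}

#' VH-VL straight-line COM distance series
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param selVH,selVL \linkS4class{ComSelection} objects.
#' @return data.frame (frame, time_ps, value, unit), Angstrom.
#' @export
vhVlDistanceSeries <- function(traj, selVH, selVL) {
  comDistanceSeries(traj, selVH, selVL)
}

#' RMSD of each frame to a reference after optimal superposition
#'
#' Per frame, the selected atoms are rigidly superposed onto the reference
#' (unweighted Kabsch, reflections disallowed) and the RMSD is reported in
#' Angstrom.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param reference a \linkS4class{Structure} sharing the selected atoms.
#' @param sel a \linkS4class{ComSelection}; indices must address the same
#'   atoms (1:1) in trajectory and reference.
#' @return data.frame (frame, time_ps, value, unit), Angstrom.
#' @export
rmsdSeries <- function(traj, reference, sel) {
  .checkSelection(traj, sel)
  if (any(sel@indices > nrow(reference@coords)))
    stop("selection references atoms beyond the reference structure",
         call. = FALSE)
  if (nAtoms(traj) != nrow(reference@coords))
    stop("trajectory and reference atom counts differ (",
         nAtoms(traj), " vs ", nrow(reference@coords), ")", call. = FALSE)
  ref <- reference@coords[sel@indices, , drop = FALSE]
  vals <- vapply(seq_len(nFrames(traj)), function(f)
    .kabschRMSD(ref, frameCoords(traj, f)[sel@indices, , drop = FALSE]), 0)
  .seriesResult(vals, traj, "angstrom")
}

#' Native heavy-atom contacts of a reference structure
#'
#' All heavy-atom (non-hydrogen) pairs within \code{cutoff} Angstrom whose
#' residues are either on different chains or at least \code{exclusion}
#' residues apart in sequence; intra-residue pairs are always excluded.
#'
#' @param reference a \linkS4class{Structure}.
#' @param cutoff distance cutoff in Angstrom (default 4.5).
#' @param exclusion minimum intra-chain residue separation (default 3).
#' @return a \linkS4class{ContactSet}.
#' @export
nativeContacts <- function(reference, cutoff = 4.5, exclusion = 3L) {
  at <- atoms(reference)
  heavy <- which(at$element != "H")
  xyz <- reference@coords[heavy, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  keep <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(keep)) {
    refd <- d[keep]
    i <- heavy[keep[, 1]]; j <- heavy[keep[, 2]]
    sameChain <- at$chain_id[i] == at$chain_id[j]
    dres <- abs(at$residue_index[i] - at$residue_index[j])
    ok <- (!sameChain) | (dres >= exclusion)
    ok <- ok & !(sameChain & dres == 0)
    i <- i[ok]; j <- j[ok]; refd <- refd[ok]
    pairs <- data.frame(
      i = i, j = j,
      ref_dist = refd,
      res_i = at$residue_index[i], chain_i = at$chain_id[i],
      res_j = at$residue_index[j], chain_j = at$chain_id[j],
      stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(i = integer(), j = integer(), ref_dist = numeric(),
                        res_i = integer(), chain_i = character(),
                        res_j = integer(), chain_j = character(),
                        stringsAsFactors = FALSE)
  }
  new("ContactSet", pairs = pairs, cutoff = cutoff,
      exclusion = as.integer(exclusion))
}

#' Per-residue native-contact retention along a trajectory
#'
#' A native contact counts as retained in a frame iff its distance does not
#' exceed cutoff x toleranceFactor. Each residue's retained fraction is the
#' number of retained contacts involving it divided by its total native
#' contacts; residues with no native contacts are absent from the output.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param contacts a \linkS4class{ContactSet} from the reference.
#' @param toleranceFactor slack on the native cutoff (default 1.2).
#' @return data.frame (residue, chain, frame, retained_fraction).
#' @export
contactRetention <- function(traj, contacts, toleranceFactor = 1.2) {
  pr <- contacts@pairs
  if (!nrow(pr)) stop("empty contact set", call. = FALSE)
  if (max(pr$i, pr$j) > nAtoms(traj))
    stop("contact atom indices exceed trajectory topology", call. = FALSE)
  thr <- contacts@cutoff * toleranceFactor
  F <- nFrames(traj)
  resKey <- unique(data.frame(residue = c(pr$res_i, pr$res_j),
                              chain = c(pr$chain_i, pr$chain_j),
                              stringsAsFactors = FALSE))
  keyOf <- function(r, ch) paste(ch, r, sep = ":")
  resIds <- keyOf(resKey$residue, resKey$chain)
  out <- vector("list", F)
  for (f in seq_len(F)) {
    xyz <- frameCoords(traj, f)
    dd <- sqrt(rowSums((xyz[pr$i, , drop = FALSE] -
                        xyz[pr$j, , drop = FALSE])^2))
    ret <- dd <= thr
    ki <- keyOf(pr$res_i, pr$chain_i); kj <- keyOf(pr$res_j, pr$chain_j)
    tot <- table(c(ki, kj))
    kept <- table(c(ki[ret], kj[ret]))
    frac <- as.numeric(kept[resIds]) / as.numeric(tot[resIds])
    frac[is.na(frac)] <- 0
    out[[f]] <- data.frame(residue = resKey$residue, chain = resKey$chain,
                           frame = f, retained_fraction = frac,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Detect a sustained unbinding excursion in a distance series
#'
#' The baseline is the mean over the first \code{baselineWindow} frames. The
#' call is positive iff there is a suffix of the series that never returns
#' below the baseline and within which at least \code{persistence} of the
#' frames exceed factor x baseline; the onset is the first frame of that
#' suffix exceeding the threshold. Transient spikes that fall back below the
#' baseline never trigger a call.
#'
#' @param series data.frame with a \code{value} column (as produced by the
#'   series functions) or a numeric vector.
#' @param baselineWindow frames used for the baseline (default: first 5% of
#'   frames, at least 2).
#' @param factor threshold multiplier on the baseline (default 1.5).
#' @param persistence minimal fraction of above-threshold frames in the
#'   suffix (default 0.1).
#' @return list(flag, onset_frame, baseline, threshold).
#' @export
detectUnbinding <- function(series, baselineWindow = NULL, factor = 1.5,
                            persistence = 0.1) {
  v <- if (is.data.frame(series)) series$value else as.numeric(series)
  if (any(!is.finite(v))) stop("non-finite values in series", call. = FALSE)
  F <- length(v)
  if (is.null(baselineWindow)) baselineWindow <- max(2L, floor(0.05 * F))
  if (F <= baselineWindow)
    stop("series must be longer than the baseline window", call. = FALSE)
  baseline <- mean(v[seq_len(baselineWindow)])
  threshold <- factor * baseline
  # first frame after which the series never drops below baseline again
  belowIdx <- which(v < baseline)
  t0 <- if (length(belowIdx)) max(belowIdx) + 1L else 1L
  flag <- FALSE; onset <- NA_integer_
  if (t0 <= F) {
    tail <- v[t0:F]
    exceed <- tail > threshold
    if (any(exceed) && mean(exceed) >= persistence) {
      flag <- TRUE
      onset <- t0 + which(exceed)[1] - 1L
    }
  }
  list(flag = flag, onset_frame = onset, baseline = baseline,
       threshold = threshold)
}
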