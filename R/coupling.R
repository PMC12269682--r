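#' @include AllClasses.R
NULL

#' Load a structural alphabet from a TSV file
#'
#' Schema: state_label, point_index (1..4), x, y, z; one row per prototype
#' point, coordinates in Angstrom. Any M-state four-point alphabet in this
#' schema is accepted (M32K25-style alphabets have M = 25).
#'
#' @param path TSV path.
#' @return an \linkS4class{AlphabetPrototypes}.
#' @export
loadAlphabet <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("state_label", "point_index", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("alphabet file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  labels <- sort(unique(tab$state_label))
  pts <- array(NA_real_, dim = c(length(labels), 4, 3))
  for (m in seq_along(labels)) {
    sub <- tab[tab$state_label == labels[m], , drop = FALSE]
    if (nrow(sub) != 4) stop("state ", labels[m], " must have 4 points",
                             call. = FALSE)
    sub <- sub[order(sub$point_index), , drop = FALSE]
    pts[m, , ] <- as.matrix(sub[, c("x", "y", "z")])
  }
  new("AlphabetPrototypes", labels = as.integer(labels), points = pts)
}

#' Write a structural alphabet to TSV
#'
#' @param prototypes an \linkS4class{AlphabetPrototypes}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeAlphabet <- function(prototypes, path) {
  rows <- do.call(rbind, lapply(seq_along(prototypes@labels), function(m)
    data.frame(state_label = prototypes@labels[m], point_index = 1:4,
               x = prototypes@points[m, , 1], y = prototypes@points[m, , 2],
               z = prototypes@points[m, , 3])))
  writeResultTable(rows, path)
}

#' Generate a synthetic structural alphabet
#'
#' Seeded generator of M well-separated four-point prototypes with backbone-
#' like spacing (consecutive points about 3.8 Angstrom apart, random turns).
#' This is a synthetic stand-in alphabet for testing and demonstration; real
#' analyses should load a published alphabet via \code{\link{loadAlphabet}}.
#'
#' @param M number of states.
#' @param seed RNG seed.
#' @return an \linkS4class{AlphabetPrototypes}.
#' @export
syntheticAlphabet <- function(M, seed = 1) {
  pts <- .withSeed(.derivedSeed(seed, 101L), {
    arr <- array(NA_real_, dim = c(M, 4, 3))
    for (m in seq_len(M)) {
      p <- matrix(0, 4, 3)
      dir <- c(1, 0, 0)
      for (k in 2:4) {
        turn <- stats::rnorm(3)
        dir <- dir + 0.8 * turn
        dir <- dir / sqrt(sum(dir^2))
        p[k, ] <- p[k - 1, ] + 3.8 * dir
      }
      arr[m, , ] <- p
    }
    arr
  })
  new("AlphabetPrototypes", labels = seq_len(M), points = pts)
}

#' Encode a trajectory chain as structural-alphabet state sequences
#'
#' Each frame of the chain is coarse-grained into consecutive four-residue
#' Calpha fragments (fragment i covers residues i..i+3); every fragment is
#' assigned the prototype with minimal Calpha RMSD after optimal rigid
#' superposition, ties broken deterministically to the lowest state label.
#' Fragments with missing Calpha atoms are excluded (with a warning) from
#' the encoding and hence from all pair analyses.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param chainId chain to encode.
#' @param prototypes an \linkS4class{AlphabetPrototypes}.
#' @return a \linkS4class{StateEncoding}.
#' @export
encodeAlphabet <- function(traj, chainId, prototypes) {
  at <- atoms(traj)
  sel <- at$chain_id == chainId & at$atom_name == "CA"
  if (!any(sel)) stop("chain '", chainId, "' has no Calpha atoms",
                      call. = FALSE)
  resIdx <- at$residue_index[sel]
  caAtom <- which(sel)[order(resIdx)]
  resIdx <- sort(resIdx)
  resAll <- sort(unique(at$residue_index[at$chain_id == chainId]))
  if (length(resAll) < 4) stop("chain must have at least 4 residues",
                               call. = FALSE)
  frags <- resAll[seq_len(length(resAll) - 3)]
  caOf <- function(r) { i <- match(r, resIdx); if (is.na(i)) NA_integer_ else caAtom[i] }
  fragAtoms <- lapply(frags, function(r) vapply(r + 0:3, caOf, 0L))
  valid <- !vapply(fragAtoms, anyNA, TRUE)
  if (!all(valid))
    warning(sum(!valid), " fragment(s) without complete Calpha coverage ",
            "excluded", call. = FALSE)
  frags <- frags[valid]; fragAtoms <- fragAtoms[valid]
  M <- length(prototypes@labels)
  protos <- lapply(seq_len(M), function(m)
    matrix(prototypes@points[m, , ], 4, 3))
  F <- nFrames(traj)
  st <- matrix(NA_integer_, length(frags), F)
  ord <- order(prototypes@labels)  # tie-break scans labels in ascending order
  for (f in seq_len(F)) {
    xyz <- frameCoords(traj, f)
    for (i in seq_along(frags)) {
      X <- xyz[fragAtoms[[i]], , drop = FALSE]
      rms <- vapply(ord, function(m) .kabschRMSD(protos[[m]], X), 0)
      st[i, f] <- prototypes@labels[ord[which.min(rms)]]
    }
  }
  new("StateEncoding", states = st, fragments = as.integer(frags),
      M = as.integer(max(prototypes@labels)))
}

#' Plug-in mutual information between two state sequences (bits)
#'
#' MI from the joint frame-wise contingency table, log base 2.
#'
#' @param x,y integer (or factor) state vectors of equal length F >= 2.
#' @return raw MI in bits.
#' @export
mutualInformation <- function(x, y) {
  if (length(x) != length(y))
    stop("sequences must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 frames", call. = FALSE)
  joint <- table(x, y) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

.jointEntropy <- function(x, y) {
  joint <- table(x, y) / length(x)
  nz <- joint > 0
  -sum(joint[nz] * log2(joint[nz]))
}

#' Corrected normalized mutual information
#'
#' Corrects the plug-in MI for finite-sampling bias and normalizes it to
#' [0, 1]. In \code{analytic} mode the first-order bias
#' (Rx - 1)(Ry - 1) / (2 F ln 2) bits (Rx, Ry = occupied state counts) is
#' subtracted; in \code{permutation} mode the mean MI over \code{nPerm}
#' seeded shuffles of \code{y} is subtracted instead. The corrected value is
#' clamped at 0 and divided by the equally corrected joint entropy
#' H(X,Y) - bias, so identical non-constant sequences score exactly 1; the
#' result is clamped to [0, 1]. Two constant sequences (H(X,Y) = 0) score 0.
#'
#' @param x,y state vectors of equal length.
#' @param correction "analytic" (default) or "permutation".
#' @param nPerm shuffles in permutation mode (default 200).
#' @param seed RNG seed for permutation mode.
#' @return corrected normalized MI in [0, 1].
#' @export
correctedNormalizedMI <- function(x, y, correction = c("analytic", "permutation"),
                                  nPerm = 200, seed = 1) {
  correction <- match.arg(correction)
  mi <- mutualInformation(x, y)
  H <- .jointEntropy(x, y)
  if (H == 0) return(0)
  bias <- if (correction == "analytic") {
    F <- length(x)
    (length(unique(x)) - 1) * (length(unique(y)) - 1) / (2 * F * log(2))
  } else {
    .withSeed(seed, mean(vapply(seq_len(nPerm), function(k)
      mutualInformation(x, sample(y)), 0)))
  }
  den <- H - bias
  if (den <= 0) return(0)
  min(1, max(0, mi - bias) / den)
}

#' Corrected normalized MI matrix over all fragment pairs of one replica
#'
#' Computes the corrected normalized MI for every fragment pair over the
#' tail analysis window (by default the last half of the frames, mirroring
#' analysis over the final portion of each replica after relaxation).
#'
#' @param encoding a \linkS4class{StateEncoding} (one replica).
#' @param frameWindow tail fraction of frames to analyze, in (0, 1]
#'   (default 0.5).
#' @param correction,nPerm,seed passed to \code{\link{correctedNormalizedMI}}.
#' @return an \linkS4class{MIMatrix}.
#' @export
miMatrix <- function(encoding, frameWindow = 0.5,
                     correction = c("analytic", "permutation"),
                     nPerm = 200, seed = 1) {
  correction <- match.arg(correction)
  st <- encoding@states
  n <- nrow(st)
  if (n < 2) stop("need at least 2 valid fragments", call. = FALSE)
  F <- ncol(st)
  from <- F - floor(F * frameWindow) + 1L
  if (from > F - 1) stop("analysis window must contain at least 2 frames",
                         call. = FALSE)
  win <- st[, from:F, drop = FALSE]
  v <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v[i, j] <- v[j, i] <- correctedNormalizedMI(
      win[i, ], win[j, ], correction = correction, nPerm = nPerm,
      seed = .derivedSeed(seed, i * 1000L + j))
  }
  new("MIMatrix", values = v, fragments = encoding@fragments,
      nFramesUsed = ncol(win))
}

.pairTable <- function(mats) {
  frag <- mats[[1]]@fragments
  for (m in mats) if (!identical(m@fragments, frag))
    stop("fragment sets differ between replicas/conditions", call. = FALSE)
  n <- length(frag)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  vals <- vapply(mats, function(m) m@values[idx], numeric(nrow(idx)))
  list(frag = frag, idx = idx, vals = matrix(vals, nrow = nrow(idx)))
}

#' Differential coupling between bound and unbound MI matrices
#'
#' Per fragment pair: condition means of the corrected normalized MI across
#' replicas, the log2 fold change
#' log2((mean_bound + pseudocount) / (mean_unbound + pseudocount)), and a
#' per-pair p-value, Benjamini-Hochberg adjusted across all pairs. Three
#' tests are available: \code{"moderated"} (default) fits the two-condition
#' contrast with limma and moderates the per-pair variance across all
#' fragment pairs (empirical-Bayes, with a mean-variance trend), which is
#' the appropriate choice at the typical 3-versus-3 replica design where
#' per-pair variance estimates alone are unstable; \code{"welch"} is a
#' plain per-pair Welch t-test; \code{"permutation"} is a replica-label
#' permutation test on |mean difference| (exhaustive when the number of
#' label assignments is at most 252, otherwise 10,000 seeded draws — note
#' its p-values are floored at 1/20 for 3v3 designs). With fewer than 2
#' replicas per condition p is NA and the fold change is still reported.
#'
#' @param bound,unbound lists of per-replica \linkS4class{MIMatrix} objects
#'   over identical fragment sets.
#' @param pseudocount guard against zero MI in fold changes (default 1e-6).
#' @param test "moderated" (default), "welch" or "permutation".
#' @param seed RNG seed for sampled permutations.
#' @return data.frame (fragment_i, fragment_j, mean_bound, mean_unbound,
#'   log2fc, p_value, padj).
#' @export
diffCoupling <- function(bound, unbound, pseudocount = 1e-6,
                         test = c("moderated", "welch", "permutation"),
                         seed = 1) {
  test <- match.arg(test)
  pb <- .pairTable(bound)
  pu <- .pairTable(unbound)
  if (!identical(pb$frag, pu$frag))
    stop("fragment sets differ between conditions", call. = FALSE)
  nb <- length(bound); nu <- length(unbound)
  mb <- rowMeans(pb$vals); mu <- rowMeans(pu$vals)
  lfc <- log2((mb + pseudocount) / (mu + pseudocount))
  p <- rep(NA_real_, length(lfc))
  if (nb >= 2 && nu >= 2) {
    if (test == "moderated") {
      y <- cbind(pb$vals, pu$vals)
      design <- cbind(intercept = 1,
                      bound = c(rep(1, nb), rep(0, nu)))
      # zero-variance rows (MI clamped at 0 in every replica) are expected;
      # limma offsets them, so silence that advisory
      fit <- suppressWarnings(
        limma::eBayes(limma::lmFit(y, design),
                      trend = nrow(y) >= 10))
      p <- fit$p.value[, "bound"]
    } else if (test == "welch") {
      for (k in seq_along(p)) {
        b <- pb$vals[k, ]; u <- pu$vals[k, ]
        if (stats::sd(b) == 0 && stats::sd(u) == 0) {
          p[k] <- if (mean(b) == mean(u)) 1 else 0
        } else {
          p[k] <- tryCatch(stats::t.test(b, u)$p.value,
                           error = function(e) NA_real_)
        }
      }
    } else {
      p <- .permutationPvalues(pb$vals, pu$vals, seed)
    }
  }
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(
    fragment_i = pb$frag[pb$idx[, 1]], fragment_j = pb$frag[pb$idx[, 2]],
    mean_bound = mb, mean_unbound = mu, log2fc = lfc,
    p_value = p, padj = padj, stringsAsFactors = FALSE)
}

# Replica-label permutation p-values on |difference of condition means|.
# Exhaustive over all choose(nb+nu, nb) assignments when feasible; the
# observed labelling is part of the reference set, so p >= 1/N.
.permutationPvalues <- function(bvals, uvals, seed, maxExhaustive = 252,
                                nDraw = 10000) {
  nb <- ncol(bvals); nu <- ncol(uvals)
  all <- cbind(bvals, uvals)
  n <- nb + nu
  nComb <- choose(n, nb)
  assignments <- if (nComb <= maxExhaustive) {
    utils::combn(n, nb, simplify = FALSE)
  } else {
    .withSeed(seed, lapply(seq_len(nDraw), function(k) sample(n, nb)))
  }
  obs <- abs(rowMeans(bvals) - rowMeans(uvals))
  stats <- vapply(assignments, function(a)
    abs(rowMeans(all[, a, drop = FALSE]) -
        rowMeans(all[, -a, drop = FALSE])), numeric(nrow(all)))
  stats <- matrix(stats, nrow = nrow(all))
  rowMeans(stats >= obs - 1e-12)
}

#' Call differential-coupling hubs
#'
#' Hubs are fragment pairs whose coupling differs between the bound and the
#' unbound ensemble beyond |log2FC| > lfcThreshold at BH-adjusted
#' p < alpha. Direction is bound-favoured for positive fold changes and
#' unbound-favoured for negative ones.
#'
#' @param dc data.frame from \code{\link{diffCoupling}}.
#' @param lfcThreshold absolute log2 fold-change threshold (default 2).
#' @param alpha FDR threshold (default 0.01).
#' @return data.frame of hub pairs with a \code{direction} column.
#' @export
callHubs <- function(dc, lfcThreshold = 2, alpha = 0.01) {
  stopifnot(all(c("log2fc", "padj") %in% names(dc)))
  hit <- !is.na(dc$padj) & abs(dc$log2fc) > lfcThreshold & dc$padj < alpha
  out <- dc[hit, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "bound", "unbound")
  rownames(out) <- NULL
  out
}

#' Per-residue hub frequency
#'
#' Fragment i covers residues i..i+3; the count at residue r is the number
#' of hub pairs with at least one member fragment covering r.
#'
#' @param hubs data.frame from \code{\link{callHubs}}.
#' @param L chain length in residues.
#' @return data.frame (residue, count).
#' @export
positionHubFrequency <- function(hubs, L) {
  counts <- integer(L)
  for (k in seq_len(nrow(hubs))) {
    cov <- unique(c(hubs$fragment_i[k] + 0:3, hubs$fragment_j[k] + 0:3))
    cov <- cov[cov >= 1 & cov <= L]
    counts[cov] <- counts[cov] + 1L
  }
  data.frame(residue = seq_len(L), count = counts)
}
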