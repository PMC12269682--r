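#' @import methods
NULL

#' Structure: a single-conformation molecular model
#'
#' Holds an ordered atom table and one set of Cartesian coordinates in
#' Angstrom. Atom rows carry (atom_id, atom_name, element, residue_index,
#' residue_name, chain_id, mass); residue indices are 1-based and per chain,
#' following PDB conventions.
#'
#' @slot atoms data.frame of per-atom records.
#' @slot coords numeric matrix, nAtoms x 3, Angstrom.
#' @aliases Structure
#' @exportClass Structure
setClass("Structure",
         representation(atoms = "data.frame", coords = "matrix"))

.ATOM_COLS <- c("atom_id", "atom_name", "element", "residue_index",
                "residue_name", "chain_id", "mass")

.validAtoms <- function(atoms) {
  if (!all(.ATOM_COLS %in% names(atoms)))
    return(paste("atom table must have columns:",
                 paste(.ATOM_COLS, collapse = ", ")))
  if (any(atoms$mass <= 0)) return("all atom masses must be > 0")
  key <- paste(atoms$atom_name, atoms$residue_index, atoms$chain_id)
  if (anyDuplicated(key))
    return("(atom_name, residue_index, chain_id) must be unique")
  TRUE
}

setValidity("Structure", function(object) {
  v <- .validAtoms(object@atoms)
  if (!isTRUE(v)) return(v)
  if (nrow(object@coords) != nrow(object@atoms))
    return("coords must have one row per atom")
  if (ncol(object@coords) != 3) return("coords must be n x 3")
  if (!all(is.finite(object@coords))) return("all coordinates must be finite")
  TRUE
})

#' Trajectory: a multi-frame coordinate ensemble over a fixed topology
#'
#' Frames are stored as an F x A x 3 array in Angstrom with nondecreasing
#' frame times in picoseconds. The topology is the same atom table used by
#' \linkS4class{Structure}.
#'
#' @slot topology data.frame of per-atom records.
#' @slot coords numeric array, frames x atoms x 3, Angstrom.
#' @slot frameTimes numeric vector of times (ps), nondecreasing.
#' @aliases Trajectory
#' @exportClass Trajectory
setClass("Trajectory",
         representation(topology = "data.frame", coords = "array",
                        frameTimes = "numeric"))

setValidity("Trajectory", function(object) {
  v <- .validAtoms(object@topology)
  if (!isTRUE(v)) return(v)
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 3) return("coords must be F x A x 3")
  if (d[1] < 1) return("at least one frame required")
  if (d[2] != nrow(object@topology))
    return("coords atom dimension must match topology")
  if (!all(is.finite(object@coords))) return("all coordinates must be finite")
  if (length(object@frameTimes) != d[1])
    return("frameTimes must have one entry per frame")
  if (is.unsorted(object@frameTimes)) return("frameTimes must be nondecreasing")
  TRUE
})

#' RegionMap: FW/CDR region annotation for antibody chains
#'
#' Inclusive residue ranges labelled with the seven variable-domain regions
#' (FW1..FW4, CDR1..CDR3) under a named numbering scheme (e.g. IMGT). Region
#' maps are produced by external numbering tools and ingested as tables.
#'
#' @slot entries data.frame with columns chain_id, region, start, end.
#' @slot scheme character scalar naming the numbering scheme.
#' @aliases RegionMap
#' @exportClass RegionMap
setClass("RegionMap",
         representation(entries = "data.frame", scheme = "character"))

.REGION_LABELS <- c("FW1", "FW2", "FW3", "FW4", "CDR1", "CDR2", "CDR3")

setValidity("RegionMap", function(object) {
  e <- object@entries
  need <- c("chain_id", "region", "start", "end")
  if (!all(need %in% names(e)))
    return("entries must have columns chain_id, region, start, end")
  if (!all(e$region %in% .REGION_LABELS))
    return(paste("unknown region label(s):",
                 paste(setdiff(e$region, .REGION_LABELS), collapse = ", ")))
  if (any(e$end < e$start)) return("region end must be >= start")
  for (ch in unique(e$chain_id)) {
    sub <- e[e$chain_id == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)]))
      return(paste0("overlapping region ranges in chain ", ch))
  }
  TRUE
})

#' ChainSequence: the amino-acid sequence of one chain
#'
#' One-letter residues paired with strictly increasing residue indices, so
#' that positions line up with structure numbering and region maps.
#'
#' @slot chainId character scalar.
#' @slot residueIndex integer vector, strictly increasing.
#' @slot residues character vector of 1-letter codes (X for unknown).
#' @aliases ChainSequence
#' @exportClass ChainSequence
setClass("ChainSequence",
         representation(chainId = "character", residueIndex = "integer",
                        residues = "character"))

setValidity("ChainSequence", function(object) {
  if (length(object@residueIndex) != length(object@residues))
    return("residueIndex and residues must have equal length")
  if (any(diff(object@residueIndex) <= 0))
    return("residueIndex must be strictly increasing")
  ok <- object@residues %in% c(.AA1, "X")
  if (!all(ok))
    return(paste("invalid residue letter(s):",
                 paste(unique(object@residues[!ok]), collapse = ", ")))
  TRUE
})

#' MutationGrid: per-position substitution probabilities
#'
#' An L x 20 matrix of per-position amino-acid probabilities from a saturated
#' masked scan; each row is a probability distribution over the 20 amino
#' acids in a fixed alphabet order.
#'
#' @slot sequence the scanned \linkS4class{ChainSequence}.
#' @slot scores numeric L x 20 matrix, rows summing to 1 within 1e-6.
#' @slot aaOrder character vector of the 20 amino-acid column labels.
#' @aliases MutationGrid
#' @exportClass MutationGrid
setClass("MutationGrid",
         representation(sequence = "ChainSequence", scores = "matrix",
                        aaOrder = "character"))

setValidity("MutationGrid", function(object) {
  if (ncol(object@scores) != 20) return("scores must have 20 columns")
  if (nrow(object@scores) != length(object@sequence@residues))
    return("scores must have one row per sequence position")
  if (length(object@aaOrder) != 20 || anyDuplicated(object@aaOrder))
    return("aaOrder must be 20 distinct letters")
  if (any(object@scores < 0 | object@scores > 1))
    return("probabilities must lie in [0, 1]")
  if (any(abs(rowSums(object@scores) - 1) > 1e-6))
    return("each row must sum to 1 within 1e-6")
  TRUE
})

#' ComSelection: a named atom selection for center-of-mass descriptors
#'
#' @slot name character scalar.
#' @slot indices integer vector of atom indices (1-based into the topology).
#' @slot massWeighted logical; mass-weighted COM (default) or plain centroid.
#' @aliases ComSelection
#' @exportClass ComSelection
setClass("ComSelection",
         representation(name = "character", indices = "integer",
                        massWeighted = "logical"))

setValidity("ComSelection", function(object) {
  if (length(object@indices) == 0) return("selection must be non-empty")
  if (any(object@indices < 1)) return("atom indices must be >= 1")
  TRUE
})

#' ContactSet: native heavy-atom contacts of a reference structure
#'
#' @slot pairs data.frame with atom indices i, j, reference distance (Angstrom)
#'   and the residue/chain labels of both partners.
#' @slot cutoff numeric, distance cutoff (Angstrom) used to define contacts.
#' @slot exclusion integer, minimum intra-chain sequence separation.
#' @aliases ContactSet
#' @exportClass ContactSet
setClass("ContactSet",
         representation(pairs = "data.frame", cutoff = "numeric",
                        exclusion = "integer"))

setValidity("ContactSet", function(object) {
  if (nrow(object@pairs) > 0 && any(object@pairs$ref_dist > object@cutoff))
    return("all reference distances must be <= cutoff")
  TRUE
})

#' AlphabetPrototypes: a structural alphabet of four-point backbone fragments
#'
#' M canonical fragments, each 4 Calpha positions in Angstrom, used to
#' discretize local backbone conformation frame by frame (M32K25-style; any
#' M-state alphabet in the same schema is accepted).
#'
#' @slot labels integer vector of state labels (1..M).
#' @slot points numeric array, M x 4 x 3.
#' @aliases AlphabetPrototypes
#' @exportClass AlphabetPrototypes
setClass("AlphabetPrototypes",
         representation(labels = "integer", points = "array"))

setValidity("AlphabetPrototypes", function(object) {
  d <- dim(object@points)
  if (length(d) != 3 || d[2] != 4 || d[3] != 3)
    return("points must be M x 4 x 3")
  if (length(object@labels) != d[1]) return("one label per prototype")
  if (anyDuplicated(object@labels)) return("labels must be unique")
  TRUE
})

#' StateEncoding: structural-alphabet state sequences of a trajectory
#'
#' Integer states per fragment (rows) and frame (columns). Fragment i covers
#' residues i..i+3 of the encoded chain; fragments without complete Calpha
#' coverage are excluded.
#'
#' @slot states integer matrix, fragments x frames.
#' @slot fragments integer vector of fragment start indices.
#' @slot M integer, alphabet cardinality.
#' @aliases StateEncoding
#' @exportClass StateEncoding
setClass("StateEncoding",
         representation(states = "matrix", fragments = "integer",
                        M = "integer"))

setValidity("StateEncoding", function(object) {
  if (nrow(object@states) != length(object@fragments))
    return("one state row per fragment")
  if (any(object@states < 1 | object@states > object@M))
    return("states must lie in 1..M")
  TRUE
})

#' MIMatrix: corrected normalized mutual information between fragment pairs
#'
#' Symmetric matrix of corrected normalized MI values in [0, 1] over the
#' fragments of one replica, computed over a designated frame window.
#'
#' @slot values numeric symmetric matrix (diagonal NA).
#' @slot fragments integer fragment start indices (row/column order).
#' @slot nFramesUsed integer, frames in the analysis window.
#' @aliases MIMatrix
#' @exportClass MIMatrix
setClass("MIMatrix",
         representation(values = "matrix", fragments = "integer",
                        nFramesUsed = "integer"))

setValidity("MIMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (nrow(v) != length(object@fragments))
    return("one row/column per fragment")
  off <- v[upper.tri(v)]
  if (any(!is.na(off) & (off < 0 | off > 1)))
    return("MI values must lie in [0, 1]")
  if (!isTRUE(all.equal(v[upper.tri(v)], t(v)[upper.tri(v)])))
    return("values must be symmetric")
  TRUE
})

#' InteractionNetwork: frame-frequency graph of residue interactions
#'
#' Nodes are residues (chain:index); edges carry an interaction type and the
#' fraction of frames in which at least one event of that type linked the
#' pair.
#'
#' @slot edges data.frame with columns res_i, res_j, type, frequency.
#' @slot nFrames integer, total frames the frequencies refer to.
#' @slot topologyId character scalar identifying the source topology
#'   (used to refuse differencing networks from different systems).
#' @aliases InteractionNetwork
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
         representation(edges = "data.frame", nFrames = "integer",
                        topologyId = "character"))

setValidity("InteractionNetwork", function(object) {
  e <- object@edges
  if (nrow(e) == 0) return(TRUE)
  if (any(e$frequency < 0 | e$frequency > 1))
    return("edge frequencies must lie in [0, 1]")
  if (any(e$res_i == e$res_j)) return("self-edges are not allowed")
  TRUE
})
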