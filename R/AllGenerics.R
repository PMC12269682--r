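#' @include AllClasses.R
NULL

#' Accessors for fwdyn S4 containers
#'
#' \code{atoms} returns the per-atom table of a \linkS4class{Structure} or the
#' topology of a \linkS4class{Trajectory}; \code{coords} the coordinates
#' (matrix or F x A x 3 array); \code{nFrames}, \code{nAtoms} and
#' \code{frameTimes} the obvious trajectory dimensions; \code{frameCoords} one
#' frame as an A x 3 matrix; \code{regionEntries} the range table of a
#' \linkS4class{RegionMap}; \code{scores} the L x 20 probability matrix of a
#' \linkS4class{MutationGrid}; \code{states} the fragment x frame matrix of a
#' \linkS4class{StateEncoding}; \code{miValues} the symmetric matrix of a
#' \linkS4class{MIMatrix}; \code{edges} the edge table of an
#' \linkS4class{InteractionNetwork}; \code{contactPairs} the pair table of a
#' \linkS4class{ContactSet}.
#'
#' @param x the object.
#' @param frame integer frame index (for \code{frameCoords}).
#' @return the slot contents described above.
#' @name accessors
#' @aliases atoms coords nFrames nAtoms frameTimes frameCoords regionEntries
#'   scores states miValues edges contactPairs
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("frameCoords", function(x, frame) standardGeneric("frameCoords"))
#' @rdname accessors
#' @export
setGeneric("regionEntries", function(x) standardGeneric("regionEntries"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("states", function(x) standardGeneric("states"))
#' @rdname accessors
#' @export
setGeneric("miValues", function(x) standardGeneric("miValues"))
#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @rdname accessors
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

#' @rdname accessors
setMethod("atoms", "Structure", function(x) x@atoms)
#' @rdname accessors
setMethod("atoms", "Trajectory", function(x) x@topology)
#' @rdname accessors
setMethod("coords", "Structure", function(x) x@coords)
#' @rdname accessors
setMethod("coords", "Trajectory", function(x) x@coords)
#' @rdname accessors
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))
#' @rdname accessors
setMethod("nAtoms", "Trajectory", function(x) nrow(x@topology))
#' @rdname accessors
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])
#' @rdname accessors
setMethod("frameTimes", "Trajectory", function(x) x@frameTimes)
#' @rdname accessors
setMethod("frameCoords", "Trajectory", function(x, frame) {
  stopifnot(frame >= 1, frame <= dim(x@coords)[1])
  matrix(x@coords[frame, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
})
#' @rdname accessors
setMethod("regionEntries", "RegionMap", function(x) x@entries)
#' @rdname accessors
setMethod("scores", "MutationGrid", function(x) x@scores)
#' @rdname accessors
setMethod("states", "StateEncoding", function(x) x@states)
#' @rdname accessors
setMethod("miValues", "MIMatrix", function(x) x@values)
#' @rdname accessors
setMethod("edges", "InteractionNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("contactPairs", "ContactSet", function(x) x@pairs)

setMethod("show", "Structure", function(object) {
  cat("Structure:", nrow(object@atoms), "atoms,",
      length(unique(object@atoms$chain_id)), "chain(s)\n")
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat("Trajectory:", d[1], "frames x", d[2], "atoms;",
      "t =", min(object@frameTimes), "-", max(object@frameTimes), "ps\n")
})

setMethod("show", "RegionMap", function(object) {
  cat("RegionMap (", object@scheme, "): ", nrow(object@entries),
      " ranges over chain(s) ",
      paste(unique(object@entries$chain_id), collapse = ", "), "\n", sep = "")
})

setMethod("show", "ChainSequence", function(object) {
  cat("ChainSequence ", object@chainId, " (", length(object@residues),
      " aa): ", paste(object@residues, collapse = ""), "\n", sep = "")
})

setMethod("show", "MutationGrid", function(object) {
  cat("MutationGrid:", nrow(object@scores), "positions x 20 amino acids\n")
})

setMethod("show", "StateEncoding", function(object) {
  cat("StateEncoding:", nrow(object@states), "fragments x",
      ncol(object@states), "frames, M =", object@M, "\n")
})

setMethod("show", "MIMatrix", function(object) {
  cat("MIMatrix:", length(object@fragments), "fragments,",
      object@nFramesUsed, "frames in window\n")
})

setMethod("show", "InteractionNetwork", function(object) {
  cat("InteractionNetwork:", nrow(object@edges), "edges over",
      object@nFrames, "frames\n")
})

setMethod("show", "ContactSet", function(object) {
  cat("ContactSet:", nrow(object@pairs), "native contacts (cutoff ",
      object@cutoff, " A, exclusion ", object@exclusion, ")\n")
})

setMethod("show", "ComSelection", function(object) {
  cat("ComSelection '", object@name, "': ", length(object@indices),
      " atoms (mass-weighted: ", object@massWeighted, ")\n", sep = "")
})

#' Construct a named atom selection
#'
#' @param name selection name (used in outputs).
#' @param indices 1-based atom indices into the topology.
#' @param massWeighted use mass weighting for the COM (default TRUE).
#' @return a \linkS4class{ComSelection}.
#' @export
comSelection <- function(name, indices, massWeighted = TRUE) {
  new("ComSelection", name = as.character(name),
      indices = as.integer(indices), massWeighted = isTRUE(massWeighted))
}
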