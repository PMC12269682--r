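#' @include AllClasses.R
NULL

# Light sanity scan of ATOM/HETATM records so parse failures report the
# offending line number (bio3d does the actual parsing).
.scanPdbLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM record at line ", i, " of ", path,
           ": record shorter than coordinate fields", call. = FALSE)
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz))))
      stop("malformed ATOM/HETATM record at line ", i, " of ", path,
           ": non-numeric coordinate field", call. = FALSE)
  }
  invisible(length(idx))
}

.atomsFromBio3d <- function(atom) {
  element <- atom$elesy
  missing <- is.na(element) | !nzchar(trimws(element))
  if (any(missing)) {
    # fall back to the first alphabetic character of the atom name
    guess <- toupper(sub("^[0-9 ]*([A-Za-z]).*$", "\\1", atom$elety[missing]))
    element[missing] <- guess
  }
  chain <- atom$chain
  chain[is.na(chain)] <- ""
  data.frame(
    atom_id = as.integer(atom$eleno),
    atom_name = trimws(atom$elety),
    element = toupper(trimws(element)),
    residue_index = as.integer(atom$resno),
    residue_name = trimws(atom$resid),
    chain_id = chain,
    mass = .elementMass(element),
    stringsAsFactors = FALSE
  )
}

#' Read a structure or multi-model trajectory from a PDB file
#'
#' Single-model files (or an explicit \code{model} index) yield a
#' \linkS4class{Structure}; multi-model files read with \code{model = "all"}
#' yield a \linkS4class{Trajectory} with one frame per MODEL record, in file
#' order. Coordinates are in Angstrom; atom order is preserved from the file.
#'
#' @param path path to a PDB file.
#' @param model \code{"all"} (default) or a 1-based model index.
#' @param frameTimes optional frame times in ps (default 0, 1, ... F-1); PDB
#'   files carry no time information.
#' @return a \linkS4class{Structure} or \linkS4class{Trajectory}.
#' @examples
#' pdb <- system.file("extdata", "toy_dipeptide.pdb", package = "fwdyn")
#' readStructure(pdb)
#' @export
readStructure <- function(path, model = "all", frameTimes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  n <- .scanPdbLines(path)
  if (n == 0) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- .atomsFromBio3d(pdb$atom)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  F <- nrow(xyz)
  if (any(!is.finite(xyz))) stop("non-finite coordinates in ", path, call. = FALSE)
  if (identical(model, "all") && F > 1) {
    co <- array(NA_real_, dim = c(F, nrow(atoms), 3))
    for (f in seq_len(F)) co[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    if (is.null(frameTimes)) frameTimes <- as.numeric(seq_len(F) - 1)
    return(new("Trajectory", topology = atoms, coords = co,
               frameTimes = frameTimes))
  }
  m <- if (identical(model, "all")) 1L else as.integer(model)
  if (m < 1 || m > F)
    stop("model index ", m, " out of range (file has ", F, " model(s))",
         call. = FALSE)
  new("Structure", atoms = atoms,
      coords = matrix(xyz[m, ], ncol = 3, byrow = TRUE,
                      dimnames = list(NULL, c("x", "y", "z"))))
}

#' Write a structure or trajectory as (multi-model) PDB
#'
#' @param x a \linkS4class{Structure} or \linkS4class{Trajectory}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeStructure <- function(x, path) {
  at <- atoms(x)
  xyz <- if (is(x, "Trajectory")) {
    F <- nFrames(x)
    t(vapply(seq_len(F), function(f) as.vector(t(frameCoords(x, f))),
             numeric(3 * nAtoms(x))))
  } else {
    matrix(as.vector(t(x@coords)), nrow = 1)
  }
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   eleno = at$atom_id, elety = at$atom_name,
                   resno = at$residue_index, resid = at$residue_name,
                   chain = ifelse(nzchar(at$chain_id), at$chain_id, " "),
                   elesy = at$element)
  invisible(path)
}

#' Extract the one-letter sequence of a chain
#'
#' Standard residues map through the 3-to-1 letter code; non-standard
#' residues (ligands, modified amino acids) map to X.
#'
#' @param s a \linkS4class{Structure} or \linkS4class{Trajectory}.
#' @param chainId chain identifier.
#' @return a \linkS4class{ChainSequence}.
#' @export
extractSequence <- function(s, chainId) {
  at <- atoms(s)
  if (!chainId %in% at$chain_id)
    stop("chain '", chainId, "' not found; available chains: ",
         paste(sort(unique(at$chain_id)), collapse = ", "), call. = FALSE)
  sub <- at[at$chain_id == chainId, , drop = FALSE]
  keep <- !duplicated(sub$residue_index)
  idx <- sub$residue_index[keep]
  res <- .aa321(sub$residue_name[keep])
  o <- order(idx)
  new("ChainSequence", chainId = chainId, residueIndex = as.integer(idx[o]),
      residues = res[o])
}

#' Construct a ChainSequence from a plain string
#'
#' @param x one-letter amino-acid string.
#' @param chainId chain identifier (default "A").
#' @param start residue index of the first position (default 1).
#' @return a \linkS4class{ChainSequence}.
#' @export
chainSequence <- function(x, chainId = "A", start = 1L) {
  res <- strsplit(toupper(x), "")[[1]]
  new("ChainSequence", chainId = chainId,
      residueIndex = as.integer(seq_along(res) + start - 1L), residues = res)
}

#' Load a FW/CDR region annotation table
#'
#' Expects a TSV with header columns chain_id, region, start, end; ranges are
#' inclusive and 1-based. Overlapping ranges or unknown region labels are
#' rejected. Region maps come from external numbering tools (e.g. IMGT via
#' ANARCI) and are ingested, never computed here.
#'
#' @param path TSV path.
#' @param scheme numbering scheme name recorded on the map (default "IMGT").
#' @return a \linkS4class{RegionMap}.
#' @export
loadRegionMap <- function(path, scheme = "IMGT") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chain_id", "region", "start", "end")
  if (!all(need %in% names(tab)))
    stop("region map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab$chain_id <- as.character(tab$chain_id)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  new("RegionMap", entries = tab[, need], scheme = scheme)
}

#' Construct a RegionMap from a data.frame
#'
#' @param entries data.frame with chain_id, region, start, end.
#' @param scheme numbering scheme name.
#' @return a \linkS4class{RegionMap}.
#' @export
regionMap <- function(entries, scheme = "IMGT") {
  entries$chain_id <- as.character(entries$chain_id)
  new("RegionMap", entries = entries, scheme = scheme)
}

#' Look up the region label of residue positions
#'
#' @param map a \linkS4class{RegionMap}.
#' @param chainId chain identifier.
#' @param positions residue indices.
#' @return character vector of region labels (NA where unlabelled).
#' @export
regionLookup <- function(map, chainId, positions) {
  e <- map@entries[map@entries$chain_id == chainId, , drop = FALSE]
  out <- rep(NA_character_, length(positions))
  for (k in seq_len(nrow(e)))
    out[positions >= e$start[k] & positions <= e$end[k]] <- e$region[k]
  out
}

#' Write a result table as TSV or JSON
#'
#' Columns keep their given order; floating-point values are written at 6
#' significant digits; missing values serialize as "NA" (TSV) / null (JSON).
#'
#' @param records a data.frame.
#' @param path output path.
#' @param format "tsv" (default) or "json".
#' @return invisibly, \code{path}.
#' @export
writeResultTable <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  if (format == "tsv") {
    ok <- tryCatch({
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write table to ", path, ": ",
                          conditionMessage(ok), call. = FALSE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
readFasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path) {
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
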