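#' @include AllClasses.R
NULL

#' Saturated per-position masked mutational scan
#'
#' Scores every position of a sequence with a pluggable per-position scorer:
#' the position is masked while the remainder of the sequence is left intact,
#' and the scorer returns 20 raw scores for the masked position, in the
#' standard alphabet order ACDEFGHIKLMNPQRSTVWY. Scorers declare through
#' their \code{"emits"} attribute whether they return \code{"logits"}
#' (converted here by a plain softmax, temperature 1) or
#' \code{"probabilities"} (validated to sum to 1 within 1e-6). The scorer is
#' invoked exactly once per position.
#'
#' @param seq a \linkS4class{ChainSequence}.
#' @param scorer function(residues, position) -> numeric(20); must carry an
#'   attribute \code{emits} equal to "logits" or "probabilities".
#' @return a \linkS4class{MutationGrid}.
#' @seealso \code{\link{genMutationScores}} for a deterministic mock scorer.
#' @export
scanPositions <- function(seq, scorer) {
  stopifnot(is(seq, "ChainSequence"), is.function(scorer))
  emits <- attr(scorer, "emits")
  if (is.null(emits) || !emits %in% c("logits", "probabilities"))
    stop("scorer must declare attr(scorer, 'emits') as 'logits' or ",
         "'probabilities'", call. = FALSE)
  L <- length(seq@residues)
  grid <- matrix(NA_real_, L, 20, dimnames = list(seq@residueIndex, .AA1))
  for (p in seq_len(L)) {
    raw <- scorer(seq@residues, p)
    if (length(raw) != 20)
      stop("scorer returned ", length(raw), " scores at position ", p,
           "; expected 20", call. = FALSE)
    if (any(!is.finite(raw)))
      stop("scorer returned non-finite score(s) at position ", p,
           call. = FALSE)
    if (emits == "logits") {
      grid[p, ] <- .softmax(raw)
    } else {
      if (any(raw < 0) || abs(sum(raw) - 1) > 1e-6)
        stop("scorer probabilities at position ", p,
             " are negative or do not sum to 1", call. = FALSE)
      grid[p, ] <- raw / sum(raw)
    }
  }
  new("MutationGrid", sequence = seq, scores = grid, aaOrder = .AA1)
}

#' Wild-type probability and rank profile of a mutation grid
#'
#' The wild-type rank at a position is 1 plus the number of amino acids whose
#' probability is strictly greater than the wild type's, so rank 1 means the
#' wild type is (jointly) the best-scoring residue and ties share the best
#' rank. Positions whose wild type is X have no defined rank and are flagged
#' missing.
#'
#' @param grid a \linkS4class{MutationGrid}.
#' @param map optional \linkS4class{RegionMap} used to annotate positions.
#' @return data.frame with columns position, wt, wt_probability, wt_rank,
#'   region (NA without a map).
#' @export
wtRankProfile <- function(grid, map = NULL) {
  seq <- grid@sequence
  sc <- grid@scores
  L <- nrow(sc)
  wt <- seq@residues
  prob <- rep(NA_real_, L)
  rank <- rep(NA_integer_, L)
  for (p in seq_len(L)) {
    if (wt[p] == "X") next
    j <- match(wt[p], grid@aaOrder)
    prob[p] <- sc[p, j]
    rank[p] <- 1L + sum(sc[p, ] > sc[p, j])
  }
  region <- if (is.null(map)) rep(NA_character_, L)
            else regionLookup(map, seq@chainId, seq@residueIndex)
  data.frame(position = seq@residueIndex, wt = wt, wt_probability = prob,
             wt_rank = rank, region = region, stringsAsFactors = FALSE)
}

#' Median and IQR of wild-type rank/probability per aligned position and region
#'
#' Aggregates scan profiles across antibodies aligned on a common numbering:
#' per-position medians and inter-quartile ranges of the wild-type rank and
#' probability, plus per-region summaries over all positions of all profiles.
#'
#' @param results list of profiles as returned by \code{\link{wtRankProfile}},
#'   all annotated with the same region scheme.
#' @param map optional \linkS4class{RegionMap} to (re)annotate positions.
#' @param chainId chain the map refers to (default "A"); ignored without map.
#' @return list with \code{perPosition} and \code{perRegion} data.frames.
#' @export
regionSummary <- function(results, map = NULL, chainId = "A") {
  stopifnot(is.list(results), length(results) >= 1)
  all <- do.call(rbind, results)
  if (!is.null(map))
    all$region <- regionLookup(map, chainId, all$position)
  iqr0 <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else unname(stats::quantile(x, .75) - stats::quantile(x, .25))
  }
  med0 <- function(x) { x <- x[!is.na(x)]; if (!length(x)) NA_real_ else stats::median(x) }
  pos <- sort(unique(all$position))
  perPos <- data.frame(
    position = pos,
    region = all$region[match(pos, all$position)],
    median_rank = vapply(pos, function(p) med0(all$wt_rank[all$position == p]), 0),
    iqr_rank = vapply(pos, function(p) iqr0(all$wt_rank[all$position == p]), 0),
    median_probability = vapply(pos, function(p) med0(all$wt_probability[all$position == p]), 0),
    iqr_probability = vapply(pos, function(p) iqr0(all$wt_probability[all$position == p]), 0),
    stringsAsFactors = FALSE
  )
  regs <- .REGION_LABELS[.REGION_LABELS %in% all$region]
  if (!is.null(map)) {
    present <- unique(map@entries$region[map@entries$chain_id == chainId])
    gone <- setdiff(present, regs)
    if (length(gone))
      warning("region(s) with no scanned positions omitted: ",
              paste(gone, collapse = ", "), call. = FALSE)
  }
  perReg <- data.frame(
    region = regs,
    median_rank = vapply(regs, function(r) med0(all$wt_rank[all$region %in% r]), 0),
    iqr_rank = vapply(regs, function(r) iqr0(all$wt_rank[all$region %in% r]), 0),
    median_probability = vapply(regs, function(r) med0(all$wt_probability[all$region %in% r]), 0),
    iqr_probability = vapply(regs, function(r) iqr0(all$wt_probability[all$region %in% r]), 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(perPosition = perPos, perRegion = perReg)
}

#' Rank correlation between wild-type confidence and germline identity
#'
#' Spearman rank correlation between per-antibody mean (or median) wild-type
#' probability and germline sequence identity. The p-value is exact for
#' n <= 9 without ties and uses the large-sample approximation otherwise
#' (as \code{stats::cor.test} does).
#'
#' @param wtProbs numeric vector, one aggregated WT probability per sequence.
#' @param identities numeric vector in [0, 1], germline identities.
#' @return list(rho, p_value, n, defined); \code{defined} is FALSE (with rho
#'   and p NA) when either vector is constant.
#' @export
germlineIdentityCorrelation <- function(wtProbs, identities) {
  stopifnot(length(wtProbs) == length(identities))
  n <- length(wtProbs)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(wtProbs) == 0 || stats::sd(identities) == 0) {
    warning("constant input vector: correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, defined = FALSE))
  }
  ct <- suppressWarnings(
    stats::cor.test(wtProbs, identities, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n, defined = TRUE)
}

#' Load a ddG table (single and/or double mutant records)
#'
#' TSV schema: pos1, wt1, mut1, pos2, wt2, mut2, ddg, scan_kind; pos2/wt2/mut2
#' are NA for single-mutant records. ddG is in kcal/mol; negative values are
#' stabilizing.
#'
#' @param path TSV path.
#' @return data.frame validated against the schema.
#' @export
loadDdGTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validateDdGTable(tab)
}

#' Validate a ddG table
#'
#' @param tab data.frame with columns pos1, wt1, mut1, pos2, wt2, mut2, ddg,
#'   scan_kind.
#' @return the validated data.frame (invisibly modified to canonical types).
#' @export
validateDdGTable <- function(tab) {
  need <- c("pos1", "wt1", "mut1", "pos2", "wt2", "mut2", "ddg", "scan_kind")
  if (!all(need %in% names(tab)))
    stop("ddG table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(tab$scan_kind %in% c("single", "double")))
    stop("scan_kind must be 'single' or 'double'", call. = FALSE)
  if (any(!is.finite(tab$ddg)))
    stop("all ddg values must be finite", call. = FALSE)
  dbl <- tab$scan_kind == "double"
  if (any(dbl & (is.na(tab$pos2) | tab$pos1 == tab$pos2)))
    stop("double records must carry two distinct positions", call. = FALSE)
  if (any(!dbl & !is.na(tab$pos2)))
    stop("single records must not carry a second position", call. = FALSE)
  tab
}

#' Classify ddG records as stabilizing or destabilizing
#'
#' Negative ddG is stabilizing, positive destabilizing; exact zero is
#' classified destabilizing (conservative tie rule: only strictly negative
#' ddG counts as stabilizing).
#'
#' @param tab a validated ddG table.
#' @return list(records, destabilizingFraction, stabilizingFraction); the
#'   records gain a \code{stability} column.
#' @export
classifyStability <- function(tab) {
  tab <- validateDdGTable(tab)
  tab$stability <- ifelse(tab$ddg < 0, "stabilizing", "destabilizing")
  fr <- mean(tab$stability == "destabilizing")
  list(records = tab, destabilizingFraction = fr, stabilizingFraction = 1 - fr)
}

#' Build a repertoire occurrence profile from sequences
#'
#' Per (position, amino acid) fraction of repertoire sequences carrying that
#' residue. Gaps/X are excluded from the counts, so per-position fractions
#' sum to at most 1.
#'
#' @param seqs character vector of equal-length sequences.
#' @return data.frame (position, aa, fraction) with attribute \code{L}.
#' @export
buildRepertoireProfile <- function(seqs) {
  stopifnot(length(seqs) >= 1)
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  if (any(nchar(seqs) != ncol(mat)))
    stop("sequences must have equal length", call. = FALSE)
  n <- nrow(mat)
  recs <- lapply(seq_len(ncol(mat)), function(p) {
    tt <- table(mat[, p])
    tt <- tt[names(tt) %in% .AA1]
    if (!length(tt)) return(NULL)
    data.frame(position = p, aa = names(tt),
               fraction = as.numeric(tt) / n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  attr(out, "L") <- ncol(mat)
  out
}

#' Occurrence fraction of an amino acid at a position in the repertoire
#'
#' @param profile profile as from \code{\link{buildRepertoireProfile}} or a
#'   TSV-loaded data.frame (position, aa, fraction) with attribute L.
#' @param position residue position.
#' @param aa one-letter amino acid.
#' @return the stored fraction, or 0 for an unobserved (position, aa).
#' @export
repertoireOccurrence <- function(profile, position, aa) {
  L <- attr(profile, "L")
  if (is.null(L)) L <- max(profile$position)
  if (position < 1 || position > L)
    stop("position ", position, " out of profile range 1..", L, call. = FALSE)
  hit <- profile$position == position & profile$aa == aa
  if (any(hit)) profile$fraction[which(hit)[1]] else 0
}

#' Filter candidate double mutants by stability and repertoire occurrence
#'
#' A candidate passes iff (a) the predicted double-mutant ddG is negative
#' (stabilizing) and (c) each mutant residue occurs in more than
#' \code{occThreshold} of the repertoire at its position. Sign agreement
#' between the double ddG and the sum of the single ddGs is recorded as a
#' \code{consistent} flag but is not required to pass: a double mutant may be
#' stabilizing even when each single substitution is individually
#' destabilizing. Doubles lacking a matching single record for either
#' position are flagged incomplete and excluded.
#'
#' @param singles single-mutant ddG table.
#' @param doubles double-mutant ddG table.
#' @param profile repertoire occurrence profile.
#' @param occThreshold minimum repertoire fraction (default 0.01, i.e. >1%).
#' @return data.frame of candidates with ddg values, occurrence fractions,
#'   pass/fail flags per filter and an overall \code{pass} column.
#' @export
filterDoubleMutants <- function(singles, doubles, profile,
                                occThreshold = 0.01) {
  singles <- validateDdGTable(singles)
  doubles <- validateDdGTable(doubles)
  singles <- singles[singles$scan_kind == "single", , drop = FALSE]
  doubles <- doubles[doubles$scan_kind == "double", , drop = FALSE]
  lookupSingle <- function(pos, wt, mut) {
    hit <- singles$pos1 == pos & singles$wt1 == wt & singles$mut1 == mut
    if (any(hit)) singles$ddg[which(hit)[1]] else NA_real_
  }
  out <- doubles[, c("pos1", "wt1", "mut1", "pos2", "wt2", "mut2", "ddg")]
  names(out)[names(out) == "ddg"] <- "ddg_double"
  out$ddg_single1 <- mapply(lookupSingle, out$pos1, out$wt1, out$mut1)
  out$ddg_single2 <- mapply(lookupSingle, out$pos2, out$wt2, out$mut2)
  out$occurrence1 <- mapply(function(p, a) repertoireOccurrence(profile, p, a),
                            out$pos1, out$mut1)
  out$occurrence2 <- mapply(function(p, a) repertoireOccurrence(profile, p, a),
                            out$pos2, out$mut2)
  out$incomplete <- is.na(out$ddg_single1) | is.na(out$ddg_single2)
  out$pass_ddg <- out$ddg_double < 0
  out$consistent <- !out$incomplete &
    sign(out$ddg_double) == sign(out$ddg_single1 + out$ddg_single2)
  out$pass_occurrence <- out$occurrence1 > occThreshold &
    out$occurrence2 > occThreshold
  out$pass <- !out$incomplete & out$pass_ddg & out$pass_occurrence
  attr(out, "occThreshold") <- occThreshold
  out
}
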