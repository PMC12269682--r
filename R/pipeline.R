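#' @include AllClasses.R
NULL

#' Write / read structural-alphabet state sequences as TSV
#'
#' Long format: columns fragment, frame, state.
#'
#' @param encoding a \linkS4class{StateEncoding}.
#' @param path TSV path.
#' @return \code{writeStateSequences}: invisibly, \code{path};
#'   \code{readStateSequences}: a \linkS4class{StateEncoding}.
#' @export
writeStateSequences <- function(encoding, path) {
  st <- encoding@states
  tab <- data.frame(
    fragment = rep(encoding@fragments, ncol(st)),
    frame = rep(seq_len(ncol(st)), each = nrow(st)),
    state = as.vector(st))
  writeResultTable(tab, path)
}

#' @rdname writeStateSequences
#' @param M alphabet cardinality (defaults to the maximum observed state).
#' @export
readStateSequences <- function(path, M = NULL) {
  tab <- utils::read.delim(path)
  frags <- sort(unique(tab$fragment))
  frames <- sort(unique(tab$frame))
  st <- matrix(NA_integer_, length(frags), length(frames))
  st[cbind(match(tab$fragment, frags), match(tab$frame, frames))] <-
    as.integer(tab$state)
  if (is.null(M)) M <- max(st)
  new("StateEncoding", states = st, fragments = as.integer(frags),
      M = as.integer(M))
}

#' Load named atom selections for a trajectory from a TSV
#'
#' Schema: name, chain, res_start, res_end, atom_filter (CA | heavy | all).
#' Rows sharing a name are unioned into one selection.
#'
#' @param path TSV path.
#' @param topology a \linkS4class{Structure} or \linkS4class{Trajectory}.
#' @return named list of \linkS4class{ComSelection} objects.
#' @export
loadSelections <- function(path, topology) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "chain", "res_start", "res_end", "atom_filter")
  if (!all(need %in% names(tab)))
    stop("selections file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  at <- atoms(topology)
  out <- list()
  for (nm in unique(tab$name)) {
    idx <- integer(0)
    for (k in which(tab$name == nm)) {
      sel <- at$chain_id == tab$chain[k] &
        at$residue_index >= tab$res_start[k] &
        at$residue_index <= tab$res_end[k]
      sel <- sel & switch(tab$atom_filter[k],
                          CA = at$atom_name == "CA",
                          heavy = at$element != "H",
                          all = TRUE,
                          stop("unknown atom_filter: ", tab$atom_filter[k],
                               call. = FALSE))
      idx <- union(idx, which(sel))
    }
    out[[nm]] <- comSelection(nm, sort(idx))
  }
  out
}

.KNOWN_STAGES <- c("simulate", "scan", "dynamics", "contacts", "coupling",
                   "mutfilter")

.stageDefaults <- list(
  simulate = list(what = "coupling", n_fragments = 10, M = 4, F = 2000,
                  replicas = 3, coupled_i = 2, coupled_j = 7,
                  strength_bound = 0.4736, strength_unbound = 0.16,
                  drift = 0, sigma = 0.1, frames = 200),
  scan = list(fasta = NULL, region_map = NULL, fw_bias = 10, cdr_bias = 0),
  dynamics = list(traj = NULL, selections = NULL, baseline_window = NULL,
                  unbinding_factor = 1.5, persistence = 0.1),
  contacts = list(traj = NULL, min_frequency = 0.1,
                  hbond_max_dist = 2.5, hbond_min_angle = 120,
                  pipi_max_dist = 5.5, pipi_max_angle = 30,
                  xh_max_dist = 4.5, xh_min_angle = 120),
  coupling = list(bound = NULL, unbound = NULL, window = 0.5,
                  correction = "analytic", test = "moderated", lfc = 2,
                  alpha = 0.01),
  mutfilter = list(singles = NULL, doubles = NULL, repertoire = NULL,
                   occ_threshold = 0.01)
)

.validateConfig <- function(config) {
  errs <- character(0)
  known <- c("seed", "output_dir", "stages")
  extra <- setdiff(names(config), known)
  if (length(extra)) errs <- c(errs, paste("unknown config key(s):",
                                           paste(extra, collapse = ", ")))
  if (is.null(config$output_dir)) errs <- c(errs, "output_dir is required")
  if (is.null(config$stages) || !length(config$stages))
    errs <- c(errs, "at least one stage is required")
  for (k in seq_along(config$stages)) {
    st <- config$stages[[k]]
    if (is.null(st$stage) || !st$stage %in% .KNOWN_STAGES) {
      errs <- c(errs, paste0("stage ", k, ": unknown stage '", st$stage, "'"))
      next
    }
    bad <- setdiff(names(st$params), names(.stageDefaults[[st$stage]]))
    if (length(bad))
      errs <- c(errs, paste0("stage ", st$stage, ": unknown parameter(s) ",
                             paste(bad, collapse = ", ")))
    for (p in c("fasta", "region_map", "traj", "selections", "singles",
                "doubles", "repertoire")) {
      v <- st$params[[p]]
      if (!is.null(v) && is.character(v) && !file.exists(v))
        errs <- c(errs, paste0("stage ", st$stage, ": missing input file ",
                               v))
    }
  }
  errs
}

.resolveParams <- function(stage, params) {
  utils::modifyList(.stageDefaults[[stage]], if (is.null(params)) list()
                    else params)
}

#' Run a configured analysis pipeline
#'
#' Executes the declared stages in order, writing stage outputs, a
#' deterministic run manifest (resolved parameters, seeds, input and output
#' checksums, package version) and a timestamped log into the output
#' directory. Any stage failure aborts with an error after writing a
#' partial manifest. Reruns with identical config and inputs reproduce
#' identical outputs.
#'
#' Config (JSON file or list): \code{seed}, \code{output_dir},
#' \code{stages} = list of \code{list(stage = <name>, params = <list>)}
#' with stages among simulate, scan, dynamics, contacts, coupling,
#' mutfilter. Unknown keys are rejected with a message listing every
#' offending key. Stages share in-memory results: e.g. a coupling stage
#' consumes the state sequences generated by a preceding simulate stage
#' when no explicit input paths are given.
#'
#' @param config path to a JSON config or an equivalent list.
#' @return invisibly, the finalized manifest list.
#' @export
runPipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  errs <- .validateConfig(config)
  if (length(errs))
    stop("invalid pipeline config:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  outDir <- config$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  logPath <- file.path(outDir, "run.log")
  logLine <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                               ..., "\n", sep = "", file = logPath,
                               append = TRUE)
  cat("", file = logPath)
  manifest <- list(
    package = "fwdyn",
    version = as.character(utils::packageVersion("fwdyn")),
    seed = seed,
    stages = list(),
    inputs = list(),
    outputs = list(),
    status = "running")
  writeManifest <- function() {
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  writeManifest()
  ctx <- new.env(parent = emptyenv())
  for (k in seq_along(config$stages)) {
    st <- config$stages[[k]]
    pars <- .resolveParams(st$stage, st$params)
    manifest$stages[[k]] <- list(stage = st$stage, params = pars)
    for (p in intersect(names(pars), c("fasta", "region_map", "traj",
                                       "selections", "singles", "doubles",
                                       "repertoire"))) {
      if (is.character(pars[[p]]) && file.exists(pars[[p]]))
        manifest$inputs[[pars[[p]]]] <-
          unname(tools::md5sum(pars[[p]]))
    }
    logLine("stage ", st$stage, " started")
    t0 <- proc.time()[3]
    ok <- tryCatch({
      .runStage(st$stage, pars, seed, outDir, ctx)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      manifest$status <- paste0("failed at stage ", st$stage, ": ",
                                conditionMessage(ok))
      writeManifest()
      logLine("stage ", st$stage, " FAILED: ", conditionMessage(ok))
      stop("pipeline failed at stage '", st$stage, "': ",
           conditionMessage(ok), call. = FALSE)
    }
    logLine("stage ", st$stage, " finished in ",
            sprintf("%.2f", proc.time()[3] - t0), " s")
  }
  outs <- setdiff(list.files(outDir, recursive = TRUE),
                  c("manifest.json", "run.log"))
  manifest$outputs <- as.list(stats::setNames(
    unname(tools::md5sum(file.path(outDir, outs))), outs))
  manifest$status <- "ok"
  writeManifest()
  invisible(manifest)
}

.runStage <- function(stage, pars, seed, outDir, ctx) {
  switch(stage,
    simulate = {
      if (pars$what %in% c("coupling", "all")) {
        cp <- data.frame(
          i = c(pars$coupled_i, pars$coupled_i),
          j = c(pars$coupled_j, pars$coupled_j),
          condition = c("bound", "unbound"),
          strength = c(pars$strength_bound, pars$strength_unbound))
        sim <- genStateSequences(pars$n_fragments, pars$M, pars$F,
                                 pars$replicas, cp, seed = seed)
        ctx$stateSequences <- sim
        for (cond in c("bound", "unbound"))
          for (r in seq_along(sim[[cond]]))
            writeStateSequences(sim[[cond]][[r]],
              file.path(outDir, sprintf("states_%s_rep%d.tsv", cond, r)))
        jsonlite::write_json(sim$groundTruth,
                             file.path(outDir, "ground_truth.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      if (pars$what %in% c("toy_complex", "all")) {
        toy <- genToyComplex(drift = pars$drift, F = pars$frames,
                             sigma = pars$sigma, seed = seed)
        ctx$toy <- toy
        writeStructure(toy$trajectory, file.path(outDir, "toy_traj.pdb"))
      }
    },
    scan = {
      if (is.null(pars$fasta) || is.null(pars$region_map))
        stop("scan stage needs fasta and region_map", call. = FALSE)
      seqs <- readFasta(pars$fasta)
      map <- loadRegionMap(pars$region_map)
      profiles <- list()
      for (nm in names(seqs)) {
        cs <- chainSequence(seqs[[nm]], chainId = map@entries$chain_id[1])
        mock <- genMutationScores(cs, map, fwBias = pars$fw_bias,
                                  cdrBias = pars$cdr_bias, seed = seed)
        grid <- scanPositions(cs, mock$scorer)
        prof <- wtRankProfile(grid, map)
        prof$antibody <- nm
        profiles[[nm]] <- prof
      }
      all <- do.call(rbind, profiles)
      writeResultTable(all, file.path(outDir, "scan_profiles.tsv"))
      summ <- regionSummary(profiles, map,
                            chainId = map@entries$chain_id[1])
      writeResultTable(summ$perRegion, file.path(outDir,
                                                 "scan_region_summary.tsv"))
      ctx$scan <- profiles
    },
    dynamics = {
      toy <- ctx$toy
      if (!is.null(pars$traj)) {
        traj <- readStructure(pars$traj, model = "all")
        sels <- loadSelections(pars$selections, traj)
      } else if (!is.null(toy)) {
        traj <- toy$trajectory
        sels <- toy$selections
      } else stop("dynamics stage needs --traj or a preceding simulate",
                  call. = FALSE)
      dist <- comDistanceSeries(traj, sels$CDR, sels$antigen)
      writeResultTable(dist, file.path(outDir, "cdr_antigen_distance.tsv"))
      ang <- vhVlAngleSeries(traj, sels$CDRL, sels$VL, sels$VH)
      writeResultTable(ang, file.path(outDir, "vh_vl_angle.tsv"))
      dvv <- vhVlDistanceSeries(traj, sels$VH, sels$VL)
      writeResultTable(dvv, file.path(outDir, "vh_vl_distance.tsv"))
      ub <- detectUnbinding(dist, baselineWindow = pars$baseline_window,
                            factor = pars$unbinding_factor,
                            persistence = pars$persistence)
      jsonlite::write_json(ub, file.path(outDir, "unbinding.json"),
                           auto_unbox = TRUE, digits = NA)
      ctx$dynamics <- list(distance = dist, unbinding = ub)
    },
    contacts = {
      toy <- ctx$toy
      traj <- if (!is.null(pars$traj)) readStructure(pars$traj, "all")
              else if (!is.null(toy)) toy$trajectory
              else stop("contacts stage needs --traj or a preceding simulate",
                        call. = FALSE)
      crit <- geomCriteria(pars$hbond_max_dist, pars$hbond_min_angle,
                           pars$pipi_max_dist, pars$pipi_max_angle,
                           pars$xh_max_dist, pars$xh_min_angle)
      rings <- if (!is.null(toy)) toy$rings else aromaticRings(traj)
      ev <- .emptyEvents()
      if (length(rings) >= 2)
        ev <- rbind(ev, detectPiPi(traj, rings, crit))
      if (!is.null(toy) && !is.null(toy$hbondTriples))
        ev <- rbind(ev, detectHBonds(traj, crit, toy$hbondTriples))
      if (!is.null(toy) && !is.null(toy$xhPairs) && length(rings))
        ev <- rbind(ev, detectXHRing(traj, rings, crit,
                                     xhPairs = toy$xhPairs))
      writeResultTable(ev, file.path(outDir, "interaction_events.tsv"))
      net <- buildNetwork(ev, nFrames(traj),
                          minFrequency = pars$min_frequency)
      writeResultTable(net@edges, file.path(outDir,
                                            "interaction_network.tsv"))
      ctx$contacts <- list(events = ev, network = net)
    },
    coupling = {
      if (!is.null(pars$bound)) {
        bound <- lapply(pars$bound, readStateSequences)
        unbound <- lapply(pars$unbound, readStateSequences)
      } else if (!is.null(ctx$stateSequences)) {
        bound <- ctx$stateSequences$bound
        unbound <- ctx$stateSequences$unbound
      } else stop("coupling stage needs --bound/--unbound or a preceding ",
                  "simulate", call. = FALSE)
      mb <- lapply(bound, miMatrix, frameWindow = pars$window,
                   correction = pars$correction, seed = seed)
      mu <- lapply(unbound, miMatrix, frameWindow = pars$window,
                   correction = pars$correction, seed = seed)
      dc <- diffCoupling(mb, mu, test = pars$test, seed = seed)
      writeResultTable(dc, file.path(outDir, "diff_coupling.tsv"))
      hubs <- callHubs(dc, lfcThreshold = pars$lfc, alpha = pars$alpha)
      writeResultTable(hubs, file.path(outDir, "hub_table.tsv"))
      L <- max(dc$fragment_j) + 3
      writeResultTable(positionHubFrequency(hubs, L),
                       file.path(outDir, "hub_frequency.tsv"))
      ctx$coupling <- list(dc = dc, hubs = hubs)
    },
    mutfilter = {
      if (is.null(pars$singles) || is.null(pars$doubles) ||
          is.null(pars$repertoire))
        stop("mutfilter stage needs singles, doubles and repertoire",
             call. = FALSE)
      singles <- loadDdGTable(pars$singles)
      doubles <- loadDdGTable(pars$doubles)
      prof <- utils::read.delim(pars$repertoire, stringsAsFactors = FALSE)
      cand <- filterDoubleMutants(singles, doubles, prof,
                                  occThreshold = pars$occ_threshold)
      writeResultTable(cand, file.path(outDir, "candidates.tsv"))
      ctx$mutfilter <- cand
    },
    stop("unknown stage: ", stage, call. = FALSE))
  invisible(NULL)
}
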