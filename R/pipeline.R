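# Run configuration, pipeline orchestration, manifest and run comparison.

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions; 1 for identical
#' partitions (up to label permutation), about 0 for independent ones.
#' Inputs may be named (matched by name) or aligned by position.
#'
#' @param a,b membership vectors
#' @return numeric ARI
#' @export
adjustedRandIndex <- function(a, b) .adjustedRandIndex(a, b)

#' Create a pipeline run configuration
#'
#' @param input either `list(spec = <SyntheticSpec>)` for a generated system
#'   or `list(topology = path, trajectory = path, dtNs = <ns>)` for files
#' @param domainMapPath optional domain-map config file; for a synthetic spec
#'   the map is derived from the spec when omitted
#' @param stages stages to run, in dependency order; `superpose` is inserted
#'   automatically when a later stage needs it
#' @param params named list of per-stage overrides: `domainPairs` (list of
#'   `c(domA, domB)`), `hbond` (list: `windowNs`, `heavyAtomOnly`), `network`
#'   (list: `cutoff`, `minFraction`, `atoms`, `windowNs`), `events` (list:
#'   `baselineNs`, `openOffset`, `smoothNs`, `dwellNs`, `keyPairs`), `hinge`
#'   (list: `apex`, `armA`, `armB` selection descriptors `c(domain, from, to)`)
#' @param outDir output directory (created)
#' @param seed integer seed (overrides a synthetic spec's seed)
#' @return a [RunConfig-class]
#' @export
runConfig <- function(input, domainMapPath = "",
                      stages = c("observables", "hbonds", "dfmap",
                                 "network", "events"),
                      params = list(), outDir = tempfile("trajnet_run_"),
                      seed = 1L) {
  new("RunConfig", input = input, domainMapPath = domainMapPath,
      stages = stages, params = params, outDir = outDir,
      seed = as.integer(seed))
}

.defaultPairs <- function(map) {
  nms <- domainNames(map)
  if (all(c("nSH2", "helical") %in% nms)) {
    prs <- list(c("nSH2", "helical"))
    if ("C2" %in% nms) prs <- c(prs, list(c("nSH2", "C2")))
    if ("kinase" %in% nms) prs <- c(prs, list(c("nSH2", "kinase")))
    prs
  } else {
    list(nms[1:2])
  }
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (load, superpose,
#' observables, hbonds, dfmap, network, events), writes each stage's
#' artifacts under `config@outDir` with fixed names, and a machine-readable
#' `manifest.json` recording inputs, parameters, package version, per-file
#' checksums and timings. A stage failure is recorded in the manifest and
#' already-written artifacts are retained.
#'
#' @param config a [RunConfig-class]
#' @return invisibly, the manifest as a list
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "RunConfig"))
  dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
  params <- config@params
  manifest <- list(inputs = list(), parameters = params,
                   version = as.character(utils::packageVersion("trajnet")),
                   seed = config@seed, stages = list(), checksums = list())
  t0all <- proc.time()[[3L]]
  log <- function(...) message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "),
                               sprintf(...))
  stageRec <- function(name, status, elapsed)
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = name, status = status, elapsed_s = round(elapsed, 3))

  # ---- load ----------------------------------------------------------------
  t0 <- proc.time()[[3L]]
  if (!is.null(config@input$spec)) {
    spec <- config@input$spec
    spec@seed <- config@seed
    gen <- generateTrajectory(spec)
    topo <- gen$topology; traj <- gen$trajectory
    map <- if (nzchar(config@domainMapPath)) readDomainMap(config@domainMapPath)
           else specDomainMap(spec)
    manifest$inputs <- list(kind = "synthetic", nframes = nFrames(traj),
                            seed = config@seed)
  } else {
    topo <- readTopology(config@input$topology)
    dt <- if (is.null(config@input$dtNs)) 1 else config@input$dtNs
    traj <- readTrajectory(topo, config@input$trajectory, dtNs = dt)
    map <- readDomainMap(config@domainMapPath)
    manifest$inputs <- list(kind = "files", topology = config@input$topology,
                            trajectory = config@input$trajectory,
                            nframes = nFrames(traj))
  }
  stageRec("load", "ok", proc.time()[[3L]] - t0)
  log("loaded %d frames x %d atoms", nFrames(traj), nAtoms(traj))

  pairs <- if (!is.null(params$domainPairs)) params$domainPairs
           else .defaultPairs(map)
  selCA <- function(nm) selectDomain(topo, map, nm, "CA")
  selAll <- function(nm) selectDomain(topo, map, nm, "all")

  # ---- superpose (auto-inserted when needed) -------------------------------
  needFit <- any(c("observables", "dfmap", "network") %in% config@stages)
  fitted <- traj
  if (needFit) {
    t0 <- proc.time()[[3L]]
    allCA <- {
      a <- topo@atoms
      new("ResidueSelection", atomIndices = which(a$name == "CA"),
          domain = "all-CA",
          residues = data.frame(chain = a$chain[a$name == "CA"],
                                resno = a$resno[a$name == "CA"],
                                resname = a$resname[a$name == "CA"],
                                stringsAsFactors = FALSE))
    }
    fitted <- superpose(traj, allCA)
    stageRec("superpose", "ok", proc.time()[[3L]] - t0)
    log("superposed on %d C-alpha atoms (auto-inserted)", nAtoms(allCA))
  }

  art <- function(nm) file.path(config@outDir, nm)
  runStage <- function(name, fn) {
    if (!name %in% config@stages) return(invisible(NULL))
    t0 <- proc.time()[[3L]]
    res <- tryCatch({ fn(); "ok" },
                    error = function(e) paste("failed:", conditionMessage(e)))
    stageRec(name, res, proc.time()[[3L]] - t0)
    log("stage %-12s %s", name, res)
  }

  comFirst <- NULL
  countFirst <- NULL
  occFirst <- NULL

  runStage("observables", function() {
    obs <- list()
    obs[[1L]] <- rmsdTimeSeries(fitted, selCA(domainNames(map)[1L]))
    for (pr in pairs)
      obs[[length(obs) + 1L]] <- comDistanceTimeSeries(
        fitted, selCA(pr[1L]), selCA(pr[2L]))
    if (!is.null(params$hinge)) {
      hg <- params$hinge
      mk <- function(d) selectResidues(topo, d[1L], as.integer(d[2L]),
                                       as.integer(d[3L]), "CA")
      obs[[length(obs) + 1L]] <- hingeAngleTimeSeries(
        fitted, mk(hg$apex), mk(hg$armA), mk(hg$armB))
    }
    comFirst <<- obs[[2L]]
    utils::write.csv(do.call(rbind, obs), art("observables.csv"),
                     row.names = FALSE)
    rmsf <- rmsfProfile(fitted, selCA(domainNames(map)[1L]))
    utils::write.csv(rmsf, art("rmsf.csv"), row.names = FALSE)
  })

  runStage("hbonds", function() {
    hb <- if (is.null(params$hbond)) list() else params$hbond
    crit <- hbondCriteria(heavyAtomOnly = isTRUE(hb$heavyAtomOnly))
    wNs <- if (is.null(hb$windowNs)) 50 else hb$windowNs
    pr <- pairs[[1L]]
    counts <- interdomainHbondCount(traj, selAll(pr[1L]), selAll(pr[2L]), crit)
    occ <- pairOccupancy(traj, selAll(pr[1L]), selAll(pr[2L]), crit, wNs)
    countFirst <<- counts
    occFirst <<- occ
    utils::write.csv(counts, art("hbond_counts.csv"), row.names = FALSE)
    writeOccupancyCSV(occ, art("hbonds_occupancy.csv"))
  })

  runStage("dfmap", function() {
    a <- topo@atoms
    allCA <- new("ResidueSelection", atomIndices = which(a$name == "CA"),
                 domain = "all-CA",
                 residues = data.frame(chain = a$chain[a$name == "CA"],
                                       resno = a$resno[a$name == "CA"],
                                       resname = a$resname[a$name == "CA"],
                                       stringsAsFactors = FALSE))
    win <- lastWindow(fitted, 200)
    dfm <- distanceFluctuationMatrix(fitted, allCA, win)
    writeDFLongCSV(dfm, art("dfmap.csv"))
  })

  runStage("network", function() {
    np <- if (is.null(params$network)) list() else params$network
    cutoff <- if (is.null(np$cutoff)) 6.5 else np$cutoff
    minFr <- if (is.null(np$minFraction)) 0.75 else np$minFraction
    atomsMode <- if (is.null(np$atoms)) "CA" else np$atoms
    wNs <- if (is.null(np$windowNs)) 200 else np$windowNs
    a <- topo@atoms
    allCA <- new("ResidueSelection", atomIndices = which(a$name == "CA"),
                 domain = "all-CA",
                 residues = data.frame(chain = a$chain[a$name == "CA"],
                                       resno = a$resno[a$name == "CA"],
                                       resname = a$resname[a$name == "CA"],
                                       stringsAsFactors = FALSE))
    win <- lastWindow(fitted, wNs)
    C <- correlationMatrix(fitted, allCA, win)
    adj <- contactAdjacency(fitted, allCA, cutoff = cutoff,
                            minFraction = minFr, window = win,
                            atoms = atomsMode)
    net <- buildNetwork(adj, C)
    part <- girvanNewmanCommunities(net)
    exportNetwork(net, art("network.graphml"), art("network_edges.csv"),
                  partition = part)
    utils::write.csv(data.frame(node = names(part@membership),
                                community = as.integer(part@membership)),
                     art("communities.csv"), row.names = FALSE)
    ce <- criticalEdges(net, part)
    utils::write.csv(ce, art("critical_edges.csv"), row.names = FALSE)
  })

  runStage("events", function() {
    ev <- if (is.null(params$events)) list() else params$events
    pr <- pairs[[1L]]
    if (is.null(comFirst))
      comFirst <<- comDistanceTimeSeries(traj, selCA(pr[1L]), selCA(pr[2L]))
    if (is.null(countFirst) || is.null(occFirst)) {
      crit <- hbondCriteria()
      countFirst <<- interdomainHbondCount(traj, selAll(pr[1L]), selAll(pr[2L]), crit)
      occFirst <<- pairOccupancy(traj, selAll(pr[1L]), selAll(pr[2L]), crit, 50)
    }
    baseNs <- if (is.null(ev$baselineNs)) c(frameTimes(traj)[1L],
                                            frameTimes(traj)[1L] + 100)
              else ev$baselineNs
    tl <- classifyStates(comFirst, baseNs,
                         openOffset = if (is.null(ev$openOffset)) 5 else ev$openOffset,
                         smoothNs = if (is.null(ev$smoothNs)) 10 else ev$smoothNs,
                         dwellNs = if (is.null(ev$dwellNs)) 50 else ev$dwellNs)
    tl <- if (is.null(ev$keyPairs))
      annotateSteps(tl, countFirst, occFirst)
    else annotateSteps(tl, countFirst, occFirst, keyPairs = ev$keyPairs)
    writeTimelineJSON(tl, art("events.json"))
  })

  # ---- manifest ------------------------------------------------------------
  files <- list.files(config@outDir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  if (length(files)) {
    sums <- tools::md5sum(files)
    manifest$checksums <- as.list(stats::setNames(unname(sums), basename(files)))
  }
  manifest$elapsed_s <- round(proc.time()[[3L]] - t0all, 3)
  jsonlite::write_json(manifest, file.path(config@outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Compare two pipeline run bundles
#'
#' Side-by-side comparison of two output directories produced by
#' [runPipeline()] (e.g. a closed-state and a detached run): per-observable
#' mean +/- SD differences, hydrogen-bond totals, mean distance fluctuation,
#' and the adjusted Rand index between community partitions (aligned on the
#' node intersection, with a warning when nodes differ). Stages present in
#' only one bundle are skipped; fully disjoint bundles yield an explicitly
#' empty comparison.
#'
#' @param dirA,dirB run directories
#' @return list with `observables` (data.frame), `hbondMeanDiff`,
#'   `meanDFDiff`, `communityARI`, `sharedStages`
#' @export
compareRuns <- function(dirA, dirB) {
  rd <- function(d, f) {
    p <- file.path(d, f)
    if (file.exists(p)) utils::read.csv(p, check.names = FALSE) else NULL
  }
  out <- list(observables = NULL, hbondMeanDiff = NA_real_,
              meanDFDiff = NA_real_, communityARI = NA_real_,
              sharedStages = character(0))
  mA <- jsonlite::read_json(file.path(dirA, "manifest.json"))
  mB <- jsonlite::read_json(file.path(dirB, "manifest.json"))
  stA <- vapply(mA$stages, `[[`, "", "stage")
  stB <- vapply(mB$stages, `[[`, "", "stage")
  out$sharedStages <- intersect(stA, stB)
  oA <- rd(dirA, "observables.csv"); oB <- rd(dirB, "observables.csv")
  if (!is.null(oA) && !is.null(oB)) {
    sm <- function(o) {
      ag <- stats::aggregate(o$value, list(label = o$label),
                             function(v) c(mean = mean(v), sd = stats::sd(v)))
      data.frame(label = ag$label, mean = ag$x[, "mean"], sd = ag$x[, "sd"])
    }
    sa <- sm(oA); sb <- sm(oB)
    m <- merge(sa, sb, by = "label", suffixes = c("A", "B"))
    m$meanDiff <- m$meanB - m$meanA
    out$observables <- m
  }
  hA <- rd(dirA, "hbond_counts.csv"); hB <- rd(dirB, "hbond_counts.csv")
  if (!is.null(hA) && !is.null(hB))
    out$hbondMeanDiff <- mean(hB$value) - mean(hA$value)
  dA <- rd(dirA, "dfmap.csv"); dB <- rd(dirB, "dfmap.csv")
  if (!is.null(dA) && !is.null(dB))
    out$meanDFDiff <- mean(dB$df_A2) - mean(dA$df_A2)
  cA <- rd(dirA, "communities.csv"); cB <- rd(dirB, "communities.csv")
  if (!is.null(cA) && !is.null(cB)) {
    common <- intersect(cA$node, cB$node)
    if (length(common) < max(nrow(cA), nrow(cB)))
      warning("community node sets differ; ARI computed on the intersection")
    if (length(common) >= 2L) {
      a <- stats::setNames(cA$community, cA$node)[common]
      b <- stats::setNames(cB$community, cB$node)[common]
      out$communityARI <- .adjustedRandIndex(a, b)
    }
  }
  out
}
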