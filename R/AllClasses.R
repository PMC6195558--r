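#' @import methods
NULL

#' Molecular topology
#'
#' Atom-level description of a molecular system: one row per atom with its
#' name, element, mass (amu) and the residue (number, name, chain) it belongs
#' to. Atom order defines the 1-based atom index used by every selection and
#' by the coordinate columns of a [Trajectory-class].
#'
#' @slot atoms data.frame with columns `serial`, `name`, `element`, `mass`,
#'   `resno`, `resname`, `chain`; one row per atom, in file order.
#' @seealso [readTopology()], [selectDomain()]
#' @export
setClass("Topology", representation(atoms = "data.frame"))

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "mass", "resno", "resname", "chain")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("topology has no atoms")
  if (any(!is.finite(a$mass)) || any(a$mass <= 0))
    return("all atom masses must be finite and > 0")
  if (any(is.na(a$resno)) || any(is.na(a$chain)))
    return("every atom must belong to a residue on a chain")
  TRUE
})

#' Coordinate trajectory
#'
#' Frames of Cartesian coordinates over a [Topology-class]. Coordinates are
#' stored internally in Angstrom as an `nframes x (3 * natoms)` matrix in
#' `x1,y1,z1,x2,...` order (the bio3d convention), with one time stamp in
#' nanoseconds per frame.
#'
#' @slot topology the [Topology-class] the coordinates refer to.
#' @slot xyz numeric matrix, `nframes x (3 * natoms)`, Angstrom.
#' @slot times numeric vector of frame times in ns, strictly increasing.
#' @seealso [readTrajectory()], [superpose()]
#' @export
setClass("Trajectory",
         representation(topology = "Topology", xyz = "matrix", times = "numeric"))

setValidity("Trajectory", function(object) {
  na <- nrow(object@topology@atoms)
  if (ncol(object@xyz) != 3L * na)
    return(sprintf("xyz has %d columns; expected 3 x %d atoms", ncol(object@xyz), na))
  if (nrow(object@xyz) == 0L) return("trajectory has zero frames")
  if (length(object@times) != nrow(object@xyz))
    return("one time stamp per frame required")
  if (any(!is.finite(object@xyz))) return("coordinates must be finite")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    return("frame times must be strictly increasing")
  TRUE
})

#' Named residue-range map
#'
#' Maps domain (or region) names to inclusive residue-number ranges on named
#' chains. One entry may span several ranges, possibly on different chains;
#' ranges of a single entry on the same chain may not overlap. Residue
#' numbering is taken verbatim from the input file (crystal numbering), so the
#' same residue number may exist on both chains of a heterodimer; the chain id
#' disambiguates.
#'
#' @slot entries named list; each element a data.frame with columns `chain`,
#'   `start`, `end` (1-based inclusive residue numbers).
#' @seealso [domainMap()], [readDomainMap()], [selectDomain()]
#' @export
setClass("DomainMap", representation(entries = "list"))

setValidity("DomainMap", function(object) {
  e <- object@entries
  if (length(e) == 0L) return("domain map has no entries")
  nm <- names(e)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    return("entries must have unique non-empty names")
  for (i in seq_along(e)) {
    d <- e[[i]]
    if (!all(c("chain", "start", "end") %in% names(d)))
      return(sprintf("entry '%s' needs chain/start/end", nm[i]))
    if (any(d$start > d$end))
      return(sprintf("entry '%s' has start > end", nm[i]))
    for (ch in unique(d$chain)) {
      r <- d[d$chain == ch, , drop = FALSE]
      if (nrow(r) > 1L) {
        r <- r[order(r$start), , drop = FALSE]
        if (any(r$start[-1L] <= r$end[-nrow(r)]))
          return(sprintf("entry '%s' has overlapping ranges on chain %s", nm[i], ch))
      }
    }
  }
  TRUE
})

#' Atom selection owned by a named domain
#'
#' Ordered atom indices into a [Topology-class], together with the residues
#' they cover and the domain-map entry they were derived from.
#'
#' @slot atomIndices integer vector of 1-based atom indices, in residue order.
#' @slot domain name of the owning domain-map entry.
#' @slot residues data.frame with columns `chain`, `resno`, `resname`.
#' @export
setClass("ResidueSelection",
         representation(atomIndices = "integer", domain = "character",
                        residues = "data.frame"))

setValidity("ResidueSelection", function(object) {
  if (length(object@atomIndices) == 0L) return("selection is empty")
  if (anyDuplicated(object@atomIndices)) return("duplicate atom indices")
  if (any(object@atomIndices < 1L)) return("atom indices must be >= 1")
  TRUE
})

#' Windowed residue-pair occupancy table
#'
#' Fraction of frames, per consecutive time window, in which a residue pair is
#' linked by at least one hydrogen bond (or salt bridge). Cells strictly below
#' 0.5 are flagged, mirroring the convention of marking sub-50% occupancy.
#'
#' @slot pairs data.frame describing each row's residue pair (`chainA`,
#'   `resnoA`, `resnameA`, `chainB`, `resnoB`, `resnameB`, `label`).
#' @slot occupancy numeric matrix, pairs x windows, values in `[0, 1]`.
#' @slot windows data.frame with columns `start_ns`, `end_ns`, `label`;
#'   windows tile the analysed interval without overlap.
#' @seealso [pairOccupancy()], [detectSaltBridges()], [occupancyFlags()]
#' @export
setClass("OccupancyTable",
         representation(pairs = "data.frame", occupancy = "matrix",
                        windows = "data.frame"))

setValidity("OccupancyTable", function(object) {
  if (nrow(object@occupancy) != nrow(object@pairs))
    return("one occupancy row per pair required")
  if (ncol(object@occupancy) != nrow(object@windows))
    return("one occupancy column per window required")
  if (nrow(object@occupancy) > 0L &&
      (any(object@occupancy < 0) || any(object@occupancy > 1)))
    return("occupancy fractions must lie in [0, 1]")
  w <- object@windows
  if (nrow(w) > 1L && any(w$start_ns[-1L] < w$end_ns[-nrow(w)] - 1e-9))
    return("windows must not overlap")
  TRUE
})

#' Correlation-weighted residue network
#'
#' Undirected residue graph: one node per residue (at its C-alpha), an edge
#' only where the contact criterion holds, and edge weight
#' `-log(|C_ij|)` (a communication cost) derived from the motional
#' correlation `C_ij`. The raw correlation is kept as an edge attribute so
#' that community detection can use it as an affinity.
#'
#' @slot graph an `igraph` object with vertex attribute `name` (node id
#'   `"chain:resno"`) and edge attributes `correlation` and `weight`.
#' @seealso [buildNetwork()], [optimalPath()], [girvanNewmanCommunities()]
#' @export
setClass("NetworkGraph", representation(graph = "ANY"))

setValidity("NetworkGraph", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must be an igraph object")
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (any(igraph::which_loop(g))) return("self-edges are not allowed")
  if (igraph::ecount(g) > 0L) {
    w <- igraph::E(g)$weight
    if (is.null(w) || any(!is.finite(w)) || any(w < 0))
      return("edge weights must be finite and >= 0")
  }
  TRUE
})

#' Community partition of a residue network
#'
#' @slot membership named integer vector, node id to community id.
#' @slot modularity modularity score of the partition, in `[-0.5, 1]`.
#' @seealso [girvanNewmanCommunities()], [criticalEdges()]
#' @export
setClass("CommunityPartition",
         representation(membership = "integer", modularity = "numeric"))

setValidity("CommunityPartition", function(object) {
  if (is.null(names(object@membership))) return("membership must be named by node id")
  if (anyDuplicated(names(object@membership))) return("every node assigned exactly once")
  q <- object@modularity
  if (length(q) != 1L || !is.finite(q) || q < -0.5 - 1e-9 || q > 1 + 1e-9)
    return("modularity must be a single value in [-0.5, 1]")
  TRUE
})

#' Optimal communication path
#'
#' Minimum-total-weight path between two residue nodes, or an explicit
#' no-path result when the nodes are disconnected (`found = FALSE`,
#' `totalWeight = Inf`).
#'
#' @slot nodes ordered node ids from source to target.
#' @slot totalWeight sum of the edge weights along the path.
#' @slot edgeWeights per-edge weights along the path.
#' @slot found logical; `FALSE` when source and target are disconnected.
#' @seealso [optimalPath()], [pathLengthCompare()]
#' @export
setClass("CommunicationPath",
         representation(nodes = "character", totalWeight = "numeric",
                        edgeWeights = "numeric", found = "logical"))

setValidity("CommunicationPath", function(object) {
  if (object@found) {
    if (length(object@edgeWeights) != length(object@nodes) - 1L)
      return("edgeWeights must have one entry per path edge")
    if (abs(object@totalWeight - sum(object@edgeWeights)) > 1e-8 * max(1, object@totalWeight))
      return("totalWeight must equal the sum of edge weights")
  }
  TRUE
})

#' Detachment-event timeline
#'
#' Per-frame state labels (`closed`, `open`, `transient`) plus stepwise
#' annotations of the detachment mechanism (step id, onset time, triggering
#' signal).
#'
#' @slot times frame times in ns.
#' @slot states character vector, one label per frame.
#' @slot steps data.frame with columns `step`, `onset_ns`, `signal`.
#' @seealso [classifyStates()], [annotateSteps()]
#' @export
setClass("EventTimeline",
         representation(times = "numeric", states = "character", steps = "data.frame"))

setValidity("EventTimeline", function(object) {
  if (length(object@states) != length(object@times))
    return("one state per frame required")
  if (!all(object@states %in% c("closed", "open", "transient")))
    return("states must be 'closed', 'open' or 'transient'")
  if (nrow(object@steps) > 1L && any(diff(object@steps$onset_ns) <= 0))
    return("step onsets must be strictly increasing in time")
  TRUE
})

#' Specification for a synthetic multi-domain trajectory
#'
#' Declares the study conditions of a generated C-alpha-resolution ensemble:
#' domain layout, block-structured motional correlations, scheduled
#' hydrogen-bond-like and salt-bridge-like contacts, and an optional scripted
#' rigid-body detachment (hinge rotation plus an exact centre-of-mass
#' separation step) of one domain.
#'
#' @slot domains data.frame with columns `name`, `chain`, `startRes`,
#'   `endRes`, `cx`, `cy`, `cz` (blob centroid, Angstrom), `sigma`
#'   (per-bead positional noise, Angstrom, > 0).
#' @slot rhoIntra planted correlation between beads of the same domain.
#' @slot rhoInter either a single planted inter-domain correlation or a named
#'   domain x domain matrix.
#' @slot layout `"blob"` (default) or `"helix"` (consecutive single-chain
#'   alpha-helical trace; requires one shared chain).
#' @slot meanCoords optional explicit mean structure (natoms x 3 matrix for
#'   the C-alpha beads, Angstrom); overrides the automatic layout.
#' @slot contacts data.frame of scheduled pseudo contact sites: columns
#'   `id`, `donorDomain`, `donorRes`, `donorResname`, `acceptorDomain`,
#'   `acceptorRes`, `acceptorResname`, `type` (`"hbond"` or `"salt"`) and a
#'   list column `on` of two-column matrices of inclusive frame intervals
#'   during which the contact is formed.
#' @slot hinge empty list, or a list with `domain`, `pivotRes` (range defining
#'   the hinge-helix beads), `armRes` (range defining the distal arm helix),
#'   `targetDomain`/`targetRes` (the static apex-arm residue), `angleStartDeg`
#'   and `angleEndDeg`.
#' @slot detach empty list, or a list with `domain`, `reference`, `deltaA`
#'   (centre-of-mass separation step, Angstrom), `frame` (first detached
#'   frame), and optionally `transientFrames = c(from, to)` plus
#'   `transientFraction` for a partial re-attachment episode, and
#'   `wobbleComA`/`wobbleRotDeg` for extra rigid-body noise of the detached
#'   domain.
#' @slot nframes number of frames.
#' @slot dtNs frame spacing in ns.
#' @slot seed random seed driving displacement noise.
#' @seealso [syntheticSpec()], [generateTrajectory()], [pi3kLikePreset()]
#' @export
setClass("SyntheticSpec",
         representation(domains = "data.frame", rhoIntra = "numeric",
                        rhoInter = "ANY", layout = "character",
                        meanCoords = "ANY", contacts = "data.frame",
                        hinge = "list", detach = "list",
                        nframes = "integer", dtNs = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  d <- object@domains
  need <- c("name", "chain", "startRes", "endRes", "cx", "cy", "cz", "sigma")
  if (!all(need %in% names(d))) return("domains needs name/chain/startRes/endRes/cx/cy/cz/sigma")
  if (anyDuplicated(d$name)) return("domain names must be unique")
  if (any(d$sigma <= 0)) return("per-bead noise sigma must be > 0")
  if (object@nframes < 1L) return("nframes must be >= 1")
  if (object@dtNs <= 0) return("dtNs must be > 0")
  if (length(object@rhoIntra) != 1L || object@rhoIntra < 0 || object@rhoIntra >= 1)
    return("rhoIntra must be a single value in [0, 1)")
  if (nrow(object@contacts) > 0L) {
    for (i in seq_len(nrow(object@contacts))) {
      iv <- object@contacts$on[[i]]
      if (!is.null(iv) && length(iv) &&
          (any(iv < 1L) || any(iv > object@nframes)))
        return(sprintf("contact '%s' schedule outside frame range",
                       object@contacts$id[i]))
    }
  }
  if (length(object@detach)) {
    f <- object@detach$frame
    if (f < 1L || f > object@nframes) return("detach frame outside frame range")
  }
  TRUE
})

#' Ground truth planted by the synthetic generator
#'
#' @slot membership named integer vector: planted community per C-alpha node.
#' @slot correlation planted bead-level correlation matrix (C-alpha nodes).
#' @slot detachFrame first detached frame index (NA if no detachment).
#' @slot detachDeltaA planted centre-of-mass separation step in Angstrom.
#' @slot transientFrames planted partial re-attachment interval (frames).
#' @slot hingeAngles numeric `c(start, end)` hinge angle in degrees.
#' @slot contacts the realised contact schedule (as in the spec).
#' @slot stepOnsetsNs named numeric: planted onset times of the stepwise
#'   detachment mechanism (`step1` .. `step4`), NA when not scripted.
#' @export
setClass("GroundTruth",
         representation(membership = "integer", correlation = "matrix",
                        detachFrame = "numeric", detachDeltaA = "numeric",
                        transientFrames = "numeric", hingeAngles = "numeric",
                        contacts = "data.frame", stepOnsetsNs = "numeric"))

#' Pipeline run configuration
#'
#' @slot input list describing the input: either `list(preset = ...)` for a
#'   generated system or `list(topology = path, trajectory = path)` for files.
#' @slot domainMapPath path to a domain-map config file ("" to derive the map
#'   from a synthetic preset).
#' @slot stages character vector of stage names to run.
#' @slot params named list of per-stage parameter overrides.
#' @slot outDir output directory.
#' @slot seed integer seed.
#' @seealso [runConfig()], [runPipeline()]
#' @export
setClass("RunConfig",
         representation(input = "list", domainMapPath = "character",
                        stages = "character", params = "list",
                        outDir = "character", seed = "integer"))
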