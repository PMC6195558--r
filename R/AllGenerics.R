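#' @include AllClasses.R
NULL

#' Number of atoms
#' @param x a [Topology-class], [Trajectory-class] or [ResidueSelection-class]
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) nrow(x@topology@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "ResidueSelection", function(x) length(x@atomIndices))

#' Number of trajectory frames
#' @param x a [Trajectory-class]
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) nrow(x@xyz))

#' Frame times in nanoseconds
#' @param x a [Trajectory-class] or [EventTimeline-class]
#' @return numeric vector of times (ns)
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "EventTimeline", function(x) x@times)

#' Atom table of a topology
#' @param x a [Topology-class] or [Trajectory-class]
#' @return data.frame with one row per atom
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "Topology", function(x) x@atoms)

#' @rdname atoms
#' @export
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)

#' Residue table (one row per residue)
#' @param x a [Topology-class] or [ResidueSelection-class]
#' @return data.frame with columns chain, resno, resname
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname residues
#' @export
setMethod("residues", "Topology", function(x) {
  a <- x@atoms
  key <- !duplicated(paste(a$chain, a$resno))
  data.frame(chain = a$chain[key], resno = a$resno[key],
             resname = a$resname[key], stringsAsFactors = FALSE)
})

#' @rdname residues
#' @export
setMethod("residues", "ResidueSelection", function(x) x@residues)

#' Topology of a trajectory
#' @param x a [Trajectory-class]
#' @return the [Topology-class]
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname topology
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' Coordinates of one frame
#' @param x a [Trajectory-class]
#' @param frame 1-based frame index
#' @return natoms x 3 numeric matrix (Angstrom)
#' @export
setGeneric("frameCoords", function(x, frame = 1L) standardGeneric("frameCoords"))

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "Trajectory", function(x, frame = 1L) {
  stopifnot(frame >= 1L, frame <= nrow(x@xyz))
  matrix(x@xyz[frame, ], ncol = 3L, byrow = TRUE)
})

#' Raw coordinate matrix (frames x 3*natoms, bio3d layout)
#' @param x a [Trajectory-class]
#' @return numeric matrix
#' @export
setGeneric("coordMatrix", function(x) standardGeneric("coordMatrix"))

#' @rdname coordMatrix
#' @export
setMethod("coordMatrix", "Trajectory", function(x) x@xyz)

#' Names of domain-map entries
#' @param x a [DomainMap-class]
#' @return character vector
#' @export
setGeneric("domainNames", function(x) standardGeneric("domainNames"))

#' @rdname domainNames
#' @export
setMethod("domainNames", "DomainMap", function(x) names(x@entries))

#' Atom indices of a selection
#' @param x a [ResidueSelection-class]
#' @return integer vector of 1-based atom indices
#' @export
setGeneric("atomIndices", function(x) standardGeneric("atomIndices"))

#' @rdname atomIndices
#' @export
setMethod("atomIndices", "ResidueSelection", function(x) x@atomIndices)

#' Community membership vector
#' @param x a [CommunityPartition-class]
#' @return named integer vector
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname membership
#' @export
setMethod("membership", "CommunityPartition", function(x) x@membership)

#' Modularity of a partition
#' @param x a [CommunityPartition-class]
#' @return numeric modularity score
#' @export
setGeneric("modularityScore", function(x) standardGeneric("modularityScore"))

#' @rdname modularityScore
#' @export
setMethod("modularityScore", "CommunityPartition", function(x) x@modularity)

#' Underlying igraph of a network
#' @param x a [NetworkGraph-class]
#' @return igraph object
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "NetworkGraph", function(x) x@graph)

#' Per-frame state labels of a timeline
#' @param x an [EventTimeline-class]
#' @return character vector of states
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname states
#' @export
setMethod("states", "EventTimeline", function(x) x@states)

#' Step annotations of a timeline
#' @param x an [EventTimeline-class]
#' @return data.frame with columns step, onset_ns, signal
#' @export
setGeneric("steps", function(x) standardGeneric("steps"))

#' @rdname steps
#' @export
setMethod("steps", "EventTimeline", function(x) x@steps)

#' Occupancy matrix of a table
#' @param x an [OccupancyTable-class]
#' @return numeric matrix, pairs x windows
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname occupancy
#' @export
setMethod("occupancy", "OccupancyTable", function(x) {
  m <- x@occupancy
  rownames(m) <- x@pairs$label
  colnames(m) <- x@windows$label
  m
})

#' Sub-50% occupancy flags
#'
#' Flags every cell with occupancy strictly below 0.5; a cell at exactly 0.5
#' is not flagged.
#' @param x an [OccupancyTable-class]
#' @return logical matrix, pairs x windows
#' @export
occupancyFlags <- function(x) {
  stopifnot(is(x, "OccupancyTable"))
  m <- occupancy(x)
  m < 0.5
}

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  cat(sprintf("Topology: %d atoms, %d residues, %d chain(s) [%s]\n",
              nrow(a), sum(!duplicated(paste(a$chain, a$resno))),
              length(unique(a$chain)), paste(unique(a$chain), collapse = ",")))
})

setMethod("show", "Trajectory", function(object) {
  t <- object@times
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %.3f..%.3f ns\n",
              nrow(object@xyz), nrow(object@topology@atoms), t[1L], t[length(t)]))
})

setMethod("show", "DomainMap", function(object) {
  cat(sprintf("DomainMap with %d entries:\n", length(object@entries)))
  for (nm in names(object@entries)) {
    d <- object@entries[[nm]]
    cat(sprintf("  %-16s %s\n", nm,
                paste(sprintf("%s:%d-%d", d$chain, d$start, d$end), collapse = ", ")))
  }
})

setMethod("show", "ResidueSelection", function(object) {
  cat(sprintf("ResidueSelection '%s': %d atoms over %d residues\n",
              object@domain, length(object@atomIndices), nrow(object@residues)))
})

setMethod("show", "OccupancyTable", function(object) {
  cat(sprintf("OccupancyTable: %d pairs x %d windows (flag: occupancy < 0.5)\n",
              nrow(object@pairs), nrow(object@windows)))
})

setMethod("show", "NetworkGraph", function(object) {
  g <- object@graph
  cat(sprintf("NetworkGraph: %d nodes, %d edges (weight = -log|C|)\n",
              igraph::vcount(g), igraph::ecount(g)))
})

setMethod("show", "CommunityPartition", function(object) {
  cat(sprintf("CommunityPartition: %d nodes in %d communities, modularity %.4f\n",
              length(object@membership), length(unique(object@membership)),
              object@modularity))
})

setMethod("show", "CommunicationPath", function(object) {
  if (!object@found) {
    cat("CommunicationPath: no path (disconnected)\n")
  } else {
    cat(sprintf("CommunicationPath: %s (weight %.4f, %d nodes)\n",
                paste(object@nodes, collapse = " -> "),
                object@totalWeight, length(object@nodes)))
  }
})

setMethod("show", "EventTimeline", function(object) {
  tab <- table(object@states)
  cat(sprintf("EventTimeline: %d frames (%s); %d step annotation(s)\n",
              length(object@states),
              paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = ", "),
              nrow(object@steps)))
  if (nrow(object@steps) > 0L)
    for (i in seq_len(nrow(object@steps)))
      cat(sprintf("  Step %d at %.1f ns (%s)\n", object@steps$step[i],
                  object@steps$onset_ns[i], object@steps$signal[i]))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d domain(s), %d frames x %.3g ns, %d scheduled contact(s)%s\n",
              nrow(object@domains), object@nframes, object@dtNs,
              nrow(object@contacts),
              if (length(object@detach)) sprintf(", detachment at frame %d",
                                                 object@detach$frame) else ""))
})
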