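# Dynamical network analysis: motional correlations between residues, a
# contact-filtered residue graph weighted by -log|C|, Girvan-Newman
# communities, critical inter-community edges and optimal communication
# paths. Graph primitives (edge betweenness, modularity, components, GraphML)
# come from igraph; the algorithms that combine them are implemented here
# with deterministic tie-breaking so runs are exactly reproducible.

#' Motional correlation matrix
#'
#' Normalized covariance of the 3-D displacement vectors from the time-mean
#' position: `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)` (scalar
#' dot-product convention, not per-axis Pearson). The trajectory should be
#' superposed over the node set first. A node with zero positional variance
#' is flagged: its off-diagonal entries are NA and it acquires no edges.
#'
#' @param traj a [Trajectory-class] (superposed)
#' @param nodes a [ResidueSelection-class]; C-alpha atoms become the nodes
#' @param window optional integer frame indices (>= 2 frames)
#' @return symmetric matrix in `[-1, 1]` with unit diagonal; dimnames are
#'   node ids `"chain:resno"`; attribute `static` lists flagged nodes
#' @export
correlationMatrix <- function(traj, nodes, window = NULL) {
  stopifnot(is(traj, "Trajectory"), is(nodes, "ResidueSelection"))
  if (is.null(window)) window <- seq_len(nFrames(traj))
  if (length(window) < 2L) stop("need >= 2 frames for correlations")
  a <- traj@topology@atoms
  idx <- nodes@atomIndices
  idx <- idx[a$name[idx] == "CA"]
  n <- length(idx)
  ids <- .nodeId(a$chain[idx], a$resno[idx])
  num <- matrix(0, n, n)
  for (ax in 0:2) {
    X <- traj@xyz[window, 3L * idx - 2L + ax, drop = FALSE]
    X <- sweep(X, 2L, colMeans(X))
    num <- num + crossprod(X)
  }
  v <- diag(num)
  static <- which(v <= 1e-12 * max(v, 1))
  denom <- sqrt(outer(v, v))
  C <- num / denom
  C[static, ] <- NA_real_
  C[, static] <- NA_real_
  C <- pmin(pmax(C, -1), 1)
  diag(C) <- 1
  dimnames(C) <- list(ids, ids)
  attr(C, "static") <- ids[static]
  C
}

#' Contact adjacency between residues
#'
#' An edge exists when any heavy-atom pair of two residues lies within
#' `cutoff` in at least `minFraction` of the window frames; same-chain
#' residues closer than or equal to `neighborExclusion` in sequence are
#' excluded. With `atoms = "CA"` only the C-alpha distance is used
#' (reduced/synthetic systems); pick a larger cutoff there.
#'
#' @param traj a [Trajectory-class]
#' @param nodes a [ResidueSelection-class] defining the node residues
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.5)
#' @param minFraction minimum fraction of frames in contact (default 0.75)
#' @param neighborExclusion exclude same-chain pairs with
#'   `|resno_i - resno_j| <=` this value (default 1)
#' @param window optional integer frame indices (default all)
#' @param atoms `"heavy"` (default) or `"CA"`
#' @return symmetric logical matrix with node-id dimnames
#' @export
contactAdjacency <- function(traj, nodes, cutoff = 4.5, minFraction = 0.75,
                             neighborExclusion = 1L, window = NULL,
                             atoms = c("heavy", "CA")) {
  stopifnot(is(traj, "Trajectory"), is(nodes, "ResidueSelection"))
  atoms <- match.arg(atoms)
  if (is.null(window)) window <- seq_len(nFrames(traj))
  a <- traj@topology@atoms
  caIdx <- nodes@atomIndices[a$name[nodes@atomIndices] == "CA"]
  n <- length(caIdx)
  ids <- .nodeId(a$chain[caIdx], a$resno[caIdx])
  chain <- a$chain[caIdx]; resno <- a$resno[caIdx]
  # atoms per node residue
  atomsOf <- if (atoms == "CA") as.list(caIdx) else {
    lapply(seq_len(n), function(k)
      which(a$chain == chain[k] & a$resno == resno[k] & a$element != "H"))
  }
  maxReach <- vapply(seq_len(n), function(k) {
    X <- .rowToXYZ(traj@xyz[window[1L], ])
    if (length(atomsOf[[k]]) == 1L) 0
    else max(sqrt(rowSums(sweep(X[atomsOf[[k]], , drop = FALSE], 2L,
                                X[caIdx[k], ])^2)))
  }, numeric(1))
  # prefilter candidate pairs by CA distance over a coarse frame sample
  sampleFrames <- window[unique(round(seq(1L, length(window), length.out = min(10L, length(window)))))]
  slack <- cutoff + 2 * max(maxReach) + 6  # 6 A of motion headroom
  candidate <- matrix(FALSE, n, n)
  for (f in sampleFrames) {
    X <- .rowToXYZ(traj@xyz[f, ])[caIdx, , drop = FALSE]
    candidate <- candidate | (as.matrix(dist(X)) <= slack)
  }
  excl <- outer(chain, chain, `==`) &
          abs(outer(resno, resno, `-`)) <= neighborExclusion
  candidate[excl] <- FALSE
  pairs <- which(candidate & upper.tri(candidate), arr.ind = TRUE)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(pairs)) {
    nf <- length(window)
    cut2 <- cutoff^2
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1L]; j <- pairs[p, 2L]
      d2min <- rep(Inf, nf)
      for (x in atomsOf[[i]]) {
        for (y in atomsOf[[j]]) {
          dx <- traj@xyz[window, 3L * x - 2L] - traj@xyz[window, 3L * y - 2L]
          dy <- traj@xyz[window, 3L * x - 1L] - traj@xyz[window, 3L * y - 1L]
          dz <- traj@xyz[window, 3L * x] - traj@xyz[window, 3L * y]
          d2min <- pmin(d2min, dx * dx + dy * dy + dz * dz)
        }
      }
      adj[i, j] <- adj[j, i] <- mean(d2min <= cut2) >= minFraction
    }
  }
  attr(adj, "cutoff") <- cutoff
  attr(adj, "minFraction") <- minFraction
  adj
}

#' Build the correlation-weighted residue network
#'
#' For every contact edge, weight `w_ij = -log(|C_ij|)` with `|C_ij|`
#' clamped to `[1e-8, 1]`; the raw correlation is kept as an edge attribute.
#' Edges whose correlation is undefined (static node) are dropped. The graph
#' may be disconnected.
#'
#' @param adjacency logical matrix from [contactAdjacency()]
#' @param correlations matrix from [correlationMatrix()] over the same nodes
#' @return a [NetworkGraph-class]
#' @export
buildNetwork <- function(adjacency, correlations) {
  ids <- rownames(adjacency)
  stopifnot(identical(ids, rownames(correlations)))
  ut <- which(adjacency & upper.tri(adjacency), arr.ind = TRUE)
  keep <- !is.na(correlations[ut])
  ut <- ut[keep, , drop = FALSE]
  cc <- correlations[ut]
  absC <- pmin(pmax(abs(cc), 1e-8), 1)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(ut)) {
    g <- igraph::add_edges(g, rbind(ut[, 1L], ut[, 2L]))
    g <- igraph::set_edge_attr(g, "correlation", value = cc)
    g <- igraph::set_edge_attr(g, "weight", value = -log(absC))
  }
  new("NetworkGraph", graph = g)
}

#' Construct a network graph from an edge list
#'
#' Convenience constructor for tests and small examples.
#'
#' @param from,to character node ids
#' @param weight non-negative edge weights (communication costs)
#' @param correlation optional raw correlations (default `exp(-weight)`)
#' @param nodes optional full node set (to include isolated nodes)
#' @return a [NetworkGraph-class]
#' @export
networkFromEdges <- function(from, to, weight, correlation = exp(-weight),
                             nodes = NULL) {
  ids <- if (is.null(nodes)) sort(unique(c(from, to))) else nodes
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::add_edges(g, rbind(match(from, ids), match(to, ids)))
  g <- igraph::set_edge_attr(g, "weight", value = weight)
  g <- igraph::set_edge_attr(g, "correlation", value = correlation)
  new("NetworkGraph", graph = g)
}

#' Optimal communication path
#'
#' Minimum-total-weight path between two nodes (Dijkstra). Ties in total
#' weight are broken deterministically in favour of the lexicographically
#' smallest node-id sequence. Disconnected source/target yields an explicit
#' no-path result with infinite weight.
#'
#' @param network a [NetworkGraph-class]
#' @param source,target node ids
#' @return a [CommunicationPath-class]
#' @export
optimalPath <- function(network, source, target) {
  g <- network@graph
  ids <- igraph::V(g)$name
  if (!source %in% ids) stop("key error: node '", source, "' not in graph")
  if (!target %in% ids) stop("key error: node '", target, "' not in graph")
  if (source == target) stop("source and target must differ")
  n <- length(ids)
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  ew <- igraph::E(g)$weight
  # edge weight lookup per (i, j)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  wmat <- new.env(hash = TRUE)
  for (e in seq_len(nrow(ends))) {
    k1 <- paste0(ends[e, 1L], ".", ends[e, 2L])
    k2 <- paste0(ends[e, 2L], ".", ends[e, 1L])
    old <- mget(k1, envir = wmat, ifnotfound = Inf)[[1L]]
    if (ew[e] < old) { assign(k1, ew[e], envir = wmat); assign(k2, ew[e], envir = wmat) }
  }
  s <- match(source, ids); t <- match(target, ids)
  distv <- rep(Inf, n); distv[s] <- 0
  paths <- vector("list", n); paths[[s]] <- ids[s]
  visited <- rep(FALSE, n)
  eps <- 1e-12
  lexLess <- function(p1, p2) {
    l <- min(length(p1), length(p2))
    for (q in seq_len(l)) {
      if (p1[q] < p2[q]) return(TRUE)
      if (p1[q] > p2[q]) return(FALSE)
    }
    length(p1) < length(p2)
  }
  repeat {
    cand <- which(!visited & is.finite(distv))
    if (length(cand) == 0L) break
    u <- cand[order(distv[cand], ids[cand])][1L]
    if (u == t) break
    visited[u] <- TRUE
    for (v in adj[[u]]) {
      if (visited[v]) next
      w <- get(paste0(u, ".", v), envir = wmat)
      nd <- distv[u] + w
      npath <- c(paths[[u]], ids[v])
      tol <- eps * max(1, abs(nd))
      if (nd < distv[v] - tol ||
          (abs(nd - distv[v]) <= tol && lexLess(npath, paths[[v]]))) {
        distv[v] <- nd
        paths[[v]] <- npath
      }
    }
  }
  if (!is.finite(distv[t]))
    return(new("CommunicationPath", nodes = character(0), totalWeight = Inf,
               edgeWeights = numeric(0), found = FALSE))
  p <- paths[[t]]
  pi <- match(p, ids)
  ewts <- vapply(seq_len(length(pi) - 1L), function(q)
    get(paste0(pi[q], ".", pi[q + 1L]), envir = wmat), numeric(1))
  new("CommunicationPath", nodes = p, totalWeight = sum(ewts),
      edgeWeights = ewts, found = TRUE)
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge with the highest weighted edge betweenness
#' (weights read as communication costs, recomputed after every removal) and
#' retains the partition along the dendrogram that maximizes modularity.
#' Modularity uses the correlation strength `|C|` as the affinity weight
#' (modularity expects affinities, not costs); set `affinity = "uniform"` to
#' score on the unweighted graph instead. Ties in betweenness are broken by
#' the lexicographically smallest (sorted) endpoint pair. An edgeless graph
#' yields singleton communities with modularity 0.
#'
#' @param network a [NetworkGraph-class]
#' @param affinity `"correlation"` (default) or `"uniform"`
#' @return a [CommunityPartition-class]
#' @export
girvanNewmanCommunities <- function(network, affinity = c("correlation", "uniform")) {
  affinity <- match.arg(affinity)
  g0 <- network@graph
  ids <- igraph::V(g0)$name
  if (igraph::ecount(g0) == 0L) {
    return(new("CommunityPartition",
               membership = stats::setNames(seq_along(ids), ids),
               modularity = 0))
  }
  qWeights <- if (affinity == "correlation") {
    cc <- igraph::E(g0)$correlation
    if (is.null(cc)) exp(-igraph::E(g0)$weight) else pmin(abs(cc), 1)
  } else rep(1, igraph::ecount(g0))
  scoreQ <- function(memIdx) igraph::modularity(g0, memIdx, weights = qWeights)
  canonical <- function(memIdx) as.integer(factor(memIdx, levels = unique(memIdx)))
  gw <- g0
  best <- igraph::components(gw)$membership
  bestQ <- scoreQ(best)
  while (igraph::ecount(gw) > 0L) {
    eb <- igraph::edge_betweenness(gw, weights = igraph::E(gw)$weight)
    mx <- max(eb)
    top <- which(eb >= mx - 1e-9 * max(1, mx))
    if (length(top) > 1L) {
      ep <- igraph::ends(gw, igraph::E(gw)[top])
      key <- apply(ep, 1L, function(r) paste(sort(r), collapse = "\r"))
      top <- top[order(key)][1L]
    }
    gw <- igraph::delete_edges(gw, top[1L])
    mem <- igraph::components(gw)$membership
    q <- scoreQ(mem)
    if (q > bestQ + 1e-12) { bestQ <- q; best <- mem }
  }
  mem <- canonical(best[ids])
  names(mem) <- ids
  new("CommunityPartition", membership = mem,
      modularity = max(min(bestQ, 1), -0.5))
}

#' Critical inter-community edges and nodes
#'
#' Ranks all inter-community edges by weighted edge betweenness on the full
#' graph; the top edge of each community pair is labelled critical and its
#' endpoints are reported as critical nodes. A single community yields an
#' empty report.
#'
#' @param network a [NetworkGraph-class]
#' @param partition a [CommunityPartition-class] covering the graph nodes
#' @return data.frame `nodeA`, `nodeB`, `communityA`, `communityB`,
#'   `weight`, `correlation`, `betweenness`, `critical`, ordered by
#'   decreasing betweenness
#' @export
criticalEdges <- function(network, partition) {
  g <- network@graph
  mem <- partition@membership
  ids <- igraph::V(g)$name
  if (!all(ids %in% names(mem)))
    stop("partition does not cover all graph nodes")
  if (igraph::ecount(g) == 0L || length(unique(mem)) < 2L)
    return(data.frame(nodeA = character(0), nodeB = character(0),
                      communityA = integer(0), communityB = integer(0),
                      weight = numeric(0), correlation = numeric(0),
                      betweenness = numeric(0), critical = logical(0)))
  eb <- igraph::edge_betweenness(g, weights = igraph::E(g)$weight)
  ep <- igraph::ends(g, igraph::E(g))
  ca <- mem[ep[, 1L]]; cb <- mem[ep[, 2L]]
  inter <- which(ca != cb)
  if (length(inter) == 0L)
    return(data.frame(nodeA = character(0), nodeB = character(0),
                      communityA = integer(0), communityB = integer(0),
                      weight = numeric(0), correlation = numeric(0),
                      betweenness = numeric(0), critical = logical(0)))
  cc <- igraph::E(g)$correlation
  if (is.null(cc)) cc <- exp(-igraph::E(g)$weight)
  df <- data.frame(nodeA = ep[inter, 1L], nodeB = ep[inter, 2L],
                   communityA = pmin(ca[inter], cb[inter]),
                   communityB = pmax(ca[inter], cb[inter]),
                   weight = igraph::E(g)$weight[inter],
                   correlation = cc[inter],
                   betweenness = eb[inter], stringsAsFactors = FALSE)
  df <- df[order(-df$betweenness, df$nodeA, df$nodeB), , drop = FALSE]
  pairKey <- paste(df$communityA, df$communityB)
  df$critical <- !duplicated(pairKey)
  rownames(df) <- NULL
  df
}

#' Compare optimal path lengths between two networks
#'
#' Computes the optimal source-to-target path in both graphs (e.g. wild type
#' vs mutant, or pre- vs post-detachment windows) and reports the weights,
#' the node-count difference and a longer/shorter/equal verdict for the
#' second graph relative to the first. A disconnected side is reported with
#' infinite weight.
#'
#' @param networkA,networkB [NetworkGraph-class] objects
#' @param source,target node ids (must exist in both graphs)
#' @return list with `pathA`, `pathB`, `weightA`, `weightB`,
#'   `nodeCountDiff`, `verdict` (`"longer"`, `"shorter"` or `"equal"`,
#'   B relative to A)
#' @export
pathLengthCompare <- function(networkA, networkB, source, target) {
  pa <- optimalPath(networkA, source, target)
  pb <- optimalPath(networkB, source, target)
  wa <- pa@totalWeight; wb <- pb@totalWeight
  verdict <- if (isTRUE(all.equal(wa, wb))) "equal"
             else if (wb > wa) "longer" else "shorter"
  list(pathA = pa, pathB = pb, weightA = wa, weightB = wb,
       nodeCountDiff = length(pb@nodes) - length(pa@nodes),
       verdict = verdict)
}

#' Export a network as GraphML and edge-list CSV
#'
#' @param network a [NetworkGraph-class]
#' @param graphmlPath output GraphML file (NULL to skip)
#' @param edgeCsvPath output CSV file (NULL to skip); columns `node_i`,
#'   `node_j`, `correlation`, `weight`, and community ids when a partition
#'   is given
#' @param partition optional [CommunityPartition-class]
#' @return invisibly, NULL
#' @export
exportNetwork <- function(network, graphmlPath = NULL, edgeCsvPath = NULL,
                          partition = NULL) {
  g <- network@graph
  if (!is.null(graphmlPath))
    igraph::write_graph(g, graphmlPath, format = "graphml")
  if (!is.null(edgeCsvPath)) {
    ep <- igraph::ends(g, igraph::E(g))
    cc <- igraph::E(g)$correlation
    if (is.null(cc)) cc <- exp(-igraph::E(g)$weight)
    df <- data.frame(node_i = ep[, 1L], node_j = ep[, 2L],
                     correlation = cc, weight = igraph::E(g)$weight,
                     stringsAsFactors = FALSE)
    if (!is.null(partition)) {
      df$community_i <- partition@membership[df$node_i]
      df$community_j <- partition@membership[df$node_j]
    }
    utils::write.csv(df, edgeCsvPath, row.names = FALSE)
  }
  invisible(NULL)
}
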