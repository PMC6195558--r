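# Independent oracles and small fixture builders shared across tests.

# ---- fixture builders ------------------------------------------------------

mkTopo <- function(names, elements, resnos, chains, resnames = "GLY",
                   masses = NULL) {
  n <- length(names)
  df <- data.frame(serial = seq_len(n), name = names, element = elements,
                   mass = if (is.null(masses)) trajnet:::.massFromElement(elements)
                          else masses,
                   resno = resnos, resname = rep_len(resnames, n),
                   chain = chains, stringsAsFactors = FALSE)
  newTopology(df)
}

mkTraj <- function(topo, frames, dtNs = 1) {
  xyz <- do.call(rbind, lapply(frames, function(m) as.numeric(t(m))))
  newTrajectory(topo, xyz, dtNs = dtNs)
}

selOf <- function(topo, idx, domain = "sel") {
  a <- atoms(topo)
  key <- !duplicated(paste(a$chain[idx], a$resno[idx]))
  new("ResidueSelection", atomIndices = as.integer(idx), domain = domain,
      residues = data.frame(chain = a$chain[idx][key], resno = a$resno[idx][key],
                            resname = a$resname[idx][key], stringsAsFactors = FALSE))
}

allCASelection <- function(topo) {
  a <- atoms(topo)
  selOf(topo, which(a$name == "CA"), "all-CA")
}

# memoised full-size preset system (generated once per test run)
presetFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- pi3kLikePreset()
      cache <<- c(list(spec = sp), generateTrajectory(sp))
    }
    cache
  }
})

# ---- geometry oracles ------------------------------------------------------

# quaternion (Horn) absolute-orientation superposition of mobile onto fixed
quaternionFit <- function(fixed, mobile) {
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(fixed, 2L, cf)
  S <- t(P) %*% Q
  K <- matrix(0, 4L, 4L)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1L]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)), 3L, 3L,
    byrow = TRUE)
  sweep(P %*% t(R), 2L, cf, `+`)
}

# ---- graph oracles ---------------------------------------------------------

# minimum simple-path weight by exhaustive DFS enumeration
bruteShortestPath <- function(net, source, target) {
  g <- asIgraph(net)
  ids <- igraph::V(g)$name
  s <- match(source, ids); t <- match(target, ids)
  w <- igraph::E(g)$weight
  best <- Inf
  rec <- function(v, visited, acc) {
    if (acc >= best) return(invisible(NULL))
    if (v == t) { best <<- acc; return(invisible(NULL)) }
    for (e in igraph::incident(g, v)) {
      vv <- igraph::ends(g, e, names = FALSE)[1L, ]
      u <- if (vv[1L] == v) vv[2L] else vv[1L]
      if (!(u %in% visited)) rec(u, c(visited, u), acc + w[as.integer(e)])
    }
  }
  rec(s, s, 0)
  best
}

# brute-force weighted edge betweenness (unordered pairs; equal split over
# co-optimal shortest paths)
bruteEdgeBetweenness <- function(g) {
  m <- igraph::ecount(g); n <- igraph::vcount(g)
  eb <- numeric(m)
  w <- igraph::E(g)$weight
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- list(); bw <- Inf
    rec <- function(v, visited, acc, edges) {
      if (acc > bw + 1e-12) return(invisible(NULL))
      if (v == t) {
        if (acc < bw - 1e-12) { bw <<- acc; paths <<- list(edges) }
        else paths[[length(paths) + 1L]] <<- edges
        return(invisible(NULL))
      }
      for (e in igraph::incident(g, v)) {
        vv <- igraph::ends(g, e, names = FALSE)[1L, ]
        u <- if (vv[1L] == v) vv[2L] else vv[1L]
        if (!(u %in% visited))
          rec(u, c(visited, u), acc + w[as.integer(e)], c(edges, as.integer(e)))
      }
    }
    rec(s, s, 0, integer(0))
    if (is.finite(bw)) for (p in paths) eb[p] <- eb[p] + 1 / length(paths)
  }
  eb
}

# all set partitions of 1..n as a matrix (restricted growth strings)
allPartitions <- function(n) {
  out <- list()
  rec <- function(s, mx) {
    if (length(s) == n) { out[[length(out) + 1L]] <<- s; return(invisible(NULL)) }
    for (v in 1:(mx + 1)) rec(c(s, v), max(mx, v))
  }
  rec(integer(0), 0L)
  do.call(rbind, out)
}

# weighted modularity of one partition (direct formula)
modularityOf <- function(p, from, to, w) {
  W <- sum(w)
  st <- numeric(max(p))
  for (e in seq_along(w)) {
    st[p[from[e]]] <- st[p[from[e]]] + w[e]
    st[p[to[e]]] <- st[p[to[e]]] + w[e]
  }
  sum(w[p[from] == p[to]]) / W - sum((st / (2 * W))^2)
}

# random two-4-clique graph joined by one weak bridge (modular regime)
cliquePairGraph <- function() {
  blk <- rep(1:2, each = 4L)
  from <- c(); to <- c(); corr <- c()
  for (i in 1:7) for (j in (i + 1):8)
    if (blk[i] == blk[j]) {
      from <- c(from, i); to <- c(to, j)
      corr <- c(corr, stats::runif(1, 0.65, 0.95))
    }
  i <- sample(1:4, 1); j <- sample(5:8, 1)
  from <- c(from, i); to <- c(to, j)
  corr <- c(corr, stats::runif(1, 0.05, 0.2))
  ids <- LETTERS[1:8]
  list(net = networkFromEdges(ids[from], ids[to], weight = -log(corr),
                              correlation = corr, nodes = ids),
       from = from, to = to, corr = corr, blocks = blk)
}

# random connected weighted graph on <= maxN nodes
randomWeightedGraph <- function(maxN = 8L) {
  repeat {
    n <- sample(4:maxN, 1)
    g <- igraph::sample_gnp(n, 0.5)
    if (igraph::ecount(g) >= 3 && igraph::is_connected(g)) break
  }
  corr <- stats::runif(igraph::ecount(g), 0.05, 0.95)
  ids <- LETTERS[seq_len(n)]
  ep <- igraph::ends(g, igraph::E(g), names = FALSE)
  networkFromEdges(ids[ep[, 1L]], ids[ep[, 2L]], weight = -log(corr),
                   correlation = corr, nodes = ids)
}

# analytic SASA of two intersecting equal spheres (accessible area of one)
twoSphereArea <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  # height of the cap of sphere 1 cut off by sphere 2
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h
}
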