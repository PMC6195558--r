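test_that("correlation matrix reproduces coherent, anti-phase and planted block motion", {
  set.seed(41)
  n <- 4L; nf <- 200L
  topo <- mkTopo(rep("CA", n), rep("C", n), 1:n, rep("A", n))
  base <- matrix(rnorm(3 * n, sd = 10), n)
  disp <- matrix(rnorm(3 * nf), nf)
  frames <- lapply(seq_len(nf), function(f) {
    m <- base
    m[1, ] <- m[1, ] + disp[f, ]
    m[2, ] <- m[2, ] + disp[f, ]     # identical displacements
    m[3, ] <- m[3, ] - disp[f, ]     # anti-phase
    m[4, ] <- m[4, ]                 # static
    m
  })
  tr <- mkTraj(topo, frames)
  C <- correlationMatrix(tr, allCASelection(topo))
  expect_equal(C["A:1", "A:2"], 1, tolerance = 1e-12)
  expect_equal(C["A:1", "A:3"], -1, tolerance = 1e-12)
  expect_equal(unname(diag(C)), rep(1, 4))
  # static node flagged, correlations undefined
  expect_true("A:4" %in% attr(C, "static"))
  expect_true(all(is.na(C["A:4", c("A:1", "A:2", "A:3")])))
  # symmetric, and PSD up to numerical noise on the defined sub-block
  Cd <- C[1:3, 1:3]
  expect_identical(Cd, t(Cd))
  expect_gt(min(eigen(Cd, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("contact adjacency applies cutoff, frame fraction and neighbor exclusion", {
  topo <- mkTopo(rep("CA", 4), rep("C", 4), 1:4, rep("A", 4))
  # residues 1 and 3: 4.0 A apart (non-neighbours); residues 3,4: 4.0 A apart
  # but sequence neighbours (|i - j| = 1), hence excluded
  nearF <- rbind(c(0, 0, 0), c(50, 50, 0), c(4, 0, 0), c(8, 0, 0))
  farF <- rbind(c(0, 0, 0), c(50, 50, 0), c(9, 0, 0), c(13, 0, 0))
  tr <- mkTraj(topo, c(replicate(3, nearF, simplify = FALSE),
                       replicate(1, farF, simplify = FALSE)))
  adj <- contactAdjacency(tr, allCASelection(topo), cutoff = 4.5,
                          minFraction = 0.75, neighborExclusion = 1L,
                          atoms = "CA")
  expect_false(adj["A:3", "A:4"])          # exclusion rule
  expect_true(adj["A:1", "A:3"])           # within cutoff in 75% of frames
  tr50 <- mkTraj(topo, list(nearF, farF, nearF, farF))
  adj50 <- contactAdjacency(tr50, allCASelection(topo), cutoff = 4.5,
                            minFraction = 0.75, neighborExclusion = 1L,
                            atoms = "CA")
  expect_false(adj50["A:1", "A:3"])        # 50% of frames is below 0.75
})

test_that("edge weights follow -log|C| with clamping", {
  ids <- c("A:1", "A:2", "A:3", "A:4")
  adj <- matrix(FALSE, 4, 4, dimnames = list(ids, ids))
  adj[1, 2] <- adj[2, 1] <- TRUE
  adj[2, 3] <- adj[3, 2] <- TRUE
  adj[3, 4] <- adj[4, 3] <- TRUE
  C <- diag(4); dimnames(C) <- list(ids, ids)
  C[1, 2] <- C[2, 1] <- 1
  C[2, 3] <- C[3, 2] <- 0.5
  C[3, 4] <- C[4, 3] <- 0
  net <- buildNetwork(adj, C)
  w <- setNames(igraph::E(asIgraph(net))$weight,
                apply(igraph::ends(asIgraph(net), igraph::E(asIgraph(net))), 1,
                      paste, collapse = "-"))
  expect_equal(unname(w["A:1-A:2"]), 0)
  expect_equal(unname(w["A:2-A:3"]), log(2))
  expect_equal(unname(w["A:3-A:4"]), -log(1e-8))   # clamped, finite ~ 18.42
})

test_that("optimal paths match closed forms and brute-force enumeration", {
  net1 <- networkFromEdges("A", "B", 1)
  p <- optimalPath(net1, "A", "B")
  expect_equal(p@nodes, c("A", "B"))
  expect_equal(p@totalWeight, 1)

  net2 <- networkFromEdges(c("A", "B", "A"), c("B", "C", "C"), c(1, 1, 3))
  p <- optimalPath(net2, "A", "C")
  expect_equal(p@nodes, c("A", "B", "C"))
  expect_equal(p@totalWeight, 2)

  # deterministic lexicographic tie-break on equal-weight routes
  net3 <- networkFromEdges(c("A", "A", "B", "C"), c("B", "C", "D", "D"),
                           c(1, 1, 1, 1))
  expect_equal(optimalPath(net3, "A", "D")@nodes, c("A", "B", "D"))

  # explicit no-path result on disconnected graphs
  net4 <- networkFromEdges(c("A", "C"), c("B", "D"), c(1, 1))
  p <- optimalPath(net4, "A", "D")
  expect_false(p@found)
  expect_identical(p@totalWeight, Inf)
  expect_error(optimalPath(net4, "A", "Z"), "key error")

  set.seed(42)
  for (i in 1:20) {
    net <- randomWeightedGraph(8L)
    ids <- igraph::V(asIgraph(net))$name
    st <- sample(ids, 2)
    p <- optimalPath(net, st[1], st[2])
    expect_equal(p@totalWeight, bruteShortestPath(net, st[1], st[2]),
                 tolerance = 1e-9)
    expect_equal(p@totalWeight, sum(p@edgeWeights))
  }
})

test_that("path weight is monotone under edge deletion and weight decrease", {
  set.seed(43)
  for (i in 1:10) {
    net <- randomWeightedGraph(7L)
    g <- asIgraph(net)
    ids <- igraph::V(g)$name
    st <- sample(ids, 2)
    w0 <- optimalPath(net, st[1], st[2])@totalWeight
    gDel <- igraph::delete_edges(g, sample(igraph::ecount(g), 1))
    wDel <- optimalPath(new("NetworkGraph", graph = gDel), st[1], st[2])@totalWeight
    expect_gte(wDel, w0 - 1e-12)
    gDec <- g
    e <- sample(igraph::ecount(g), 1)
    igraph::E(gDec)$weight[e] <- igraph::E(gDec)$weight[e] / 2
    wDec <- optimalPath(new("NetworkGraph", graph = gDec), st[1], st[2])@totalWeight
    expect_lte(wDec, w0 + 1e-12)
  }
})

test_that("Girvan-Newman splits cliques at bridges and keeps complete graphs whole", {
  # two 4-cliques joined by one bridge: split exactly at the bridge, matching
  # exhaustive modularity maximization
  g <- cliquePairGraph()
  part <- girvanNewmanCommunities(g$net)
  memb <- membership(part)
  expect_equal(length(unique(memb)), 2L)
  expect_equal(adjustedRandIndex(memb, setNames(g$blocks, LETTERS[1:8])), 1)
  qs <- apply(allPartitions(8L), 1, modularityOf, from = g$from, to = g$to,
              w = g$corr)
  expect_equal(modularityScore(part), max(qs), tolerance = 1e-9)

  # complete K5 with equal weights: one community
  from <- c(); to <- c()
  for (i in 1:4) for (j in (i + 1):5) { from <- c(from, i); to <- c(to, j) }
  k5 <- networkFromEdges(LETTERS[from], LETTERS[to], weight = rep(0.3, 10),
                         correlation = rep(0.74, 10))
  p5 <- girvanNewmanCommunities(k5)
  expect_equal(length(unique(membership(p5))), 1L)

  # edgeless graph: singleton communities, modularity 0
  e0 <- networkFromEdges(character(0), character(0), numeric(0),
                         nodes = c("A", "B", "C"))
  p0 <- girvanNewmanCommunities(e0)
  expect_equal(length(unique(membership(p0))), 3L)
  expect_identical(modularityScore(p0), 0)
})

test_that("edge betweenness used for removals matches a brute-force path-counting oracle", {
  set.seed(44)
  for (i in 1:8) {
    net <- randomWeightedGraph(7L)
    g <- asIgraph(net)
    eb <- igraph::edge_betweenness(g, weights = igraph::E(g)$weight)
    expect_equal(eb, bruteEdgeBetweenness(g), tolerance = 1e-8)
  }
})

test_that("critical edges are the top-betweenness inter-community connectors", {
  g <- cliquePairGraph()
  part <- girvanNewmanCommunities(g$net)
  ce <- criticalEdges(g$net, part)
  expect_equal(sum(ce$critical), 1L)       # single bridge, single critical edge
  bridge <- which(g$blocks[g$from] != g$blocks[g$to])
  expect_setequal(c(ce$nodeA[ce$critical], ce$nodeB[ce$critical]),
                  LETTERS[c(g$from[bridge], g$to[bridge])])

  # two parallel inter-community edges: the higher-traffic one ranks first,
  # confirmed against brute-force betweenness
  from <- c("A", "A", "B", "D", "D", "E", "A", "B")
  to <- c("B", "C", "C", "E", "F", "F", "D", "E")
  corr <- c(.8, .8, .8, .8, .8, .8, .4, .1)
  net <- networkFromEdges(from, to, weight = -log(corr), correlation = corr)
  part <- girvanNewmanCommunities(net)
  ce <- criticalEdges(net, part)
  expect_equal(length(unique(membership(part))), 2L)
  eb <- bruteEdgeBetweenness(asIgraph(net))
  # A-D has lower weight (higher |C|) than B-E, so it carries the traffic
  expect_equal(sort(c(ce$nodeA[1], ce$nodeB[1])), c("A", "D"))
  expect_gt(ce$betweenness[1], ce$betweenness[2])
  expect_true(ce$critical[1])
  expect_false(ce$critical[2])

  # single community: empty report
  k3 <- networkFromEdges(c("A", "B", "A"), c("B", "C", "C"), rep(0.2, 3),
                         correlation = rep(0.8, 3))
  pk <- girvanNewmanCommunities(k3)
  expect_equal(nrow(criticalEdges(k3, pk)), 0L)
})

test_that("pathLengthCompare reports equal, monotone and detachment verdicts", {
  net <- networkFromEdges(c("A", "B", "A"), c("B", "C", "C"), c(1, 1, 3))
  cmp <- pathLengthCompare(net, net, "A", "C")
  expect_equal(cmp$verdict, "equal")
  expect_equal(cmp$nodeCountDiff, 0L)
  g2 <- igraph::delete_edges(asIgraph(net), 1)   # drop an interfacial edge
  cmp2 <- pathLengthCompare(net, new("NetworkGraph", graph = g2), "A", "C")
  expect_gte(cmp2$weightB, cmp2$weightA)
  expect_equal(cmp2$verdict, "longer")
})

test_that("GraphML and edge-list exports round-trip node, weight and community data", {
  g <- cliquePairGraph()
  part <- girvanNewmanCommunities(g$net)
  gml <- tempfile(fileext = ".graphml")
  csv <- tempfile(fileext = ".csv")
  exportNetwork(g$net, gml, csv, partition = part)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 8)
  expect_equal(sort(igraph::V(back)$name), LETTERS[1:8])
  expect_equal(sort(igraph::E(back)$weight), sort(-log(g$corr)), tolerance = 1e-6)
  df <- read.csv(csv)
  expect_equal(nrow(df), length(g$corr))
  expect_true(all(c("node_i", "node_j", "correlation", "weight",
                    "community_i", "community_j") %in% names(df)))
})
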