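test_that("bipartite projection applies the role rules", {
  rn <- reactionNetwork(entities = rbind(
    entityRecord("A"), entityRecord("E"), entityRecord("B"),
    entityRecord("X"), entityRecord("Y")))
  rn <- addReaction(rn, "rx1", "catalysis", data.frame(
    node_id = c("A", "E", "B"),
    role = c("SUBSTRATE", "CATALYZES", "PRODUCT"), stringsAsFactors = FALSE))
  rn <- addReaction(rn, "rx2", "inhibition", data.frame(
    node_id = c("X", "Y"), role = c("INHIBITS", "PRODUCT"),
    stringsAsFactors = FALSE))
  net <- bipartiteProjection(rn)
  ed <- edges(net)
  expect_setequal(paste(ed$source_id, ed$target_id),
                  c("A B", "E B", "X Y"))
  expect_equal(ed$sign[ed$source_id == "X"], "inhibition")
  expect_true(all(ed$sign[ed$source_id != "X"] == "activation"))
  expect_true(all(ed$directed))
  expect_equal(ed$provenance[ed$source_id == "A"], "rx1")
})

test_that("a reaction chain projects to a traversable directed path", {
  rn <- reactionNetwork(entities = do.call(rbind, lapply(
    c("A", "B", "C", "D"), entityRecord)))
  chain <- list(c("A", "B"), c("B", "C"), c("C", "D"))
  for (i in seq_along(chain))
    rn <- addReaction(rn, sprintf("rx%d", i), "activation", data.frame(
      node_id = chain[[i]], role = c("ACTIVATES", "PRODUCT"),
      stringsAsFactors = FALSE))
  net <- bipartiteProjection(rn)
  adj <- oracleAdj(edges(net), entities(net)$id)
  expect_equal(unname(oracleBfsDist(adj, "A")["D"]), 3)
  res <- allShortestPaths(net, "A", "D")
  expect_equal(res@paths, list(c("A", "B", "C", "D")))

  # a reaction with no output-like participant is skipped with a warning
  rn2 <- addReaction(rn, "rx9", "degradation", data.frame(
    node_id = "D", role = "SUBSTRATE", stringsAsFactors = FALSE),
    source_sink = FALSE)
  expect_warning(bipartiteProjection(rn2), "rx9")
})

test_that("all shortest paths match the BFS enumeration oracle", {
  for (seed in 1:25) {
    net <- randomNetwork(sample(10:40, 1), sample(20:80, 1), seed = seed)
    ids <- entities(net)$id
    picks <- withr::with_seed(seed, sample(ids, 4))
    sources <- picks[1:2]; targets <- picks[3:4]
    for (mode in c("directed", "undirected")) {
      res <- allShortestPaths(net, sources, targets, mode = mode)
      adj <- oracleAdj(edges(net), ids, mode = mode)
      want <- list()
      for (s in sources) for (t in targets)
        want <- c(want, oracleAllShortestPaths(adj, s, t))
      expect_equal(pathSetKey(res@paths), pathSetKey(want),
                   info = sprintf("seed %d mode %s", seed, mode))
      # distances agree too
      for (s in sources) {
        d <- oracleBfsDist(adj, s)
        for (t in targets) {
          got <- res@distances$distance[res@distances$source == s &
                                          res@distances$target == t]
          expect_equal(got, if (is.finite(d[t])) as.integer(d[t])
                            else NA_integer_)
        }
      }
    }
  }
})

test_that("planted unique path is recovered exactly amid detours", {
  fx <- generateNetwork(planted_path_length = 3, seed = 11)
  res <- allShortestPaths(fx$network, fx$truth$path_source,
                          fx$truth$path_target)
  expect_equal(res@paths, list(fx$truth$path))
  expect_equal(unname(pathLengthHistogram(res)), 1L)
  expect_equal(names(pathLengthHistogram(res)), "3")
})

test_that("zero-length and unreachable pairs are handled", {
  net <- mkNet(list(e("A", "B")), extra_nodes = "Z")
  res <- allShortestPaths(net, c("A", "B"), c("B", "Z"))
  # B is both source and target: zero-length path
  zero <- res@pathInfo$length[res@pathInfo$source == "B" &
                                res@pathInfo$target == "B"]
  expect_equal(zero, 0L)
  expect_true(list("B") %in% res@paths)
  # Z unreachable: NA distance, no path
  expect_true(is.na(res@distances$distance[res@distances$target == "Z" &
                                             res@distances$source == "A"]))
  expect_error(allShortestPaths(net, "GHOST", "B"), "source")
  expect_warning(allShortestPaths(net, c("A", "GHOST"), "B"), "GHOST")
})

test_that("directed mode traverses undirected binding edges both ways", {
  net <- mkNet(list(e("A", "B", type = "binding", directed = FALSE,
                      sign = "unknown"),
                    e("B", "C")))
  res <- allShortestPaths(net, "C", "A", mode = "directed")
  expect_equal(nrow(res@pathInfo), 0)  # C->B is against the arrow
  res2 <- allShortestPaths(net, "A", "C", mode = "directed")
  expect_equal(res2@paths, list(c("A", "B", "C")))  # binding traversed
})

test_that("closestSources and restrictToClosest keep per-target argmins", {
  # S1 -> T in 2 steps, S2 -> T in 2, S3 -> T in 4
  net <- mkNet(list(e("S1", "m1"), e("m1", "T"),
                    e("S2", "m2"), e("m2", "T"),
                    e("S3", "a"), e("a", "b"), e("b", "c"), e("c", "T")))
  res <- allShortestPaths(net, c("S1", "S2", "S3"), "T")
  expect_equal(closestSources(res, "T"), c("S1", "S2"))
  expect_error(closestSources(res, "NOPE"), "NOPE")

  kept <- restrictToClosest(res)
  expect_setequal(unique(kept@pathInfo$source), c("S1", "S2"))
  # distances unchanged; no distance increased
  expect_equal(kept@distances, res@distances)
  # merged rebuilt from surviving paths only
  expect_false("S3" %in% entities(kept@merged)$id)

  # all sources equidistant -> identity on paths
  eq <- mkNet(list(e("S1", "T"), e("S2", "T")))
  r2 <- allShortestPaths(eq, c("S1", "S2"), "T")
  expect_equal(restrictToClosest(r2)@paths, r2@paths)

  # a target in the source set keeps its zero-length self-path
  net3 <- mkNet(list(e("S1", "a"), e("a", "T2")))
  r3 <- allShortestPaths(net3, c("S1", "T2"), "T2")
  k3 <- restrictToClosest(r3)
  expect_equal(k3@paths, list("T2"))

  # random fixtures: closest set equals a brute-force distance scan
  for (seed in 1:10) {
    net <- randomNetwork(20, 40, seed = seed)
    ids <- entities(net)$id
    res <- allShortestPaths(net, ids[1:3], ids[18:20])
    adj <- oracleAdj(edges(net), ids)
    for (t in ids[18:20]) {
      d <- vapply(ids[1:3], function(s) oracleBfsDist(adj, s)[[t]], 0)
      want <- if (all(is.infinite(d))) character(0)
              else sort(names(d)[d == min(d)])
      expect_equal(closestSources(res, t), want)
    }
  }
})

test_that("merged network is exactly the union of path nodes and edges", {
  for (seed in 1:8) {
    net <- randomNetwork(25, 50, seed = seed)
    ids <- entities(net)$id
    res <- allShortestPaths(net, ids[1:3], ids[22:25])
    expect_setequal(entities(res@merged)$id, unique(unlist(res@paths)))
    # every merged edge lies on a consecutive pair of some path
    ed <- edges(res@merged)
    onPath <- function(u, v) {
      any(vapply(res@paths, function(p) {
        if (length(p) < 2) return(FALSE)
        any(p[-length(p)] == u & p[-1] == v)
      }, logical(1)))
    }
    for (i in seq_len(nrow(ed))) {
      expect_true(onPath(ed$source_id[i], ed$target_id[i]) ||
                    (!ed$directed[i] &&
                       onPath(ed$target_id[i], ed$source_id[i])))
    }
  }
})

test_that("expandFirstNeighbors equals the radius-1 neighborhood", {
  net <- mkNet(list(e("A", "B"), e("B", "C"), e("B", "D"), e("D", "E"),
                    e("F", "G")))
  sub <- allShortestPaths(net, "A", "C")@merged
  exp1 <- expandFirstNeighbors(net, sub)
  expect_setequal(entities(exp1)$id, c("A", "B", "C", "D"))
  # whole network expands to itself
  expect_equal(nEntities(expandFirstNeighbors(net, net)), nEntities(net))
  # cross-check with neighborhoodSubnetwork on random fixtures
  for (seed in 1:5) {
    rnet <- randomNetwork(20, 35, seed = seed)
    ids <- entities(rnet)$id[1:4]
    a <- expandFirstNeighbors(rnet, ids)
    b <- neighborhoodSubnetwork(rnet, ids, radius = 1)
    expect_setequal(entities(a)$id, entities(b)$id)
  }
})

test_that("path length histogram tallies pairs by distance with a zero bin", {
  net <- mkNet(list(e("S1", "T1"), e("S2", "T2"),
                    e("S3", "a"), e("a", "b"), e("b", "c"), e("c", "T3")))
  res <- allShortestPaths(net, c("S1", "S2", "S3", "T1"),
                          c("T1", "T2", "T3"))
  h <- pathLengthHistogram(res)
  expect_equal(h[["0"]], 1L)  # T1 in both sets
  expect_equal(h[["1"]], 2L)
  expect_equal(h[["4"]], 1L)
})
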