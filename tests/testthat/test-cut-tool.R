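randomFlowNet <- function(seed, n_nodes = NULL, n_edges = NULL) {
  withr::with_seed(seed, {
    n <- n_nodes %||% sample(4:8, 1)
    m <- n_edges %||% sample(4:10, 1)
    net <- randomNetwork(n, m, frac_directed = 0.8, seed = seed)
    ids <- entities(net)$id
    sources <- sample(ids, sample(1:2, 1))
    target <- sample(setdiff(ids, sources), 1)
    list(net = net, sources = sources, target = target)
  })
}

test_that("capacity rule follows rank + 1 and is monotone", {
  expect_equal(capacityFromRank(0), 1)
  expect_equal(capacityFromRank(4), 5)
  expect_equal(capacityFromRank(0:4), c(1, 2, 3, 4, 5))
  expect_true(all(diff(capacityFromRank(0:4)) > 0))
  expect_equal(capacityFromRank(0:4, "unit"), rep(1, 5))
  expect_error(capacityFromRank(5), "0..4")
})

test_that("super-source wiring has effectively infinite capacity", {
  net <- mkNet(list(e("S1", "T"), e("S2", "T", rank = 3),
                    e("S3", "a", rank = 2)))
  aug <- addSuperSource(net, c("S1", "S2", "S3"))
  dummyEdges <- edges(aug$network)
  dummyEdges <- dummyEdges[dummyEdges$source_id == aug$dummy_id, ]
  expect_equal(nrow(dummyEdges), 3)
  # total real capacity = (1+1) + (3+1) + (2+1) = 9 -> dummy capacity 10
  expect_equal(aug$dummy_capacity, 10)
  expect_error(addSuperSource(net, "GHOST"), "GHOST")
})

test_that("min cut equals the exhaustive subset oracle on small instances", {
  checked <- 0
  for (seed in 1:150) {
    inst <- randomFlowNet(seed)
    if (inst$target %in% inst$sources) next
    res <- minCut(inst$net, inst$sources, inst$target)
    oracle <- oracleMinCut(edges(inst$net), entities(inst$net)$id,
                           inst$sources, inst$target)
    expect_equal(res@cutCapacity, oracle$capacity,
                 info = sprintf("seed %d", seed))
    expect_equal(res@flowValue, res@cutCapacity)
    # the reported cut itself disconnects
    v <- verifyCut(inst$net, res@cutEdges, inst$sources, inst$target)
    expect_true(v$valid)
    checked <- checked + 1
  }
  expect_gte(checked, 140)
})

test_that("dummy edges never appear in reported cut-sets", {
  for (seed in 1:100) {
    inst <- randomFlowNet(seed)
    res <- minCut(inst$net, inst$sources, inst$target)
    expect_false(any(res@cutEdges$provenance == "dummy"))
    expect_true(all(res@cutEdges$edge_index <= nEdges(inst$net)))
  }
})

test_that("diamond and chain motifs cut as enumerated by hand", {
  diamond <- mkNet(list(e("S", "A", rank = 0), e("A", "T", rank = 0),
                        e("S", "B", rank = 0), e("B", "T", rank = 0)))
  res <- minCut(diamond, "S", "T")
  expect_equal(res@cutCapacity, 2)
  expect_equal(nrow(res@cutEdges), 2)

  chain <- mkNet(list(e("S", "a", rank = 0), e("a", "b", rank = 2),
                      e("b", "T", rank = 4)))
  res <- minCut(chain, "S", "T")
  # cheapest single severable edge is the rank-0 one (capacity 1)
  expect_equal(res@cutCapacity, 1)
  expect_equal(res@cutEdges$rank, 0L)

  # under unit capacities any single chain edge suffices; capacity 1
  expect_equal(minCut(chain, "S", "T", capacity_rule = "unit")@cutCapacity, 1)
})

test_that("cut is minimal: removing any cut edge re-opens a witness path", {
  for (seed in c(3, 9, 27, 81)) {
    inst <- randomFlowNet(seed, n_nodes = 6, n_edges = 9)
    res <- minCut(inst$net, inst$sources, inst$target)
    if (nrow(res@cutEdges) == 0) next
    for (i in seq_len(nrow(res@cutEdges))) {
      partial <- res@cutEdges[-i, , drop = FALSE]
      v <- verifyCut(inst$net, partial, inst$sources, inst$target)
      expect_false(v$valid)
      expect_true(length(v$witness) >= 2)
      # witness really is a traversable path in the residual network
      keepRows <- setdiff(seq_len(nEdges(inst$net)), partial$edge_index)
      adj <- oracleAdj(edges(inst$net)[keepRows, , drop = FALSE],
                       entities(inst$net)$id)
      for (k in seq_len(length(v$witness) - 1))
        expect_true(v$witness[k + 1] %in% adj[[v$witness[k]]])
    }
  }
})

test_that("verifyCut rejects an empty cut on a connected instance", {
  net <- mkNet(list(e("S", "T")))
  empty <- edges(net)[0, , drop = FALSE]
  v <- verifyCut(net, empty, "S", "T")
  expect_false(v$valid)
  expect_equal(v$witness, c("S", "T"))
})

test_that("unreachable target yields the trivial zero cut", {
  net <- mkNet(list(e("S", "A")), extra_nodes = "T")
  res <- minCut(net, "S", "T")
  expect_equal(res@flowValue, 0)
  expect_equal(res@cutCapacity, 0)
  expect_equal(nrow(res@cutEdges), 0)
})

test_that("undirected edges are one severable object with shared capacity", {
  # S=A undirected binding, A->T directed; both rank 0
  net <- mkNet(list(e("S", "A", type = "binding", directed = FALSE,
                      sign = "unknown", rank = 0),
                    e("A", "T", rank = 0)))
  res <- minCut(net, "S", "T")
  expect_equal(res@cutCapacity, 1)
  expect_equal(nrow(res@cutEdges), 1)
})

test_that("per-target cuts merge and jointly disconnect", {
  # shared bottleneck: S -> B -> {T1, T2}; bottleneck is S->B at rank 0,
  # downstream edges are expensive
  shared <- mkNet(list(e("S", "B", rank = 0), e("B", "T1", rank = 4),
                       e("B", "T2", rank = 4)))
  res <- minCutPerTarget(shared, "S", c("T1", "T2"))
  expect_equal(nrow(res$merged_cut), 1)
  expect_equal(c(res$merged_cut$source_id, res$merged_cut$target_id),
               c("S", "B"))

  # independent branches: merged cut is the union of disjoint cuts
  branches <- mkNet(list(e("S", "a", rank = 0), e("a", "T1", rank = 2),
                         e("S", "b", rank = 0), e("b", "T2", rank = 2)))
  res2 <- minCutPerTarget(branches, "S", c("T1", "T2"))
  expect_equal(nrow(res2$merged_cut), 2)
  for (t in c("T1", "T2")) {
    v <- verifyCut(branches, res2$merged_cut, "S", t)
    expect_true(v$valid)
  }

  # single target: merged cut equals its own cut
  res3 <- minCutPerTarget(branches, "S", "T1")
  expect_equal(res3$merged_cut$edge_index,
               res3$per_target[["T1"]]@cutEdges$edge_index)
})

test_that("two-regulator motif severs both regulatory edges or both nodes", {
  motif <- twoRegulatorMotif()
  res <- minCutPerTarget(motif$network, motif$sources, motif$target)
  cut <- res$per_target[[motif$target]]
  expect_equal(nrow(cut@cutEdges), 2)
  expect_setequal(paste(cut@cutEdges$source_id, cut@cutEdges$target_id),
                  paste(motif$cut_edges$source_id,
                        motif$cut_edges$target_id))
  expect_equal(cut@cutCapacity, 2)

  ko <- minCut(motif$network, motif$sources, motif$target,
               node_knockout = TRUE)
  expect_setequal(ko@cutNodes, motif$regulators)
  expect_equal(nrow(ko@cutEdges), 0)
  v <- verifyCut(motif$network, ko@cutEdges, motif$sources, motif$target,
                 cut_nodes = ko@cutNodes)
  expect_true(v$valid)
})

test_that("planted bottleneck is found at its planted capacity", {
  for (cap in c(1, 3, 5)) {
    fx <- generateNetwork(planted_path_length = NULL,
                          planted_bottleneck_capacity = cap, seed = cap)
    res <- minCut(fx$network, fx$truth$cut_source, fx$truth$cut_target)
    expect_equal(res@cutCapacity, cap)
    expect_equal(paste(res@cutEdges$source_id, res@cutEdges$target_id),
                 paste(fx$truth$cut_edge[1], fx$truth$cut_edge[2]))
  }
})
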