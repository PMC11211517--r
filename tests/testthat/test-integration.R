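writeSourceTSV <- function(df) {
  p <- tempfile(fileext = ".tsv")
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

test_that("loadSourceTable parses rows, honors per-row evidence, reports rejects", {
  tab <- data.frame(source_id = c("A", "B", ""),
                    target_id = c("B", "C", "D"),
                    interaction_type = "binding",
                    evidence_class = c("", "targeted_experimental", ""),
                    stringsAsFactors = FALSE)
  meta <- sourceMeta("resX", "high_throughput")
  got <- loadSourceTable(writeSourceTSV(tab), meta)
  expect_equal(nrow(got$raw), 2)
  expect_equal(nrow(got$rejects), 1)
  # per-row class overrides the meta default; blank falls back
  expect_equal(got$raw$evidence_class,
               c("high_throughput", "targeted_experimental"))
  expect_false(any(got$raw$directed))  # binding is undirected by default

  noCol <- data.frame(source_id = "A", stringsAsFactors = FALSE)
  expect_error(loadSourceTable(writeSourceTSV(noCol), meta), "target_id")
})

test_that("assignRank is the bijective evidence-class map", {
  expect_equal(assignRank("curated_pss"), 0L)
  expect_equal(assignRank("targeted_experimental"), 1L)
  expect_equal(assignRank("high_throughput"), 2L)
  expect_equal(assignRank("literature_or_validated_prediction"), 3L)
  expect_equal(assignRank("in_silico_prediction"), 4L)
  expect_error(assignRank("hearsay"), "hearsay")
})

test_that("integrateSources keeps parallel edges and conserves counts", {
  r1 <- rawRow("A", "B", resource = "res1")
  r2 <- rawRow("A", "B", resource = "res2")
  multi <- integrateSources(list(r1, r2))
  expect_equal(nrow(multi), 2)
  mult <- edgeMultiplicity(multi)
  expect_equal(mult$n[mult$node_a == "a" & mult$node_b == "b"], 2)

  # 25 one-edge sources, disjoint or parallel: total count conserved
  srcs <- lapply(1:25, function(i)
    rawRow(sprintf("G%02d", i %% 7), sprintf("H%02d", i),
           resource = sprintf("res%02d", i)))
  multi25 <- integrateSources(srcs)
  expect_equal(nrow(multi25), 25)
  expect_equal(sum(edgeMultiplicity(multi25)$n), 25)
})

test_that("condense merges per (pair, type) with best-rank precedence and provenance union", {
  multi <- integrateSources(list(
    rawRow("A", "B", class = "targeted_experimental", resource = "res1"),
    rawRow("A", "B", class = "literature_or_validated_prediction",
           resource = "res2"),
    rawRow("A", "B", type = "tf_regulation", directed = TRUE,
           sign = "activation", class = "high_throughput",
           resource = "res3")))
  net <- condenseEdges(multi)
  ed <- edges(net)
  expect_equal(nrow(ed), 2)  # binding collapsed, tf_regulation separate
  bind <- ed[ed$interaction_type == "binding", ]
  expect_equal(bind$rank, 1L)
  expect_equal(bind$provenance, "res1;res2")
  expect_false(bind$directed)
  expect_true(all(entities(net)$stub))
})

test_that("condensed edge count equals the distinct (pair,type) key count", {
  for (seed in 1:20) {
    multi <- withr::with_seed(seed, {
      n <- 200
      integrateSources(data.frame(
        source_id = sample(LETTERS[1:8], n, TRUE),
        target_id = sample(LETTERS[1:8], n, TRUE),
        interaction_type = sample(c("binding", "ptm"), n, TRUE),
        directed = FALSE, sign = "unknown",
        evidence_class = sample(names(evidenceClasses()), n, TRUE),
        resource_name = sample(sprintf("r%d", 1:5), n, TRUE),
        reference = "", stringsAsFactors = FALSE))
    })
    multi <- multi[multi$source_id != multi$target_id, , drop = FALSE]
    net <- condenseEdges(multi)
    # independent key count: unordered pair + type
    key <- paste(pmin(tolower(multi$source_id), tolower(multi$target_id)),
                 pmax(tolower(multi$source_id), tolower(multi$target_id)),
                 multi$interaction_type)
    expect_equal(nEdges(net), length(unique(key)))
    # rank precedence: condensed rank is the minimum of merged raw ranks
    ed <- edges(net)
    for (i in seq_len(nrow(ed))) {
      k <- paste(pmin(tolower(ed$source_id[i]), tolower(ed$target_id[i])),
                 pmax(tolower(ed$source_id[i]), tolower(ed$target_id[i])),
                 ed$interaction_type[i])
      expect_equal(ed$rank[i], min(multi$rank[key == k]))
    }
    # provenance conservation: union of contributing resources per pair
    for (i in seq_len(nrow(ed))) {
      k <- paste(pmin(tolower(ed$source_id[i]), tolower(ed$target_id[i])),
                 pmax(tolower(ed$source_id[i]), tolower(ed$target_id[i])),
                 ed$interaction_type[i])
      expect_setequal(strsplit(ed$provenance[i], ";")[[1]],
                      unique(multi$resource_name[key == k]))
    }
  }
})

test_that("condense is idempotent and resolves conflicts deterministically", {
  multi <- integrateSources(list(
    rawRow("A", "B", type = "tf_regulation", directed = TRUE, sign = "activation",
           class = "high_throughput", resource = "r1"),
    rawRow("A", "B", type = "tf_regulation", directed = TRUE, sign = "inhibition",
           class = "high_throughput", resource = "r2"),
    rawRow("B", "A", type = "tf_regulation", directed = TRUE, sign = "activation",
           class = "targeted_experimental", resource = "r3")))
  net <- condenseEdges(multi)
  ed <- edges(net)
  # mixed-direction duplicates of a directed type stay as two edges
  expect_equal(nrow(ed), 2)
  ab <- ed[tolower(ed$source_id) == "a", ]
  expect_equal(ab$sign, "unknown")  # equal-rank sign conflict
  expect_true(nrow(metadata(net)$condense_report) >= 1)

  # idempotence: re-condensing the condensed table is a fixed point
  again <- stressnet:::.condenseEdgeTable(ed)$edges
  expect_equal(again, ed)

  # direction from the more reliable edge when directed+undirected merge
  m2 <- integrateSources(list(
    rawRow("X", "Y", type = "ptm", directed = TRUE, sign = "activation",
           class = "curated_pss", resource = "r1"),
    rawRow("X", "Y", type = "ptm", directed = FALSE,
           class = "in_silico_prediction", resource = "r2")))
  ed2 <- edges(condenseEdges(m2))
  expect_equal(nrow(ed2), 1)
  expect_true(ed2$directed)
  expect_equal(ed2$rank, 0L)
  expect_equal(ed2$provenance, "r1;r2")
})

test_that("updateIdentifiers renames, removes obsolete, merges collisions", {
  net <- mkNet(list(e("X", "A"), e("X", "B"), e("Y", "B"), e("Q", "R")))
  # rename X -> Z (absent): Z inherits both edges
  up <- updateIdentifiers(net, data.frame(old_id = "X", new_id = "Z"))
  expect_true("Z" %in% entities(up$network)$id)
  expect_equal(sum(edges(up$network)$source_id == "Z"), 2)
  expect_equal(up$report$action, "renamed")

  # obsolete removal drops node and incident edges, reported
  ob <- updateIdentifiers(net, data.frame(old_id = "X", new_id = "OBSOLETE"))
  expect_false("X" %in% entities(ob$network)$id)
  expect_equal(nEdges(ob$network), 2)
  expect_equal(ob$report$n_edges_removed, 2L)

  # rename X -> Y (present): merge; X->B and Y->B dedupe to one edge
  mg <- updateIdentifiers(net, data.frame(old_id = "X", new_id = "Y"))
  expect_false("X" %in% entities(mg$network)$id)
  expect_equal(nEdges(mg$network), 3)  # Y->A, Y->B, Q->R
  expect_equal(mg$report$action, "merged")

  # no orphan edges after any update
  for (res in list(up, ob, mg))
    expect_equal(sum(validateNetwork(res$network)$rule == "orphan_edge"), 0)

  expect_error(updateIdentifiers(net, data.frame(old_id = c("X", "x"),
                                                 new_id = c("Y", "Z"))),
               "unique")
})

test_that("expandClusters performs the Cartesian gene-level expansion", {
  rn <- reactionNetwork(entities = rbind(
    entityRecord("g1"), entityRecord("g2"), entityRecord("g3"),
    entityRecord("h1"), entityRecord("h2")))
  rn <- addCluster(rn, "CLA", c("g1", "g2", "g3"))
  rn <- addCluster(rn, "CLB", c("h1", "h2"))
  rn <- addReaction(rn, "rx1", "activation", data.frame(
    node_id = c("CLA", "CLB"), role = c("ACTIVATES", "PRODUCT"),
    stringsAsFactors = FALSE))
  ed <- expandClusters(rn)
  expect_equal(nrow(ed), 6)  # 3 x 2
  expect_true(all(ed$rank == 0))
  expect_true(all(ed$provenance == "rx1"))

  # brute-force nested-loop oracle over an overlapping-cluster fixture
  rn2 <- addCluster(rn, "CLC", c("g1", "h1"))
  rn2 <- addReaction(rn2, "rx2", "inhibition", data.frame(
    node_id = c("CLC", "g3"), role = c("INHIBITS", "PRODUCT"),
    stringsAsFactors = FALSE))
  got <- expandClusters(rn2)
  members <- list(CLA = c("g1", "g2", "g3"), CLB = c("h1", "h2"),
                  CLC = c("g1", "h1"))
  proj <- edges(bipartiteProjection(rn2))
  want <- list()
  for (i in seq_len(nrow(proj))) {
    ss <- members[[proj$source_id[i]]] %||% proj$source_id[i]
    tt <- members[[proj$target_id[i]]] %||% proj$target_id[i]
    for (a in ss) for (b in tt) want <- c(want, list(c(a, b)))
  }
  expect_setequal(paste(got$source_id, got$target_id),
                  vapply(want, paste, "", collapse = " "))

  # singleton clusters expand to the original edge
  rn3 <- reactionNetwork(entities = rbind(entityRecord("a"),
                                          entityRecord("b")))
  rn3 <- addCluster(rn3, "CS", "a")
  rn3 <- addReaction(rn3, "rx1", "activation", data.frame(
    node_id = c("CS", "b"), role = c("ACTIVATES", "PRODUCT"),
    stringsAsFactors = FALSE))
  one <- expandClusters(rn3)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$source_id, one$target_id), c("a", "b"))
})
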