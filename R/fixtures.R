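## Seeded synthetic fixture generators with planted ground truth. Every
## generator is a pure function of its parameters and seed (the caller's
## RNG state is preserved), and planted structures are built constructively
## -- layered wiring with detour padding, not rejection sampling -- so the
## ground truth (unique shortest path, unique bottleneck cut, hub degrees)
## holds by construction.

.rankFromProbs <- function(n, rank_probs) {
  stopIfNot(abs(sum(rank_probs) - 1) < 1e-8, "rank_probs must sum to 1")
  sample(0:4, n, replace = TRUE, prob = rank_probs)
}

.mkEdge <- function(src, tgt, type = "other", directed = TRUE,
                    sign = "unknown", rank = 2L, prov = "fixture") {
  data.frame(source_id = src, target_id = tgt, interaction_type = type,
             directed = directed, sign = sign, rank = as.integer(rank),
             provenance = prov, stringsAsFactors = FALSE)
}

#' Random knowledge network (no planted structure)
#'
#' Plain seeded random graph used for property tests and oracle-equivalence
#' checks: `n_edges` distinct node pairs, each edge directed with
#' probability `frac_directed`, ranks drawn from `rank_probs`, inhibition
#' sign with probability `frac_inhibition` (activation otherwise).
#'
#' @param n_nodes,n_edges Graph size (`n_edges` is capped at the number of
#'   distinct ordered pairs).
#' @param rank_probs Probabilities over ranks 0--4.
#' @param frac_directed,frac_inhibition Edge attribute probabilities.
#' @param seed Integer seed.
#' @return A [KnowledgeNetwork-class].
#' @export
randomNetwork <- function(n_nodes, n_edges,
                          rank_probs = c(.2, .2, .2, .2, .2),
                          frac_directed = 0.7, frac_inhibition = 0.2,
                          seed = 1L) {
  withSeed(seed, {
    ids <- sprintf("N%03d", seq_len(n_nodes))
    pairs <- expand.grid(s = seq_len(n_nodes), t = seq_len(n_nodes))
    pairs <- pairs[pairs$s != pairs$t, , drop = FALSE]
    take <- pairs[sample(nrow(pairs), min(n_edges, nrow(pairs))), ,
                  drop = FALSE]
    n <- nrow(take)
    directed <- stats::runif(n) < frac_directed
    ed <- .mkEdge(ids[take$s], ids[take$t],
                  type = ifelse(directed, "tf_regulation", "binding"),
                  directed = directed,
                  sign = ifelse(stats::runif(n) < frac_inhibition,
                                "inhibition", "activation"),
                  rank = .rankFromProbs(n, rank_probs))
    ## undirected duplicates of the same unordered pair collapse to one
    ed <- ed[!duplicated(condensedEdgeKey(ed)), , drop = FALSE]
    en <- do.call(rbind, lapply(ids, entityRecord))
    knowledgeNetwork(entities = en, edges = ed)
  })
}

#' Seeded network fixture with planted ground truth
#'
#' Builds a network containing, on demand, (i) a unique planted shortest
#' path of a stated length between a dedicated source/target pair, padded
#' with a longer detour and noise so the planted route stays uniquely
#' shortest; (ii) a unique bottleneck minimum cut of stated capacity; and
#' (iii) a hub with stated in/out degree. Structures occupy disjoint node
#' sets so each ground-truth record is exact.
#'
#' Noise edges around the path component only ever leave path nodes (into a
#' pool of decoy nodes with no edges back), so no shorter source-to-target
#' route can arise -- the constructive layering guarantee.
#'
#' @param n_noise_nodes Decoy nodes added around the planted path.
#' @param rank_probs Rank distribution for noise and path edges.
#' @param planted_path_length Integer >= 1, or NULL to omit.
#' @param planted_bottleneck_capacity Capacity 1--5 of the unique bottleneck
#'   edge (rank = capacity - 1), or NULL to omit.
#' @param planted_hub c(in_degree, out_degree), or NULL to omit.
#' @param seed Integer seed.
#' @return List with `network` and `truth` (planted path node sequence and
#'   endpoints, bottleneck cut edge and capacity, hub id and degrees).
#' @export
generateNetwork <- function(n_noise_nodes = 10,
                            rank_probs = c(.2, .2, .2, .2, .2),
                            planted_path_length = 4,
                            planted_bottleneck_capacity = NULL,
                            planted_hub = NULL, seed = 1L) {
  withSeed(seed, {
    en <- list(); ed <- list()
    truth <- list(seed = seed)
    if (!is.null(planted_path_length)) {
      k <- planted_path_length
      stopIfNot(k >= 1, "planted path length must be >= 1")
      pathIds <- c("PSRC", if (k > 1) sprintf("P%02d", seq_len(k - 1)),
                   "PTGT")
      en <- c(en, lapply(pathIds, entityRecord))
      ed <- c(ed, lapply(seq_len(k), function(i)
        .mkEdge(pathIds[i], pathIds[i + 1], type = "tf_regulation",
                sign = "activation", rank = .rankFromProbs(1, rank_probs),
                prov = "planted_path")))
      ## longer detour: length k + 2 via dedicated nodes
      det <- sprintf("D%02d", seq_len(k + 1))
      en <- c(en, lapply(det, entityRecord))
      chain <- c("PSRC", det, "PTGT")
      ed <- c(ed, lapply(seq_len(length(chain) - 1), function(i)
        .mkEdge(chain[i], chain[i + 1], type = "tf_regulation",
                sign = "activation", rank = .rankFromProbs(1, rank_probs),
                prov = "detour")))
      ## noise: decoy nodes reachable FROM the path, never feeding back
      if (n_noise_nodes > 0) {
        noise <- sprintf("X%03d", seq_len(n_noise_nodes))
        en <- c(en, lapply(noise, entityRecord))
        for (x in noise) {
          fromNode <- sample(c(pathIds, noise[noise < x]), 1)
          ed <- c(ed, list(.mkEdge(fromNode, x, type = "tf_regulation",
                                   sign = "activation",
                                   rank = .rankFromProbs(1, rank_probs),
                                   prov = "noise")))
        }
      }
      truth$path <- pathIds
      truth$path_source <- "PSRC"; truth$path_target <- "PTGT"
      truth$path_length <- k
    }
    if (!is.null(planted_bottleneck_capacity)) {
      cap <- planted_bottleneck_capacity
      stopIfNot(cap >= 1 && cap <= 5, "bottleneck capacity must be 1..5")
      cut <- c("CSRC", "CA1", "CA2", "CA3", "CB", "CTGT")
      en <- c(en, lapply(cut, entityRecord))
      for (a in c("CA1", "CA2", "CA3")) {
        ed <- c(ed, list(.mkEdge("CSRC", a, rank = 4L, sign = "activation",
                                 prov = "cut_fixture"),
                         .mkEdge(a, "CB", rank = 4L, sign = "activation",
                                 prov = "cut_fixture")))
      }
      ed <- c(ed, list(.mkEdge("CB", "CTGT", rank = cap - 1L,
                               sign = "activation", prov = "bottleneck")))
      truth$cut_source <- "CSRC"; truth$cut_target <- "CTGT"
      truth$cut_capacity <- cap
      truth$cut_edge <- c("CB", "CTGT")
    }
    if (!is.null(planted_hub)) {
      din <- planted_hub[1]; dout <- planted_hub[2]
      en <- c(en, list(entityRecord("HUB")))
      feeders <- sprintf("HF%02d", seq_len(din))
      outs <- sprintf("HT%02d", seq_len(dout))
      en <- c(en, lapply(c(feeders, outs), entityRecord))
      ed <- c(ed, lapply(feeders, function(f)
        .mkEdge(f, "HUB", sign = "activation", rank = 1L, prov = "hub")))
      ed <- c(ed, lapply(outs, function(o)
        .mkEdge("HUB", o, sign = "activation", rank = 1L, prov = "hub")))
      truth$hub <- "HUB"
      truth$hub_in <- din; truth$hub_out <- dout
      truth$hub_sources <- feeders; truth$hub_targets <- outs
    }
    net <- knowledgeNetwork(entities = do.call(rbind, en),
                            edges = do.call(rbind, ed))
    list(network = net, truth = truth)
  })
}

#' Layered hormone-cascade reaction fixture
#'
#' A compact curated-style reaction network: a foreign stressor is perceived
#' by a receptor, relayed through a kinase functional cluster (used by
#' several reactions), onto a transcription factor that switches on a
#' responsive gene; a phosphatase-like inhibitor contributes an inhibition
#' crosslink onto the kinase step. Exercises projection, path queries and
#' Boolean export: with the stressor on and the inhibitor off, the
#' responsive gene is on at the synchronous fixed point.
#'
#' @param seed Unused (the fixture is fully deterministic); kept so all
#'   generators share a signature.
#' @return A [ReactionNetwork-class].
#' @export
generateReactionFixture <- function(seed = 1L) {
  en <- rbind(
    entityRecord("STRESSOR1", "oxidative stress", entity_type = "foreign",
                 origin = "foreign"),
    entityRecord("REC1", "receptor kinase", entity_type = "protein",
                 species = "ath"),
    entityRecord("MPK3", entity_type = "gene", species = "ath"),
    entityRecord("MPK6", entity_type = "gene", species = "ath"),
    entityRecord("INH1", "phosphatase", entity_type = "protein",
                 species = "ath"),
    entityRecord("TF1", "stress TF", entity_type = "protein",
                 species = "ath"),
    entityRecord("GENE1", "responsive gene", entity_type = "gene",
                 species = "ath"))
  rn <- reactionNetwork(entities = en)
  rn <- addCluster(rn, "CL.MPK", c("MPK3", "MPK6"))
  pp <- function(...) {
    x <- list(...)
    data.frame(node_id = vapply(x, `[`, "", 1),
               role = vapply(x, `[`, "", 2),
               location = vapply(x, `[`, "", 3),
               form = vapply(x, `[`, "", 4), stringsAsFactors = FALSE)
  }
  rn <- addReaction(rn, "rx001", "activation",
    pp(c("STRESSOR1", "ACTIVATES", "apoplast", "unspecified"),
       c("REC1", "PRODUCT", "plasma membrane", "protein")),
    provenance = "doi:fixture/1")
  rn <- addReaction(rn, "rx002", "activation",
    pp(c("REC1", "ACTIVATES", "plasma membrane", "protein"),
       c("CL.MPK", "PRODUCT", "cytoplasm", "protein")),
    provenance = "doi:fixture/2")
  rn <- addReaction(rn, "rx003", "inhibition",
    pp(c("INH1", "INHIBITS", "cytoplasm", "protein"),
       c("CL.MPK", "PRODUCT", "cytoplasm", "protein")),
    provenance = "doi:fixture/3")
  rn <- addReaction(rn, "rx004", "activation",
    pp(c("CL.MPK", "ACTIVATES", "cytoplasm", "protein"),
       c("TF1", "PRODUCT", "nucleus", "protein")),
    provenance = "doi:fixture/4")
  rn <- addReaction(rn, "rx005", "transcription",
    pp(c("TF1", "ACTIVATES", "nucleus", "protein"),
       c("GENE1", "PRODUCT", "nucleus", "gene")),
    provenance = "doi:fixture/5")
  rn
}

#' Two-regulator knockout motif
#'
#' The toy intervention motif: four upstream sources each feed two
#' regulators, and both regulators (alone) control one downstream target
#' through manually curated (rank 0) regulatory edges. Disconnecting the
#' target requires severing exactly the two incoming regulatory edges --
#' or, in node-knockout mode, removing both regulator nodes.
#'
#' @return List with `network`, `sources`, `target`, `regulators` and
#'   `cut_edges` (the ground-truth minimum cut).
#' @export
twoRegulatorMotif <- function() {
  srcs <- sprintf("S%d", 1:4)
  en <- do.call(rbind, lapply(c(srcs, "REG1", "REG2", "TGT1"), entityRecord))
  ed <- list()
  for (s in srcs) for (r in c("REG1", "REG2"))
    ed <- c(ed, list(.mkEdge(s, r, type = "tf_regulation",
                             sign = "activation", rank = 2L, prov = "motif")))
  ed <- c(ed, list(
    .mkEdge("REG1", "TGT1", type = "tf_regulation", sign = "activation",
            rank = 0L, prov = "motif"),
    .mkEdge("REG2", "TGT1", type = "tf_regulation", sign = "activation",
            rank = 0L, prov = "motif")))
  net <- knowledgeNetwork(entities = en, edges = do.call(rbind, ed))
  list(network = net, sources = srcs, target = "TGT1",
       regulators = c("REG1", "REG2"),
       cut_edges = data.frame(source_id = c("REG1", "REG2"),
                              target_id = c("TGT1", "TGT1"),
                              stringsAsFactors = FALSE))
}

#' Synthetic two-contrast omics table with planted responders
#'
#' Emulates the two-contrast blocker design at two timepoints: planted
#' responders get a primary-contrast log2 fold change of about
#' `effect_size` (alternating sign) and a conditional-contrast fold change
#' of about 0, with significant q-values only where planted, so the
#' contrast difference is at least 1 by construction at the default effect
#' size. Non-responders are either null in both contrasts or identically
#' regulated in both (and thus removed by the subtraction rule). A fraction
#' of rows fails the replicate filter via low detection counts.
#'
#' @param n_groups Total protein groups.
#' @param n_responders Planted responders.
#' @param effect_size Primary-contrast |log2FC| for planted rows; default 2.
#' @param noise_sd Gaussian noise added to every fold change; default 0.
#' @param missingness Fraction of rows given detection counts below the
#'   3-of-5 rule; default 0.
#' @param seed Integer seed.
#' @return List with `table`, `truth` (responder group ids) and `pair`
#'   (the matching [contrastPair()]).
#' @export
generateOmicsTable <- function(n_groups = 40, n_responders = 8,
                               effect_size = 2, noise_sd = 0,
                               missingness = 0, seed = 1L) {
  withSeed(seed, {
    stopIfNot(n_responders <= n_groups, "more responders than groups")
    gid <- sprintf("G%03d", seq_len(n_groups))
    members <- sprintf("AT%dG%05d", sample(1:5, n_groups, TRUE),
                       sample(10000:99999, n_groups))
    isResp <- seq_len(n_groups) <= n_responders
    sgn <- rep(c(1, -1), length.out = n_groups)
    ## non-responders alternate between null-null and same-direction pairs
    coReg <- !isResp & (seq_len(n_groups) %% 2 == 0)
    labels <- c("h2o2_10", "h2o2_30", "lah2o2_10", "lah2o2_30")
    tab <- data.frame(group_id = gid, member_ids = members,
                      stringsAsFactors = FALSE)
    noise <- function(n) stats::rnorm(n, 0, noise_sd)
    for (tp in c("10", "30")) {
      Lp <- ifelse(isResp | coReg, sgn * effect_size, 0) + noise(n_groups)
      qp <- ifelse(isResp | coReg, 0.001, 0.8)
      Lc <- ifelse(coReg, sgn * effect_size, 0) + noise(n_groups)
      qc <- ifelse(coReg, 0.001, 0.8)
      tab[[paste0("L_h2o2_", tp)]] <- Lp
      tab[[paste0("q_h2o2_", tp)]] <- qp
      tab[[paste0("L_lah2o2_", tp)]] <- Lc
      tab[[paste0("q_lah2o2_", tp)]] <- qc
    }
    lowDetect <- stats::runif(n_groups) < missingness
    tab$detected_mock <- ifelse(lowDetect, 1L, 5L)
    tab$detected_h2o2 <- ifelse(lowDetect, 2L, sample(3:5, n_groups, TRUE))
    tab$detected_la <- ifelse(lowDetect, 0L, sample(3:5, n_groups, TRUE))
    tab$detected_lah2o2 <- ifelse(lowDetect, 2L,
                                  sample(3:5, n_groups, TRUE))
    pair <- contrastPair(primary = c("h2o2_10", "h2o2_30"),
                         conditional = c("lah2o2_10", "lah2o2_30"))
    list(table = tab, truth = gid[isResp & !lowDetect], pair = pair)
  })
}
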