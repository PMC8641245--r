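# a hand-built CellNetworkSet with known per-cell edges, for downstream ops
stubNet <- function(edgesByCell, allPairs = NULL) {
    cells <- names(edgesByCell)
    if (is.null(allPairs))
        allPairs <- unique(do.call(rbind, edgesByCell))
    key <- paste(allPairs$mirna, allPairs$mrna)
    z <- matrix(-10, nrow(allPairs), length(cells),
                dimnames = list(NULL, cells))
    for (cc in cells) {
        ek <- paste(edgesByCell[[cc]]$mirna, edgesByCell[[cc]]$mrna)
        z[key %in% ek, cc] <- 10
    }
    new("CellNetworkSet", pairs = allPairs, realCellIds = cells,
        zFinal = z, pFinal = stats::pnorm(z, lower.tail = FALSE),
        perRunZ = array(numeric(0), c(0L, 0L, 0L)), alpha = 0.01)
}
edf <- function(mirna, mrna) data.frame(mirna = mirna, mrna = mrna,
                                        stringsAsFactors = FALSE)

test_that("hub selection uses ceil(fraction * active) with lexicographic ties", {
    e <- edf(c("A", "A", "A", "B", "C", "D", "E"),
             paste0("g", 1:7))
    expect_identical(hubMirnas(e, 0.2), "A")        # 5 active -> 1 hub
    e2 <- edf(c("A", "A", "A", "B", "B", "B", "C"), paste0("g", 1:7))
    # degrees A=3, B=3, C=1; ceil(0.34 * 3) = 2; tie resolved by id
    expect_identical(hubMirnas(e2, 0.34), c("A", "B"))
    expect_warning(h0 <- hubMirnas(edf(character(0), character(0))), "empty")
    expect_identical(h0, character(0))
})

test_that("conserved and rewired items are split by presence counts", {
    cells <- paste0("c", 1:5)
    common <- edf("miR-a", "g1")
    once <- edf("miR-b", "g9")
    mid <- edf("miR-c", "g5")
    byCell <- list(
        c1 = rbind(common, once, mid), c2 = rbind(common, mid),
        c3 = rbind(common, mid), c4 = common, c5 = common)
    net <- stubNet(byCell)
    cr <- conservedAndRewired(net, conservedMinCells = 5)
    expect_identical(pairFrame(cr$conservedEdges), common)
    expect_identical(pairFrame(cr$rewiredEdges), once)
    # presence in 3 of 5 cells: neither conserved nor rewired, but counted
    expect_identical(unname(cr$edgeCounts[["miR-c\rg5"]]), 3L)
    expect_length(intersect(names(cr$edgeCounts)[cr$edgeCounts >= 5],
                            names(cr$edgeCounts)[cr$edgeCounts == 1]), 0)
    expect_error(conservedAndRewired(net, conservedMinCells = 9), "exceed")
})

test_that("overlap similarity follows |intersection| / min size", {
    expect_identical(pairwiseSimilarity(letters[1:4], letters[1:4]), 1)
    expect_identical(pairwiseSimilarity(letters[1:3], letters[10:12]), 0)
    expect_identical(pairwiseSimilarity(c("a", "b", "c", "d"),
                                        c("c", "d", "x", "y", "z", "w")),
                     0.5)
    expect_warning(s <- pairwiseSimilarity(character(0), "a"), "empty")
    expect_identical(s, 0)
})

test_that("similarity matrices are symmetric with unit diagonal", {
    e1 <- edf(c("A", "A", "B"), c("g1", "g2", "g3"))
    e2 <- edf(c("A", "B"), c("g1", "g3"))
    e3 <- edf("C", "g9")
    net <- stubNet(list(c1 = e1, c2 = e2, c3 = e3))
    sim <- similarityMatrix(net, "interaction")
    expect_identical(diag(sim), c(c1 = 1, c2 = 1, c3 = 1))
    expect_identical(sim, t(sim))
    expect_identical(sim["c1", "c2"], 1)       # e2 is a subset of e1
    expect_identical(sim["c1", "c3"], 0)
    # identical networks give an all-ones matrix
    same <- stubNet(list(a = e1, b = e1, c = e1))
    expect_true(all(similarityMatrix(same, "interaction") == 1))
})

test_that("expression distances min-max normalize over off-diagonal values", {
    d <- matched(matrix(c(0, 3, 4), 1), matrix(c(0, 0, 0), 1))
    dm <- expressionDistanceMatrix(d)
    expect_identical(unname(dm$raw["c1", "c2"]), 3)
    expect_equal(unname(dm$normalized[upper.tri(dm$normalized)]),
                 c(2 / 3, 1, 0))
    expect_true(all(dm$normalized >= 0 & dm$normalized <= 1))
    # duplicated cells are the off-diagonal minimum -> normalized 0
    d2 <- matched(matrix(c(1, 1, 4), 1), matrix(c(2, 2, 7), 1))
    expect_identical(unname(expressionDistanceMatrix(d2)$normalized[1, 2]), 0)
    # two cells: the single off-diagonal distance has no range
    dflat <- matched(matrix(c(1, 2), 1), matrix(c(5, 6), 1))
    expect_error(expressionDistanceMatrix(dflat), "zero distance range")
})

test_that("hierarchical clustering recovers planted blocks", {
    ids <- paste0("c", 1:6)
    sim <- matrix(0.1, 6, 6, dimnames = list(ids, ids))
    sim[1:3, 1:3] <- 0.9; sim[4:6, 4:6] <- 0.9; diag(sim) <- 1
    cl <- hierarchicalClustering(sim, nClusters = 2)
    expect_identical(unname(cl$labels[1:3]), rep(cl$labels[["c1"]], 3))
    expect_identical(unname(cl$labels[4:6]), rep(cl$labels[["c4"]], 3))
    expect_false(cl$labels[["c1"]] == cl$labels[["c4"]])
    # one cluster per cell at the other extreme
    expect_identical(sort(unname(hierarchicalClustering(sim, 6)$labels)),
                     1:6)
    expect_error(hierarchicalClustering(sim, 0), "between 1")
    # three planted blocks with a wide margin
    sim3 <- matrix(0.1, 9, 9, dimnames = list(paste0("x", 1:9),
                                              paste0("x", 1:9)))
    for (b in list(1:3, 4:6, 7:9)) sim3[b, b] <- 0.9
    diag(sim3) <- 1
    l3 <- hierarchicalClustering(sim3, 3)$labels
    expect_identical(length(unique(l3[1:3])), 1L)
    expect_identical(length(unique(l3[4:6])), 1L)
    expect_identical(length(unique(l3[7:9])), 1L)
    expect_identical(length(unique(l3)), 3L)
})

test_that("crosstalk edges require similarity strictly above the median", {
    ids <- paste0("c", 1:4)
    sim <- diag(4); dimnames(sim) <- list(ids, ids)
    vals <- c(0.9, 0.8, 0.5, 0.4, 0.3, 0.2)
    sim[upper.tri(sim)] <- vals
    sim[lower.tri(sim)] <- t(sim)[lower.tri(sim)]
    ct <- crosstalkNetwork(sim)
    expect_identical(ct$threshold, 0.45)
    expect_identical(nrow(ct$edges), 3L)
    expect_true(all(ct$edges$similarity > 0.45))
    # all-equal similarities: nothing exceeds the median strictly
    flat <- matrix(0.5, 4, 4, dimnames = list(ids, ids)); diag(flat) <- 1
    expect_identical(nrow(crosstalkNetwork(flat)$edges), 0L)
})

test_that("hub cells follow the same top-fraction rule as hub miRNAs", {
    star <- list(cells = paste0("c", 1:5),
                 edges = data.frame(i = "c3", j = paste0("c", c(1, 2, 4, 5))))
    expect_identical(hubCells(star, 0.2), "c3")
    lonely <- list(cells = paste0("c", 1:4),
                   edges = data.frame(i = character(0), j = character(0)))
    expect_warning(h <- hubCells(lonely, 0.2), "edgeless")
    expect_identical(h, character(0))
    # 19 connected cells -> ceil(3.8) = 4 hubs
    ring <- list(cells = paste0("c", 1:19),
                 edges = data.frame(i = paste0("c", 1:19),
                                    j = paste0("c", c(2:19, 1))))
    expect_identical(length(hubCells(ring, 0.2)), 4L)
})

test_that("Markov clustering separates cliques and filters small modules", {
    tri <- function(ids) t(combn(ids, 2))
    two <- rbind(tri(paste0("a", 1:3)), tri(paste0("b", 1:3)))
    ct <- list(cells = c(paste0("a", 1:3), paste0("b", 1:3)),
               edges = data.frame(i = two[, 1], j = two[, 2]))
    res <- mclModules(ct, inflation = 2, minSize = 3)
    expect_true(res$converged)
    expect_identical(res$modules,
                     list(paste0("a", 1:3), paste0("b", 1:3)))
    # a triangle plus an isolated edge: the pair is filtered out
    ct2 <- list(cells = c(paste0("a", 1:3), "x", "y"),
                edges = data.frame(i = c(tri(paste0("a", 1:3))[, 1], "x"),
                                   j = c(tri(paste0("a", 1:3))[, 2], "y")))
    expect_identical(mclModules(ct2, 2, 3)$modules, list(paste0("a", 1:3)))
    expect_error(mclModules(ct, inflation = 1), "inflation")
})

test_that("Markov clustering matches an independent reference on toys", {
    clique <- function(ids) t(combn(ids, 2))
    ids <- c(paste0("p", 1:5), paste0("q", 1:5))
    edges <- rbind(clique(ids[1:5]), clique(ids[6:10]),
                   c("p1", "q1"))                     # bridged two-clique
    adj <- matrix(0, 10, 10, dimnames = list(ids, ids))
    adj[edges] <- 1; adj <- adj + t(adj); adj[adj > 1] <- 1
    got <- mclModules(list(cells = ids,
                           edges = data.frame(i = edges[, 1],
                                              j = edges[, 2])),
                      inflation = 2, minSize = 1)$modules
    ref <- oracleMcl(adj, inflation = 2)
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(ref, paste, character(1), collapse = ","))
})

test_that("the KS distance spans [0, 1] with the expected extremes", {
    same <- ksTwoSample(c(1, 5, 9, 2), c(1, 5, 9, 2))
    expect_identical(same$D, 0)
    expect_identical(same$p, 1)
    apart <- ksTwoSample(c(1, 2, 3), c(4, 5, 6))
    expect_identical(apart$D, 1)
    x <- rnorm(40)
    expect_identical(ksTwoSample(x, sample(x))$D, 0)
    expect_error(ksTwoSample(numeric(0), 1), "nonempty")
})

test_that("family profiles count per-run calls and reference percentages", {
    set.seed(31)
    fx <- generateSynthetic(syntheticSpec(nMirnas = 8, nMrnas = 30,
                                          nCells = 10, nTruePairs = 5,
                                          nPriorPairs = 60, dropout = 0,
                                          seed = 13))
    ens <- bootstrapEnsemble(fx$data, q = 3, B = 3, seed = 2)
    net <- buildCellNetworks(ens, fx$prior, keepPerRun = TRUE)
    family <- unique(fx$truth@mirna)
    prof <- familyRegulationProfile(net, family, validated = fx$truth)
    expect_identical(nrow(prof), 10L * 3L)
    # recompute one (cell, run) entry from the retained per-run z directly
    fIdx <- which(net@pairs$mirna %in% family)
    p11 <- stats::pnorm(net@perRunZ[fIdx, 1, 1], lower.tail = FALSE)
    expect_identical(prof$nTargets[prof$cell == realCells(net)[1] &
                                   prof$run == 1], sum(p11 < 0.01))
    ok <- !is.na(prof$pctValidated)
    expect_true(all(prof$pctValidated[ok] >= 0 & prof$pctValidated[ok] <= 100))
    # per-run retention is required, absent families warn
    netNo <- buildCellNetworks(ens, fx$prior, keepPerRun = FALSE)
    expect_error(familyRegulationProfile(netNo, family), "keepPerRun")
    expect_warning(empty <- familyRegulationProfile(net, "miR-none"),
                   "no family member")
    expect_identical(nrow(empty), 0L)
})

test_that("reference evaluation reports validated and random percentages", {
    e1 <- edf(c("A", "B"), c("g1", "g2"))
    e2 <- edf("A", "g3")
    prior <- PairSet(c("A", "B", "A", "B"), c("g1", "g2", "g3", "g4"))
    net <- stubNet(list(c1 = e1, c2 = e2, c3 = edf(character(0),
                                                   character(0))),
                   allPairs = pairFrame(prior))
    full <- evaluateAgainstReference(net, prior, nRandom = 5, seed = 1)
    expect_equal(full$validatedPct[1:2], c(100, 100))
    expect_equal(full$randomPct[1:2], c(100, 100))   # everything validated
    expect_true(is.na(full$validatedPct[3]))         # no edges -> missing
    none <- evaluateAgainstReference(net, PairSet("Z", "z"), nRandom = 5,
                                     seed = 1)
    expect_equal(none$validatedPct[1:2], c(0, 0))
    partial <- evaluateAgainstReference(net, PairSet("A", "g1"),
                                        nRandom = 200, seed = 3)
    expect_equal(partial$validatedPct[1], 50)
    # random baseline: drawing 2 of 4 prior pairs, 1 validated -> mean 25%
    expect_equal(partial$randomPct[1], 25, tolerance = 0.25)
})
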