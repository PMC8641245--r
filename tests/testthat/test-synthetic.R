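test_that("generation is deterministic and the truth sits inside the prior", {
    a <- generateSynthetic(syntheticSpec(seed = 9))
    b <- generateSynthetic(syntheticSpec(seed = 9))
    expect_identical(exprValues(mirMatrix(a$data)),
                     exprValues(mirMatrix(b$data)))
    expect_identical(pairFrame(a$prior), pairFrame(b$prior))
    expect_false(identical(
        exprValues(mirMatrix(generateSynthetic(syntheticSpec(seed = 10))$data)),
        exprValues(mirMatrix(a$data))))
    expect_true(all(paste(a$truth@mirna, a$truth@mrna) %in%
                    paste(a$prior@mirna, a$prior@mrna)))
    expect_identical(length(a$prior), 2000L)
})

test_that("the packaged fixture mirrors the study dimensions", {
    fx <- fixtureSmall()
    expect_identical(length(cellIds(fx$data)), 19L)
    expect_identical(length(fx$truth), 20L)
    expect_lte(nrow(exprValues(mirMatrix(fx$data))), 50L)
    expect_lte(nrow(exprValues(mrnaMatrix(fx$data))), 300L)
    expect_true(isTransformed(fx$data))
    aug <- interpolatePseudoCells(fx$data, q = 5, seed = 1)
    expect_identical(length(cellIds(aug)), 109L)
})

test_that("dropout censoring controls the zero fraction", {
    clean <- generateSynthetic(syntheticSpec(dropout = 0, seed = 4))
    noisy <- generateSynthetic(syntheticSpec(dropout = 0.3, seed = 4))
    zf <- function(x) mean(exprValues(mirMatrix(x$data)) == 0)
    expect_lt(zf(clean), 0.02)            # only truncation zeros remain
    expect_gt(zf(noisy), 0.25)
    expect_lt(zf(noisy), 0.40)
    # censoring removes the lowest values of each gene, never high ones
    mir0 <- exprValues(mirMatrix(clean$data))
    mir3 <- exprValues(mirMatrix(noisy$data))
    shared <- intersect(rownames(mir0), rownames(mir3))
    g <- shared[1]
    dropped <- mir3[g, ] == 0 & mir0[g, ] > 0
    if (any(dropped) && any(!dropped))
        expect_lt(max(mir0[g, dropped]), min(mir0[g, mir3[g, ] > 0]) + 1e-9)
})

test_that("full coupling without dropout beats every decoy correlation", {
    fx <- generateSynthetic(syntheticSpec(nCells = 60, coupling = 1,
                                          dropout = 0, seed = 6))
    mir <- exprValues(mirMatrix(fx$data))
    mrna <- exprValues(mrnaMatrix(fx$data))
    corOf <- function(ps) {
        keep <- ps@mirna %in% rownames(mir) & ps@mrna %in% rownames(mrna)
        vapply(which(keep), function(i)
            abs(stats::cor(mir[ps@mirna[i], ], mrna[ps@mrna[i], ])),
            numeric(1))
    }
    trueCor <- corOf(fx$truth)
    dk <- strsplit(setdiff(paste(fx$prior@mirna, fx$prior@mrna),
                           paste(fx$truth@mirna, fx$truth@mrna)), " ")
    decoyCor <- corOf(PairSet(vapply(dk, `[[`, character(1), 1),
                              vapply(dk, `[[`, character(1), 2)))
    expect_gt(min(trueCor), max(decoyCor))
})

test_that("planted cell blocks partition the cells", {
    fx <- generateSynthetic(syntheticSpec(nBlocks = 3, seed = 2))
    expect_identical(sort(unique(unname(fx$blockLabels))), 1:3)
    expect_identical(names(fx$blockLabels), cellIds(fx$data))
})

test_that("infeasible specifications are rejected", {
    expect_error(syntheticSpec(nMirnas = 2, nMrnas = 2, nTruePairs = 5),
                 "more true pairs")
    expect_error(syntheticSpec(nPriorPairs = 10, nTruePairs = 20),
                 "nPriorPairs")
    expect_error(syntheticSpec(coupling = 1.2), "coupling")
    expect_error(syntheticSpec(dropout = 1), "dropout")
    expect_error(syntheticSpec(nBlocks = 40), "nBlocks")
})
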