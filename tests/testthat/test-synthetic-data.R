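test_that("generated interaction networks are simple, connected-backbone graphs", {
    g <- generatePPI(2, meanDegree = 1, seed = 1)
    expect_equal(igraph::gsize(g), 1)
    expect_setequal(igraph::V(g)$name, c("g0001", "g0002"))

    for (s in 1:3) {
        g <- generatePPI(120, meanDegree = 5, seed = s,
                         moduleGenes = sprintf("g%04d", 1:30))
        expect_false(igraph::any_loop(g))
        expect_false(igraph::any_multiple(g))
        expect_equal(igraph::count_components(g), 1)
    }

    g <- generatePPI(500, meanDegree = 4, seed = 1)
    realized <- 2 * igraph::gsize(g) / igraph::vcount(g)
    expect_lt(abs(realized - 4) / 4, 0.25)

    expect_error(generatePPI(1, 1), "invalid sizes")
    expect_error(generatePPI(10, 20), "invalid sizes")
})

test_that("identical configurations reproduce bit-identical worlds", {
    cfg <- syntheticConfig(nGenes = 150, nDatasets = 2, nDrugs = 15,
                           diseaseModuleSize = 30, seed = 7)
    w1 <- generateWorld(cfg)
    w2 <- generateWorld(cfg)
    expect_identical(exprsMatrix(w1@datasets[[1]]),
                     exprsMatrix(w2@datasets[[1]]))
    expect_identical(zScores(w1@signatures), zScores(w2@signatures))
    expect_identical(w1@targets, w2@targets)
    expect_identical(w1@diseaseGenes, w2@diseaseGenes)
    expect_identical(igraph::as_edgelist(w1@graph),
                     igraph::as_edgelist(w2@graph))

    w3 <- generateWorld(syntheticConfig(nGenes = 150, nDatasets = 2,
                                        nDrugs = 15,
                                        diseaseModuleSize = 30, seed = 8))
    expect_false(identical(zScores(w1@signatures), zScores(w3@signatures)))
})

test_that("expression datasets carry the planted module structure", {
    cfg <- syntheticConfig(nGenes = 200, nDatasets = 2, nCase = 6,
                           nControl = 6, diseaseModuleSize = 40,
                           effectSize = 3, noiseSd = 0.5, nDrugs = 10,
                           seed = 3)
    w <- generateWorld(cfg)
    expect_length(w@datasets, 2)
    ds <- w@datasets[[1]]
    expect_equal(ncol(exprsMatrix(ds)), 12)
    expect_equal(sum(sampleGroups(ds) == "case"), 6)
    # planted genes shift case means in the planted direction
    m <- exprsMatrix(ds)
    grp <- sampleGroups(ds)
    obs <- rowMeans(m[, grp == "case"]) - rowMeans(m[, grp == "control"])
    planted <- w@foldChanges[w@foldChanges != 0]
    expect_gt(cor(obs[names(planted)], planted), 0.95)
    expect_lt(mean(abs(obs[setdiff(names(obs), names(planted))])), 0.5)
    # sign of the shift is shared across datasets
    m2 <- exprsMatrix(w@datasets[[2]])
    obs2 <- rowMeans(m2[, grp == "case"]) - rowMeans(m2[, grp == "control"])
    expect_true(all(sign(obs[names(planted)]) == sign(obs2[names(planted)])))
})

test_that("counts mode produces integer data that the DE stage handles", {
    cfg <- syntheticConfig(nGenes = 120, nDatasets = 1, nCase = 5,
                           nControl = 5, diseaseModuleSize = 24,
                           nDrugs = 5, assayKind = "counts", seed = 5)
    w <- generateWorld(cfg)
    m <- exprsMatrix(w@datasets[[1]])
    expect_true(all(m == round(m)) && all(m >= 0))
    tab <- differentialTest(w@datasets[[1]])
    planted <- names(w@foldChanges)[w@foldChanges != 0]
    expect_gt(mean(tab$significant[tab$gene %in% planted]), 0.8)
})

test_that("planted reversal drugs anti-correlate with fold changes, decoys do not", {
    cfg <- syntheticConfig(nGenes = 1000, nDatasets = 1, nDrugs = 60,
                           diseaseModuleSize = 200, nTherapeutic = 3,
                           nCellLines = 1, reversalNoise = 0.05, seed = 9)
    w <- generateWorld(cfg)
    z <- zScores(w@signatures)
    fc <- w@foldChanges
    mod <- names(fc)[fc != 0]
    ther <- signatureDrugs(w@signatures) %in% w@therapeuticDrugs
    rhoT <- apply(z[mod, ther, drop = FALSE], 2,
                  function(col) cor(col, fc[mod], method = "spearman"))
    expect_true(all(rhoT < -0.9))
    rhoD <- apply(z[, !ther, drop = FALSE], 2,
                  function(col) cor(col, fc, method = "spearman"))
    expect_lt(mean(abs(rhoD)), 0.2)
})

test_that("target maps respect the in-module fraction", {
    cfg <- syntheticConfig(nGenes = 200, nDatasets = 1, nDrugs = 20,
                           diseaseModuleSize = 50, nTherapeutic = 4,
                           targetsPerDrug = 4, fracTargetsInModule = 1,
                           seed = 2)
    w <- generateWorld(cfg)
    for (dr in w@therapeuticDrugs)
        expect_true(all(w@targets[[dr]] %in% w@diseaseGenes))
    expect_true(all(lengths(w@targets) == 4))
})

test_that("reference sets export the truth and round-trip through GMT", {
    w <- smallWorld()
    expect_identical(w@knownDrugs, w@therapeuticDrugs)  # nKnown = nTherapeutic
    expect_true("disease_module" %in% names(w@pathways))
    expect_identical(w@pathways$disease_module, w@diseaseGenes)

    f <- tempfile(fileext = ".gmt")
    writeGmt(w@pathways, f)
    back <- readGmt(f)
    expect_identical(lapply(back, identity), w@pathways[names(back)])
    expect_setequal(names(back), names(w@pathways))

    # padded known-drug set keeps every planted drug
    cfg <- syntheticConfig(nGenes = 150, nDatasets = 1, nDrugs = 30,
                           diseaseModuleSize = 30, nTherapeutic = 2,
                           nKnownDrugs = 6, seed = 4)
    w2 <- generateWorld(cfg)
    expect_length(w2@knownDrugs, 6)
    expect_true(all(w2@therapeuticDrugs %in% w2@knownDrugs))
})

test_that("invalid configurations are rejected", {
    expect_error(syntheticConfig(nTherapeutic = 10, nDrugs = 5),
                 "nTherapeutic")
    expect_error(syntheticConfig(diseaseModuleSize = 50, nGenes = 20),
                 "diseaseModuleSize")
    expect_error(syntheticConfig(fracTargetsInModule = 1.5),
                 "fracTargetsInModule")
    expect_error(syntheticConfig(nGenes = 0), "strictly positive")
})
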