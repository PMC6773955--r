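test_that("KS scores match hand-evaluated cases", {
    ranks10 <- setNames(1:10, paste0("g", 1:10))
    r1 <- ksScore("g1", ranks10)
    expect_equal(r1$a, 0.9)
    expect_equal(r1$b, 0.1)
    expect_equal(r1$ks, 0.9)

    r2 <- ksScore("g10", ranks10)
    expect_equal(r2$a, 0)
    expect_equal(r2$b, 1.0)
    expect_equal(r2$ks, -1.0)

    ranks4 <- setNames(1:4, paste0("g", 1:4))
    r3 <- ksScore(c("g1", "g2"), ranks4)
    expect_equal(r3$a, 0.5)
    expect_equal(r3$b, 0.25)
    expect_equal(r3$ks, 0.5)
})

test_that("genes absent from the signature shrink t; empty overlap is NA", {
    ranks <- setNames(1:10, paste0("g", 1:10))
    r <- ksScore(c("g1", "gX"), ranks)
    expect_equal(r$t, 1L)
    expect_equal(r$ks, 0.9)
    expect_true(is.na(ksScore(c("gX", "gY"), ranks)$ks))
})

test_that("KS equals the explicit-scan oracle on random instances", {
    set.seed(31)
    for (i in 1:150) {
        n <- sample(2:30, 1)
        t <- sample(1:n, 1)
        genes <- paste0("g", 1:n)
        ranks <- setNames(sample(n), genes)
        query <- sample(genes, t)
        got <- ksScore(query, ranks)
        expect_equal(got$ks, bruteForceKS(unname(ranks[query]), n))
        expect_gte(got$ks, -1); expect_lte(got$ks, 1)
    }
})

test_that("matrix KS agrees with the scalar implementation", {
    set.seed(32)
    n <- 50
    genes <- paste0("g", 1:n)
    rankMatrix <- sapply(1:8, function(i) sample(n))
    rownames(rankMatrix) <- genes
    for (t in c(1, 5, 12)) {
        query <- sample(genes, t)
        mat <- ksScoreMatrix(query, rankMatrix)
        ind <- sapply(1:8, function(j)
            ksScore(query, setNames(rankMatrix[, j], genes))$ks)
        expect_equal(mat, ind)
    }
})

test_that("weighted connectivity follows the sign rule", {
    expect_equal(weightedConnectivity(0.5, 0.3), 0)
    expect_equal(weightedConnectivity(-0.6, 0.4), -1.0)
    expect_equal(weightedConnectivity(0.4, -0.2), 0.6)
    expect_equal(weightedConnectivity(-0.2, -0.4), 0)
    expect_true(is.na(weightedConnectivity(NA, 0.3)))
    # vectorized and bounded
    set.seed(2)
    u <- runif(100, -1, 1); d <- runif(100, -1, 1)
    W <- weightedConnectivity(u, d)
    expect_true(all(abs(W) <= 2))
    expect_true(all(W[sign(u) == sign(d)] == 0))
})

test_that("reversal placement drives the sign of W", {
    n <- 100
    genes <- paste0("g", 1:n)
    ranks <- setNames(1:n, genes)
    for (t in c(1, 5, 10)) {
        up <- genes[(n - t + 1):n]   # up-genes at the bottom
        down <- genes[1:t]           # down-genes at the top
        W <- weightedConnectivity(ksScore(up, ranks)$ks,
                                  ksScore(down, ranks)$ks)
        expect_lt(W, 0)
        Wm <- weightedConnectivity(ksScore(down, ranks)$ks,
                                   ksScore(up, ranks)$ks)
        expect_gt(Wm, 0)
    }
})

test_that("NCS normalization preserves sign and scales by group means", {
    expect_equal(normalizeNCS(c(2, 4, -3, -1)),
                 c(2 / 3, 4 / 3, -1.5, -0.5))
    expect_warning(one <- normalizeNCS(c(3, 3, 3)), "one sign only")
    expect_equal(one, c(1, 1, 1))
    expect_equal(suppressWarnings(normalizeNCS(c(0, 2, 4)))[1], 0)
    # grouped normalization is independent across strata
    W <- c(2, 4, -3, -1, 10, -5, -15)
    g <- c(1, 1, 1, 1, 2, 2, 2)
    ncs <- suppressWarnings(normalizeNCS(W, g))
    expect_equal(ncs[1:4], normalizeNCS(W[1:4]))
    expect_equal(ncs[5:7], suppressWarnings(normalizeNCS(W[5:7])))
    expect_true(all(sign(ncs) == sign(W)))
})

test_that("tau is the signed strict percentile of |NCS|", {
    # |NCS_q| exceeds exactly 90 of 100 reference values
    ref <- c(seq_len(90) / 100, seq(2, 3, length.out = 10))
    expect_equal(abs(tauScore(1.5, ref)), 90)
    expect_equal(tauScore(-1.5, ref), -90)
    expect_equal(tauScore(1, rep(1, 7)), 0)       # strict inequality
    expect_equal(tauScore(-3, c(-3, 2, 1, 0.5, -0.2)), -80)
    expect_error(tauScore(1, numeric()), "empty")

    # invariance under positive rescaling; monotone in |NCS_q|
    set.seed(8)
    ref2 <- rnorm(50)
    q <- c(0.2, 0.9, 1.7)
    expect_equal(sapply(q, tauScore, ncsReference = ref2),
                 sapply(3.7 * q, tauScore, ncsReference = 3.7 * ref2))
    taus <- sapply(q, tauScore, ncsReference = ref2)
    expect_true(all(diff(taus) >= 0))
    expect_true(all(abs(taus) <= 100))
})

test_that("per-drug summaries take min over cells then mean over variants", {
    ct <- data.frame(
        drug = "d1", cellLine = rep(c("c1", "c2"), 4),
        dataset = "ds1",
        variant = rep(c("v1", "v2", "v3", "v4"), each = 2),
        tau = c(-50, 10, -30, -10, -20, 5, -40, -40))
    s <- summarizeDrug(ct)
    expect_equal(s$meanTau, mean(c(-50, -30, -20, -40)))  # -35
    expect_equal(s$nVariants, 4)

    # a variant with only NA tau is excluded from the mean
    ct2 <- rbind(ct, data.frame(drug = "d1", cellLine = "c1",
                                dataset = "ds1", variant = "v5",
                                tau = NA))
    expect_warning(s2 <- summarizeDrug(ct2), "undefined tau")
    expect_equal(s2$meanTau, -35)
})

test_that("candidate selection reproduces the top-fraction arithmetic", {
    set.seed(77)
    mk <- function(ds, n) data.frame(
        drug = sprintf("drug%03d", 1:n), dataset = ds,
        meanTau = rnorm(n))
    s <- rbind(mk("a", 100), mk("b", 100))
    out <- selectCandidates(s, fraction = 0.05, consensusSize = 10)
    per <- attr(out, "perDataset")
    expect_equal(nrow(per$a), 5)   # floor(0.05 * 100)
    expect_equal(nrow(per$b), 5)
    # per-dataset lists hold the most negative scores
    sa <- s[s$dataset == "a", ]
    expect_setequal(per$a$drug,
                    sa$drug[order(sa$meanTau)][1:5])
    # frequency-ranked consensus, padded from single appearances
    expect_true(all(diff(out$frequency) <= 0))

    one <- selectCandidates(mk("solo", 60), consensusSize = 3)
    expect_equal(one$drug,
                 attr(one, "perDataset")$solo$drug[1:3])

    expect_message(
        small <- selectCandidates(mk("a", 40), consensusSize = 38),
        "fewer distinct drugs")
    expect_equal(nrow(small), 2)   # floor(0.05*40) = 2 appear at all
})

test_that("connectivity table scores a library end to end", {
    w <- smallWorld()
    datasets <- setNames(w@datasets,
                         paste0("ds", seq_along(w@datasets)))
    tabs <- lapply(datasets, differentialTest)
    sigs <- suppressWarnings(
        lapply(tabs, signatureVariants, graph = w@graph,
               Ks = c(30L, 50L)))
    ct <- suppressWarnings(connectivityTable(w@signatures, sigs))
    expect_setequal(unique(ct$dataset), names(datasets))
    expect_true(all(c("ksUp", "ksDown", "W", "NCS", "tau") %in%
                    names(ct)))
    expect_true(all(abs(ct$W) <= 2, na.rm = TRUE))
    expect_true(all(abs(ct$tau) <= 100, na.rm = TRUE))
    expect_true(all(sign(ct$NCS) == sign(ct$W), na.rm = TRUE))
    # planted reversers carry the most negative summaries; queries with
    # an empty direction (possible for the articulation variant) yield
    # undefined tau and are excluded with a warning
    s <- suppressWarnings(summarizeDrug(ct))
    agg <- tapply(s$meanTau, s$drug, mean)
    ther <- mean(agg[w@therapeuticDrugs])
    expect_lt(ther, quantile(agg, 0.05) + 1e-9)
})
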