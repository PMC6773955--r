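test_that("edge lists become deduplicated simple graphs", {
    g <- suppressMessages(
        buildGraph(rbind(c("a", "b"), c("b", "a"), c("a", "a"))))
    expect_setequal(igraph::V(g)$name, c("a", "b"))
    expect_equal(igraph::gsize(g), 1)

    expect_equal(igraph::vcount(buildGraph(NULL)), 0)

    tri <- buildGraph(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
    expect_equal(igraph::gsize(tri), 3)

    expect_error(buildGraph(rbind(c("a", NA))), "malformed")
})

test_that("induced subgraphs keep exactly the in-set edges", {
    tri <- buildGraph(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
    sub <- inducedSubgraph(tri, c("a", "b"))
    expect_setequal(igraph::V(sub)$name, c("a", "b"))
    expect_equal(igraph::gsize(sub), 1)

    expect_equal(igraph::vcount(inducedSubgraph(tri, c("x", "y"))), 0)
    expect_equal(igraph::gsize(inducedSubgraph(tri, c("a", "b", "c"))), 3)

    # idempotence and monotonicity
    set.seed(5)
    for (i in 1:10) {
        g <- randomNamedGraph(10, 0.35)
        s1 <- sample(igraph::V(g)$name, 6)
        s2 <- sample(s1, 4)
        g1 <- inducedSubgraph(g, s1)
        expect_equal(igraph::gsize(inducedSubgraph(g1, s1)),
                     igraph::gsize(g1))
        expect_lte(igraph::gsize(inducedSubgraph(g, s2)),
                   igraph::gsize(g1))
    }
})

test_that("articulation points match the remove-and-count oracle", {
    path <- buildGraph(rbind(c("a", "b"), c("b", "c")))
    expect_equal(articulationPoints(path), "b")
    tri <- buildGraph(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
    expect_equal(articulationPoints(tri), character())
    star <- buildGraph(rbind(c("c", "x"), c("c", "y"), c("c", "z")))
    expect_equal(articulationPoints(star), "c")
    expect_equal(articulationPoints(buildGraph(NULL)), character())

    set.seed(11)
    for (i in 1:60) {
        g <- randomNamedGraph(sample(4:12, 1), runif(1, 0.15, 0.5))
        expect_equal(articulationPoints(g), naiveArticulation(g))
    }
})

test_that("consensus DEGs require the stated support", {
    sets <- list(c("a", "b"), c("a", "c"), c("a", "b"), c("d"), c("b"))
    expect_equal(consensusDegs(sets, 3), c("a", "b"))  # a in 3, b in 3
    expect_false("c" %in% consensusDegs(sets, 3))
    expect_setequal(consensusDegs(sets, 1), c("a", "b", "c", "d"))
    expect_error(consensusDegs(sets, 6), "exceeds")
    expect_error(consensusDegs(sets, 0), ">= 1")
    # direction-free: duplicated entries within a set count once
    expect_equal(consensusDegs(list(c("a", "a"), "a", "b"), 2), "a")
})

test_that("target-network relations distinguish inside/boundary/outside", {
    global <- buildGraph(rbind(c("d1", "d2"), c("d2", "d3"),
                               c("d3", "b1"), c("b1", "o1"),
                               c("o1", "o2")))
    diseaseNet <- inducedSubgraph(global, c("d1", "d2", "d3"))
    expect_equal(classifyTargetRelation(global, diseaseNet, "d2"),
                 "inside")
    expect_equal(classifyTargetRelation(global, diseaseNet, "b1"),
                 "boundary")
    expect_equal(classifyTargetRelation(global, diseaseNet, "o2"),
                 "outside")
    expect_equal(classifyTargetRelation(global, diseaseNet, "absent"),
                 "outside")
    # inside wins over boundary when both kinds of target exist
    expect_equal(classifyTargetRelation(global, diseaseNet,
                                        c("o2", "b1", "d1")), "inside")
})

test_that("MOA networks contain exactly the bounded shortest paths", {
    net <- buildGraph(rbind(c("y", "x"), c("y", "c"), c("c", "x2"),
                            c("x2", "far1"), c("far1", "far2"),
                            c("far2", "x3")))
    m <- moaNetwork(net, sDisease = c("x", "x2"), sDrug = "y",
                    maxSteps = 2)
    expect_true(all(c("x", "x2", "y", "c") %in% moaGenes(m)))
    expect_equal(unname(moaRoles(m)[c("x", "y", "c")]),
                 c("disease", "target", "connector"))
    expect_false("far1" %in% moaGenes(m))

    # distance-3 disease gene excluded by the bound, admitted at 3 steps
    m2 <- moaNetwork(net, sDisease = "x3", sDrug = "y", maxSteps = 2)
    expect_length(moaGenes(m2), 0)
    m3 <- moaNetwork(net, sDisease = "x3", sDrug = "x2", maxSteps = 3)
    expect_true(all(c("x2", "far1", "far2", "x3") %in% moaGenes(m3)))

    # both tied shortest paths are included
    sq <- buildGraph(rbind(c("y", "a"), c("y", "b"), c("a", "x"),
                           c("b", "x")))
    m4 <- moaNetwork(sq, sDisease = "x", sDrug = "y", maxSteps = 2)
    expect_setequal(moaGenes(m4), c("y", "a", "b", "x"))
    expect_equal(igraph::gsize(m4@graph), 4)

    # empty-set contract
    expect_length(moaGenes(moaNetwork(net, "absent", "y")), 0)
})

test_that("every connector lies on a qualifying shortest path (brute force)", {
    set.seed(23)
    for (i in 1:25) {
        g <- randomNamedGraph(9, 0.3)
        nm <- igraph::V(g)$name
        sDis <- sample(nm, 2)
        sDrg <- sample(setdiff(nm, sDis), 2)
        m <- moaNetwork(g, sDis, sDrg, maxSteps = 2)
        conn <- names(moaRoles(m))[moaRoles(m) == "connector"]
        d <- igraph::distances(g)
        for (v in conn) {
            ok <- FALSE
            for (s in sDrg) for (t in sDis) {
                if (is.finite(d[s, t]) && d[s, t] <= 2 &&
                    d[s, v] + d[v, t] == d[s, t]) ok <- TRUE
            }
            expect_true(ok)
        }
        # every path respects the bound and endpoints
        for (p in m@paths) {
            expect_lte(length(p) - 1, 2)
            expect_true(p[1] %in% c(sDrg, sDis) &&
                        p[length(p)] %in% c(sDrg, sDis))
        }
    }
})

test_that("all-pairs mode admits disease-disease and target-target paths", {
    g <- buildGraph(rbind(c("x1", "x2"), c("x2", "y1")))
    def <- moaNetwork(g, sDisease = c("x1", "x2"), sDrug = "y1")
    ap <- moaNetwork(g, sDisease = c("x1", "x2"), sDrug = "y1",
                     allPairs = TRUE)
    # default pairing: only drug-disease paths; x1-x2 edge appears anyway
    # because it lies on the shortest path y1..x1
    expect_setequal(moaGenes(def), c("x1", "x2", "y1"))
    expect_gte(length(ap@paths), length(def@paths))
})
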