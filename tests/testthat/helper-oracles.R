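# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (explicit loops, exhaustive enumeration) and are
# never shared with the implementation code paths they check.

# Benjamini-Hochberg by direct definition: min_{j >= i} m * p_(j) / j
bruteForceBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- vapply(seq_len(m), function(i)
        min(1, min(m * ps[i:m] / (i:m))), numeric(1))
    out <- numeric(m)
    out[o] <- adj
    out
}

# KS enrichment score by explicit scan over all j
bruteForceKS <- function(V, n) {
    V <- sort(V)
    t <- length(V)
    a <- -Inf; b <- -Inf
    for (j in seq_len(t)) {
        a <- max(a, j / t - V[j] / n)
        b <- max(b, V[j] / n - (j - 1) / t)
    }
    if (a > b) a else -b
}

# articulation points by removing each vertex and recounting components
naiveArticulation <- function(g) {
    base <- igraph::count_components(g)
    nm <- igraph::V(g)$name
    hits <- vapply(nm, function(v)
        igraph::count_components(igraph::delete_vertices(g, v)) > base,
        logical(1))
    sort(nm[hits])
}

# upper-tail hypergeometric probability by exhaustive summation
exhaustiveHyperTail <- function(k, setSize, universe, querySize) {
    hi <- min(setSize, querySize)
    if (k > hi) return(0)
    sum(vapply(k:hi, function(i)
        choose(setSize, i) * choose(universe - setSize, querySize - i),
        numeric(1))) / choose(universe, querySize)
}

# small named random graph
randomNamedGraph <- function(n, p = 0.3) {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- paste0("v", seq_len(n))
    g
}

# a small synthetic world reused by several files (cheap to build)
smallWorld <- function(seed = 101) {
    generateWorld(syntheticConfig(
        nGenes = 300L, nDatasets = 3L, nCase = 8L, nControl = 8L,
        diseaseModuleSize = 60L, nDrugs = 40L, nCellLines = 2L,
        nTherapeutic = 2L, seed = seed))
}
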