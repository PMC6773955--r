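#' Build a simple undirected interaction network from an edge list
#'
#' Self-loops and duplicate (unordered) pairs are dropped; the number of
#' discarded records is reported via \code{message}.
#'
#' @param edges two-column matrix or data.frame of gene-id pairs.
#' @return An undirected simple \code{igraph} graph.
#' @examples
#' g <- buildGraph(rbind(c("a", "b"), c("b", "a"), c("a", "a")))
#' igraph::gsize(g)  # 1
#' @export
buildGraph <- function(edges) {
    if (is.null(edges) || NROW(edges) == 0)
        return(igraph::make_empty_graph(directed = FALSE))
    edges <- as.matrix(edges)
    if (ncol(edges) < 2)
        stop("edge records must have two columns")
    if (any(is.na(edges[, 1:2])))
        stop("malformed edge record at line ",
             which(rowSums(is.na(edges[, 1:2, drop = FALSE])) > 0)[1])
    g <- igraph::graph_from_edgelist(edges[, 1:2, drop = FALSE],
                                     directed = FALSE)
    gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    dropped <- igraph::gsize(g) - igraph::gsize(gs)
    if (dropped > 0)
        message(dropped, " self-loop/duplicate edge(s) dropped")
    gs
}

#' Induced subgraph on a gene set
#'
#' Nodes are the intersection of \code{genes} with the graph's vertices;
#' edges are all original edges with both endpoints retained. Genes absent
#' from the graph are ignored.
#'
#' @param g an igraph graph.
#' @param genes character vector of gene ids.
#' @return The induced \code{igraph} subgraph.
#' @export
inducedSubgraph <- function(g, genes) {
    keep <- intersect(genes, igraph::V(g)$name)
    igraph::induced_subgraph(g, keep)
}

#' Articulation points of a network
#'
#' The vertices whose removal increases the number of connected
#' components. Computed per connected component (a disconnected input is
#' allowed).
#'
#' @param g an igraph graph.
#' @return Character vector of articulation gene ids (possibly empty).
#' @examples
#' path <- buildGraph(rbind(c("a", "b"), c("b", "c")))
#' articulationPoints(path)  # "b"
#' @export
articulationPoints <- function(g) {
    if (igraph::vcount(g) == 0) return(character())
    sort(igraph::V(g)$name[igraph::articulation_points(g)])
}

#' Consensus differentially expressed genes across datasets
#'
#' Genes present in at least \code{minSupport} of the supplied DEG sets,
#' irrespective of regulation direction.
#'
#' @param degSets list of character vectors (one DEG set per dataset).
#' @param minSupport minimum number of sets a gene must appear in
#'   (default 3).
#' @return Sorted character vector of consensus genes.
#' @export
consensusDegs <- function(degSets, minSupport = 3L) {
    if (minSupport < 1) stop("minSupport must be >= 1")
    if (minSupport > length(degSets))
        stop("minSupport exceeds the number of DEG sets")
    counts <- table(unlist(lapply(degSets, unique)))
    sort(names(counts)[counts >= minSupport])
}

#' Classify the relation between a drug's targets and the disease network
#'
#' Three relations are distinguished: \code{"inside"} (at least one target
#' is a node of the disease network), \code{"boundary"} (no target inside,
#' but at least one target interacts with a disease-network node in the
#' global network), and \code{"outside"}. Only \code{"inside"} drugs pass
#' the final candidate filter.
#'
#' @param global global interaction network (igraph).
#' @param diseaseNet disease subnetwork (igraph), a subgraph of
#'   \code{global}.
#' @param targets character vector of the drug's target genes.
#' @return One of \code{"inside"}, \code{"boundary"}, \code{"outside"}.
#' @export
classifyTargetRelation <- function(global, diseaseNet, targets) {
    dnodes <- igraph::V(diseaseNet)$name
    if (any(targets %in% dnodes)) return("inside")
    present <- intersect(targets, igraph::V(global)$name)
    for (t in present) {
        nb <- igraph::neighbors(global, t)$name
        if (any(nb %in% dnodes)) return("boundary")
    }
    "outside"
}

#' Bounded shortest-path mode-of-action network
#'
#' Extracts from the disease network the union of all shortest paths of
#' length at most \code{maxSteps} edges whose endpoints are a drug target
#' (\code{sDrug}) and a known disease gene (\code{sDisease}); with
#' \code{allPairs = TRUE} any pair of genes from the union of the two sets
#' qualifies as endpoints. For every qualifying endpoint pair, \emph{all}
#' tied shortest paths are included. Nodes are labelled by role: disease
#' gene, drug target, both, or connector (interior path node belonging to
#' neither set).
#'
#' @param diseaseNet disease subnetwork (igraph).
#' @param sDisease known disease genes; intersected with the network.
#' @param sDrug drug target genes; intersected with the network.
#' @param maxSteps maximum admissible path length in edges (default 2,
#'   i.e. fewer than three steps).
#' @param allPairs if \code{TRUE}, endpoints may come from either set.
#' @return A \linkS4class{MOANetwork}; empty if no pair qualifies.
#' @export
moaNetwork <- function(diseaseNet, sDisease, sDrug, maxSteps = 2L,
                       allPairs = FALSE) {
    stopifnot(maxSteps >= 1)
    nodes <- igraph::V(diseaseNet)$name
    sDisease <- intersect(sDisease, nodes)
    sDrug <- intersect(sDrug, nodes)
    emptyNet <- new("MOANetwork",
                    graph = igraph::make_empty_graph(directed = FALSE),
                    roles = setNames(character(), character()),
                    paths = list(), maxSteps = as.integer(maxSteps))
    if (!length(sDisease) || !length(sDrug)) return(emptyNet)
    if (allPairs) {
        sources <- union(sDrug, sDisease)
        destOf <- function(s) setdiff(union(sDrug, sDisease), s)
    } else {
        sources <- sDrug
        destOf <- function(s) sDisease
    }
    paths <- list()
    seen <- character()
    for (s in sources) {
        to <- setdiff(destOf(s), seen)
        if (!length(to)) next
        sp <- igraph::all_shortest_paths(diseaseNet, from = s, to = to,
                                         mode = "all")$vpaths
        for (p in sp) {
            pn <- igraph::V(diseaseNet)$name[p]
            if (length(pn) - 1 <= maxSteps)
                paths[[length(paths) + 1L]] <- pn
        }
        seen <- c(seen, s)  # avoid double-counting unordered pairs
    }
    if (!length(paths)) return(emptyNet)
    keep <- unique(unlist(paths))
    sub <- inducedSubgraphFromPaths(diseaseNet, paths)
    roles <- vapply(keep, function(v) {
        d <- v %in% sDisease; t <- v %in% sDrug
        if (d && t) "both" else if (d) "disease"
        else if (t) "target" else "connector"
    }, character(1))
    new("MOANetwork", graph = sub, roles = roles, paths = paths,
        maxSteps = as.integer(maxSteps))
}

# subgraph containing exactly the edges traversed by the qualifying paths
inducedSubgraphFromPaths <- function(g, paths) {
    ep <- do.call(rbind, lapply(paths, function(p) {
        if (length(p) < 2) return(NULL)
        cbind(p[-length(p)], p[-1])
    }))
    nodes <- unique(unlist(paths))
    if (is.null(ep)) {
        sub <- igraph::make_empty_graph(directed = FALSE) +
            igraph::vertices(nodes)
        return(sub)
    }
    key <- apply(ep, 1, function(r) paste(sort(r), collapse = "\r"))
    ep <- ep[!duplicated(key), , drop = FALSE]
    igraph::graph_from_edgelist(ep, directed = FALSE) +
        igraph::vertices(setdiff(nodes, unique(as.vector(ep))))
}
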