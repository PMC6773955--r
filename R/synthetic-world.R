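#' Create a synthetic-world configuration
#'
#' Builds a validated \linkS4class{SyntheticConfig}. The defaults are the
#' reference simulation conditions used by the package's own validation
#' experiments; see the class documentation for their meaning.
#'
#' @param nGenes size of the gene universe.
#' @param nDatasets number of case/control expression cohorts.
#' @param nCase,nControl samples per group in every cohort.
#' @param diseaseModuleSize number of planted disease genes.
#' @param effectSize mean |log2 fold change| of planted disease genes.
#' @param noiseSd within-group standard deviation of expression values.
#' @param nDrugs number of drugs in the perturbation library.
#' @param nCellLines cell lines profiled per drug.
#' @param nTherapeutic number of planted reversal drugs.
#' @param targetsPerDrug targets assigned to every drug.
#' @param fracTargetsInModule fraction of a planted drug's targets drawn
#'   from the disease module.
#' @param reversalNoise standard deviation of the noise added to planted
#'   reversal z-scores.
#' @param nKnownDrugs size of the positive-control ("known drug") set; must
#'   be at least \code{nTherapeutic}, extras are decoys.
#' @param meanDegree target mean degree of the interaction network.
#' @param assayKind \code{"continuous"} (log intensities) or
#'   \code{"counts"} (Poisson counts).
#' @param seed RNG seed; the whole world is a deterministic function of the
#'   configuration including this seed.
#' @return A \linkS4class{SyntheticConfig}.
#' @examples
#' syntheticConfig(nGenes = 200, nDrugs = 20, seed = 7)
#' @export
syntheticConfig <- function(nGenes = 1000L, nDatasets = 5L, nCase = 10L,
                            nControl = 10L, diseaseModuleSize = 200L,
                            effectSize = 3, noiseSd = 0.5, nDrugs = 200L,
                            nCellLines = 3L, nTherapeutic = 3L,
                            targetsPerDrug = 5L,
                            fracTargetsInModule = 0.8,
                            reversalNoise = 0.3,
                            nKnownDrugs = nTherapeutic,
                            meanDegree = 6, assayKind = "continuous",
                            seed = 1L) {
    new("SyntheticConfig", nGenes = as.integer(nGenes),
        nDatasets = as.integer(nDatasets), nCase = as.integer(nCase),
        nControl = as.integer(nControl),
        diseaseModuleSize = as.integer(diseaseModuleSize),
        effectSize = as.numeric(effectSize), noiseSd = as.numeric(noiseSd),
        nDrugs = as.integer(nDrugs), nCellLines = as.integer(nCellLines),
        nTherapeutic = as.integer(nTherapeutic),
        targetsPerDrug = as.integer(targetsPerDrug),
        fracTargetsInModule = as.numeric(fracTargetsInModule),
        reversalNoise = as.numeric(reversalNoise),
        nKnownDrugs = as.integer(nKnownDrugs),
        meanDegree = as.numeric(meanDegree),
        assayKind = as.character(assayKind), seed = as.integer(seed))
}

geneIds <- function(n) sprintf("g%04d", seq_len(n))
drugIds <- function(n) sprintf("drug%03d", seq_len(n))

#' Generate a synthetic protein-protein interaction network
#'
#' A preferential-attachment (scale-free) backbone guarantees a connected
#' simple graph; when \code{moduleGenes} is supplied, additional random
#' edges are planted within the module so that the disease subnetwork has
#' above-background interconnection and a non-trivial induced subgraph.
#'
#' @param nGenes number of genes (nodes); at least 2.
#' @param meanDegree target mean degree, below \code{nGenes}.
#' @param seed optional seed; \code{NULL} uses the current RNG stream.
#' @param moduleGenes optional character vector of disease-module genes to
#'   wire more densely.
#' @param genes optional node names (defaults to \code{g0001..}).
#' @return An undirected simple \code{igraph} graph.
#' @examples
#' g <- generatePPI(100, meanDegree = 4, seed = 1)
#' igraph::gsize(g)
#' @export
generatePPI <- function(nGenes, meanDegree, seed = NULL,
                        moduleGenes = NULL, genes = NULL) {
    if (nGenes < 2 || meanDegree >= nGenes || meanDegree <= 0)
        stop("invalid sizes: need nGenes >= 2 and 0 < meanDegree < nGenes")
    if (!is.null(seed)) set.seed(seed)
    if (is.null(genes)) genes <- geneIds(nGenes)
    m <- max(1L, as.integer(round(meanDegree / 2)))
    g <- igraph::sample_pa(nGenes, m = m, directed = FALSE)
    igraph::V(g)$name <- genes
    if (!is.null(moduleGenes) && length(moduleGenes) >= 2) {
        moduleGenes <- intersect(moduleGenes, genes)
        k <- length(moduleGenes)
        # plant ~2 extra within-module edges per module gene
        nExtra <- min(k * 2L, choose(k, 2))
        pairs <- cbind(sample(moduleGenes, nExtra, replace = TRUE),
                       sample(moduleGenes, nExtra, replace = TRUE))
        pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
        g <- igraph::add_edges(g, t(pairs))
    }
    igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Generate case/control expression datasets with a planted disease module
#'
#' Non-module genes share a common baseline in both groups; disease-module
#' genes are shifted in cases by a signed per-gene log2 fold change whose
#' magnitude is centred on \code{effectSize}. The sign and magnitude of
#' each gene's shift are fixed across datasets, so a cross-dataset
#' consensus of differentially expressed genes exists by construction.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param foldChanges named numeric vector of planted signed log2 fold
#'   changes over the full universe; \code{NULL} draws them (half the
#'   module up, half down, magnitudes \code{effectSize} +/- 20%).
#' @param moduleGenes disease-module gene ids; \code{NULL} takes the first
#'   \code{diseaseModuleSize} universe genes.
#' @param seed optional seed; \code{NULL} uses the current RNG stream.
#' @return A list with \code{datasets} (list of
#'   \linkS4class{ExpressionDataset}) and \code{foldChanges} (the planted
#'   truth table).
#' @export
generateExpression <- function(config, foldChanges = NULL,
                               moduleGenes = NULL, seed = NULL) {
    stopifnot(is(config, "SyntheticConfig"))
    if (!is.null(seed)) set.seed(seed)
    genes <- geneIds(config@nGenes)
    if (is.null(moduleGenes))
        moduleGenes <- genes[seq_len(config@diseaseModuleSize)]
    if (is.null(foldChanges))
        foldChanges <- plantFoldChanges(config, genes, moduleGenes)
    nS <- config@nCase + config@nControl
    group <- rep(c("case", "control"), c(config@nCase, config@nControl))
    baseline <- runif(config@nGenes, min = 5, max = 9)
    names(baseline) <- genes
    datasets <- vector("list", config@nDatasets)
    for (d in seq_len(config@nDatasets)) {
        mu <- matrix(baseline, nrow = config@nGenes, ncol = nS)
        mu[, group == "case"] <- mu[, group == "case"] + foldChanges
        vals <- mu + matrix(rnorm(config@nGenes * nS, sd = config@noiseSd),
                            nrow = config@nGenes)
        dimnames(vals) <- list(genes, sprintf("d%d_s%02d", d, seq_len(nS)))
        if (config@assayKind == "counts")
            vals <- matrix(rpois(length(vals), lambda = 2^vals),
                           nrow = config@nGenes, dimnames = dimnames(vals))
        datasets[[d]] <- ExpressionDataset(vals, group,
                                           assayKind = config@assayKind)
    }
    list(datasets = datasets, foldChanges = foldChanges)
}

plantFoldChanges <- function(config, genes, moduleGenes) {
    fc <- setNames(numeric(length(genes)), genes)
    k <- length(moduleGenes)
    sign <- rep(c(1, -1), length.out = k)
    mag <- config@effectSize * runif(k, min = 0.8, max = 1.2)
    fc[moduleGenes] <- sign * mag
    fc
}

#' Generate the drug signature library and drug-target map
#'
#' Planted therapeutic drugs receive z-scores negatively proportional to
#' the planted disease fold changes plus Gaussian noise (an expression
#' reversal); all other drugs receive independent standard-normal noise.
#' Every drug gets \code{targetsPerDrug} targets; therapeutic drugs draw
#' \code{fracTargetsInModule} of theirs from the disease module, decoys
#' draw uniformly from the universe.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param foldChanges named numeric, planted signed log2 fold changes.
#' @param therapeuticDrugs drug ids to plant as reversers; \code{NULL}
#'   samples \code{nTherapeutic} of them.
#' @param seed optional seed; \code{NULL} uses the current RNG stream.
#' @return A list with \code{signatures}
#'   (\linkS4class{SignatureLibrary}), \code{targets} (named list) and
#'   \code{therapeuticDrugs}.
#' @export
generateSignaturesAndTargets <- function(config, foldChanges,
                                         therapeuticDrugs = NULL,
                                         seed = NULL) {
    stopifnot(is(config, "SyntheticConfig"))
    if (!is.null(seed)) set.seed(seed)
    genes <- names(foldChanges)
    drugs <- drugIds(config@nDrugs)
    cells <- sprintf("CL%d", seq_len(config@nCellLines))
    if (is.null(therapeuticDrugs))
        therapeuticDrugs <- sort(sample(drugs, config@nTherapeutic))
    moduleGenes <- genes[foldChanges != 0]
    nSig <- config@nDrugs * config@nCellLines
    drugCol <- rep(drugs, each = config@nCellLines)
    cellCol <- rep(cells, times = config@nDrugs)
    z <- matrix(rnorm(length(genes) * nSig), nrow = length(genes),
                dimnames = list(genes, NULL))
    # reversal scaled so z-magnitudes stay comparable to the noise columns
    scale <- 1 / max(abs(foldChanges), 1)
    for (j in which(drugCol %in% therapeuticDrugs)) {
        z[, j] <- -foldChanges * scale * 3 +
            rnorm(length(genes), sd = config@reversalNoise)
    }
    targets <- vector("list", config@nDrugs)
    names(targets) <- drugs
    nIn <- round(config@fracTargetsInModule * config@targetsPerDrug)
    for (dr in drugs) {
        if (dr %in% therapeuticDrugs && length(moduleGenes)) {
            inMod <- sample(moduleGenes, min(nIn, length(moduleGenes)))
            rest <- sample(setdiff(genes, inMod),
                           config@targetsPerDrug - length(inMod))
            targets[[dr]] <- sort(c(inMod, rest))
        } else {
            targets[[dr]] <- sort(sample(genes, config@targetsPerDrug))
        }
    }
    list(signatures = SignatureLibrary(z, drugCol, cellCol),
         targets = targets, therapeuticDrugs = therapeuticDrugs)
}

#' Generate reference sets: disease genes, known drugs, pathway collection
#'
#' Exports the planted disease module as the known-disease-gene reference,
#' a known-drug list containing every planted therapeutic drug (padded
#' with decoys up to \code{nKnownDrugs}), and a gene-set collection of
#' random synthetic "pathways" that always includes one set identical to
#' the disease module.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param diseaseGenes planted disease-module genes.
#' @param therapeuticDrugs planted reversal drugs.
#' @param nPathways number of decoy pathway sets.
#' @param seed optional seed; \code{NULL} uses the current RNG stream.
#' @return A list with \code{diseaseGenes}, \code{knownDrugs} and
#'   \code{pathways} (named list of gene sets).
#' @export
generateReferenceSets <- function(config, diseaseGenes, therapeuticDrugs,
                                  nPathways = 19L, seed = NULL) {
    stopifnot(is(config, "SyntheticConfig"))
    if (!is.null(seed)) set.seed(seed)
    genes <- geneIds(config@nGenes)
    drugs <- drugIds(config@nDrugs)
    nExtra <- config@nKnownDrugs - length(therapeuticDrugs)
    extras <- character()
    if (nExtra > 0)
        extras <- sample(setdiff(drugs, therapeuticDrugs), nExtra)
    pathways <- list(disease_module = sort(diseaseGenes))
    for (i in seq_len(nPathways)) {
        size <- sample(20:80, 1)
        pathways[[sprintf("pathway%02d", i)]] <- sort(sample(genes, size))
    }
    list(diseaseGenes = sort(diseaseGenes),
         knownDrugs = sort(c(therapeuticDrugs, extras)),
         pathways = pathways)
}

#' Generate a complete synthetic world
#'
#' Seeds one global RNG stream from \code{config@seed} and draws the
#' components in a fixed order (module and fold changes, PPI network,
#' expression datasets, signatures and targets, reference sets), so an
#' identical configuration reproduces an identical world.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return A \linkS4class{SyntheticWorld}.
#' @examples
#' w <- generateWorld(syntheticConfig(nGenes = 200, nDatasets = 3,
#'                                    nDrugs = 30, seed = 42))
#' w
#' @export
generateWorld <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    set.seed(config@seed)
    genes <- geneIds(config@nGenes)
    moduleGenes <- sort(sample(genes, config@diseaseModuleSize))
    foldChanges <- plantFoldChanges(config, genes, moduleGenes)
    graph <- generatePPI(config@nGenes, config@meanDegree,
                         moduleGenes = moduleGenes, genes = genes)
    expr <- generateExpression(config, foldChanges = foldChanges,
                               moduleGenes = moduleGenes)
    sig <- generateSignaturesAndTargets(config, foldChanges)
    refs <- generateReferenceSets(config, moduleGenes,
                                  sig$therapeuticDrugs)
    new("SyntheticWorld", config = config, graph = graph,
        datasets = expr$datasets, signatures = sig$signatures,
        targets = sig$targets, diseaseGenes = refs$diseaseGenes,
        therapeuticDrugs = sort(sig$therapeuticDrugs),
        knownDrugs = refs$knownDrugs, foldChanges = foldChanges,
        pathways = refs$pathways)
}

#' Export a synthetic world as plain-text files
#'
#' Writes every component in the pipeline's file formats: per-dataset
#' expression and group TSVs, the signature library (long TSV), the
#' target map, the PPI edge list, the pathway collection (GMT), and the
#' disease-gene and known-drug reference lists. All files parse back
#' through the package's readers.
#'
#' @param world a \linkS4class{SyntheticWorld}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of written file paths.
#' @export
exportWorld <- function(world, dir) {
    stopifnot(is(world, "SyntheticWorld"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    for (i in seq_along(world@datasets))
        writeExpression(world@datasets[[i]],
                        p(sprintf("expression_%02d.tsv", i)),
                        p(sprintf("groups_%02d.tsv", i)))
    writeSignatures(world@signatures, p("signatures.tsv"))
    writeTargets(world@targets, p("targets.tsv"))
    writeEdges(world@graph, p("ppi.tsv"))
    writeGmt(world@pathways, p("pathways.gmt"))
    writeDrugList(world@knownDrugs, p("known_drugs.txt"))
    writeLines(world@diseaseGenes, p("disease_genes.txt"))
    invisible(list.files(dir, full.names = TRUE))
}
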