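#' Run the full two-step repositioning analysis
#'
#' Executes every stage in order on in-memory inputs: per-dataset
#' differential expression, the four disease-signature variants,
#' connectivity scoring (KS, W, NCS, tau), per-drug summarization and
#' cross-dataset preliminary candidate selection; then the network step:
#' consensus DEGs, the disease subnetwork, target-relation
#' classification and the final candidate filter; finally per-candidate
#' mode-of-action networks, their pathway enrichment, and the drug-set
#' enrichment validation against \code{knownDrugs}.
#'
#' @param datasets list of \linkS4class{ExpressionDataset}, named or not.
#' @param library a \linkS4class{SignatureLibrary}.
#' @param graph global interaction network (igraph).
#' @param targets named list: drug -> target genes.
#' @param diseaseGenes known disease genes (for MOA networks).
#' @param knownDrugs reference drug set for enrichment (\code{NULL}
#'   skips that stage).
#' @param pathways named list of gene sets (\code{NULL} skips pathway
#'   enrichment).
#' @param alpha DEG adjusted-p cutoff.
#' @param Ks top-K signature sizes.
#' @param split signature split mode (\code{"total"} or \code{"each"}).
#' @param minSupport consensus DEG support (default 3).
#' @param fraction per-dataset candidate fraction (default 0.05).
#' @param consensusSize consensus candidate list size (default 38).
#' @param maxSteps MOA shortest-path bound (default 2).
#' @param allPairs MOA pairing mode.
#' @param topN pathways reported per candidate (default 10).
#' @param outDir optional directory; when given, every intermediate is
#'   persisted as TSV alongside a run manifest.
#' @return A list with elements \code{degTables}, \code{signatures},
#'   \code{connectivity}, \code{drugScores}, \code{preliminary},
#'   \code{consensusDegs}, \code{diseaseNetwork}, \code{relations},
#'   \code{candidates} (the CandidateReport data.frame), \code{moa}
#'   (per final candidate), \code{pathwayReports}, \code{enrichment}.
#' @export
runPipeline <- function(datasets, library, graph, targets,
                        diseaseGenes = NULL, knownDrugs = NULL,
                        pathways = NULL, alpha = 0.05,
                        Ks = c(150L, 250L, 350L), split = "total",
                        minSupport = 3L, fraction = 0.05,
                        consensusSize = 38L, maxSteps = 2L,
                        allPairs = FALSE, topN = 10L, outDir = NULL) {
    if (is.null(names(datasets)) || any(names(datasets) == ""))
        names(datasets) <- sprintf("dataset%02d", seq_along(datasets))

    degTables <- lapply(datasets, differentialTest, alpha = alpha)
    signatures <- lapply(degTables, signatureVariants, graph = graph,
                         Ks = Ks, split = split)

    ct <- connectivityTable(library, signatures)
    drugScores <- summarizeDrug(ct)
    preliminary <- selectCandidates(drugScores, fraction = fraction,
                                    consensusSize = consensusSize)

    degSets <- lapply(degTables, function(t) t$gene[t$significant])
    consensus <- consensusDegs(degSets,
                               minSupport = min(minSupport,
                                                length(degSets)))
    diseaseNet <- inducedSubgraph(graph, consensus)

    relations <- vapply(preliminary$drug, function(dr)
        classifyTargetRelation(graph, diseaseNet,
                               targets[[dr]] %||% character()),
        character(1))
    candidates <- data.frame(
        drug = preliminary$drug,
        frequency = preliminary$frequency,
        meanScore = preliminary$meanScore,
        preliminaryFlag = TRUE,
        relation = unname(relations),
        finalFlag = unname(relations) == "inside",
        stringsAsFactors = FALSE)

    finals <- candidates$drug[candidates$finalFlag]
    moa <- list(); pathwayReports <- list()
    for (dr in finals) {
        m <- moaNetwork(diseaseNet,
                        sDisease = diseaseGenes %||% character(),
                        sDrug = targets[[dr]] %||% character(),
                        maxSteps = maxSteps, allPairs = allPairs)
        moa[[dr]] <- m
        if (!is.null(pathways) && length(moaGenes(m))) {
            res <- fisherEnrichment(moaGenes(m), pathways,
                                    universe = igraph::vcount(graph))
            pathwayReports[[dr]] <- reportTop(res, topN = topN)
        }
    }

    enrichment <- NULL
    if (!is.null(knownDrugs))
        enrichment <- drugSetEnrichment(drugScores, knownDrugs)

    out <- list(degTables = degTables, signatures = signatures,
                connectivity = ct, drugScores = drugScores,
                preliminary = preliminary, consensusDegs = consensus,
                diseaseNetwork = diseaseNet, relations = relations,
                candidates = candidates, moa = moa,
                pathwayReports = pathwayReports, enrichment = enrichment)
    if (!is.null(outDir)) persistRun(out, datasets, outDir)
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

persistRun <- function(res, datasets, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, f) write.table(df, file.path(outDir, f),
                                     sep = "\t", quote = FALSE,
                                     row.names = FALSE)
    for (ds in names(res$degTables))
        w(res$degTables[[ds]], paste0("deg_", ds, ".tsv"))
    w(res$connectivity, "connectivity.tsv")
    w(res$drugScores, "drug_scores.tsv")
    w(res$preliminary, "preliminary_candidates.tsv")
    w(res$candidates, "candidate_report.tsv")
    writeLines(res$consensusDegs, file.path(outDir, "consensus_degs.txt"))
    writeEdges(res$diseaseNetwork, file.path(outDir, "disease_network.tsv"))
    for (dr in names(res$moa))
        writeMOANetwork(res$moa[[dr]],
                        file.path(outDir, paste0("moa_", dr, ".sif")),
                        file.path(outDir, paste0("moa_", dr, "_roles.tsv")))
    for (dr in names(res$pathwayReports))
        w(res$pathwayReports[[dr]], paste0("pathways_", dr, ".tsv"))
    if (!is.null(res$enrichment)) {
        w(res$enrichment$perDataset, "drugset_enrichment.tsv")
        m <- res$enrichment$meta
        w(data.frame(pooled = m$pooled, se = m$se, z = m$z, p = m$p,
                     Q = m$Q, I2 = m$I2, fisherP = m$fisherP,
                     tippettP = m$tippettP), "drugset_meta.tsv")
    }
    manifest <- c(
        paste0("datasets\t", length(datasets)),
        paste0("drugs\t", length(unique(res$drugScores$drug))),
        paste0("consensus_degs\t", length(res$consensusDegs)),
        paste0("preliminary_candidates\t", nrow(res$preliminary)),
        paste0("final_candidates\t", sum(res$candidates$finalFlag)))
    writeLines(manifest, file.path(outDir, "manifest.tsv"))
    invisible(NULL)
}

#' Run the pipeline on a synthetic world
#'
#' Convenience wrapper unpacking a \linkS4class{SyntheticWorld} into
#' \code{\link{runPipeline}}. The top-K list defaults to sizes suited to
#' the world's planted module; pass \code{Ks} to override.
#'
#' @param world a \linkS4class{SyntheticWorld}.
#' @param ... passed to \code{\link{runPipeline}}.
#' @return See \code{\link{runPipeline}}.
#' @export
runPipelineOnWorld <- function(world, ...) {
    stopifnot(is(world, "SyntheticWorld"))
    args <- list(...)
    if (is.null(args$Ks)) {
        k <- world@config@diseaseModuleSize
        args$Ks <- as.integer(unique(pmax(2, round(c(0.5, 0.75, 1) * k))))
    }
    do.call(runPipeline, c(list(
        datasets = world@datasets, library = world@signatures,
        graph = world@graph, targets = world@targets,
        diseaseGenes = world@diseaseGenes,
        knownDrugs = world@knownDrugs,
        pathways = world@pathways), args))
}

#' Validate cross-file identifier consistency
#'
#' Checks the gene universes of expression data, signature library,
#' interaction network and target map against each other and reports
#' coverage fractions and unmatched identifiers. Disjoint
#' expression/signature universes, or query coverage below
#' \code{minCoverage}, are hard errors.
#'
#' @param datasets list of \linkS4class{ExpressionDataset}.
#' @param library a \linkS4class{SignatureLibrary}.
#' @param graph igraph network.
#' @param targets named list of target genes.
#' @param minCoverage minimum fraction of expression genes that must be
#'   present in the signature universe (default 0.5).
#' @return A list with \code{coverage} (named fractions),
#'   \code{unmatchedTargets}, \code{unmatchedPpi} and \code{ok}.
#' @export
validateInputs <- function(datasets, library, graph, targets,
                           minCoverage = 0.5) {
    exprGenes <- unique(unlist(lapply(datasets, rownames)))
    sigGenes <- rownames(zScores(library))
    ppiGenes <- igraph::V(graph)$name
    targetGenes <- unique(unlist(targets))
    covSig <- mean(exprGenes %in% sigGenes)
    if (covSig == 0)
        stop("expression and signature gene universes are disjoint")
    if (covSig < minCoverage)
        stop(sprintf(
            "only %.0f%% of expression genes found in the signature universe",
            100 * covSig))
    out <- list(
        coverage = c(expression_in_signatures = covSig,
                     expression_in_ppi = mean(exprGenes %in% ppiGenes),
                     targets_in_ppi = mean(targetGenes %in% ppiGenes)),
        unmatchedTargets = setdiff(targetGenes, ppiGenes),
        unmatchedPpi = setdiff(ppiGenes, exprGenes),
        ok = TRUE)
    out
}
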