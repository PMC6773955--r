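#' @import methods
#' @importFrom stats p.adjust pnorm pchisq phyper rnorm rpois runif pt setNames
#' @importFrom utils combn head read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' Expression dataset with case/control labels
#'
#' An \code{ExpressionDataset} extends
#' \linkS4class{SummarizedExperiment} with a fixed contract: a single assay
#' named \code{"exprs"} (genes x samples), a \code{group} column in
#' \code{colData} with levels \code{"control"} and \code{"case"}, and an
#' \code{assayKind} metadata flag distinguishing continuous log-scale
#' intensities (microarray-like) from integer counts (RNA-seq-like).
#'
#' @slot .  inherits all slots from \code{SummarizedExperiment}.
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    cd <- SummarizedExperiment::colData(object)
    if (!"group" %in% colnames(cd)) {
        msg <- c(msg, "colData must contain a 'group' column")
    } else {
        grp <- as.character(cd$group)
        if (!all(grp %in% c("case", "control")))
            msg <- c(msg, "group labels must be 'case' or 'control'")
        if (length(unique(grp)) < 2L)
            msg <- c(msg, "both case and control groups must be non-empty")
    }
    kind <- S4Vectors::metadata(object)$assayKind
    if (is.null(kind) || !kind %in% c("continuous", "counts"))
        msg <- c(msg, "metadata assayKind must be 'continuous' or 'counts'")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicated gene identifiers are not allowed")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param exprs numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns.
#' @param group character/factor vector of \code{"case"}/\code{"control"}
#'   labels, one per column of \code{exprs}.
#' @param assayKind \code{"continuous"} for log-scale intensities or
#'   \code{"counts"} for integer counts.
#' @return An \code{ExpressionDataset}.
#' @examples
#' m <- matrix(rnorm(40), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' ExpressionDataset(m, c("case", "case", "control", "control"))
#' @export
ExpressionDataset <- function(exprs, group,
                              assayKind = c("continuous", "counts")) {
    assayKind <- match.arg(assayKind)
    if (is.null(rownames(exprs)))
        stop("expression matrix must have gene ids as rownames")
    if (length(group) != ncol(exprs))
        stop("length of 'group' must equal the number of samples")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = exprs),
        colData = S4Vectors::DataFrame(group = as.character(group),
                                       row.names = colnames(exprs)))
    S4Vectors::metadata(se)$assayKind <- assayKind
    new("ExpressionDataset", se)
}

#' Disease expression signature (ordered up/down gene lists)
#'
#' One of the four query-signature variants fed to connectivity scoring:
#' the top-K genes by fold change (K in 150/250/350 by default) or the
#' articulation-point genes of the differential-expression subnetwork.
#'
#' @slot variant character, one of \code{"top150"}, \code{"top250"},
#'   \code{"top350"}, \code{"articulation"} (or \code{"topK"} for other K).
#' @slot up character vector of up-regulated genes, descending fold change.
#' @slot down character vector of down-regulated genes, ascending fold
#'   change (most down-regulated first).
#' @slot K integer, requested size parameter (NA for articulation variant).
#' @export
setClass("DiseaseSignature",
    representation(variant = "character", up = "character",
                   down = "character", K = "integer"))

setValidity("DiseaseSignature", function(object) {
    msg <- character()
    if (length(intersect(object@up, object@down)))
        msg <- c(msg, "up and down gene lists must be disjoint")
    if (anyDuplicated(object@up) || anyDuplicated(object@down))
        msg <- c(msg, "gene lists must not contain duplicates")
    if (length(msg)) msg else TRUE
})

#' Drug perturbation signature library
#'
#' Genome-wide z-score vectors, one per (drug, cell line) pair, over a
#' common gene universe.
#'
#' @slot zscores numeric matrix, genes x signatures; rownames are gene ids.
#' @slot drug character vector, drug id per signature column.
#' @slot cellLine character vector, cell line per signature column.
#' @export
setClass("SignatureLibrary",
    representation(zscores = "matrix", drug = "character",
                   cellLine = "character"))

setValidity("SignatureLibrary", function(object) {
    msg <- character()
    ns <- ncol(object@zscores)
    if (length(object@drug) != ns || length(object@cellLine) != ns)
        msg <- c(msg, "drug and cellLine must have one entry per column")
    if (is.null(rownames(object@zscores)))
        msg <- c(msg, "zscores must have gene ids as rownames")
    if (anyDuplicated(paste(object@drug, object@cellLine)))
        msg <- c(msg, "duplicate (drug, cellLine) signatures")
    if (length(msg)) msg else TRUE
})

#' @describeIn SignatureLibrary-class constructor.
#' @param zscores,drug,cellLine see slot documentation.
#' @export
SignatureLibrary <- function(zscores, drug, cellLine) {
    colnames(zscores) <- paste(drug, cellLine, sep = "|")
    new("SignatureLibrary", zscores = zscores, drug = as.character(drug),
        cellLine = as.character(cellLine))
}

#' Configuration of the synthetic world generator
#'
#' Defaults describe the reference simulation used throughout the package:
#' five case/control cohorts of 10 vs 10 samples over 1000 genes, a planted
#' 200-gene disease module with mean |log2 fold change| 3 and within-group
#' standard deviation 0.5, a 200-drug library profiled in 3 cell lines with
#' 3 planted reversal ("therapeutic") drugs, and drug-target maps placing
#' 80% of the planted drugs' targets inside the disease module.
#'
#' @slot nGenes,nDatasets,nCase,nControl,diseaseModuleSize,nDrugs,nCellLines,nTherapeutic,targetsPerDrug,nKnownDrugs integer counts.
#' @slot effectSize,noiseSd,fracTargetsInModule,reversalNoise,meanDegree numeric parameters.
#' @slot assayKind character, expression platform emulated.
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticConfig",
    representation(nGenes = "integer", nDatasets = "integer",
                   nCase = "integer", nControl = "integer",
                   diseaseModuleSize = "integer", effectSize = "numeric",
                   noiseSd = "numeric", nDrugs = "integer",
                   nCellLines = "integer", nTherapeutic = "integer",
                   targetsPerDrug = "integer",
                   fracTargetsInModule = "numeric",
                   reversalNoise = "numeric", nKnownDrugs = "integer",
                   meanDegree = "numeric", assayKind = "character",
                   seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    counts <- c(nGenes = object@nGenes, nDatasets = object@nDatasets,
                nCase = object@nCase, nControl = object@nControl,
                diseaseModuleSize = object@diseaseModuleSize,
                nDrugs = object@nDrugs, nCellLines = object@nCellLines,
                nTherapeutic = object@nTherapeutic,
                targetsPerDrug = object@targetsPerDrug,
                nKnownDrugs = object@nKnownDrugs)
    bad <- names(counts)[counts < 1L]
    if (length(bad))
        msg <- c(msg, paste0("counts must be strictly positive: ",
                             paste(bad, collapse = ", ")))
    if (object@nTherapeutic > object@nDrugs)
        msg <- c(msg, "nTherapeutic must not exceed nDrugs")
    if (object@nKnownDrugs > object@nDrugs)
        msg <- c(msg, "nKnownDrugs must not exceed nDrugs")
    if (object@diseaseModuleSize > object@nGenes)
        msg <- c(msg, "diseaseModuleSize must not exceed nGenes")
    if (object@fracTargetsInModule < 0 || object@fracTargetsInModule > 1)
        msg <- c(msg, "fracTargetsInModule must lie in [0, 1]")
    if (object@effectSize < 0 || object@noiseSd <= 0)
        msg <- c(msg, "effectSize must be >= 0 and noiseSd > 0")
    if (object@meanDegree >= object@nGenes || object@meanDegree <= 0)
        msg <- c(msg, "meanDegree must be positive and below nGenes")
    if (!object@assayKind %in% c("continuous", "counts"))
        msg <- c(msg, "assayKind must be 'continuous' or 'counts'")
    if (length(msg)) msg else TRUE
})

#' Synthetic world: all inputs of the pipeline with known ground truth
#'
#' @slot config the generating \linkS4class{SyntheticConfig}.
#' @slot graph global protein-protein interaction network (igraph).
#' @slot datasets list of \linkS4class{ExpressionDataset}.
#' @slot signatures \linkS4class{SignatureLibrary}.
#' @slot targets named list: drug id -> character vector of target genes.
#' @slot diseaseGenes planted disease-module genes (exported as the
#'   known-disease-gene reference).
#' @slot therapeuticDrugs planted reversal drugs (ground truth).
#' @slot knownDrugs positive-control drug set for drug-set enrichment.
#' @slot foldChanges named numeric, planted signed log2 fold change per
#'   gene (0 outside the module).
#' @slot pathways named list of gene sets (synthetic pathway collection,
#'   includes the disease module itself).
#' @export
setClass("SyntheticWorld",
    representation(config = "SyntheticConfig", graph = "ANY",
                   datasets = "list", signatures = "SignatureLibrary",
                   targets = "list", diseaseGenes = "character",
                   therapeuticDrugs = "character", knownDrugs = "character",
                   foldChanges = "numeric", pathways = "list"))

setValidity("SyntheticWorld", function(object) {
    msg <- character()
    universe <- rownames(object@signatures@zscores)
    if (!all(object@diseaseGenes %in% universe))
        msg <- c(msg, "disease genes outside the gene universe")
    if (!all(unlist(object@targets) %in% universe))
        msg <- c(msg, "target genes outside the gene universe")
    if (!all(object@therapeuticDrugs %in% names(object@targets)))
        msg <- c(msg, "therapeutic drugs missing from the target map")
    if (length(msg)) msg else TRUE
})

#' Mode-of-action (drug-disease) network
#'
#' The union of all shortest paths of length at most \code{maxSteps}
#' between a drug's in-network targets and known disease genes, extracted
#' from the disease network. Nodes carry role labels: \code{"disease"},
#' \code{"target"}, \code{"both"}, or \code{"connector"}.
#'
#' @slot graph igraph subgraph.
#' @slot roles named character vector, role per node.
#' @slot paths list of character vectors, the qualifying shortest paths.
#' @slot maxSteps integer bound on path length (edges).
#' @export
setClass("MOANetwork",
    representation(graph = "ANY", roles = "character", paths = "list",
                   maxSteps = "integer"))
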