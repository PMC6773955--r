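#' Accessors for package classes
#'
#' \code{exprsMatrix} returns the genes x samples value matrix of an
#' \linkS4class{ExpressionDataset}; \code{sampleGroups} its case/control
#' labels; \code{assayKind} its platform flag. \code{zScores},
#' \code{signatureDrugs} and \code{signatureCells} access a
#' \linkS4class{SignatureLibrary}; \code{upGenes}/\code{downGenes} a
#' \linkS4class{DiseaseSignature}; \code{moaGenes}/\code{moaRoles} a
#' \linkS4class{MOANetwork}.
#'
#' @param x an object of the corresponding class.
#' @return The matrix, character vector or labels stored in the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprsMatrix", function(x) standardGeneric("exprsMatrix"))
#' @rdname accessors
#' @export
setMethod("exprsMatrix", "ExpressionDataset", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname accessors
#' @export
setMethod("sampleGroups", "ExpressionDataset", function(x)
    as.character(SummarizedExperiment::colData(x)$group))

#' @rdname accessors
#' @export
setGeneric("assayKind", function(x) standardGeneric("assayKind"))
#' @rdname accessors
#' @export
setMethod("assayKind", "ExpressionDataset", function(x)
    S4Vectors::metadata(x)$assayKind)

#' @rdname accessors
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))
#' @rdname accessors
#' @export
setMethod("zScores", "SignatureLibrary", function(x) x@zscores)

#' @rdname accessors
#' @export
setGeneric("signatureDrugs", function(x) standardGeneric("signatureDrugs"))
#' @rdname accessors
#' @export
setMethod("signatureDrugs", "SignatureLibrary", function(x) x@drug)

#' @rdname accessors
#' @export
setGeneric("signatureCells", function(x) standardGeneric("signatureCells"))
#' @rdname accessors
#' @export
setMethod("signatureCells", "SignatureLibrary", function(x) x@cellLine)

#' @rdname accessors
#' @export
setGeneric("upGenes", function(x) standardGeneric("upGenes"))
#' @rdname accessors
#' @export
setMethod("upGenes", "DiseaseSignature", function(x) x@up)

#' @rdname accessors
#' @export
setGeneric("downGenes", function(x) standardGeneric("downGenes"))
#' @rdname accessors
#' @export
setMethod("downGenes", "DiseaseSignature", function(x) x@down)

#' @rdname accessors
#' @export
setGeneric("moaGenes", function(x) standardGeneric("moaGenes"))
#' @rdname accessors
#' @export
setMethod("moaGenes", "MOANetwork", function(x) names(x@roles))

#' @rdname accessors
#' @export
setGeneric("moaRoles", function(x) standardGeneric("moaRoles"))
#' @rdname accessors
#' @export
setMethod("moaRoles", "MOANetwork", function(x) x@roles)

setMethod("show", "ExpressionDataset", function(object) {
    grp <- sampleGroups(object)
    cat("ExpressionDataset (", assayKind(object), "): ",
        nrow(object), " genes, ", sum(grp == "case"), " case vs ",
        sum(grp == "control"), " control samples\n", sep = "")
})

setMethod("show", "DiseaseSignature", function(object) {
    cat("DiseaseSignature [", object@variant, "]: ",
        length(object@up), " up, ", length(object@down),
        " down genes\n", sep = "")
})

setMethod("show", "SignatureLibrary", function(object) {
    cat("SignatureLibrary: ", nrow(object@zscores), " genes, ",
        ncol(object@zscores), " signatures (",
        length(unique(object@drug)), " drugs x ",
        length(unique(object@cellLine)), " cell lines)\n", sep = "")
})

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig: ", object@nGenes, " genes, ", object@nDatasets,
        " datasets (", object@nCase, "v", object@nControl, "), ",
        object@nDrugs, " drugs (", object@nTherapeutic,
        " therapeutic), module ", object@diseaseModuleSize,
        ", effect ", object@effectSize, ", seed ", object@seed,
        "\n", sep = "")
})

setMethod("show", "SyntheticWorld", function(object) {
    cat("SyntheticWorld: ", length(object@datasets), " datasets, ",
        ncol(object@signatures@zscores), " drug signatures, ",
        igraph::gsize(object@graph), " PPI edges, ",
        length(object@diseaseGenes), " planted disease genes\n", sep = "")
})

setMethod("show", "MOANetwork", function(object) {
    cat("MOANetwork: ", length(object@roles), " genes (",
        sum(object@roles %in% c("disease", "both")), " disease, ",
        sum(object@roles %in% c("target", "both")), " target, ",
        sum(object@roles == "connector"), " connector), ",
        length(object@paths), " shortest paths, maxSteps = ",
        object@maxSteps, "\n", sep = "")
})
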