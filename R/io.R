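#' Readers and writers for the pipeline's plain-text formats
#'
#' All intermediates and synthetic-world exports are tab-separated text:
#' expression matrices (genes x samples, first column \code{gene}) with a
#' companion two-column sample/group table, drug signatures in long
#' format (\code{drug}, \code{cell_line}, \code{gene}, \code{z}),
#' drug-target and interaction-network edge lists as two-column TSV,
#' gene-set collections as GMT, and drug lists as one id per line.
#'
#' @name io
NULL

#' @rdname io
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param exprsFile,groupsFile paths for the matrix and group TSV.
#' @export
writeExpression <- function(dataset, exprsFile, groupsFile) {
    m <- exprsMatrix(dataset)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    write.table(df, exprsFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(sample = colnames(m),
                           group = sampleGroups(dataset)),
                groupsFile, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}

#' @rdname io
#' @param assayKind platform flag for the reconstructed dataset.
#' @export
readExpression <- function(exprsFile, groupsFile,
                           assayKind = "continuous") {
    df <- read.delim(exprsFile, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    grp <- read.delim(groupsFile)
    ExpressionDataset(m, grp$group[match(colnames(m), grp$sample)],
                      assayKind = assayKind)
}

#' @rdname io
#' @param library a \linkS4class{SignatureLibrary}.
#' @param file output path.
#' @export
writeSignatures <- function(library, file) {
    z <- zScores(library)
    long <- data.frame(
        drug = rep(signatureDrugs(library), each = nrow(z)),
        cell_line = rep(signatureCells(library), each = nrow(z)),
        gene = rep(rownames(z), times = ncol(z)),
        z = as.vector(z))
    write.table(long, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}

#' @rdname io
#' @export
readSignatures <- function(file) {
    long <- read.delim(file)
    genes <- unique(long$gene)
    key <- paste(long$drug, long$cell_line, sep = "|")
    cols <- unique(key)
    z <- matrix(NA_real_, nrow = length(genes), ncol = length(cols),
                dimnames = list(genes, cols))
    z[cbind(match(long$gene, genes), match(key, cols))] <- long$z
    meta <- do.call(rbind, strsplit(cols, "|", fixed = TRUE))
    SignatureLibrary(z, meta[, 1], meta[, 2])
}

#' @rdname io
#' @param targets named list of target gene vectors.
#' @export
writeTargets <- function(targets, file) {
    df <- data.frame(drug = rep(names(targets), lengths(targets)),
                     gene = unlist(targets, use.names = FALSE))
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}

#' @rdname io
#' @export
readTargets <- function(file) {
    df <- read.delim(file)
    split(df$gene, df$drug)
}

#' @rdname io
#' @param graph an igraph network.
#' @export
writeEdges <- function(graph, file) {
    el <- igraph::as_edgelist(graph)
    write.table(data.frame(gene1 = el[, 1], gene2 = el[, 2]), file,
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}

#' @rdname io
#' @export
readEdges <- function(file) {
    buildGraph(read.delim(file, colClasses = "character"))
}

#' @rdname io
#' @param sets named list of gene sets.
#' @export
writeGmt <- function(sets, file) {
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
    writeLines(lines, file)
    invisible(NULL)
}

#' @rdname io
#' @export
readGmt <- function(file) {
    fgsea::gmtPathways(file)
}

#' @rdname io
#' @param drugs character vector of drug ids.
#' @export
writeDrugList <- function(drugs, file) {
    writeLines(drugs, file)
    invisible(NULL)
}

#' @rdname io
#' @export
readDrugList <- function(file) {
    readLines(file)
}

#' @rdname io
#' @param moa a \linkS4class{MOANetwork}.
#' @param sifFile SIF output (\code{node<TAB>pp<TAB>node}).
#' @param rolesFile node-attribute TSV (\code{node}, \code{role}).
#' @export
writeMOANetwork <- function(moa, sifFile, rolesFile) {
    el <- igraph::as_edgelist(moa@graph)
    if (nrow(el)) {
        writeLines(paste(el[, 1], "pp", el[, 2], sep = "\t"), sifFile)
    } else writeLines(character(), sifFile)
    write.table(data.frame(node = names(moa@roles), role = moa@roles),
                rolesFile, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}
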