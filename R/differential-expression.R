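#' Per-gene differential expression test
#'
#' A two-group Welch t-test per gene on log-scale values, with
#' Benjamini-Hochberg adjustment across genes. Count data are first
#' transformed to log2 counts-per-million with a pseudocount of 0.5 and
#' then tested identically. The test stage is deliberately simple and
#' pluggable: any per-gene table with the same columns can be substituted
#' downstream.
#'
#' Genes with zero variance in both groups are assigned p = 1 and flagged
#' in the \code{degenerate} column; their log2 fold change is still the
#' difference of group means.
#'
#' @param dataset an \linkS4class{ExpressionDataset} with at least two
#'   samples per group.
#' @param alpha adjusted-p significance cutoff (default 0.05).
#' @return A \code{data.frame} with one row per gene: \code{gene},
#'   \code{log2fc} (case minus control), \code{p}, \code{padj},
#'   \code{significant}, \code{degenerate}.
#' @examples
#' m <- matrix(rnorm(400), nrow = 100,
#'             dimnames = list(sprintf("g%03d", 1:100), NULL))
#' ds <- ExpressionDataset(m, rep(c("case", "control"), each = 2))
#' head(differentialTest(ds))
#' @export
differentialTest <- function(dataset, alpha = 0.05) {
    stopifnot(is(dataset, "ExpressionDataset"))
    grp <- sampleGroups(dataset)
    if (sum(grp == "case") < 2 || sum(grp == "control") < 2)
        stop("each group needs at least 2 samples")
    x <- exprsMatrix(dataset)
    if (assayKind(dataset) == "counts") {
        libSize <- colSums(x)
        x <- log2(t((t(x) + 0.5) / (libSize + 1) * 1e6))
    }
    a <- x[, grp == "case", drop = FALSE]
    b <- x[, grp == "control", drop = FALSE]
    na <- ncol(a); nb <- ncol(b)
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- rowSums((a - ma)^2) / (na - 1)
    vb <- rowSums((b - mb)^2) / (nb - 1)
    lfc <- ma - mb
    sePool <- va / na + vb / nb
    degenerate <- sePool == 0
    tstat <- ifelse(degenerate, 0, lfc / sqrt(sePool))
    df <- ifelse(degenerate, 1,
                 sePool^2 / (((va / na)^2 / (na - 1)) +
                             ((vb / nb)^2 / (nb - 1))))
    p <- ifelse(degenerate, 1, 2 * pt(-abs(tstat), df))
    padj <- bhAdjust(p)
    data.frame(gene = rownames(x), log2fc = lfc, p = p, padj = padj,
               significant = padj < alpha, degenerate = degenerate,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values in the original input
#' order (a validated front end to \code{\link[stats]{p.adjust}}).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, elementwise no smaller than the input and
#'   capped at 1.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Build a disease signature from a DEG table
#'
#' For the top-K variants, selects the K/2 most up-regulated and K/2 most
#' down-regulated significant genes by fold change (set
#' \code{split = "each"} to take K per direction instead). For the
#' articulation variant, splits the supplied articulation genes by the
#' sign of their fold change and orders each list by |log2 fold change|.
#' Fold-change ties break by smaller raw p, then gene id.
#'
#' If fewer significant genes are available than requested, all available
#' genes are returned with a warning.
#'
#' @param table a DEG table from \code{\link{differentialTest}}.
#' @param variant \code{"topK"} or \code{"articulation"}.
#' @param K total requested signature size for the top-K variant.
#' @param articulationGenes gene set for the articulation variant.
#' @param split \code{"total"} (K split evenly across directions) or
#'   \code{"each"} (K per direction).
#' @return A \linkS4class{DiseaseSignature}.
#' @export
buildSignature <- function(table, variant = c("topK", "articulation"),
                           K = 150L, articulationGenes = NULL,
                           split = c("total", "each")) {
    variant <- match.arg(variant)
    split <- match.arg(split)
    sig <- table[table$significant & !table$degenerate, , drop = FALSE]
    ord <- order(-sig$log2fc, sig$p, sig$gene)
    sig <- sig[ord, , drop = FALSE]
    if (variant == "articulation") {
        if (is.null(articulationGenes))
            stop("articulation variant requires articulationGenes")
        art <- sig[sig$gene %in% articulationGenes, , drop = FALSE]
        up <- art[art$log2fc > 0, , drop = FALSE]
        dn <- art[art$log2fc < 0, , drop = FALSE]
        return(new("DiseaseSignature", variant = "articulation",
                   up = up$gene[order(-abs(up$log2fc), up$p, up$gene)],
                   down = dn$gene[order(-abs(dn$log2fc), dn$p, dn$gene)],
                   K = NA_integer_))
    }
    kSide <- if (split == "total") ceiling(K / 2) else K
    up <- sig[sig$log2fc > 0, , drop = FALSE]
    dn <- sig[sig$log2fc < 0, , drop = FALSE]
    dn <- dn[order(dn$log2fc, dn$p, dn$gene), , drop = FALSE]  # most negative first
    if (nrow(up) < kSide || nrow(dn) < kSide)
        warning(sprintf(
            "requested %d genes per direction but only %d up / %d down significant DEGs available",
            kSide, nrow(up), nrow(dn)))
    new("DiseaseSignature", variant = paste0("top", K),
        up = head(up$gene, kSide), down = head(dn$gene, kSide),
        K = as.integer(K))
}

#' Build all four disease-signature variants for one dataset
#'
#' Convenience wrapper producing the top-K signatures for each requested K
#' plus the articulation-gene variant derived from the induced
#' differential-expression subnetwork of \code{graph}.
#'
#' @param table DEG table from \code{\link{differentialTest}}.
#' @param graph global interaction network (igraph) used to find
#'   articulation genes among the significant DEGs.
#' @param Ks integer vector of top-K sizes.
#' @param split passed to \code{\link{buildSignature}}.
#' @return Named list of \linkS4class{DiseaseSignature} objects.
#' @export
signatureVariants <- function(table, graph, Ks = c(150L, 250L, 350L),
                              split = "total") {
    degs <- table$gene[table$significant]
    sub <- inducedSubgraph(graph, degs)
    art <- articulationPoints(sub)
    out <- lapply(Ks, function(k)
        buildSignature(table, "topK", K = k, split = split))
    names(out) <- paste0("top", Ks)
    out$articulation <- buildSignature(table, "articulation",
                                       articulationGenes = art)
    out
}
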