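#' Gene-set over-representation analysis
#'
#' One-sided Fisher's exact test (hypergeometric upper tail) per gene set
#' on the 2x2 table of query membership vs set membership within the
#' universe, Benjamini-Hochberg adjustment across the collection, and a
#' combined score \code{-ln(p) x (overlap / expected overlap)} for
#' ranking, where the expected overlap is
#' \code{querySize x setSize / universeSize}.
#'
#' Query genes outside the universe are dropped with a warning.
#'
#' @param query character vector of query genes (e.g. the genes of a
#'   mode-of-action network).
#' @param collection named list of gene sets.
#' @param universe character vector of universe genes, or a single
#'   integer universe size (sets and query are then assumed in-universe).
#' @return A \code{data.frame}, one row per set: \code{set},
#'   \code{overlap}, \code{querySize}, \code{setSize},
#'   \code{universeSize}, \code{oddsRatio}, \code{p}, \code{padj},
#'   \code{combinedScore}, ordered by descending combined score.
#' @examples
#' fisherEnrichment(letters[1:5],
#'                  list(s = letters[1:10]), universe = letters[1:20])
#' @export
fisherEnrichment <- function(query, collection, universe) {
    if (length(universe) == 1 && is.numeric(universe)) {
        nU <- as.integer(universe)
    } else {
        nU <- length(unique(universe))
        drop <- setdiff(query, universe)
        if (length(drop)) {
            warning(length(drop), " query gene(s) outside the universe dropped")
            query <- intersect(query, universe)
        }
        collection <- lapply(collection, intersect, y = universe)
    }
    query <- unique(query)
    if (!length(query)) stop("query is empty after universe filtering")
    rows <- lapply(names(collection), function(nm) {
        set <- unique(collection[[nm]])
        k <- length(intersect(query, set))
        nQ <- length(query); nS <- length(set)
        # hypergeometric upper tail P(X >= k)
        p <- phyper(k - 1, nS, nU - nS, nQ, lower.tail = FALSE)
        expected <- nQ * nS / nU
        or <- (k * (nU - nS - nQ + k)) / max(1e-300, (nS - k) * (nQ - k))
        data.frame(set = nm, overlap = k, querySize = nQ, setSize = nS,
                   universeSize = nU, oddsRatio = or, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$padj <- bhAdjust(out$p)
    out$combinedScore <- mapply(combinedScore, out$p, out$overlap,
                                out$querySize * out$setSize / nU)
    out <- out[order(-out$combinedScore, out$p, out$set), ]
    rownames(out) <- NULL
    out
}

#' Combined enrichment score
#'
#' \code{-ln(p)} times the fold enrichment (observed over expected
#' overlap). Monotone increasing in both significance and enrichment
#' strength; zero when p = 1.
#'
#' @param p enrichment p-value in (0, 1].
#' @param overlap observed overlap count.
#' @param expectedOverlap expected overlap under independence (> 0).
#' @return Numeric score.
#' @examples
#' combinedScore(exp(-1), 2, 1)  # 2
#' @export
combinedScore <- function(p, overlap, expectedOverlap) {
    stopifnot(expectedOverlap > 0)
    if (p <= 0) p <- .Machine$double.xmin
    -log(p) * (overlap / expectedOverlap)
}

#' Top significant pathways
#'
#' Keeps sets with adjusted p below \code{alpha}, ranks them by
#' descending combined score and returns the first \code{topN}. Sets
#' named in \code{diseaseLabels} are flagged in the
#' \code{diseaseRelated} column.
#'
#' @param results data.frame from \code{\link{fisherEnrichment}}.
#' @param topN number of top pathways to report (default 10).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param diseaseLabels optional character vector of set names considered
#'   disease-related.
#' @return The filtered, ranked data.frame with a \code{rank} column.
#' @export
reportTop <- function(results, topN = 10L, alpha = 0.05,
                      diseaseLabels = character()) {
    sig <- results[results$padj < alpha, , drop = FALSE]
    sig <- sig[order(-sig$combinedScore, sig$p, sig$set), , drop = FALSE]
    sig <- head(sig, topN)
    if (nrow(sig)) sig$rank <- seq_len(nrow(sig))
    else sig$rank <- integer()
    sig$diseaseRelated <- sig$set %in% diseaseLabels
    rownames(sig) <- NULL
    sig
}
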