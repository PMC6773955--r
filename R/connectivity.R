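#' Order a drug signature by z-score
#'
#' Sorts a z-score vector in descending order (up-regulated genes at the
#' top) and returns the 1-based rank position of every gene, the lookup
#' \code{V(gene)} used by the connectivity statistic. Ties are broken by
#' gene id for determinism.
#'
#' @param z named numeric vector of z-scores over the gene universe.
#' @return Named integer vector of positions (a permutation of
#'   \code{1..length(z)}).
#' @export
orderSignature <- function(z) {
    if (is.null(names(z))) stop("z-scores must be named by gene")
    ord <- order(-z, names(z))
    ranks <- integer(length(z))
    ranks[ord] <- seq_along(z)
    names(ranks) <- names(z)
    ranks
}

#' Kolmogorov-Smirnov connectivity enrichment score
#'
#' The signed running-maximum statistic of connectivity-map scoring.
#' Given a query gene list and an ordered signature of \code{n} genes, let
#' \code{V(j)} be the position of the query's j-th gene after sorting the
#' query by ascending position, and \code{t} the query length. Then
#' \deqn{a = \max_j [j/t - V(j)/n], \quad
#'       b = \max_j [V(j)/n - (j-1)/t]}
#' and KS = \code{a} if \code{a > b}, else \code{-b}. A positive score
#' means the query concentrates at the top of the signature, a negative
#' score at the bottom.
#'
#' Query genes absent from the signature universe are dropped (reducing
#' \code{t}); an empty intersection yields \code{NA}.
#'
#' @param query character vector of query genes.
#' @param ranks named integer vector of signature positions from
#'   \code{\link{orderSignature}} (or any permutation of \code{1..n}).
#' @return A list with elements \code{a}, \code{b}, \code{ks} and
#'   \code{t}.
#' @examples
#' ranks <- setNames(1:10, paste0("g", 1:10))
#' ksScore("g1", ranks)$ks   #  0.9
#' ksScore("g10", ranks)$ks  # -1.0
#' @export
ksScore <- function(query, ranks) {
    n <- length(ranks)
    V <- ranks[intersect(query, names(ranks))]
    t <- length(V)
    if (t == 0)
        return(list(a = NA_real_, b = NA_real_, ks = NA_real_, t = 0L))
    V <- sort(as.numeric(V))
    j <- seq_len(t)
    a <- max(j / t - V / n)
    b <- max(V / n - (j - 1) / t)
    list(a = a, b = b, ks = if (a > b) a else -b, t = t)
}

# Columnwise KS for one query against every signature in a rank matrix
# (genes x signatures, each column a permutation of 1..n). Returns a
# numeric vector of KS scores. Used by the pipeline for speed; agrees
# with ksScore per column.
ksScoreMatrix <- function(query, rankMatrix) {
    n <- nrow(rankMatrix)
    q <- intersect(query, rownames(rankMatrix))
    t <- length(q)
    if (t == 0) return(rep(NA_real_, ncol(rankMatrix)))
    V <- rankMatrix[q, , drop = FALSE]
    V <- apply(V, 2, sort)           # t x nsig, ascending positions
    if (t == 1) V <- matrix(V, nrow = 1)
    j <- seq_len(t)
    a <- apply(j / t - V / n, 2, max)
    b <- apply(V / n - (j - 1) / t, 2, max)
    ifelse(a > b, a, -b)
}

#' Weighted connectivity score
#'
#' \code{W = KS_up - KS_down} when the two directional enrichment scores
#' disagree in sign, and 0 otherwise. A negative W indicates an
#' expression-reversing (potentially therapeutic) relation between drug
#' and disease signatures. Vectorized over its arguments.
#'
#' @param ksUp,ksDown numeric KS scores for the up- and down-regulated
#'   query lists against the same signature.
#' @return Numeric W in [-2, 2]; \code{NA} if either input is \code{NA}.
#' @examples
#' weightedConnectivity(0.5, 0.3)    # 0 (same sign)
#' weightedConnectivity(-0.6, 0.4)   # -1.0
#' @export
weightedConnectivity <- function(ksUp, ksDown) {
    ifelse(is.na(ksUp) | is.na(ksDown), NA_real_,
           ifelse(sign(ksUp) != sign(ksDown), ksUp - ksDown, 0))
}

#' Normalize weighted connectivity scores within a stratum
#'
#' Scales each W by the magnitude of the mean of its sign group within a
#' (cell line, perturbation type) stratum: positive scores are divided by
#' |mean of positive W|, negative scores by |mean of negative W|, and
#' zeros stay zero. Dividing by the magnitude (rather than the signed
#' mean) keeps the sign of every score, which the downstream tau
#' percentile relies on. If a stratum lacks positive (or negative)
#' scores, that branch passes through unscaled with a warning.
#'
#' @param W numeric vector of weighted connectivity scores.
#' @param group optional factor assigning each W to a stratum; default is
#'   a single stratum.
#' @return Numeric vector of normalized connectivity scores (NCS), same
#'   order and sign pattern as \code{W}.
#' @examples
#' normalizeNCS(c(2, 4, -3, -1))  # 0.667 1.333 -1.5 -0.5
#' @export
normalizeNCS <- function(W, group = NULL) {
    if (is.null(group)) group <- rep(1L, length(W))
    out <- rep(NA_real_, length(W))
    for (g in unique(group)) {
        idx <- which(group == g & !is.na(W))
        w <- W[idx]
        pos <- w > 0; neg <- w < 0
        muP <- if (any(pos)) mean(w[pos]) else NA_real_
        muN <- if (any(neg)) mean(w[neg]) else NA_real_
        ncs <- w
        if (any(pos)) ncs[pos] <- w[pos] / abs(muP)
        if (any(neg)) ncs[neg] <- w[neg] / abs(muN)
        if (xor(any(pos), any(neg)))
            warning("stratum ", g, " has scores of one sign only")
        out[idx] <- ncs
    }
    out
}

#' Tau: signed percentile connectivity score
#'
#' Compares one normalized connectivity score against the population of
#' scores of all drug signatures for the same query:
#' \deqn{\tau = sgn(NCS_q) \frac{100}{N} \sum_i [|NCS_i| < |NCS_q|]}
#' where N is the reference population size (the query's own score may be
#' a member; strict inequality makes it contribute zero). Tau ranges over
#' [-100, 100]; a |tau| of 90 means 10\% of all signatures show stronger
#' connectivity. Negative tau indicates expression reversal.
#'
#' @param ncsQuery the query signature's NCS (scalar).
#' @param ncsReference numeric vector of NCS values for the same query
#'   gene set across all drug signatures.
#' @return Numeric tau.
#' @examples
#' tauScore(-3, c(-3, 2, 1, 0.5, -0.2))  # -80
#' @export
tauScore <- function(ncsQuery, ncsReference) {
    if (!length(ncsReference)) stop("reference population is empty")
    if (is.na(ncsQuery)) return(NA_real_)
    ref <- ncsReference[!is.na(ncsReference)]
    sign(ncsQuery) * 100 / length(ref) * sum(abs(ref) < abs(ncsQuery))
}

#' Full connectivity scoring of a signature library against disease signatures
#'
#' For every combination of drug signature (drug x cell line) and disease
#' signature (dataset x variant), computes KS_up, KS_down, the weighted
#' connectivity score W, the stratum-normalized NCS (strata = cell line,
#' the perturbation type being constant), and the tau percentile against
#' all signatures for the same query.
#'
#' @param library a \linkS4class{SignatureLibrary}.
#' @param signatures nested list of \linkS4class{DiseaseSignature}:
#'   \code{signatures[[dataset]][[variant]]}.
#' @return A long-format \code{data.frame} with columns \code{drug},
#'   \code{cellLine}, \code{dataset}, \code{variant}, \code{ksUp},
#'   \code{ksDown}, \code{W}, \code{NCS}, \code{tau}.
#' @export
connectivityTable <- function(library, signatures) {
    stopifnot(is(library, "SignatureLibrary"))
    z <- zScores(library)
    rankMatrix <- apply(z, 2, function(col) orderSignature(setNames(col, rownames(z))))
    rownames(rankMatrix) <- rownames(z)
    nSig <- ncol(rankMatrix)
    rows <- list()
    for (ds in names(signatures)) {
        for (vn in names(signatures[[ds]])) {
            sig <- signatures[[ds]][[vn]]
            ksUp <- ksScoreMatrix(upGenes(sig), rankMatrix)
            ksDown <- ksScoreMatrix(downGenes(sig), rankMatrix)
            W <- weightedConnectivity(ksUp, ksDown)
            NCS <- normalizeNCS(W, group = signatureCells(library))
            tau <- vapply(seq_len(nSig), function(i)
                tauScore(NCS[i], NCS), numeric(1))
            rows[[paste(ds, vn)]] <- data.frame(
                drug = signatureDrugs(library),
                cellLine = signatureCells(library),
                dataset = ds, variant = vn,
                ksUp = ksUp, ksDown = ksDown, W = W, NCS = NCS,
                tau = tau, row.names = NULL,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Per-drug connectivity summary
#'
#' For every (drug, dataset): takes the minimum (most negative) tau over
#' cell lines within each signature variant, then averages the per-variant
#' minima into the drug's final connectivity score for that dataset.
#' Variants with no defined tau are excluded with a warning; drugs with no
#' defined tau at all are dropped.
#'
#' @param ct connectivity table from \code{\link{connectivityTable}}.
#' @return A \code{data.frame} with columns \code{drug}, \code{dataset},
#'   \code{meanTau} (mean over variants of the per-variant cross-cell
#'   minimum) and \code{nVariants}.
#' @export
summarizeDrug <- function(ct) {
    ok <- !is.na(ct$tau)
    if (!all(ok)) {
        warning(sum(!ok), " undefined tau value(s) excluded")
        ct <- ct[ok, , drop = FALSE]
    }
    minTau <- stats::aggregate(tau ~ drug + dataset + variant, data = ct,
                               FUN = min)
    out <- stats::aggregate(tau ~ drug + dataset, data = minTau,
                            FUN = mean)
    nv <- stats::aggregate(variant ~ drug + dataset, data = minTau,
                           FUN = length)
    names(out)[names(out) == "tau"] <- "meanTau"
    out$nVariants <- nv$variant[match(paste(out$drug, out$dataset),
                                      paste(nv$drug, nv$dataset))]
    out[order(out$dataset, out$drug), ]
}

#' Select preliminary candidate drugs
#'
#' Per dataset, the \code{floor(fraction x number of drugs)} drugs with
#' the most negative final score are taken (ties broken by drug id); the
#' per-dataset lists are then combined and drugs ranked by appearance
#' frequency (ties by more negative mean score), and the top
#' \code{consensusSize} drugs returned as preliminary candidates.
#'
#' @param scores per-drug summary from \code{\link{summarizeDrug}}.
#' @param fraction per-dataset selection fraction (default 0.05).
#' @param consensusSize consensus list size (default 38).
#' @return A \code{data.frame} of preliminary candidates with columns
#'   \code{drug}, \code{frequency}, \code{meanScore}, plus the attribute
#'   \code{"perDataset"} holding each dataset's top list.
#' @examples
#' s <- data.frame(drug = rep(paste0("d", 1:100), 2),
#'                 dataset = rep(c("a", "b"), each = 100),
#'                 meanTau = rnorm(200))
#' nrow(attr(selectCandidates(s), "perDataset")$a)  # floor(0.05*100) = 5
#' @export
selectCandidates <- function(scores, fraction = 0.05, consensusSize = 38L) {
    stopifnot(all(c("drug", "dataset", "meanTau") %in% names(scores)))
    perDataset <- lapply(split(scores, scores$dataset), function(df) {
        k <- floor(fraction * nrow(df))
        df <- df[order(df$meanTau, df$drug), , drop = FALSE]
        head(df, k)
    })
    pooled <- do.call(rbind, perDataset)
    if (is.null(pooled) || nrow(pooled) == 0) {
        out <- data.frame(drug = character(), frequency = integer(),
                          meanScore = numeric())
        attr(out, "perDataset") <- perDataset
        return(out)
    }
    freq <- table(pooled$drug)
    meanScore <- tapply(pooled$meanTau, pooled$drug, mean)
    out <- data.frame(drug = names(freq),
                      frequency = as.integer(freq),
                      meanScore = as.numeric(meanScore[names(freq)]),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$frequency, out$meanScore, out$drug), ]
    if (consensusSize > nrow(out))
        message("fewer distinct drugs (", nrow(out),
                ") than requested consensus size ", consensusSize)
    out <- head(out, consensusSize)
    rownames(out) <- NULL
    attr(out, "perDataset") <- perDataset
    out
}
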