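## log marginal likelihood of (m matches, u non-matches) under a
## Beta(a, b) prior on the match probability, relative to the prior:
## ln B(a+m, b+u) - ln B(a, b). Counts may be non-integer (weighted mass).
lbb <- function(m, u, a, b) {
    lbeta(a + m, b + u) - lbeta(a, b)
}

#' Weighted residue composition of an alignment
#'
#' Pooled weighted frequencies of the 20 amino acids over the whole
#' alignment (gaps and `X` excluded), with a 0.5 pseudocount per residue so
#' every amino acid has nonzero probability. This composition supplies the
#' null residue-set probability `q` of the contrast model.
#'
#' @param msa a [ProteinMSA-class].
#' @return Named numeric of length 20 summing to 1.
#' @export
alignmentComposition <- function(msa) {
    stopifnot(is(msa, "ProteinMSA"))
    code <- encodeResidues(residueMatrix(msa))
    w <- seqWeights(msa)
    counts <- setNames(rep(0.5, 20L), AA20)
    for (a in seq_len(20L))
        counts[a] <- counts[a] + sum(w * rowSums(code == a))
    counts / sum(counts)
}

#' Weighted foreground/background match counts at one column
#'
#' Tallies the weighted mass of foreground and background sequences whose
#' residue at `column` belongs to the residue set (`mF`, `mB`) and the
#' remaining mass (`uF`, `uB`). Gaps and `X` always accrue to the non-match
#' mass.
#'
#' @param msa a [ProteinMSA-class] (weights used if present).
#' @param fg,bg disjoint character vectors of sequence ids.
#' @param column alignment column (1-based).
#' @param rset character vector of amino acids (the pattern residue set).
#' @return List with numeric `mF`, `uF`, `mB`, `uB`.
#' @export
columnCounts <- function(msa, fg, bg, column, rset) {
    stopifnot(is(msa, "ProteinMSA"))
    if (length(fg) == 0L) stop("empty foreground")
    if (length(bg) == 0L) stop("empty background")
    if (length(intersect(fg, bg))) stop("fg and bg must be disjoint")
    if (column < 1L || column > alignmentLength(msa))
        stop("column out of range")
    if (!all(rset %in% AA20))
        stop("residue set must contain amino acids only")
    w <- seqWeights(msa)
    res <- residueMatrix(msa)[, column]
    hit <- setNames(res %in% rset, names(res))
    list(mF = sum(w[fg][hit[fg]]), uF = sum(w[fg][!hit[fg]]),
         mB = sum(w[bg][hit[bg]]), uB = sum(w[bg][!hit[bg]]))
}

#' Per-column contrast evidence in nats
#'
#' The position's contribution to the posterior log-likelihood ratio of the
#' contrast model: a three-part beta-binomial Bayes factor comparing (i)
#' foreground match counts under the high-conservation Beta(aF, bF) prior and
#' (ii) background counts under the composition-matched null Beta(A q,
#' A(1-q)), against (iii) the pooled counts under the same null,
#'
#' `LLR = lbb(mF, uF; aF, bF) + lbb(mB, uB; Aq, A(1-q))
#'        - lbb(mF+mB, uF+uB; Aq, A(1-q))`
#'
#' with `lbb(m, u; a, b) = ln B(a+m, b+u) - ln B(a, b)`. Positive values mean
#' the column separates a conserved foreground from a divergent background.
#'
#' @param counts list with `mF`, `uF`, `mB`, `uB` (weighted, nonnegative),
#'   as returned by [columnCounts()].
#' @param priors a [PriorConfig-class].
#' @param q pooled probability of the residue set under the alignment
#'   composition, in (0, 1).
#' @return Evidence in nats (finite).
#' @export
columnLLR <- function(counts, priors = PriorConfig(), q) {
    with(counts, {
        if (any(c(mF, uF, mB, uB) < 0)) stop("negative counts")
        if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
        A <- priors@nullConcentration
        lbb(mF, uF, priors@fgPrior[1L], priors@fgPrior[2L]) +
            lbb(mB, uB, A * q, A * (1 - q)) -
            lbb(mF + mB, uF + uB, A * q, A * (1 - q))
    })
}

## Vectorized llr over parallel count vectors and q vector.
columnLLRVec <- function(mF, uF, mB, uB, priors, q) {
    A <- priors@nullConcentration
    lbb(mF, uF, priors@fgPrior[1L], priors@fgPrior[2L]) +
        lbb(mB, uB, A * q, A * (1 - q)) -
        lbb(mF + mB, uF + uB, A * q, A * (1 - q))
}

## 20 x L matrix of weighted amino-acid mass per column for the given
## (integer) row indices of a coded alignment.
weightedCountMatrix <- function(code, w, rows) {
    sub <- code[rows, , drop = FALSE]
    wr <- w[rows]
    out <- matrix(0, 20L, ncol(code), dimnames = list(AA20, NULL))
    for (a in seq_len(20L))
        out[a, ] <- colSums(wr * (sub == a))
    out
}

## Best nested residue set at one column given precomputed foreground and
## background count matrices. Returns NULL if the foreground has no residue
## mass at the column, or (with minFgFreq > 0) when no candidate set is
## conserved in the foreground. `incumbent` (a residue set) is also evaluated
## when supplied, so a refreshed position can never lose evidence.
bestSetAtColumn <- function(cf, cb, totF, totB, priors, comp,
                            incumbent = NULL, minFgFreq = 0) {
    ord <- order(-cf, seq_len(20L))
    if (cf[ord[1L]] <= 0)
        return(NULL)
    kmax <- min(priors@maxSetSize, sum(cf > 0))
    ks <- seq_len(kmax)
    mF <- cumsum(cf[ord])[ks]
    mB <- cumsum(cb[ord])[ks]
    q <- pmin(cumsum(comp[ord])[ks], 1 - 1e-9)
    llr <- columnLLRVec(mF, totF - mF, mB, totB - mB, priors, q)
    ok <- mF / totF >= minFgFreq
    if (!any(ok))
        return(NULL)
    llr[!ok] <- -Inf
    best <- which(llr > max(llr) - 1e-12)[1L]   # ties -> smaller set
    set <- AA20[sort(ord[seq_len(best)])]
    bestLLR <- llr[best]
    if (!is.null(incumbent)) {
        idx <- match(incumbent, AA20)
        mFi <- sum(cf[idx]); mBi <- sum(cb[idx])
        qi <- min(sum(comp[idx]), 1 - 1e-9)
        if (mFi / totF >= minFgFreq) {
            llri <- columnLLRVec(mFi, totF - mFi, mBi, totB - mBi,
                                 priors, qi)
            if (llri > bestLLR + 1e-12) {
                set <- sort(incumbent)
                bestLLR <- llri
            }
        }
    }
    if (!is.finite(bestLLR))
        return(NULL)
    list(set = set, nats = unname(bestLLR))
}

#' Best discriminating residue set at a column
#'
#' Ranks foreground residues by weighted frequency and evaluates the nested
#' candidate sets `{top1}`, `{top1, top2}`, ... up to `maxSetSize`, returning
#' the set with the highest contrast evidence ([columnLLR()]); ties go to the
#' smaller set.
#'
#' @inheritParams columnCounts
#' @param priors a [PriorConfig-class].
#' @param composition optional precomputed [alignmentComposition()].
#' @param minConservation minimum weighted foreground frequency a candidate
#'   set must reach (default 0: pure evidence maximisation; the sampler's
#'   pattern sweep uses the prior's `minConservation`).
#' @return List with `set` (character vector) and `nats`, or `NULL` when the
#'   foreground carries no residue at the column (all gap/`X`) or no
#'   candidate reaches `minConservation`.
#' @export
bestResidueSet <- function(msa, fg, bg, column, priors = PriorConfig(),
                           composition = NULL, minConservation = 0) {
    stopifnot(is(msa, "ProteinMSA"))
    if (length(fg) == 0L) stop("empty foreground")
    if (is.null(composition)) composition <- alignmentComposition(msa)
    code <- encodeResidues(residueMatrix(msa))
    w <- seqWeights(msa)
    fgi <- match(fg, msaIds(msa))
    bgi <- match(bg, msaIds(msa))
    cf <- weightedCountMatrix(code, w, fgi)[, column]
    cb <- weightedCountMatrix(code, w, bgi)[, column]
    bestSetAtColumn(cf, cb, sum(w[fgi]), sum(w[bgi]), priors, composition,
                    minFgFreq = minConservation)
}

#' Total log posterior of a sampler state
#'
#' Sums, over categories, the per-position contrast evidence of the current
#' pattern plus the pattern-size prior `ln(rho/(1-rho))` per included column,
#' and adds the (uniform) assignment prior over subgroup rows for non-seed
#' sequences. Recomputed from scratch; the sampler asserts its incremental
#' bookkeeping against this value.
#'
#' @param state a [SamplerState-class].
#' @param hp a [Hyperpartition-class].
#' @param msa the [ProteinMSA-class] being classified.
#' @param priors a [PriorConfig-class].
#' @param composition optional precomputed [alignmentComposition()].
#' @return Log posterior (finite).
#' @export
totalLogPosterior <- function(state, hp, msa, priors = PriorConfig(),
                              composition = NULL) {
    stopifnot(is(state, "SamplerState"))
    if (is.null(composition)) composition <- alignmentComposition(msa)
    assign <- assignments(state)
    w <- seqWeights(msa)
    pen <- inclusionPenalty(priors)
    total <- 0
    for (cat in categoryNames(hp)) {
        p <- statePatterns(state)[[cat]]
        if (is.null(p) || patternSize(p) == 0L) next
        parts <- categoryPartitions(hp, cat)
        fg <- names(assign)[assign %in% parts$fg]
        bg <- names(assign)[assign %in% parts$bg]
        if (length(fg) == 0L || length(bg) == 0L) next
        for (k in seq_len(patternSize(p))) {
            col <- p@columns[k]
            set <- p@residueSets[[k]]
            cnt <- columnCounts(msa, fg, bg, col, set)
            q <- min(sum(composition[set]), 1 - 1e-9)
            total <- total + columnLLR(cnt, priors, q) + pen
        }
    }
    nonSeed <- setdiff(msaIds(msa), state@seedIds)
    total - length(nonSeed) * log(nrow(hpCells(hp)))
}
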