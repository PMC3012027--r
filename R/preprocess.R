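#' Pairwise percent identity of two aligned residue strings
#'
#' Identity is the fraction of matching residues over columns where both
#' sequences are non-gap; a fragment aligned to a full-length sequence is
#' therefore judged only on its own span. `X` compares like any residue
#' (identical bytes match). Returns 0 when the two sequences share no
#' jointly non-gap column.
#'
#' @param a,b aligned residue strings of equal length.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' percentIdentity("AC-D", "AAGD")  # columns 1,2,4 compared -> 2/3
#' @export
percentIdentity <- function(a, b) {
    if (nchar(a) != nchar(b))
        stop("unequal lengths: ", nchar(a), " vs ", nchar(b))
    av <- strsplit(a, "", fixed = TRUE)[[1L]]
    bv <- strsplit(b, "", fixed = TRUE)[[1L]]
    both <- av != GAP & bv != GAP
    if (!any(both)) return(0)
    sum(av[both] == bv[both]) / sum(both)
}

## identity of one coded row against many coded rows (vectorized over rows)
identityToMany <- function(row, mat) {
    gapCode <- match(GAP, ALPHABET)
    rowNonGap <- row != gapCode
    apply(mat, 1L, function(r) {
        both <- rowNonGap & r != gapCode
        n <- sum(both)
        if (n == 0L) 0 else sum(row[both] == r[both]) / n
    })
}

#' Purge fragments and near-identical sequences
#'
#' Applies the two-stage redundancy purge used before sampling: sequences with
#' fewer than `minResidues` non-gap residues or covering less than
#' `minCoverage` of the alignment columns are removed as fragments; the
#' remainder is filtered greedily in input order, keeping a sequence only if
#' its identity to every previously kept sequence is at or below
#' `identityThreshold` (so ">98% identical" pairs lose their later member
#' under the defaults).
#'
#' @param msa a [ProteinMSA-class].
#' @param cfg a [PreprocessConfig-class].
#' @return A list with `msa` (the purged [ProteinMSA-class]) and `removed`
#'   (data.frame of columns `id`, `reason`; reason is `"fragment"` or
#'   `"redundant:<kept_id>"`).
#' @export
purgeAlignment <- function(msa, cfg = PreprocessConfig()) {
    stopifnot(is(msa, "ProteinMSA"), is(cfg, "PreprocessConfig"))
    mat <- encodeResidues(residueMatrix(msa))
    gapCode <- match(GAP, ALPHABET)
    ids <- msaIds(msa)
    nres <- rowSums(mat != gapCode)
    isFragment <- nres < cfg@minResidues |
        nres / ncol(mat) < cfg@minCoverage
    removedId <- ids[isFragment]
    removedReason <- rep("fragment", sum(isFragment))

    keep <- character(0)
    keptIdx <- integer(0)
    for (k in which(!isFragment)) {
        if (length(keptIdx)) {
            idn <- identityToMany(mat[k, ], mat[keptIdx, , drop = FALSE])
            hit <- which(idn > cfg@identityThreshold)
            if (length(hit)) {
                removedId <- c(removedId, ids[k])
                removedReason <- c(removedReason,
                                   paste0("redundant:", ids[keptIdx[hit[1L]]]))
                next
            }
        }
        keptIdx <- c(keptIdx, k)
        keep <- c(keep, ids[k])
    }
    if (length(keep) == 0L)
        stop("empty after purge")
    removed <- data.frame(id = removedId, reason = removedReason,
                          stringsAsFactors = FALSE)
    ## report removals in input order
    removed <- removed[order(match(removed$id, ids)), , drop = FALSE]
    rownames(removed) <- NULL
    list(msa = subsetSequences(msa, keep), removed = removed)
}

#' Write a purge removal log as TSV
#'
#' @param removed the `removed` data.frame from [purgeAlignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRemovalLog <- function(removed, path) {
    write.table(removed, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Position-based (Henikoff) redundancy down-weights
#'
#' Computes the PSI-BLAST-style position-based sequence weights: in each
#' column a sequence receives `1/(r*s)` where `r` is the number of distinct
#' symbols in the column (gaps and `X` count as symbol types) and `s` the
#' number of sequences carrying that sequence's symbol; the raw per-sequence
#' weight is the mean over columns, rescaled so the weights have mean 1.
#'
#' @param msa a [ProteinMSA-class].
#' @return The same [ProteinMSA-class] with weights attached.
#' @examples
#' msa <- ProteinMSA(c(a = "ACDA", b = "ACDA", c = "AWGV"))
#' seqWeights(computeWeights(msa))
#' @export
computeWeights <- function(msa) {
    stopifnot(is(msa, "ProteinMSA"))
    mat <- encodeResidues(residueMatrix(msa))
    n <- nrow(mat)
    raw <- numeric(n)
    for (j in seq_len(ncol(mat))) {
        col <- mat[, j]
        counts <- tabulate(col, nbins = length(ALPHABET))
        r <- sum(counts > 0L)
        raw <- raw + 1 / (r * counts[col])
    }
    raw <- raw / ncol(mat)
    w <- raw / mean(raw)
    new("ProteinMSA", mat = residueMatrix(msa), weights = unname(w))
}
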