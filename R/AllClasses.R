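#' ProteinMSA: an aligned set of protein sequences
#'
#' Container for a fixed-width protein multiple sequence alignment. Residues
#' are stored as a character matrix (one row per sequence, one column per
#' alignment column) over the alphabet returned by [residueAlphabet()].
#' Per-sequence redundancy down-weights (mean 1 across sequences) are optional
#' and attached by [computeWeights()].
#'
#' @slot mat character matrix of residues; rownames are the sequence ids.
#' @slot weights numeric vector of per-sequence weights (length 0 until
#'   computed; otherwise one positive value per sequence, mean 1).
#' @export
setClass("ProteinMSA",
    representation(mat = "matrix", weights = "numeric"),
    prototype(mat = matrix(character(0), 0, 0), weights = numeric(0)))

setValidity("ProteinMSA", function(object) {
    msgs <- character(0)
    m <- object@mat
    if (!is.character(m))
        msgs <- c(msgs, "residue matrix must be character")
    ids <- rownames(m)
    if (nrow(m) > 0 && (is.null(ids) || anyDuplicated(ids)))
        msgs <- c(msgs, "sequence ids must be present and unique")
    if (length(m) && !all(m %in% ALPHABET))
        msgs <- c(msgs, "residues outside the 20 amino acids + 'X' + '-'")
    w <- object@weights
    if (length(w)) {
        if (length(w) != nrow(m))
            msgs <- c(msgs, "weights length must equal number of sequences")
        else if (any(!is.finite(w)) || any(w <= 0))
            msgs <- c(msgs, "weights must be positive and finite")
        else if (abs(mean(w) - 1) > 1e-8)
            msgs <- c(msgs, "weights must have mean 1")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a ProteinMSA from aligned sequence strings
#'
#' @param seqs named character vector of equal-length aligned sequences.
#'   Lowercase letters are uppercased, '.' becomes '-', and characters outside
#'   the alphabet become 'X'.
#' @param weights optional per-sequence weights (positive, mean 1).
#' @return A [ProteinMSA-class] object.
#' @examples
#' msa <- ProteinMSA(c(s1 = "AC-D", s2 = "ACGD"))
#' alignmentLength(msa)
#' @export
ProteinMSA <- function(seqs, weights = numeric(0)) {
    if (length(seqs) == 0L)
        stop("no sequences")
    ids <- names(seqs)
    if (is.null(ids) || any(ids == ""))
        stop("all sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
        stop("ragged alignment: sequence '",
             ids[which(lens != lens[1L])[1L]],
             "' has length ", lens[which(lens != lens[1L])[1L]],
             ", expected ", lens[1L])
    if (anyDuplicated(ids))
        stop("duplicate identifier: '", ids[duplicated(ids)][1L], "'")
    mat <- matrix(normalizeResidues(unlist(strsplit(seqs, "", fixed = TRUE),
                                           use.names = FALSE)),
                  nrow = length(seqs), byrow = TRUE,
                  dimnames = list(ids, NULL))
    new("ProteinMSA", mat = mat, weights = as.numeric(weights))
}

#' @describeIn ProteinMSA-class sequence identifiers, in input order.
#' @param x,object a `ProteinMSA`.
#' @export
msaIds <- function(x) rownames(x@mat)

#' @describeIn ProteinMSA-class number of sequences.
#' @export
nSequences <- function(x) nrow(x@mat)

#' @describeIn ProteinMSA-class number of alignment columns.
#' @export
alignmentLength <- function(x) ncol(x@mat)

#' @describeIn ProteinMSA-class residue character matrix (rows = sequences).
#' @export
residueMatrix <- function(x) x@mat

#' @describeIn ProteinMSA-class per-sequence redundancy weights; unit weights
#'   are returned when none have been computed yet.
#' @export
seqWeights <- function(x) {
    if (length(x@weights)) setNames(x@weights, msaIds(x))
    else setNames(rep(1, nSequences(x)), msaIds(x))
}

#' @describeIn ProteinMSA-class whether weights have been computed.
#' @export
hasWeights <- function(x) length(x@weights) > 0L

#' @describeIn ProteinMSA-class subset sequences by id or index, keeping
#'   weights (renormalised to mean 1).
#' @param i sequence ids or indices.
#' @export
subsetSequences <- function(x, i) {
    mat <- x@mat[i, , drop = FALSE]
    w <- if (hasWeights(x)) {
        wi <- seqWeights(x)[i]
        wi / mean(wi)
    } else numeric(0)
    new("ProteinMSA", mat = mat, weights = unname(w))
}

## Aligned residue strings, one per sequence.
msaStrings <- function(x) {
    setNames(apply(x@mat, 1L, paste, collapse = ""), msaIds(x))
}

setMethod("show", "ProteinMSA", function(object) {
    cat("ProteinMSA with", nSequences(object), "sequences x",
        alignmentLength(object), "columns",
        if (hasWeights(object)) "(weighted)\n" else "\n")
    ids <- head(msaIds(object), 3L)
    for (id in ids) {
        s <- paste(object@mat[id, seq_len(min(50L, alignmentLength(object)))],
                   collapse = "")
        cat(" ", id, " ", s,
            if (alignmentLength(object) > 50L) "...\n" else "\n", sep = "")
    }
    if (nSequences(object) > 3L) cat("  ...\n")
})

#' SeedAlignment: curated sequences anchoring one subgroup
#'
#' A small aligned set of sequences known to belong to a subgroup. Seeds act
#' as Bayesian priors: seed sequences present in the main alignment stay
#' pinned to their subgroup throughout sampling. A seed may be a consensus
#' sequence rather than a real protein.
#'
#' @slot subgroupName label of the subgroup the seeds define.
#' @slot msa a [ProteinMSA-class] whose column count matches the main
#'   alignment.
#' @slot isConsensus logical flag.
#' @export
setClass("SeedAlignment",
    representation(subgroupName = "character", msa = "ProteinMSA",
                   isConsensus = "logical"),
    prototype(isConsensus = FALSE))

setValidity("SeedAlignment", function(object) {
    msgs <- character(0)
    if (length(object@subgroupName) != 1L || !nzchar(object@subgroupName))
        msgs <- c(msgs, "subgroupName must be a single non-empty string")
    if (nSequences(object@msa) < 1L)
        msgs <- c(msgs, "seed alignment needs at least one sequence")
    if (length(msgs)) msgs else TRUE
})

#' @rdname SeedAlignment-class
#' @param subgroupName,msa,isConsensus see slots.
#' @export
SeedAlignment <- function(subgroupName, msa, isConsensus = FALSE) {
    new("SeedAlignment", subgroupName = subgroupName, msa = msa,
        isConsensus = isConsensus)
}

setMethod("show", "SeedAlignment", function(object) {
    cat("SeedAlignment '", object@subgroupName, "': ",
        nSequences(object@msa), " sequence(s)",
        if (object@isConsensus) " [consensus]\n" else "\n", sep = "")
})

#' Hyperpartition: the N x M foreground/background/omit scheme
#'
#' Each row is a sequence subgroup and each column a contrast category. The
#' cell symbol assigns the subgroup to that category's foreground (`"+"`),
#' background (`"-"`) or non-participating set (`"o"`). A row named
#' `"Rejected"` is the sink for aberrant/random sequences; it never has a
#' foreground cell. Rows flagged miscellaneous correspond to internal tree
#' nodes (sequences in a clade but in none of its leaf subfamilies).
#'
#' @slot cells character matrix of `"+"`, `"-"`, `"o"`; rownames are subgroup
#'   names, colnames category names.
#' @slot miscFlags named logical, one per subgroup.
#' @export
setClass("Hyperpartition",
    representation(cells = "matrix", miscFlags = "logical"))

setValidity("Hyperpartition", function(object) {
    msgs <- character(0)
    cells <- object@cells
    if (!is.character(cells) || is.null(rownames(cells)) ||
        is.null(colnames(cells)))
        msgs <- c(msgs, "cells must be a named character matrix")
    else {
        if (!all(cells %in% c("+", "-", "o")))
            msgs <- c(msgs, "cells must be '+', '-' or 'o'")
        if (anyDuplicated(rownames(cells)))
            msgs <- c(msgs, "duplicate subgroup names")
        if (anyDuplicated(colnames(cells)))
            msgs <- c(msgs, "duplicate category names")
        if (length(object@miscFlags) != nrow(cells))
            msgs <- c(msgs, "miscFlags must have one entry per subgroup")
    }
    if (length(msgs)) msgs else TRUE
})

#' @rdname Hyperpartition-class
#' @param cells,miscFlags see slots.
#' @param addRejected append an all-'o' "Rejected" row when none is present.
#' @export
Hyperpartition <- function(cells, miscFlags = NULL, addRejected = TRUE) {
    if (is.null(miscFlags))
        miscFlags <- setNames(rep(FALSE, nrow(cells)), rownames(cells))
    if (addRejected && !("Rejected" %in% rownames(cells))) {
        cells <- rbind(cells, Rejected = rep("o", ncol(cells)))
        miscFlags <- c(miscFlags, Rejected = FALSE)
    }
    new("Hyperpartition", cells = cells, miscFlags = miscFlags)
}

#' @describeIn Hyperpartition-class subgroup (row) names.
#' @param x,object a `Hyperpartition`.
#' @export
subgroupNames <- function(x) rownames(x@cells)

#' @describeIn Hyperpartition-class category (column) names.
#' @export
categoryNames <- function(x) colnames(x@cells)

#' @describeIn Hyperpartition-class the symbol matrix.
#' @export
hpCells <- function(x) x@cells

#' @describeIn Hyperpartition-class named logical of miscellaneous-subgroup
#'   flags.
#' @export
miscFlags <- function(x) x@miscFlags

#' @describeIn Hyperpartition-class name of the rejected row, or `NA` if
#'   absent.
#' @export
rejectedName <- function(x) {
    if ("Rejected" %in% rownames(x@cells)) "Rejected" else NA_character_
}

setMethod("show", "Hyperpartition", function(object) {
    cells <- object@cells
    cat("Hyperpartition: ", nrow(cells), " subgroups x ", ncol(cells),
        " categories\n", sep = "")
    pat <- apply(cells, 1L, paste, collapse = "")
    nm <- rownames(cells)
    nm[object@miscFlags] <- paste0(nm[object@miscFlags], "*")
    for (k in seq_along(pat))
        cat(sprintf("  %-16s %s\n", nm[k], pat[k]))
    if (any(object@miscFlags)) cat("  (* = miscellaneous subgroup)\n")
})

#' PriorConfig: hyperparameters of the column contrast model
#'
#' Per pattern column the model contrasts three beta-binomial marginal
#' likelihoods: foreground match counts under a high-conservation Beta(aF, bF)
#' prior, background counts under a composition-matched null Beta(A q, A(1-q))
#' (q = pooled probability of the residue set), and pooled counts under the
#' same null. Pattern size is penalised by an independent Bernoulli(rho)
#' column-inclusion prior.
#'
#' @slot fgPrior numeric(2): Beta pseudocounts (aF, bF) for the foreground
#'   match probability; default c(9, 1), i.e. a 90% conservation prior.
#' @slot nullConcentration concentration A of the null Beta; default 20.
#' @slot rho prior per-column pattern inclusion probability; default 0.02.
#' @slot maxSetSize maximum residues in a pattern residue set; default 4.
#' @slot minConservation minimum weighted foreground frequency of a residue
#'   set for the sampler to accept the position as a pattern position
#'   (default 0.5). This is the operational meaning of "conserved in the
#'   foreground": a pattern residue must be carried by a weighted majority of
#'   the foreground, which keeps positions that merely differ between
#'   foreground and background (without being conserved) out of the pattern.
#' @export
setClass("PriorConfig",
    representation(fgPrior = "numeric", nullConcentration = "numeric",
                   rho = "numeric", maxSetSize = "integer",
                   minConservation = "numeric"),
    prototype(fgPrior = c(9, 1), nullConcentration = 20, rho = 0.02,
              maxSetSize = 4L, minConservation = 0.5))

setValidity("PriorConfig", function(object) {
    msgs <- character(0)
    if (length(object@fgPrior) != 2L || any(object@fgPrior <= 0))
        msgs <- c(msgs, "fgPrior must be two positive pseudocounts")
    if (object@nullConcentration <= 0)
        msgs <- c(msgs, "nullConcentration must be positive")
    if (object@rho <= 0 || object@rho >= 1)
        msgs <- c(msgs, "rho must be in (0, 1)")
    if (object@maxSetSize < 1L)
        msgs <- c(msgs, "maxSetSize must be >= 1")
    if (object@minConservation < 0 || object@minConservation >= 1)
        msgs <- c(msgs, "minConservation must be in [0, 1)")
    if (length(msgs)) msgs else TRUE
})

#' @rdname PriorConfig-class
#' @param fgPrior,nullConcentration,rho,maxSetSize,minConservation see slots.
#' @export
PriorConfig <- function(fgPrior = c(9, 1), nullConcentration = 20,
                        rho = 0.02, maxSetSize = 4L,
                        minConservation = 0.5) {
    new("PriorConfig", fgPrior = as.numeric(fgPrior),
        nullConcentration = as.numeric(nullConcentration),
        rho = as.numeric(rho), maxSetSize = as.integer(maxSetSize),
        minConservation = as.numeric(minConservation))
}

## log prior odds of including a column in the pattern
inclusionPenalty <- function(priors) log(priors@rho / (1 - priors@rho))

#' PreprocessConfig: fragment and redundancy purge settings
#'
#' @slot identityThreshold retained pairs must share identity at or below this
#'   fraction (default 0.98, i.e. ">98% identical" sequences are purged).
#' @slot minResidues minimum non-gap residues per sequence (default 100).
#' @slot minCoverage minimum fraction of alignment columns that are non-gap
#'   (default 0.5); sequences below either bound are fragments.
#' @export
setClass("PreprocessConfig",
    representation(identityThreshold = "numeric", minResidues = "integer",
                   minCoverage = "numeric"),
    prototype(identityThreshold = 0.98, minResidues = 100L,
              minCoverage = 0.5))

setValidity("PreprocessConfig", function(object) {
    msgs <- character(0)
    if (object@identityThreshold <= 0 || object@identityThreshold > 1)
        msgs <- c(msgs, "identityThreshold must be in (0, 1]")
    if (object@minResidues < 1L)
        msgs <- c(msgs, "minResidues must be >= 1")
    if (object@minCoverage <= 0 || object@minCoverage > 1)
        msgs <- c(msgs, "minCoverage must be in (0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' @rdname PreprocessConfig-class
#' @param identityThreshold,minResidues,minCoverage see slots.
#' @export
PreprocessConfig <- function(identityThreshold = 0.98, minResidues = 100L,
                             minCoverage = 0.5) {
    new("PreprocessConfig", identityThreshold = as.numeric(identityThreshold),
        minResidues = as.integer(minResidues),
        minCoverage = as.numeric(minCoverage))
}

#' SamplerConfig: Gibbs sampler schedule
#'
#' @slot maxSweeps maximum number of assignment+pattern sweeps (default 500).
#' @slot patience consecutive zero-change sweeps required to declare
#'   convergence (default 3).
#' @slot tempStart initial temperature in sample mode (default 2).
#' @slot annealFactor geometric cooling factor per sweep (default 0.98);
#'   sampling anneals toward the greedy limit.
#' @slot mode `"sample"` (annealed Gibbs) or `"greedy"` (deterministic
#'   conditional argmax).
#' @slot rngSeed integer seed controlling the whole trajectory.
#' @export
setClass("SamplerConfig",
    representation(maxSweeps = "integer", patience = "integer",
                   tempStart = "numeric", annealFactor = "numeric",
                   mode = "character", rngSeed = "integer"),
    prototype(maxSweeps = 500L, patience = 3L, tempStart = 2,
              annealFactor = 0.98, mode = "sample", rngSeed = 1L))

setValidity("SamplerConfig", function(object) {
    msgs <- character(0)
    if (object@maxSweeps < 1L) msgs <- c(msgs, "maxSweeps must be >= 1")
    if (object@patience < 1L) msgs <- c(msgs, "patience must be >= 1")
    if (!(object@mode %in% c("sample", "greedy")))
        msgs <- c(msgs, "mode must be 'sample' or 'greedy'")
    if (object@annealFactor <= 0 || object@annealFactor > 1)
        msgs <- c(msgs, "annealFactor must be in (0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' @rdname SamplerConfig-class
#' @param maxSweeps,patience,tempStart,annealFactor,mode,rngSeed see slots.
#' @export
SamplerConfig <- function(maxSweeps = 500L, patience = 3L, tempStart = 2,
                          annealFactor = 0.98, mode = c("sample", "greedy"),
                          rngSeed = 1L) {
    new("SamplerConfig", maxSweeps = as.integer(maxSweeps),
        patience = as.integer(patience), tempStart = as.numeric(tempStart),
        annealFactor = as.numeric(annealFactor), mode = match.arg(mode),
        rngSeed = as.integer(rngSeed))
}

#' Pattern: one category's discriminating residue pattern
#'
#' A set of alignment columns, each with a residue set (the amino acids that
#' count as a foreground match there) and a strength: the position's
#' contribution in nats to the posterior log-likelihood ratio.
#'
#' @slot category category name.
#' @slot columns integer alignment columns (1-based, distinct).
#' @slot residueSets list of character vectors, one per column.
#' @slot nats numeric per-column strengths.
#' @export
setClass("Pattern",
    representation(category = "character", columns = "integer",
                   residueSets = "list", nats = "numeric"))

setValidity("Pattern", function(object) {
    msgs <- character(0)
    k <- length(object@columns)
    if (anyDuplicated(object@columns))
        msgs <- c(msgs, "pattern columns must be distinct")
    if (length(object@residueSets) != k || length(object@nats) != k)
        msgs <- c(msgs, "columns, residueSets and nats must align")
    if (k && any(!is.finite(object@nats)))
        msgs <- c(msgs, "nats must be finite")
    bad <- vapply(object@residueSets, function(s) {
        length(s) == 0L || anyDuplicated(s) > 0L || !all(s %in% AA20)
    }, logical(1))
    if (any(bad))
        msgs <- c(msgs, "residue sets must be nonempty distinct amino acids")
    if (length(msgs)) msgs else TRUE
})

#' @rdname Pattern-class
#' @param category,columns,residueSets,nats see slots.
#' @export
Pattern <- function(category, columns = integer(0), residueSets = list(),
                    nats = numeric(0)) {
    new("Pattern", category = category, columns = as.integer(columns),
        residueSets = residueSets, nats = as.numeric(nats))
}

#' @describeIn Pattern-class number of pattern positions.
#' @param x,object a `Pattern`.
#' @export
patternSize <- function(x) length(x@columns)

#' @describeIn Pattern-class pattern columns.
#' @export
patternColumns <- function(x) x@columns

#' @describeIn Pattern-class residue sets, named by column.
#' @export
patternResidueSets <- function(x) setNames(x@residueSets, x@columns)

#' @describeIn Pattern-class per-position strengths in nats, named by column.
#' @export
patternNats <- function(x) setNames(x@nats, x@columns)

setMethod("show", "Pattern", function(object) {
    cat("Pattern for category '", object@category, "': ",
        patternSize(object), " positions\n", sep = "")
    if (patternSize(object)) {
        o <- order(-object@nats, object@columns)
        for (k in head(o, 8L)) {
            cat(sprintf("  col %4d  [%s]  %.2f nats\n", object@columns[k],
                        paste(object@residueSets[[k]], collapse = ""),
                        object@nats[k]))
        }
        if (patternSize(object) > 8L) cat("  ...\n")
    }
})

#' SamplerState: assignment, patterns and posterior of one sampler iteration
#'
#' @slot assignment named character: sequence id -> subgroup row (including
#'   "Rejected").
#' @slot patterns named list of [Pattern-class], one per category.
#' @slot logPosterior total log posterior of the state.
#' @slot iteration sweep counter at which the state was recorded.
#' @slot rngSeed seed of the run that produced the state.
#' @slot seedIds ids pinned to their subgroup (seed sequences present in the
#'   main alignment).
#' @export
setClass("SamplerState",
    representation(assignment = "character", patterns = "list",
                   logPosterior = "numeric", iteration = "integer",
                   rngSeed = "integer", seedIds = "character"),
    prototype(logPosterior = NA_real_, iteration = 0L, rngSeed = NA_integer_,
              seedIds = character(0)))

setValidity("SamplerState", function(object) {
    msgs <- character(0)
    if (length(object@assignment) && is.null(names(object@assignment)))
        msgs <- c(msgs, "assignment must be named by sequence id")
    if (length(object@patterns) && is.null(names(object@patterns)))
        msgs <- c(msgs, "patterns must be named by category")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn SamplerState-class named assignment vector.
#' @param x,object a `SamplerState`.
#' @export
assignments <- function(x) x@assignment

#' @describeIn SamplerState-class list of per-category patterns.
#' @export
statePatterns <- function(x) x@patterns

#' @describeIn SamplerState-class total log posterior.
#' @export
logPosterior <- function(x) x@logPosterior

setMethod("show", "SamplerState", function(object) {
    cat("SamplerState at sweep ", object@iteration, ": log posterior ",
        sprintf("%.3f", object@logPosterior), "\n", sep = "")
    tab <- table(object@assignment)
    for (nm in names(tab))
        cat(sprintf("  %-16s %d sequences\n", nm, tab[[nm]]))
    sizes <- vapply(object@patterns, patternSize, integer(1))
    cat("  pattern positions:",
        paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
})
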