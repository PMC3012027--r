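#' SyntheticSpec: recipe for a subgroup-structured benchmark alignment
#'
#' Describes an alignment with known truth: sequences fall into subgroups;
#' each contrast category plants discriminating columns where foreground
#' subgroups draw from the column's residue set with probability `pF` and
#' background subgroups with probability `pB` (non-participating subgroups
#' use the pooled rate); all other cells are drawn from the background
#' composition. Decoys are composition-only sequences emulating pseudogene
#' products and other non-functional homologs; duplicates and fragments
#' exercise the redundancy purge.
#'
#' @slot hyperpartition the [Hyperpartition-class] defining subgroups and
#'   categories.
#' @slot counts named integer: sequences per (non-rejected) subgroup.
#' @slot length alignment columns.
#' @slot planted named list per category: `list(columns = , sets = )`.
#' @slot pF,pB foreground / background set-draw probabilities (0 <= pB < pF
#'   <= 1; defaults 0.9 / 0.1).
#' @slot background numeric(20) residue composition (default uniform).
#' @slot nDecoys,nDuplicates,nFragments extra sequence counts.
#' @slot seedsPerSubgroup how many leading members form each seed alignment.
#' @slot rngSeed integer seed.
#' @export
setClass("SyntheticSpec",
    representation(hyperpartition = "Hyperpartition", counts = "integer",
                   length = "integer", planted = "list", pF = "numeric",
                   pB = "numeric", background = "numeric",
                   nDecoys = "integer", nDuplicates = "integer",
                   nFragments = "integer", seedsPerSubgroup = "integer",
                   rngSeed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msgs <- character(0)
    if (object@pB < 0 || object@pF > 1 || object@pB >= object@pF)
        msgs <- c(msgs, "need 0 <= pB < pF <= 1")
    if (any(object@counts < 0L))
        msgs <- c(msgs, "counts must be nonnegative")
    if (length(object@background) != 20L ||
        abs(sum(object@background) - 1) > 1e-8)
        msgs <- c(msgs, "background must be 20 probabilities summing to 1")
    for (cat in names(object@planted)) {
        pl <- object@planted[[cat]]
        if (any(pl$columns < 1L) || any(pl$columns > object@length))
            msgs <- c(msgs, paste0("planted columns outside alignment: ",
                                   cat))
        if (length(pl$columns) != length(pl$sets))
            msgs <- c(msgs, paste0("columns/sets mismatch: ", cat))
    }
    if (!all(names(object@planted) %in%
             categoryNames(object@hyperpartition)))
        msgs <- c(msgs, "planted categories must exist in hyperpartition")
    if (length(msgs)) msgs else TRUE
})

## identity scheme: subgroup i is the foreground of category i, background
## of every other category
identityHyperpartition <- function(subgroups) {
    m <- length(subgroups)
    cells <- matrix("-", m, m,
                    dimnames = list(subgroups,
                                    paste0("C", seq_len(m))))
    diag(cells) <- "+"
    Hyperpartition(cells)
}

## deterministic default plant: interleaved columns, residue sets cycling
## through the amino-acid alphabet (sizes alternating 1 and 2)
defaultPlanted <- function(cats, nPositions, length) {
    m <- length(cats)
    planted <- list()
    for (j in seq_len(m)) {
        cols <- 5L + (seq_len(nPositions) - 1L) * m + (j - 1L)
        stopifnot(max(cols) <= length)
        sets <- lapply(seq_len(nPositions), function(k) {
            a <- ((j - 1L) * nPositions + (k - 1L)) %% 20L + 1L
            if (k %% 2L == 0L) AA20[c(a, a %% 20L + 1L)] else AA20[a]
        })
        planted[[cats[j]]] <- list(columns = cols, sets = sets)
    }
    planted
}

#' Build a SyntheticSpec
#'
#' Defaults describe the standard benchmark: 3 subgroups of 100 sequences
#' over a 200-column alignment, an identity hyperpartition (subgroup i is the
#' foreground of category i), 10 planted positions per category with
#' foreground conservation 0.9 and background set-frequency 0.1, uniform
#' background composition, and 30 random-composition decoys.
#'
#' @param subgroups subgroup names.
#' @param nPerSubgroup sequences per subgroup (recycled).
#' @param length alignment columns.
#' @param hyperpartition optional [Hyperpartition-class]; default identity.
#' @param planted optional plant description; default 10 interleaved
#'   positions per category.
#' @param positionsPerCategory planted positions per category when `planted`
#'   is NULL.
#' @param pF,pB,background,nDecoys,nDuplicates,nFragments,seedsPerSubgroup,rngSeed
#'   see [SyntheticSpec-class].
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(subgroups = c("SG1", "SG2", "SG3"),
                          nPerSubgroup = 100L, length = 200L,
                          hyperpartition = NULL, planted = NULL,
                          positionsPerCategory = 10L,
                          pF = 0.9, pB = 0.1,
                          background = rep(1 / 20, 20L),
                          nDecoys = 30L, nDuplicates = 0L, nFragments = 0L,
                          seedsPerSubgroup = 3L, rngSeed = 1L) {
    if (is.null(hyperpartition))
        hyperpartition <- identityHyperpartition(subgroups)
    if (is.null(planted))
        planted <- defaultPlanted(categoryNames(hyperpartition),
                                  positionsPerCategory, length)
    counts <- setNames(as.integer(rep(nPerSubgroup,
                                      length.out = length(subgroups))),
                       subgroups)
    new("SyntheticSpec", hyperpartition = hyperpartition, counts = counts,
        length = as.integer(length), planted = planted, pF = pF, pB = pB,
        background = background, nDecoys = as.integer(nDecoys),
        nDuplicates = as.integer(nDuplicates),
        nFragments = as.integer(nFragments),
        seedsPerSubgroup = as.integer(seedsPerSubgroup),
        rngSeed = as.integer(rngSeed))
}

#' Generate a benchmark alignment with known truth
#'
#' Draws the alignment the spec describes, deterministically for a given
#' `rngSeed`. The first `seedsPerSubgroup` sequences of each subgroup are
#' emitted as its seed alignment (seeds are members of the main alignment).
#'
#' @param spec a [SyntheticSpec-class].
#' @return List with `msa` ([ProteinMSA-class]), `seeds` (named list of
#'   [SeedAlignment-class]), `truth` (data.frame `id`, `subgroup`),
#'   `hyperpartition`, and `plantedTruth` (the spec's plant, for
#'   recall/precision scoring).
#' @export
generateSynthetic <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    set.seed(spec@rngSeed)
    hp <- spec@hyperpartition
    cells <- hpCells(hp)
    L <- spec@length
    subgroups <- names(spec@counts)

    drawBackground <- function(n) {
        matrix(sample(AA20, n * L, replace = TRUE, prob = spec@background),
               nrow = n)
    }
    nFg <- function(cat) sum(spec@counts[names(which(cells[subgroups, cat]
                                                     == "+"))])
    nBg <- function(cat) sum(spec@counts[names(which(cells[subgroups, cat]
                                                     == "-"))])

    mats <- list(); idsAll <- character(0); truthSg <- character(0)
    for (sg in subgroups) {
        n <- spec@counts[[sg]]
        if (n == 0L) next
        mat <- drawBackground(n)
        for (cat in names(spec@planted)) {
            sym <- cells[sg, cat]
            rate <- if (sym == "+") spec@pF
                    else if (sym == "-") spec@pB
                    else {
                        tot <- nFg(cat) + nBg(cat)
                        if (tot > 0) (nFg(cat) * spec@pF +
                                      nBg(cat) * spec@pB) / tot
                        else spec@pB
                    }
            pl <- spec@planted[[cat]]
            for (k in seq_along(pl$columns)) {
                set <- pl$sets[[k]]
                nonSet <- setdiff(AA20, set)
                pOut <- spec@background[match(nonSet, AA20)]
                hit <- runif(n) < rate
                ## misses draw from the non-set composition, so the set
                ## frequency is exactly the intended rate in expectation
                if (any(hit))
                    mat[hit, pl$columns[k]] <-
                        sample(set, sum(hit), replace = TRUE)
                if (any(!hit))
                    mat[!hit, pl$columns[k]] <-
                        sample(nonSet, sum(!hit), replace = TRUE,
                               prob = pOut)
            }
        }
        ids <- sprintf("%s_seq%03d", sg, seq_len(n))
        mats[[sg]] <- mat
        idsAll <- c(idsAll, ids)
        truthSg <- c(truthSg, rep(sg, n))
    }
    big <- do.call(rbind, mats)

    if (spec@nDecoys > 0L) {
        big <- rbind(big, drawBackground(spec@nDecoys))
        idsAll <- c(idsAll, sprintf("decoy%03d", seq_len(spec@nDecoys)))
        truthSg <- c(truthSg, rep("Rejected", spec@nDecoys))
    }
    memberIds <- idsAll[truthSg != "Rejected"]
    if (spec@nDuplicates > 0L) {
        src <- rep(seq_along(memberIds),
                   length.out = spec@nDuplicates)
        big <- rbind(big, big[match(memberIds[src], idsAll), ,
                              drop = FALSE])
        idsAll <- c(idsAll, paste0(memberIds[src], "_dup",
                                   seq_len(spec@nDuplicates)))
        truthSg <- c(truthSg, truthSg[match(memberIds[src], idsAll)])
    }
    if (spec@nFragments > 0L) {
        src <- rep(seq_along(memberIds), length.out = spec@nFragments)
        keepFrom <- floor(L * 0.35) + 1L
        keepTo <- floor(L * 0.65)
        frag <- big[match(memberIds[src], idsAll), , drop = FALSE]
        frag[, -seq.int(keepFrom, keepTo)] <- GAP
        big <- rbind(big, frag)
        idsAll <- c(idsAll, paste0(memberIds[src], "_frag",
                                   seq_len(spec@nFragments)))
        truthSg <- c(truthSg, truthSg[match(memberIds[src], idsAll)])
    }
    rownames(big) <- idsAll
    msa <- new("ProteinMSA", mat = big, weights = numeric(0))

    seeds <- list()
    for (sg in subgroups) {
        n <- min(spec@seedsPerSubgroup, spec@counts[[sg]])
        if (n == 0L) next
        ids <- sprintf("%s_seq%03d", sg, seq_len(n))
        seeds[[sg]] <- SeedAlignment(sg, subsetSequences(msa, ids))
    }
    list(msa = msa, seeds = seeds,
         truth = data.frame(id = idsAll, subgroup = truthSg,
                            stringsAsFactors = FALSE),
         hyperpartition = hp, plantedTruth = spec@planted)
}

#' Write a generated fixture to disk
#'
#' Emits `alignment.fasta`, `seeds/<subgroup>.fasta`, `hyperpartition.tsv`
#' and `truth.tsv` under `outdir`.
#'
#' @param spec a [SyntheticSpec-class].
#' @param outdir output directory (created).
#' @return Invisible list of written paths plus the generated objects.
#' @export
writeSyntheticFixture <- function(spec, outdir) {
    gen <- generateSynthetic(spec)
    dir.create(file.path(outdir, "seeds"), showWarnings = FALSE,
               recursive = TRUE)
    writeAlignment(gen$msa, file.path(outdir, "alignment.fasta"))
    for (sg in names(gen$seeds))
        writeAlignment(gen$seeds[[sg]]@msa,
                       file.path(outdir, "seeds", paste0(sg, ".fasta")))
    writeHyperpartition(gen$hyperpartition,
                        file.path(outdir, "hyperpartition.tsv"))
    write.table(gen$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(c(gen, list(dir = outdir)))
}
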