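#' ContrastAlignment: rendered view of one category's pattern
#'
#' A fixed-width text block: a constraint histogram, the seed-alignment rows,
#' the foreground pattern and its weighted residue frequencies (in integer
#' tenths), and the background counterparts (prefixed `bg|`). All residue
#' field lines have exactly one character per alignment column.
#'
#' @slot category category name.
#' @slot header one-line title (includes a rejected-category notice when the
#'   pattern is empty).
#' @slot labels row labels (histogram, seed ids, pattern lines).
#' @slot fields residue-field strings, one per label, all of equal length.
#' @slot displayedColumns alignment columns highlighted under the contrast
#'   setting.
#' @export
setClass("ContrastAlignment",
    representation(category = "character", header = "character",
                   labels = "character", fields = "character",
                   displayedColumns = "integer"))

setValidity("ContrastAlignment", function(object) {
    if (length(object@labels) != length(object@fields))
        return("labels and fields must align")
    if (length(object@fields) &&
        length(unique(nchar(object@fields))) != 1L)
        return("all field lines must have equal length")
    TRUE
})

#' @describeIn ContrastAlignment-class the block as printable text lines.
#' @param x,object a `ContrastAlignment`.
#' @export
contrastText <- function(x) {
    if (!length(x@labels)) return(x@header)
    width <- max(nchar(x@labels)) + 2L
    c(x@header, paste0(formatC(x@labels, width = -width), x@fields))
}

setMethod("show", "ContrastAlignment", function(object) {
    writeLines(contrastText(object))
})

#' Integer-tenths digit of a weighted frequency
#'
#' Encodes a weighted residue frequency as a single decimal digit: `'8'`
#' means the residue occurs in 80%-90% of the (weighted) sequences. The digit
#' is `floor(10 f)` clamped to 9, so a fully conserved position (f = 1)
#' renders `'9'` and stays one character wide.
#'
#' @param f frequency in `[0, 1]` (vectorized).
#' @return Single-digit character(s).
#' @examples
#' freqDigit(c(0.85, 0, 1))
#' @export
freqDigit <- function(f) {
    if (any(f < 0 | f > 1 | !is.finite(f)))
        stop("frequency outside [0, 1]")
    as.character(pmin(floor(10 * f), 9))
}

#' Columns highlighted under a contrast setting
#'
#' The contrast setting determines how many of the most discriminating
#' pattern positions are highlighted: the `contrastSetting` columns with the
#' highest nats are selected (ties to the lower column index). A setting at
#' or above the pattern size selects every position.
#'
#' @param pattern a [Pattern-class].
#' @param contrastSetting positive integer.
#' @return Integer vector of alignment columns, ascending.
#' @export
selectDisplayed <- function(pattern, contrastSetting) {
    stopifnot(is(pattern, "Pattern"), contrastSetting >= 1)
    k <- min(contrastSetting, patternSize(pattern))
    if (k == 0L) return(integer(0))
    o <- order(-pattern@nats, pattern@columns)
    sort(pattern@columns[o[seq_len(k)]])
}

## weighted frequency of a residue set at a column among the given ids
setFrequency <- function(msa, ids, column, rset) {
    if (length(ids) == 0L) return(NA_real_)
    w <- seqWeights(msa)[ids]
    res <- residueMatrix(msa)[ids, column]
    sum(w[res %in% rset]) / sum(w)
}

#' Render the contrast alignment of one category
#'
#' Builds the printable block for a category: the seed rows of the foreground
#' subgroup, the foreground pattern and `wt_res_freqs` digits (weighted
#' frequency of the pattern residue set among current foreground sequences),
#' the background pattern and digits (same set, background sequences,
#' prefixed `bg|`), and a histogram of per-position constraint strengths
#' (nats linearly rescaled to bar heights 1-10 over the displayed positions;
#' `.` elsewhere). Only the top-`contrastSetting` positions are highlighted.
#' The displayed pattern character at a column is the residue set's most
#' frequent foreground member.
#'
#' @param state a [SamplerState-class] (typically [fitState()] of a run).
#' @param hp the [Hyperpartition-class] of the run.
#' @param msa the classified [ProteinMSA-class].
#' @param seed the [SeedAlignment-class] whose sequences are displayed.
#' @param category category name or index.
#' @param contrastSetting how many top positions to highlight (default 10).
#' @return A [ContrastAlignment-class]; rendering is deterministic in its
#'   inputs.
#' @export
renderContrast <- function(state, hp, msa, seed, category,
                           contrastSetting = 10L) {
    stopifnot(is(state, "SamplerState"), is(seed, "SeedAlignment"))
    if (is.numeric(category)) category <- categoryNames(hp)[category]
    pattern <- statePatterns(state)[[category]]
    L <- alignmentLength(msa)
    if (is.null(pattern) || patternSize(pattern) == 0L) {
        return(new("ContrastAlignment", category = category,
                   header = paste0("category ", category,
                                   ": rejected (no supporting pattern)"),
                   labels = character(0), fields = character(0),
                   displayedColumns = integer(0)))
    }
    disp <- selectDisplayed(pattern, contrastSetting)
    parts <- categoryPartitions(hp, category)
    assign <- assignments(state)
    fgIds <- names(assign)[assign %in% parts$fg]
    bgIds <- names(assign)[assign %in% parts$bg]

    hist <- rep(".", L)
    fgPat <- rep(".", L); fgDig <- rep(".", L)
    bgPat <- rep(".", L); bgDig <- rep(".", L)
    dispNats <- patternNats(pattern)[as.character(disp)]
    heights <- pmax(1L, ceiling(10 * dispNats / max(dispNats)))
    histChars <- c(as.character(1:9), "*")
    sets <- patternResidueSets(pattern)
    for (k in seq_along(disp)) {
        col <- disp[k]
        set <- sets[[as.character(col)]]
        ## most frequent foreground member represents the set in one column
        freqs <- vapply(set, function(r)
            setFrequency(msa, fgIds, col, r), numeric(1))
        top <- set[order(-freqs, set)][1L]
        fgF <- setFrequency(msa, fgIds, col, set)
        bgF <- setFrequency(msa, bgIds, col, set)
        hist[col] <- histChars[heights[k]]
        fgPat[col] <- top
        fgDig[col] <- freqDigit(fgF)
        if (!is.na(bgF)) {
            bgTop <- names(which.max(vapply(AA20, function(r)
                setFrequency(msa, bgIds, col, r), numeric(1))))
            bgPat[col] <- bgTop
            bgDig[col] <- freqDigit(bgF)
        }
    }
    seedRows <- msaStrings(seed@msa)
    labels <- c("histogram:", names(seedRows), "pattern:", "wt_res_freqs:",
                "bg|pattern:", "bg|wt_res_freqs:")
    fields <- c(paste(hist, collapse = ""), unname(seedRows),
                paste(fgPat, collapse = ""), paste(fgDig, collapse = ""),
                paste(bgPat, collapse = ""), paste(bgDig, collapse = ""))
    new("ContrastAlignment", category = category,
        header = sprintf("category %s: %d pattern positions (%d displayed)",
                         category, patternSize(pattern), length(disp)),
        labels = labels, fields = fields,
        displayedColumns = as.integer(disp))
}

#' Write the pattern information report
#'
#' One TSV row per retained pattern position: category, alignment column, a
#' reference label in the numbering of the category's first seeded foreground
#' sequence, the residue set, its contribution in nats to the posterior
#' log-likelihood ratio, and the weighted foreground/background frequencies
#' of the set. Rows are sorted by category, then nats descending.
#'
#' @param state a [SamplerState-class].
#' @param hp,msa as in [renderContrast()].
#' @param seeds named list of [SeedAlignment-class] (for reference
#'   numbering; optional).
#' @param path output TSV path.
#' @return The report data.frame, invisibly.
#' @export
writePatternInfo <- function(state, hp, msa, seeds = list(), path) {
    assign <- assignments(state)
    rows <- list()
    for (cat in categoryNames(hp)) {
        p <- statePatterns(state)[[cat]]
        if (is.null(p) || patternSize(p) == 0L) next
        parts <- categoryPartitions(hp, cat)
        fgIds <- names(assign)[assign %in% parts$fg]
        bgIds <- names(assign)[assign %in% parts$bg]
        refSg <- intersect(parts$fg, names(seeds))
        refSeq <- refId <- NULL
        if (length(refSg)) {
            refMsa <- seeds[[refSg[1L]]]@msa
            refId <- msaIds(refMsa)[1L]
            refSeq <- residueMatrix(refMsa)[1L, ]
        }
        o <- order(-p@nats, p@columns)
        for (k in o) {
            col <- p@columns[k]
            set <- p@residueSets[[k]]
            label <- if (is.null(refSeq) || refSeq[col] == GAP) "-"
                     else sprintf("%s%d^%s", refSeq[col],
                                  sum(refSeq[seq_len(col)] != GAP), refId)
            rows[[length(rows) + 1L]] <- data.frame(
                category = cat, column = col, ref = label,
                residue_set = paste(set, collapse = ""),
                nats = p@nats[k],
                fg_freq = setFrequency(msa, fgIds, col, set),
                bg_freq = setFrequency(msa, bgIds, col, set))
        }
    }
    info <- if (length(rows)) do.call(rbind, rows)
            else data.frame(category = character(0), column = integer(0),
                            ref = character(0), residue_set = character(0),
                            nats = numeric(0), fg_freq = numeric(0),
                            bg_freq = numeric(0))
    write.table(info, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(info)
}

#' Write the final assignment table
#'
#' TSV with one row per sequence: id, assigned subgroup, and the predictive
#' membership probability of that subgroup ([membershipProbabilities()]).
#'
#' @inheritParams writePatternInfo
#' @param priors the [PriorConfig-class] of the run.
#' @param path output TSV path.
#' @return The data.frame, invisibly.
#' @export
writeAssignmentTable <- function(state, hp, msa, priors = PriorConfig(),
                                 path) {
    ctx <- scoringContext(state, hp, msa, priors)
    assign <- assignments(state)
    ids <- msaIds(msa)
    prob <- vapply(ids, function(id)
        membershipProbabilities(id, state, hp, msa, priors,
                                context = ctx)[[assign[[id]]]],
        numeric(1))
    out <- data.frame(id = ids, subgroup = unname(assign[ids]),
                      probability = sprintf("%.6f", prob))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(out)
}

#' Write the per-sweep sampler trace
#'
#' @param fit a [BppsFit-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(fit, path) {
    write.table(fitTrace(fit)[, c("sweep", "log_posterior", "n_reassigned",
                                  "total_pattern_positions")],
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
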