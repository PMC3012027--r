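#' Read an aligned FASTA file
#'
#' Reads a protein multiple sequence alignment in aligned FASTA (all records
#' equal length, gaps as `-`). Lowercase residues are uppercased, `.` gaps
#' become `-`, and characters outside the 20 amino acids become `X`.
#'
#' @param path path to an aligned FASTA file.
#' @return A [ProteinMSA-class].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "AC-D", ">b", "AC-E"), f)
#' readAlignment(f)
#' @export
readAlignment <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L)
        stop("no sequences in ", path)
    seqs <- as.character(set)
    ## FASTA headers: id = first whitespace-delimited token
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    ProteinMSA(seqs)
}

#' Write a ProteinMSA as aligned FASTA
#'
#' @param msa a [ProteinMSA-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(msa, path) {
    stopifnot(is(msa, "ProteinMSA"))
    set <- Biostrings::BStringSet(msaStrings(msa))
    Biostrings::writeXStringSet(set, path, width = 20000L)
    invisible(path)
}

#' Read one seed alignment per subgroup from a directory
#'
#' Seed files are named `<subgroup>.fasta` (or `.fa`); a subgroup whose file
#' has the suffix `.consensus.fasta` is flagged as a consensus seed.
#'
#' @param dir directory of seed FASTA files.
#' @param expectedLength if given, the alignment width every seed must match.
#' @return Named list of [SeedAlignment-class], one per subgroup.
#' @export
readSeedAlignments <- function(dir, expectedLength = NULL) {
    if (!dir.exists(dir))
        stop("seeds directory not found: ", dir)
    files <- list.files(dir, pattern = "\\.(fasta|fa)$", full.names = TRUE)
    if (length(files) == 0L)
        stop("no seed FASTA files in ", dir)
    seeds <- lapply(files, function(f) {
        base <- sub("\\.(fasta|fa)$", "", basename(f))
        isCons <- grepl("\\.consensus$", base)
        name <- sub("\\.consensus$", "", base)
        msa <- readAlignment(f)
        if (!is.null(expectedLength) && alignmentLength(msa) != expectedLength)
            stop("seed alignment '", name, "' has ", alignmentLength(msa),
                 " columns, expected ", expectedLength)
        SeedAlignment(name, msa, isConsensus = isCons)
    })
    names(seeds) <- vapply(seeds, function(s) s@subgroupName, character(1))
    seeds[order(names(seeds))]
}

#' Write assigned sequences to one aligned FASTA per subgroup
#'
#' Each subgroup named in `assignment` gets a file `<subgroup>.fasta` in
#' `outdir` holding exactly its assigned sequences, in input order. Subgroups
#' listed in `subgroups` but assigned no sequence yield a zero-record file.
#'
#' @param msa a [ProteinMSA-class].
#' @param assignment named character vector: sequence id -> subgroup.
#' @param outdir output directory (created if missing).
#' @param subgroups optional superset of subgroup names to emit files for.
#' @return Named character vector of written file paths.
#' @export
writeSubgroupFastas <- function(msa, assignment, outdir,
                                subgroups = NULL) {
    stopifnot(is(msa, "ProteinMSA"))
    ids <- names(assignment)
    unknown <- setdiff(ids, msaIds(msa))
    if (length(unknown))
        stop("unknown id in assignment: '", unknown[1L], "'")
    groups <- unique(c(subgroups, unname(assignment)))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    strings <- msaStrings(msa)
    paths <- setNames(character(length(groups)), groups)
    for (g in groups) {
        memberIds <- ids[assignment == g]
        ## preserve main-alignment order
        memberIds <- msaIds(msa)[msaIds(msa) %in% memberIds]
        path <- file.path(outdir, paste0(g, ".fasta"))
        if (length(memberIds)) {
            Biostrings::writeXStringSet(
                Biostrings::BStringSet(strings[memberIds]), path,
                width = 20000L)
        } else {
            file.create(path)
        }
        paths[[g]] <- path
    }
    paths
}
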