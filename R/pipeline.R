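#' Run the full classification pipeline
#'
#' Ties the modules together the way the command-line tool does: read the
#' alignment, purge fragments and >98%-identity redundancy, compute
#' position-based weights, read and validate the hyperpartition, read the
#' seed alignments, run the sampler, and write every output: the assignment
#' table, per-subgroup FASTAs, one contrast alignment per (subgroup,
#' foreground category) pair, the pattern information report, the sweep
#' trace, the purge log, and a machine-readable run manifest.
#'
#' @param alignment path to the aligned FASTA input.
#' @param hyperpartition path to the hyperpartition file.
#' @param seedsDir directory of per-subgroup seed FASTAs
#'   (`<subgroup>.fasta`).
#' @param outDir output directory (created; must not require more than one
#'   missing parent).
#' @param preprocess a [PreprocessConfig-class].
#' @param priors a [PriorConfig-class].
#' @param sampler a [SamplerConfig-class].
#' @param contrastSetting how many top pattern positions each contrast
#'   alignment highlights (default 10).
#' @param verbose log one line per stage to stderr.
#' @return Invisibly, a list with the [BppsFit-class], the purged weighted
#'   [ProteinMSA-class], and the paths written.
#' @export
runPipeline <- function(alignment, hyperpartition, seedsDir, outDir,
                        preprocess = PreprocessConfig(),
                        priors = PriorConfig(),
                        sampler = SamplerConfig(),
                        contrastSetting = 10L, verbose = TRUE) {
    say <- function(...) if (verbose) message("[bpps] ", ...)
    msa <- readAlignment(alignment)
    say("read ", nSequences(msa), " sequences x ", alignmentLength(msa),
        " columns")
    hp <- readHyperpartition(hyperpartition)
    viol <- validateHyperpartition(hp)
    if (length(viol))
        stop("invalid hyperpartition: ", paste(viol, collapse = "; "))
    seeds <- readSeedAlignments(seedsDir,
                                expectedLength = alignmentLength(msa))

    purged <- purgeAlignment(msa, preprocess)
    say("purge removed ", nrow(purged$removed), " sequences (",
        nSequences(purged$msa), " kept)")
    ## seed sequences must survive the purge to stay pinned
    seedIds <- unique(unlist(lapply(seeds, function(s) msaIds(s@msa))))
    lost <- intersect(seedIds, purged$removed$id)
    if (length(lost)) {
        keep <- union(msaIds(purged$msa),
                      intersect(lost, msaIds(msa)))
        keep <- msaIds(msa)[msaIds(msa) %in% keep]
        purged$msa <- subsetSequences(msa, keep)
        say("re-admitted ", length(lost), " purged seed sequence(s)")
    }
    wmsa <- computeWeights(purged$msa)
    say("weights computed (mean 1 over ", nSequences(wmsa), " sequences)")

    fit <- runSampler(wmsa, hp, seeds, priors, sampler)
    state <- fitState(fit)
    say("sampler finished after ", nrow(fitTrace(fit)),
        " sweeps; best log posterior ",
        sprintf("%.2f", logPosterior(state)))

    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
        assignment = file.path(outDir, "assignment.tsv"),
        patternInfo = file.path(outDir, "pattern_info.tsv"),
        trace = file.path(outDir, "trace.tsv"),
        purgeLog = file.path(outDir, "purge_log.tsv"),
        manifest = file.path(outDir, "manifest.json"),
        subgroupDir = file.path(outDir, "subgroups"))
    writeAssignmentTable(state, hp, wmsa, priors, paths$assignment)
    writePatternInfo(state, hp, wmsa, seeds, paths$patternInfo)
    writeTrace(fit, paths$trace)
    writeRemovalLog(purged$removed, paths$purgeLog)
    writeSubgroupFastas(wmsa, assignments(state), paths$subgroupDir,
                        subgroups = subgroupNames(hp))

    cells <- hpCells(hp)
    contrasts <- character(0)
    for (sg in intersect(subgroupNames(hp), names(seeds))) {
        for (cat in categoryNames(hp)[cells[sg, ] == "+"]) {
            ca <- renderContrast(state, hp, wmsa, seeds[[sg]], cat,
                                 contrastSetting)
            p <- file.path(outDir,
                           sprintf("contrast_%s_%s.txt", sg, cat))
            writeLines(contrastText(ca), p)
            contrasts <- c(contrasts, p)
        }
    }
    paths$contrasts <- contrasts

    manifest <- list(
        inputs = list(alignment = alignment,
                      hyperpartition = hyperpartition,
                      seedsDir = seedsDir),
        config = list(
            preprocess = list(identityThreshold =
                                  preprocess@identityThreshold,
                              minResidues = preprocess@minResidues,
                              minCoverage = preprocess@minCoverage),
            priors = list(fgPrior = priors@fgPrior,
                          nullConcentration = priors@nullConcentration,
                          rho = priors@rho,
                          maxSetSize = priors@maxSetSize),
            sampler = list(maxSweeps = sampler@maxSweeps,
                           patience = sampler@patience,
                           tempStart = sampler@tempStart,
                           annealFactor = sampler@annealFactor,
                           mode = sampler@mode,
                           rngSeed = sampler@rngSeed),
            contrastSetting = contrastSetting),
        rngSeed = sampler@rngSeed,
        versions = list(bpps = as.character(packageVersion("bpps")),
                        R = paste(R.version$major, R.version$minor,
                                  sep = ".")))
    manifest$configHash <- contentHash(jsonlite::toJSON(manifest$config,
                                                        auto_unbox = TRUE))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    say("outputs written to ", outDir)
    invisible(list(fit = fit, msa = wmsa, hyperpartition = hp,
                   seeds = seeds, paths = paths))
}

#' Convert a Newick tree file into a hyperpartition file
#'
#' Thin wrapper over [hyperpartitionFromTree()]: reads a rooted Newick tree
#' (internal-node labels become subgroup names) and writes the derived
#' hyperpartition.
#'
#' @param newick path to a Newick file.
#' @param out output hyperpartition path.
#' @return The [Hyperpartition-class], invisibly.
#' @export
treeFileToHyperpartition <- function(newick, out) {
    tree <- ape::read.tree(newick)
    if (is.null(tree))
        stop("could not parse Newick file: ", newick)
    hp <- hyperpartitionFromTree(tree)
    writeHyperpartition(hp, out)
    invisible(hp)
}

#' Read a pipeline run configuration from YAML
#'
#' The file may hold `alignment`, `hyperpartition`, `seeds_dir`, `out_dir`,
#' `contrast_setting`, and nested `preprocess`, `priors` and `sampler`
#' blocks whose keys match the corresponding config constructors.
#'
#' @param path YAML file.
#' @return List of arguments for [runPipeline()].
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    build <- function(ctor, block) {
        if (is.null(block)) ctor() else do.call(ctor, block)
    }
    list(alignment = y$alignment, hyperpartition = y$hyperpartition,
         seedsDir = y$seeds_dir, outDir = y$out_dir,
         preprocess = build(PreprocessConfig, y$preprocess),
         priors = build(PriorConfig, y$priors),
         sampler = build(SamplerConfig, y$sampler),
         contrastSetting = if (is.null(y$contrast_setting)) 10L
                           else as.integer(y$contrast_setting))
}
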