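#' BppsFit: result of a sampler run
#'
#' @slot state the best-scoring [SamplerState-class] visited (the MAP
#'   estimate under the model).
#' @slot finalState the state at the last sweep.
#' @slot trace data.frame with one row per sweep: `sweep`, `log_posterior`,
#'   `n_reassigned`, `total_pattern_positions`, `temperature`.
#' @slot hyperpartition the validated [Hyperpartition-class] used.
#' @slot priors the [PriorConfig-class] used.
#' @slot config the [SamplerConfig-class] used.
#' @export
setClass("BppsFit",
    representation(state = "SamplerState", finalState = "SamplerState",
                   trace = "data.frame", hyperpartition = "Hyperpartition",
                   priors = "PriorConfig", config = "SamplerConfig"))

#' @describeIn BppsFit-class the MAP [SamplerState-class].
#' @param x,object a `BppsFit`.
#' @export
fitState <- function(x) x@state

#' @describeIn BppsFit-class per-sweep trace data.frame.
#' @export
fitTrace <- function(x) x@trace

setMethod("show", "BppsFit", function(object) {
    cat("BppsFit:", nrow(object@trace), "sweeps, best log posterior",
        sprintf("%.3f", logPosterior(object@state)), "at sweep",
        object@state@iteration, "\n")
    show(object@state)
})

## ---- internal sampler machinery ------------------------------------------

## Flattened view of all pattern positions across categories, plus the
## weighted count buckets the sweeps update incrementally.
rebuildPositions <- function(env) {
    cols <- integer(0); catIdx <- integer(0); sets <- list()
    for (jj in seq_along(env$cats)) {
        p <- env$patterns[[env$cats[jj]]]
        if (is.null(p) || patternSize(p) == 0L) next
        cols <- c(cols, p@columns)
        catIdx <- c(catIdx, rep(jj, patternSize(p)))
        sets <- c(sets, p@residueSets)
    }
    env$P <- length(cols)
    env$posCol <- cols
    env$posCat <- catIdx
    env$posQ <- vapply(sets, function(s)
        min(sum(env$comp[s]), 1 - 1e-9), numeric(1))
    if (env$P) {
        setCodes <- lapply(sets, match, ALPHABET)
        env$Mmask <- vapply(seq_len(env$P), function(p)
            env$code[, cols[p]] %in% setCodes[[p]], logical(env$n))
        if (env$n == 1L) env$Mmask <- matrix(env$Mmask, nrow = 1L)
        ## role of each subgroup row at each position
        env$roleSym <- env$cells[, catIdx, drop = FALSE]
        env$plusMask <- (env$roleSym == "+") * 1
        env$minusMask <- (env$roleSym == "-") * 1
    } else {
        env$Mmask <- matrix(logical(0), env$n, 0L)
        env$roleSym <- matrix(character(0), length(env$rows), 0L)
        env$plusMask <- env$minusMask <-
            matrix(0, length(env$rows), 0L)
    }
    rebuildCounts(env)
    invisible(env)
}

rebuildCounts <- function(env) {
    if (env$P == 0L) {
        env$mF <- env$uF <- env$mB <- env$uB <- numeric(0)
        return(invisible(env))
    }
    roleMat <- env$cells[env$assign, env$posCat, drop = FALSE]
    isF <- roleMat == "+"
    isB <- roleMat == "-"
    M <- env$Mmask
    env$mF <- colSums(env$w * (isF & M))
    env$uF <- colSums(env$w * (isF & !M))
    env$mB <- colSums(env$w * (isB & M))
    env$uB <- colSums(env$w * (isB & !M))
    invisible(env)
}

## Add (sgn = +1) or remove (sgn = -1) sequence i under subgroup row r.
applyCounts <- function(env, i, r, sgn) {
    if (env$P == 0L) return(invisible(env))
    sym <- env$roleSym[r, ]
    d <- env$Mmask[i, ]
    wi <- env$w[i] * sgn
    isF <- sym == "+"
    isB <- sym == "-"
    env$mF <- pmax(env$mF + wi * (isF & d), 0)
    env$uF <- pmax(env$uF + wi * (isF & !d), 0)
    env$mB <- pmax(env$mB + wi * (isB & d), 0)
    env$uB <- pmax(env$uB + wi * (isB & !d), 0)
    invisible(env)
}

## Per-row conditional log-posterior differences for sequence i, with the
## sequence removed from the counts. Exact leave-one-out beta-binomial
## marginal ratios, so a greedy argmax move can never lower the posterior.
rowScores <- function(env, i) {
    nr <- length(env$rows)
    if (env$P == 0L) return(numeric(nr))
    d <- env$Mmask[i, ]
    wi <- env$w[i]
    aF <- env$priors@fgPrior[1L]; bF <- env$priors@fgPrior[2L]
    A <- env$priors@nullConcentration
    aB <- A * env$posQ; bB <- A * (1 - env$posQ)
    dm <- wi * d; du <- wi * (1 - d)
    dFG <- lbeta(aF + env$mF + dm, bF + env$uF + du) -
        lbeta(aF + env$mF, bF + env$uF)
    dBG <- lbeta(aB + env$mB + dm, bB + env$uB + du) -
        lbeta(aB + env$mB, bB + env$uB)
    mP <- env$mF + env$mB; uP <- env$uF + env$uB
    dP <- lbeta(aB + mP + dm, bB + uP + du) - lbeta(aB + mP, bB + uP)
    as.numeric(env$plusMask %*% (dFG - dP) + env$minusMask %*% (dBG - dP))
}

## One pass of sequence reassignment. Returns the number of moves.
sweepAssignmentsInternal <- function(env, temperature, mode) {
    moves <- 0L
    for (i in seq_len(env$n)) {
        id <- env$ids[i]
        if (id %in% env$pinned) next
        r1 <- env$assign[[id]]
        applyCounts(env, i, r1, -1)
        sc <- rowScores(env, i)
        if (mode == "greedy" || temperature <= 1e-8) {
            mx <- max(sc)
            cand <- which(sc >= mx - 1e-9)
            r2 <- if (match(r1, env$rows) %in% cand) r1
                  else env$rows[cand[1L]]
        } else {
            p <- exp((sc - max(sc)) / temperature)
            r2 <- env$rows[sample.int(length(env$rows), 1L, prob = p)]
        }
        if (r2 != r1) {
            env$assign[[id]] <- r2
            moves <- moves + 1L
        }
        applyCounts(env, i, r2, +1)
    }
    moves
}

## Resample every category's pattern from the current assignment: each column
## is re-evaluated with its best nested residue set (the incumbent set stays
## in the candidate list) and included when the evidence beats the
## ln(rho/(1-rho)) size penalty (greedy) or with the matching sigmoid
## probability (sample mode). Returns the number of changed positions.
sweepPatternsInternal <- function(env, temperature, mode) {
    changes <- 0L
    newPatterns <- env$patterns
    for (jj in seq_along(env$cats)) {
        cat <- env$cats[jj]
        colSym <- env$cells[, jj]
        fgRows <- env$rows[colSym == "+"]
        bgRows <- env$rows[colSym == "-"]
        fgIdx <- which(env$assign %in% fgRows)
        bgIdx <- which(env$assign %in% bgRows)
        old <- env$patterns[[cat]]
        oldSets <- if (is.null(old)) list()
                   else setNames(old@residueSets, old@columns)
        if (length(fgIdx) == 0L || length(bgIdx) == 0L) {
            newPatterns[[cat]] <- Pattern(cat)   # category rejected
            changes <- changes + length(oldSets)
            next
        }
        CF <- weightedCountMatrix(env$code, env$w, fgIdx)
        CB <- weightedCountMatrix(env$code, env$w, bgIdx)
        totF <- sum(env$w[fgIdx]); totB <- sum(env$w[bgIdx])
        cols <- integer(0); sets <- list(); nats <- numeric(0)
        for (col in seq_len(ncol(env$code))) {
            b <- bestSetAtColumn(CF[, col], CB[, col], totF, totB,
                                 env$priors, env$comp,
                                 incumbent = oldSets[[as.character(col)]],
                                 minFgFreq = env$priors@minConservation)
            if (is.null(b)) next
            score <- b$nats + env$pen
            include <- if (mode == "greedy" || temperature <= 1e-8)
                score > 0
            else runif(1L) < stats::plogis(score / temperature)
            if (include) {
                cols <- c(cols, col)
                sets <- c(sets, list(b$set))
                nats <- c(nats, b$nats)
            }
        }
        newPatterns[[cat]] <- Pattern(cat, cols, sets, nats)
        ## count added, removed, and set-changed positions
        oldCols <- as.integer(names(oldSets))
        changes <- changes + length(setdiff(oldCols, cols)) +
            length(setdiff(cols, oldCols)) +
            sum(vapply(intersect(cols, oldCols), function(cc) {
                !identical(sort(oldSets[[as.character(cc)]]),
                           sets[[match(cc, cols)]])
            }, logical(1)))
    }
    env$patterns <- newPatterns
    rebuildPositions(env)
    changes
}

## Nearest-seed initial assignment: each non-seed sequence goes to the
## subgroup whose seed alignment gives it the highest fractional identity;
## ties go to Rejected.
initialAssignment <- function(msa, hp, seeds) {
    ids <- msaIds(msa)
    code <- encodeResidues(residueMatrix(msa))
    rows <- subgroupNames(hp)
    rej <- rejectedName(hp)
    idn <- matrix(-Inf, length(ids), length(seeds),
                  dimnames = list(ids, names(seeds)))
    for (sg in names(seeds)) {
        seedCode <- encodeResidues(residueMatrix(seeds[[sg]]@msa))
        per <- apply(seedCode, 1L, function(srow)
            identityToMany(srow, code))
        idn[, sg] <- apply(matrix(per, nrow = length(ids)), 1L, max)
    }
    assign <- setNames(character(length(ids)), ids)
    for (i in seq_along(ids)) {
        best <- max(idn[i, ])
        cand <- colnames(idn)[idn[i, ] >= best - 1e-12]
        assign[[ids[i]]] <- if (length(cand) == 1L) cand
                            else if (!is.na(rej)) rej else cand[1L]
    }
    pinned <- character(0)
    for (sg in names(seeds)) {
        present <- intersect(msaIds(seeds[[sg]]@msa), ids)
        assign[present] <- sg
        pinned <- c(pinned, present)
    }
    list(assign = assign, pinned = pinned)
}

makeSamplerEnv <- function(msa, hp, assign, pinned, patterns, priors,
                           composition) {
    env <- new.env(parent = emptyenv())
    env$code <- encodeResidues(residueMatrix(msa))
    env$ids <- msaIds(msa)
    env$n <- nSequences(msa)
    env$w <- unname(seqWeights(msa))
    env$cells <- hpCells(hp)
    env$rows <- subgroupNames(hp)
    env$cats <- categoryNames(hp)
    env$priors <- priors
    env$pen <- inclusionPenalty(priors)
    env$comp <- composition
    env$assign <- assign
    env$pinned <- pinned
    env$patterns <- patterns
    rebuildPositions(env)
    env
}

snapshotState <- function(env, logpost, sweep, seed) {
    new("SamplerState", assignment = env$assign, patterns = env$patterns,
        logPosterior = logpost, iteration = as.integer(sweep),
        rngSeed = as.integer(seed), seedIds = env$pinned)
}

## fast from-scratch log posterior using the env's cached structures
envLogPosterior <- function(env) {
    total <- -sum(!(env$ids %in% env$pinned)) * log(length(env$rows))
    if (env$P == 0L) return(total)
    aF <- env$priors@fgPrior[1L]; bF <- env$priors@fgPrior[2L]
    A <- env$priors@nullConcentration
    llr <- lbb(env$mF, env$uF, aF, bF) +
        lbb(env$mB, env$uB, A * env$posQ, A * (1 - env$posQ)) -
        lbb(env$mF + env$mB, env$uF + env$uB,
            A * env$posQ, A * (1 - env$posQ))
    total + sum(llr) + env$P * env$pen
}

## ---- exported sampler surface --------------------------------------------

#' Run the multi-category partition/pattern Gibbs sampler
#'
#' Jointly classifies the alignment's sequences into the hyperpartition's
#' subgroups and selects, for every category, the residue pattern that best
#' separates its foreground from its background. Seed sequences present in
#' the alignment stay pinned to their subgroups throughout. Each sweep first
#' reassigns every non-seed sequence (conditional argmax in greedy mode, or a
#' draw proportional to `exp(score/T)` under a geometrically annealed
#' temperature in sample mode) and then resamples all category patterns. The
#' run stops after `patience` consecutive sweeps without any change, or at
#' `maxSweeps`; the best-scoring state visited is returned alongside the
#' final state and the per-sweep trace.
#'
#' @param msa a [ProteinMSA-class] (purged and weighted, typically).
#' @param hp a valid [Hyperpartition-class].
#' @param seeds named list of [SeedAlignment-class], one per seeded subgroup;
#'   every name must match a hyperpartition row.
#' @param priors a [PriorConfig-class].
#' @param config a [SamplerConfig-class].
#' @return A [BppsFit-class].
#' @export
runSampler <- function(msa, hp, seeds, priors = PriorConfig(),
                       config = SamplerConfig()) {
    stopifnot(is(msa, "ProteinMSA"), is(hp, "Hyperpartition"))
    viol <- validateHyperpartition(hp)
    if (length(viol))
        stop("invalid hyperpartition: ", paste(viol, collapse = "; "))
    badSeed <- setdiff(names(seeds), subgroupNames(hp))
    if (length(badSeed))
        stop("seed subgroup not in hyperpartition: '", badSeed[1L], "'")
    for (s in seeds)
        if (alignmentLength(s@msa) != alignmentLength(msa))
            stop("seed alignment '", s@subgroupName,
                 "' column count differs from main alignment")

    set.seed(config@rngSeed)
    init <- initialAssignment(msa, hp, seeds)
    comp <- alignmentComposition(msa)
    env <- makeSamplerEnv(msa, hp, init$assign, init$pinned,
                          setNames(vector("list", length(categoryNames(hp))),
                                   categoryNames(hp)),
                          priors, comp)
    ## initial patterns: greedy scan from the nearest-seed assignment
    sweepPatternsInternal(env, 0, "greedy")

    for (cat in categoryNames(hp)) {
        parts <- categoryPartitions(hp, cat)
        if (!any(env$assign %in% parts$fg))
            stop("category '", cat,
                 "' has an empty foreground after initialization")
    }

    trace <- vector("list", config@maxSweeps)
    best <- NULL
    streak <- 0L
    mode <- config@mode
    lastSweep <- 0L
    for (sweep in seq_len(config@maxSweeps)) {
        temperature <- if (mode == "greedy") 0
                       else config@tempStart * config@annealFactor^(sweep - 1L)
        moves <- sweepAssignmentsInternal(env, temperature, mode)
        patChanges <- sweepPatternsInternal(env, temperature, mode)
        logpost <- envLogPosterior(env)
        trace[[sweep]] <- data.frame(
            sweep = sweep, log_posterior = logpost, n_reassigned = moves,
            total_pattern_positions = env$P, temperature = temperature)
        if (is.null(best) || logpost > logPosterior(best))
            best <- snapshotState(env, logpost, sweep, config@rngSeed)
        lastSweep <- sweep
        streak <- if (moves + patChanges == 0L) streak + 1L else 0L
        if (streak >= config@patience) break
    }
    final <- snapshotState(env, envLogPosterior(env), lastSweep,
                           config@rngSeed)
    new("BppsFit", state = best, finalState = final,
        trace = do.call(rbind, trace[seq_len(lastSweep)]),
        hyperpartition = hp, priors = priors, config = config)
}

## shared scoring context for the exported predictive surface
scoringContext <- function(state, hp, msa, priors) {
    comp <- alignmentComposition(msa)
    env <- makeSamplerEnv(msa, hp, assignments(state), state@seedIds,
                          statePatterns(state), priors, comp)
    env
}

#' Predictive log score of a sequence under one subgroup row
#'
#' Sums, over categories and pattern positions, the log predictive
#' probability of the sequence's residue (match/non-match of the position's
#' residue set) under the model the row's cell dictates: the foreground
#' posterior-mean match model for `"+"`, the background model for `"-"`, and
#' the pooled model for `"o"` (the Rejected row is therefore scored entirely
#' under the pooled model). A uniform assignment prior over rows is added.
#'
#' @param seqId sequence identifier.
#' @param row subgroup row name.
#' @param state a [SamplerState-class].
#' @param hp,msa,priors as in [runSampler()].
#' @param context internal precomputed scoring context (optional).
#' @return Log score (finite).
#' @export
scoreSequence <- function(seqId, row, state, hp, msa,
                          priors = PriorConfig(), context = NULL) {
    env <- if (is.null(context)) scoringContext(state, hp, msa, priors)
           else context
    i <- match(seqId, env$ids)
    if (is.na(i)) stop("unknown sequence id: '", seqId, "'")
    r <- match(row, env$rows)
    if (is.na(r)) stop("unknown subgroup row: '", row, "'")
    prior <- -log(length(env$rows))
    if (env$P == 0L) return(prior)
    d <- env$Mmask[i, ]
    wi <- env$w[i]
    aF <- env$priors@fgPrior[1L]; bF <- env$priors@fgPrior[2L]
    A <- env$priors@nullConcentration
    aB <- A * env$posQ; bB <- A * (1 - env$posQ)
    dm <- wi * d; du <- wi * (1 - d)
    dFG <- lbeta(aF + env$mF + dm, bF + env$uF + du) -
        lbeta(aF + env$mF, bF + env$uF)
    dBG <- lbeta(aB + env$mB + dm, bB + env$uB + du) -
        lbeta(aB + env$mB, bB + env$uB)
    mP <- env$mF + env$mB; uP <- env$uF + env$uB
    dP <- lbeta(aB + mP + dm, bB + uP + du) - lbeta(aB + mP, bB + uP)
    sym <- env$roleSym[r, ]
    prior + sum(dFG[sym == "+"]) + sum(dBG[sym == "-"]) +
        sum(dP[sym == "o"])
}

#' Predictive membership probabilities of a sequence
#'
#' Softmax of [scoreSequence()] over all subgroup rows (including Rejected);
#' probabilities sum to 1.
#'
#' @inheritParams scoreSequence
#' @return Named numeric vector over subgroup rows.
#' @export
membershipProbabilities <- function(seqId, state, hp, msa,
                                    priors = PriorConfig(), context = NULL) {
    env <- if (is.null(context)) scoringContext(state, hp, msa, priors)
           else context
    sc <- vapply(env$rows, function(r)
        scoreSequence(seqId, r, state, hp, msa, priors, context = env),
        numeric(1))
    p <- exp(sc - max(sc))
    p / sum(p)
}
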