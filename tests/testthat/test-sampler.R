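test_that("seed sequences are never reassigned", {
    gen <- smallFixture()
    for (mode in c("greedy", "sample")) {
        fit <- runSampler(gen$msa, gen$hyperpartition, gen$seeds,
                          config = SamplerConfig(mode = mode, rngSeed = 9L))
        for (st in list(fitState(fit), fit@finalState)) {
            for (sg in names(gen$seeds)) {
                ids <- msaIds(gen$seeds[[sg]]@msa)
                expect_true(all(assignments(st)[ids] == sg))
                expect_true(all(ids %in% st@seedIds))
            }
        }
    }
})

test_that("greedy log posterior is non-decreasing across sweeps", {
    for (seed in c(21L, 22L, 23L)) {
        gen <- smallFixture(rngSeed = seed)
        fit <- runSampler(gen$msa, gen$hyperpartition, gen$seeds,
                          config = SamplerConfig(mode = "greedy",
                                                 rngSeed = seed))
        lp <- fitTrace(fit)$log_posterior
        expect_true(all(diff(lp) >= -1e-9))
    }
})

test_that("fixed seed gives a bit-reproducible trajectory", {
    gen <- smallFixture()
    cfg <- SamplerConfig(mode = "sample", rngSeed = 77L)
    fit1 <- runSampler(gen$msa, gen$hyperpartition, gen$seeds, config = cfg)
    fit2 <- runSampler(gen$msa, gen$hyperpartition, gen$seeds, config = cfg)
    expect_identical(fitTrace(fit1), fitTrace(fit2))
    expect_identical(assignments(fitState(fit1)),
                     assignments(fitState(fit2)))
    expect_identical(statePatterns(fitState(fit1)),
                     statePatterns(fitState(fit2)))
})

test_that("sampling at vanishing temperature reduces to greedy", {
    gen <- smallFixture()
    cold <- runSampler(gen$msa, gen$hyperpartition, gen$seeds,
                       config = SamplerConfig(mode = "sample",
                                              tempStart = 1e-9,
                                              rngSeed = 5L))
    greedy <- runSampler(gen$msa, gen$hyperpartition, gen$seeds,
                         config = SamplerConfig(mode = "greedy",
                                                rngSeed = 5L))
    expect_identical(assignments(fitState(cold)),
                     assignments(fitState(greedy)))
    expect_identical(statePatterns(fitState(cold)),
                     statePatterns(fitState(greedy)))
})

test_that("sampler recovers planted structure and rejects decoys", {
    gen <- smallFixture(n = 50L, nDecoys = 10L, rngSeed = 31L)
    fit <- runSampler(gen$msa, gen$hyperpartition, gen$seeds,
                      config = SamplerConfig(mode = "greedy", rngSeed = 1L))
    stats <- recoveryStats(fit, gen)
    expect_gt(stats$accuracy, 0.9)
    expect_gte(stats$decoyRejection, 0.9)
    expect_true(all(stats$recall >= 0.8))
    expect_true(all(stats$precision >= 0.8))
})

test_that("a planted column is adopted within two greedy sweeps", {
    gen <- smallFixture(n = 30L, nDecoys = 0L, rngSeed = 13L)
    fit <- runSampler(gen$msa, gen$hyperpartition, gen$seeds,
                      config = SamplerConfig(mode = "greedy", maxSweeps = 2L,
                                             patience = 2L, rngSeed = 1L))
    pats <- statePatterns(fitState(fit))
    for (cat in names(gen$plantedTruth))
        expect_gte(mean(gen$plantedTruth[[cat]]$columns %in%
                            patternColumns(pats[[cat]])), 0.8)
})

test_that("a two-subgroup scheme reduces to the single-category split", {
    spec <- syntheticSpec(subgroups = c("FG", "BG"), nPerSubgroup = 25L,
                          length = 60L, positionsPerCategory = 5L,
                          nDecoys = 6L, rngSeed = 17L)
    gen <- generateSynthetic(spec)
    gen$msa <- computeWeights(gen$msa)
    fit <- runSampler(gen$msa, gen$hyperpartition, gen$seeds,
                      config = SamplerConfig(mode = "greedy", rngSeed = 2L))
    stats <- recoveryStats(fit, gen)
    expect_gt(stats$accuracy, 0.9)
    expect_true(all(stats$recall >= 0.8))
})

test_that("accuracy degrades gracefully at weaker conservation", {
    ## standard-size benchmark with foreground conservation lowered to 0.7
    gen <- generateSynthetic(syntheticSpec(pF = 0.7, rngSeed = 2L))
    gen$msa <- computeWeights(gen$msa)
    fit <- runSampler(gen$msa, gen$hyperpartition, gen$seeds,
                      config = SamplerConfig(mode = "greedy", rngSeed = 2L))
    expect_gt(recoveryStats(fit, gen)$accuracy, 0.8)
})

test_that("empty patterns score all rows alike; probabilities normalize", {
    gen <- smallFixture(n = 5L, nDecoys = 2L)
    hp <- gen$hyperpartition
    truth <- truthVector(gen)
    emptyPat <- setNames(lapply(categoryNames(hp), Pattern),
                         categoryNames(hp))
    st <- new("SamplerState", assignment = truth, patterns = emptyPat,
              logPosterior = NA_real_, iteration = 0L, rngSeed = 1L,
              seedIds = character(0))
    id <- msaIds(gen$msa)[1]
    sc <- vapply(subgroupNames(hp), function(r)
        scoreSequence(id, r, st, hp, gen$msa), numeric(1))
    expect_true(all(abs(sc - sc[1]) < 1e-12))
    pr <- membershipProbabilities(id, st, hp, gen$msa)
    expect_equal(sum(pr), 1)
    expect_true(all(abs(pr - 1 / length(pr)) < 1e-12))
})

test_that("row scores match a per-position enumeration oracle on a toy", {
    ## 5 sequences, unit weights: predictive terms reduce to posterior-mean
    ## match probabilities, enumerable by hand
    seqs <- c(s1 = "SSA", s2 = "SSC", s3 = "GAC", s4 = "GAC", s5 = "SAC")
    msa <- ProteinMSA(seqs)
    cells <- rbind(G1 = "+", G2 = "-")
    colnames(cells) <- "C1"
    hp <- Hyperpartition(cells)
    assign <- c(s1 = "G1", s2 = "G1", s3 = "G2", s4 = "G2", s5 = "Rejected")
    pat <- list(C1 = Pattern("C1", c(1L, 2L), list("S", "S"), c(1, 1)))
    st <- new("SamplerState", assignment = assign, patterns = pat,
              logPosterior = NA_real_, iteration = 0L, rngSeed = 1L,
              seedIds = character(0))
    priors <- PriorConfig()
    comp <- alignmentComposition(msa)

    oracle <- function(id, row) {
        total <- -log(3)    # uniform assignment prior over 3 rows
        for (k in 1:2) {
            rset <- "S"
            q <- comp[["S"]]
            hit <- residueMatrix(msa)[id, k] == "S"
            cnt <- columnCounts(msa, c("s1", "s2"), c("s3", "s4"), k, rset)
            th <- switch(hpCells(hp)[row, "C1"],
                "+" = (priors@fgPrior[1] + cnt$mF) /
                      (sum(priors@fgPrior) + cnt$mF + cnt$uF),
                "-" = (priors@nullConcentration * q + cnt$mB) /
                      (priors@nullConcentration + cnt$mB + cnt$uB),
                "o" = (priors@nullConcentration * q + cnt$mF + cnt$mB) /
                      (priors@nullConcentration + cnt$mF + cnt$uF +
                       cnt$mB + cnt$uB))
            total <- total + log(if (hit) th else 1 - th)
        }
        total
    }
    for (id in names(seqs)) {
        for (row in subgroupNames(hp)) {
            expect_equal(scoreSequence(id, row, st, hp, msa, priors),
                         oracle(id, row), tolerance = 1e-10,
                         label = paste(id, row))
        }
    }
    ## softmax over rows therefore matches the enumeration too
    pr <- membershipProbabilities("s5", st, hp, msa, priors)
    sc <- vapply(subgroupNames(hp), function(r) oracle("s5", r), numeric(1))
    expect_equal(unname(pr), unname(exp(sc - max(sc)) /
                                       sum(exp(sc - max(sc)))),
                 tolerance = 1e-10)
})

test_that("seed sequences get modal probability for their own subgroup", {
    gen <- smallFixture(n = 20L, rngSeed = 23L)
    fit <- runSampler(gen$msa, gen$hyperpartition, gen$seeds,
                      config = SamplerConfig(mode = "greedy", rngSeed = 1L))
    st <- fitState(fit)
    for (sg in names(gen$seeds)) {
        id <- msaIds(gen$seeds[[sg]]@msa)[1]
        pr <- membershipProbabilities(id, st, gen$hyperpartition, gen$msa)
        expect_equal(names(which.max(pr)), sg)
        expect_equal(sum(pr), 1)
    }
})

test_that("invalid inputs fail fast", {
    gen <- smallFixture(n = 5L)
    badSeeds <- gen$seeds
    names(badSeeds)[1] <- "NotARow"
    badSeeds[[1]]@subgroupName <- "NotARow"
    expect_error(runSampler(gen$msa, gen$hyperpartition, badSeeds),
                 "seed subgroup not in hyperpartition")

    cells <- rbind(A = c("+", "+"), B = c("-", "o"))
    colnames(cells) <- c("C1", "C2")
    expect_error(runSampler(gen$msa, Hyperpartition(cells), gen$seeds),
                 "invalid hyperpartition")
})
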