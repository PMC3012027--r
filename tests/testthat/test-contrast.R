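test_that("frequency digits follow the integer-tenths encoding", {
    expect_equal(freqDigit(0.85), "8")
    expect_equal(freqDigit(0), "0")
    expect_equal(freqDigit(1), "9")    # clamp keeps one character
    ## monotone non-decreasing and surjective onto 0..9
    grid <- seq(0, 1, by = 0.001)
    digits <- as.integer(freqDigit(grid))
    expect_true(all(diff(digits) >= 0))
    expect_setequal(unique(digits), 0:9)
    expect_error(freqDigit(1.2), "outside")
    expect_error(freqDigit(-0.1), "outside")
})

test_that("contrast setting selects the top-strength columns", {
    set.seed(8)
    for (rep in 1:10) {
        k <- sample(3:12, 1)
        cols <- sort(sample(100L, k))
        nats <- round(runif(k, 0, 5), 2)
        pat <- Pattern("C", cols, as.list(rep("A", k)), nats)
        setting <- sample(1:15, 1)
        got <- selectDisplayed(pat, setting)
        ## sort-based oracle with lower-column tie-break
        o <- order(-nats, cols)
        want <- sort(cols[o[seq_len(min(setting, k))]])
        expect_identical(got, as.integer(want))
        if (setting >= k) expect_identical(got, as.integer(cols))
        expect_true(all(nats[match(got, cols)] >=
                            max(c(nats[!cols %in% got], -Inf))))
    }
})

## hand-built one-position state: foreground set frequency 0.95, background
## 0.12 (unit weights over 20 + 25 sequences)
onePositionFixture <- function() {
    fgRes <- c(rep("K", 19), "A")                 # 19/20 = 0.95
    bgRes <- c(rep("K", 3), rep("G", 22))         # 3/25 = 0.12
    seqs <- setNames(paste0(c(fgRes, bgRes), "A"),
                     c(sprintf("f%02d", 1:20), sprintf("b%02d", 1:25)))
    msa <- ProteinMSA(seqs)
    cells <- rbind(G1 = "+", G2 = "-")
    colnames(cells) <- "C1"
    hp <- Hyperpartition(cells)
    assign <- setNames(c(rep("G1", 20), rep("G2", 25)), names(seqs))
    st <- new("SamplerState", assignment = assign,
              patterns = list(C1 = Pattern("C1", 1L, list("K"), 2.5)),
              logPosterior = NA_real_, iteration = 1L, rngSeed = 1L,
              seedIds = character(0))
    seed <- SeedAlignment("G1", subsetSequences(msa, c("f01", "f02")))
    list(msa = msa, hp = hp, st = st, seed = seed)
}

test_that("rendered digits reflect weighted fg/bg frequencies", {
    fx <- onePositionFixture()
    ca <- renderContrast(fx$st, fx$hp, fx$msa, fx$seed, "C1", 5L)
    field <- function(label) ca@fields[match(label, ca@labels)]
    expect_equal(substr(field("wt_res_freqs:"), 1, 1), "9")      # 0.95
    expect_equal(substr(field("bg|wt_res_freqs:"), 1, 1), "1")   # 0.12
    expect_equal(substr(field("pattern:"), 1, 1), "K")
    expect_equal(substr(field("bg|pattern:"), 1, 1), "G")
    ## all field lines equal length (alignment width)
    expect_length(unique(nchar(ca@fields)), 1L)
    expect_equal(nchar(ca@fields[1]), alignmentLength(fx$msa))
})

test_that("rendering is a pure function of its inputs", {
    fx <- onePositionFixture()
    a <- contrastText(renderContrast(fx$st, fx$hp, fx$msa, fx$seed, "C1"))
    b <- contrastText(renderContrast(fx$st, fx$hp, fx$msa, fx$seed, "C1"))
    expect_identical(a, b)
})

test_that("an empty pattern renders a category-rejected notice", {
    fx <- onePositionFixture()
    st <- fx$st
    st@patterns <- list(C1 = Pattern("C1"))
    ca <- renderContrast(st, fx$hp, fx$msa, fx$seed, "C1")
    expect_match(ca@header, "rejected")
    expect_length(ca@fields, 0L)
})

test_that("contrast block matches the committed golden rendering", {
    gen <- smallFixture(n = 40L, nDecoys = 5L, rngSeed = 29L)
    fit <- runSampler(gen$msa, gen$hyperpartition, gen$seeds,
                      config = SamplerConfig(mode = "greedy", rngSeed = 1L))
    ca <- renderContrast(fitState(fit), gen$hyperpartition, gen$msa,
                         gen$seeds[["SG1"]], "C1", 5L)
    golden <- readLines(test_path("golden_contrast_SG1_C1.txt"))
    expect_identical(contrastText(ca), golden)
})

test_that("histogram marks exactly the displayed columns", {
    gen <- smallFixture(n = 15L, rngSeed = 37L)
    fit <- runSampler(gen$msa, gen$hyperpartition, gen$seeds,
                      config = SamplerConfig(mode = "greedy", rngSeed = 1L))
    ca <- renderContrast(fitState(fit), gen$hyperpartition, gen$msa,
                         gen$seeds[["SG2"]], "C2", 3L)
    expect_length(ca@displayedColumns, 3L)
    hist <- strsplit(ca@fields[1], "")[[1]]
    expect_setequal(which(hist != "."), ca@displayedColumns)
    ## digits appear only at displayed pattern columns
    digits <- strsplit(ca@fields[length(ca@fields) - 2L], "")[[1]]
    expect_true(all(which(digits != ".") %in% ca@displayedColumns))
})

test_that("pattern info report is complete, sorted and consistent", {
    gen <- smallFixture(n = 15L, rngSeed = 41L)
    fit <- runSampler(gen$msa, gen$hyperpartition, gen$seeds,
                      config = SamplerConfig(mode = "greedy", rngSeed = 1L))
    st <- fit@finalState
    path <- withr::local_tempfile(fileext = ".tsv")
    info <- writePatternInfo(st, gen$hyperpartition, gen$msa, gen$seeds,
                             path)
    onDisk <- read.delim(path)
    expect_equal(nrow(onDisk), nrow(info))
    expect_true(all(info$nats >= 0))
    ## sorted by category then descending strength
    expect_false(is.unsorted(info$category))
    for (cat in unique(info$category))
        expect_false(is.unsorted(-info$nats[info$category == cat]))
    ## per-position nats plus priors reproduce the trace's log posterior
    pen <- log(0.02 / 0.98)
    nRows <- length(subgroupNames(gen$hyperpartition))
    nonSeed <- sum(!(msaIds(gen$msa) %in% st@seedIds))
    expect_equal(sum(info$nats) + nrow(info) * pen - nonSeed * log(nRows),
                 fitTrace(fit)$log_posterior[nrow(fitTrace(fit))],
                 tolerance = 1e-6)
    ## reference labels carry seed numbering
    expect_true(all(grepl("^([A-Z]\\d+\\^|-)", info$ref)))

    ## a category with no pattern contributes zero rows
    st2 <- st
    st2@patterns[["C1"]] <- Pattern("C1")
    info2 <- writePatternInfo(st2, gen$hyperpartition, gen$msa, gen$seeds,
                              path)
    expect_false("C1" %in% info2$category)
})
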