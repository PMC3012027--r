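## Shared fixture builders. Everything is generated in code; nothing is
## downloaded or stored in binary form.

## small benchmark: 3 subgroups x n sequences, 60 columns, 5 planted
## positions per category
smallSpec <- function(n = 20L, nDecoys = 8L, pF = 0.9, pB = 0.1,
                      rngSeed = 11L, ...) {
    syntheticSpec(nPerSubgroup = n, length = 60L,
                  positionsPerCategory = 5L, pF = pF, pB = pB,
                  nDecoys = nDecoys, rngSeed = rngSeed, ...)
}

smallFixture <- function(...) {
    gen <- generateSynthetic(smallSpec(...))
    gen$msa <- computeWeights(gen$msa)
    gen
}

## a tiny unweighted MSA for hand checks
toyMSA <- function() {
    ProteinMSA(c(a = "ACDA", b = "ACDA", c = "AWGV"))
}

## truth lookup helpers
truthVector <- function(gen) setNames(gen$truth$subgroup, gen$truth$id)

recoveryStats <- function(fit, gen) {
    st <- fitState(fit)
    truth <- truthVector(gen)
    nonSeed <- setdiff(names(truth), st@seedIds)
    decoys <- grep("^decoy", names(truth), value = TRUE)
    pats <- statePatterns(st)
    rec <- vapply(names(gen$plantedTruth), function(cat) {
        mean(gen$plantedTruth[[cat]]$columns %in%
                 patternColumns(pats[[cat]]))
    }, numeric(1))
    prec <- vapply(names(gen$plantedTruth), function(cat) {
        cols <- patternColumns(pats[[cat]])
        if (length(cols) == 0L) return(NA_real_)
        mean(cols %in% gen$plantedTruth[[cat]]$columns)
    }, numeric(1))
    list(accuracy = mean(assignments(st)[nonSeed] == truth[nonSeed]),
         decoyRejection = if (length(decoys))
             mean(assignments(st)[decoys] == "Rejected") else NA_real_,
         recall = rec, precision = prec)
}

## independent quadrature oracle for a beta-binomial log marginal:
## log integral of theta^m (1-theta)^u under Beta(a, b), trapezoid rule
lbbQuadrature <- function(m, u, a, b, npts = 1e5) {
    theta <- seq(1e-9, 1 - 1e-9, length.out = npts)
    logf <- m * log(theta) + u * log1p(-theta) +
        stats::dbeta(theta, a, b, log = TRUE)
    mx <- max(logf)
    wts <- rep(1, npts); wts[c(1, npts)] <- 0.5
    mx + log(sum(wts * exp(logf - mx)) * (theta[2] - theta[1]))
}

columnLLRQuadrature <- function(counts, priors, q) {
    A <- priors@nullConcentration
    lbbQuadrature(counts$mF, counts$uF,
                  priors@fgPrior[1], priors@fgPrior[2]) +
        lbbQuadrature(counts$mB, counts$uB, A * q, A * (1 - q)) -
        lbbQuadrature(counts$mF + counts$mB, counts$uF + counts$uB,
                      A * q, A * (1 - q))
}

## brute-force ancestor-walk implementation of the tree-to-hyperpartition
## rule, independent of the package's traversal
treeCellsOracle <- function(tree) {
    ntip <- length(tree$tip.label)
    total <- ntip + tree$Nnode
    labels <- c(tree$tip.label,
                if (!is.null(tree$node.label) &&
                    length(tree$node.label) == tree$Nnode) tree$node.label
                else rep("", tree$Nnode))
    blank <- which(labels == "" | is.na(labels))
    labels[blank] <- paste0("node", blank)
    parent <- rep(NA_integer_, total)
    for (k in seq_len(nrow(tree$edge)))
        parent[tree$edge[k, 2]] <- tree$edge[k, 1]
    ancestorsSelf <- function(v) {
        out <- v
        while (!is.na(parent[v])) {
            v <- parent[v]
            out <- c(out, v)
        }
        out
    }
    inSubtree <- function(i, j) j %in% ancestorsSelf(i)
    siblings <- function(j) {
        if (is.na(parent[j])) return(integer(0))
        setdiff(which(parent == parent[j]), j)
    }
    cells <- matrix("o", total, total, dimnames = list(labels, labels))
    for (i in seq_len(total)) {
        for (j in seq_len(total)) {
            if (inSubtree(i, j)) cells[i, j] <- "+"
            else if (any(vapply(siblings(j), function(s)
                inSubtree(i, s), logical(1)))) cells[i, j] <- "-"
        }
    }
    cells
}

## all-pairs greedy purge oracle over aligned strings (quadratic)
purgeOracle <- function(strings, threshold = 0.98, minResidues = 100L,
                        minCoverage = 0.5) {
    nres <- vapply(strings, function(s)
        sum(strsplit(s, "")[[1]] != "-"), numeric(1))
    L <- nchar(strings[[1]])
    pass <- nres >= minResidues & nres / L >= minCoverage
    kept <- character(0)
    for (id in names(strings)[pass]) {
        sim <- vapply(kept, function(k)
            percentIdentity(strings[[id]], strings[[k]]), numeric(1))
        if (!length(sim) || all(sim <= threshold))
            kept <- c(kept, id)
    }
    kept
}
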