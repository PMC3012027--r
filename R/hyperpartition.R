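#' Validate a hyperpartition against the scheme's restrictions
#'
#' Checks the rules a usable hyperpartition must satisfy: every non-rejected
#' subgroup has at least one foreground cell, no two rows share an identical
#' foreground column set, there are at least as many categories as
#' (non-rejected) subgroups, every category has at least one foreground and
#' one background row, and the Rejected row (if present) is never foreground.
#' Violations are returned as data, not raised as errors.
#'
#' @param hp a [Hyperpartition-class].
#' @return Character vector of violation messages; empty when valid.
#' @export
validateHyperpartition <- function(hp) {
    stopifnot(is(hp, "Hyperpartition"))
    cells <- hpCells(hp)
    rows <- rownames(cells)
    rej <- rejectedName(hp)
    real <- setdiff(rows, rej)
    out <- character(0)

    noFg <- real[rowSums(cells[real, , drop = FALSE] == "+") == 0L]
    if (length(noFg))
        out <- c(out, paste0("row lacks foreground: ", noFg))

    sig <- apply(cells[real, , drop = FALSE] == "+", 1L, paste,
                 collapse = "")
    dup <- duplicated(sig)
    if (any(dup)) {
        for (k in which(dup)) {
            first <- real[which(sig == sig[k])[1L]]
            out <- c(out, paste0("duplicate foreground signature: ",
                                 first, "/", real[k]))
        }
    }

    if (ncol(cells) < length(real))
        out <- c(out, sprintf(
            "fewer categories than subgroups (M=%d < N=%d)",
            ncol(cells), length(real)))

    noFgCat <- colnames(cells)[colSums(cells == "+") == 0L]
    if (length(noFgCat))
        out <- c(out, paste0("category lacks foreground: ", noFgCat))
    noBgCat <- colnames(cells)[colSums(cells == "-") == 0L]
    if (length(noBgCat))
        out <- c(out, paste0("category lacks background: ", noBgCat))

    if (!is.na(rej) && any(cells[rej, ] == "+"))
        out <- c(out, "rejected row has foreground cell")
    out
}

## children list and preorder of an ape phylo, with labels for every node
treeStructure <- function(tree) {
    if (!inherits(tree, "phylo"))
        stop("expected an ape 'phylo' tree")
    ntip <- length(tree$tip.label)
    if (ntip < 2L)
        stop("tree must contain at least two nodes below the root")
    if (!ape::is.rooted(tree))
        stop("tree must be rooted")
    nnode <- tree$Nnode
    total <- ntip + nnode
    labels <- c(tree$tip.label,
                if (!is.null(tree$node.label) &&
                    length(tree$node.label) == nnode) tree$node.label
                else rep("", nnode))
    blank <- which(labels == "" | is.na(labels))
    if (length(blank))
        labels[blank] <- paste0("node", blank)
    if (anyDuplicated(labels))
        stop("duplicate node labels in tree: '",
             labels[duplicated(labels)][1L], "'")
    children <- vector("list", total)
    for (k in seq_len(nrow(tree$edge)))
        children[[tree$edge[k, 1L]]] <-
            c(children[[tree$edge[k, 1L]]], tree$edge[k, 2L])
    root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
    if (length(root) != 1L)
        stop("tree must have a single root")
    list(labels = labels, children = children, root = root, total = total)
}

## logical membership vector: which nodes lie in the subtree rooted at v
subtreeMembers <- function(children, v, total) {
    inSub <- rep(FALSE, total)
    stack <- v
    while (length(stack)) {
        node <- stack[[1L]]
        stack <- stack[-1L]
        inSub[node] <- TRUE
        stack <- c(stack, children[[node]])
    }
    inSub
}

#' Convert a rooted tree into a hyperpartition
#'
#' Builds the canonical tree-derived scheme: one subgroup row and one category
#' column per tree node. Node `i` is `"+"` in column `j` when it lies in the
#' subtree rooted at `j`, `"-"` when it lies in a sibling subtree of `j`, and
#' `"o"` otherwise. Internal-node rows are flagged miscellaneous (sequences
#' assigned to a clade but to none of its leaf subfamilies). A `Rejected` row
#' is appended; it serves as the random-sequence background of the root's
#' category and is omitted everywhere else.
#'
#' @param tree an [ape::read.tree()] `phylo` object (rooted; internal-node
#'   labels are used as subgroup names, unlabeled internals are auto-named).
#' @return A valid [Hyperpartition-class] with N rows = M columns (plus the
#'   Rejected row).
#' @examples
#' tr <- ape::read.tree(text = "(A,B)R;")
#' hpCells(hyperpartitionFromTree(tr))
#' @export
hyperpartitionFromTree <- function(tree) {
    st <- treeStructure(tree)
    total <- st$total
    ## preorder: root first, children in parsed order
    order <- integer(0)
    stack <- st$root
    while (length(stack)) {
        node <- stack[[1L]]
        stack <- stack[-1L]
        order <- c(order, node)
        stack <- c(st$children[[node]], stack)
    }
    inSub <- vapply(seq_len(total),
                    function(v) subtreeMembers(st$children, v, total),
                    logical(total))          # inSub[i, j]: i in subtree(j)
    parent <- rep(NA_integer_, total)
    for (v in seq_len(total))
        parent[st$children[[v]]] <- v

    cells <- matrix("o", total, total,
                    dimnames = list(st$labels[order], st$labels[order]))
    for (jj in seq_along(order)) {
        j <- order[jj]
        sibs <- if (is.na(parent[j])) integer(0)
                else setdiff(st$children[[parent[j]]], j)
        inSib <- rep(FALSE, total)
        for (s in sibs) inSib <- inSib | inSub[, s]
        col <- ifelse(inSub[, j], "+", ifelse(inSib, "-", "o"))
        cells[, jj] <- col[order]
    }
    misc <- setNames(order > length(tree$tip.label), st$labels[order])

    ## the rejected sink is the random-sequence background of the root column
    cells <- rbind(cells, Rejected = c("-", rep("o", total - 1L)))
    misc <- c(misc, Rejected = FALSE)
    hp <- new("Hyperpartition", cells = cells, miscFlags = misc)
    viol <- validateHyperpartition(hp)
    if (length(viol))
        stop("tree-derived hyperpartition invalid: ",
             paste(viol, collapse = "; "))
    hp
}

#' Foreground/background/omit row sets of one category
#'
#' @param hp a [Hyperpartition-class].
#' @param j category index or name.
#' @return List with character vectors `fg`, `bg`, `omit` (disjoint; their
#'   union is all subgroup rows).
#' @export
categoryPartitions <- function(hp, j) {
    cells <- hpCells(hp)
    if (is.character(j)) j <- match(j, colnames(cells))
    if (is.na(j) || j < 1L || j > ncol(cells))
        stop("no such category")
    col <- cells[, j]
    list(fg = names(col)[col == "+"],
         bg = names(col)[col == "-"],
         omit = names(col)[col == "o"])
}

#' Read / write the hyperpartition file format
#'
#' The file is UTF-8 text: line 1 holds the tab-separated category names; each
#' further line holds a subgroup name, a tab, and a string of M characters
#' from `{+,-,o}`. A subgroup name suffixed `!misc` marks a miscellaneous
#' subgroup. A final `Rejected` row is optional; one is appended when absent.
#' Violations of the scheme's restrictions are reported as warnings on read.
#'
#' @param path file path.
#' @return [readHyperpartition()]: a [Hyperpartition-class].
#' @export
readHyperpartition <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2L)
        stop("hyperpartition file needs a header and at least one subgroup")
    cats <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    m <- length(cats)
    rows <- lapply(seq.int(2L, length(lines)), function(k) {
        parts <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
        if (length(parts) != 2L)
            stop("line ", k, ": expected 'name<TAB>symbols'")
        sym <- strsplit(parts[2L], "", fixed = TRUE)[[1L]]
        if (length(sym) != m)
            stop("line ", k, ": row has ", length(sym),
                 " symbols, expected ", m)
        bad <- which(!(sym %in% c("+", "-", "o")))
        if (length(bad))
            stop("line ", k, ", category ", bad[1L], ": symbol '",
                 sym[bad[1L]], "' outside {+,-,o}")
        list(name = parts[1L], sym = sym)
    })
    names <- vapply(rows, `[[`, character(1), "name")
    misc <- grepl("!misc$", names)
    names <- sub("!misc$", "", names)
    cells <- do.call(rbind, lapply(rows, `[[`, "sym"))
    dimnames(cells) <- list(names, cats)
    hp <- Hyperpartition(cells, setNames(misc, names))
    viol <- validateHyperpartition(hp)
    if (length(viol))
        warning("hyperpartition violations: ", paste(viol, collapse = "; "))
    hp
}

#' @rdname readHyperpartition
#' @param hp a [Hyperpartition-class] to serialize.
#' @return [writeHyperpartition()]: `path`, invisibly.
#' @export
writeHyperpartition <- function(hp, path) {
    stopifnot(is(hp, "Hyperpartition"))
    cells <- hpCells(hp)
    names <- rownames(cells)
    names[miscFlags(hp)] <- paste0(names[miscFlags(hp)], "!misc")
    lines <- c(paste(colnames(cells), collapse = "\t"),
               paste0(names, "\t", apply(cells, 1L, paste, collapse = "")))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}
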