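#' @import methods
#' @importFrom stats rmultinom runif setNames
#' @importFrom utils write.table packageVersion head
NULL

## Canonical residue alphabet. 'X' is an unknown residue and never matches a
## pattern residue set; '-' is the gap character.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP <- "-"
UNKNOWN <- "X"
ALPHABET <- c(AA20, UNKNOWN, GAP)

#' Amino-acid alphabet used throughout the package
#'
#' Twenty canonical amino acids, `"X"` for an unknown residue and `"-"` for a
#' gap. `"X"` never matches a pattern residue set and gaps always count as
#' non-matches in the contrast model.
#'
#' @return Character vector of length 22.
#' @examples
#' residueAlphabet()
#' @export
residueAlphabet <- function() ALPHABET

## Map arbitrary input characters onto the package alphabet:
## lowercase -> uppercase, '.' -> '-', anything else unknown -> 'X'.
normalizeResidues <- function(x) {
    x <- toupper(x)
    x[x == "."] <- GAP
    x[!(x %in% ALPHABET)] <- UNKNOWN
    x
}

## Integer-code a residue character matrix against ALPHABET (1..22).
encodeResidues <- function(mat) {
    out <- match(mat, ALPHABET)
    dim(out) <- dim(mat)
    dimnames(out) <- dimnames(mat)
    out
}

## Content fingerprint for the run manifest: md5 of the serialized text.
contentHash <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(as.character(x), f)
    unname(tools::md5sum(f))
}
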