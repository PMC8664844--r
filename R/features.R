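#' Index of an ordered dipeptide
#'
#' Maps an ordered residue pair to its 1-based position in the canonical
#' 400-element ordering (first residue slowest, alphabetical by one-letter
#' code), i.e. `20 * rank(first) + rank(second)` counted from zero.
#'
#' @param first,second Single standard one-letter residue codes (vectorized).
#' @return Integer index in 1..400 matching [dipeptideNames()].
#' @examples
#' dipeptideIndex("A", "A")  # 1
#' dipeptideIndex("Y", "Y")  # 400
#' @export
dipeptideIndex <- function(first, second) {
    i <- match(first, AA_STANDARD)
    j <- match(second, AA_STANDARD)
    if (anyNA(i) || anyNA(j))
        stop("nonstandard residue: ",
             paste(unique(c(first[is.na(i)], second[is.na(j)])), collapse = ", "))
    20L * (i - 1L) + j
}

# normalize sequence containers to a named character vector
# (base as.character would silently drop the names of a character input)
.asNamedSequences <- function(seqs) {
    if (is(seqs, "LabeledProteinSet")) seqs <- sequences(seqs)
    if (!is.character(seqs)) seqs <- as.character(seqs)
    seqs
}

# residue codes of one sequence as integers 1..20 (NA for nonstandard)
.residueCodes <- function(seq) {
    match(strsplit(seq, "")[[1]], AA_STANDARD)
}

#' Count g-gap dipeptides of one sequence
#'
#' Tallies every ordered residue pair at positions `(p, p + g + 1)`, i.e.
#' pairs separated by `g` intervening residues; `g = 0` counts adjacent
#' pairs (classic dipeptide composition). A sequence of length `L` yields
#' exactly `L - g - 1` pairs.
#'
#' @param seq A single sequence string of standard residues, length >= g + 2.
#' @param g Non-negative gap size.
#' @return Named integer vector of 400 counts in [dipeptideNames()] order.
#' @examples
#' countDipeptides("ACDE", g = 1)[c("AD", "CE")]
#' @export
countDipeptides <- function(seq, g = 0L) {
    stopifnot(length(seq) == 1L, g >= 0L)
    code <- .residueCodes(seq)
    if (anyNA(code))
        stop("sequence contains nonstandard residues")
    L <- length(code)
    if (L < g + 2L)
        stop("sequence of length ", L, " is too short for gap ", g,
             " (needs at least ", g + 2L, " residues)")
    first <- code[seq_len(L - g - 1L)]
    second <- code[seq_len(L - g - 1L) + g + 1L]
    idx <- 20L * (first - 1L) + second
    setNames(tabulate(idx, nbins = 400L), dipeptideNames())
}

#' g-gap dipeptide composition (GDC) of one sequence
#'
#' The 400-dimensional composition vector: each g-gap dipeptide count
#' divided by the total number of pairs `L - g - 1`, so the entries are
#' fractions summing to 1 regardless of sequence length.
#'
#' @inheritParams countDipeptides
#' @return Named numeric vector of 400 fractions summing to 1.
#' @examples
#' gdcCompose("ACD", g = 0)[c("AC", "CD")]
#' @export
gdcCompose <- function(seq, g = 0L) {
    n <- countDipeptides(seq, g)
    n / sum(n)
}

#' GDC feature matrix of a sequence collection
#'
#' @param seqs Named character vector or `AAStringSet` of sequences, or a
#'   [LabeledProteinSet].
#' @param g Non-negative gap size.
#' @return Numeric matrix, one row per sequence (rownames = ids), 400
#'   columns named by [dipeptideNames()]; rows sum to 1.
#' @seealso [gdcCompose()]
#' @export
gdcMatrix <- function(seqs, g = 0L) {
    seqs <- .asNamedSequences(seqs)
    m <- t(vapply(seqs, gdcCompose, numeric(400L), g = g))
    rownames(m) <- names(seqs)
    m
}

#' Export a GDC feature matrix as CSV
#'
#' Writes one row per sequence id with the 400 dipeptide columns.
#'
#' @param seqs,g As in [gdcMatrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeGdcCsv <- function(seqs, g, path) {
    m <- gdcMatrix(seqs, g)
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
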