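#' Read protein sequences from a FASTA file
#'
#' Reads a FASTA file, concatenates wrapped sequence lines, strips whitespace
#' inside sequence data, upper-cases residues and takes the first
#' whitespace-delimited token of each header as the record id. Records may
#' still contain nonstandard letters at this point; use [filterStandard()] to
#' drop them.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of upper-case sequences (names = ids),
#'   in file order.
#' @seealso [writeFastaProteins()], [filterStandard()]
#' @export
readFastaProteins <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    if (file.size(path) == 0L)
        return(setNames(character(0), character(0)))
    x <- Biostrings::readBStringSet(path)
    ids <- vapply(strsplit(names(x), "[ \t]+"), `[`, character(1), 1L)
    seqs <- toupper(gsub("[ \t\r]", "", as.character(x)))
    if (any(seqs == ""))
        stop("empty sequence record(s): ", paste(ids[seqs == ""], collapse = ", "))
    if (anyDuplicated(ids))
        stop("duplicate sequence ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    setNames(seqs, ids)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector or `AAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFastaProteins <- function(seqs, path) {
    x <- Biostrings::AAStringSet(seqs)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Drop sequences containing nonstandard residues
#'
#' Keeps only sequences written entirely in the 20 standard one-letter
#' amino-acid codes; any other symbol (B, U, X, Z, J, O, ...) disqualifies
#' the whole sequence. Ambiguity codes carry no composition information for
#' a dipeptide model, so affected records are removed rather than recoded.
#'
#' @param seqs Named character vector of upper-case sequences.
#' @return A list with `kept` (named character vector) and `dropped`
#'   (character vector of removed ids).
#' @examples
#' filterStandard(c(a = "ACDEF", b = "ABXDE"))
#' @export
filterStandard <- function(seqs) {
    if (length(seqs) == 0L)
        return(list(kept = setNames(character(0), character(0)),
                    dropped = character(0)))
    ok <- !grepl(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), seqs)
    list(kept = seqs[ok], dropped = names(seqs)[!ok])
}

#' Balanced train/test split of a two-class sequence collection
#'
#' Randomly assigns `floor(trainFraction * n_pos)` positives to the training
#' set and the remainder to the test set, then samples negatives without
#' replacement to match the positive count in each partition, discarding any
#' surplus negatives. The split is a deterministic function of `seed`.
#'
#' @param positives,negatives Named character vectors of sequences.
#' @param trainFraction Fraction of positives assigned to training (0, 1].
#' @param seed Integer seed controlling the draw.
#' @return A list with `train` and `test`, each a [LabeledProteinSet]
#'   (the test set may have zero sequences when `trainFraction = 1`).
#' @export
splitBalanced <- function(positives, negatives, trainFraction = 0.8, seed = 1L) {
    stopifnot(trainFraction > 0, trainFraction <= 1)
    nPos <- length(positives)
    if (length(negatives) < nPos)
        stop("need at least as many negatives (", length(negatives),
             ") as positives (", nPos, ")")
    nTrain <- floor(trainFraction * nPos)
    res <- withSeed(seed, {
        posIdx <- sample.int(nPos, nTrain)
        negIdx <- sample.int(length(negatives), nPos)  # matched, surplus dropped
        list(posIdx = posIdx, negIdx = negIdx)
    })
    posTrain <- sort(res$posIdx)
    posTest <- setdiff(seq_len(nPos), posTrain)
    negTrain <- res$negIdx[seq_len(nTrain)]
    negTest <- res$negIdx[setdiff(seq_len(nPos), seq_len(nTrain))]
    list(train = LabeledProteinSet(positives[posTrain], negatives[sort(negTrain)]),
         test = LabeledProteinSet(positives[posTest], negatives[sort(negTest)]))
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}
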