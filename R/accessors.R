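#' Accessors for LabeledProteinSet
#'
#' @param x A [LabeledProteinSet].
#' @return `sequences()` returns the full [Biostrings::AAStringSet];
#'   `classLabels()` the per-sequence factor (`negative`/`positive`);
#'   `positives()` and `negatives()` the class subsets.
#' @name LabeledProteinSet-accessors
NULL

#' @rdname LabeledProteinSet-accessors
#' @export
sequences <- function(x) {
    stopifnot(is(x, "LabeledProteinSet"))
    x@sequences
}

#' @rdname LabeledProteinSet-accessors
#' @export
classLabels <- function(x) {
    stopifnot(is(x, "LabeledProteinSet"))
    x@label
}

#' @rdname LabeledProteinSet-accessors
#' @export
positives <- function(x) x@sequences[x@label == "positive"]

#' @rdname LabeledProteinSet-accessors
#' @export
negatives <- function(x) x@sequences[x@label == "negative"]

setMethod("show", "LabeledProteinSet", function(object) {
    cat("LabeledProteinSet with", sum(object@label == "positive"),
        "positive and", sum(object@label == "negative"),
        "negative sequences\n")
    w <- Biostrings::width(object@sequences)
    if (length(w))
        cat("  lengths:", min(w), "-", max(w), "residues\n")
})

#' Accessors for PropensityTable
#'
#' @param x A [PropensityTable].
#' @param value Replacement threshold (score units).
#' @return `propensityScores()` returns the named 400-vector of scores;
#'   `gapSize()` the gap `g`; `cutoff()` the decision threshold (`NA` if
#'   unset); `provenance()` `"initial"` or `"optimized"`.
#' @name PropensityTable-accessors
NULL

#' @rdname PropensityTable-accessors
#' @export
propensityScores <- function(x) {
    stopifnot(is(x, "PropensityTable"))
    x@scores
}

#' @rdname PropensityTable-accessors
#' @export
gapSize <- function(x) {
    stopifnot(is(x, "PropensityTable"))
    x@g
}

#' @rdname PropensityTable-accessors
#' @export
cutoff <- function(x) {
    stopifnot(is(x, "PropensityTable"))
    x@threshold
}

#' @rdname PropensityTable-accessors
#' @export
`cutoff<-` <- function(x, value) {
    x@threshold <- as.numeric(value)
    validObject(x)
    x
}

#' @rdname PropensityTable-accessors
#' @export
provenance <- function(x) {
    stopifnot(is(x, "PropensityTable"))
    x@provenance
}

setMethod("show", "PropensityTable", function(object) {
    cat("PropensityTable (", object@provenance, ") g =", object@g, "\n")
    cat("  scores: [", round(min(object@scores), 2), ",",
        round(max(object@scores), 2), "]  threshold:",
        if (is.na(object@threshold)) "unset" else round(object@threshold, 2),
        "\n")
    top <- names(sort(object@scores, decreasing = TRUE))[1:5]
    cat("  top dipeptides:", paste(top, collapse = " "), "\n")
})

setMethod("show", "GaConfig", function(object) {
    cat("GaConfig: population", object@populationSize, "x",
        object@generations, "generations;",
        "fitness =", object@w1, "* AUC_cv +", object@w2, "* R;",
        object@folds, "folds,", object@runs, "runs, seed", object@seed, "\n")
})

setMethod("show", "SimulationParams", function(object) {
    cat("SimulationParams:", object@nPos, "positives /", object@nNeg,
        "negatives, lengths", object@lengthMin, "-", object@lengthMax, "\n")
    cat("  planted signal:", length(object@enriched), "dipeptides at gap",
        object@gSignal, " seed", object@seed, "\n")
})
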