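#' Estimate initial dipeptide propensity scores
#'
#' For every dipeptide the class-mean composition difference
#' `mean_f(positives) - mean_f(negatives)` is computed from per-sequence
#' g-gap compositions (sequences weighted equally regardless of length) and
#' min-max rescaled onto the canonical [0, 1000] score scale, so the most
#' positively enriched dipeptide scores 1000 and the most depleted scores 0.
#' If every difference is identical (e.g. both classes identical) all scores
#' are set to the 500 midpoint.
#'
#' @param train A [LabeledProteinSet] with both classes non-empty.
#' @param g Non-negative gap size.
#' @return A [PropensityTable] with `provenance = "initial"` and an unset
#'   threshold.
#' @seealso [gaOptimize()], [scoreProteins()]
#' @export
estimateInitial <- function(train, g = 0L) {
    stopifnot(is(train, "LabeledProteinSet"))
    pos <- positives(train)
    neg <- negatives(train)
    if (length(pos) == 0L || length(neg) == 0L)
        stop("both classes must be non-empty")
    diff <- colMeans(gdcMatrix(pos, g)) - colMeans(gdcMatrix(neg, g))
    rng <- range(diff)
    scores <- if (rng[2] - rng[1] <= 0) {
        setNames(rep(500, 400L), dipeptideNames())
    } else {
        # clamp: floating-point rescaling may overshoot the bounds by an ulp
        pmin(pmax(1000 * (diff - rng[1]) / (rng[2] - rng[1]), 0), 1000)
    }
    PropensityTable(scores, g = g, provenance = "initial",
                    metadata = list(nPos = length(pos), nNeg = length(neg)))
}

#' Score proteins with a propensity table
#'
#' The TPP score of a protein is the composition-weighted sum of dipeptide
#' propensity scores, `S(P) = sum_d w_d * PS_d`. With the default
#' `scoreMode = "fraction"` the weights are the normalized g-gap composition,
#' making the score a convex combination of the 400 propensity scores (and
#' hence bounded by their range and independent of sequence length). The
#' `"count"` mode uses raw pair counts instead, giving a length-dependent
#' unbounded sum.
#'
#' @param seqs Sequences (named character vector, `AAStringSet`, or a
#'   [LabeledProteinSet]); each must be valid for the table's gap size.
#' @param table A [PropensityTable].
#' @param scoreMode `"fraction"` (default) or `"count"`.
#' @return Named numeric vector of scores.
#' @examples
#' tab <- PropensityTable(setNames(rep(500, 400), dipeptideNames()), g = 0)
#' scoreProteins(c(x = "MEEK"), tab)  # 500
#' @export
scoreProteins <- function(seqs, table, scoreMode = c("fraction", "count")) {
    scoreMode <- match.arg(scoreMode)
    stopifnot(is(table, "PropensityTable"))
    seqs <- .asNamedSequences(seqs)
    g <- gapSize(table)
    w <- t(vapply(seqs, countDipeptides, numeric(400L), g = g))
    if (scoreMode == "fraction") w <- w / rowSums(w)
    drop(w %*% propensityScores(table))
}

#' Classify scores against a threshold
#'
#' A protein is called positive (thermophilic) when its score is greater
#' than or equal to the threshold, negative otherwise; a score exactly at
#' the threshold is positive by convention.
#'
#' @param scores Numeric scores as from [scoreProteins()].
#' @param threshold Decision cutoff; defaults must be supplied explicitly or
#'   taken from a table's [cutoff()].
#' @return Character vector of `"positive"` / `"negative"`, named like
#'   `scores`.
#' @export
classifyScores <- function(scores, threshold) {
    if (length(threshold) != 1L || is.na(threshold))
        stop("threshold is unset; train or set cutoff() first")
    setNames(ifelse(scores >= threshold, "positive", "negative"), names(scores))
}

#' Predict labels for a sequence set
#'
#' Convenience wrapper: scores every sequence with the table and classifies
#' against the table's stored threshold.
#'
#' @inheritParams scoreProteins
#' @return A data.frame with columns `id`, `score`, `label`.
#' @export
predictProteins <- function(seqs, table, scoreMode = "fraction") {
    s <- scoreProteins(seqs, table, scoreMode)
    data.frame(id = names(s), score = unname(s),
               label = unname(classifyScores(s, cutoff(table))),
               row.names = NULL)
}

#' Per-residue propensity scores
#'
#' Averages, for each amino acid, the propensity scores of the 40 dipeptide
#' slots that contain it (20 with the residue first, 20 with it second; the
#' homodipeptide therefore contributes twice). High values mark residues
#' enriched in the positive class.
#'
#' @param table A [PropensityTable].
#' @return Named numeric vector of 20 per-residue scores.
#' @export
aaPropensity <- function(table) {
    s <- propensityScores(table)
    first <- substr(names(s), 1L, 1L)
    second <- substr(names(s), 2L, 2L)
    out <- (rowsum(s, first)[, 1] + rowsum(s, second)[, 1]) / 40
    out[AA_STANDARD]
}

#' Rank proteins by TPP score
#'
#' @param dataset A [LabeledProteinSet] or named character vector of
#'   sequences.
#' @param table A [PropensityTable].
#' @param k Number of top-ranked proteins to return (clamped to the dataset
#'   size).
#' @return A data.frame (`id`, `score`, and `label` when available) sorted
#'   by descending score, ties broken by id.
#' @export
rankProteins <- function(dataset, table, k = 10L) {
    stopifnot(k >= 1L)
    lab <- NULL
    if (is(dataset, "LabeledProteinSet")) {
        lab <- as.character(classLabels(dataset))
        names(lab) <- names(sequences(dataset))
    }
    s <- scoreProteins(dataset, table)
    ord <- order(-s, names(s))
    top <- head(ord, min(k, length(s)))
    out <- data.frame(id = names(s)[top], score = unname(s[top]),
                      row.names = NULL)
    if (!is.null(lab)) out$label <- unname(lab[out$id])
    out
}

#' Serialize a propensity table to JSON
#'
#' The model file stores the 400 scores keyed by two-letter dipeptide (so it
#' is independent of internal ordering), the gap size, threshold, provenance
#' and metadata, in a human-inspectable JSON layout.
#'
#' @param table A [PropensityTable].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePropensityTable <- function(table, path) {
    stopifnot(is(table, "PropensityTable"))
    obj <- list(g = gapSize(table),
                threshold = if (is.na(cutoff(table))) NULL else cutoff(table),
                provenance = provenance(table),
                metadata = table@metadata,
                scores = as.list(propensityScores(table)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writePropensityTable
#' @export
readPropensityTable <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    PropensityTable(unlist(obj$scores), g = obj$g,
                    threshold = if (is.null(obj$threshold)) NA_real_
                                else obj$threshold,
                    provenance = obj$provenance,
                    metadata = as.list(obj$metadata))
}
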