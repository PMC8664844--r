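#' Confusion counts for a two-class prediction
#'
#' @param truth,predicted Vectors of `"positive"` / `"negative"` labels (or
#'   factors) of equal length; positive is the thermophilic class.
#' @return Named integer vector with elements `TP`, `TN`, `FP`, `FN`.
#' @export
confusionCounts <- function(truth, predicted) {
    truth <- as.character(truth)
    predicted <- as.character(predicted)
    if (length(truth) != length(predicted))
        stop("truth and predicted must have equal length")
    c(TP = sum(truth == "positive" & predicted == "positive"),
      TN = sum(truth == "negative" & predicted == "negative"),
      FP = sum(truth == "negative" & predicted == "positive"),
      FN = sum(truth == "positive" & predicted == "negative"))
}

#' Threshold metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Zero-denominator
#' cases return 0 by convention (Sn when there are no positives, Sp when no
#' negatives, MCC when any marginal is empty), keeping reports total and
#' comparable.
#'
#' @param counts Named vector with `TP`, `TN`, `FP`, `FN` as from
#'   [confusionCounts()].
#' @param auc Optional AUC to carry along in the report.
#' @param context Optional free-form list (g, fold, run) stored as an
#'   attribute.
#' @return A one-row data.frame with columns `TP`, `TN`, `FP`, `FN`, `acc`,
#'   `sn`, `sp`, `mcc`, `auc`.
#' @export
computeMetrics <- function(counts, auc = NA_real_, context = NULL) {
    tp <- counts[["TP"]]; tn <- counts[["TN"]]
    fp <- counts[["FP"]]; fn <- counts[["FN"]]
    n <- tp + tn + fp + fn
    if (n == 0L) stop("no evaluated items")
    sn <- if (tp + fn > 0) tp / (tp + fn) else 0
    sp <- if (tn + fp > 0) tn / (tn + fp) else 0
    den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
    out <- data.frame(TP = tp, TN = tn, FP = fp, FN = fn,
                      acc = (tp + tn) / n, sn = sn, sp = sp, mcc = mcc,
                      auc = auc)
    if (!is.null(context)) attr(out, "context") <- context
    out
}

#' Rank-based area under the ROC curve
#'
#' The probability that a uniformly drawn positive outscores a uniformly
#' drawn negative, with ties credited 0.5 — identical to the trapezoidal
#' area under the empirical ROC curve.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels `"positive"` / `"negative"` labels, one per score.
#' @return AUC in [0, 1].
#' @export
rocAUC <- function(scores, labels) {
    labels <- as.character(labels)
    pos <- labels == "positive"
    nPos <- sum(pos); nNeg <- sum(!pos)
    if (nPos == 0L || nNeg == 0L)
        stop("both classes must be present to compute AUC")
    r <- rank(scores, ties.method = "average")
    (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Stratified cross-validation fold plan
#'
#' Assigns each item a fold in 1..folds such that folds partition the data
#' and class balance is preserved within one item per fold; the plan is a
#' deterministic function of `seed`.
#'
#' @param labels `"positive"` / `"negative"` labels.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold assignments, same length as `labels`.
#' @export
foldPlan <- function(labels, folds = 10L, seed = 1L) {
    labels <- as.character(labels)
    stopifnot(folds >= 2L)
    if (min(table(factor(labels, c("negative", "positive")))) < folds)
        stop("folds must not exceed the size of the smaller class")
    plan <- integer(length(labels))
    withSeed(seed, {
        for (cl in c("positive", "negative")) {
            idx <- which(labels == cl)
            plan[idx] <- sample(rep_len(seq_len(folds), length(idx)))
        }
    })
    plan
}

# Fold-held-out metrics of a FIXED table: score each held-out fold, classify
# with the table's threshold, average metrics across folds. Used for fitness
# AUC and for selecting among GA runs; no re-estimation happens per fold.
cvTableMetrics <- function(table, dataset, folds = 10L, seed = 1L,
                           plan = NULL) {
    labels <- as.character(classLabels(dataset))
    if (is.null(plan)) plan <- foldPlan(labels, folds, seed)
    s <- scoreProteins(dataset, table)
    th <- cutoff(table)
    rows <- lapply(sort(unique(plan)), function(f) {
        i <- plan == f
        auc <- rocAUC(s[i], labels[i])
        if (is.na(th)) {
            data.frame(TP = NA, TN = NA, FP = NA, FN = NA, acc = NA,
                       sn = NA, sp = NA, mcc = NA, auc = auc)
        } else {
            computeMetrics(confusionCounts(labels[i], classifyScores(s[i], th)),
                           auc = auc)
        }
    })
    colMeans(do.call(rbind, rows))
}

#' Honest cross-validation of the full SCM pipeline
#'
#' For each fold of a stratified seeded plan, an initial propensity table is
#' estimated on the in-fold training part, refined by a single GA run and
#' thresholded there, then evaluated on the held-out part. Estimating and
#' optimizing inside every fold prevents information leakage into the
#' reported metrics.
#'
#' @param train A [LabeledProteinSet].
#' @param g Gap size.
#' @param config A [GaConfig]; per-fold GA seeds are derived from
#'   `config@seed` and the fold index.
#' @param folds Number of folds.
#' @param seed Seed for the fold plan.
#' @return A list with `mean` and `sd` (named numeric summaries over folds)
#'   and `perFold` (data.frame of per-fold metrics).
#' @export
crossValidate <- function(train, g = 0L, config = gaConfig(), folds = 10L,
                          seed = 1L) {
    labels <- as.character(classLabels(train))
    seqs <- as.character(sequences(train))
    plan <- foldPlan(labels, folds, seed)
    rows <- lapply(seq_len(folds), function(f) {
        inIdx <- plan != f
        sub <- LabeledProteinSet(seqs[inIdx & labels == "positive"],
                                 seqs[inIdx & labels == "negative"])
        cfg <- config
        cfg@seed <- config@seed + f
        tab <- gaOptimize(estimateInitial(sub, g), sub, cfg)
        sHeld <- scoreProteins(seqs[!inIdx], tab)
        labHeld <- labels[!inIdx]
        computeMetrics(confusionCounts(labHeld, classifyScores(sHeld, cutoff(tab))),
                       auc = rocAUC(sHeld, labHeld),
                       context = list(fold = f, g = g))
    })
    perFold <- do.call(rbind, rows)
    agg <- aggregateMetrics(perFold)
    list(mean = agg$mean, sd = agg$sd, perFold = perFold)
}

#' Mean and standard deviation over metric reports
#'
#' Column-wise arithmetic mean and sample (n-1) standard deviation over a
#' set of metric rows, as used for the mean/SD summary rows of
#' cross-validation tables.
#'
#' @param reports A data.frame of metric rows (e.g. rbind-ed outputs of
#'   [computeMetrics()]) or a numeric matrix.
#' @return List with `mean` and `sd`, named numeric vectors (a single
#'   report yields SD 0).
#' @export
aggregateMetrics <- function(reports) {
    if (is.null(dim(reports)) || nrow(reports) == 0L)
        stop("reports must contain at least one row")
    m <- as.matrix(reports)
    sds <- if (nrow(m) == 1L) setNames(rep(0, ncol(m)), colnames(m))
           else apply(m, 2L, stats::sd)
    list(mean = colMeans(m), sd = sds)
}
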