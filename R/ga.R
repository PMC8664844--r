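# mean held-out-fold AUC of one score vector under a fixed fold plan
.foldAUC <- function(scores, labels, plan) {
    mean(vapply(sort(unique(plan)), function(f)
        rocAUC(scores[plan == f], labels[plan == f]), numeric(1)))
}

# Pearson correlation to the initial scores; 0 for zero-variance candidates
.scoreR <- function(candidate, initial) {
    if (stats::sd(candidate) == 0 || stats::sd(initial) == 0) return(0)
    stats::cor(candidate, initial)
}

#' Composite GA fitness of a candidate propensity table
#'
#' `fitness = w1 * AUC_cv + w2 * R`, where `AUC_cv` is the mean held-out-fold
#' AUC of the candidate's protein scores over a seeded stratified fold plan
#' of the training set, and `R` is the Pearson correlation between the 400
#' candidate scores and the 400 initial scores (0 by convention if the
#' candidate is constant). The correlation term penalizes drifting far from
#' the statistical estimate, which limits overfitting of the search.
#'
#' @param candidate,initial [PropensityTable]s sharing the same gap size.
#' @param train A [LabeledProteinSet].
#' @param config A [GaConfig] supplying `w1`, `w2`, `folds` and the fold-plan
#'   seed.
#' @return Fitness value (at most 1).
#' @export
scmFitness <- function(candidate, initial, train, config = gaConfig()) {
    stopifnot(gapSize(candidate) == gapSize(initial))
    labels <- as.character(classLabels(train))
    plan <- foldPlan(labels, config@folds, config@seed)
    s <- scoreProteins(train, candidate)
    config@w1 * .foldAUC(s, labels, plan) +
        config@w2 * .scoreR(propensityScores(candidate),
                            propensityScores(initial))
}

#' Optimal accuracy threshold for a score vector
#'
#' Scans the midpoints between consecutive sorted unique scores and returns
#' the one maximizing training accuracy of the rule "positive iff score >=
#' threshold"; among equally accurate candidates the smallest midpoint is
#' returned. If all scores are identical there is no midpoint and the common
#' score itself is returned (every item classified positive).
#'
#' @param scores Numeric scores.
#' @param labels `"positive"` / `"negative"` labels, one per score.
#' @return The selected threshold (score units).
#' @examples
#' chooseThreshold(c(10, 9, 1, 2),
#'                 c("positive", "positive", "negative", "negative"))  # 5.5
#' @export
chooseThreshold <- function(scores, labels) {
    labels <- as.character(labels)
    if (length(unique(labels)) < 2L)
        stop("both classes must be present to choose a threshold")
    u <- sort(unique(scores))
    if (length(u) == 1L) return(u)
    cand <- (u[-1] + u[-length(u)]) / 2
    acc <- vapply(cand, function(th)
        mean(ifelse(scores >= th, "positive", "negative") == labels),
        numeric(1))
    cand[which.max(acc)]  # which.max takes the first, i.e. smallest midpoint
}

#' Genetic-algorithm refinement of a propensity table
#'
#' Runs an elitist real-valued GA over the 400 dipeptide scores. The seed
#' population is the initial table plus Gaussian-perturbed copies; each
#' generation applies size-2 tournament selection, uniform per-gene
#' crossover, per-gene Gaussian mutation and clipping to [0, 1000], while
#' `eliteCount` best individuals survive unchanged, so best-so-far fitness
#' never decreases. The run is a deterministic function of its inputs and
#' `config@seed`. The returned table carries a threshold chosen on the full
#' training set by [chooseThreshold()] and metadata recording the attained
#' fitness.
#'
#' @param initial A [PropensityTable] (typically from [estimateInitial()]).
#' @param train A [LabeledProteinSet].
#' @param config A [GaConfig].
#' @param trace Optional path; if given, a per-generation best-fitness trace
#'   is written there as CSV.
#' @return An optimized [PropensityTable] (`provenance = "optimized"`).
#' @export
gaOptimize <- function(initial, train, config = gaConfig(), trace = NULL) {
    stopifnot(is(initial, "PropensityTable"), is(train, "LabeledProteinSet"))
    g <- gapSize(initial)
    labels <- as.character(classLabels(train))
    G <- gdcMatrix(train, g)               # n x 400, rows sum to 1
    s0 <- propensityScores(initial)
    pop <- config@populationSize
    nElite <- config@eliteCount

    evalFitness <- function(P, plan) {
        # P: pop x 400 matrix of candidate scores
        S <- G %*% t(P)                    # n x pop protein scores
        vapply(seq_len(ncol(S)), function(j)
            config@w1 * .foldAUC(S[, j], labels, plan) +
                config@w2 * .scoreR(P[j, ], s0),
            numeric(1))
    }

    res <- withSeed(config@seed, {
        plan <- foldPlan(labels, config@folds,
                         seed = stats::runif(1, 1, .Machine$integer.max))
        P <- matrix(rep(s0, each = pop), nrow = pop)
        if (pop > 1L) {
            noise <- matrix(stats::rnorm((pop - 1L) * 400L,
                                         sd = config@mutationStep),
                            nrow = pop - 1L)
            P[-1L, ] <- pmin(pmax(P[-1L, ] + noise, 0), 1000)
        }
        fit <- evalFitness(P, plan)
        best <- numeric(0)
        gen <- 0L
        while (gen < config@generations) {
            ord <- order(-fit)
            elite <- P[ord[seq_len(nElite)], , drop = FALSE]
            nChild <- pop - nElite
            # size-2 tournament selection for two parents per child
            pick <- function() {
                ij <- sample.int(pop, 2L)
                if (fit[ij[1]] >= fit[ij[2]]) ij[1] else ij[2]
            }
            children <- matrix(0, nChild, 400L)
            for (c in seq_len(nChild)) {
                p1 <- P[pick(), ]
                if (stats::runif(1) < config@crossoverRate) {
                    p2 <- P[pick(), ]
                    mask <- stats::runif(400L) < 0.5
                    p1[mask] <- p2[mask]
                }
                mut <- stats::runif(400L) < config@mutationRate
                if (any(mut))
                    p1[mut] <- p1[mut] + stats::rnorm(sum(mut),
                                                      sd = config@mutationStep)
                children[c, ] <- p1
            }
            children <- pmin(pmax(children, 0), 1000)
            P <- rbind(elite, children)
            fit <- c(fit[ord[seq_len(nElite)]], evalFitness(children, plan))
            gen <- gen + 1L
            best <- c(best, max(fit))
        }
        i <- which.max(fit)
        list(scores = P[i, ], fitness = fit[i], trace = best)
    })

    if (!is.null(trace))
        utils::write.csv(data.frame(generation = seq_along(res$trace),
                                    bestFitness = res$trace),
                         trace, row.names = FALSE)
    scores <- setNames(res$scores, dipeptideNames())
    th <- chooseThreshold(drop(G %*% scores), labels)
    PropensityTable(scores, g = g, threshold = th, provenance = "optimized",
                    metadata = list(fitness = res$fitness, seed = config@seed))
}

#' Repeated GA runs with selection by cross-validated MCC
#'
#' Executes [gaOptimize()] `config@runs` times with seeds `seed + 0 ...
#' seed + runs - 1`, evaluates every optimized table by its fold-held-out
#' Matthews correlation coefficient on the training set, and returns the
#' best table (ties broken by lower run index). Metadata records the run
#' index and the per-run MCC values.
#'
#' @inheritParams gaOptimize
#' @return The selected optimized [PropensityTable].
#' @export
gaOptimizeRepeated <- function(initial, train, config = gaConfig()) {
    stopifnot(config@runs >= 1L)
    tables <- vector("list", config@runs)
    mcc <- numeric(config@runs)
    for (r in seq_len(config@runs)) {
        cfg <- config
        cfg@seed <- config@seed + (r - 1L)
        tables[[r]] <- gaOptimize(initial, train, cfg)
        mcc[r] <- cvTableMetrics(tables[[r]], train, config@folds,
                                 seed = config@seed)[["mcc"]]
    }
    i <- which.max(mcc)   # first maximum = lowest run index on ties
    out <- tables[[i]]
    out@metadata <- c(out@metadata, list(run = i, cvMCC = mcc))
    out
}

#' Train a scoring-card model end to end
#'
#' Estimates initial propensity scores on the training set and refines them
#' with repeated GA runs, returning the table selected by cross-validated
#' MCC.
#'
#' @param train A [LabeledProteinSet].
#' @param g Gap size.
#' @param config A [GaConfig].
#' @return An optimized [PropensityTable].
#' @examples
#' \donttest{
#' d <- generateDataset(simParams(nPos = 40, nNeg = 40, lengthMin = 60,
#'                                lengthMax = 120, seed = 1))
#' tab <- trainSCM(d, g = 0, gaConfig(populationSize = 10, generations = 5,
#'                                    runs = 1, folds = 5, seed = 1))
#' tab
#' }
#' @export
trainSCM <- function(train, g = 0L, config = gaConfig()) {
    gaOptimizeRepeated(estimateInitial(train, g), train, config)
}
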