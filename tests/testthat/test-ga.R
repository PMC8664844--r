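mkTrain <- function(seed = 2, n = 30) {
    generateDataset(simParams(nPos = n, nNeg = n, lengthMin = 60,
                              lengthMax = 120, seed = seed))
}

test_that("fitness combines fold-held-out AUC with score correlation", {
    d <- mkTrain()
    tab <- estimateInitial(d, 0)
    cfg <- gaConfig(folds = 5, seed = 3)

    # self-correlation R = 1: fitness = 0.9 * AUC_cv + 0.1
    plan <- foldPlan(as.character(classLabels(d)), 5, 3)
    s <- scoreProteins(d, tab)
    aucCV <- mean(vapply(1:5, function(f)
        rocAUC(s[plan == f], as.character(classLabels(d))[plan == f]),
        numeric(1)))
    expect_equal(scmFitness(tab, tab, d, cfg), 0.9 * aucCV + 0.1,
                 tolerance = 1e-12)
    expect_lte(scmFitness(tab, tab, d, cfg), 1)

    # constant candidate: R convention contributes 0, only the AUC term remains
    const <- constantTable(500)
    sConst <- scoreProteins(d, const)
    aucConst <- mean(vapply(1:5, function(f)
        rocAUC(sConst[plan == f], as.character(classLabels(d))[plan == f]),
        numeric(1)))
    expect_equal(scmFitness(const, tab, d, cfg), 0.9 * aucConst,
                 tolerance = 1e-12)

    # forced arithmetic: w1*AUC + w2*R
    expect_equal(0.9 * 0.8 + 0.1 * 0.5, 0.77)
})

test_that("threshold choice maximizes training accuracy over score midpoints", {
    lab <- c("positive", "positive", "negative", "negative")
    # brute-force oracle over all midpoints
    bruteBest <- function(scores, labels) {
        u <- sort(unique(scores))
        cand <- (u[-1] + u[-length(u)]) / 2
        acc <- vapply(cand, function(th)
            mean(ifelse(scores >= th, "positive", "negative") == labels),
            numeric(1))
        cand[which.max(acc)]
    }
    expect_equal(chooseThreshold(c(10, 9, 1, 2), lab), 5.5)
    expect_equal(chooseThreshold(c(10, 9, 1, 2), lab),
                 bruteBest(c(10, 9, 1, 2), lab))
    expect_equal(chooseThreshold(c(6, 4), c("positive", "negative")), 5)

    set.seed(37)
    for (i in 1:20) {
        s <- round(rnorm(20), 2)
        l <- sample(c("positive", "negative"), 20, TRUE, prob = c(0.5, 0.5))
        if (length(unique(l)) < 2) next
        expect_equal(chooseThreshold(s, l), bruteBest(s, l))
    }

    # degenerate: all scores equal -> the common score itself
    expect_equal(chooseThreshold(c(5, 5, 5, 5), lab), 5)
    expect_error(chooseThreshold(1:3, rep("positive", 3)), "both classes")
})

test_that("GA is elitist, bounded, and bit-reproducible", {
    d <- mkTrain(seed = 5)
    init <- estimateInitial(d, 0)
    cfg <- gaConfig(populationSize = 10, generations = 8, folds = 5,
                    runs = 1, seed = 11)
    tr <- withr::local_tempfile(fileext = ".csv")
    opt <- gaOptimize(init, d, cfg, trace = tr)

    expect_s4_class(opt, "PropensityTable")
    expect_identical(provenance(opt), "optimized")
    expect_true(all(propensityScores(opt) >= 0 & propensityScores(opt) <= 1000))
    expect_false(is.na(cutoff(opt)))

    # best-so-far fitness non-decreasing across generations
    trace <- read.csv(tr)
    expect_equal(nrow(trace), 8)
    expect_true(all(diff(trace$bestFitness) >= -1e-12))
    expect_lte(max(trace$bestFitness), 1)

    # bit-identical reproduction under the same seed
    opt2 <- gaOptimize(init, d, cfg)
    expect_identical(propensityScores(opt), propensityScores(opt2))
    expect_identical(cutoff(opt), cutoff(opt2))

    # zero generations: best of the seed population, never worse than init
    cfg0 <- gaConfig(populationSize = 10, generations = 0, folds = 5, seed = 11)
    opt0 <- gaOptimize(init, d, cfg0)
    expect_gte(opt0@metadata$fitness, scmFitness(init, init, d, cfg0) - 1e-9)
})

test_that("optimization improves cross-validated AUC on planted-signal data", {
    d <- generateDataset(simParams(nPos = 60, nNeg = 60, lengthMin = 80,
                                   lengthMax = 160, seed = 7))
    init <- estimateInitial(d, 0)
    cfg <- gaConfig(populationSize = 12, generations = 10, folds = 5,
                    runs = 1, seed = 7)
    opt <- gaOptimize(init, d, cfg)
    plan <- foldPlan(as.character(classLabels(d)), 5, 99)
    heldAUC <- function(tab) {
        s <- scoreProteins(d, tab)
        mean(vapply(1:5, function(f)
            rocAUC(s[plan == f], as.character(classLabels(d))[plan == f]),
            numeric(1)))
    }
    expect_gte(heldAUC(opt), heldAUC(init) - 1e-9)
})

test_that("pure-correlation fitness (w2 = 1) keeps the initial table optimal", {
    d <- mkTrain(seed = 9, n = 15)
    init <- estimateInitial(d, 0)
    cfg <- gaConfig(populationSize = 8, generations = 5, folds = 3,
                    w1 = 0, w2 = 1, seed = 2)
    opt <- gaOptimize(init, d, cfg)
    expect_equal(cor(propensityScores(opt), propensityScores(init)), 1,
                 tolerance = 1e-9)
})

test_that("repeated runs select by fold-held-out MCC with low-index ties", {
    d <- mkTrain(seed = 12, n = 25)
    init <- estimateInitial(d, 0)
    cfg <- gaConfig(populationSize = 8, generations = 4, folds = 5,
                    runs = 3, seed = 40)
    sel <- gaOptimizeRepeated(init, d, cfg)
    mccs <- sel@metadata$cvMCC
    expect_length(mccs, 3)
    expect_equal(sel@metadata$run, which.max(mccs))
    expect_gte(max(mccs), median(mccs))

    # runs = 1 reduces to a single optimize call
    cfg1 <- gaConfig(populationSize = 8, generations = 4, folds = 5,
                     runs = 1, seed = 40)
    one <- gaOptimizeRepeated(init, d, cfg1)
    direct <- gaOptimize(init, d, cfg1)
    expect_identical(propensityScores(one), propensityScores(direct))
})

test_that("config validity catches inconsistent settings", {
    expect_error(gaConfig(w1 = 0.8, w2 = 0.3), "sum to 1")
    expect_error(gaConfig(populationSize = 1), "at least 2")
    expect_error(gaConfig(eliteCount = 50, populationSize = 10), "smaller")
})
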