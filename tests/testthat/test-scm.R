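test_that("initial estimation maps class differences onto [0, 1000] with midpoint 500", {
    # positives all EEEE, negatives all AAAA: diff(EE)=+1, diff(AA)=-1, rest 0
    d <- LabeledProteinSet(c(p1 = "EEEE", p2 = "EEEE"),
                           c(n1 = "AAAA", n2 = "AAAA"))
    tab <- estimateInitial(d, g = 0)
    s <- propensityScores(tab)
    expect_equal(s[["EE"]], 1000)
    expect_equal(s[["AA"]], 0)
    expect_equal(unname(s[setdiff(dipeptideNames(), c("EE", "AA"))]),
                 rep(500, 398))
    expect_identical(provenance(tab), "initial")
    expect_true(is.na(cutoff(tab)))

    # identical classes: degenerate all-500 convention
    same <- LabeledProteinSet(c(p = "ACDEFG"), c(n = "ACDEFG"))
    expect_equal(unname(propensityScores(estimateInitial(same, 0))),
                 rep(500, 400))

    expect_error(estimateInitial(
        LabeledProteinSet(character(0), c(n = "ACD")), 0), "non-empty")
})

test_that("estimation agrees with direct recomputation of class-mean compositions", {
    set.seed(21)
    pos <- setNames(vapply(1:50, function(i) randomSeq(40), character(1)),
                    paste0("p", 1:50))
    neg <- setNames(vapply(1:50, function(i) randomSeq(40), character(1)),
                    paste0("n", 1:50))
    d <- LabeledProteinSet(pos, neg)
    tab <- estimateInitial(d, g = 1)

    # oracle: recompute diffs and rescale
    diff <- colMeans(t(vapply(pos, function(s) {
        x <- oracleCounts(s, 1); x / sum(x) }, numeric(400)))) -
        colMeans(t(vapply(neg, function(s) {
            x <- oracleCounts(s, 1); x / sum(x) }, numeric(400))))
    expected <- 1000 * (diff - min(diff)) / (max(diff) - min(diff))
    expect_equal(unname(propensityScores(tab)), unname(expected),
                 tolerance = 1e-12)

    # no signal: scores concentrate near the 500 midpoint
    expect_lt(abs(mean(propensityScores(tab)) - 500), 50)
})

test_that("class swap reflects scores through the midpoint s -> 1000 - s", {
    set.seed(31)
    pos <- setNames(vapply(1:30, function(i) randomSeq(50), character(1)),
                    paste0("p", 1:30))
    neg <- setNames(vapply(1:30, function(i) randomSeq(50), character(1)),
                    paste0("n", 1:30))
    a <- propensityScores(estimateInitial(LabeledProteinSet(pos, neg), 0))
    b <- propensityScores(estimateInitial(LabeledProteinSet(neg, pos), 0))
    expect_equal(a, 1000 - b, tolerance = 1e-9)
})

test_that("protein scoring is the composition-weighted propensity sum", {
    expect_equal(unname(scoreProteins(c(x = randomSeq(25)), constantTable(500))),
                 500)
    expect_equal(unname(scoreProteins(c(x = "EEE"),
                                      sparseTable(c(EE = 1000)))), 1000)
    # "ACA" at g=0: half AC, half CA
    expect_equal(unname(scoreProteins(c(x = "ACA"),
                                      sparseTable(c(AC = 600, CA = 400)))), 500)
    # count mode keeps raw totals: 2 pairs -> 600 + 400
    expect_equal(unname(scoreProteins(c(x = "ACA"),
                                      sparseTable(c(AC = 600, CA = 400)),
                                      scoreMode = "count")), 1000)
})

test_that("scores stay within table range and respect monotonicity", {
    set.seed(41)
    tab <- estimateInitial(generateDataset(simParams(nPos = 20, nNeg = 20,
                                                     lengthMin = 50,
                                                     lengthMax = 80, seed = 2)),
                           0)
    s <- scoreProteins(c(a = randomSeq(60), b = randomSeq(200)), tab)
    expect_true(all(s >= min(propensityScores(tab)) &
                    s <= max(propensityScores(tab))))

    # raising the score of a present dipeptide never lowers the protein score
    seq <- randomSeq(60)
    present <- names(which(countDipeptides(seq, 0) > 0))
    s0 <- scoreProteins(setNames(seq, "x"), tab)
    sc <- propensityScores(tab)
    sc[present[1]] <- min(1000, sc[present[1]] + 100)
    s1 <- scoreProteins(setNames(seq, "x"), PropensityTable(sc, g = 0))
    expect_gte(s1, s0)
})

test_that("self-concatenation leaves the g=0 score nearly unchanged", {
    set.seed(43)
    tab <- estimateInitial(generateDataset(simParams(nPos = 20, nNeg = 20,
                                                     lengthMin = 50,
                                                     lengthMax = 80, seed = 3)),
                           0)
    s <- randomSeq(150)
    s1 <- scoreProteins(c(x = s), tab)
    s2 <- scoreProteins(c(x = paste0(s, s)), tab)
    # one boundary dipeptide out of 2L-1 pairs
    expect_lt(abs(s1 - s2), 1000 / 150)
})

test_that("threshold classification is >= with ties positive", {
    expect_equal(unname(classifyScores(528.74, 418)), "positive")
    expect_equal(unname(classifyScores(319.67, 418)), "negative")
    expect_equal(unname(classifyScores(418, 418)), "positive")
    expect_error(classifyScores(500, NA_real_), "unset")
})

test_that("per-residue propensities average the 40 containing dipeptide slots", {
    expect_equal(unname(aaPropensity(constantTable(42))), rep(42, 20))
    aa <- aaPropensity(sparseTable(c(EE = 1000)))
    expect_equal(aa[["E"]], 50)    # homodipeptide counted twice: 2000/40
    expect_equal(aa[["A"]], 0)
    expect_length(aa, 20)

    # affine rescale of the table maps propensities by the same affine map
    set.seed(7)
    sc <- setNames(runif(400, 100, 900), dipeptideNames())
    a1 <- aaPropensity(PropensityTable(sc, g = 0))
    a2 <- aaPropensity(PropensityTable(0.5 * sc + 100, g = 0))
    expect_equal(a2, 0.5 * a1 + 100, tolerance = 1e-9)
})

test_that("protein ranking sorts by descending score with id tie-break", {
    tab <- sparseTable(c(EE = 1000), threshold = 100)
    d <- LabeledProteinSet(c(hi = "EEEE"), c(lo = "ACDF", lo2 = "ACDF"))
    r <- rankProteins(d, tab, k = 1)
    expect_equal(r$id, "hi")
    r3 <- rankProteins(d, tab, k = 10)       # k clamps to dataset size
    expect_equal(nrow(r3), 3)
    expect_equal(r3$id[2:3], c("lo", "lo2")) # equal scores: alphabetical
    expect_equal(r3$label, c("positive", "negative", "negative"))
})

test_that("model JSON round trip preserves the table", {
    set.seed(13)
    sc <- setNames(runif(400, 0, 1000), dipeptideNames())
    tab <- PropensityTable(sc, g = 2, threshold = 444.4,
                           provenance = "optimized",
                           metadata = list(fitness = 0.9, seed = 3))
    f <- withr::local_tempfile(fileext = ".json")
    writePropensityTable(tab, f)
    back <- readPropensityTable(f)
    expect_equal(propensityScores(back), propensityScores(tab))
    expect_equal(gapSize(back), 2)
    expect_equal(cutoff(back), 444.4)
    expect_equal(provenance(back), "optimized")
    expect_equal(back@metadata$fitness, 0.9)
})
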