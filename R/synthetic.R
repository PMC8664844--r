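# Positive-class transition matrix at the planted gap: row a gives
# P(second = b | first = a) with pair weights background[a]*background[b]*mult.
.transitionMatrix <- function(params) {
    mult <- matrix(1, 20L, 20L, dimnames = list(AA_STANDARD, AA_STANDARD))
    if (length(params@enriched)) {
        first <- substr(names(params@enriched), 1L, 1L)
        second <- substr(names(params@enriched), 2L, 2L)
        mult[cbind(first, second)] <- params@enriched
    }
    W <- outer(params@background, params@background) * mult
    W / rowSums(W)
}

# Stationary distribution of a transition matrix (left Perron eigenvector).
.stationary <- function(T) {
    e <- eigen(t(T))
    v <- Re(e$vectors[, which.max(Re(e$values))])
    v <- abs(v)
    setNames(v / sum(v), rownames(T))
}

# one positive-class sequence: g+1 interleaved first-order chains so the
# dependency sits exactly at distance g+1; all positions start at the
# stationary law, making planted pair probabilities exact in expectation.
.onePositive <- function(L, T, pi0, g) {
    cumT <- t(apply(T, 1L, cumsum))
    x <- integer(L)
    step <- g + 1L
    x[seq_len(min(step, L))] <- findInterval(stats::runif(min(step, L)),
                                             cumsum(pi0)) + 1L
    if (L > step)
        for (p in (step + 1L):L)
            x[p] <- findInterval(stats::runif(1), cumT[x[p - step], ]) + 1L
    paste(AA_STANDARD[x], collapse = "")
}

#' Generate a two-class synthetic protein dataset
#'
#' Negatives are drawn residue-by-residue from the background frequencies;
#' positives come from a first-order chain over positions `g + 1` apart
#' whose transitions are the background products reweighted by the planted
#' enrichment map and renormalized per preceding residue (initial residues
#' drawn from the chain's stationary law). Sequence lengths are uniform on
#' `[lengthMin, lengthMax]`. Every sequence uses its own RNG substream
#' derived from `params@seed`, so the dataset is reproducible and
#' insensitive to generation order.
#'
#' @param params A [SimulationParams] object (see [simParams()]).
#' @return A [LabeledProteinSet] with ids `pos_1...` / `neg_1...`.
#' @seealso [plantedTruth()]
#' @export
generateDataset <- function(params) {
    stopifnot(is(params, "SimulationParams"))
    validObject(params)
    n <- params@nPos + params@nNeg
    seqSeeds <- withSeed(params@seed,
                         sample.int(.Machine$integer.max - 1L, n))
    T <- .transitionMatrix(params)
    pi0 <- .stationary(T)
    cumBg <- cumsum(params@background)
    gen1 <- function(i) {
        withSeed(seqSeeds[i], {
            L <- sample(params@lengthMin:params@lengthMax, 1L)
            if (i <= params@nPos)
                .onePositive(L, T, pi0, params@gSignal)
            else
                paste(AA_STANDARD[findInterval(stats::runif(L), cumBg) + 1L],
                      collapse = "")
        })
    }
    seqs <- vapply(seq_len(n), gen1, character(1))
    LabeledProteinSet(
        setNames(seqs[seq_len(params@nPos)],
                 paste0("pos_", seq_len(params@nPos))),
        setNames(seqs[params@nPos + seq_len(params@nNeg)],
                 paste0("neg_", seq_len(params@nNeg))))
}

#' Analytic planted composition differences
#'
#' Expected g-gap pair probability of every dipeptide under the positive
#' generator minus that under the negative generator, at the planted gap.
#' Positives follow `pi[a] * T[a, b]` with `pi` the stationary law of the
#' enriched transition matrix `T`; negatives follow the independent product
#' `background[a] * background[b]`. Useful as ground truth for
#' signal-recovery checks against [estimateInitial()].
#'
#' @param params A [SimulationParams] object.
#' @return Named numeric vector of 400 expected composition differences in
#'   [dipeptideNames()] order (all zero when nothing is enriched).
#' @export
plantedTruth <- function(params) {
    stopifnot(is(params, "SimulationParams"))
    T <- .transitionMatrix(params)
    pi0 <- .stationary(T)
    posP <- pi0 * T                       # joint law rows scaled by pi
    negP <- outer(params@background, params@background)
    setNames(as.vector(t(posP - negP)), dipeptideNames())
}
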