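# Shared helpers: tiny deterministic datasets and oracle implementations.

# naive double-loop g-gap dipeptide counter, independent of the package path
oracleCounts <- function(seq, g) {
    ch <- strsplit(seq, "")[[1]]
    out <- setNames(integer(400), dipeptideNames())
    for (p in seq_len(length(ch) - g - 1)) {
        d <- paste0(ch[p], ch[p + g + 1])
        out[d] <- out[d] + 1L
    }
    out
}

# random standard-alphabet sequence
randomSeq <- function(len) {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    paste(sample(aa, len, replace = TRUE), collapse = "")
}

# uniform propensity table at a constant score
constantTable <- function(value = 500, g = 0L) {
    PropensityTable(setNames(rep(value, 400), dipeptideNames()), g = g)
}

# table that is zero except for the named dipeptides
sparseTable <- function(..., g = 0L, threshold = NA_real_) {
    v <- c(...)
    s <- setNames(rep(0, 400), dipeptideNames())
    s[names(v)] <- v
    PropensityTable(s, g = g, threshold = threshold)
}

extdata <- function(f) system.file("extdata", f, package = "thermoSCM")

# the bundled per-residue propensity / composition fixture as named vectors
aaFixture <- function() {
    df <- read.csv(extdata("aa_propensity_tpp.csv"))
    list(propensity = setNames(df$propensity, df$aa),
         difference = setNames(df$difference, df$aa))
}
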