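#' Parse an AAindex1 flat file
#'
#' Reads physicochemical property records in the AAindex1 format: each
#' record starts with an `H <accession>` line, carries a `D` title, and lists
#' its 20 per-residue values after the `I` line in two rows of ten following
#' the canonical `A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V` layout; `NA`
#' entries are allowed and recorded as missing; records end with `//`.
#'
#' @param path Path to an AAindex1-format file.
#' @return A list of properties, each a list with `accession`, `title`, and
#'   `values` (numeric named by the 20 residues, `NA` where missing).
#' @export
parseAAindex1 <- function(path) {
    if (!file.exists(path)) stop("AAindex file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    rowOrder <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
    props <- list()
    i <- 1L
    while (i <= length(lines)) {
        if (!startsWith(lines[i], "H ")) { i <- i + 1L; next }
        acc <- trimws(sub("^H ", "", lines[i]))
        title <- ""
        vals <- NULL
        j <- i + 1L
        while (j <= length(lines) && !startsWith(lines[j], "//")) {
            if (startsWith(lines[j], "D "))
                title <- trimws(sub("^D ", "", lines[j]))
            if (startsWith(lines[j], "I ")) {
                if (j + 2L > length(lines))
                    stop("malformed AAindex record (truncated values): ", acc)
                tok <- unlist(strsplit(trimws(lines[j + 1:2]), "[ \t]+"))
                if (length(tok) != 20L)
                    stop("malformed AAindex record (expected 20 values): ", acc)
                vals <- suppressWarnings(as.numeric(ifelse(tok == "NA", NA, tok)))
                if (any(is.na(vals) & tok != "NA"))
                    stop("malformed AAindex record (non-numeric value): ", acc)
                names(vals) <- rowOrder
                j <- j + 2L
            }
            j <- j + 1L
        }
        if (is.null(vals))
            stop("malformed AAindex record (no I block): ", acc)
        props[[length(props) + 1L]] <-
            list(accession = acc, title = title,
                 values = vals[AA_STANDARD])
        i <- j + 1L
    }
    props
}

#' Correlate per-residue propensities with a physicochemical property
#'
#' Pearson correlation between the 20 per-residue propensity scores and a
#' property's per-residue values, computed over the residues present in
#' both (pairwise deletion of missing property entries).
#'
#' @param aa Named numeric vector of per-residue propensity scores, as from
#'   [aaPropensity()].
#' @param prop A property as returned by [parseAAindex1()] (or a named
#'   numeric vector of per-residue values).
#' @return Pearson R.
#' @export
correlateProperty <- function(aa, prop) {
    v <- if (is.list(prop)) prop$values else prop
    common <- intersect(names(aa)[!is.na(aa)], names(v)[!is.na(v)])
    if (length(common) < 3L)
        stop("fewer than 3 residues shared between propensity and property")
    x <- aa[common]; y <- v[common]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("correlation undefined: zero variance")
    stats::cor(x, y)
}

#' Rank physicochemical properties by propensity correlation
#'
#' Correlates every property with the per-residue propensity scores and
#' returns the `k` most positively and most negatively correlated ones
#' (signed R, not absolute). Properties whose correlation is undefined
#' (too few residues or zero variance) are excluded and reported.
#'
#' @param aa Per-residue propensity scores ([aaPropensity()]).
#' @param props List of properties ([parseAAindex1()]).
#' @param k Number of properties per list (clamped).
#' @return List with `top` and `bottom` data.frames (`accession`, `title`,
#'   `R`, sorted by descending / ascending R) and `excluded` (character
#'   vector of accessions).
#' @export
rankProperties <- function(aa, props, k = 20L) {
    stopifnot(length(props) >= 1L)
    r <- vapply(props, function(p)
        tryCatch(correlateProperty(aa, p), error = function(e) NA_real_),
        numeric(1))
    acc <- vapply(props, `[[`, character(1), "accession")
    title <- vapply(props, function(p)
        if (is.null(p$title)) "" else p$title, character(1))
    ok <- !is.na(r)
    df <- data.frame(accession = acc[ok], title = title[ok], R = r[ok],
                     row.names = NULL)
    df <- df[order(-df$R, df$accession), ]
    kk <- min(k, nrow(df))
    list(top = head(df, kk),
         bottom = df[rev(tail(seq_len(nrow(df)), kk)), ],
         excluded = acc[!ok])
}

#' Highest- and lowest-scoring dipeptides of a table
#'
#' @param table A [PropensityTable].
#' @param k Number of dipeptides per list (clamped to 400).
#' @return List with `highest` and `lowest` data.frames (`dipeptide`,
#'   `score`), ties broken alphabetically.
#' @export
topDipeptides <- function(table, k = 10L) {
    stopifnot(k >= 1L)
    s <- propensityScores(table)
    kk <- min(k, length(s))
    up <- order(-s, names(s))
    down <- order(s, names(s))
    list(highest = data.frame(dipeptide = names(s)[up[seq_len(kk)]],
                              score = unname(s[up[seq_len(kk)]]),
                              row.names = NULL),
         lowest = data.frame(dipeptide = names(s)[down[seq_len(kk)]],
                             score = unname(s[down[seq_len(kk)]]),
                             row.names = NULL))
}

#' Per-class score histogram
#'
#' Scores every sequence and bins the two classes on shared bin edges
#' spanning the pooled score range, with per-class mean and standard
#' deviation — the data behind a score-separation histogram of a trained
#' model.
#'
#' @param dataset A [LabeledProteinSet] with both classes non-empty.
#' @param table A [PropensityTable].
#' @param bins Number of equal-width bins (>= 1).
#' @return List with `breaks` (length bins + 1), `counts` (2 x bins matrix,
#'   rows `positive` / `negative`), and `stats` (data.frame of per-class
#'   `n`, `mean`, `sd`).
#' @export
scoreHistogram <- function(dataset, table, bins = 20L) {
    stopifnot(bins >= 1L)
    lab <- as.character(classLabels(dataset))
    if (!all(c("positive", "negative") %in% lab))
        stop("both classes must be non-empty")
    s <- scoreProteins(dataset, table)
    rng <- range(s)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
    cnt <- function(x) {
        b <- findInterval(x, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
        tabulate(b, nbins = bins)
    }
    counts <- rbind(positive = cnt(s[lab == "positive"]),
                    negative = cnt(s[lab == "negative"]))
    stats <- data.frame(
        class = c("positive", "negative"),
        n = c(sum(lab == "positive"), sum(lab == "negative")),
        mean = c(mean(s[lab == "positive"]), mean(s[lab == "negative"])),
        sd = c(stats::sd(s[lab == "positive"]), stats::sd(s[lab == "negative"])))
    stats$sd[stats$n == 1L] <- 0
    list(breaks = breaks, counts = counts, stats = stats)
}
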