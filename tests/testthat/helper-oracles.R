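# Independent brute-force oracles and tiny fixture builders used across
# the suite. These deliberately re-derive results by the most naive route
# available so they stay independent of the package implementation.

randomSeq <- function(n, letters = c("A", "C", "G", "T")) {
    paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Enumerate every ATG, walk codon by codon to the first stop; a codon
# containing N before any stop invalidates the candidate. Longest span
# wins, ties to the 5'-most start.
oracleLongestOrf <- function(seq) {
    n <- nchar(seq)
    stops <- c("TAA", "TAG", "TGA")
    best <- c(start = 0L, len = 0L)
    for (s in seq_len(max(n - 5L, 0L))) {
        if (substr(seq, s, s + 2L) != "ATG") next
        p <- s + 3L
        len <- 0L
        while (p + 2L <= n) {
            cod <- substr(seq, p, p + 2L)
            if (cod %in% stops) {
                len <- p + 2L - s + 1L
                break
            }
            if (grepl("N", cod, fixed = TRUE)) break
            p <- p + 3L
        }
        if (len > best[["len"]]) best <- c(start = s, len = len)
    }
    best
}

# Memoized recursive re-implementation of the base-pair maximization
# pseudo-energy (same scores and loop constraint, different control flow).
oracleNussinov <- function(seq, min_loop = 3L) {
    chars <- strsplit(seq, "")[[1]]
    n <- length(chars)
    score <- function(a, b) {
        key <- paste0(a, b)
        switch(key, GC = -3, CG = -3, AT = -2, TA = -2, AU = -2,
               UA = -2, GT = -1, TG = -1, GU = -1, UG = -1, 1)
    }
    memo <- new.env(hash = TRUE)
    rec <- function(i, j) {
        if (j - i < 1L) return(0)
        key <- paste(i, j)
        if (!is.null(memo[[key]])) return(memo[[key]])
        best <- min(rec(i + 1L, j), rec(i, j - 1L))
        if (j - i > min_loop) {
            s <- score(chars[i], chars[j])
            if (s < 0) best <- min(best, rec(i + 1L, j - 1L) + s)
        }
        if (j - i >= 2L)
            for (k in (i + 1L):(j - 1L))
                best <- min(best, rec(i, k) + rec(k + 1L, j))
        memo[[key]] <- best
        best
    }
    rec(1L, n)
}

# Linearly separable two-feature toy set: coding mass at (+1,+1),
# noncoding at (-1,-1).
toySeparable <- function(n_per_class = 20L, seed = 11L) {
    set.seed(seed)
    x <- rbind(
        matrix(rnorm(2 * n_per_class, mean = 1, sd = 0.15), ncol = 2),
        matrix(rnorm(2 * n_per_class, mean = -1, sd = 0.15), ncol = 2))
    feats <- data.frame(transcript_id = sprintf("t%02d", seq_len(2 * n_per_class)),
                        orf_ratio = (x[, 1] + 2) / 4,
                        mfe = x[, 2] * 100 - 150)
    labels <- rep(c("coding", "noncoding"), each = n_per_class)
    list(features = feats, labels = labels)
}

writeLines2 <- function(lines, path) {
    writeLines(lines, path)
    path
}
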