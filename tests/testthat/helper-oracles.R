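# Independent brute-force oracles used by the property tests.  These are
# deliberately self-contained (no calls into the package's scoring or
# folding paths) so they can serve as references.

# exhaustive enumeration of nested pairings: maximum number of
# {AU, GC, GU} pairs with hairpin loops of at least minLoop unpaired bases
bruteMaxPairs <- function(seq, minLoop = 3L, allowGU = TRUE) {
    s <- strsplit(seq, "")[[1]]
    ok <- function(a, b) {
        key <- paste0(a, b)
        key %in% c("AU", "UA", "GC", "CG") ||
            (allowGU && key %in% c("GU", "UG"))
    }
    rec <- function(i, j) {
        if (i >= j || j - i <= minLoop) return(0L)
        best <- rec(i + 1L, j)
        for (k in (i + minLoop + 1L):j) {
            if (ok(s[i], s[k]))
                best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
        }
        best
    }
    rec(1L, length(s))
}

# brute-force longest AUG..stop ORF over the three forward frames, nt
# including the stop codon
bruteLongestOrf <- function(seq) {
    ch <- strsplit(seq, "")[[1]]
    n <- length(ch)
    best <- 0L
    if (n < 6L) return(best)
    for (i in seq_len(n - 5L)) {
        if (paste(ch[i:(i + 2L)], collapse = "") != "AUG") next
        j <- i + 3L
        while (j + 2L <= n) {
            codon <- paste(ch[j:(j + 2L)], collapse = "")
            if (codon %in% c("UAA", "UAG", "UGA")) {
                best <- max(best, j + 2L - i + 1L)
                break
            }
            j <- j + 3L
        }
    }
    best
}

# self-contained re-scoring of every offset of a transcript against a
# miRNA under the mismatch criteria (weights 0 / 0.5 / 1); returns a
# data.frame of 0-based starts with weighted counts and the 3-criterion
# verdict
bruteScanMismatch <- function(mirSeq, txSeq, maxTotal = 4,
                              forbidden = 10:11, fpWin = 1:12,
                              maxFp = 2.5) {
    ms <- strsplit(mirSeq, "")[[1]]
    ts <- strsplit(txSeq, "")[[1]]
    m <- length(ms); n <- length(ts)
    if (n < m) return(data.frame(start = integer(), total = numeric(),
                                 fp = numeric(), pass = logical()))
    wc <- c(A = "U", C = "G", G = "C", U = "A")
    wob <- c(G = "U", U = "G")
    rows <- lapply(0:(n - m), function(st) {
        site <- rev(ts[(st + 1):(st + m)])  # 3'->5', aligned
        w <- vapply(seq_len(m), function(i) {
            if (wc[[ms[i]]] == site[i]) 0
            else if (!is.na(wob[ms[i]]) && wob[[ms[i]]] == site[i]) 0.5
            else 1
        }, numeric(1))
        data.frame(start = st, total = sum(w), fp = sum(w[fpWin]),
                   pass = sum(w) <= maxTotal && sum(w[forbidden]) == 0 &&
                       sum(w[fpWin]) <= maxFp)
    })
    do.call(rbind, rows)
}

# construct y with an exact sample Pearson correlation rho against x
exactCorVector <- function(x, rho, seed = 1L) {
    set.seed(seed)
    z <- stats::rnorm(length(x))
    zr <- stats::residuals(stats::lm(z ~ x))
    xs <- as.numeric(scale(x))
    zs <- as.numeric(scale(zr))
    rho * xs + sqrt(1 - rho^2) * zs
}

randomRnaSeq <- function(len) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

mismatchOnlyCriteria <- function(...) {
    filterCriteria(enabled = c(total = TRUE, central = TRUE,
                               fivePrime = TRUE, energy = FALSE), ...)
}
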