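#' Filter small-RNA reads by length
#'
#' Keeps reads whose length lies within the inclusive bounds (18-30 nt by
#' default, the size window isolated for small-RNA libraries) and records
#' how many were kept and dropped.
#'
#' @param reads named character vector of reads, or an XStringSet.
#' @param minLen,maxLen inclusive nt bounds.
#' @return a \linkS4class{ReadSet}.
#' @export
filterReads <- function(reads, minLen = 18L, maxLen = 30L) {
    if (minLen > maxLen) stop("minLen > maxLen")
    seqs <- as.character(reads)
    if (length(seqs)) seqs <- normalizeRna(seqs, "reads")
    keep <- nchar(seqs) >= minLen & nchar(seqs) <= maxLen
    new("ReadSet", reads = seqs[keep],
        lengthRange = as.integer(c(minLen, maxLen)),
        nKept = sum(keep), nDropped = sum(!keep))
}

#' @rdname accessors
#' @export
setMethod("reads", "ReadSet", function(x) x@reads)

setMethod("show", "ReadSet", function(object) {
    cat(sprintf("ReadSet: %d reads (%d-%d nt; %d dropped on filtering)\n",
                length(object@reads), object@lengthRange[1],
                object@lengthRange[2], object@nDropped))
})

#' Read-length histogram
#'
#' @param readset a \linkS4class{ReadSet}.
#' @return list with \code{counts} (named by length), \code{modalLength}
#'   and \code{modalFraction}.
#' @export
lengthHistogram <- function(readset) {
    stopifnot(is(readset, "ReadSet"))
    len <- nchar(readset@reads)
    counts <- table(len)
    if (!length(len))
        return(list(counts = counts, modalLength = NA_integer_,
                    modalFraction = NA_real_))
    modal <- which.max(counts)
    list(counts = counts,
         modalLength = as.integer(names(counts)[modal]),
         modalFraction = as.numeric(counts[modal]) / length(len))
}

#' 5'-nucleotide bias of a read set
#'
#' Frequency of A, C, G, U at read position 1; small-RNA libraries loaded
#' into Argonaute typically show a 5'-U excess.
#'
#' @param readset a \linkS4class{ReadSet}.
#' @return named numeric frequencies summing to 1.
#' @export
fivePrimeBias <- function(readset) {
    stopifnot(is(readset, "ReadSet"))
    if (!length(readset@reads)) stop("empty read set")
    first <- substr(readset@reads, 1L, 1L)
    out <- c(A = 0, C = 0, G = 0, U = 0)
    tab <- table(first) / length(first)
    out[names(tab)] <- as.numeric(tab)
    out
}

# pairing predicate for the fold: Watson-Crick, plus G:U when allowed
.canPair <- function(a, b, allowGU) {
    key <- paste0(a, b)
    key %in% c("AU", "UA", "GC", "CG") ||
        (allowGU && key %in% c("GU", "UG"))
}

#' Maximum base-pairing fold (Nussinov)
#'
#' Dynamic program maximizing the number of nested \{A:U, G:C, G:U\} pairs
#' with hairpin loops of at least \code{minLoop} unpaired bases.  The
#' traceback is deterministic: whenever the optimum can be achieved by
#' pairing the leftmost position, it is paired with the smallest admissible
#' partner.  This is a maximum-pairing stand-in for an energy-based fold.
#'
#' @param seq RNA sequence.
#' @param minLoop minimum unpaired span enclosed by a pair.
#' @param allowGU allow G:U wobble pairs?
#' @return a \linkS4class{HairpinFold}.
#' @examples
#' nussinovFold("GGGAAAACCC")  # "(((....)))"
#' @export
nussinovFold <- function(seq, minLoop = 3L, allowGU = TRUE) {
    seq <- normalizeRna(seq, "fold input")
    s <- strsplit(seq, "")[[1]]
    n <- length(s)
    emptyFold <- function() new("HairpinFold", seq = seq,
                                pairs = matrix(integer(), ncol = 2,
                                               dimnames = list(NULL, c("i", "j"))),
                                structure = paste(rep(".", n), collapse = ""),
                                nPairs = 0L)
    if (n <= minLoop + 1L) return(emptyFold())
    M <- matrix(0L, n, n)
    for (span in (minLoop + 1L):(n - 1L)) {
        for (i in seq_len(n - span)) {
            j <- i + span
            best <- M[i + 1L, j]  # i unpaired
            for (k in (i + minLoop + 1L):j) {
                if (.canPair(s[i], s[k], allowGU)) {
                    inner <- if (k - i > 1L) M[i + 1L, k - 1L] else 0L
                    rest <- if (k < j) M[k + 1L, j] else 0L
                    cand <- 1L + inner + rest
                    if (cand > best) best <- cand
                }
            }
            M[i, j] <- best
        }
    }
    pairs <- matrix(integer(), ncol = 2)
    stack <- list(c(1L, n))
    while (length(stack)) {
        iv <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        i <- iv[1]; j <- iv[2]
        if (i >= j || j - i <= minLoop || M[i, j] == 0L) next
        paired <- FALSE
        for (k in (i + minLoop + 1L):j) {  # smallest partner first
            if (.canPair(s[i], s[k], allowGU)) {
                inner <- if (k - i > 1L) M[i + 1L, k - 1L] else 0L
                rest <- if (k < j) M[k + 1L, j] else 0L
                if (M[i, j] == 1L + inner + rest) {
                    pairs <- rbind(pairs, c(i, k))
                    if (k - i > 1L) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
                    if (k < j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
                    paired <- TRUE
                    break
                }
            }
        }
        if (!paired) stack[[length(stack) + 1L]] <- c(i + 1L, j)
    }
    if (!nrow(pairs)) return(emptyFold())
    db <- rep(".", n)
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
    pairs0 <- pairs - 1L  # report 0-based
    pairs0 <- pairs0[order(pairs0[, 1]), , drop = FALSE]
    colnames(pairs0) <- c("i", "j")
    new("HairpinFold", seq = seq, pairs = pairs0,
        structure = paste(db, collapse = ""), nPairs = nrow(pairs0))
}

setMethod("show", "HairpinFold", function(object) {
    cat(sprintf("HairpinFold: %d pairs over %d nt\n  %s\n  %s\n",
                object@nPairs, nchar(object@seq), object@seq,
                object@structure))
})

# innermost (hairpin-closing) pairs: no other pair nested inside
.hairpinLoops <- function(fold) {
    p <- fold@pairs
    if (!nrow(p)) return(p)
    inner <- vapply(seq_len(nrow(p)), function(a) {
        !any(p[, 1] > p[a, 1] & p[, 2] < p[a, 2])
    }, logical(1))
    p[inner, , drop = FALSE]
}

#' Validate a candidate miRNA precursor hairpin
#'
#' A precursor is accepted when the mature miRNA occurs in it, lies entirely
#' on one arm of the fold's largest hairpin loop (entirely 5' of the loop's
#' closing pair or entirely 3' of it), and at least
#' \code{minPairedFraction} of its positions are base-paired in the
#' maximum-pairing fold.  These criteria are a documented stand-in for a
#' full precursor-prediction pipeline.
#'
#' @param precursor candidate precursor sequence.
#' @param mature a \linkS4class{MatureMiRNA} (or bare sequence).
#' @param minPairedFraction minimum fraction of paired mature positions.
#' @param minLoop,allowGU passed to \code{\link{nussinovFold}}.
#' @return list with \code{valid}, \code{reason}, \code{pairedFraction},
#'   \code{arm} ("5p"/"3p"/NA), \code{matureStart} (0-based) and the
#'   \code{fold}.
#' @export
validatePrecursor <- function(precursor, mature, minPairedFraction = 0.6,
                              minLoop = 3L, allowGU = TRUE) {
    if (!is(mature, "MatureMiRNA")) mature <- MatureMiRNA("mature", mature)
    precursor <- normalizeRna(precursor, "precursor")
    pos <- regexpr(mature@seq, precursor, fixed = TRUE)[1]
    out <- list(valid = FALSE, reason = "", pairedFraction = NA_real_,
                arm = NA_character_, matureStart = NA_integer_, fold = NULL)
    if (pos < 0) {
        out$reason <- "mature sequence not found in precursor"
        return(out)
    }
    m0 <- pos - 1L                     # 0-based start
    m1 <- m0 + nchar(mature@seq) - 1L  # 0-based inclusive end
    out$matureStart <- m0
    fold <- nussinovFold(precursor, minLoop = minLoop, allowGU = allowGU)
    out$fold <- fold
    if (!fold@nPairs) {
        out$reason <- "precursor does not fold"
        return(out)
    }
    loops <- .hairpinLoops(fold)
    main <- loops[which.max(loops[, 2] - loops[, 1]), ]
    pairedIdx <- c(fold@pairs[, 1], fold@pairs[, 2])
    out$pairedFraction <- mean(m0:m1 %in% pairedIdx)
    if (m1 <= main[1]) out$arm <- "5p"
    else if (m0 >= main[2]) out$arm <- "3p"
    else {
        out$reason <- "mature spans the main hairpin loop"
        return(out)
    }
    if (out$pairedFraction < minPairedFraction) {
        out$reason <- sprintf("only %.0f%% of mature positions paired",
                              100 * out$pairedFraction)
        return(out)
    }
    out$valid <- TRUE
    out$reason <- "ok"
    out
}
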