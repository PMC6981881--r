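#' Classify one miRNA:target base apposition
#'
#' Watson-Crick pairs (A:U, U:A, G:C, C:G) map to \code{"|"}, G:U wobbles
#' (G:U, U:G) to \code{"o"}, everything else to \code{"x"}.  Vectorized over
#' equal-length inputs.
#'
#' @param mirnaBase base(s) on the miRNA strand.
#' @param targetBase facing base(s) on the target strand.
#' @return character vector over \code{"|"}, \code{"o"}, \code{"x"}.
#' @examples
#' classifyPair("U", "A")  # "|"
#' classifyPair("G", "U")  # "o"
#' classifyPair("G", "G")  # "x"
#' @export
classifyPair <- function(mirnaBase, targetBase) {
    a <- normalizeRna(mirnaBase, "miRNA base")
    b <- normalizeRna(targetBase, "target base")
    key <- paste0(a, b)
    out <- rep("x", length(key))
    out[key %in% c("AU", "UA", "GC", "CG")] <- "|"
    out[key %in% c("GU", "UG")] <- "o"
    out
}

#' Align a miRNA with a same-length target region
#'
#' Builds the ungapped antiparallel duplex between a mature miRNA (5'->3')
#' and a target region written 3'->5', classifying every apposition with
#' \code{\link{classifyPair}}.  Gapped or bulged duplexes are not supported
#' and unequal lengths are rejected.
#'
#' @param mirna a \linkS4class{MatureMiRNA} (or a bare sequence, coerced).
#' @param site3to5 target region 3'->5', same length as the miRNA.
#' @return an \linkS4class{RNADuplex}.
#' @examples
#' mir <- MatureMiRNA("novel-m3234-5p", "UCCAGCCCGGCGUUGAUGGC")
#' d <- alignDuplex(mir, "AGGUGGGGCCGGAAGUACCU")
#' pairingString(d)  # "||||x||||||x||x||||x"
#' @export
alignDuplex <- function(mirna, site3to5) {
    if (!is(mirna, "MatureMiRNA")) mirna <- MatureMiRNA("miRNA", mirna)
    site3to5 <- normalizeRna(site3to5, "target region")
    if (nchar(site3to5) != nchar(mirna@seq))
        stop(sprintf(
            "site length %d != miRNA length %d: gapped duplexes unsupported",
            nchar(site3to5), nchar(mirna@seq)))
    pairing <- paste(classifyPair(strsplit(mirna@seq, "")[[1]],
                                  strsplit(site3to5, "")[[1]]),
                     collapse = "")
    new("RNADuplex", mirna = mirna, site3to5 = site3to5, pairing = pairing)
}

#' Perfect-complement duplex of a miRNA
#'
#' @param mirna a \linkS4class{MatureMiRNA}.
#' @return the all-Watson-Crick \linkS4class{RNADuplex}.
#' @export
perfectComplementDuplex <- function(mirna) {
    if (!is(mirna, "MatureMiRNA")) mirna <- MatureMiRNA("miRNA", mirna)
    alignDuplex(mirna, rnaComplement(mirna@seq))
}

#' @rdname accessors
#' @export
setMethod("pairingString", "RNADuplex", function(x) x@pairing)

#' @rdname accessors
#' @export
setMethod("siteSeq3to5", "RNADuplex", function(x) x@site3to5)

#' @rdname accessors
#' @export
setMethod("siteSeq5to3", "RNADuplex", function(x) reverseSeq(x@site3to5))

#' @rdname accessors
#' @export
setMethod("mirnaId", "RNADuplex", function(x) x@mirna@id)

#' @rdname accessors
#' @export
setMethod("mirnaSeq", "RNADuplex", function(x) x@mirna@seq)

setMethod("show", "RNADuplex", function(object) {
    cat(sprintf("RNADuplex (%d nt, %s)\n", nchar(object@pairing),
                object@mirna@id))
    cat(sprintf("  miRNA  5'-%s-3'\n", object@mirna@seq))
    cat(sprintf("            %s\n", object@pairing))
    cat(sprintf("  target 3'-%s-5'\n", object@site3to5))
})

#' Weighted mismatch count over a duplex window
#'
#' Sums the mismatch weights of the pairing symbols in a 1-based inclusive
#' position window (the full duplex when \code{window} is NULL).  Watson-Crick
#' pairs contribute 0, G:U wobbles 0.5 and other mismatches 1 under the
#' default weights.  Additive over disjoint windows.
#'
#' @param x an \linkS4class{RNADuplex} or a bare pairing string.
#' @param window integer pair \code{c(lo, hi)}, 1-based inclusive.
#' @param weights a \linkS4class{MismatchWeights}.
#' @return weighted mismatch count.
#' @examples
#' weightedMismatch("o||xx||||||||o||||||", c(1, 12))  # 2.5
#' @export
#' @rdname weightedMismatch
setMethod("weightedMismatch", "RNADuplex", function(x, window, weights) {
    weightedMismatch(x@pairing, window, weights)
})

#' @rdname weightedMismatch
#' @export
setMethod("weightedMismatch", "character", function(x, window, weights) {
    stopifnot(length(x) == 1L)
    sym <- strsplit(x, "")[[1]]
    if (!all(sym %in% c("|", "o", "x")))
        stop("pairing string may only contain |, o, x")
    n <- length(sym)
    if (is.null(window)) window <- c(1L, n)
    window <- as.integer(window)
    if (length(window) != 2L || window[1] > window[2])
        stop("window must be c(lo, hi) with lo <= hi")
    if (window[1] < 1L || window[2] > n)
        stop(sprintf("window [%d, %d] outside duplex positions [1, %d]",
                     window[1], window[2], n))
    w <- c("|" = weights@watsonCrick, "o" = weights@guWobble,
           "x" = weights@other)
    sum(w[sym[window[1]:window[2]]])
})

#' Evaluate the four target-site filter criteria
#'
#' Applies the weighted-mismatch and energy-ratio criteria to a duplex.
#' Criterion 2 ("no mismatches in the central window") fails on any nonzero
#' weighted mismatch there, so a 0.5-weight G:U wobble fails under the strict
#' default; set \code{centralWobbleFails = FALSE} in the criteria to count
#' only full mismatches.  Disabled criteria are reported but excluded from
#' the overall verdict.
#'
#' @param duplex an \linkS4class{RNADuplex}.
#' @param energyRatio precomputed |dG| ratio against the perfect complement
#'   (see \code{\link{energyRatio}}); may be NA when the energy criterion is
#'   disabled.
#' @param criteria a \linkS4class{FilterCriteria}.
#' @param weights a \linkS4class{MismatchWeights}.
#' @return named logical vector: \code{total}, \code{central},
#'   \code{fivePrime}, \code{energy}, \code{pass}.
#' @export
checkCriteria <- function(duplex, energyRatio = NA_real_,
                          criteria = filterCriteria(),
                          weights = mismatchWeights()) {
    total <- weightedMismatch(duplex, NULL, weights)
    fp <- weightedMismatch(duplex, criteria@fivePrimeWindow, weights)
    if (criteria@centralWobbleFails) {
        central <- weightedMismatch(duplex, criteria@forbiddenWindow, weights)
        okCentral <- central == 0
    } else {
        sym <- strsplit(pairingString(duplex), "")[[1]]
        win <- criteria@forbiddenWindow[1]:criteria@forbiddenWindow[2]
        okCentral <- !any(sym[win] == "x")
    }
    v <- c(total = total <= criteria@maxTotalMismatch,
           central = okCentral,
           fivePrime = fp <= criteria@maxFivePrimeMismatch,
           energy = if (is.na(energyRatio)) NA
                    else energyRatio >= criteria@minEnergyRatio)
    use <- criteria@enabled[names(v)]
    considered <- v[use]
    pass <- length(considered) == 0L || (!anyNA(considered) && all(considered))
    if (anyNA(considered))
        stop("energy criterion enabled but energyRatio is NA")
    c(v, pass = pass)
}

#' Scan a transcript for candidate miRNA target sites
#'
#' Evaluates every offset of the transcript exhaustively: the window read
#' 5'->3' on the transcript is reversed to 3'->5' so that target position i
#' faces miRNA position i, then aligned, scored and filtered.  Transcripts
#' shorter than the miRNA yield no sites.
#'
#' @param mirna a \linkS4class{MatureMiRNA}.
#' @param transcriptSeq transcript sequence 5'->3' (T normalized to U).
#' @param criteria a \linkS4class{FilterCriteria}.
#' @param weights a \linkS4class{MismatchWeights}.
#' @param params a \linkS4class{NNParameterSet} for the energy criterion.
#' @param transcriptId id used in the result table.
#' @param keepAll keep failing sites too (sorted by start)?
#' @param bestPerTranscript collapse to the minimum-mismatch passing site
#'   (ties broken by smallest start)?
#' @return data.frame with 0-based half-open coordinates (\code{start},
#'   \code{end}), the site in both orientations, the pairing string, weighted
#'   mismatch counts, energy ratio, the four per-criterion verdicts and the
#'   overall \code{pass}; passing sites sorted by (total_mismatch, start).
#' @export
scanTranscript <- function(mirna, transcriptSeq,
                           criteria = filterCriteria(),
                           weights = mismatchWeights(),
                           params = nnParameters(),
                           transcriptId = "transcript",
                           keepAll = FALSE,
                           bestPerTranscript = FALSE) {
    if (!is(mirna, "MatureMiRNA")) mirna <- MatureMiRNA("miRNA", mirna)
    if (!nzchar(mirna@seq)) stop("empty miRNA")
    tx <- normalizeRna(transcriptSeq, sprintf("transcript '%s'", transcriptId))
    m <- nchar(mirna@seq)
    n <- nchar(tx)
    empty <- data.frame(transcript_id = character(), start = integer(),
                        end = integer(), site_5to3 = character(),
                        site_3to5 = character(), pairing = character(),
                        total_mismatch = numeric(),
                        five_prime_mismatch = numeric(),
                        energy_ratio = numeric(), crit_total = logical(),
                        crit_central = logical(), crit_five_prime = logical(),
                        crit_energy = logical(), pass = logical(),
                        stringsAsFactors = FALSE)
    if (n < m) return(empty)
    needEnergy <- criteria@enabled[["energy"]]
    # vectorized scan: integer-coded bases, lookup tables for pairing
    # symbols, weights and stacking increments
    baseIdx <- c(A = 1L, C = 2L, G = 3L, U = 4L)
    sIdx <- baseIdx[strsplit(tx, "")[[1]]]
    mIdx <- baseIdx[strsplit(mirna@seq, "")[[1]]]
    symMat <- matrix("x", 4, 4)
    for (a in names(baseIdx)) for (b in names(baseIdx))
        symMat[baseIdx[[a]], baseIdx[[b]]] <- classifyPair(a, b)
    wLookup <- c("|" = weights@watsonCrick, "o" = weights@guWobble,
                 "x" = weights@other)
    fpWin <- criteria@fivePrimeWindow[1]:criteria@fivePrimeWindow[2]
    cWin <- criteria@forbiddenWindow[1]:criteria@forbiddenWindow[2]
    if (needEnergy) {
        stackArr <- array(NA_real_, c(4, 4, 4, 4))
        for (key in names(params@stackDg)) {
            ch <- strsplit(key, "")[[1]]  # "AB/CD"
            stackArr[baseIdx[[ch[1]]], baseIdx[[ch[2]]],
                     baseIdx[[ch[4]]], baseIdx[[ch[5]]]] <-
                params@stackDg[[key]]
        }
        basisDg <- duplexDeltaG(perfectComplementDuplex(mirna), params)@deltaG
        if (basisDg >= 0)
            stop(sprintf("degenerate miRNA '%s': perfect-complement dG >= 0",
                         mirna@id))
    }
    offsets <- 0:(n - m)
    nOff <- length(offsets)
    site5 <- site3 <- pairingV <- character(nOff)
    totalW <- fpW <- erV <- numeric(nOff)
    okC <- logical(nOff)
    for (ii in seq_len(nOff)) {
        s <- offsets[ii]
        winIdx <- sIdx[(s + 1L):(s + m)]
        tIdx <- rev(winIdx)                 # 3'->5', aligned with miRNA
        sym <- symMat[cbind(mIdx, tIdx)]
        wv <- wLookup[sym]
        totalW[ii] <- sum(wv)
        fpW[ii] <- sum(wv[fpWin])
        okC[ii] <- if (criteria@centralWobbleFails) sum(wv[cWin]) == 0
                   else !any(sym[cWin] == "x")
        site5[ii] <- paste(names(baseIdx)[winIdx], collapse = "")
        site3[ii] <- paste(names(baseIdx)[tIdx], collapse = "")
        pairingV[ii] <- paste(sym, collapse = "")
        if (needEnergy) {
            paired <- sym %in% c("|", "o")
            both <- paired[-m] & paired[-1L]
            dg <- params@initDg +
                params@loopDg * sum(rle(!paired)$values)
            if (any(both))
                dg <- dg + sum(stackArr[cbind(mIdx[-m][both], mIdx[-1L][both],
                                              tIdx[-m][both], tIdx[-1L][both])])
            erV[ii] <- if (dg >= 0) 0 else abs(dg) / abs(basisDg)
        } else erV[ii] <- NA_real_
    }
    critTotal <- totalW <= criteria@maxTotalMismatch
    critFp <- fpW <= criteria@maxFivePrimeMismatch
    critEnergy <- if (needEnergy) erV >= criteria@minEnergyRatio
                  else rep(NA, nOff)
    en <- criteria@enabled
    passV <- rep(TRUE, nOff)
    if (en[["total"]]) passV <- passV & critTotal
    if (en[["central"]]) passV <- passV & okC
    if (en[["fivePrime"]]) passV <- passV & critFp
    if (en[["energy"]]) passV <- passV & critEnergy
    res <- data.frame(transcript_id = transcriptId, start = offsets,
                      end = offsets + m, site_5to3 = site5,
                      site_3to5 = site3, pairing = pairingV,
                      total_mismatch = totalW, five_prime_mismatch = fpW,
                      energy_ratio = erV, crit_total = critTotal,
                      crit_central = okC, crit_five_prime = critFp,
                      crit_energy = critEnergy, pass = passV,
                      stringsAsFactors = FALSE)
    if (!keepAll) {
        res <- res[res$pass, , drop = FALSE]
        res <- res[order(res$total_mismatch, res$start), , drop = FALSE]
        if (bestPerTranscript && nrow(res) > 1L)
            res <- res[1L, , drop = FALSE]
    } else {
        res <- res[order(res$start), , drop = FALSE]
    }
    rownames(res) <- NULL
    res
}

#' Scan several transcripts
#'
#' @param mirna a \linkS4class{MatureMiRNA}.
#' @param transcripts named character vector (or XStringSet) of transcript
#'   sequences.
#' @param ... passed to \code{\link{scanTranscript}}.
#' @return row-bound site table across transcripts.
#' @export
scanTranscripts <- function(mirna, transcripts, ...) {
    ids <- names(transcripts)
    seqs <- as.character(transcripts)
    if (is.null(ids)) ids <- names(seqs)
    if (is.null(ids)) ids <- sprintf("tx%03d", seq_along(seqs))
    do.call(rbind, lapply(seq_along(seqs), function(i)
        scanTranscript(mirna, seqs[[i]], transcriptId = ids[[i]], ...)))
}
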