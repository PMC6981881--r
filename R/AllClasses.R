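#' @import methods
NULL

#' Mature microRNA
#'
#' A mature miRNA sequence written 5'->3' over the RNA alphabet.  DNA input
#' (T, lower case) is normalized on construction.  Mature miRNAs outside the
#' canonical 18-30 nt small-RNA size range are accepted with a warning.
#'
#' @slot id single identifier string.
#' @slot seq RNA sequence 5'->3' (characters A, C, G, U).
#' @export
setClass("MatureMiRNA", representation(id = "character", seq = "character"))

setValidity("MatureMiRNA", function(object) {
    if (length(object@id) != 1L || !nzchar(object@id))
        return("'id' must be a single non-empty string")
    if (length(object@seq) != 1L || !nzchar(object@seq))
        return("'seq' must be a single non-empty RNA string")
    bad <- setdiff(strsplit(object@seq, "")[[1]], c("A", "C", "G", "U"))
    if (length(bad))
        return(sprintf("non-RNA character(s) in seq: %s",
                       paste(unique(bad), collapse = ", ")))
    TRUE
})

#' Ungapped miRNA:target duplex
#'
#' An antiparallel, gap-free alignment of a mature miRNA (5'->3') with a
#' same-length target region written 3'->5', so that position i of the target
#' faces position i of the miRNA.  The pairing string uses the vocabulary
#' \code{|} (Watson-Crick), \code{o} (G:U wobble) and \code{x} (mismatch),
#' reported in miRNA 5'->3' order.  Positions are 1-based from the miRNA 5'
#' end throughout the package.
#'
#' @slot mirna the \linkS4class{MatureMiRNA}.
#' @slot site3to5 target region, 3'->5', aligned position-by-position.
#' @slot pairing pairing string over \code{|}, \code{o}, \code{x}.
#' @export
setClass("RNADuplex",
         representation(mirna = "MatureMiRNA", site3to5 = "character",
                        pairing = "character"))

setValidity("RNADuplex", function(object) {
    m <- object@mirna@seq
    if (nchar(object@site3to5) != nchar(m))
        return("site and miRNA lengths differ (gapped duplexes unsupported)")
    if (nchar(object@pairing) != nchar(m))
        return("pairing string length differs from duplex length")
    expected <- paste(classifyPair(strsplit(m, "")[[1]],
                                   strsplit(object@site3to5, "")[[1]]),
                      collapse = "")
    if (!identical(expected, object@pairing))
        return("pairing string is inconsistent with the aligned bases")
    TRUE
})

#' Mismatch weights for duplex scoring
#'
#' Watson-Crick pairs count 0, G:U wobbles count 0.5 and any other
#' apposition counts 1 by default.
#'
#' @export
setClass("MismatchWeights",
         representation(watsonCrick = "numeric", guWobble = "numeric",
                        other = "numeric"))

setValidity("MismatchWeights", function(object) {
    w <- c(object@watsonCrick, object@guWobble, object@other)
    if (length(w) != 3L || anyNA(w)) return("weights must be single numbers")
    if (object@guWobble < 0 || object@guWobble > object@other)
        return("need 0 <= guWobble <= other")
    TRUE
})

#' Target-site filter criteria
#'
#' The four-criterion plant-style target filter: (1) total weighted mismatch
#' over the whole duplex at most \code{maxTotalMismatch}; (2) no mismatches in
#' the central window (positions 10-11 by default); (3) weighted mismatch over
#' the 5' window (positions 1-12) at most \code{maxFivePrimeMismatch};
#' (4) hybridization free energy at least \code{minEnergyRatio} of the
#' perfect-complement energy.  Each criterion can be toggled via
#' \code{enabled}.  \code{centralWobbleFails} controls whether a G:U wobble
#' in the central window counts against criterion 2 (strict reading of
#' "no mismatches"; the default).
#'
#' @export
setClass("FilterCriteria",
         representation(maxTotalMismatch = "numeric",
                        forbiddenWindow = "integer",
                        fivePrimeWindow = "integer",
                        maxFivePrimeMismatch = "numeric",
                        minEnergyRatio = "numeric",
                        enabled = "logical",
                        centralWobbleFails = "logical"))

setValidity("FilterCriteria", function(object) {
    if (any(c(object@maxTotalMismatch, object@maxFivePrimeMismatch,
              object@minEnergyRatio) < 0))
        return("thresholds must be >= 0")
    for (w in list(object@forbiddenWindow, object@fivePrimeWindow)) {
        if (length(w) != 2L || w[1] > w[2] || w[1] < 1L)
            return("windows must be 1-based inclusive ranges lo <= hi")
    }
    if (!identical(sort(names(object@enabled)),
                   sort(c("total", "central", "fivePrime", "energy"))))
        return("'enabled' needs flags total, central, fivePrime, energy")
    TRUE
})

#' Nearest-neighbor duplex energy parameters
#'
#' Helix stacking increments for adjacent paired doublets (top strand read
#' 5'->3', bottom strand 3'->5'), a duplex initiation penalty, and a flat
#' penalty per maximal run of unpaired positions.  All values in kcal/mol at
#' 37 C.  A doublet absent from the table is a hard error, never silently 0.
#'
#' @slot stackDg named numeric, names like \code{"GC/CG"}.
#' @slot initDg duplex initiation penalty (> 0).
#' @slot loopDg penalty per maximal mismatch run (>= 0).
#' @slot sourceTag provenance of the parameter values.
#' @export
setClass("NNParameterSet",
         representation(stackDg = "numeric", initDg = "numeric",
                        loopDg = "numeric", sourceTag = "character"))

setValidity("NNParameterSet", function(object) {
    if (is.null(names(object@stackDg)) || anyNA(object@stackDg))
        return("stackDg must be a complete named numeric vector")
    if (object@initDg <= 0) return("initDg must be > 0")
    if (object@loopDg < 0) return("loopDg must be >= 0")
    wc <- c("AU", "UA", "CG", "GC")
    comp <- c(A = "U", U = "A", C = "G", G = "C")
    for (top in wc) {
        for (bot in wc) {
            a <- strsplit(top, "")[[1]]; b <- strsplit(bot, "")[[1]]
            if (comp[[a[1]]] == b[1] && comp[[a[2]]] == b[2]) {
                key <- paste0(top, "/", bot)
                if (!key %in% names(object@stackDg))
                    return(sprintf("missing Watson-Crick stack %s", key))
                if (object@stackDg[[key]] >= 0)
                    return(sprintf("Watson-Crick stack %s must be < 0", key))
            }
        }
    }
    TRUE
})

#' Duplex free-energy result
#'
#' @slot deltaG free energy of the duplex, kcal/mol.
#' @slot nStacks number of stacking terms summed.
#' @slot nLoops number of maximal mismatch runs penalized.
#' @export
setClass("EnergyResult",
         representation(deltaG = "numeric", nStacks = "integer",
                        nLoops = "integer"))

#' Filtered small-RNA read set
#'
#' @slot reads named character vector of RNA reads.
#' @slot lengthRange inclusive nt bounds applied.
#' @slot nKept,nDropped filtering bookkeeping.
#' @export
setClass("ReadSet",
         representation(reads = "character", lengthRange = "integer",
                        nKept = "integer", nDropped = "integer"))

setValidity("ReadSet", function(object) {
    if (length(object@reads)) {
        len <- nchar(object@reads)
        if (any(len < object@lengthRange[1] | len > object@lengthRange[2]))
            return("reads outside the stated length range")
    }
    TRUE
})

#' Maximum base-pairing hairpin fold
#'
#' Nested secondary structure maximizing the number of {A:U, G:C, G:U} pairs,
#' with hairpin loops of at least \code{min_loop} unpaired bases.
#'
#' @slot seq the folded RNA sequence.
#' @slot pairs two-column integer matrix of 0-based (i, j) pairs, i < j.
#' @slot structure dot-bracket string.
#' @slot nPairs number of base pairs.
#' @export
setClass("HairpinFold",
         representation(seq = "character", pairs = "matrix",
                        structure = "character", nPairs = "integer"))

setValidity("HairpinFold", function(object) {
    p <- object@pairs
    if (nrow(p)) {
        if (any(p[, 1] >= p[, 2])) return("pairs must have i < j")
        idx <- c(p[, 1], p[, 2])
        if (anyDuplicated(idx)) return("an index occurs in more than one pair")
        # nested (non-crossing): for sorted-by-i pairs no i < i' < j < j'
        o <- order(p[, 1])
        pi <- p[o, 1]; pj <- p[o, 2]
        if (nrow(p) > 1L) {
            for (a in seq_len(nrow(p) - 1L)) {
                b <- which(pi > pi[a] & pi < pj[a] & pj > pj[a])
                if (length(b)) return("crossing (pseudoknotted) pairs")
            }
        }
    }
    TRUE
})

#' Circadian expression profile
#'
#' Fold changes relative to the baseline timepoint (ZT2 by convention), so
#' the baseline entry is exactly 1.
#'
#' @slot timepoints hours on the Zeitgeber Time scale.
#' @slot foldChanges fold change relative to baseline, same length.
#' @slot photoperiod light:dark descriptor such as "12:12".
#' @export
setClass("CircadianProfile",
         representation(timepoints = "numeric", foldChanges = "numeric",
                        photoperiod = "character"))

setValidity("CircadianProfile", function(object) {
    if (length(object@timepoints) != length(object@foldChanges))
        return("timepoints and foldChanges differ in length")
    TRUE
})

#' Typed miRNA / mRNA / lincRNA regulatory network
#'
#' Wraps an igraph graph whose vertices carry a \code{type} in
#' \{miRNA, mRNA, lincRNA\} and whose edges carry a \code{type} in
#' \{represses, coexpressed, shares_miRNA\}.  \code{represses} edges are
#' directed miRNA -> mRNA; the other kinds are undirected in meaning and
#' stored once with canonically ordered endpoints.
#'
#' @slot graph the underlying igraph object.
#' @export
setClass("RegulatoryNetwork", representation(graph = "ANY"))
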