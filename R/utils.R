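#' Normalize a nucleotide string to the RNA alphabet
#'
#' Upper-cases the input and converts T to U.  Any character outside
#' A, C, G, U after normalization is an error naming the offending symbol.
#'
#' @param x character vector of nucleotide strings.
#' @param what label used in error messages.
#' @return character vector over \{A, C, G, U\}.
#' @export
normalizeRna <- function(x, what = "sequence") {
    x <- chartr("t", "u", toupper(as.character(x)))
    x <- chartr("T", "U", x)
    bad <- setdiff(unique(unlist(strsplit(x, ""))), c("A", "C", "G", "U"))
    if (length(bad))
        stop(sprintf("non-RNA character(s) in %s: %s", what,
                     paste(bad, collapse = ", ")), call. = FALSE)
    x
}

#' Position-wise RNA complement
#'
#' Complements each base in place (A<->U, C<->G).  For a miRNA written
#' 5'->3' this yields its perfect-complement target region written 3'->5',
#' i.e. already aligned position-by-position.
#'
#' @param x RNA string(s).
#' @return complemented string(s), same orientation convention as described.
#' @export
rnaComplement <- function(x) chartr("ACGU", "UGCA", normalizeRna(x))

#' Reverse a sequence string
#'
#' Converts between the 3'->5' aligned representation of a target region and
#' its natural 5'->3' orientation on the transcript.
#'
#' @param x character vector.
#' @return reversed string(s).
#' @export
reverseSeq <- function(x) {
    vapply(strsplit(as.character(x), ""),
           function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Construct a mature miRNA
#'
#' @param id identifier.
#' @param seq sequence 5'->3'; T and lower case are normalized.
#' @return a \linkS4class{MatureMiRNA}.
#' @examples
#' MatureMiRNA("novel-m3234-5p", "UCCAGCCCGGCGUUGAUGGC")
#' @export
MatureMiRNA <- function(id, seq) {
    seq <- normalizeRna(seq, what = sprintf("miRNA '%s'", id))
    n <- nchar(seq)
    if (n < 18L || n > 30L)
        warning(sprintf("miRNA '%s' length %d outside the usual 18-30 nt", id, n))
    new("MatureMiRNA", id = as.character(id), seq = seq)
}

#' @rdname accessors
#' @param x an object of the relevant class.
#' @export
setMethod("mirnaId", "MatureMiRNA", function(x) x@id)

#' @rdname accessors
#' @export
setMethod("mirnaSeq", "MatureMiRNA", function(x) x@seq)

setMethod("show", "MatureMiRNA", function(object) {
    cat(sprintf("MatureMiRNA %s (%d nt)\n  5'-%s-3'\n",
                object@id, nchar(object@seq), object@seq))
})

#' Mismatch weight set
#'
#' @param watsonCrick weight of a Watson-Crick pair (default 0).
#' @param guWobble weight of a G:U wobble (default 0.5).
#' @param other weight of any other apposition (default 1).
#' @return a \linkS4class{MismatchWeights}.
#' @export
mismatchWeights <- function(watsonCrick = 0, guWobble = 0.5, other = 1) {
    new("MismatchWeights", watsonCrick = watsonCrick, guWobble = guWobble,
        other = other)
}

#' Target filter criteria
#'
#' Defaults follow the four-condition screen used for the kelp CRY-DASH
#' target search: total weighted mismatch at most 4, no mismatch at
#' positions 10-11, at most 2.5 weighted mismatches at positions 1-12, and
#' a duplex:perfect-complement energy ratio of at least 0.74.
#'
#' @param maxTotalMismatch criterion 1 threshold.
#' @param forbiddenWindow central window, 1-based inclusive.
#' @param fivePrimeWindow 5'-end window, 1-based inclusive.
#' @param maxFivePrimeMismatch criterion 3 threshold.
#' @param minEnergyRatio criterion 4 threshold.
#' @param enabled named logicals toggling the four criteria.
#' @param centralWobbleFails should a G:U wobble at positions 10-11 fail
#'   criterion 2 (strict reading; default TRUE)?
#' @return a \linkS4class{FilterCriteria}.
#' @export
filterCriteria <- function(maxTotalMismatch = 4,
                           forbiddenWindow = c(10L, 11L),
                           fivePrimeWindow = c(1L, 12L),
                           maxFivePrimeMismatch = 2.5,
                           minEnergyRatio = 0.74,
                           enabled = c(total = TRUE, central = TRUE,
                                       fivePrime = TRUE, energy = TRUE),
                           centralWobbleFails = TRUE) {
    new("FilterCriteria",
        maxTotalMismatch = maxTotalMismatch,
        forbiddenWindow = as.integer(forbiddenWindow),
        fivePrimeWindow = as.integer(fivePrimeWindow),
        maxFivePrimeMismatch = maxFivePrimeMismatch,
        minEnergyRatio = minEnergyRatio,
        enabled = enabled,
        centralWobbleFails = centralWobbleFails)
}

#' ORF length arithmetic
#'
#' Number of amino acids encoded by an open reading frame of \code{ntLen}
#' nucleotides including its stop codon: one codon per residue plus the
#' stop, so \code{ntLen/3 - 1}.
#'
#' @param ntLen ORF length in nucleotides, a multiple of 3.
#' @return encoded peptide length in amino acids.
#' @examples
#' orfPeptideLength(1779)  # 592
#' @export
orfPeptideLength <- function(ntLen) {
    if (any(ntLen %% 3 != 0))
        stop("ORF length must be a multiple of 3")
    ntLen / 3 - 1
}

# internal: seeded substreams so adding a generator never perturbs another.
# Each generator uses a fixed offset; the derived seed stays below 2^31.
withSubstreamSeed <- function(seed, offset, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed((as.integer(seed) + offset * 7919L) %% 2147483647L)
    expr
}

randomRna <- function(n, len) {
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
              collapse = ""), character(1))
}
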