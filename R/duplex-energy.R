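#' Load a nearest-neighbor energy parameter set
#'
#' Reads a plain-text stacking table (columns \code{top_5to3},
#' \code{bottom_3to5}, \code{delta_g}) and combines it with a duplex
#' initiation penalty and a flat per-loop penalty.  The default table is the
#' Turner 2004 RNA set at 37 C shipped with the package, covering all 36
#' ordered doublets of Watson-Crick and G:U pairs; the default initiation
#' penalty (4.10 kcal/mol) comes from the same set.  Terminal A:U / G:U end
#' penalties are not applied.
#'
#' @param file path to a stacking table; NULL for the packaged default.
#' @param initDg duplex initiation penalty, kcal/mol.
#' @param loopDg flat penalty per maximal run of mismatched positions,
#'   kcal/mol.  Mismatches terminate helices in this model; a short internal
#'   loop costs one flat penalty regardless of its sequence.
#' @param sourceTag provenance string recorded with the parameters.
#' @return an \linkS4class{NNParameterSet}.
#' @export
nnParameters <- function(file = NULL, initDg = 4.10, loopDg = 2.0,
                         sourceTag = NULL) {
    if (is.null(file)) {
        file <- system.file("extdata", "nn_stack_rna_37C.tsv",
                            package = "cryptarget", mustWork = TRUE)
        if (is.null(sourceTag))
            sourceTag <- "Turner 2004 RNA nearest-neighbor set, 37 C; flat loop penalty; no terminal end penalties"
    }
    if (is.null(sourceTag)) sourceTag <- file
    tab <- utils::read.table(file, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    stopifnot(all(c("top_5to3", "bottom_3to5", "delta_g") %in% names(tab)))
    dg <- tab$delta_g
    names(dg) <- paste0(tab$top_5to3, "/", tab$bottom_3to5)
    new("NNParameterSet", stackDg = dg, initDg = initDg, loopDg = loopDg,
        sourceTag = sourceTag)
}

#' Nearest-neighbor free energy of an ungapped duplex
#'
#' dG = initiation + sum of stacking increments over every adjacent position
#' pair where both positions are paired (Watson-Crick or wobble) + one flat
#' loop penalty per maximal run of mismatched (x) positions.  A duplex with
#' no paired positions returns the initiation penalty alone.  A doublet
#' missing from the stacking table is an error naming the doublet.
#'
#' @param duplex an \linkS4class{RNADuplex}.
#' @param params an \linkS4class{NNParameterSet}.
#' @return an \linkS4class{EnergyResult}.
#' @export
duplexDeltaG <- function(duplex, params = nnParameters()) {
    sym <- strsplit(duplex@pairing, "")[[1]]
    top <- strsplit(duplex@mirna@seq, "")[[1]]
    bot <- strsplit(duplex@site3to5, "")[[1]]
    n <- length(sym)
    paired <- sym %in% c("|", "o")
    dg <- params@initDg
    nStacks <- 0L
    if (n > 1L) {
        for (i in seq_len(n - 1L)) {
            if (paired[i] && paired[i + 1L]) {
                key <- paste0(top[i], top[i + 1L], "/", bot[i], bot[i + 1L])
                if (!key %in% names(params@stackDg))
                    stop(sprintf("stacking doublet %s absent from parameter table (%s)",
                                 key, params@sourceTag))
                dg <- dg + params@stackDg[[key]]
                nStacks <- nStacks + 1L
            }
        }
    }
    r <- rle(!paired)
    nLoops <- sum(r$values)
    dg <- dg + params@loopDg * nLoops
    new("EnergyResult", deltaG = dg, nStacks = nStacks,
        nLoops = as.integer(nLoops))
}

#' @rdname accessors
#' @export
setMethod("deltaG", "EnergyResult", function(x) x@deltaG)

setMethod("show", "EnergyResult", function(object) {
    cat(sprintf("EnergyResult: dG = %.2f kcal/mol (%d stacks, %d loops)\n",
                object@deltaG, object@nStacks, object@nLoops))
})

#' Free-energy ratio against the perfect complement
#'
#' |dG(duplex)| / |dG(perfect complement of the same miRNA)|.  A duplex
#' whose dG is non-negative (no stabilizing helix) is clamped to ratio 0.
#' A miRNA whose perfect complement has non-negative dG is degenerate and
#' raises an error.  The target criterion passes when the ratio reaches
#' \code{minEnergyRatio} (0.74 by default).
#'
#' @param duplex an \linkS4class{RNADuplex}.
#' @param params an \linkS4class{NNParameterSet}.
#' @return ratio in [0, ~1.5].
#' @export
energyRatio <- function(duplex, params = nnParameters()) {
    basis <- duplexDeltaG(perfectComplementDuplex(duplex@mirna), params)
    if (basis@deltaG >= 0)
        stop(sprintf("degenerate miRNA '%s': perfect-complement dG = %.2f >= 0",
                     duplex@mirna@id, basis@deltaG))
    dg <- duplexDeltaG(duplex, params)@deltaG
    if (dg >= 0) return(0)
    abs(dg) / abs(basis@deltaG)
}
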