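#' Build transcript models as a GRanges
#'
#' Convenience constructor for the annotation container used by the lncRNA
#' classification and cis-target screens: a \code{GRanges} with metadata
#' columns \code{tx_id} and \code{biotype} ("coding" or "lncRNA").
#' Coordinates are 1-based inclusive (GFF3 convention).
#'
#' @param id transcript identifiers.
#' @param chrom chromosome/scaffold names.
#' @param start,end 1-based inclusive coordinates.
#' @param strand "+" or "-".
#' @param biotype "coding" or "lncRNA".
#' @return a \code{GRanges}.
#' @export
transcriptModels <- function(id, chrom, start, end, strand, biotype) {
    stopifnot(all(start <= end), all(biotype %in% c("coding", "lncRNA")))
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = start, end = end),
        strand = strand)
    S4Vectors::mcols(gr)$tx_id <- as.character(id)
    S4Vectors::mcols(gr)$biotype <- as.character(biotype)
    gr
}

#' Read transcript models from GFF3 or BED
#'
#' Thin wrappers over \code{rtracklayer::import}; BED's 0-based half-open
#' coordinates are converted to the 1-based inclusive convention by the
#' import itself.  The \code{biotype} column is taken from the GFF3
#' \code{type}/attributes when present, otherwise supplied.
#'
#' @param path file path.
#' @param biotype biotype assigned to all records when the file carries none.
#' @return a \code{GRanges} in the \code{\link{transcriptModels}} layout.
#' @export
readTranscriptModels <- function(path, biotype = "coding") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
        stop("rtracklayer is required to read GFF3/BED annotation")
    gr <- rtracklayer::import(path)
    mc <- S4Vectors::mcols(gr)
    id <- if ("ID" %in% names(mc)) mc$ID
          else if ("name" %in% names(mc)) mc$name
          else sprintf("tx%05d", seq_along(gr))
    bt <- if ("biotype" %in% names(mc)) mc$biotype else biotype
    transcriptModels(id, as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr), GenomicRanges::end(gr),
                     as.character(GenomicRanges::strand(gr)), bt)
}

#' Classify lncRNAs by position relative to coding genes
#'
#' A lncRNA overlapping (>= 1 bp, closed 1-based intervals) a coding gene on
#' the same strand is "sense"; overlapping only on the opposite strand,
#' "antisense"; with no overlap at all, "lincRNA".  Overlap uses the gene's
#' full span.  A lncRNA on a chromosome absent from the gene annotation is
#' classified lincRNA with a warning.  Setting \code{mergeAntisense} folds
#' antisense overlaps into the "sense" bucket, for comparison with
#' annotations that report only lincRNA and natural-sense classes.
#'
#' @param lnc lncRNA models (\code{\link{transcriptModels}} layout).
#' @param genes coding gene models.
#' @param mergeAntisense report antisense overlaps as "sense"?
#' @return data.frame with \code{tx_id}, \code{label} and \code{evidence}
#'   (overlapping gene id, or nearest-gene distance for lincRNAs).
#' @export
classifyLncrna <- function(lnc, genes, mergeAntisense = FALSE) {
    stopifnot(is(lnc, "GRanges"), is(genes, "GRanges"))
    if (length(lnc) && !all(S4Vectors::mcols(lnc)$biotype == "lncRNA"))
        stop("all query transcripts must have biotype 'lncRNA'")
    unknown <- !as.character(GenomicRanges::seqnames(lnc)) %in%
        as.character(GenomicRanges::seqnames(genes))
    if (any(unknown))
        warning(sprintf("%d lncRNA(s) on chromosomes without annotated genes; classified lincRNA",
                        sum(unknown)))
    hitsSame <- suppressWarnings(
        GenomicRanges::findOverlaps(lnc, genes, ignore.strand = FALSE))
    hitsAny <- suppressWarnings(
        GenomicRanges::findOverlaps(lnc, genes, ignore.strand = TRUE))
    geneIds <- S4Vectors::mcols(genes)$tx_id
    label <- rep("lincRNA", length(lnc))
    evidence <- rep(NA_character_, length(lnc))
    anyIdx <- unique(S4Vectors::queryHits(hitsAny))
    sameIdx <- unique(S4Vectors::queryHits(hitsSame))
    label[anyIdx] <- "antisense"
    label[sameIdx] <- "sense"
    for (q in anyIdx) {
        hs <- S4Vectors::subjectHits(hitsSame)[S4Vectors::queryHits(hitsSame) == q]
        ha <- S4Vectors::subjectHits(hitsAny)[S4Vectors::queryHits(hitsAny) == q]
        evidence[q] <- geneIds[if (length(hs)) hs[1] else ha[1]]
    }
    linc <- which(label == "lincRNA")
    if (length(linc) && length(genes)) {
        d <- suppressWarnings(
            GenomicRanges::distanceToNearest(lnc[linc], genes,
                                             ignore.strand = TRUE))
        evidence[linc[S4Vectors::queryHits(d)]] <-
            as.character(S4Vectors::mcols(d)$distance)
    }
    if (mergeAntisense) label[label == "antisense"] <- "sense"
    data.frame(tx_id = S4Vectors::mcols(lnc)$tx_id, label = label,
               evidence = evidence, stringsAsFactors = FALSE)
}

#' Three-band coding-potential label
#'
#' Scores below \code{lower} are "noncoding", above \code{upper} "coding",
#' and scores in between "ambiguous" (the -1/+1 band convention of coding
#' potential calculators).  Vectorized.
#'
#' @param score numeric scores.
#' @param lower,upper band boundaries.
#' @return character vector of labels.
#' @export
codingLabel <- function(score, lower = -1, upper = 1) {
    if (lower >= upper) stop("need lower < upper")
    ifelse(score < lower, "noncoding",
           ifelse(score > upper, "coding", "ambiguous"))
}

#' Longest open reading frame in the forward frames
#'
#' Scans the three forward reading frames (transcript orientation is known)
#' for AUG..stop open reading frames and returns the longest, measured in
#' nucleotides including the stop codon.  ORFs without an in-frame stop are
#' not counted.
#'
#' @param seq transcript sequence (T normalized to U).
#' @return list with \code{length} (nt, 0 when no ORF), \code{start}
#'   (0-based, NA when none) and \code{frame} (0/1/2, NA when none).
#' @export
longestOrf <- function(seq) {
    seq <- normalizeRna(seq, "transcript")
    n <- nchar(seq)
    best <- list(length = 0L, start = NA_integer_, frame = NA_integer_)
    if (n < 6L) return(best)
    stops <- c("UAA", "UAG", "UGA")
    ch <- strsplit(seq, "")[[1]]
    for (f in 0:2) {
        starts <- integer(0)
        i <- f + 1L
        while (i + 2L <= n) {
            codon <- paste(ch[i:(i + 2L)], collapse = "")
            if (codon == "AUG") starts <- c(starts, i)
            if (codon %in% stops && length(starts)) {
                len <- i + 2L - starts[1] + 1L
                if (len > best$length)
                    best <- list(length = len, start = starts[1] - 1L,
                                 frame = f)
                starts <- integer(0)  # ORFs ended by this stop
            }
            i <- i + 3L
        }
    }
    best
}

#' Heuristic coding-potential score from ORF content
#'
#' A deterministic score increasing with the longest forward-frame ORF and
#' its coverage of the transcript, affinely anchored so that a transcript
#' with no ORF scores below -1 (noncoding band) and an ORF covering at
#' least 90\% of a transcript of 300 nt or more scores above +1 (coding
#' band):
#' \deqn{score = offset + scale \cdot \min(1, cov/0.9) \cdot \min(1, L/270)}
#' with offset -1.1 and scale 2.2 by default.  This is a transparent
#' package-native score, not a reimplementation of any published coding
#' potential calculator.
#'
#' @param seq transcript sequence.
#' @param anchorLen ORF length (nt) at which the length term saturates.
#' @param anchorCov ORF coverage at which the coverage term saturates.
#' @param offset,scale affine mapping constants.
#' @return numeric score.
#' @export
orfScore <- function(seq, anchorLen = 270, anchorCov = 0.9,
                     offset = -1.1, scale = 2.2) {
    seq <- normalizeRna(seq, "transcript")
    if (nchar(seq) < 3L) return(offset)
    orf <- longestOrf(seq)
    cov <- orf$length / nchar(seq)
    offset + scale * min(1, cov / anchorCov) * min(1, orf$length / anchorLen)
}

#' Cis-acting target candidates of a lncRNA
#'
#' Protein-coding genes on the same chromosome whose distance to the lncRNA
#' is strictly below the window (100 kb by default).  Distance is 0 for
#' overlapping intervals and otherwise the number of bases strictly between
#' the nearest interval ends; both strands are eligible.
#'
#' @param lnc a single-lncRNA \code{GRanges} (or the full set; each row is
#'   screened independently).
#' @param genes coding gene models.
#' @param window distance bound in bp (strict inequality).
#' @return data.frame with \code{lncrna_id}, \code{gene_id},
#'   \code{distance}, sorted by distance within each lncRNA.
#' @export
cisCandidates <- function(lnc, genes, window = 100000L) {
    stopifnot(is(lnc, "GRanges"), is(genes, "GRanges"))
    out <- list()
    geneIds <- S4Vectors::mcols(genes)$tx_id
    for (q in seq_along(lnc)) {
        same <- as.character(GenomicRanges::seqnames(genes)) ==
            as.character(GenomicRanges::seqnames(lnc[q]))
        if (!any(same)) next
        d <- suppressWarnings(GenomicRanges::distance(
            lnc[q], genes[same], ignore.strand = TRUE))
        keep <- !is.na(d) & d < window
        if (!any(keep)) next
        df <- data.frame(
            lncrna_id = S4Vectors::mcols(lnc)$tx_id[q],
            gene_id = geneIds[same][keep],
            distance = d[keep], stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- df[order(df$distance), , drop = FALSE]
    }
    if (!length(out))
        return(data.frame(lncrna_id = character(), gene_id = character(),
                          distance = integer(), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
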