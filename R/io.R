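#' Read RNA sequences from FASTA
#'
#' Reads a FASTA file via Biostrings and normalizes to the RNA alphabet
#' (T -> U), so DNA-alphabet transcript files are accepted.
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences.
#' @export
readRnaFasta <- function(path) {
    x <- Biostrings::readBStringSet(path)
    stats::setNames(normalizeRna(as.character(x), basename(path)), names(x))
}

#' Write RNA sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
writeRnaFasta <- function(seqs, path) {
    Biostrings::writeXStringSet(Biostrings::RNAStringSet(seqs), path)
    invisible(path)
}

#' Write a target-site table as TSV
#'
#' @param sites output of \code{\link{scanTranscript}} /
#'   \code{\link{scanTranscripts}}.
#' @param path output file.
#' @export
writeTargetTable <- function(sites, path) {
    utils::write.table(sites, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write target sites as GFF3-style features
#'
#' Features live on transcript coordinates (seqid = transcript id); the
#' 0-based half-open scan coordinates are converted to GFF3's 1-based
#' inclusive convention.
#'
#' @param sites output of \code{\link{scanTranscript}}.
#' @param path output file.
#' @param source source column value.
#' @export
writeTargetGff3 <- function(sites, path, source = "cryptarget") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    if (nrow(sites)) {
        attrs <- sprintf(
            "ID=site%03d;pairing=%s;total_mismatch=%g;energy_ratio=%g",
            seq_len(nrow(sites)), sites$pairing, sites$total_mismatch,
            sites$energy_ratio)
        writeLines(sprintf("%s\t%s\tmiRNA_target_site\t%d\t%d\t.\t+\t.\t%s",
                           sites$transcript_id, source, sites$start + 1L,
                           sites$end, attrs), con)
    }
    invisible(path)
}

#' Reported miRNA:mRNA duplex table
#'
#' The packaged table of printed complementarities between the mature miRNA
#' novel-m3234-5p and its candidate target mRNAs: target regions written
#' 3'->5' aligned with the miRNA 5'->3', and the published pairing strings.
#'
#' @return data.frame with mirna_id, target_id, target_region_3to5,
#'   pairing, mirna_seq_5to3.
#' @export
targetDuplexTable <- function() {
    utils::read.table(system.file("extdata", "mir3234_target_duplexes.tsv",
                                  package = "cryptarget", mustWork = TRUE),
                      header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
}

#' Reported trans-acting lncRNA correlation table
#'
#' The packaged table of lincRNAs reported as trans-acting partners of the
#' focal CRY-DASH gene, with their published Pearson correlations.
#'
#' @return data.frame with lncrna_id, classification, target, correlation.
#' @export
transCorrelationTable <- function() {
    utils::read.table(system.file("extdata", "trans_lncrna_correlations.tsv",
                                  package = "cryptarget", mustWork = TRUE),
                      header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
}
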