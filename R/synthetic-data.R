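# Seeded generators producing inputs with the planted structure each
# pipeline stage assumes.  One user-facing seed fans out to fixed
# per-generator substreams (utils.R::withSubstreamSeed), so adding a
# generator never perturbs the output of another.  Offsets: transcripts 1,
# hairpin 2, expression 3, Ct 4, reads 5.

# bases that neither Watson-Crick- nor wobble-pair with a given miRNA base
.nonPairing <- list(A = c("A", "C", "G"), C = c("A", "C", "U"),
                    G = c("A", "G"), U = c("C", "U"))

# site base creating a G:U wobble against a given miRNA base (NA: impossible)
.wobbleBase <- c(A = NA, C = NA, G = "U", U = "G")

#' Generate transcripts with planted miRNA target sites
#'
#' Each row of \code{siteSpecs} yields one random-background transcript with
#' one planted site built by mutating the miRNA's perfect complement:
#' \code{n_x} positions become non-pairing substitutions and \code{n_o}
#' positions become wobble-creating substitutions (only where the miRNA
#' base admits a wobble, i.e. G or U).  With \code{must_pass}, mutated
#' positions avoid the central window (10-11) and the 5' window weight is
#' kept within the filter bound; an unsatisfiable spec is an error.  The
#' ground-truth table records the planted location and the mismatch-filter
#' verdict implied by construction (criteria on total, central and 5'
#' weighted mismatches), independently of the scanner.
#'
#' @param mirna a \linkS4class{MatureMiRNA}.
#' @param siteSpecs data.frame with columns \code{n_x}, \code{n_o} and
#'   logical \code{must_pass}.
#' @param lengthRange transcript length bounds (nt).
#' @param seed integer seed.
#' @return list with \code{transcripts} (named character) and \code{truth}
#'   (data.frame: transcript_id, start, n_x, n_o, site_3to5,
#'   expected_pass_mismatch).
#' @export
genTranscriptsWithSites <- function(mirna, siteSpecs,
                                    lengthRange = c(300L, 800L), seed = 1L) {
    if (!is(mirna, "MatureMiRNA")) mirna <- MatureMiRNA("miRNA", mirna)
    stopifnot(all(c("n_x", "n_o", "must_pass") %in% names(siteSpecs)))
    m <- nchar(mirna@seq)
    mbase <- strsplit(mirna@seq, "")[[1]]
    wobbleOk <- which(!is.na(.wobbleBase[mbase]))
    withSubstreamSeed(seed, 1L, {
        txs <- character(0)
        truth <- list()
        for (r in seq_len(nrow(siteSpecs))) {
            nx <- siteSpecs$n_x[r]; no <- siteSpecs$n_o[r]
            mustPass <- siteSpecs$must_pass[r]
            if (nx + no > m) stop("more mutations than duplex positions")
            if (mustPass && nx + 0.5 * no > 4)
                stop("must_pass spec exceeds the total-mismatch bound")
            candX <- seq_len(m)
            candO <- wobbleOk
            if (mustPass) {
                candX <- setdiff(candX, 10:11)
                candO <- setdiff(candO, 10:11)
            }
            placed <- NULL
            for (try in 1:200) {
                if (length(candX) < nx || nx < 0) break
                xPos <- if (nx) sample(candX, nx) else integer(0)
                oCand <- setdiff(candO, xPos)
                if (length(oCand) < no) {
                    if (no > length(wobbleOk))
                        stop("wobble count exceeds wobble-capable positions")
                    next
                }
                oPos <- if (no) sample(oCand, no) else integer(0)
                fpW <- sum(xPos <= 12) + 0.5 * sum(oPos <= 12)
                if (mustPass && fpW > 2.5) next
                placed <- list(x = xPos, o = oPos)
                break
            }
            if (is.null(placed))
                stop(sprintf("unsatisfiable site spec in row %d", r))
            site <- strsplit(rnaComplement(mirna@seq), "")[[1]]
            for (p in placed$x)
                site[p] <- sample(.nonPairing[[mbase[p]]], 1)
            for (p in placed$o)
                site[p] <- .wobbleBase[[mbase[p]]]
            site3to5 <- paste(site, collapse = "")
            len <- sample(lengthRange[1]:lengthRange[2], 1)
            start <- sample(0:(len - m), 1)
            bg <- strsplit(randomRna(1, len), "")[[1]]
            window <- rev(site)  # transcript carries the site 5'->3'
            bg[(start + 1):(start + m)] <- window
            txId <- sprintf("synth_tx_%03d", r)
            txs[txId] <- paste(bg, collapse = "")
            totW <- length(placed$x) + 0.5 * length(placed$o)
            centralW <- sum(placed$x %in% 10:11) +
                0.5 * sum(placed$o %in% 10:11)
            fpW <- sum(placed$x <= 12) + 0.5 * sum(placed$o <= 12)
            truth[[r]] <- data.frame(
                transcript_id = txId, start = start, n_x = nx, n_o = no,
                site_3to5 = site3to5,
                expected_pass_mismatch = totW <= 4 && centralW == 0 &&
                    fpW <= 2.5,
                stringsAsFactors = FALSE)
        }
        list(transcripts = txs, truth = do.call(rbind, truth))
    })
}

#' Generate a synthetic miRNA precursor hairpin
#'
#' Precursor = mature arm + loop + the reverse complement of the mature
#' (with a configurable fraction of wobble substitutions), in either arm
#' order.  With default settings the product validates as a precursor.
#' Setting \code{scrambleArm} shuffles the complementary arm, which breaks
#' the hairpin.
#'
#' @param mature a \linkS4class{MatureMiRNA} (or bare sequence).
#' @param loopLen loop length (>= 4 to leave room for a hairpin loop).
#' @param arm which arm carries the mature miRNA ("5p" or "3p").
#' @param wobbleFraction fraction of arm positions converted to G:U pairs.
#' @param scrambleArm shuffle the complementary arm?
#' @param seed integer seed.
#' @return list with \code{precursor}, \code{arm}, \code{matureStart}
#'   (0-based).
#' @export
genHairpin <- function(mature, loopLen = 8L, arm = c("5p", "3p"),
                       wobbleFraction = 0.1, scrambleArm = FALSE, seed = 1L) {
    arm <- match.arg(arm)
    if (!is(mature, "MatureMiRNA")) mature <- MatureMiRNA("mature", mature)
    stopifnot(loopLen >= 4L)
    withSubstreamSeed(seed, 2L, {
        comp <- strsplit(reverseSeq(rnaComplement(mature@seq)), "")[[1]]
        nW <- round(wobbleFraction * length(comp))
        if (nW > 0) {
            # C->U faces G (G:U); A->G faces U (U:G)
            idx <- which(comp %in% c("A", "C"))
            idx <- if (length(idx) > nW) sample(idx, nW) else idx
            comp[idx] <- ifelse(comp[idx] == "C", "U", "G")
        }
        if (scrambleArm) comp <- sample(comp)
        otherArm <- paste(comp, collapse = "")
        loop <- paste(sample(c("A", "C"), loopLen, replace = TRUE),
                      collapse = "")
        if (arm == "5p") {
            precursor <- paste0(mature@seq, loop, otherArm)
            matureStart <- 0L
        } else {
            precursor <- paste0(otherArm, loop, mature@seq)
            matureStart <- nchar(otherArm) + loopLen
        }
        list(precursor = precursor, arm = arm, matureStart = matureStart)
    })
}

#' Generate a circadian expression matrix with planted structure
#'
#' The focal gene follows a cosine with the given period, amplitude and
#' phase plus Gaussian noise.  Planted lincRNAs are affine transforms of the
#' focal profile with noise scaled in closed form so the expected Pearson
#' correlation hits each target rho (exact at zero noise).  The planted
#' miRNA is a negatively scaled transform (anti-correlated with the focal
#' gene), and decoys are independent noise.
#'
#' @param seed integer seed.
#' @param timepoints sampling times, hours (ZT scale).
#' @param photoperiod light:dark descriptor.
#' @param amplitude,baseline,phase cosine parameters (expression units,
#'   units, hours).
#' @param period oscillation period, hours.
#' @param noiseSd Gaussian noise sd on the focal profile.
#' @param rhoTargets target correlations of the planted lincRNAs.
#' @param nDecoys number of independent-noise decoy features.
#' @param focalId,mirnaId feature ids of the planted focal gene and miRNA.
#' @return list with \code{expr} (features x conditions matrix) and
#'   \code{truth} (ids and targets).
#' @export
genExpression <- function(seed = 1L, timepoints = seq(2, 46, by = 4),
                          photoperiod = "12:12", amplitude = 5, baseline = 8,
                          phase = 6, period = 24, noiseSd = 0.5,
                          rhoTargets = rep(0.995, 6), nDecoys = 10,
                          focalId = "CRY-DASH", mirnaId = "planted-miR") {
    withSubstreamSeed(seed, 3L, {
        t <- timepoints
        clean <- baseline + amplitude * cos(2 * pi * (t - phase) / period)
        focal <- clean + stats::rnorm(length(t), 0, noiseSd)
        rows <- list()
        rows[[focalId]] <- focal
        rows[[mirnaId]] <- baseline - 0.9 * (focal - mean(focal)) +
            stats::rnorm(length(t), 0, noiseSd / 2)
        lincIds <- sprintf("linc%02d", seq_along(rhoTargets))
        sdF <- stats::sd(focal)
        for (i in seq_along(rhoTargets)) {
            rho <- rhoTargets[i]
            b <- 0.8
            noiseScale <- if (rho >= 1) 0 else b * sdF * sqrt(1 / rho^2 - 1)
            rows[[lincIds[i]]] <- 2 + b * focal +
                stats::rnorm(length(t), 0, noiseScale)
        }
        if (nDecoys > 0) {
            for (i in seq_len(nDecoys))
                rows[[sprintf("decoy%02d", i)]] <-
                    stats::runif(1, 2, 10) + stats::rnorm(length(t), 0, 1)
        }
        expr <- do.call(rbind, rows)
        colnames(expr) <- sprintf("ZT%g", t)
        list(expr = expr,
             truth = list(focalId = focalId, mirnaId = mirnaId,
                          lincIds = lincIds,
                          rhoTargets = stats::setNames(rhoTargets, lincIds)))
    })
}

#' Generate a qPCR Ct table with planted fold changes
#'
#' Ct values are constructed so that \code{\link{ddctFoldChange}} recovers
#' the planted fold change exactly at zero noise: the reference gene sits at
#' a fixed Ct, the calibrator target at \code{calCt}, and each sample's
#' target at \code{calCt - log2(fold)}.
#'
#' @param foldChanges named numeric vector: planted fold change per sample.
#' @param targetGene,referenceGene,calibratorSample table labels.
#' @param refCt,calCt construction anchors (cycles).
#' @param noiseSd Gaussian noise added to every Ct (cycles).
#' @param nReplicates biological replicates per (sample, gene).
#' @param seed integer seed.
#' @return list with \code{ct} (a \code{\link{ctTable}}) and \code{truth}.
#' @export
genCtTable <- function(foldChanges, targetGene = "CRY-DASH",
                       referenceGene = "ACT", calibratorSample = "dark",
                       refCt = 20, calCt = 25, noiseSd = 0,
                       nReplicates = 1L, seed = 1L) {
    stopifnot(!is.null(names(foldChanges)), all(foldChanges > 0))
    withSubstreamSeed(seed, 4L, {
        samples <- c(calibratorSample, names(foldChanges))
        targetCt <- c(calCt, calCt - log2(foldChanges))
        rows <- list()
        for (i in seq_along(samples)) {
            for (rep in seq_len(nReplicates)) {
                rows[[length(rows) + 1L]] <- data.frame(
                    sample = samples[i],
                    gene = c(targetGene, referenceGene),
                    ct = c(targetCt[i], refCt) +
                        stats::rnorm(2, 0, noiseSd),
                    replicate = rep, stringsAsFactors = FALSE)
            }
        }
        df <- do.call(rbind, rows)
        if (nReplicates == 1L) df$replicate <- NULL
        list(ct = ctTable(df, referenceGene, calibratorSample),
             truth = foldChanges)
    })
}

#' Generate a synthetic small-RNA read set
#'
#' Read lengths are drawn from a configurable distribution (default: a
#' prominent 21-nt mode carrying 61\% of the mass within 18-30 nt) and the
#' first base is U with the configured probability (default 0.7; remaining
#' positions are uniform over A, C, G, U).
#'
#' @param n number of reads.
#' @param lengthProbs named numeric: probability per read length.
#' @param fivePrimeU probability that a read starts with U.
#' @param seed integer seed.
#' @return named character vector of reads.
#' @export
genReads <- function(n = 1000L,
                     lengthProbs = c("18" = 0.02, "19" = 0.04, "20" = 0.12,
                                     "21" = 0.61, "22" = 0.10, "23" = 0.04,
                                     "24" = 0.02, "25" = 0.015, "26" = 0.01,
                                     "27" = 0.008, "28" = 0.007,
                                     "29" = 0.005, "30" = 0.005),
                     fivePrimeU = 0.7, seed = 1L) {
    stopifnot(abs(sum(lengthProbs) - 1) < 1e-9)
    withSubstreamSeed(seed, 5L, {
        if (n == 0L) return(stats::setNames(character(0), character(0)))
        lens <- as.integer(sample(names(lengthProbs), n, replace = TRUE,
                                  prob = lengthProbs))
        reads <- vapply(lens, function(L) {
            first <- if (stats::runif(1) < fivePrimeU) "U"
                     else sample(c("A", "C", "G"), 1)
            paste0(first, paste(sample(c("A", "C", "G", "U"), L - 1L,
                                       replace = TRUE), collapse = ""))
        }, character(1))
        stats::setNames(reads, sprintf("read%06d", seq_len(n)))
    })
}
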