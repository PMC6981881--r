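mir3234 <- MatureMiRNA("novel-m3234-5p", "UCCAGCCCGGCGUUGAUGGC")

test_that("base appositions classify as Watson-Crick, wobble or mismatch", {
    expect_identical(classifyPair("U", "A"), "|")
    expect_identical(classifyPair("G", "U"), "o")
    expect_identical(classifyPair("G", "G"), "x")
    expect_identical(classifyPair(c("A", "C", "U"), c("U", "G", "G")),
                     c("|", "|", "o"))
    # strand swap preserves the class for paired bases
    for (p in list(c("A", "U"), c("G", "C"), c("G", "U"))) {
        expect_identical(classifyPair(p[1], p[2]), classifyPair(p[2], p[1]))
    }
    expect_error(classifyPair("N", "A"), "non-RNA.*N")
})

test_that("duplex alignment reproduces printed pairing strings", {
    d <- alignDuplex(mir3234, "AGGUGGGGCCGGAAGUACCU")
    expect_identical(pairingString(d), "||||x||||||x||x||||x")
    expect_identical(pairingString(perfectComplementDuplex(mir3234)),
                     strrep("|", 20))
    expect_identical(
        pairingString(alignDuplex(suppressWarnings(MatureMiRNA("t", "UCGA")),
                                  "AGUU")),
        "||o|")
    expect_error(alignDuplex(mir3234, "AGGU"), "gapped")
    # DNA input and case are normalized
    expect_identical(
        pairingString(alignDuplex(MatureMiRNA("d", "uccagcccggcgttgatggc"),
                                  "AGGUGGGGCCGGAAGUACCU")),
        "||||x||||||x||x||||x")
})

test_that("site orientation round-trips between 3'->5' and 5'->3'", {
    d <- alignDuplex(mir3234, "AGGUGGGGCCGGAAGUACCU")
    expect_identical(reverseSeq(siteSeq5to3(d)), siteSeq3to5(d))
})

test_that("weighted mismatch counts wobbles as half mismatches", {
    expect_equal(weightedMismatch("o||xx||||||||o||||||", c(1, 12)), 2.5)
    expect_equal(weightedMismatch("||||||x||||||||x||xx", c(1, 20)), 4.0)
    expect_equal(weightedMismatch(strrep("|", 20)), 0)
    # custom weights
    expect_equal(weightedMismatch("ox|", NULL, mismatchWeights(0, 1, 1)), 2)
    expect_error(weightedMismatch("|x|", c(2, 1)), "lo <= hi")
    expect_error(weightedMismatch("|x|", c(1, 9)), "outside")
})

test_that("weighted mismatch is additive and window-monotone", {
    set.seed(11)
    for (rep in 1:20) {
        p <- paste(sample(c("|", "o", "x"), 20, replace = TRUE,
                          prob = c(0.7, 0.15, 0.15)), collapse = "")
        cut <- sample(2:19, 1)
        expect_equal(weightedMismatch(p, c(1, cut)) +
                     weightedMismatch(p, c(cut + 1, 20)),
                     weightedMismatch(p))
        expect_gte(weightedMismatch(p, c(1, cut + 1)),
                   weightedMismatch(p, c(1, cut)))
    }
})

test_that("the four filter criteria evaluate and toggle correctly", {
    d <- alignDuplex(mir3234, "AGGUGGGGCCGGAAGUACCU")  # 4 x, [1,12] = 2
    v <- checkCriteria(d, energyRatio = 0.80)
    expect_true(v[["total"]]); expect_true(v[["central"]])
    expect_true(v[["fivePrime"]]); expect_true(v[["energy"]])
    expect_true(v[["pass"]])
    # mismatch at position 10 fails the central criterion
    site <- strsplit(rnaComplement(mirnaSeq(mir3234)), "")[[1]]
    site[10] <- "A"  # miRNA position 10 is G; A is non-pairing
    d10 <- alignDuplex(mir3234, paste(site, collapse = ""))
    v10 <- checkCriteria(d10, energyRatio = 1)
    expect_false(v10[["central"]]); expect_false(v10[["pass"]])
    # five full mismatches fail the total criterion
    site5 <- strsplit(rnaComplement(mirnaSeq(mir3234)), "")[[1]]
    site5[c(1, 3, 5, 7, 9)] <- c("C", "U", "A", "A", "G")
    v5 <- checkCriteria(alignDuplex(mir3234, paste(site5, collapse = "")),
                        energyRatio = 1)
    expect_false(v5[["total"]]); expect_false(v5[["pass"]])
    # a wobble at position 10 fails strictly but passes the lenient flag
    siteW <- strsplit(rnaComplement(mirnaSeq(mir3234)), "")[[1]]
    siteW[10] <- "U"  # G:U wobble
    dW <- alignDuplex(mir3234, paste(siteW, collapse = ""))
    expect_false(checkCriteria(dW, 1)[["central"]])
    expect_true(checkCriteria(dW, 1,
        filterCriteria(centralWobbleFails = FALSE))[["central"]])
    # disabled energy criterion drops out of the overall verdict
    expect_true(checkCriteria(d, NA, mismatchOnlyCriteria())[["pass"]])
    expect_error(checkCriteria(d, NA), "energyRatio is NA")
})

test_that("transcript scan finds a planted perfect-complement site", {
    set.seed(42)
    bg <- randomRnaSeq(500)
    site5 <- reverseSeq(rnaComplement(mirnaSeq(mir3234)))
    tx <- paste0(substr(bg, 1, 137), site5, substr(bg, 158, 500))
    res <- scanTranscript(mir3234, tx)
    expect_equal(nrow(res), 1L)
    expect_equal(res$start, 137)
    expect_equal(res$end, 157)
    expect_equal(res$total_mismatch, 0)
    expect_equal(res$energy_ratio, 1)
})

test_that("transcripts shorter than the miRNA and bad sites yield nothing", {
    expect_equal(nrow(scanTranscript(mir3234, "ACGUACGUA")), 0L)
    g <- genTranscriptsWithSites(
        mir3234, data.frame(n_x = 5, n_o = 0, must_pass = FALSE), seed = 9)
    res <- scanTranscript(mir3234, g$transcripts[[1]],
                          criteria = mismatchOnlyCriteria())
    expect_false(g$truth$start %in% res$start)
})

test_that("fast scan equals brute-force re-evaluation of every offset", {
    set.seed(77)
    for (rep in 1:10) {
        tx <- randomRnaSeq(200)
        fast <- scanTranscript(mir3234, tx, criteria = mismatchOnlyCriteria(),
                               keepAll = TRUE)
        slow <- bruteScanMismatch(mirnaSeq(mir3234), tx)
        expect_equal(fast$start, slow$start)
        expect_equal(fast$total_mismatch, slow$total)
        expect_equal(fast$five_prime_mismatch, slow$fp)
        expect_equal(fast$pass, slow$pass)
    }
})

test_that("passing sites sort by mismatch then start; best-site collapses", {
    # two planted sites: one perfect, one with a single wobble
    siteW <- strsplit(rnaComplement(mirnaSeq(mir3234)), "")[[1]]
    siteW[5] <- "U"  # miRNA G -> G:U wobble
    wob5 <- reverseSeq(paste(siteW, collapse = ""))
    perf5 <- reverseSeq(rnaComplement(mirnaSeq(mir3234)))
    set.seed(4)
    tx <- paste0(wob5, randomRnaSeq(40), perf5)
    res <- scanTranscript(mir3234, tx)
    expect_equal(nrow(res), 2L)
    expect_equal(res$start[1], 60)   # perfect site first despite larger start
    expect_equal(res$total_mismatch, c(0, 0.5))
    best <- scanTranscript(mir3234, tx, bestPerTranscript = TRUE)
    expect_equal(nrow(best), 1L)
    expect_equal(best$start, 60)
})
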