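genes <- transcriptModels(
    id = c("gene1", "gene2"), chrom = c("chr1", "chr1"),
    start = c(1500, 5000), end = c(3000, 6000),
    strand = c("+", "+"), biotype = c("coding", "coding"))

test_that("lncRNAs classify by overlap and strand", {
    lnc <- transcriptModels(
        id = c("l_sense", "l_linc", "l_anti"),
        chrom = "chr1", start = c(1000, 1000, 1000),
        end = c(2000, 1400, 2000), strand = c("+", "+", "-"),
        biotype = "lncRNA")
    cls <- classifyLncrna(lnc, genes)
    expect_equal(cls$label, c("sense", "lincRNA", "antisense"))
    expect_equal(cls$evidence[1], "gene1")
    expect_equal(cls$evidence[3], "gene1")
    # lincRNA evidence is the nearest-gene distance
    expect_equal(as.numeric(cls$evidence[2]), 99)
    merged <- classifyLncrna(lnc, genes, mergeAntisense = TRUE)
    expect_equal(merged$label, c("sense", "lincRNA", "sense"))
})

test_that("unknown chromosomes classify as lincRNA with a warning", {
    lnc <- transcriptModels("lX", "chrUn", 100, 200, "+", "lncRNA")
    expect_warning(cls <- classifyLncrna(lnc, genes), "without annotated")
    expect_equal(cls$label, "lincRNA")
})

test_that("classification partitions any lncRNA set", {
    set.seed(8)
    n <- 40
    lnc <- transcriptModels(
        id = sprintf("l%02d", 1:n), chrom = "chr1",
        start = s <- sample(1:10000, n),
        end = s + sample(100:2000, n, replace = TRUE),
        strand = sample(c("+", "-"), n, replace = TRUE),
        biotype = "lncRNA")
    cls <- classifyLncrna(lnc, genes)
    expect_equal(nrow(cls), n)
    expect_true(all(cls$label %in% c("lincRNA", "sense", "antisense")))
    expect_equal(sum(table(cls$label)), n)
})

test_that("coding labels follow the -1/+1 three-band convention", {
    expect_equal(codingLabel(-2.3), "noncoding")
    expect_equal(codingLabel(0.0), "ambiguous")
    expect_equal(codingLabel(2.0), "coding")
    expect_error(codingLabel(0, lower = 1, upper = -1), "lower < upper")
    scores <- seq(-3, 3, by = 0.5)
    lab <- codingLabel(scores)
    expect_equal(lab, ifelse(scores < -1, "noncoding",
                             ifelse(scores > 1, "coding", "ambiguous")))
})

test_that("longest-ORF scan matches brute force on random transcripts", {
    set.seed(12)
    for (rep in 1:20) {
        s <- randomRnaSeq(400)
        expect_equal(longestOrf(s)$length, bruteLongestOrf(s), info = s)
    }
})

test_that("ORF score anchors the noncoding and coding bands", {
    expect_lte(orfScore(strrep("U", 500)), -1)      # no AUG at all
    # one continuous 600-nt ORF: start + 198 non-stop codons + stop
    orf600 <- paste0("AUG", strrep("GCU", 198), "UAA")
    expect_equal(nchar(orf600), 600)
    expect_gte(orfScore(orf600), 1)
    expect_equal(codingLabel(orfScore(orf600)), "coding")
    expect_equal(codingLabel(orfScore(strrep("U", 500))), "noncoding")
    # score grows with ORF length
    shorter <- paste0("AUG", strrep("GCU", 20), "UAA",
                      strrep("C", 600 - 69))
    expect_lt(orfScore(shorter), orfScore(orf600))
})

test_that("ORF arithmetic counts residues excluding the stop codon", {
    expect_equal(orfPeptideLength(1779), 592)
    expect_equal(orfPeptideLength(3), 0)
    expect_error(orfPeptideLength(100), "multiple of 3")
})

test_that("cis candidates use a strict 100-kb window", {
    lnc <- transcriptModels("lnc1", "chr1", 1000, 2000, "+", "lncRNA")
    far <- transcriptModels(
        id = c("near", "boundary", "far", "overlap"),
        chrom = "chr1",
        start = c(52001, 102001, 152001, 1500),
        end = c(53000, 103000, 153000, 2500),
        strand = "+", biotype = "coding")
    cc <- cisCandidates(lnc, far)
    expect_equal(cc$gene_id, c("overlap", "near"))
    expect_equal(cc$distance, c(0, 50000))
    # exactly at the window: excluded (strict inequality)
    expect_false("boundary" %in% cc$gene_id)
})

test_that("cis candidacy is symmetric in distance", {
    set.seed(3)
    lnc <- transcriptModels("L", "chr2", 500000, 501000, "+", "lncRNA")
    g <- transcriptModels(sprintf("g%d", 1:10), "chr2",
                          s <- sample(1:1000000, 10),
                          s + 800, "+", "coding")
    fwd <- cisCandidates(lnc, g)
    for (i in seq_along(g)) {
        gAsLnc <- transcriptModels(
            sprintf("g%d", i), "chr2",
            GenomicRanges::start(g)[i], GenomicRanges::end(g)[i],
            "+", "lncRNA")
        back <- cisCandidates(gAsLnc, transcriptModels(
            "L", "chr2", 500000, 501000, "+", "coding"))
        expect_equal(sprintf("g%d", i) %in% fwd$gene_id,
                     "L" %in% back$gene_id)
    }
})

test_that("annotation round-trips through GFF3 via rtracklayer", {
    path <- tempfile(fileext = ".gff3")
    gr <- genes
    names(S4Vectors::mcols(gr))[1] <- "ID"
    rtracklayer::export(gr, path, format = "gff3")
    back <- readTranscriptModels(path, biotype = "coding")
    expect_equal(GenomicRanges::start(back), GenomicRanges::start(genes))
    expect_equal(GenomicRanges::end(back), GenomicRanges::end(genes))
    expect_equal(S4Vectors::mcols(back)$tx_id,
                 S4Vectors::mcols(genes)$tx_id)
})
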