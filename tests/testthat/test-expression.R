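test_that("Pearson correlation behaves under affine maps and rejects junk", {
    x <- c(1, 2, 3, 4)
    expect_equal(pearsonR(x, 2 * x + 1), 1.0)
    expect_equal(pearsonR(x, -x), -1.0)
    y <- c(1, 2, 3, 5)
    # hand computation by the product-moment formula
    num <- sum((x - mean(x)) * (y - mean(y)))
    den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearsonR(x, y), num / den)
    set.seed(2)
    a <- rnorm(10); b <- rnorm(10)
    expect_equal(pearsonR(3 * a + 2, b), pearsonR(a, b))
    expect_equal(pearsonR(-3 * a, b), -pearsonR(a, b))
    expect_error(pearsonR(c(1, 2), c(1, 2)), "at least 3")
    expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("trans screen retains planted high-correlation pairs", {
    e <- genExpression(seed = 17)
    focal <- e$expr[e$truth$focalId, , drop = FALSE]
    lincs <- e$expr[e$truth$lincIds, , drop = FALSE]
    hits <- transCandidates(lincs, focal)
    expect_setequal(hits$lncrna_id, e$truth$lincIds)
    expect_true(all(abs(hits$r) >= 0.9))
    expect_equal(order(-abs(hits$r)), seq_len(nrow(hits)))
    # independent-noise decoys are excluded
    decoys <- e$expr[grep("decoy", rownames(e$expr)), , drop = FALSE]
    expect_equal(nrow(transCandidates(decoys, focal)), 0L)
    expect_error(transCandidates(lincs[, 1:2], focal[, 1:2, drop = FALSE]),
                 "fewer than 3")
})

test_that("fixture vectors reproduce the printed screen correlations", {
    tab <- transCorrelationTable()
    expect_equal(nrow(tab), 9L)
    x <- as.numeric(1:12)
    rows <- lapply(seq_len(nrow(tab)), function(i)
        exactCorVector(x, tab$correlation[i], seed = i))
    lnc <- do.call(rbind, rows)
    rownames(lnc) <- tab$lncrna_id
    colnames(lnc) <- sprintf("ZT%d", seq(2, 46, 4))
    focal <- matrix(x, 1, dimnames = list("CRY-DASH", colnames(lnc)))
    hits <- transCandidates(lnc, focal, rMin = 0.99)
    expect_equal(nrow(hits), 9L)
    # realized sample correlations equal the printed values at 6 decimals
    expect_equal(round(hits$r[match(tab$lncrna_id, hits$lncrna_id)], 6),
                 tab$correlation)
})

test_that("2^-ddCt arithmetic recovers planted fold changes", {
    df <- data.frame(
        sample = c("s", "s", "cal", "cal"),
        gene = c("tgt", "ref", "tgt", "ref"),
        ct = c(24, 20, 26, 21))
    ct <- ctTable(df, "ref", "cal")
    # dCt(sample) = 4, dCt(cal) = 5, ddCt = -1 -> 2
    expect_equal(ddctFoldChange(ct, "tgt", "s"), 2.0)
    # the calibrator itself is exactly 1 for every gene
    expect_equal(ddctFoldChange(ct, "tgt", "cal"), 1.0)
    expect_error(ddctFoldChange(ct, "tgt", "nope"), "missing Ct")
    # ddCt = 0 and -2 cases
    g <- genCtTable(c(a = 1, b = 4), seed = 1)
    expect_equal(ddctFoldChange(g$ct, "CRY-DASH", "a"), 1.0)
    expect_equal(ddctFoldChange(g$ct, "CRY-DASH", "b"), 4.0)
})

test_that("replicated Ct tables give mean and sd across replicates", {
    g <- genCtTable(c(BL = 2), noiseSd = 0.2, nReplicates = 6, seed = 4)
    fc <- ddctFoldChange(g$ct, "CRY-DASH", "BL")
    expect_equal(attr(fc, "n"), 6L)
    expect_gt(attr(fc, "sd"), 0)
    expect_equal(as.numeric(fc), 2, tolerance = 0.5)
})

test_that("relative profiles are anchored at the baseline timepoint", {
    row <- setNames(c(2, 4, 2, 1), c("ZT2", "ZT6", "ZT10", "ZT14"))
    pr <- relativeProfile(row)
    expect_equal(pr@foldChanges, c(1, 2, 1, 0.5))
    constant <- setNames(rep(3, 4), c("ZT2", "ZT6", "ZT10", "ZT14"))
    expect_equal(relativeProfile(constant)@foldChanges, rep(1, 4))
    expect_error(relativeProfile(setNames(c(0, 1), c("ZT2", "ZT6"))),
                 "zero baseline")
    expect_error(relativeProfile(c(1, 2, 3)), "named")
})

test_that("peak summary detects 24-h periodicity and rejects others", {
    t <- seq(2, 70, by = 4)
    mk <- function(period) {
        row <- setNames(2 + cos(2 * pi * (t - 6) / period),
                        sprintf("ZT%g", t))
        relativeProfile(row)
    }
    s24 <- peakSummary(mk(24))
    expect_equal(s24$peakTimes, c(6, 30, 54))
    expect_true(s24$hasPeriodicity)
    s12 <- peakSummary(mk(12))
    expect_equal(unique(diff(s12$peakTimes)), 12)
    expect_false(s12$hasPeriodicity)
    mono <- relativeProfile(setNames(c(1, 2, 3, 4, 5),
                                     sprintf("ZT%d", seq(2, 18, 4))))
    sm <- peakSummary(mono)
    expect_equal(length(sm$peakTimes), 0L)
    expect_false(sm$hasPeriodicity)
    expect_error(peakSummary(relativeProfile(
        setNames(c(1, 2, 1), sprintf("ZT%d", c(2, 6, 10))))), "4 timepoints")
})

test_that("profile clustering recovers planted opposite-phase groups", {
    t <- seq(2, 46, by = 4)
    set.seed(6)
    up <- t(sapply(1:5, function(i)
        5 + 3 * cos(2 * pi * (t - 6) / 24) + rnorm(length(t), 0, 0.2)))
    down <- t(sapply(1:5, function(i)
        5 - 3 * cos(2 * pi * (t - 6) / 24) + rnorm(length(t), 0, 0.2)))
    expr <- rbind(up, down)
    rownames(expr) <- sprintf("f%02d", 1:10)
    colnames(expr) <- sprintf("ZT%d", t)
    cl <- clusterProfiles(expr, k = 2)
    expect_equal(length(unique(cl[1:5])), 1L)
    expect_equal(length(unique(cl[6:10])), 1L)
    expect_false(cl[[1]] == cl[[6]])
    # permutation invariance up to relabeling
    perm <- sample(nrow(expr))
    cl2 <- clusterProfiles(expr[perm, ], k = 2)
    expect_equal(unname(cl2[rownames(expr)] == cl2[["f01"]]),
                 unname(cl == cl[["f01"]]))
    # k = n puts every feature in its own cluster
    expect_equal(length(unique(clusterProfiles(expr, k = 10))), 10L)
    # identical rows join a single cluster at any positive cut
    same <- expr[rep(1, 3), ]
    rownames(same) <- c("a", "b", "c")
    expect_equal(length(unique(clusterProfiles(same, cutHeight = 0.1))), 1L)
    # constant rows are reported by name
    bad <- rbind(expr, constant = rep(1, length(t)))
    expect_error(clusterProfiles(bad, k = 2), "constant")
})
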