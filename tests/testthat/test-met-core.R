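test_that("column standardization centres, scales and preserves correlations", {
    ## symmetric linear case: (1, 2, 3) -> (-1, 0, 1)
    v <- array(NA_real_, c(3, 2, 1))
    v[, 1, 1] <- c(1, 2, 3)
    v[, 2, 1] <- c(4, 8, 12)
    s <- standardizeMET(METArray(v))
    expect_equal(metValues(s)[, 1, 1], c(G1 = -1, G2 = 0, G3 = 1))
    expect_equal(unname(colMean(s)[1, 1]), 2)
    expect_equal(unname(colSd(s)[1, 1]), 1)

    ## every fully observed column sums to zero and has unit sample SD
    raw <- makeArray(15, 4, 3, seed = 5)
    s <- standardizeMET(raw)
    m <- matrix(metValues(s), 15, 12)
    expect_true(all(abs(colSums(m)) < 1e-10))
    expect_true(all(abs(apply(m, 2, sd) - 1) < 1e-10))

    ## within-environment attribute correlations are unchanged
    rawv <- metValues(raw)
    for (j in 1:4) {
        expect_equal(cor(rawv[, j, 1], rawv[, j, 2]),
                     cor(metValues(s)[, j, 1], metValues(s)[, j, 2]))
    }
})

test_that("standardization handles missing entries and degenerate columns", {
    raw <- makeArray(10, 3, 2, seed = 7)
    v <- metValues(raw)
    v[3:5, 2, 1] <- NA           # partially observed column
    v[, 3, 2] <- NA              # wholly missing column
    s <- standardizeMET(METArray(v))
    expect_equal(unname(colMean(s)[2, 1]), mean(v[-(3:5), 2, 1]))
    expect_true(is.na(colMean(s)[3, 2]) && is.na(colSd(s)[3, 2]))

    ## back-transform reproduces the raw observed values
    back <- backTransform(s)
    expect_equal(metValues(back)[!is.na(v)], v[!is.na(v)], tolerance = 1e-10)

    ## single observed value and zero variance are hard errors naming (j, k)
    v1 <- metValues(raw); v1[2:10, 1, 1] <- NA
    expect_error(standardizeMET(METArray(v1)), "single observed value.*E1.*A1")
    v2 <- metValues(raw); v2[, 1, 1] <- 3
    expect_error(standardizeMET(METArray(v2)), "zero variance")
})

test_that("wide views are lossless bijections with the documented layout", {
    v <- array(seq_len(8), c(2, 2, 2))
    s <- standardizeMET(makeArray(2, 2, 2))   # only for class; replace values
    s@values <- array(as.numeric(seq_len(8)), c(2, 2, 2),
                      dimnames = dimnames(s@values))
    w <- toWide(s)
    ## environments nested within attributes: column (k-1)*J + j
    expect_equal(unname(w@matrix[1, 3]), s@values[1, 1, 2])
    idx <- wideIndex(w, rep(1:2, 4), rep(1:4, each = 2))
    expect_equal(w@matrix[cbind(rep(1:2, 4), rep(1:4, each = 2))],
                 s@values[idx])
    expect_identical(fromWide(w), s@values)

    w2 <- toWide(s, "env_by_geno_attr")
    expect_identical(fromWide(w2), s@values)
    expect_equal(unname(w2@matrix[2, 3]), s@values[1, 2, 2])
})

test_that("a missing column is all-missing only in the I x JK orientation", {
    raw <- makeArray(6, 4, 3, seed = 3)
    v <- metValues(raw)
    v[, 1, 2] <- NA
    s <- standardizeMET(METArray(v))
    wide1 <- toWide(s)@matrix
    expect_equal(sum(colSums(!is.na(wide1)) == 0), 1L)
    wide2 <- toWide(s, "env_by_geno_attr")@matrix
    expect_true(all(colSums(!is.na(wide2)) > 0))
})

test_that("missing patterns have the documented counts and are reproducible", {
    raw <- makeArray(58, 8, 6, seed = 11)
    p <- generateMissingPattern(raw, 0.05, nColumns = 1, seed = 4)
    ## round(0.05 * 2784) = 139 = 58 column cells + 81 free cells
    expect_equal(nrow(patternCells(p, expand = TRUE)), 139L)
    expect_equal(nrow(p@cells), 81L)

    p2 <- generateMissingPattern(raw, 0.05, nColumns = 1, seed = 4)
    expect_identical(p@cells, p2@cells)
    expect_identical(p@columns, p2@columns)

    ## boundary: percent covering exactly the column leaves no free cells
    p3 <- generateMissingPattern(raw, 58 / 2784, nColumns = 1, seed = 4)
    expect_equal(nrow(p3@cells), 0L)

    expect_error(generateMissingPattern(raw, 1.2, seed = 1), "percent")
    expect_error(generateMissingPattern(raw, 0.004, nColumns = 1, seed = 1),
                 "too small")
})

test_that("patterns never empty a genotype-attribute row", {
    raw <- makeArray(8, 4, 2, seed = 2)
    for (seed in 1:25) {
        p <- generateMissingPattern(raw, 0.3, nColumns = 1, seed = seed)
        idx <- patternCells(p, expand = TRUE)
        cnt <- table(factor(paste(idx[, 1], idx[, 3]),
                            levels = as.vector(outer(1:8, 1:2, paste))))
        expect_true(all(cnt < 4), label = paste("seed", seed))
    }
})

test_that("applyPattern masks exactly the pattern entries", {
    fix <- makeMasked(12, 5, 3, percent = 0.15)
    idx <- patternCells(fix$pattern, expand = TRUE)
    v <- metValues(fix$masked)
    expect_true(all(is.na(v[idx])))
    expect_equal(sum(is.na(v)), nrow(idx))
})

test_that("long CSV, frontal slices and pattern JSON round-trip", {
    raw <- makeArray(6, 4, 2, seed = 9)
    v <- metValues(raw); v[2, 3, 1] <- NA
    x <- METArray(v)

    f <- tempfile(fileext = ".csv")
    writeMETLong(x, f)
    y <- readMETLong(f)
    expect_equal(metValues(y), metValues(x))

    d <- tempfile()
    paths <- suppressWarnings(writeFrontalSlices(x, d))
    z <- readFrontalSlices(setNames(file.path(d, c("A1.csv", "A2.csv")),
                                    c("A1", "A2")))
    expect_equal(unname(metValues(z)), unname(metValues(x)))

    p <- generateMissingPattern(raw, 0.2, seed = 5)
    pf <- tempfile(fileext = ".json")
    writePattern(p, pf)
    q <- readPattern(pf)
    expect_equal(unname(q@cells), unname(p@cells))
    expect_equal(unname(q@columns), unname(p@columns))
    expect_equal(q@percent, p@percent)
})
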