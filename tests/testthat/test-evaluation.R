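test_that("Rubin pooling reproduces the hand formulas", {
    ## Ubar = 1, B = 1, H = 5 -> T = 2.2, nu = 4 (1 + 1/1.2)^2
    est <- matrix(c(0, 1, 2, -1, 3), 5, 1)   # var = 2.5; rescale below
    est <- est / sqrt(2.5)                    # per-value B = 1
    pool <- rubinPool(est, withinVars = rep(1, 5))
    expect_equal(pool$B, 1)
    expect_equal(pool$T, 2.2)
    expect_equal(pool$nu, 4 * (1 + 1 / 1.2)^2, tolerance = 1e-12)
    expect_equal(pool$nu, 13.4444, tolerance = 1e-4)

    ## identical imputations: B = 0 and T = Ubar
    est0 <- matrix(2, 4, 3)
    p0 <- rubinPool(est0, withinVars = rep(0.5, 4))
    expect_equal(p0$B, rep(0, 3))
    expect_equal(p0$T, rep(0.5, 3))

    ## H = 2 with estimates (0, 2): two-point variance 2
    p2 <- rubinPool(matrix(c(0, 2), 2, 1), withinVars = c(1, 1))
    expect_equal(p2$B, 2)

    expect_error(rubinPool(matrix(1, 1, 2)), "H >= 2")

    ## random-vector identity check for H in {2, 3, 5}
    set.seed(70)
    for (H in c(2, 3, 5)) {
        est <- matrix(rnorm(H * 7), H, 7)
        u <- runif(H)
        p <- rubinPool(est, u)
        Qbar <- colMeans(est)
        B <- colSums(sweep(est, 2, Qbar)^2) / (H - 1)
        expect_equal(p$Qbar, Qbar)
        expect_equal(p$B, B)
        expect_equal(p$T, mean(u) + (1 + 1 / H) * B)
        expect_equal(p$nu, (H - 1) * (1 + mean(u) / ((1 + 1 / H) * B))^2)
    }
})

test_that("coverage intervals behave at the extremes and match a direct oracle", {
    est <- matrix(rnorm(5 * 4, sd = 0.3), 5, 4) + rep(c(0, 1, -1, 2), each = 5)
    ## truth exactly at the pooled mean is always covered
    truth <- colMeans(est)
    cov <- coverageCI(truth, est, withinVars = rep(0.5, 5))
    expect_equal(cov$coverage, 100)

    ## truth displaced by 100 sqrt(T) is never covered
    pool <- rubinPool(est, rep(0.5, 5))
    far <- pool$Qbar + 100 * sqrt(pool$T)
    expect_equal(coverageCI(far, est, rep(0.5, 5))$coverage, 0)

    ## brute-force interval oracle
    set.seed(71)
    H <- 5; M <- 200
    est <- matrix(rnorm(H * M), H, M)
    u <- runif(H, 0.5, 1.5)
    truth <- rnorm(M)
    got <- coverageCI(truth, est, u)
    inside <- vapply(seq_len(M), function(m) {
        q <- est[, m]
        B <- var(q); Ub <- mean(u)
        Tt <- Ub + (1 + 1 / H) * B
        nu <- (H - 1) * (1 + Ub / ((1 + 1 / H) * B))^2
        half <- qt(0.975, nu) * sqrt(Tt)
        abs(truth[m] - mean(q)) <= half
    }, logical(1))
    expect_equal(got$coverage, 100 * mean(inside))

    ## degenerate B = 0 falls back to a normal interval with a warning
    estc <- matrix(1, 4, 2)
    expect_warning(cz <- coverageCI(c(1, 10), estc, rep(0.25, 4)),
                   "zero between-imputation")
    expect_equal(cz$covered, c(TRUE, FALSE))
})

test_that("NRMSE is zero for perfect completions and affine-invariant", {
    raw <- makeArray(10, 4, 2, seed = 80)
    std <- standardizeMET(raw)
    expect_equal(nrmse(std, metValues(std)), 0)
    expect_equal(nrmse(raw, metValues(std)), 0)

    ## adding a per-column constant is removed by re-standardization
    shifted <- metValues(std) + 3
    expect_equal(nrmse(std, shifted), 0, tolerance = 1e-12)
    scaled <- sweep(metValues(std), 2, c(2, 3, 4, 5), "*")
    expect_equal(nrmse(std, scaled), 0, tolerance = 1e-12)

    ## hand-computed 2 x 2 x 1 example
    orig <- array(c(-1, 1, -1, 1), c(2, 2, 1))
    stdo <- new("StandardizedMET",
                values = array(c(-1, 1, -1, 1), c(2, 2, 1),
                               dimnames = list(c("G1", "G2"), c("E1", "E2"),
                                               "A1")),
                colMean = matrix(0, 2, 1), colSd = matrix(sqrt(2), 2, 1))
    est <- array(c(-1, 1, 1, -1), c(2, 2, 1))   # second column flipped
    ## hand evaluation: re-standardized est columns are (-1,1)/sd and
    ## (1,-1)/sd; the flipped column contributes the full squared error
    m <- matrix(est, 2, 2)
    zz <- sweep(sweep(m, 2, colMeans(m)), 2, apply(m, 2, sd), "/")
    expected <- sqrt(mean((as.vector(orig) - as.vector(zz))^2) /
                     var(as.vector(orig)))
    expect_equal(nrmse(stdo, est), expected)
})

test_that("pooled imputations average the allocated raw sets", {
    est <- matrix(rnorm(100 * 3), 100, 3)
    pooled <- poolImputations(est, H = 5, seed = 9)
    expect_equal(dim(pooled), c(5L, 3L))
    expect_equal(colMeans(pooled), colMeans(est))
    ## pool of size one reproduces the raw imputations
    est5 <- matrix(rnorm(5 * 2), 5, 2)
    p5 <- poolImputations(est5, H = 5, seed = 9)
    expect_equal(sort(p5[, 1]), sort(est5[, 1]))
    expect_error(poolImputations(est, H = 3), "%%")
})

test_that("protocol runners are reproducible and correctly shaped", {
    raw <- makeArray(24, 5, 3, seed = 90)
    df1 <- runCellsProtocol(raw, methods = c("mahc", "norm-nba"),
                            percents = c(10, 20), reps = 2,
                            nImputations = 10, poolSize = 5, seed = 17)
    df2 <- runCellsProtocol(raw, methods = c("mahc", "norm-nba"),
                            percents = c(10, 20), reps = 2,
                            nImputations = 10, poolSize = 5, seed = 17)
    expect_identical(df1, df2)
    expect_equal(nrow(df1), 2 * 2 * 2)
    expect_true(all(df1$coverage >= 0 & df1$coverage <= 100))
    ## nested patterns: the 10% run has fewer missing cells than the 20% run
    agg <- aggregate(nMissingCells ~ percent, df1, unique)
    expect_lt(agg$nMissingCells[1], agg$nMissingCells[2])

    dc <- runColumnProtocol(raw, methods = "mahc", attrs = 2,
                            nImputations = 10, seed = 18)
    expect_equal(nrow(dc), 5L)      # one row per environment
    expect_true(all(dc$attribute == 2))

    dn <- runNrmseProtocol(raw, methods = c("norm-nba", "em"),
                           percents = 15, reps = 2, nImputations = 10,
                           seed = 19)
    expect_equal(nrow(dn), 4L)
    expect_true(all(dn$nrmse > 0))

    s <- summarizeProtocol(df1, "coverage")
    expect_equal(nrow(s), 4L)
    expect_true(all(c("mean", "se") %in% names(s)))
})
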