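test_that("design matrices have the documented dimensions and zeros", {
    fix <- makeMasked(8, 3, 2, percent = 0.25, seedData = 2, seedPattern = 4)
    std <- fix$std        # fully observed for the dimension checks
    R <- correlationR(std)
    expect_equal(ncol(buildDesign(std, c(1, 1), 1)), 5L)   # JK - 1
    expect_equal(ncol(buildDesign(std, c(1, 1), 2)), 4L)   # K(J - 1)
    expect_equal(ncol(buildDesign(std, c(1, 1), 3, R)), 5L) # KJ - 1
    expect_equal(ncol(buildDesign(std, c(1, 1), 4)), 1L)   # K - 1

    ## dimension formulas hold across random shapes
    for (rep in 1:5) {
        J <- sample(3:6, 1); K <- sample(2:4, 1)
        s <- standardizeMET(makeArray(7, J, K, seed = rep))
        Rr <- correlationR(s)
        expect_equal(ncol(buildDesign(s, c(2, 1), 1)), J * K - 1L)
        expect_equal(ncol(buildDesign(s, c(2, 1), 2)), K * (J - 1L))
        expect_equal(ncol(buildDesign(s, c(2, 1), 3, Rr)), K * J - 1L)
        expect_equal(ncol(buildDesign(s, c(2, 1), 4)), K - 1L)
    }

    ## option 4 is the target environment's other-attribute columns verbatim
    X4 <- buildDesign(std, c(2, 1), 4)
    expect_equal(unname(X4[, 1]), unname(metValues(std)[, 2, 2]))

    ## masked cells appear as exact zeros in the design
    stdm <- fix$masked
    X1 <- buildDesign(stdm, c(1, 1), 1)
    wide <- matrix(metValues(stdm), 8, 6)[, -1]  # drop target column (1, 1)
    expect_true(all(X1[is.na(wide)] == 0))
    expect_error(buildDesign(std, c(1, 1), 5), "1, 2, 3 or 4")
})

test_that("NRM MLE matches exact fits and a normal-equations oracle", {
    ## exact linear data recovers the coefficients with zero residual
    set.seed(5)
    X <- matrix(rnorm(30), 10, 3)
    b <- c(2, -1, 0.5)
    f <- nrmMLE(drop(X %*% b), X)
    expect_equal(f$beta, b, tolerance = 1e-10)
    expect_equal(f$sigma2, 0, tolerance = 1e-12)

    expect_equal(nrmMLE(c(2, 4, 6), cbind(c(1, 2, 3)))$beta, 2)

    ## independent oracle: explicit normal-equations inversion, and the
    ## printed (n - 2) residual denominator
    set.seed(6)
    X <- matrix(rnorm(80), 20, 4)
    y <- drop(X %*% c(1, 0, -2, 0.3)) + rnorm(20, sd = 0.4)
    f <- nrmMLE(y, X)
    betaOracle <- solve(t(X) %*% X) %*% t(X) %*% y
    expect_equal(f$beta, drop(betaOracle), tolerance = 1e-10)
    expect_equal(f$sigma2, sum((y - X %*% betaOracle)^2) / (20 - 2))

    expect_error(nrmMLE(c(1, 2), cbind(1:2)), "at least 3")
})

test_that("NRM Gibbs approaches the MLE under a flat prior and recovers truth", {
    set.seed(8)
    X <- matrix(rnorm(120), 40, 3)
    b <- c(1.2, -0.7, 0.4)
    y <- drop(X %*% b) + rnorm(40, sd = 0.5)
    mle <- nrmMLE(y, X)
    flat <- nrmGibbs(y, X, tau2 = 1e8, nSamples = 20000, burn = 2000, seed = 3)
    sdPost <- sqrt(mle$sigma2 * diag(solve(t(X) %*% X)))
    expect_true(all(abs(flat$beta - mle$beta) < 0.3 * sdPost))

    ## parameter recovery at n = 200 within 3 posterior SDs
    set.seed(9)
    X <- matrix(rnorm(800), 200, 4)
    b <- c(0.8, -0.5, 0.3, 0)
    y <- drop(X %*% b) + rnorm(200, sd = 0.6)
    fit <- nrmGibbs(y, X, nSamples = 6000, burn = 500, seed = 4)
    sdPost <- sqrt(0.36 * diag(solve(t(X) %*% X)))
    expect_true(all(abs(fit$beta - b) < 3 * sdPost + 0.02))

    f1 <- nrmGibbs(y, X, nSamples = 300, burn = 30, seed = 11)
    f2 <- nrmGibbs(y, X, nSamples = 300, burn = 30, seed = 11)
    expect_identical(f1, f2)
})

test_that("cell imputation draws around the regression prediction", {
    params <- list(beta = c(2, -1), sigma2 = 0)
    Xm <- rbind(c(1, 1), c(2, 0))
    expect_equal(imputeCellsNRM(params, Xm), c(1, 4))

    set.seed(14)
    params$sigma2 <- 0.25
    draws <- replicate(4000, imputeCellsNRM(params, Xm))
    expect_equal(rowMeans(draws), c(1, 4), tolerance = 0.05)
    ## zero design row: pure noise around zero
    expect_equal(mean(replicate(4000, imputeCellsNRM(params, rbind(c(0, 0))))),
                 0, tolerance = 0.05)
})

test_that("correlationR matches hand Pearson computations and flags gaps", {
    raw <- makeArray(5, 3, 3, seed = 10)
    std <- standardizeMET(raw)
    R <- correlationR(std)
    expect_equal(dim(R), c(3L, 3L))
    v <- metValues(std)
    for (j in 1:3) {
        expect_equal(unname(R[j, pairIndex(1, 2, 3)]), cor(v[, j, 1], v[, j, 2]))
        expect_equal(unname(R[j, pairIndex(2, 3, 3)]), cor(v[, j, 2], v[, j, 3]))
    }

    ## duplicated attribute gives correlation 1 everywhere
    v2 <- metValues(raw)
    v2[, , 3] <- 2 * v2[, , 1] + 1
    R2 <- correlationR(standardizeMET(METArray(v2)))
    expect_equal(unname(R2[, pairIndex(1, 3, 3)]), rep(1, 3), tolerance = 1e-10)

    ## a wholly missing column blanks every pair involving it in that row
    v3 <- metValues(raw)
    v3[, 2, 3] <- NA
    R3 <- correlationR(standardizeMET(METArray(v3)), warn = FALSE)
    expect_true(all(is.na(R3[2, c(pairIndex(1, 3, 3), pairIndex(2, 3, 3))])))
    expect_false(anyNA(R3[2, pairIndex(1, 2, 3)]))

    ## under 3 joint observations -> NA with a warning
    v4 <- metValues(raw)
    v4[1:3, 1, 1] <- NA
    v4[4:5, 1, 2] <- NA
    expect_warning(R4 <- correlationR(standardizeMET(METArray(v4))),
                   "fewer than 3")
    expect_true(is.na(R4[1, pairIndex(1, 2, 3)]))
})

test_that("the average-correlation rule obeys its limiting cases", {
    ## K = 2 with duplicated attributes: rbar = 1 and the imputed column
    ## equals the other attribute's column
    raw <- makeArray(8, 4, 1, seed = 12)
    v <- array(NA_real_, c(8, 4, 2))
    v[, , 1] <- metValues(raw)[, , 1]
    v[, , 2] <- metValues(raw)[, , 1] * 3 + 2
    std <- standardizeMET(METArray(v))
    vstd <- metValues(std)
    vstd[, 2, 2] <- NA
    stdm <- std; stdm@values <- vstd
    R <- correlationR(stdm, warn = FALSE)
    out <- imputeColumnAvg(stdm, c(2, 2), R, sigmaBar = 0)
    expect_equal(out, unname(vstd[, 2, 1]), tolerance = 1e-10)

    ## all rbar = 0: prediction is zero plus noise
    set.seed(3)
    vr <- array(rnorm(8 * 4 * 2), c(8, 4, 2))
    stdr <- standardizeMET(METArray(vr))
    Rz <- correlationR(stdr)
    Rz[, ] <- 0
    vz <- metValues(stdr); vz[, 1, 1] <- NA
    stdz <- stdr; stdz@values <- vz
    expect_equal(imputeColumnAvg(stdz, c(1, 1), Rz, sigmaBar = 0),
                 rep(0, 8))

    ## hand evaluation on a 3-environment, 3-attribute toy
    raw3 <- makeArray(6, 3, 3, seed = 15)
    std3 <- standardizeMET(raw3)
    v3 <- metValues(std3); v3[, 1, 2] <- NA
    std3m <- std3; std3m@values <- v3
    R3 <- correlationR(std3m, warn = FALSE)
    rbar12 <- mean(R3[2:3, pairIndex(1, 2, 3)])
    rbar23 <- mean(R3[2:3, pairIndex(2, 3, 3)])
    hand <- (rbar12 * v3[, 1, 1] + rbar23 * v3[, 1, 3]) / 2
    expect_equal(imputeColumnAvg(std3m, c(1, 2), R3, sigmaBar = 0),
                 unname(hand), tolerance = 1e-10)
    expect_error(imputeColumnAvg(standardizeMET(makeArray(5, 3, 1)),
                                 c(1, 1), NULL, 0), "single attribute")
})

test_that("the linear-correlation rule degenerates and recovers linear structure", {
    ## identical correlation rows: prediction reduces to the common row,
    ## hence to the average-correlation rule
    raw <- makeArray(10, 4, 3, seed = 18)
    std <- standardizeMET(raw)
    v <- metValues(std); v[, 2, 1] <- NA
    stdm <- std; stdm@values <- v
    R <- correlationR(stdm, warn = FALSE)
    common <- c(0.6, 0.3, 0.2)
    Rfake <- R
    for (j in 1:4) Rfake[j, ] <- common
    Rfake[2, c(pairIndex(1, 2, 3), pairIndex(1, 3, 3))] <- NA
    a <- imputeColumnAvg(stdm, c(2, 1), Rfake, 0)
    b <- imputeColumnLinreg(stdm, c(2, 1), Rfake, 0)
    expect_equal(a, b, tolerance = 1e-10)

    ## exact linear structure r_target = 0.5 * r_donor recovers slope 0.5
    base <- c(0.8, 0.4, -0.2)
    Rlin <- rbind(base, base, base, base)
    colnames(Rlin) <- colnames(R)
    Rlin[2, ] <- 0.5 * base
    Rlin[2, pairIndex(1, 3, 3)] <- NA    # slot to predict
    p <- METimpute:::.columnLinregPred(stdm, c(2, 1), Rlin)
    expect_equal(unname(p$r[2]), 0.5 * base[pairIndex(1, 3, 3)],
                 tolerance = 1e-10)

    ## too few complete rows advises the average rule
    Rbad <- R; Rbad[, 1] <- NA
    expect_error(imputeColumnLinreg(stdm, c(2, 1), Rbad, 0),
                 "average-correlation")
})

test_that("nrmImpute converges to its regression predictions and handles columns", {
    fix <- makeMasked(15, 5, 3, percent = 0.12, seedData = 21, seedPattern = 22)
    res <- nrmImpute(fix$masked, H = 400, option = 3, seed = 33)
    ## averaged over many imputations the estimates approach X_m beta_hat
    v <- metValues(fix$masked)
    R <- correlationR(fix$masked, warn = FALSE)
    cell <- fix$pattern@cells[1, ]
    X <- buildDesign(fix$masked, cell[2:3], option = 3, R = R)
    y <- v[, cell[2], cell[3]]
    obs <- !is.na(y)
    fit <- nrmMLE(y[obs], X[obs, , drop = FALSE])
    pred <- drop(X[cell[1], , drop = FALSE] %*% fit$beta)
    m <- which(res@cells[, 1] == cell[1] & res@cells[, 2] == cell[2] &
               res@cells[, 3] == cell[3])
    expect_equal(mean(res@estimates[, m]), pred,
                 tolerance = 5 * sqrt(fit$sigma2 / 400) + 1e-8)

    ## determinism and column handling
    res2 <- nrmImpute(fix$masked, H = 400, option = 3, seed = 33)
    expect_identical(res@estimates, res2@estimates)
    inCol <- res@cells[, 2] == fix$pattern@columns[1, 1] &
        res@cells[, 3] == fix$pattern@columns[1, 2]
    expect_equal(sum(inCol), 15L)
    expect_true(all(is.finite(res@estimates[, inCol])))
})
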